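test_that("median split follows the tie-to-low convention", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 5)), c("low", "low", "low", "high"))
  expect_equal(median_split(rep(3, 4)), rep("low", 4))
  expect_equal(median_split(c(1, 2, 2, 5), ties = "high"),
               c("low", "high", "high", "high"))
})

test_that("Kaplan-Meier estimator matches hand computation and is duplication-invariant", {
  km <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km$surv, c(1, 0.5, 0))        # censored at 1, events at 2 and 3
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  t <- c(1, 2, 2, 5); s <- c(1, 0, 1, 1)
  expect_equal(km_estimate(t, s)$surv, km_estimate(rep(t, 2), rep(s, 2))$surv)
})

test_that("log-rank matches the hand-computed 4-subject fixture and symmetries", {
  lr <- logrank_test(c(1, 3, 2, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, 8 / 13, tolerance = 1e-12)   # = 0.6154
  expect_equal(lr$p, pchisq(8 / 13, 1, lower.tail = FALSE))
  # identical groups: statistic 0
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chi2, 0)
  # invariance under label swap
  d <- random_surv_data(10, 4)
  g2 <- ifelse(d$group == "a", "b", "a")
  expect_equal(logrank_test(d$time, d$status, d$group)$chi2,
               logrank_test(d$time, d$status, g2)$chi2)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "b", "c")), "two groups")
})

test_that("KM and log-rank match textbook oracles on random small datasets", {
  for (seed in 1:100) {
    d <- random_surv_data(sample(4:12, 1), seed)
    for (g in unique(d$group)) {
      mine <- km_estimate(d$time[d$group == g], d$status[d$group == g])
      orc <- km_oracle(d$time[d$group == g], d$status[d$group == g])
      expect_equal(mine$surv, orc$surv, tolerance = 1e-10)
    }
    if (length(unique(d$group)) == 2 && sum(d$status) > 0) {
      chi2 <- logrank_test(d$time, d$status, d$group)$chi2
      expect_equal(chi2, logrank_oracle(d$time, d$status, d$group == "a"),
                   tolerance = 1e-10)
    }
  }
})

test_that("Cox NR agrees with a grid-search oracle and the reference implementation", {
  set.seed(21)
  n_checked <- 0
  while (n_checked < 20) {
    n <- sample(6:10, 1)
    time <- sample(1:5, n, replace = TRUE)
    status <- rbinom(n, 1, 0.8)
    x <- rbinom(n, 1, 0.5)
    if (sum(status) < 2 || length(unique(x)) < 2) next
    fit <- suppressWarnings(cox_univariate(time, status, x))
    if (fit$monotone || !fit$converged) next
    opt <- stats::optimize(function(b) efron_loglik_oracle(b, time, status, x),
                           c(-5, 5), maximum = TRUE, tol = 1e-8)
    expect_equal(fit$beta, opt$maximum, tolerance = 1e-4)
    ref <- survival::coxph(survival::Surv(time, status) ~ x, ties = "efron")
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
})

test_that("Cox symmetry, antisymmetry and monotone-likelihood flagging", {
  # identical time/status profiles in both groups: beta ~ 0
  time <- c(1, 2, 3, 1, 2, 3); status <- rep(1, 6); x <- rep(c(0, 1), each = 3)
  fit <- cox_univariate(time, status, x)
  expect_lt(abs(fit$beta), 1e-6)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  # swapping group labels negates beta
  d <- random_surv_data(30, 9)
  xg <- as.numeric(d$group == "a")
  f1 <- cox_univariate(d$time, d$status, xg)
  f2 <- cox_univariate(d$time, d$status, 1 - xg)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-6)
  # complete separation of event order: flagged, not an error
  expect_warning(
    fit <- cox_univariate(1:6, rep(1, 6), c(0, 0, 0, 1, 1, 1)),
    "monotone")
  expect_true(fit$monotone)
  expect_true(fit$hr_ci_low <= fit$hr & fit$hr <= fit$hr_ci_high)
})

test_that("survival screen partitions features and labels favored/unfavored", {
  set.seed(14)
  n <- 120
  samples <- data.frame(
    sample_id = paste0("s", 1:n), sex = rep(c("male", "female"), each = n / 2),
    tissue = "tumor", os_status = 1, stringsAsFactors = FALSE)
  expr <- rbind(risky = rnorm(n), protective = rnorm(n), null = rnorm(n))
  colnames(expr) <- samples$sample_id
  # high risky expression shortens male survival; protective lengthens both
  base <- rexp(n, 1 / 100)
  samples$os_time <- round(base * exp(
    -1.4 * (expr["risky", ] > median(expr["risky", ])) * (samples$sex == "male") +
      1.4 * (expr["protective", ] > 0)), 2)
  scr <- survival_screen(rownames(expr), expr, samples)
  expect_true("risky" %in% scr$summary$male_only)
  expect_true("protective" %in% scr$summary$both)
  expect_true("null" %in% scr$summary$neither)
  # partition is disjoint and exhaustive
  all_parts <- unlist(scr$summary)
  expect_equal(sort(unname(all_parts)), sort(rownames(expr)))
  risky_m <- scr$calls[scr$calls$feature == "risky" & scr$calls$stratum == "male", ]
  expect_equal(risky_m$label, "unfavored")
  expect_gt(risky_m$hr, 1)
  prot <- scr$calls[scr$calls$feature == "protective" & scr$calls$significant, ]
  expect_true(all(prot$label == "favored"))
})

test_that("degenerate strata are skipped with a warning", {
  samples <- data.frame(sample_id = paste0("s", 1:10),
                        sex = c(rep("male", 8), "female", "female"),
                        tissue = "tumor", os_time = 1:10, os_status = 1)
  expr <- rbind(f = rnorm(10)); colnames(expr) <- samples$sample_id
  expect_warning(scr <- survival_screen("f", expr, samples), "female")
  expect_true(all(scr$calls$stratum == "male"))
})
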