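#' Median dichotomization of expression
#'
#' Splits samples at the within-stratum median: strictly above the median
#' is `"high"`, at or below is `"low"` (the tie convention is configurable;
#' ties default to the low group).
#'
#' @param x numeric expression values for one feature within one stratum.
#' @param ties group receiving values equal to the median (`"low"` default).
#' @return character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(x, ties = c("low", "high")) {
  ties <- match.arg(ties)
  med <- stats::median(x)
  if (ties == "low") ifelse(x > med, "high", "low")
  else ifelse(x >= med, "high", "low")
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes, per group, the step function S(t) over the distinct event
#' times; censored subjects leave the risk set after their time.
#'
#' @param time follow-up times (>= 0).
#' @param status 1 = event (deceased), 0 = censored.
#' @param group optional group labels (single group if omitted).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (survival just after `time`), restricted to distinct
#'   times with at least one event or censoring.
#' @export
km_estimate <- function(time, status, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(time) == length(status), length(time) == length(group),
            all(time >= 0), all(status %in% c(0, 1)))
  out <- lapply(split(seq_along(time), group), function(ix) {
    tt <- time[ix]; ss <- status[ix]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ss == 1), numeric(1))
    n_censor <- vapply(ut, function(u) sum(tt == u & ss == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = group[ix[1]], time = ut, n_risk = n_risk,
               n_event = n_event, n_censor = n_censor, surv = surv,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with the hypergeometric expectation given the risk sets;
#' `chi2 = (sum(O - E))^2 / sum(V)` is referred to a chi-square with 1 df.
#'
#' @param time,status as in [km_estimate()].
#' @param group two-level group labels.
#' @return list with `chi2`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, status, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) != 2) stop("log-rank test requires exactly two groups")
  g1 <- group == lv[1]
  ev_times <- sort(unique(time[status == 1]))
  O <- E <- V <- 0
  for (u in ev_times) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(chi2 = chi2, p = p,
       observed = stats::setNames(c(O, sum(status == 1) - O), lv),
       expected = stats::setNames(c(E, sum(status == 1) - E), lv))
}

# Efron-tie partial log-likelihood, gradient and Hessian for one covariate
efron_derivs <- function(beta, time, status, x) {
  ll <- grad <- hess <- 0
  ev_times <- sort(unique(time[status == 1]))
  for (u in ev_times) {
    risk <- which(time >= u)
    dead <- which(time == u & status == 1)
    d <- length(dead)
    e <- exp(beta * x)
    s0r <- sum(e[risk]);  s1r <- sum(e[risk] * x[risk]);  s2r <- sum(e[risk] * x[risk]^2)
    s0d <- sum(e[dead]);  s1d <- sum(e[dead] * x[dead]);  s2d <- sum(e[dead] * x[dead]^2)
    ll <- ll + beta * sum(x[dead])
    for (j in seq_len(d) - 1) {
      f <- j / d
      s0 <- s0r - f * s0d; s1 <- s1r - f * s1d; s2 <- s2r - f * s2d
      ll <- ll - log(s0)
      grad <- grad - s1 / s0
      hess <- hess - (s2 / s0 - (s1 / s0)^2)
    }
    grad <- grad + sum(x[dead])
  }
  list(ll = ll, grad = grad, hess = hess)
}

#' Univariate Cox proportional-hazards model
#'
#' Maximizes the Efron-tie partial likelihood by Newton-Raphson with step
#' halving.  Monotone likelihoods (complete separation of the event order
#' by the covariate) are detected by coefficient divergence; the fit is
#' returned at the iteration cap with `monotone = TRUE` and a warning
#' rather than an error, so screening loops can continue.
#'
#' @param time,status as in [km_estimate()].
#' @param x numeric covariate (e.g. 1 = high, 0 = low expression group).
#' @param max_iter Newton iterations (default 40).
#' @param tol convergence tolerance on the coefficient.
#' @return list with `beta`, `se`, `hr`, `hr_ci_low`, `hr_ci_high`, `p`
#'   (Wald), `loglik`, `converged`, `monotone`.
#' @export
cox_univariate <- function(time, status, x, max_iter = 40, tol = 1e-9) {
  x <- as.numeric(x)
  stopifnot(length(time) == length(status), length(time) == length(x))
  if (sum(status) == 0 || stats::sd(x) == 0)
    return(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                hr_ci_low = NA_real_, hr_ci_high = NA_real_, p = NA_real_,
                loglik = NA_real_, converged = FALSE, monotone = FALSE))
  beta <- 0; conv <- FALSE; monotone <- FALSE
  d0 <- efron_derivs(beta, time, status, x)
  for (it in seq_len(max_iter)) {
    if (abs(d0$hess) < 1e-12) { monotone <- TRUE; break }
    step <- -d0$grad / d0$hess
    # step halving keeps the likelihood nondecreasing
    for (h in 0:20) {
      cand <- beta + step / 2^h
      dc <- efron_derivs(cand, time, status, x)
      if (is.finite(dc$ll) && dc$ll >= d0$ll - 1e-12) break
    }
    moved <- abs(cand - beta)
    beta <- cand; d0 <- dc
    if (moved < tol) { conv <- TRUE; break }
    if (abs(beta) > 15) { monotone <- TRUE; break }
  }
  if (monotone)
    warning("monotone partial likelihood (complete separation); ",
            "coefficient reported at the iteration cap")
  se <- if (d0$hess < 0) sqrt(-1 / d0$hess) else NA_real_
  z <- beta / se
  list(beta = beta, se = se, hr = exp(beta),
       hr_ci_low = exp(beta - 1.96 * se), hr_ci_high = exp(beta + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), loglik = d0$ll,
       converged = conv, monotone = monotone)
}

#' Sex-stratified survival screen over a feature panel
#'
#' For each feature and each sex stratum: dichotomize expression at the
#' within-stratum median, run the log-rank test and a univariate Cox model
#' on the high-vs-low indicator, and label the feature `unfavored`
#' (significant, HR > 1: high expression does worse) or `favored`
#' (significant, HR < 1).  Significance for the cross-sex partition uses
#' the log-rank p-value by default (`use = "cox"` switches to the Cox Wald
#' p).
#'
#' @param features character vector of features to screen.
#' @param expression matrix (features x samples) of normalized or
#'   variance-stabilized expression.
#' @param samples sample sheet with `os_time` and `os_status`; only tumor
#'   samples with nonmissing survival are used.
#' @param alpha significance threshold (default 0.05).
#' @param use p-value defining significance: `"logrank"` (default) or
#'   `"cox"`.
#' @param min_stratum minimum samples per sex stratum (default 4; smaller
#'   strata are skipped with a warning).
#' @return list with `calls` (one row per feature x stratum) and `summary`
#'   (`male_only`, `female_only`, `both`, `neither` feature sets).
#' @export
survival_screen <- function(features, expression, samples, alpha = 0.05,
                            use = c("logrank", "cox"), min_stratum = 4) {
  use <- match.arg(use)
  samples <- validate_samples(samples)
  samples <- samples[samples$tissue == "tumor" & !is.na(samples$os_time) &
                       !is.na(samples$os_status), , drop = FALSE]
  samples <- samples[samples$sample_id %in% colnames(expression), , drop = FALSE]
  rows <- list()
  for (sx in c("male", "female")) {
    sub <- samples[samples$sex == sx, , drop = FALSE]
    if (nrow(sub) < min_stratum) {
      warning("fewer than ", min_stratum, " ", sx, " samples; stratum skipped")
      next
    }
    for (f in features) {
      if (!f %in% rownames(expression)) next
      ex <- expression[f, sub$sample_id]
      grp <- median_split(ex)
      if (length(unique(grp)) < 2) next   # degenerate: all values at the median
      lr <- logrank_test(sub$os_time, sub$os_status, grp)
      cx <- suppressWarnings(
        cox_univariate(sub$os_time, sub$os_status, as.numeric(grp == "high")))
      pv <- if (use == "logrank") lr$p else cx$p
      label <- if (is.na(pv) || pv >= alpha) "ns"
               else if (!is.na(cx$hr) && cx$hr > 1) "unfavored" else "favored"
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, stratum = sx, n_high = sum(grp == "high"),
        n_low = sum(grp == "low"), logrank_chi2 = lr$chi2, logrank_p = lr$p,
        beta = cx$beta, hr = cx$hr, hr_ci_low = cx$hr_ci_low,
        hr_ci_high = cx$hr_ci_high, cox_p = cx$p, monotone = cx$monotone,
        significant = !is.na(pv) && pv < alpha, label = label,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), stratum = character())
  sig_m <- unique(calls$feature[calls$stratum == "male" & calls$significant])
  sig_f <- unique(calls$feature[calls$stratum == "female" & calls$significant])
  list(calls = calls,
       summary = list(male_only = setdiff(sig_m, sig_f),
                      female_only = setdiff(sig_f, sig_m),
                      both = intersect(sig_m, sig_f),
                      neither = setdiff(features, union(sig_m, sig_f))))
}
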