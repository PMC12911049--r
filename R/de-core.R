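#' Filter lowly expressed features
#'
#' Retains features with at least `min_count` reads in at least
#' `min_fraction` of samples, preserving feature order.  An empty result is
#' permitted (with a warning): it signals thresholds too strict for the
#' data, not a programming error.
#'
#' @param counts a [count_matrix()].
#' @param min_count minimum raw count (default 10).
#' @param min_fraction minimum fraction of samples reaching `min_count`
#'   (default 0.2).
#' @return filtered [count_matrix()].
#' @export
filter_low_expression <- function(counts, min_count = 10, min_fraction = 0.2) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  m <- as_count_input(counts)
  keep <- rowMeans(m >= min_count) >= min_fraction
  if (!any(keep)) warning("no features pass the low-expression filter")
  if (inherits(counts, "count_matrix")) counts[keep, ] else m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over
#' everywhere-expressed features of the ratio of its count to the feature's
#' geometric mean across samples.
#'
#' @param counts a [count_matrix()] or matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- as_count_input(counts)
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no feature is expressed in every sample; apply a stricter ",
         "low-expression filter before normalization")
  lg <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  stats::setNames(sf, colnames(m))
}

# design matrix for the sex contrast plus optional clinical covariates;
# ordinal stage/grade are coded as integers, errors name collinear columns
build_design <- function(samples, covariates, reference_sex = "female") {
  sex_num <- ifelse(samples$sex == reference_sex, 0, 1)
  X <- cbind(`(Intercept)` = 1, sex = sex_num)
  for (cv in covariates) {
    if (!cv %in% names(samples)) stop("covariate '", cv, "' not in sample sheet")
    v <- samples[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.integer(factor(v, levels = sort(unique(v))))
    v <- as.numeric(v)
    if (anyNA(v)) stop("covariate '", cv, "' has missing values")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is not full rank; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  X
}

# one negative-binomial IRLS fit with log link, fixed dispersion phi and
# offset; returns coefficients, covariance and convergence flag
nb_irls <- function(y, X, offset, phi, max_iter = 50, tol = 1e-10) {
  beta <- c(log(mean(y) + 0.5) - mean(offset), rep(0, ncol(X) - 1))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(converged = FALSE))
    newbeta <- drop(fit)
    if (max(abs(newbeta - beta)) < tol) { beta <- newbeta; conv <- TRUE; break }
    beta <- newbeta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  cov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
  if (is.null(cov)) return(list(converged = FALSE))
  list(beta = beta, cov = cov, mu = mu, converged = conv)
}

# method-of-moments dispersion from Pearson residuals of a mean fit,
# df-corrected, floored; optionally shrunk toward a 1/mean trend fitted
# across features (log-scale midpoint between feature and trend)
estimate_dispersions <- function(raw_phi, base_mean, shrink = TRUE,
                                 floor = 1e-8) {
  phi <- pmax(raw_phi, floor)
  if (!shrink || length(phi) < 10) return(phi)
  use <- phi > floor & base_mean > 0
  if (sum(use) < 10) return(phi)
  tf <- tryCatch(
    stats::lm(phi[use] ~ I(1 / base_mean[use])),
    error = function(e) NULL)
  if (is.null(tf)) return(phi)
  trend <- pmax(stats::coef(tf)[1] + stats::coef(tf)[2] / base_mean, floor)
  exp((log(phi) + log(trend)) / 2)
}

#' Negative-binomial Wald test for sex-differential expression
#'
#' Fits, per feature, a negative-binomial log-linear model
#' `log mu = log(size factor) + X beta` with a male-vs-female contrast and
#' optional clinical covariates, and tests the sex coefficient with a Wald
#' statistic.  Dispersion is estimated per feature by method of moments
#' (Pearson-residual matching against a mean fit, floored at 1e-8) and by
#' default shrunk toward a mean-dispersion trend fitted across features.
#' Positive `log2fc` means higher expression in males.
#'
#' Features whose fit fails to converge get `NA` p-values and are excluded
#' from the Benjamini-Hochberg family.
#'
#' @param counts a [count_matrix()] (filtered).
#' @param samples sample sheet (see [validate_samples()]); only rows matching
#'   the columns of `counts` are used.
#' @param covariates character vector of sample-sheet columns to adjust for
#'   (e.g. `c("age","stage","grade")`); default none.
#' @param reference_sex baseline level of the contrast; with the default
#'   `"female"`, positive log2 fold changes are male-biased.
#' @param dispersion `"moments"` (estimate per feature) or `"fixed"`.
#' @param fixed_disp dispersion value when `dispersion = "fixed"`.
#' @param shrink shrink dispersions toward the fitted trend (default TRUE).
#' @param pvalue reference distribution for the Wald statistic: `"t"`
#'   (Student t with n - p degrees of freedom, the default: with a plain
#'   plug-in dispersion the normal reference is anticonservative at
#'   moderate n) or `"normal"`.
#' @param alpha,lfc significance thresholds passed to [call_significance()].
#' @return data.frame with columns `feature`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p`, `padj`, `significant`, `direction`, `dispersion`.
#' @export
nb_wald <- function(counts, samples, covariates = NULL,
                    reference_sex = "female",
                    dispersion = c("moments", "fixed"), fixed_disp = NULL,
                    shrink = TRUE, pvalue = c("t", "normal"),
                    alpha = 0.05, lfc = 0.58) {
  dispersion <- match.arg(dispersion)
  pvalue <- match.arg(pvalue)
  samples <- validate_samples(samples)
  m <- as_count_input(counts)
  m <- m[, colnames(m) %in% samples$sample_id, drop = FALSE]
  if (!ncol(m)) stop("no count-matrix sample appears in the sample sheet")
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  X <- build_design(samples, covariates, reference_sex)
  n <- ncol(m); p <- ncol(X)
  if (n <= p) stop("more model parameters than samples")
  sf <- size_factors(m)
  offset <- log(sf)
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)

  nf <- nrow(m)
  raw_phi <- numeric(nf)
  fits <- vector("list", nf)
  for (i in seq_len(nf)) {
    y <- m[i, ]
    if (all(y == 0)) { fits[[i]] <- list(converged = FALSE); next }
    # Poisson pre-fit (phi = 0) gives the mean structure for the MoM estimator
    f0 <- nb_irls(y, X, offset, phi = 0)
    if (!isTRUE(f0$converged)) { fits[[i]] <- list(converged = FALSE); next }
    mu <- f0$mu
    raw_phi[i] <- sum((y - mu)^2 - mu) / sum(mu^2) * n / (n - p)
    fits[[i]] <- f0
  }
  phi <- if (dispersion == "fixed") {
    if (is.null(fixed_disp) || fixed_disp < 0) stop("fixed_disp must be >= 0")
    rep(max(fixed_disp, 1e-12), nf)
  } else estimate_dispersions(raw_phi, base_mean, shrink = shrink)

  log2fc <- se <- wald <- pval <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    if (!isTRUE(fits[[i]]$converged)) next
    f <- nb_irls(m[i, ], X, offset, phi = phi[i])
    if (!isTRUE(f$converged)) next
    b <- f$beta[2]
    s <- sqrt(f$cov[2, 2])
    log2fc[i] <- b / log(2)
    se[i] <- s / log(2)
    wald[i] <- b / s
    pval[i] <- if (pvalue == "t") 2 * stats::pt(-abs(b / s), df = n - p)
               else 2 * stats::pnorm(-abs(b / s))
  }
  res <- data.frame(feature = rownames(m), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald_stat = wald, p = pval,
                    padj = bh_adjust(pval), dispersion = phi,
                    stringsAsFactors = FALSE, row.names = NULL)
  call_significance(res, alpha = alpha, lfc = lfc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj(i) = min over j with p(j) >= p(i) of m * p(j) / rank(j)`, capped at
#' 1; `NA` entries are excluded from the family and returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[order(o)]
  out[ok] <- adj
  out
}

#' Apply the significance rule to a DE table
#'
#' Significant iff `padj < alpha` and `|log2fc| > lfc` (strict
#' inequalities).  Direction is `male_biased` for positive significant fold
#' changes, `female_biased` for negative, `none` otherwise.
#'
#' @param res DE data.frame with `padj` and `log2fc` columns.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 0.58).
#' @return `res` with `significant` and `direction` columns (re)computed.
#' @export
call_significance <- function(res, alpha = 0.05, lfc = 0.58) {
  sig <- !is.na(res$padj) & res$padj < alpha & abs(res$log2fc) > lfc
  res$significant <- sig
  res$direction <- ifelse(!sig, "none",
                          ifelse(res$log2fc > 0, "male_biased", "female_biased"))
  res
}

#' PCA on log-normalized counts for QC
#'
#' Singular value decomposition of the feature-centered
#' `log2(count / size factor + 1)` matrix; returns per-sample scores on the
#' leading components and the fraction of variance each explains.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param n_components number of components to return (default 2, at least 2).
#' @return list with `scores` (samples x components) and `var_explained`.
#' @export
pca_qc <- function(counts, n_components = 2) {
  m <- as_count_input(counts)
  if (ncol(m) < 3) stop("PCA QC requires at least 3 samples")
  n_components <- max(2, n_components)
  sf <- size_factors(m)
  lg <- log2(sweep(m, 2, sf, "/") + 1)
  cent <- lg - rowMeans(lg)
  sv <- svd(t(cent))
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, var_explained = sv$d^2 / sum(sv$d^2))
}
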