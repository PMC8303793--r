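.h_data <- function(h) {
  if (inherits(h, "harmonized_set")) h$data
  else if (is.data.frame(h)) h
  else stop("expected a harmonized_set or data frame", call. = FALSE)
}

.mr_estimate <- function(method, theta, se, pval, n_snp, Q = NA_real_,
                         sigma2 = NA_real_, intercept = NA_real_,
                         intercept_se = NA_real_, intercept_pval = NA_real_) {
  structure(list(method = method, theta = theta, se = se, pval = pval,
                 ci_low = theta - stats::qnorm(0.975) * se,
                 ci_high = theta + stats::qnorm(0.975) * se,
                 n_snp = n_snp, Q = Q, sigma2 = sigma2,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = intercept_pval),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta = %.4g (SE %.4g, p = %.3g), J = %d\n",
              x$method, x$theta, x$se, x$pval, x$n_snp))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Per-SNP Wald ratio
#'
#' The ratio estimate theta_j = beta_y / beta_x of the causal effect
#' contributed by one SNP, with first-order delta-method standard error
#' se_y / |beta_x|. Optionally the second-order expansion adds the
#' exposure-side uncertainty.
#'
#' @param beta_x,beta_y SNP effects on exposure and outcome (vectorised).
#' @param se_y Standard error of `beta_y`.
#' @param se_x Standard error of `beta_x`; only used when
#'   `second_order = TRUE`.
#' @param second_order If `TRUE`, se_j = sqrt(se_y^2/beta_x^2 +
#'   beta_y^2 se_x^2 / beta_x^4).
#' @return A data frame with `theta_j`, `se_j` and the inverse-variance
#'   weight `w_j = 1/se_j^2`.
#' @export
wald_ratio <- function(beta_x, beta_y, se_y, se_x = NULL, second_order = FALSE) {
  if (any(beta_x == 0)) stop("undefined Wald ratio: beta_x == 0", call. = FALSE)
  stopifnot(all(se_y > 0))
  theta_j <- beta_y / beta_x
  se_j <- if (second_order) {
    if (is.null(se_x)) stop("second_order = TRUE needs se_x", call. = FALSE)
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else se_y / abs(beta_x)
  data.frame(theta_j = theta_j, se_j = se_j, w_j = 1 / se_j^2)
}

#' Wald ratios for a harmonized set
#' @param h A `harmonized_set` or its data frame.
#' @inheritParams wald_ratio
#' @return As [wald_ratio()].
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  d <- .h_data(h)
  wald_ratio(d$beta_exposure, d$beta_outcome, d$se_outcome,
             se_x = d$se_exposure, second_order = second_order)
}

#' Inverse-variance-weighted causal estimate
#'
#' Zero-intercept weighted regression of the outcome effects on the exposure
#' effects with weights 1/se_y^2:
#' theta = sum(w bx by) / sum(w bx^2), fixed-effect SE = sqrt(1/sum(w bx^2)).
#' The random-effects variant applies multiplicative overdispersion
#' sigma2 = max(1, Q/(J-1)) to the SE, leaving the point estimate unchanged;
#' p-values are two-sided normal.
#'
#' @param h A `harmonized_set` or its data frame (needs beta/se columns).
#' @param effects `"random"` (default, the primary analysis) or `"fixed"`.
#' @return An `mr_estimate` with fields theta, se, pval, Q, sigma2, n_snp.
#' @export
mr_ivw <- function(h, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  d <- .h_data(h)
  J <- nrow(d)
  if (J < 2) stop("IVW requires at least 2 SNPs", call. = FALSE)
  bx <- d$beta_exposure; by <- d$beta_outcome
  w <- 1 / d$se_outcome^2
  denom <- sum(w * bx^2)
  theta <- sum(w * bx * by) / denom
  se_fe <- sqrt(1 / denom)
  Q <- sum(w * (by - theta * bx)^2)
  sigma2 <- max(1, Q / (J - 1))
  se <- if (effects == "random") se_fe * sqrt(sigma2) else se_fe
  .mr_estimate(paste0("ivw_", substr(effects, 1, 1), "e"),
               theta, se, 2 * stats::pnorm(-abs(theta / se)), J,
               Q = Q, sigma2 = sigma2)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, after reorienting every SNP so beta_x > 0 (negating both
#' betas where needed). The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates average directional pleiotropy and its test is the
#' horizontal-pleiotropy test. Standard errors carry multiplicative
#' overdispersion sqrt(max(1, Q_E/(J-2))); p-values use t with J-2 df.
#'
#' @param h A `harmonized_set` or its data frame.
#' @return An `mr_estimate` with slope fields plus intercept,
#'   intercept_se, intercept_pval.
#' @export
mr_egger <- function(h) {
  d <- .h_data(h)
  J <- nrow(d)
  if (J < 3) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- d$beta_exposure < 0
  bx <- ifelse(flip, -d$beta_exposure, d$beta_exposure)
  by <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  w <- 1 / d$se_outcome^2
  if (stats::var(bx) == 0)
    stop("degenerate design: zero variance in oriented beta_exposure", call. = FALSE)
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); sx <- sum(w * bx); sxx <- sum(w * bx^2)
  sy <- sum(w * by); sxy <- sum(w * bx * by)
  det <- sw * sxx - sx^2
  b0 <- (sxx * sy - sx * sxy) / det
  b1 <- (sw * sxy - sx * sy) / det
  resid <- by - b0 - b1 * bx
  Q_E <- sum(w * resid^2)
  sigma2 <- max(1, Q_E / (J - 2))
  se0 <- sqrt(sxx / det * sigma2)
  se1 <- sqrt(sw / det * sigma2)
  est <- .mr_estimate("egger", b1, se1,
                      2 * stats::pt(-abs(b1 / se1), df = J - 2), J,
                      Q = Q_E, sigma2 = sigma2,
                      intercept = b0, intercept_se = se0,
                      intercept_pval = 2 * stats::pt(-abs(b0 / se0), df = J - 2))
  est
}

# weighted median with linear interpolation of the cumulative weight at 0.5
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

# canonical orientation (beta_exposure > 0): leaves every ratio and weight
# unchanged but makes the bootstrap, and hence the reported SE, invariant to
# the arbitrary allele orientation of the input
.orient <- function(d) {
  flip <- d$beta_exposure < 0
  d$beta_exposure[flip] <- -d$beta_exposure[flip]
  d$beta_outcome[flip] <- -d$beta_outcome[flip]
  d
}

.boot_se <- function(d, n_boot, seed, stat_fun) {
  set.seed(as.integer(seed))
  J <- nrow(d)
  reps <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(J, d$beta_exposure, d$se_exposure)
    by <- stats::rnorm(J, d$beta_outcome, d$se_outcome)
    stat_fun(bx, by)
  }, numeric(1))
  stats::sd(reps)
}

#' Median-based causal estimate
#'
#' The simple variant takes the sample median of the per-SNP Wald ratios;
#' the weighted variant takes the weighted median under normalized
#' inverse-variance weights (of the ratios), which is consistent when at
#' least 50% of the instrument weight is valid. The SE comes from a seeded
#' parametric bootstrap resampling beta_x and beta_y from their sampling
#' distributions.
#'
#' @param h A `harmonized_set` or its data frame.
#' @param weighted Use inverse-variance weights (default) or equal weights.
#' @param n_boot Bootstrap replicates for the SE (>= 1).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_median <- function(h, weighted = TRUE, n_boot = 1000, seed = 1L) {
  d <- .h_data(h)
  J <- nrow(d)
  if (J < 3) stop("median estimator requires at least 3 SNPs", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  d <- .orient(d)
  est_fun <- function(bx, by) {
    r <- by / bx
    w <- if (weighted) bx^2 / d$se_outcome^2 else rep(1, length(r))
    .weighted_median(r, w)
  }
  theta <- est_fun(d$beta_exposure, d$beta_outcome)
  se <- .boot_se(d, n_boot, seed, est_fun)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  .mr_estimate(if (weighted) "median_weighted" else "median_simple",
               theta, se, 2 * stats::pnorm(-abs(theta / se)), J)
}

#' Mode-based causal estimate
#'
#' Smooths the empirical distribution of the Wald ratios with a Gaussian
#' kernel and takes the mode (argmax over a 512-point grid spanning the
#' ratios plus 3 bandwidths). Under the zero-modal-pleiotropy assumption the
#' largest cluster of ratios identifies the causal effect even when most
#' instruments are invalid. Bandwidth is `phi` times the modified Silverman
#' scale 0.9 min(sd, mad) J^(-1/5); the weighted variant weights each
#' kernel by the SNP's normalized inverse-variance weight. Ties in the
#' argmax are broken toward the median ratio. SE by seeded parametric
#' bootstrap.
#'
#' @param h A `harmonized_set` or its data frame.
#' @param weighted Weight the density by inverse-variance weights.
#' @param phi Bandwidth multiplier (> 0), default 1.
#' @param n_boot Bootstrap replicates for the SE (>= 1).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1L) {
  d <- .h_data(h)
  J <- nrow(d)
  if (J < 3) stop("mode estimator requires at least 3 SNPs", call. = FALSE)
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  d <- .orient(d)
  mode_of <- function(bx, by) {
    r <- by / bx
    if (length(unique(r)) == 1) return(r[1])
    w <- if (weighted) bx^2 / d$se_outcome^2 else rep(1, length(r))
    w <- w / sum(w)
    s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
    if (s == 0) s <- 0.9 * stats::sd(r) * length(r)^(-1 / 5)  # mad degenerate
    bw <- phi * s
    grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 512)
    dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / bw))
    peaks <- which(dens == max(dens))
    grid[peaks[which.min(abs(grid[peaks] - stats::median(r)))]]
  }
  theta <- mode_of(d$beta_exposure, d$beta_outcome)
  se <- .boot_se(d, n_boot, seed, mode_of)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  .mr_estimate(if (weighted) "mode_weighted" else "mode_simple",
               theta, se, 2 * stats::pnorm(-abs(theta / se)), J)
}

#' Run a set of MR estimators on one harmonized pair
#'
#' @param h A `harmonized_set`.
#' @param methods Subset of `c("ivw_re", "ivw_fe", "egger", "median_simple",
#'   "median_weighted", "mode_simple", "mode_weighted")`.
#' @param n_boot,seed Bootstrap controls for median/mode SEs.
#' @return Named list of `mr_estimate` objects.
#' @export
mr_all <- function(h, methods = c("ivw_re", "egger", "median_weighted",
                                  "mode_weighted"),
                   n_boot = 1000, seed = 1L) {
  known <- c("ivw_re", "ivw_fe", "egger", "median_simple", "median_weighted",
             "mode_simple", "mode_weighted")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- lapply(methods, function(m) switch(m,
    ivw_re = mr_ivw(h, "random"),
    ivw_fe = mr_ivw(h, "fixed"),
    egger = mr_egger(h),
    median_simple = mr_median(h, weighted = FALSE, n_boot = n_boot, seed = seed),
    median_weighted = mr_median(h, weighted = TRUE, n_boot = n_boot, seed = seed),
    mode_simple = mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed),
    mode_weighted = mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed)
  ))
  stats::setNames(out, methods)
}
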