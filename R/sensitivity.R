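#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over SNPs of w'_j (theta_j - theta_ref)^2, with w'_j the
#' ratio-scale inverse variances beta_x^2 / se_y^2. Excess heterogeneity of
#' the per-SNP ratios around the pooled estimate is a signature of (possibly
#' balanced) horizontal pleiotropy. The p-value is the upper tail of
#' chi-square with J-1 df in the IVW context or J-2 in the Egger context
#' (one extra parameter estimated).
#'
#' @param theta_j Per-SNP Wald ratios.
#' @param w Ratio-scale inverse-variance weights (beta_x^2 / se_y^2).
#' @param theta_ref Pooled reference estimate the deviations are taken from.
#' @param context `"ivw"` (df = J-1) or `"egger"` (df = J-2).
#' @return List of class `heterogeneity_result`: Q, df, pval, context.
#' @export
cochran_q <- function(theta_j, w, theta_ref, context = c("ivw", "egger")) {
  context <- match.arg(context)
  stopifnot(length(theta_j) == length(w), all(w > 0))
  J <- length(theta_j)
  df <- J - if (context == "ivw") 1L else 2L
  if (df <= 0) stop("nonpositive degrees of freedom for Cochran's Q", call. = FALSE)
  Q <- sum(w * (theta_j - theta_ref)^2)
  structure(list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE),
                 context = context),
            class = "heterogeneity_result")
}

#' Heterogeneity diagnostics for a harmonized pair
#'
#' Computes Cochran's Q around the IVW estimate and the Egger-residual Q
#' (Rucker's Q'), each with its own df.
#'
#' @param h A `harmonized_set` or its data frame.
#' @return Named list with `ivw` and (when J >= 3) `egger`
#'   `heterogeneity_result`s.
#' @export
mr_heterogeneity <- function(h) {
  d <- .h_data(h)
  w <- d$beta_exposure^2 / d$se_outcome^2
  r <- d$beta_outcome / d$beta_exposure
  ivw <- mr_ivw(d, "fixed")
  out <- list(ivw = cochran_q(r, w, ivw$theta, "ivw"))
  if (nrow(d) >= 3) {
    eg <- mr_egger(d)
    J <- nrow(d)
    out$egger <- structure(list(Q = eg$Q, df = J - 2L,
                                pval = stats::pchisq(eg$Q, J - 2, lower.tail = FALSE),
                                context = "egger"),
                           class = "heterogeneity_result")
  }
  out
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Re-estimates the (random-effects) IVW causal effect J times, dropping one
#' SNP each time, to expose dominant instruments. A left-out SNP is flagged
#' when its removal moves the estimate by more than `se_multiple` times the
#' reduced-set (J-1) standard error. The reduced-set SE is used rather than
#' the full-set one because an influential outlier inflates the full-set
#' random-effects SE through Q, which would mask exactly the SNP the
#' diagnostic exists to find.
#'
#' @param h A `harmonized_set` or its data frame.
#' @param se_multiple Flagging threshold in reduced-set SE units (default 1).
#' @return Data frame with one row per left-out rsid (theta, se, pval,
#'   J_used, shift, flagged) and the full-set estimate in attributes
#'   `full` (an `mr_estimate`).
#' @export
leave_one_out <- function(h, se_multiple = 1) {
  d <- .h_data(h)
  J <- nrow(d)
  if (J < 3) stop("leave-one-out requires at least 3 SNPs", call. = FALSE)
  full <- mr_ivw(d, "random")
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(d[-j, , drop = FALSE], "random")
    data.frame(rsid = d$rsid[j], theta = e$theta, se = e$se, pval = e$pval,
               J_used = J - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$shift <- abs(out$theta - full$theta)
  out$flagged <- out$shift > se_multiple * out$se
  attr(out, "full") <- full
  out
}

#' Steiger directionality test
#'
#' Tests whether the instruments explain more variance in the exposure than
#' in the outcome. Per SNP the variance explained is r2_j = Z^2/(Z^2 + n - 2)
#' with Z = beta/se for the respective study (an eaf-based variant
#' 2 maf (1-maf) beta^2 is available); study-level r = sqrt(sum r2_j), capped
#' below 1. The Z statistic compares the two Fisher-transformed correlations
#' from the disjoint cohorts; when significant, its sign assigns the causal
#' direction.
#'
#' @param h A `harmonized_set` or its data frame.
#' @param n_x,n_y Study sample sizes (default: median of the per-SNP n).
#' @param alpha Significance level for direction assignment.
#' @param use_eaf Use the allele-frequency-based variance-explained formula
#'   instead of the Z-based one (requires eaf).
#' @return List of class `steiger_result`: r2_exposure, r2_outcome, z, pval,
#'   direction in `c("exposure_to_outcome", "outcome_to_exposure",
#'   "indeterminate")`.
#' @export
steiger_direction <- function(h, n_x = NULL, n_y = NULL, alpha = 0.05,
                              use_eaf = FALSE) {
  d <- .h_data(h)
  if (is.null(n_x)) n_x <- stats::median(d$n_exposure)
  if (is.null(n_y)) n_y <- stats::median(d$n_outcome)
  if (is.na(n_x) || is.na(n_y) || n_x < 3 || n_y < 3)
    stop("sample sizes must be >= 3", call. = FALSE)
  r2_of <- function(beta, se, n) {
    if (use_eaf) {
      v <- 2 * d$eaf * (1 - d$eaf) * beta^2
      v / (v + 2 * d$eaf * (1 - d$eaf) * se^2 * n)
    } else {
      z <- beta / se
      z^2 / (z^2 + n - 2)
    }
  }
  cap <- function(r2) {
    if (r2 > 1) {
      warning("summed variance explained exceeds 1; capped", call. = FALSE)
      r2 <- 1
    }
    r2
  }
  r2x <- cap(sum(r2_of(d$beta_exposure, d$se_exposure, n_x)))
  r2y <- cap(sum(r2_of(d$beta_outcome, d$se_outcome, n_y)))
  rx <- min(sqrt(r2x), 1 - 1e-12)
  ry <- min(sqrt(r2y), 1 - 1e-12)
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  pval <- 2 * stats::pnorm(-abs(z))
  direction <- if (pval < alpha) {
    if (z > 0) "exposure_to_outcome" else "outcome_to_exposure"
  } else "indeterminate"
  structure(list(r2_exposure = r2x, r2_outcome = r2y, z = z, pval = pval,
                 direction = direction),
            class = "steiger_result")
}
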