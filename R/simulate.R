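#' Configuration for the two-sample summary-statistics simulator
#'
#' Collects and validates every knob of the generative model. Per SNP j the
#' simulator draws an instrument strength gamma_j (the SNP -> exposure effect),
#' an optional pleiotropic effect alpha_j (a direct SNP -> outcome path), and
#' sets the true SNP -> outcome effect to theta * gamma_j + alpha_j. Observed
#' effects are the truth plus Gaussian sampling noise whose standard error
#' follows the additive-genetics approximation 1 / sqrt(2 * maf * (1 - maf) * n).
#'
#' @param n_snps Number of instrument SNPs J (>= 1).
#' @param theta True causal effect of the exposure on the outcome (unitless,
#'   exposure SD -> outcome units).
#' @param gamma_dist Instrument-strength distribution: either
#'   `list(dist = "uniform", lower =, upper =)` or
#'   `list(dist = "normal", mean =, sd =)`.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (alpha_j centred at 0)
#'   or `"directional"` (alpha_j centred at `alpha_mean`).
#' @param alpha_mean,alpha_sd Mean and SD of the pleiotropic effects.
#' @param frac_pleiotropic Fraction of SNPs receiving a pleiotropic effect
#'   (the rest have alpha_j = 0); models partly-invalid instrument sets.
#' @param inside_violation Correlation knob in [0, 1): adds
#'   `inside_violation * (gamma_j - mean(gamma))` to alpha_j, breaking the
#'   InSIDE assumption (instrument strength independent of direct effect).
#'   Default 0, i.e. InSIDE holds.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 2).
#' @param maf_range Minor-allele-frequency interval, within (0, 0.5).
#' @param frac_palindromic Fraction of SNPs given A/T or G/C allele pairs.
#' @param frac_flipped Fraction of (non-palindromic) outcome records emitted
#'   with swapped effect/other alleles and negated beta, which a correct
#'   harmonizer must restore.
#' @param flip_exposure_coding If `TRUE`, the exposure study is emitted under
#'   the opposite trait coding (all exposure betas negated), emulating e.g. a
#'   morningness- rather than eveningness-coded chronotype GWAS; the effective
#'   causal effect on the emitted scale is `-theta`.
#' @param seed Integer RNG seed; fixes every emitted byte.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps,
                       theta,
                       gamma_dist = list(dist = "uniform", lower = 0.05, upper = 0.15),
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       alpha_mean = 0,
                       alpha_sd = 0,
                       frac_pleiotropic = 1,
                       inside_violation = 0,
                       n_exposure = 50000,
                       n_outcome = 50000,
                       maf_range = c(0.1, 0.5),
                       frac_palindromic = 0,
                       frac_flipped = 0,
                       flip_exposure_coding = FALSE,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  bad <- character(0)
  if (!is.numeric(n_snps) || length(n_snps) != 1 || n_snps < 1) bad <- c(bad, "n_snps")
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) bad <- c(bad, "theta")
  if (!is.list(gamma_dist) || is.null(gamma_dist$dist) ||
      !gamma_dist$dist %in% c("uniform", "normal")) bad <- c(bad, "gamma_dist")
  for (f in c("frac_pleiotropic", "frac_palindromic", "frac_flipped")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) bad <- c(bad, f)
  }
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    bad <- c(bad, "maf_range")
  if (!is.numeric(n_exposure) || n_exposure < 2) bad <- c(bad, "n_exposure")
  if (!is.numeric(n_outcome) || n_outcome < 2) bad <- c(bad, "n_outcome")
  if (!is.numeric(alpha_sd) || alpha_sd < 0) bad <- c(bad, "alpha_sd")
  if (length(bad))
    stop("invalid sim_config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    n_snps = as.integer(n_snps), theta = theta, gamma_dist = gamma_dist,
    pleiotropy_mode = pleiotropy_mode, alpha_mean = alpha_mean,
    alpha_sd = alpha_sd, frac_pleiotropic = frac_pleiotropic,
    inside_violation = inside_violation,
    n_exposure = n_exposure, n_outcome = n_outcome, maf_range = maf_range,
    frac_palindromic = frac_palindromic, frac_flipped = frac_flipped,
    flip_exposure_coding = flip_exposure_coding, seed = as.integer(seed)
  ), class = "sim_config")
}

# ordered non-palindromic allele pairs; palindromic ones handled separately
.nonpal_pairs <- matrix(c(
  "A", "G", "A", "C", "G", "A", "C", "A",
  "T", "G", "T", "C", "G", "T", "C", "T"
), ncol = 2, byrow = TRUE)
.pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)

.draw_gamma <- function(gd, J) {
  if (gd$dist == "uniform") stats::runif(J, gd$lower, gd$upper)
  else stats::rnorm(J, gd$mean, gd$sd)
}

#' Simulate a pair of two-sample GWAS summary-statistics studies
#'
#' Generates exposure and outcome summary statistics sharing J SNPs, with
#' known causal effect, instrument strengths and pleiotropy, plus allele-level
#' corruptions (palindromic pairs, strand flips in the outcome) for exercising
#' harmonization. Returns the ground truth alongside the data.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure` and `outcome` summary-statistics data frames
#'   (columns rsid, chrom, pos, effect_allele, other_allele, beta, se, pval,
#'   eaf, n, trait_id) and `truth`: a list holding `theta` (on the emitted
#'   exposure coding), per-SNP `snps` data frame (gamma, alpha, true and
#'   pre-corruption observed outcome betas, palindromic/flipped flags), and
#'   the rsid sets `palindromic_rsids` and `flipped_rsids`.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_snps
  rsid <- sprintf("rs%06d", seq_len(J))
  pos <- seq_len(J) * 1000000L
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  gamma <- .draw_gamma(config$gamma_dist, J)

  alpha <- numeric(J)
  n_pl <- round(config$frac_pleiotropic * J)
  if (config$pleiotropy_mode != "none" && n_pl > 0) {
    idx <- sample.int(J, n_pl)
    mu <- if (config$pleiotropy_mode == "directional") config$alpha_mean else 0
    alpha[idx] <- stats::rnorm(n_pl, mu, config$alpha_sd)
  }
  if (config$inside_violation != 0)
    alpha <- alpha + config$inside_violation * (gamma - mean(gamma))

  Gamma <- config$theta * gamma + alpha
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
  beta_x <- gamma + stats::rnorm(J) * se_x
  beta_y <- Gamma + stats::rnorm(J) * se_y
  if (config$flip_exposure_coding) {
    beta_x <- -beta_x
    gamma <- -gamma
  }

  # allele pairs: palindromic fraction first, the rest non-palindromic
  n_pal <- round(config$frac_palindromic * J)
  pal_idx <- if (n_pal > 0) sample.int(J, n_pal) else integer(0)
  al <- .nonpal_pairs[sample.int(nrow(.nonpal_pairs), J, replace = TRUE), , drop = FALSE]
  if (n_pal > 0)
    al[pal_idx, ] <- .pal_pairs[sample.int(nrow(.pal_pairs), n_pal, replace = TRUE), , drop = FALSE]

  mk <- function(beta, se, n, trait) data.frame(
    rsid = rsid, chrom = "1", pos = pos,
    effect_allele = al[, 1], other_allele = al[, 2],
    beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
    eaf = maf, n = n, trait_id = trait, stringsAsFactors = FALSE
  )
  exposure <- mk(beta_x, se_x, config$n_exposure, "sim-exposure")
  outcome <- mk(beta_y, se_y, config$n_outcome, "sim-outcome")

  # strand-flip corruption: swap alleles and negate beta jointly (restorable);
  # only non-palindromic records are flipped (palindromic ones are ambiguous
  # by definition and are dropped downstream regardless)
  n_flip <- round(config$frac_flipped * J)
  cand <- setdiff(seq_len(J), pal_idx)
  flip_idx <- if (n_flip > 0 && length(cand) > 0)
    sample(cand, min(n_flip, length(cand))) else integer(0)
  if (length(flip_idx)) {
    ea <- outcome$effect_allele[flip_idx]
    outcome$effect_allele[flip_idx] <- outcome$other_allele[flip_idx]
    outcome$other_allele[flip_idx] <- ea
    outcome$beta[flip_idx] <- -outcome$beta[flip_idx]
    outcome$eaf[flip_idx] <- 1 - outcome$eaf[flip_idx]
  }

  truth <- list(
    theta = if (config$flip_exposure_coding) -config$theta else config$theta,
    snps = data.frame(
      rsid = rsid, gamma = gamma, alpha = alpha,
      beta_x_obs = beta_x, beta_y_obs = beta_y,
      palindromic = seq_len(J) %in% pal_idx,
      flipped = seq_len(J) %in% flip_idx,
      stringsAsFactors = FALSE
    ),
    palindromic_rsids = rsid[sort(pal_idx)],
    flipped_rsids = rsid[sort(flip_idx)]
  )
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate summary statistics with block-structured LD
#'
#' Builds a block-diagonal LD r-squared matrix (within-block r2 =
#' `block_corr`, between-block r2 = 0) and one study of summary statistics
#' whose sampling noise is correlated accordingly. Block members sit within
#' a few hundred base pairs of each other so a default 10 kb clumping window
#' spans each block; distinct blocks are megabases apart.
#'
#' @param config A [sim_config()]; `n_snps` is the total SNP count.
#' @param block_corr Within-block r-squared, in [0, 1).
#' @param block_size Number of SNPs per block (last block may be smaller).
#' @return A list with `stats` (summary-statistics data frame) and `ld`
#'   (named J x J r-squared matrix, positive semi-definite by construction).
#' @export
simulate_ld_block <- function(config, block_corr, block_size = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(block_corr) || block_corr < 0 || block_corr >= 1)
    stop("block_corr must be in [0, 1)", call. = FALSE)
  set.seed(config$seed)
  J <- config$n_snps
  rsid <- sprintf("rs%06d", seq_len(J))
  block <- rep(seq_len(ceiling(J / block_size)), each = block_size)[seq_len(J)]
  pos <- (block - 1L) * 1000000L + (seq_len(J) - (block - 1L) * block_size) * 100L

  ld <- (outer(block, block, `==`)) * block_corr
  diag(ld) <- 1
  dimnames(ld) <- list(rsid, rsid)

  # noise correlation: compound symmetry per block with r = sqrt(r2) >= 0,
  # PSD for any r in [0, 1)
  rmat <- (outer(block, block, `==`)) * sqrt(block_corr)
  diag(rmat) <- 1
  L <- chol(rmat)

  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  gamma <- .draw_gamma(config$gamma_dist, J)
  se <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  beta <- gamma + as.vector(crossprod(L, stats::rnorm(J))) * se
  stats <- data.frame(
    rsid = rsid, chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G",
    beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
    eaf = maf, n = config$n_exposure, trait_id = "sim-ld",
    stringsAsFactors = FALSE
  )
  list(stats = stats, ld = ld)
}

#' Specify a trait network with planted third-trait roles
#'
#' @param exposure,outcome Names of the focal exposure and outcome traits.
#' @param roles Named character vector mapping third-trait names to roles in
#'   `c("confounder", "intermediate", "reverse_intermediate", "collider")`.
#' @param null_traits Character vector of traits connected only by
#'   non-significant edges.
#' @param extra_edges Optional data frame (from, to, beta) of additional true
#'   edges; must be acyclic together with the exposure -> outcome edge.
#' @return A validated list of class `network_spec`.
#' @export
network_spec <- function(exposure, outcome, roles = character(0),
                         null_traits = character(0), extra_edges = NULL) {
  if (identical(exposure, outcome)) stop("exposure and outcome must differ", call. = FALSE)
  ok <- c("confounder", "intermediate", "reverse_intermediate", "collider")
  if (length(roles) && (!all(roles %in% ok) || is.null(names(roles))))
    stop("roles must be a named vector with values in: ", paste(ok, collapse = ", "),
         call. = FALSE)
  if (any(names(roles) %in% c(exposure, outcome)))
    stop("third traits must differ from exposure and outcome", call. = FALSE)
  if (!is.null(extra_edges)) {
    ed <- rbind(data.frame(from = exposure, to = outcome),
                extra_edges[, c("from", "to")])
    g <- igraph::graph_from_data_frame(ed, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("extra_edges create a cycle in the true-edge graph", call. = FALSE)
  }
  structure(list(exposure = exposure, outcome = outcome, roles = roles,
                 null_traits = null_traits, extra_edges = extra_edges),
            class = "network_spec")
}

#' Simulate an MR edge list from a planted trait network
#'
#' Emits directed trait-to-trait MR edges (beta, se, p) consistent with the
#' planted roles: a confounder C gets significant C->E and C->O edges, an
#' intermediate E->C and C->O, a reverse intermediate C->E and O->C, and a
#' collider E->C and O->C. The exposure -> outcome causal edge is always
#' emitted as significant. Traits listed in `null_traits` receive only
#' non-significant edges (p drawn well above `p_sig`).
#'
#' @param spec A [network_spec()].
#' @param seed Integer RNG seed.
#' @param p_sig Significance level the planted edges comfortably beat.
#' @return A data frame of MR edges (exposure_id, outcome_id, beta, se, pval,
#'   method), fixed-effects IVW by convention.
#' @export
simulate_trait_network <- function(spec, seed = 1L, p_sig = 1e-5) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(as.integer(seed))
  E <- spec$exposure; O <- spec$outcome
  sig_edge <- function(from, to) {
    beta <- stats::runif(1, 0.1, 0.5) * sample(c(-1, 1), 1)
    data.frame(exposure_id = from, outcome_id = to, beta = beta,
               se = abs(beta) / 8,
               pval = 10^stats::runif(1, -12, log10(p_sig) - 1),
               method = "ivw_fe", stringsAsFactors = FALSE)
  }
  null_edge <- function(from, to) data.frame(
    exposure_id = from, outcome_id = to,
    beta = stats::rnorm(1, 0, 0.02), se = 0.05,
    pval = stats::runif(1, min(1, p_sig * 1e3), 1),
    method = "ivw_fe", stringsAsFactors = FALSE
  )
  out <- list(sig_edge(E, O))
  for (C in names(spec$roles)) {
    out <- c(out, switch(spec$roles[[C]],
      confounder = list(sig_edge(C, E), sig_edge(C, O)),
      intermediate = list(sig_edge(E, C), sig_edge(C, O)),
      reverse_intermediate = list(sig_edge(C, E), sig_edge(O, C)),
      collider = list(sig_edge(E, C), sig_edge(O, C))
    ))
  }
  for (C in spec$null_traits)
    out <- c(out, list(null_edge(C, E), null_edge(C, O)))
  if (!is.null(spec$extra_edges))
    out <- c(out, lapply(seq_len(nrow(spec$extra_edges)), function(i)
      sig_edge(spec$extra_edges$from[i], spec$extra_edges$to[i])))
  do.call(rbind, out)
}
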