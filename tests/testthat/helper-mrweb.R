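# shared fixtures and independent oracles, built in code at test time

# bare harmonized data frame from effect vectors
make_h <- function(bx, by, se_y, se_x = rep(0.01, length(bx)),
                   n_x = 50000, n_y = 50000) {
  data.frame(
    rsid = sprintf("rs%04d", seq_along(bx)), chrom = "1",
    pos = seq_along(bx) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = se_x,
    pval_exposure = 2 * pnorm(-abs(bx / se_x)),
    beta_outcome = by, se_outcome = se_y,
    pval_outcome = 2 * pnorm(-abs(by / se_y)),
    eaf = 0.3, n_exposure = n_x, n_outcome = n_y,
    stringsAsFactors = FALSE
  )
}

# simulate and harmonize in one step
sim_h <- function(...) {
  s <- simulate_two_sample(sim_config(...))
  harmonize_studies(s$exposure, s$outcome)
}

# concatenate simulator outputs with disambiguated rsids (multi-cluster sets)
combine_sims <- function(sims) {
  for (k in seq_along(sims)) {
    tag <- letters[k]
    sims[[k]]$exposure$rsid <- paste0(sims[[k]]$exposure$rsid, "_", tag)
    sims[[k]]$outcome$rsid <- paste0(sims[[k]]$outcome$rsid, "_", tag)
  }
  list(exposure = do.call(rbind, lapply(sims, `[[`, "exposure")),
       outcome = do.call(rbind, lapply(sims, `[[`, "outcome")))
}

# naive all-pairs greedy clumping oracle: walk SNPs by ascending p-value and
# check every retained SNP explicitly (no early exit, no vectorisation)
clump_oracle <- function(stats, ld, r2_threshold, window_bp) {
  ord <- order(stats$pval, stats$pos, stats$rsid)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      same_chr <- stats$chrom[k] == stats$chrom[i]
      close <- abs(stats$pos[k] - stats$pos[i]) <= window_bp
      if (same_chr && close &&
          ld[stats$rsid[i], stats$rsid[k]] >= r2_threshold)
        conflict <- TRUE
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(stats$rsid[kept])
}

# random symmetric r-squared matrix with unit diagonal
random_ld <- function(rsids, max_r2 = 1) {
  J <- length(rsids)
  U <- matrix(runif(J * J, 0, max_r2), J, J)
  R <- (U + t(U)) / 2
  diag(R) <- 1
  dimnames(R) <- list(rsids, rsids)
  R
}

# candidate study batch with n_true causal pairs followed by n_null nulls
make_candidates <- function(n_true, n_null, theta = 0.3, seed_base = 0,
                            J = 30, n = 1e5) {
  lapply(seq_len(n_true + n_null), function(i) {
    th <- if (i <= n_true) theta else 0
    s <- simulate_two_sample(sim_config(
      n_snps = J, theta = th, n_exposure = n, n_outcome = n,
      seed = seed_base + i
    ))
    list(exposure = s$exposure, outcome = s$outcome,
         exposure_id = sprintf("exp_%02d", i),
         outcome_id = sprintf("out_%02d", i),
         true_effect = th != 0)
  })
}

# exhaustive enumeration oracle for third-trait role classification:
# tests every (E, O, C) triple against the four motif definitions directly
web_oracle <- function(pairs, edges, p_threshold) {
  sig <- edges[edges$pval < p_threshold, , drop = FALSE]
  has <- function(a, b) any(sig$exposure_id == a & sig$outcome_id == b)
  traits <- unique(c(edges$exposure_id, edges$outcome_id,
                     pairs$exposure_id, pairs$outcome_id))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    E <- pairs$exposure_id[i]; O <- pairs$outcome_id[i]
    for (C in setdiff(traits, c(E, O))) {
      if (has(C, E) && has(C, O))
        out[[length(out) + 1]] <- c(E, O, C, "confounder")
      if (has(E, C) && has(C, O))
        out[[length(out) + 1]] <- c(E, O, C, "intermediate")
      if (has(C, E) && has(O, C))
        out[[length(out) + 1]] <- c(E, O, C, "reverse_intermediate")
      if (has(E, C) && has(O, C))
        out[[length(out) + 1]] <- c(E, O, C, "collider")
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# flatten a trait_graph's assignments to the oracle's key format
assignment_keys <- function(graph) {
  a <- graph$assignments
  if (!nrow(a)) return(character(0))
  sort(paste(a$exposure, a$outcome, a$third, a$role, sep = "|"))
}
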