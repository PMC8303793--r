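test_that("palindromic allele pairs are recognised", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_equal(is_palindromic(c("A", "G", "T"), c("T", "A", "A")),
               c(TRUE, FALSE, TRUE))
  expect_error(is_palindromic("A", "N"), "non-ACGT")
})

test_that("align_pair resolves every allele configuration", {
  ex <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.1, se = 0.01, eaf = 0.3, stringsAsFactors = FALSE)
  ou <- function(ea, oa, beta = 0.05, eaf = 0.3)
    data.frame(rsid = "rs1", effect_allele = ea, other_allele = oa,
               beta = beta, se = 0.02, eaf = eaf, stringsAsFactors = FALSE)
  # identity
  r <- align_pair(ex, ou("A", "G"))
  expect_true(r$kept); expect_equal(r$outcome$beta, 0.05)
  # reversed: beta negated, eaf reflected
  r <- align_pair(ex, ou("G", "A", eaf = 0.7))
  expect_true(r$kept)
  expect_equal(r$outcome$beta, -0.05)
  expect_equal(r$outcome$eaf, 0.3)
  # strand complement (T/C complements to A/G): kept unchanged
  r <- align_pair(ex, ou("T", "C"))
  expect_true(r$kept); expect_equal(r$outcome$beta, 0.05)
  # complement then reversed: negated
  r <- align_pair(ex, ou("C", "T"))
  expect_true(r$kept); expect_equal(r$outcome$beta, -0.05)
  # palindromic exposure dropped whatever the outcome
  exp_pal <- ex; exp_pal$other_allele <- "T"
  r <- align_pair(exp_pal, ou("A", "T"))
  expect_false(r$kept); expect_equal(r$reason, "palindromic")
  # irreconcilable alleles
  r <- align_pair(ex, ou("A", "C"))
  expect_false(r$kept); expect_equal(r$reason, "allele_mismatch")
  # mismatched rsids are a caller bug
  ou_bad <- ou("A", "G"); ou_bad$rsid <- "rs2"
  expect_error(align_pair(ex, ou_bad), "rsid mismatch")
})

test_that("clumping is greedy on p-value with window and r2 rules", {
  stats <- data.frame(
    rsid = c("A", "B", "C"), chrom = "1", pos = c(100, 200, 300),
    pval = c(1e-10, 1e-8, 1e-6), stringsAsFactors = FALSE
  )
  ld <- diag(3); dimnames(ld) <- list(stats$rsid, stats$rsid)
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  ld["A", "C"] <- ld["C", "A"] <- 1e-4
  ld["B", "C"] <- ld["C", "B"] <- 1e-4
  expect_equal(clump(stats, ld, 0.001, 10000), c("A", "C"))
  # identity matrix keeps everything
  expect_equal(clump(stats, diag(3, 3) |>
                       `dimnames<-`(list(stats$rsid, stats$rsid)), 0.001, 10000),
               stats$rsid)
  # outside the window the r2 is never consulted
  far <- stats; far$pos <- c(100, 1e6, 2e6)
  expect_equal(clump(far, ld, 0.001, 10000), far$rsid)
  # missing LD entries are an error naming the pair
  ld2 <- ld[1:2, 1:2]
  expect_error(clump(stats, ld2, 0.001, 10000), "\\(C, A\\)|\\(C, B\\)")
})

test_that("harmonization inverts strand flips exactly and audits palindromes", {
  s <- simulate_two_sample(sim_config(
    n_snps = 100, theta = 0.2, frac_palindromic = 0.2, frac_flipped = 0.3,
    seed = 17
  ))
  h <- harmonize_studies(s$exposure, s$outcome)
  truth <- s$truth$snps
  kept <- truth[match(h$data$rsid, truth$rsid), ]
  expect_identical(h$data$beta_outcome, kept$beta_y_obs)  # exact restoration
  expect_setequal(h$audit$rsid[h$audit$reason == "palindromic"],
                  s$truth$palindromic_rsids)
  expect_equal(nrow(h$data), 80)
})

test_that("self-harmonization keeps everything and equates the betas", {
  x <- simulate_two_sample(sim_config(n_snps = 50, theta = 0.2, seed = 2))$exposure
  h <- harmonize_studies(x, x)
  expect_equal(nrow(h$audit), 0)
  expect_identical(h$data$beta_exposure, h$data$beta_outcome)
})

test_that("rsid accounting conserves and missing outcome SNPs are audited", {
  s <- simulate_two_sample(sim_config(n_snps = 60, theta = 0.2,
                                      frac_palindromic = 0.1, seed = 4))
  out <- s$outcome[-(1:10), ]  # 10 SNPs absent from the outcome study
  h <- harmonize_studies(s$exposure, out)
  expect_equal(sum(h$audit$reason == "missing_in_outcome"), 10)
  expect_setequal(c(h$data$rsid, h$audit$rsid), s$exposure$rsid)
  expect_equal(nrow(h$data) + nrow(h$audit), nrow(s$exposure))
})

test_that("harmonization is idempotent", {
  s <- simulate_two_sample(sim_config(n_snps = 40, theta = 0.2,
                                      frac_flipped = 0.5, seed = 8))
  h1 <- harmonize_studies(s$exposure, s$outcome)
  ex2 <- data.frame(
    rsid = h1$data$rsid, chrom = h1$data$chrom, pos = h1$data$pos,
    effect_allele = h1$data$effect_allele, other_allele = h1$data$other_allele,
    beta = h1$data$beta_exposure, se = h1$data$se_exposure,
    pval = h1$data$pval_exposure, eaf = h1$data$eaf,
    n = h1$data$n_exposure, stringsAsFactors = FALSE
  )
  ou2 <- ex2
  ou2$beta <- h1$data$beta_outcome; ou2$se <- h1$data$se_outcome
  ou2$pval <- h1$data$pval_outcome; ou2$n <- h1$data$n_outcome
  h2 <- harmonize_studies(ex2, ou2)
  expect_equal(nrow(h2$audit), 0)
  expect_identical(h2$data$beta_outcome, h1$data$beta_outcome)
  expect_identical(h2$data$beta_exposure, h1$data$beta_exposure)
})

test_that("outcome orientation is immaterial to the harmonized set", {
  s <- simulate_two_sample(sim_config(n_snps = 30, theta = 0.2, seed = 12))
  h0 <- harmonize_studies(s$exposure, s$outcome)
  flip_rec <- function(o, idx) {
    ea <- o$effect_allele[idx]
    o$effect_allele[idx] <- o$other_allele[idx]
    o$other_allele[idx] <- ea
    o$beta[idx] <- -o$beta[idx]
    o$eaf[idx] <- 1 - o$eaf[idx]
    o
  }
  set.seed(1)
  for (rep in 1:5) {
    idx <- sample(30, sample(30, 1))
    h1 <- harmonize_studies(s$exposure, flip_rec(s$outcome, idx))
    expect_equal(h1$data, h0$data)
  }
})

test_that("vectorised harmonization agrees with per-record alignment", {
  s <- simulate_two_sample(sim_config(
    n_snps = 80, theta = 0.2, frac_palindromic = 0.25, frac_flipped = 0.4,
    seed = 23
  ))
  h <- harmonize_studies(s$exposure, s$outcome)
  for (i in seq_len(nrow(s$exposure))) {
    r <- align_pair(s$exposure[i, ], s$outcome[i, ])
    rsid <- s$exposure$rsid[i]
    if (r$kept) {
      expect_true(rsid %in% h$data$rsid)
      expect_identical(h$data$beta_outcome[h$data$rsid == rsid], r$outcome$beta)
    } else {
      expect_identical(h$audit$reason[h$audit$rsid == rsid], r$reason)
    }
  }
})

test_that("an empty post-harmonization set is an explicit error", {
  s <- simulate_two_sample(sim_config(n_snps = 10, theta = 0.2,
                                      frac_palindromic = 1, seed = 1))
  expect_error(harmonize_studies(s$exposure, s$outcome), "no valid instruments")
  expect_error(harmonize_studies(s$exposure[0, ], s$outcome), "empty")
})
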