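.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A palindromic SNP carries the same base pair on both strands (A/T or C/G),
#' so its strand cannot be resolved from the alleles alone; the harmonizer
#' discards such SNPs.
#'
#' @param effect_allele,other_allele Single bases in A/C/G/T (vectorised).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ok <- effect_allele %in% names(.complement) & other_allele %in% names(.complement)
  if (!all(ok)) stop("non-ACGT allele", call. = FALSE)
  unname(.complement[effect_allele] == other_allele)
}

#' Align one outcome record to the exposure's effect allele
#'
#' Resolution order: identical allele order is kept unchanged; reversed order
#' (effect and other swapped) negates the outcome beta and reflects eaf;
#' if neither matches, the outcome alleles are strand-complemented and the
#' two checks re-run; palindromic SNPs are dropped; anything else is an
#' irreconcilable allele mismatch.
#'
#' @param exposure_record,outcome_record Single-row summary-statistics data
#'   frames for the same rsid.
#' @return A list: `kept` (logical), the aligned `outcome` row when kept,
#'   otherwise `reason` (`"palindromic"` or `"allele_mismatch"`).
#' @export
align_pair <- function(exposure_record, outcome_record) {
  if (!identical(exposure_record$rsid, outcome_record$rsid))
    stop("rsid mismatch in align_pair: ", exposure_record$rsid, " vs ",
         outcome_record$rsid, call. = FALSE)
  if (is_palindromic(exposure_record$effect_allele, exposure_record$other_allele) ||
      is_palindromic(outcome_record$effect_allele, outcome_record$other_allele))
    return(list(kept = FALSE, reason = "palindromic"))
  ea <- exposure_record$effect_allele; oa <- exposure_record$other_allele
  try_orient <- function(rec) {
    if (rec$effect_allele == ea && rec$other_allele == oa) return(rec)
    if (rec$effect_allele == oa && rec$other_allele == ea) {
      rec$effect_allele <- ea; rec$other_allele <- oa
      rec$beta <- -rec$beta
      if (!is.na(rec$eaf)) rec$eaf <- 1 - rec$eaf
      return(rec)
    }
    NULL
  }
  out <- try_orient(outcome_record)
  if (is.null(out)) {
    flipped <- outcome_record
    flipped$effect_allele <- unname(.complement[outcome_record$effect_allele])
    flipped$other_allele <- unname(.complement[outcome_record$other_allele])
    out <- try_orient(flipped)
  }
  if (is.null(out)) return(list(kept = FALSE, reason = "allele_mismatch"))
  list(kept = TRUE, outcome = out)
}

#' Greedy LD clumping to approximately independent SNPs
#'
#' SNPs are visited in ascending p-value (ties broken by position, then
#' rsid); each is retained iff its r-squared with every already-retained SNP
#' on the same chromosome within `window_bp` is below `r2_threshold`.
#'
#' @param stats Summary-statistics data frame (rsid, chrom, pos, pval).
#' @param ld Square r-squared matrix with rsid dimnames covering the stats.
#' @param r2_threshold Retention cutoff, in (0, 1); default 0.001.
#' @param window_bp Window in base pairs within which LD is consulted.
#' @return Character vector of retained rsids (in input order).
#' @export
clump <- function(stats, ld, r2_threshold = 0.001, window_bp = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold < 1, window_bp > 0)
  ord <- order(stats$pval, stats$pos, stats$rsid)
  kept <- integer(0)
  for (i in ord) {
    near <- kept[stats$chrom[kept] == stats$chrom[i] &
                   abs(stats$pos[kept] - stats$pos[i]) <= window_bp]
    ok <- TRUE
    for (k in near) {
      a <- stats$rsid[i]; b <- stats$rsid[k]
      if (!a %in% rownames(ld) || !b %in% colnames(ld))
        stop("missing LD entry for pair (", a, ", ", b, ")", call. = FALSE)
      if (ld[a, b] >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  stats$rsid[sort(kept)]
}

#' Harmonize an exposure/outcome study pair
#'
#' Intersects rsids (outcome-absent SNPs are dropped with reason
#' `missing_in_outcome`; no proxy search is attempted), aligns each outcome
#' record to the exposure's effect allele via the [align_pair()] rules,
#' discards palindromic SNPs, and optionally LD-clumps the survivors on
#' exposure p-values. Every input exposure rsid is accounted for exactly once
#' across the kept set and the audit trail.
#'
#' @param exposure,outcome Summary-statistics data frames.
#' @param ld Optional r-squared matrix; when `NULL`, clumping is skipped
#'   (instruments assumed independent, e.g. pre-clumped input).
#' @param r2_threshold,window_bp Clumping parameters; the window default of
#'   10000 bp is deliberately conservative — production clumping pipelines
#'   conventionally use a 10000 kb window, so set `window_bp = 1e7` to match
#'   them.
#' @return An object of class `harmonized_set`: list with `data` (per-SNP
#'   rsid, chrom, pos, effect_allele, other_allele, beta_exposure,
#'   se_exposure, pval_exposure, beta_outcome, se_outcome, pval_outcome,
#'   eaf, n_exposure, n_outcome) and `audit` (rsid, reason).
#' @export
harmonize_studies <- function(exposure, outcome, ld = NULL,
                              r2_threshold = 0.001, window_bp = 10000) {
  if (nrow(exposure) == 0) stop("exposure study is empty", call. = FALSE)
  audit <- data.frame(rsid = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  add_audit <- function(rsids, reason) {
    if (length(rsids))
      audit <<- rbind(audit, data.frame(rsid = rsids, reason = reason,
                                        stringsAsFactors = FALSE))
  }
  missing <- setdiff(exposure$rsid, outcome$rsid)
  add_audit(missing, "missing_in_outcome")
  ex <- exposure[!exposure$rsid %in% missing, , drop = FALSE]
  ou <- outcome[match(ex$rsid, outcome$rsid), , drop = FALSE]

  # vectorised align_pair semantics
  pal <- is_palindromic(ex$effect_allele, ex$other_allele) |
    is_palindromic(ou$effect_allele, ou$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  rev <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  cea <- unname(.complement[ou$effect_allele])
  coa <- unname(.complement[ou$other_allele])
  csame <- cea == ex$effect_allele & coa == ex$other_allele
  crev <- cea == ex$other_allele & coa == ex$effect_allele
  keep <- !pal & (same | rev | csame | crev)
  flip <- !pal & !same & (rev | (!csame & crev))
  add_audit(ex$rsid[pal], "palindromic")
  add_audit(ex$rsid[!pal & !keep], "allele_mismatch")

  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  h <- data.frame(
    rsid = ex$rsid, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, pval_exposure = ex$pval,
    beta_outcome = beta_y, se_outcome = ou$se, pval_outcome = ou$pval,
    eaf = ex$eaf, n_exposure = ex$n, n_outcome = ou$n,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  if (!is.null(ld) && nrow(h) > 0) {
    retained <- clump(
      data.frame(rsid = h$rsid, chrom = h$chrom, pos = h$pos,
                 pval = h$pval_exposure, stringsAsFactors = FALSE),
      ld, r2_threshold = r2_threshold, window_bp = window_bp
    )
    add_audit(setdiff(h$rsid, retained), "clumped")
    h <- h[h$rsid %in% retained, , drop = FALSE]
  }
  if (nrow(h) == 0)
    stop("no valid instruments after harmonization", call. = FALSE)
  rownames(h) <- NULL
  structure(list(data = h, audit = audit), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("harmonized_set:", nrow(x$data), "instruments kept,",
      nrow(x$audit), "dropped\n")
  if (nrow(x$audit)) print(table(x$audit$reason))
  invisible(x)
}
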