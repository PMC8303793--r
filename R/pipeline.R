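#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values: with p sorted ascending,
#' q_(i) = min over k >= i of p_(k) * m / k, restored to input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values, elementwise >= the input and <= 1.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Pipeline configuration
#'
#' @param screen_p Candidate-retention threshold on the primary IVW p-value
#'   (genome-wide convention 5e-8; set to 1 to retain all pairs).
#' @param fdr_threshold FDR level for significance (default 0.05).
#' @param methods Estimators to run on retained pairs; the first must be the
#'   primary (FDR-screened) method, random-effects IVW by default.
#' @param r2_threshold,window_bp Clumping parameters passed to
#'   [harmonize_studies()].
#' @param n_boot,seed Bootstrap controls.
#' @param run_loo,run_steiger Toggle sensitivity analyses.
#' @param include,exclude Optional manual-curation lists of pair keys
#'   `"exposure_id::outcome_id"`: `include` (if non-NULL) whitelists pairs,
#'   `exclude` removes pairs, before screening.
#' @return List of class `mr_pipeline_config`.
#' @export
pipeline_config <- function(screen_p = 5e-8, fdr_threshold = 0.05,
                            methods = c("ivw_re", "egger", "median_weighted",
                                        "mode_weighted"),
                            r2_threshold = 0.001, window_bp = 10000,
                            n_boot = 1000, seed = 1L,
                            run_loo = TRUE, run_steiger = TRUE,
                            include = NULL, exclude = NULL) {
  stopifnot(screen_p > 0, screen_p <= 1, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(screen_p = screen_p, fdr_threshold = fdr_threshold,
                 methods = methods, r2_threshold = r2_threshold,
                 window_bp = window_bp, n_boot = n_boot,
                 seed = as.integer(seed), run_loo = run_loo,
                 run_steiger = run_steiger, include = include,
                 exclude = exclude),
            class = "mr_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any argument of [pipeline_config()] plus a `candidates`
#' list of `{exposure: path, outcome: path}` entries.
#'
#' @param path YAML file path.
#' @return List with `config` (an `mr_pipeline_config`) and `candidates`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files", call. = FALSE)
  y <- yaml::yaml.load_file(path)
  cand <- y$candidates
  y$candidates <- NULL
  list(config = do.call(pipeline_config, y), candidates = cand)
}

.pair_input <- function(x) {
  if (is.character(x)) read_sumstats(x) else x
}

#' Screen candidate exposure/outcome pairs and run the full MR analysis
#'
#' For every candidate pair: harmonize, compute the primary (first-listed,
#' random-effects IVW by default) estimate, and retain pairs whose primary
#' p-value passes `screen_p`. Benjamini-Hochberg FDR is then applied across
#' the retained pairs' primary p-values only; the remaining estimators and
#' sensitivity analyses (heterogeneity, leave-one-out, Steiger) run on each
#' retained pair and are reported unadjusted. Pairs failing harmonization
#' ("no valid instruments") are recorded as failed, never silently dropped.
#'
#' @param candidates List of candidate pairs; each element a list with
#'   `exposure` and `outcome` (summary-statistics data frames or file paths)
#'   and optional `exposure_id`/`outcome_id`/`ld`.
#' @param config An [pipeline_config()].
#' @return List of class `mr_screen`: `results` (one record per retained
#'   pair: ids, estimates, heterogeneity, steiger, loo, ivw_qvalue,
#'   significant), `failed` (ids + error message), `forest` (the per-study
#'   forest table: theta, 95% CI, p, q, significance).
#' @export
screen_and_analyze <- function(candidates, config = pipeline_config()) {
  stopifnot(inherits(config, "mr_pipeline_config"), length(candidates) >= 1)
  primary <- config$methods[1]
  key_of <- function(cand, i) {
    ex_id <- cand$exposure_id %||% sprintf("exposure_%02d", i)
    ou_id <- cand$outcome_id %||% sprintf("outcome_%02d", i)
    c(ex_id, ou_id)
  }
  results <- list(); failed <- list()
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    ids <- key_of(cand, i)
    key <- paste(ids, collapse = "::")
    if (!is.null(config$include) && !key %in% config$include) next
    if (!is.null(config$exclude) && key %in% config$exclude) next
    h <- tryCatch(
      harmonize_studies(.pair_input(cand$exposure), .pair_input(cand$outcome),
                        ld = cand$ld, r2_threshold = config$r2_threshold,
                        window_bp = config$window_bp),
      error = function(e) e
    )
    if (inherits(h, "error")) {
      failed[[length(failed) + 1]] <- list(exposure_id = ids[1],
                                           outcome_id = ids[2],
                                           error = conditionMessage(h))
      next
    }
    prim <- tryCatch(mr_all(h, primary, n_boot = config$n_boot,
                            seed = config$seed)[[1]],
                     error = function(e) e)
    if (inherits(prim, "error")) {
      failed[[length(failed) + 1]] <- list(exposure_id = ids[1],
                                           outcome_id = ids[2],
                                           error = conditionMessage(prim))
      next
    }
    if (prim$pval >= config$screen_p) next
    rec <- list(exposure_id = ids[1], outcome_id = ids[2], harmonized = h,
                estimates = stats::setNames(list(prim), primary))
    results[[length(results) + 1]] <- rec
  }
  if (length(results)) {
    # deterministic ordering so FDR bookkeeping is input-order invariant
    ord <- order(vapply(results, function(r)
      paste(r$exposure_id, r$outcome_id, sep = "::"), character(1)))
    results <- results[ord]
    pvals <- vapply(results, function(r) r$estimates[[1]]$pval, numeric(1))
    # normal p-values underflow to 0 for very strong effects; clamp to the
    # smallest positive double so BH (defined on (0,1]) is applicable
    qvals <- bh_fdr(pmax(pvals, .Machine$double.xmin))
    for (i in seq_along(results)) {
      r <- results[[i]]
      rest <- setdiff(config$methods, config$methods[1])
      if (length(rest))
        r$estimates <- c(r$estimates,
                         mr_all(r$harmonized, rest, n_boot = config$n_boot,
                                seed = config$seed))
      r$heterogeneity <- mr_heterogeneity(r$harmonized)
      if (config$run_loo && nrow(r$harmonized$data) >= 3)
        r$loo <- leave_one_out(r$harmonized)
      if (config$run_steiger)
        r$steiger <- tryCatch(steiger_direction(r$harmonized),
                              error = function(e) NULL)
      r$ivw_qvalue <- qvals[i]
      r$significant <- qvals[i] < config$fdr_threshold
      results[[i]] <- r
    }
  }
  forest <- if (length(results)) do.call(rbind, lapply(results, function(r) {
    e <- r$estimates[[1]]
    data.frame(exposure_id = r$exposure_id, outcome_id = r$outcome_id,
               method = e$method, n_snp = e$n_snp, theta = e$theta,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               qval = r$ivw_qvalue, significant = r$significant,
               stringsAsFactors = FALSE)
  })) else data.frame()
  structure(list(results = results, failed = failed, forest = forest),
            class = "mr_screen")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mr_screen <- function(x, ...) {
  cat("mr_screen:", length(x$results), "retained pair(s),",
      sum(vapply(x$results, `[[`, logical(1), "significant")),
      "FDR-significant,", length(x$failed), "failed\n")
  invisible(x)
}
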