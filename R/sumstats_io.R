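#' @keywords internal
.sumstats_cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "pval", "eaf", "n", "trait_id")
.mandatory_cols <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")

# row-level invariant screen; returns character reasons ("" = keep)
.sumstats_drop_reason <- function(df) {
  reason <- character(nrow(df))
  flag <- function(bad, why) reason[bad & reason == ""] <<- why
  flag(is.na(df$rsid) | df$rsid == "", "missing rsid")
  flag(duplicated(df$rsid), "duplicate rsid")
  flag(!df$effect_allele %in% c("A", "C", "G", "T") |
         !df$other_allele %in% c("A", "C", "G", "T"), "invalid allele")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(!is.finite(df$beta), "nonfinite beta")
  flag(!is.finite(df$se) | df$se <= 0, "nonpositive se")
  flag(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  if ("eaf" %in% names(df))
    flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  if ("n" %in% names(df))
    flag(!is.na(df$n) & df$n < 2, "sample size < 2")
  reason
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Native dialect: TSV with a header row and columns rsid, chrom, pos,
#' effect_allele, other_allele, beta, se, pval, eaf, n, trait_id (the last
#' five of which are optional). Other layouts (e.g. MR-Base exports) are
#' ingested by supplying `column_map`. Rows violating the record invariants
#' are dropped, not silently coerced, and accounted for in the attached
#' drop log (kept + dropped = input).
#'
#' @param path Path to the TSV file.
#' @param column_map Optional named character vector mapping native column
#'   names to the names used in the file, e.g. `c(rsid = "SNP", beta = "b")`.
#' @param log_or If `TRUE`, the effect column holds odds ratios and is
#'   converted to log(OR) on read (ORs must be positive).
#' @return A data frame of validated records with attribute `drop_log`
#'   (data frame: rsid, row, reason).
#' @export
read_sumstats <- function(path, column_map = NULL, log_or = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = NA)
  if (!is.null(column_map)) {
    for (native in names(column_map)) {
      src <- column_map[[native]]
      if (!src %in% names(df))
        stop("column_map names absent column: ", src, call. = FALSE)
      names(df)[names(df) == src] <- native
    }
  }
  miss <- setdiff(.mandatory_cols, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("empty summary-statistics file: ", path, call. = FALSE)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  if (log_or) {
    if (any(df$beta <= 0, na.rm = TRUE))
      stop("log_or = TRUE but nonpositive odds ratios present", call. = FALSE)
    df$beta <- log(df$beta)
  }
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  df$chrom <- as.character(df$chrom)
  if (!"pos" %in% names(df)) df$pos <- NA_integer_
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  if (!"trait_id" %in% names(df)) df$trait_id <- NA_character_
  df$pos <- as.integer(df$pos)
  for (cn in c("beta", "se", "pval", "eaf", "n"))
    df[[cn]] <- as.numeric(df[[cn]])
  df <- df[.sumstats_cols]
  reason <- .sumstats_drop_reason(df)
  kept <- df[reason == "", , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "drop_log") <- data.frame(
    rsid = df$rsid[reason != ""], row = which(reason != ""),
    reason = reason[reason != ""], stringsAsFactors = FALSE
  )
  kept
}

#' Write summary statistics in the native TSV dialect
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` round-trips losslessly.
#'
#' @param stats Summary-statistics data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- stats[intersect(.sumstats_cols, names(stats))]
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a directed MR edge list
#'
#' TSV with header exposure_id, outcome_id, beta, se, pval, method
#' (se and method optional). Direction is exposure -> outcome as ordered.
#' Duplicate (exposure_id, outcome_id, method) triples are an error.
#'
#' @param path Path to the edge-list TSV.
#' @return Data frame of MR edges.
#' @export
read_mr_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("exposure_id", "outcome_id", "beta", "pval"), names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("empty edge-list file: ", path, call. = FALSE)
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"method" %in% names(df)) df$method <- NA_character_
  key <- paste(df$exposure_id, df$outcome_id, df$method, sep = " -> ")
  if (anyDuplicated(key))
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  bad <- !is.finite(df$pval) | df$pval <= 0 | df$pval > 1
  if (any(bad))
    stop("pval outside (0,1] for edge(s): ", paste(key[bad], collapse = "; "),
         call. = FALSE)
  df[c("exposure_id", "outcome_id", "beta", "se", "pval", "method")]
}

#' Write an MR edge list in the native TSV dialect
#' @param edges Data frame of MR edges.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_edges <- function(edges, path) {
  out <- edges
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export a causal-web trait graph
#'
#' Writes the weighted directed graph assembled by [build_causal_web()] as
#' GraphML (node attribute `role` in exposure/outcome/third; edge attributes
#' `beta`, `pval`, `edge_role`), as a Cytoscape-importable edge table
#' (TSV: source, target, beta, pval, edge_role, source_role, target_role),
#' or as JSON (nodes + edges). Edge roles follow the causal /
#' confounder_link / intermediate_link / reverse_intermediate_link /
#' collider_link taxonomy.
#'
#' @param graph A `trait_graph` from [build_causal_web()].
#' @param path Output path.
#' @param format One of `"graphml"`, `"edge_table"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_web_graph <- function(graph, path, format = c("graphml", "edge_table", "json")) {
  stopifnot(inherits(graph, "trait_graph"))
  if (!is.character(format) || !format[1] %in% c("graphml", "edge_table", "json"))
    stop("unknown graph format: ", format[1], call. = FALSE)
  format <- format[1]
  nodes <- graph$nodes
  edges <- graph$edges
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[c("source", "target", "beta", "pval", "edge_role")],
      directed = TRUE, vertices = nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edge_table") {
    role_of <- stats::setNames(nodes$role, nodes$id)
    out <- edges
    out$source_role <- unname(role_of[out$source])
    out$target_role <- unname(role_of[out$target])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
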