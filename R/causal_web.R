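.role_patterns <- list(
  confounder = function(CE, EC, CO, OC) CE & CO,
  intermediate = function(CE, EC, CO, OC) EC & CO,
  reverse_intermediate = function(CE, EC, CO, OC) CE & OC,
  collider = function(CE, EC, CO, OC) EC & OC
)

.best_edge <- function(edges, from, to) {
  m <- edges[edges$exposure_id == from & edges$outcome_id == to, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  m[which.min(m$pval), , drop = FALSE]
}

#' Classify a third trait's role relative to an exposure/outcome pair
#'
#' Using only edges with p below `p_threshold` (strict), the four directed
#' two-edge motifs a third trait C can form with exposure E and outcome O
#' are tested: C->E and C->O makes C a confounder; E->C and C->O an
#' intermediate (mediator); C->E and O->C a reverse intermediate; E->C and
#' O->C a collider. A trait can satisfy several motifs through distinct edge
#' pairs; all matches are returned.
#'
#' @param edges MR edge-list data frame (exposure_id, outcome_id, beta, se,
#'   pval, method).
#' @param exposure,outcome,third Distinct trait identifiers E, O, C.
#' @param p_threshold Retention threshold (default 1e-5, strict `<`).
#' @return Data frame of role assignments (zero to four rows): exposure,
#'   outcome, third, role, and the two supporting edges' endpoints, betas
#'   and p-values.
#' @export
classify_third_trait <- function(edges, exposure, outcome, third,
                                 p_threshold = 1e-5) {
  if (any(edges$exposure_id == edges$outcome_id))
    stop("self-loop edge(s) in input", call. = FALSE)
  if (length(unique(c(exposure, outcome, third))) != 3)
    stop("exposure, outcome and third trait must be distinct", call. = FALSE)
  sig <- edges[edges$pval < p_threshold, , drop = FALSE]
  E <- exposure; O <- outcome; C <- third
  ce <- .best_edge(sig, C, E); ec <- .best_edge(sig, E, C)
  co <- .best_edge(sig, C, O); oc <- .best_edge(sig, O, C)
  present <- c(CE = !is.null(ce), EC = !is.null(ec),
               CO = !is.null(co), OC = !is.null(oc))
  rows <- list()
  support <- list(
    confounder = list(ce, co), intermediate = list(ec, co),
    reverse_intermediate = list(ce, oc), collider = list(ec, oc)
  )
  for (role in names(.role_patterns)) {
    if (.role_patterns[[role]](present["CE"], present["EC"],
                               present["CO"], present["OC"])) {
      e1 <- support[[role]][[1]]; e2 <- support[[role]][[2]]
      rows[[length(rows) + 1]] <- data.frame(
        exposure = E, outcome = O, third = C, role = role,
        edge1_from = e1$exposure_id, edge1_to = e1$outcome_id,
        edge1_beta = e1$beta, edge1_pval = e1$pval,
        edge2_from = e2$exposure_id, edge2_to = e2$outcome_id,
        edge2_beta = e2$beta, edge2_pval = e2$pval,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Assemble the causal-web trait graph
#'
#' For each significant exposure/outcome pair, the causal E->O edge is added
#' and every other trait appearing in the edge list is classified via
#' [classify_third_trait()]; supporting edges enter the graph labeled with
#' their motif (`confounder_link`, `intermediate_link`,
#' `reverse_intermediate_link`, `collider_link`). A trait shared between
#' pairs appears once as a node and accumulates one labeled edge set per
#' motif it participates in.
#'
#' @param pairs Data frame with columns exposure_id, outcome_id (one row per
#'   significant pair), or the `forest` table of an [screen_and_analyze()]
#'   result restricted to significant rows.
#' @param edges MR edge-list data frame.
#' @param p_threshold Retention threshold for third-trait edges (strict `<`).
#' @return Object of class `trait_graph`: `nodes` (id, role), `edges`
#'   (source, target, beta, pval, edge_role), `assignments` (per-pair role
#'   table), `role_counts` (named integer vector over the four roles).
#' @export
build_causal_web <- function(pairs, edges, p_threshold = 1e-5) {
  stopifnot(nrow(pairs) >= 1)
  if (any(edges$exposure_id == edges$outcome_id))
    stop("self-loop edge(s) in input", call. = FALSE)
  assignments <- list()
  edge_rows <- list()
  add_edge <- function(from, to, beta, pval, role) {
    edge_rows[[length(edge_rows) + 1]] <<- data.frame(
      source = from, target = to, beta = beta, pval = pval, edge_role = role,
      stringsAsFactors = FALSE)
  }
  all_traits <- unique(c(edges$exposure_id, edges$outcome_id,
                         pairs$exposure_id, pairs$outcome_id))
  for (i in seq_len(nrow(pairs))) {
    E <- pairs$exposure_id[i]; O <- pairs$outcome_id[i]
    causal <- .best_edge(edges, E, O)
    if (is.null(causal)) add_edge(E, O, NA_real_, NA_real_, "causal")
    else add_edge(E, O, causal$beta, causal$pval, "causal")
    for (C in setdiff(all_traits, c(E, O))) {
      a <- classify_third_trait(edges, E, O, C, p_threshold)
      if (is.null(a)) next
      assignments[[length(assignments) + 1]] <- a
      for (j in seq_len(nrow(a))) {
        role_lab <- paste0(a$role[j], "_link")
        add_edge(a$edge1_from[j], a$edge1_to[j], a$edge1_beta[j],
                 a$edge1_pval[j], role_lab)
        add_edge(a$edge2_from[j], a$edge2_to[j], a$edge2_beta[j],
                 a$edge2_pval[j], role_lab)
      }
    }
  }
  assignments <- if (length(assignments)) do.call(rbind, assignments)
  else data.frame()
  edge_df <- unique(do.call(rbind, edge_rows))
  rownames(edge_df) <- NULL
  node_ids <- unique(c(edge_df$source, edge_df$target))
  role <- rep("third", length(node_ids))
  role[node_ids %in% pairs$exposure_id] <- "exposure"
  role[node_ids %in% pairs$outcome_id] <- "outcome"
  counts <- vapply(names(.role_patterns), function(r)
    if (nrow(assignments)) sum(assignments$role == r) else 0L, integer(1))
  structure(list(
    nodes = data.frame(id = node_ids, role = role, stringsAsFactors = FALSE),
    edges = edge_df, assignments = assignments, role_counts = counts
  ), class = "trait_graph")
}

#' @export
print.trait_graph <- function(x, ...) {
  cat("trait_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("role counts:",
      paste(names(x$role_counts), x$role_counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
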