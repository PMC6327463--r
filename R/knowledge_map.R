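#' Construct a knowledge map
#'
#' A knowledge map is a set of N labelled concepts (genes, proteins, miRNAs,
#' phenotypes) plus a sparse directed, weighted edge set: the NxN relationship
#' matrix W of a fuzzy/neutrosophic cognitive map. Cell `[i, j]` holds the
#' causal effect of concept i ON concept j. Weights are real numbers in
#' `[-1, 1]`; an indeterminate ("I") relationship is stored as `NA`. A weight
#' of exactly 0 means "no known relationship" and is never stored as an edge.
#'
#' @param labels character vector of unique concept labels (whitespace is
#'   trimmed; comparison is case-sensitive, since gene symbols are
#'   case-meaningful).
#' @param edges a data frame with integer columns `from` and `to` (1-based
#'   node indices) and numeric `weight` (`NA` = indeterminate), or `NULL` for
#'   an edgeless map.
#' @return an object of class `knowledge_map`.
#' @examples
#' m <- knowledge_map(c("A", "B"), data.frame(from = 1, to = 2, weight = 0.5))
#' n_edges(m)
#' @export
knowledge_map <- function(labels, edges = NULL) {
  labels <- trimws(as.character(labels))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0))
  }
  edges <- data.frame(from = as.integer(edges$from),
                      to = as.integer(edges$to),
                      weight = as.numeric(edges$weight))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  map <- structure(list(labels = labels, edges = edges),
                   class = "knowledge_map")
  validate_knowledge_map(map)
}

#' @rdname knowledge_map
#' @param map a `knowledge_map`.
#' @export
validate_knowledge_map <- function(map) {
  labels <- map$labels
  edges <- map$edges
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop_ncm("map_error", "duplicate concept label: ",
             paste(unique(dup), collapse = ", "))
  }
  n <- length(labels)
  if (nrow(edges)) {
    bad <- edges$from < 1L | edges$from > n | edges$to < 1L | edges$to > n |
      is.na(edges$from) | is.na(edges$to)
    if (any(bad)) {
      stop_ncm("map_error", "edge endpoint out of range [1, ", n, "]")
    }
    if (anyDuplicated(edges[c("from", "to")])) {
      stop_ncm("map_error", "duplicate edge (same source and target)")
    }
    w <- edges$weight
    det <- !is.na(w)
    if (any(!is.finite(w[det]) | abs(w[det]) > 1)) {
      stop_ncm("map_error",
               "edge weights must be finite and within [-1, 1]")
    }
    if (any(w[det] == 0)) {
      stop_ncm("map_error",
               "zero weights mean 'no relationship' and are never stored")
    }
  }
  map
}

#' @rdname knowledge_map
#' @export
n_nodes <- function(map) length(map$labels)

#' @rdname knowledge_map
#' @export
n_edges <- function(map) nrow(map$edges)

#' @export
print.knowledge_map <- function(x, ...) {
  n_ind <- sum(is.na(x$edges$weight))
  cat(sprintf("knowledge_map: %d concepts, %d edges (%d indeterminate)\n",
              n_nodes(x), n_edges(x), n_ind))
  invisible(x)
}

#' Resolve indeterminate relationships to zero
#'
#' Converts a neutrosophic map into its fuzzy projection by dropping every
#' indeterminate ("I") edge: an indeterminate relationship contributes nothing
#' to the dynamics, and a weight of zero is represented as "no edge".
#' Determinate edges are untouched; the input map is not modified. Idempotent.
#'
#' @param map a `knowledge_map`.
#' @return a `knowledge_map` with no indeterminate edges.
#' @export
to_fuzzy <- function(map) {
  keep <- !is.na(map$edges$weight)
  if (all(keep)) return(map)
  knowledge_map(map$labels, map$edges[keep, , drop = FALSE])
}

#' Descriptive statistics of a knowledge map
#'
#' Counts nodes, stored edges and indeterminate edges, and computes mean
#' in-/out-degree (`n_edges / n_nodes`) and the positive/negative fractions of
#' the determinate edges. The positive fraction is the network's pretest
#' probability of a positive outcome prediction, used as the biased null of
#' the binomial validation test.
#'
#' Degrees are `NA` on an empty (0-node) map; sign fractions are `NA` when the
#' map has no determinate nonzero edge.
#'
#' @param map a `knowledge_map`.
#' @return an object of class `map_statistics`: a list with `n_nodes`,
#'   `n_edges`, `mean_in_degree`, `mean_out_degree`, `positive_fraction`,
#'   `negative_fraction`, `indeterminate_count`.
#' @export
compute_statistics <- function(map) {
  w <- map$edges$weight
  n <- n_nodes(map)
  e <- n_edges(map)
  det <- w[!is.na(w)]
  deg <- if (n > 0) e / n else NA_real_
  pos <- if (length(det) > 0) sum(det > 0) / length(det) else NA_real_
  structure(list(
    n_nodes = n,
    n_edges = e,
    mean_in_degree = deg,
    mean_out_degree = deg,
    positive_fraction = pos,
    negative_fraction = if (is.na(pos)) NA_real_ else 1 - pos,
    indeterminate_count = sum(is.na(w))
  ), class = "map_statistics")
}

#' @export
print.map_statistics <- function(x, ...) {
  cat(sprintf("nodes: %d\nedges: %d (indeterminate: %d)\n",
              x$n_nodes, x$n_edges, x$indeterminate_count))
  cat(sprintf("mean in-degree = mean out-degree: %s\n",
              format(x$mean_in_degree, digits = 6)))
  cat(sprintf("positive fraction: %s   negative fraction: %s\n",
              format(x$positive_fraction, digits = 6),
              format(x$negative_fraction, digits = 6)))
  invisible(x)
}

# classed conditions so callers / the CLI can map them to exit statuses
stop_ncm <- function(class, ...) {
  stop(structure(class = c(class, "ncm_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
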