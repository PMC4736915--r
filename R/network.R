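#' Bipartite network from a weighted incidence matrix
#'
#' Constructs the central data object of the package: an r x c matrix of
#' non-negative interaction weights between `r` row nodes (e.g. plants) and
#' `c` column nodes (e.g. pollinators), with node labels. A binary network is
#' simply the special case in which every weight is 0 or 1; all statistics
#' and optimizers treat it uniformly.
#'
#' @param weights Matrix (or object coercible to one) of non-negative finite
#'   numbers. Row/column names are used as node labels when present.
#' @param row_labels,col_labels Optional character vectors of node labels;
#'   default to the dimnames of `weights`, or `R1..Rr` / `C1..Cc`.
#' @return An object of class `bipartite_network`.
#' @export
#' @examples
#' net <- bipartite_network(matrix(c(1, 0, 0, 1), 2, 2))
#' total_weight(net)
bipartite_network <- function(weights, row_labels = NULL, col_labels = NULL) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(weights) <- "double"
  if (nrow(weights) < 1L || ncol(weights) < 1L) {
    stop("network must have at least one row and one column node", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("all weights must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop(
      "negative weights are not allowed: this modularity is only defined ",
      "for networks in which all connections are positive",
      call. = FALSE
    )
  }
  if (is.null(row_labels)) {
    row_labels <- rownames(weights)
    if (is.null(row_labels)) row_labels <- paste0("R", seq_len(nrow(weights)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(weights)
    if (is.null(col_labels)) col_labels <- paste0("C", seq_len(ncol(weights)))
  }
  row_labels <- as.character(row_labels)
  col_labels <- as.character(col_labels)
  if (length(row_labels) != nrow(weights) || length(col_labels) != ncol(weights)) {
    stop("label lengths do not match the matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("node labels must be unique within each class", call. = FALSE)
  }
  dimnames(weights) <- list(row_labels, col_labels)
  structure(list(weights = weights), class = "bipartite_network")
}

#' @export
dim.bipartite_network <- function(x) dim(x$weights)

#' @export
print.bipartite_network <- function(x, ...) {
  d <- dim(x)
  cat(
    "<bipartite_network> ", d[1L], " x ", d[2L],
    " nodes, total weight M = ", format(total_weight(x)),
    ", fill m = ", sum(x$weights > 0), "\n",
    sep = ""
  )
  invisible(x)
}

#' Network accessors
#'
#' `total_weight()` returns M, the sum of all entries (the fill m for a
#' binary matrix). `row_strength()` and `col_strength()` return the marginal
#' totals y and z, which generalize the binary node degrees k and d.
#'
#' @param net A `bipartite_network`.
#' @return A number (`total_weight`) or a named numeric vector.
#' @export
total_weight <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  sum(net$weights)
}

#' @rdname total_weight
#' @export
row_strength <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  rowSums(net$weights)
}

#' @rdname total_weight
#' @export
col_strength <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  colSums(net$weights)
}

#' Binarize a weighted network
#'
#' Any positive weight becomes 1, giving the binary incidence matrix whose
#' marginal totals are the node degrees. Idempotent on binary input.
#'
#' @param net A `bipartite_network`.
#' @return A binary `bipartite_network` with the same labels.
#' @export
binarize <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  w <- net$weights
  w[] <- as.double(w > 0)
  bipartite_network(w)
}

#' Drop empty rows and columns
#'
#' Rows and columns with no interaction data carry no information for module
#' detection and are removed before analysis. Removed labels are reported via
#' [message()].
#'
#' @param net A `bipartite_network`.
#' @return A `bipartite_network` with all-zero rows/columns removed.
#' @export
clean_network <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  w <- net$weights
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stop("network is empty after removing all-zero rows and columns", call. = FALSE)
  }
  if (all(keep_r) && all(keep_c)) {
    return(net)
  }
  dropped <- c(rownames(w)[!keep_r], colnames(w)[!keep_c])
  message("clean_network: removed ", length(dropped), " empty node(s): ",
          paste(dropped, collapse = ", "))
  bipartite_network(w[keep_r, keep_c, drop = FALSE])
}
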