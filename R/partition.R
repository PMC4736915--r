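#' Joint module assignment for a bipartite network
#'
#' A partition assigns one module label to every row node (the vector g) and
#' every column node (the vector h); a module is the joint set of row and
#' column nodes sharing a label. Labels are opaque identifiers: every
#' statistic in the package is invariant under relabelling. `NA` marks a node
#' whose label has not yet been set (used only during optimizer
#' initialization); metrics refuse incomplete partitions.
#'
#' @param row_modules,col_modules Atomic vectors of module labels, one per
#'   row/column node. Labels may be integers, characters or factors; they are
#'   recoded internally to integer codes over their union.
#' @return An object of class `bip_partition` with integer-coded
#'   `row_modules`, `col_modules` and the original `labels` in use.
#' @export
#' @examples
#' p <- bip_partition(c(1, 2), c(1, 2))
#' n_modules(p)
bip_partition <- function(row_modules, col_modules) {
  if (!is.atomic(row_modules) || !is.atomic(col_modules)) {
    stop("module labels must be atomic vectors", call. = FALSE)
  }
  r <- length(row_modules)
  f <- factor(c(as.character(row_modules), as.character(col_modules)))
  codes <- as.integer(f)
  structure(
    list(
      row_modules = codes[seq_len(r)],
      col_modules = codes[-seq_len(r)],
      labels = levels(f)
    ),
    class = "bip_partition"
  )
}

#' @export
print.bip_partition <- function(x, ...) {
  cat(
    "<bip_partition> ", length(x$row_modules), " row + ",
    length(x$col_modules), " column nodes in ", n_modules(x), " module(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of distinct modules in a partition
#'
#' @param part A `bip_partition`.
#' @return Integer count of distinct labels in use across both node classes.
#' @export
n_modules <- function(part) {
  stopifnot(inherits(part, "bip_partition"))
  length(unique(stats::na.omit(c(part$row_modules, part$col_modules))))
}

# All labels set?
partition_complete <- function(part) {
  !anyNA(part$row_modules) && !anyNA(part$col_modules)
}

# Relabel modules as 1..F in order of first appearance over (rows, columns).
# Two partitions are the same community structure iff their canonical integer
# vectors are identical.
canonicalize <- function(part) {
  all_lab <- c(part$row_modules, part$col_modules)
  codes <- match(all_lab, unique(all_lab[!is.na(all_lab)]))
  r <- length(part$row_modules)
  bip_partition(codes[seq_len(r)], codes[-seq_len(r)])
}

partition_signature <- function(part) {
  cp <- canonicalize(part)
  paste(c(cp$row_modules, "|", cp$col_modules), collapse = ",")
}

check_net_part <- function(net, part) {
  stopifnot(inherits(net, "bipartite_network"), inherits(part, "bip_partition"))
  d <- dim(net)
  if (length(part$row_modules) != d[1L] || length(part$col_modules) != d[2L]) {
    stop("partition dimensions do not match the network", call. = FALSE)
  }
  if (!partition_complete(part)) {
    stop("partition has unset (NA) labels", call. = FALSE)
  }
  invisible(TRUE)
}

# 0/1 indicator matrix: length(labels) x length(levels)
label_indicator <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}

#' Module membership indicator matrices
#'
#' Returns the binary label matrices used by the matrix (trace) form of the
#' modularity: `R` is F x r with one 1 per column (row-node memberships) and
#' `C` is c x F with one 1 per row (column-node memberships).
#'
#' @param part A complete `bip_partition`.
#' @return A list with elements `R`, `C` and the module `levels`.
#' @export
membership_matrices <- function(part) {
  stopifnot(inherits(part, "bip_partition"))
  if (!partition_complete(part)) {
    stop("partition has unset (NA) labels", call. = FALSE)
  }
  lev <- sort(unique(c(part$row_modules, part$col_modules)))
  list(
    R = t(label_indicator(part$row_modules, lev)),
    C = label_indicator(part$col_modules, lev),
    levels = lev
  )
}
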