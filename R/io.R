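#' Read a bipartite network from a delimited file
#'
#' Two dialects are supported. `"matrix"`: a TSV/CSV incidence matrix whose
#' first row holds column-node labels and first column holds row-node
#' labels, with non-negative numeric cells. `"edgelist"`: three columns
#' (row label, column label, weight); repeated (row, column) pairs have
#' their weights summed. Lines starting with `#` are ignored, which is how
#' fixture provenance headers are carried.
#'
#' @param path Path to the file.
#' @param dialect `"matrix"` (default) or `"edgelist"`.
#' @param sep Field separator; by default inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @return A `bipartite_network`.
#' @export
read_network <- function(path, dialect = c("matrix", "edgelist"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  if (dialect == "matrix") {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      stop("matrix file contains non-numeric cells (ragged or malformed rows?)",
           call. = FALSE)
    }
    bipartite_network(m)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) != 3L) {
      stop("edge list must have exactly three columns: row label, column ",
           "label, weight", call. = FALSE)
    }
    names(df) <- c("row", "col", "weight")
    if (!is.numeric(df$weight)) {
      stop("edge-list weights must be numeric", call. = FALSE)
    }
    if (any(df$weight < 0)) {
      stop("negative weights are not allowed", call. = FALSE)
    }
    rl <- unique(as.character(df$row))
    cl <- unique(as.character(df$col))
    m <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
    for (i in seq_len(nrow(df))) {
      m[as.character(df$row[i]), as.character(df$col[i])] <-
        m[as.character(df$row[i]), as.character(df$col[i])] + df$weight[i]
    }
    bipartite_network(m)
  }
}

#' Write a bipartite network to a delimited file
#'
#' Inverse of [read_network()]; `read_network(write_network(net, path))`
#' restores the network exactly, including label order.
#'
#' @param net A `bipartite_network`.
#' @param path Output path.
#' @param dialect `"matrix"` (default) or `"edgelist"` (positive cells only).
#' @param sep Field separator; inferred from the extension by default.
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, dialect = c("matrix", "edgelist"),
                          sep = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  dialect <- match.arg(dialect)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  if (dialect == "matrix") {
    utils::write.table(net$weights, path, sep = sep, quote = FALSE,
                       col.names = NA)
  } else {
    idx <- which(net$weights > 0, arr.ind = TRUE)
    df <- data.frame(
      row = rownames(net$weights)[idx[, 1L]],
      col = colnames(net$weights)[idx[, 2L]],
      weight = net$weights[idx]
    )
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a partition file
#'
#' A partition file is a TSV with columns `node_id`, `node_class`
#' (`row`/`col`) and `module_label`; every node of the network appears
#' exactly once. `read_partition()` reorders the file rows to match the
#' network's label order.
#'
#' @param path Path to the partition TSV.
#' @param net The `bipartite_network` the partition belongs to.
#' @return A `bip_partition`.
#' @export
read_partition <- function(path, net) {
  stopifnot(inherits(net, "bipartite_network"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("node_id", "node_class", "module_label")
  if (!all(need %in% names(df))) {
    stop("partition file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- df[df$node_class == "row", ]
  cols <- df[df$node_class == "col", ]
  rl <- rownames(net$weights)
  cl <- colnames(net$weights)
  if (!setequal(rows$node_id, rl) || !setequal(cols$node_id, cl) ||
      nrow(rows) != length(rl) || nrow(cols) != length(cl)) {
    stop("partition file does not cover every network node exactly once",
         call. = FALSE)
  }
  bip_partition(rows$module_label[match(rl, rows$node_id)],
                cols$module_label[match(cl, cols$node_id)])
}

#' @rdname read_partition
#' @param part A complete `bip_partition`.
#' @export
write_partition <- function(part, path, net) {
  stopifnot(inherits(part, "bip_partition"), inherits(net, "bipartite_network"))
  check_net_part(net, part)
  df <- data.frame(
    node_id = c(rownames(net$weights), colnames(net$weights)),
    node_class = c(rep("row", nrow(net$weights)), rep("col", ncol(net$weights))),
    module_label = c(part$row_modules, part$col_modules)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled worked-example network (synthetic)
#'
#' A small 10 x 12 weighted bipartite network bundled for worked examples,
#' documentation and the command-line interface tests, shaped like a field
#' visitation web (integer counts, a few modules, moderate noise). It is
#' *synthetic*: drawn once, at a fixed seed, from the package's own
#' planted-partition generator ([plant_modules()] plus [rewire_noise()]) and
#' stored under `inst/extdata/` with its generation provenance in the file
#' header. It stands in for a published visitation matrix and carries no
#' field data.
#'
#' @param representation `"weighted"` (default) or `"binary"`.
#' @return A 10 x 12 `bipartite_network`.
#' @export
worked_example_network <- function(representation = c("weighted", "binary")) {
  representation <- match.arg(representation)
  path <- system.file("extdata", "worked_example_10x12_synthetic.tsv",
                      package = "bipartmod", mustWork = TRUE)
  net <- read_network(path, "matrix")
  if (representation == "binary") binarize(net) else net
}
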