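# Per-module aggregates shared by all modularity statistics:
#   w   within-module weight (row nodes of module t to column nodes of t)
#   Y   summed row marginals of the row nodes in t
#   Z   summed column marginals of the column nodes in t
module_aggregates <- function(net, part) {
  check_net_part(net, part)
  W <- net$weights
  lev <- sort(unique(c(part$row_modules, part$col_modules)))
  Rm <- label_indicator(part$row_modules, lev) # r x F
  Cm <- label_indicator(part$col_modules, lev) # c x F
  X <- crossprod(Rm, W %*% Cm)                 # F x F cross-module weight
  list(
    w = diag(X),
    X = X,
    Y = as.vector(crossprod(Rm, rowSums(W))),
    Z = as.vector(crossprod(Cm, colSums(W))),
    M = sum(W),
    levels = lev
  )
}

#' Weighted bipartite modularity
#'
#' The weighted extension of Barber's bipartite modularity: the fraction of
#' total interaction weight that falls within modules, in excess of the
#' expectation of a null model that preserves the marginal totals,
#' \deqn{Q_W = \frac{1}{M} \sum_{u,v} \left(W_{uv} - \frac{y_u z_v}{M}\right)
#'   \delta(g_u, h_v),}
#' where M is the total edge weight, y and z the row and column marginal
#' totals, and \eqn{\delta} compares the module labels of row node u and
#' column node v. On a binary matrix this is exactly Barber's modularity.
#'
#' Two algebraically identical evaluation routes are provided: the explicit
#' double sum over all node pairs, and the vectorized trace form
#' \eqn{Q_W = \mathrm{tr}(R (W - E) C)/M} built on the module membership
#' matrices; `form` selects between them (they agree to numerical rounding
#' and the default trace form is the faster).
#'
#' @param net A `bipartite_network` with positive total weight.
#' @param part A complete `bip_partition` matching the network's dimensions.
#' @param form `"trace"` (default) or `"sum"`.
#' @return Q, a number in \[-1, 1\]. Zero for the single-module partition.
#' @seealso [binary_modularity()], [max_modularity()], [realized_modularity()]
#' @export
#' @examples
#' net <- bipartite_network(diag(2))
#' weighted_modularity(net, bip_partition(1:2, 1:2)) # 0.5
weighted_modularity <- function(net, part, form = c("trace", "sum")) {
  form <- match.arg(form)
  check_net_part(net, part)
  M <- total_weight(net)
  if (M <= 0) {
    stop("modularity is undefined for a network with zero total weight", call. = FALSE)
  }
  if (form == "trace") {
    ag <- module_aggregates(net, part)
    (sum(ag$w) - sum(ag$Y * ag$Z) / M) / M
  } else {
    W <- net$weights
    E <- outer(rowSums(W), colSums(W)) / M
    same <- outer(part$row_modules, part$col_modules, "==")
    sum((W - E)[same]) / M
  }
}

#' Binary (Barber's) bipartite modularity
#'
#' Modularity of the binarized network: the incidence matrix is reduced to
#' presence/absence (any positive weight becomes 1) and scored with the same
#' null model, which then uses node degrees and the number of edges.
#'
#' @inheritParams weighted_modularity
#' @return Q_B, a number in \[-1, 1\].
#' @export
binary_modularity <- function(net, part, form = c("trace", "sum")) {
  weighted_modularity(binarize(net), part, form = form)
}

#' Maximum attainable modularity of a partition
#'
#' The modularity the same module assignment would score in the "perfectly
#' mixed" network in which every edge falls within a module:
#' \deqn{Q_{max} = \frac{1}{M}\left(M - \sum_{u,v} \frac{y_u z_v}{M}
#'   \delta(g_u, h_v)\right).}
#' Used to normalize Q for comparison across networks of different size and
#' fill. For any partition, \eqn{Q \le Q_{max}}.
#'
#' @inheritParams weighted_modularity
#' @return Q_max. Zero for the single-module partition.
#' @export
max_modularity <- function(net, part) {
  check_net_part(net, part)
  M <- total_weight(net)
  if (M <= 0) {
    stop("modularity is undefined for a network with zero total weight", call. = FALSE)
  }
  ag <- module_aggregates(net, part)
  1 - sum(ag$Y * ag$Z) / M^2
}

#' Normalized modularity
#'
#' `Q / Q_max`: the achieved fraction of the modularity this partition could
#' score in a perfectly mixed network, comparable across networks. When
#' `Q_max` is zero (the single-module partition) the ratio is undefined and
#' `NA` is returned as an explicit undefined marker rather than a number.
#'
#' @inheritParams weighted_modularity
#' @return Q_norm (at most 1), or `NA_real_` when undefined.
#' @export
normalized_modularity <- function(net, part) {
  qmax <- max_modularity(net, part)
  if (abs(qmax) <= modularity_tolerance()) {
    return(NA_real_)
  }
  weighted_modularity(net, part) / qmax
}

#' Realized modularity
#'
#' A posterior, null-model-free view of partition quality:
#' \deqn{Q'_R = 2\frac{H}{M} - 1,} where H is the total within-module edge
#' weight. It is 1 when every interaction joins nodes of the same module,
#' 0 when half of the edge weight is within modules, and -1 when none is.
#'
#' @inheritParams weighted_modularity
#' @return Q'_R in \[-1, 1\].
#' @export
realized_modularity <- function(net, part) {
  check_net_part(net, part)
  M <- total_weight(net)
  if (M <= 0) {
    stop("realized modularity is undefined for a network with zero total weight",
         call. = FALSE)
  }
  ag <- module_aggregates(net, part)
  2 * sum(ag$w) / M - 1
}

#' Normalized mutual information between two partitions
#'
#' Compares two module assignments of the same network over all n = r + c
#' nodes of both classes jointly. With confusion matrix N (nodes in module i
#' of A and module j of B), row sums N_i and column sums N_j,
#' \deqn{NMI(A;B) = \frac{-2 \sum_{ij} N_{ij}
#'   \log(N_{ij} n / N_i N_j)}{\sum_i N_i \log(N_i/n) +
#'   \sum_j N_j \log(N_j/n)}.}
#' NMI is 1 iff the partitions are identical up to relabelling and 0 when
#' they share no information. Terms with \eqn{N_{ij} = 0} contribute zero.
#' The value does not depend on the logarithm base (numerator and
#' denominator share it); `base` is exposed only so that this invariance can
#' be asserted. When both partitions are the single-module partition the
#' ratio is 0/0 but the partitions are identical, so NMI is defined as 1.
#'
#' @param part_a,part_b Complete `bip_partition`s over the same node set
#'   (equal numbers of row and column nodes).
#' @param base Logarithm base (default natural log).
#' @return NMI in \[0, 1\]; symmetric in its arguments.
#' @export
nmi <- function(part_a, part_b, base = exp(1)) {
  stopifnot(inherits(part_a, "bip_partition"), inherits(part_b, "bip_partition"))
  if (length(part_a$row_modules) != length(part_b$row_modules) ||
      length(part_a$col_modules) != length(part_b$col_modules)) {
    stop("partitions do not cover the same node set", call. = FALSE)
  }
  if (!partition_complete(part_a) || !partition_complete(part_b)) {
    stop("partition has unset (NA) labels", call. = FALSE)
  }
  la <- c(part_a$row_modules, part_a$col_modules)
  lb <- c(part_b$row_modules, part_b$col_modules)
  n <- length(la)
  N <- table(la, lb)
  Ni <- rowSums(N)
  Nj <- colSums(N)
  den <- sum(Ni * log(Ni / n, base = base)) + sum(Nj * log(Nj / n, base = base))
  if (abs(den) < .Machine$double.eps * n) {
    # both partitions put every node in one module: identical structures
    return(1)
  }
  pos <- N > 0
  if (all(rowSums(pos) == 1) && all(colSums(pos) == 1)) {
    # one-to-one module correspondence: identical up to relabelling
    return(1)
  }
  num <- -2 * sum(N[pos] * log(N[pos] * n / outer(Ni, Nj)[pos], base = base))
  min(1, max(0, num / den))
}
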