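# ---------------------------------------------------------------------------
# Internal engine. Works on the raw weight matrix W with marginals y, z and
# total M, and on integer label vectors g (rows) and h (columns); NA marks a
# node not yet assigned. All randomness (tie-breaks, restarts) is drawn from
# the current RNG stream, so a single set.seed() upstream makes whole runs
# reproducible bit for bit.
# ---------------------------------------------------------------------------

mod_from_labels <- function(W, y, z, M, g, h) {
  lev <- sort(unique(c(g, h)))
  Rm <- label_indicator(g, lev)
  Cm <- label_indicator(h, lev)
  w_within <- sum(crossprod(Rm, W %*% Cm) * diag(length(lev)))
  Yl <- as.vector(crossprod(Rm, y))
  Zl <- as.vector(crossprod(Cm, z))
  (w_within - sum(Yl * Zl) / M) / M
}

# One half-sweep: every column node adopts the label h maximizing
# N_xh - Y_h z_x / M over the labels present among row nodes. All column
# scores depend only on the (fixed) row labels, so the class updates jointly;
# ties are broken uniformly at random from the run's RNG stream.
update_col_labels <- function(W, y, z, M, g, h) {
  lev <- sort(unique(g))
  Rm <- label_indicator(g, lev)                  # r x F
  S <- crossprod(W, Rm) - tcrossprod(z, as.vector(crossprod(Rm, y))) / M
  lev[max.col(S, ties.method = "random")]
}

update_row_labels <- function(W, y, z, M, g, h) {
  lev <- sort(unique(h))
  Cm <- label_indicator(h, lev)                  # c x F
  S <- W %*% Cm - tcrossprod(y, as.vector(crossprod(Cm, z))) / M
  lev[max.col(S, ties.method = "random")]
}

# Stage 1: alternate the two half-sweeps until a full double sweep gains no
# more than `tol` modularity. The unassigned class (if any) is updated first.
propagate_core <- function(W, y, z, M, g, h, tol) {
  cols_first <- anyNA(h) || !anyNA(g)
  if (anyNA(g) && anyNA(h)) {
    stop("at least one node class must carry labels before propagation",
         call. = FALSE)
  }
  q <- -Inf
  repeat {
    if (cols_first) {
      h <- update_col_labels(W, y, z, M, g, h)
      g <- update_row_labels(W, y, z, M, g, h)
    } else {
      g <- update_row_labels(W, y, z, M, g, h)
      h <- update_col_labels(W, y, z, M, g, h)
    }
    q_new <- mod_from_labels(W, y, z, M, g, h)
    if (is.finite(q) && q_new - q <= tol) {
      return(list(g = g, h = h, q = q_new))
    }
    q <- q_new
  }
}

# Gain in modularity from merging every ordered pair of modules, from the
# module-level aggregates: merging a and b adds the cross-module weight
# X[a,b] + X[b,a] and the null-model term (Y_a Z_b + Y_b Z_a)/M.
merge_gains <- function(W, y, z, M, g, h) {
  lev <- sort(unique(c(g, h)))
  Rm <- label_indicator(g, lev)
  Cm <- label_indicator(h, lev)
  X <- crossprod(Rm, W %*% Cm)
  Yl <- as.vector(crossprod(Rm, y))
  Zl <- as.vector(crossprod(Cm, z))
  YZ <- tcrossprod(Yl, Zl)
  dq <- (X + t(X) - (YZ + t(YZ)) / M) / M
  diag(dq) <- -Inf
  list(dq = dq, levels = lev)
}

# Stage 2: merge mutually best module pairs whose gain exceeds `tol`.
# A pair (a, b) merges only if each is the other's best merge partner, which
# enforces the rule that no third module offers a larger gain with either;
# all such (necessarily disjoint) pairs are applied in one pass.
agglomerate_core <- function(W, y, z, M, g, h, tol) {
  mg <- merge_gains(W, y, z, M, g, h)
  nl <- length(mg$levels)
  if (nl < 2L) {
    return(list(g = g, h = h, q = mod_from_labels(W, y, z, M, g, h), merged = FALSE))
  }
  best <- max.col(mg$dq, ties.method = "first")
  best_gain <- mg$dq[cbind(seq_len(nl), best)]
  a <- which(best[best] == seq_len(nl) & best_gain > tol & seq_len(nl) < best)
  if (length(a) == 0L) {
    return(list(g = g, h = h, q = mod_from_labels(W, y, z, M, g, h), merged = FALSE))
  }
  for (i in a) {
    from <- mg$levels[best[i]]
    to <- mg$levels[i]
    g[g == from] <- to
    h[h == from] <- to
  }
  list(g = g, h = h, q = mod_from_labels(W, y, z, M, g, h), merged = TRUE)
}

# Full LPAwb+ engine: repeat stage 1 then stage 2 until no merge is applied.
lpawb_core <- function(W, g, h, tol) {
  y <- rowSums(W)
  z <- colSums(W)
  M <- sum(W)
  if (M <= 0) {
    stop("cannot optimize a network with zero total weight", call. = FALSE)
  }
  trace <- numeric(0)
  repeat {
    st <- propagate_core(W, y, z, M, g, h, tol)
    g <- st$g
    h <- st$h
    trace <- c(trace, stage1 = st$q)
    ag <- agglomerate_core(W, y, z, M, g, h, tol)
    if (!ag$merged) {
      return(list(g = g, h = h, q = st$q, trace = trace))
    }
    g <- ag$g
    h <- ag$h
    trace <- c(trace, stage2 = ag$q)
  }
}

unique_init_labels <- function(r, c) {
  # unique labels on the smaller class (rows on a tie); the other class is
  # left unassigned and resolved by its first propagation half-sweep
  if (r <= c) {
    list(g = seq_len(r), h = rep(NA_integer_, c))
  } else {
    list(g = rep(NA_integer_, r), h = seq_len(c))
  }
}

make_result <- function(net, g, h, q, trace, algorithm, seed, restarts = NULL) {
  part <- canonicalize(bip_partition(g, h))
  structure(
    list(
      partition = part,
      modularity = q,
      n_modules = n_modules(part),
      trace = trace,
      algorithm = algorithm,
      seed = seed,
      restarts = restarts
    ),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(
    "<optimization_result> ", x$algorithm, ": Q = ", format(x$modularity),
    " with ", x$n_modules, " module(s)",
    if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n",
    sep = ""
  )
  invisible(x)
}

# ---------------------------------------------------------------------------
# User-facing operations
# ---------------------------------------------------------------------------

#' Initialize module labels for the optimizer
#'
#' `"unique"` mode gives each node of the smaller class its own label and
#' leaves the larger class unset (`NA`), to be resolved by the first
#' propagation sweep; this is the canonical LPAwb+ start and bounds the
#' module count by min(r, c). `"random_k"` mode draws every node's label
#' uniformly from `mu` possible labels and is the restart initialization
#' used by [dirtlpawb_plus()].
#'
#' @param net A `bipartite_network`.
#' @param mode `"unique"` or `"random_k"`.
#' @param mu Number of labels to draw from in `"random_k"` mode; must not
#'   exceed min(r, c).
#' @param seed Optional integer seed for the draw.
#' @return A `bip_partition` (possibly with `NA` labels in `"unique"` mode).
#' @export
initialize_labels <- function(net, mode = c("unique", "random_k"), mu = NULL,
                              seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  mode <- match.arg(mode)
  d <- dim(net)
  if (mode == "unique") {
    init <- unique_init_labels(d[1L], d[2L])
    return(bip_partition(init$g, init$h))
  }
  if (is.null(mu) || mu < 1) {
    stop("`mu` must be a positive integer in random_k mode", call. = FALSE)
  }
  if (mu > min(d)) {
    stop("`mu` cannot exceed min(r, c), the maximum number of modules",
         call. = FALSE)
  }
  with_seed(seed, {
    bip_partition(sample.int(mu, d[1L], replace = TRUE),
                  sample.int(mu, d[2L], replace = TRUE))
  })
}

#' Label-propagation stage of LPAwb+
#'
#' Runs the "bottom-up" stage alone: alternating half-sweeps in which every
#' column node, then every row node, adopts the label that maximizes its own
#' modularity contribution given the other class, until a full double sweep
#' improves modularity by no more than the package tolerance. Modularity
#' never decreases across sweeps; a partition already at a local optimum is
#' returned unchanged.
#'
#' @param net A `bipartite_network`.
#' @param part A `bip_partition`; at least one class must be fully labelled.
#' @param seed Optional integer seed (tie-breaks are random).
#' @param tolerance Minimum modularity gain counted as an improvement.
#' @return A list with the updated `partition` and its `modularity`.
#' @export
propagate_labels <- function(net, part, seed = NULL,
                             tolerance = modularity_tolerance()) {
  stopifnot(inherits(net, "bipartite_network"), inherits(part, "bip_partition"))
  d <- dim(net)
  if (length(part$row_modules) != d[1L] || length(part$col_modules) != d[2L]) {
    stop("partition dimensions do not match the network", call. = FALSE)
  }
  W <- net$weights
  st <- with_seed(seed, propagate_core(W, rowSums(W), colSums(W), sum(W),
                                       part$row_modules, part$col_modules,
                                       tolerance))
  list(partition = canonicalize(bip_partition(st$g, st$h)), modularity = st$q)
}

#' Agglomeration stage of LPAwb+
#'
#' Runs the "top-down" stage alone: module pairs that are each other's best
#' merge partner and whose merger increases modularity by more than the
#' tolerance are merged in one pass. If no pair qualifies the partition is
#' returned unchanged.
#'
#' @inheritParams propagate_labels
#' @param part A complete `bip_partition`.
#' @return A list with the updated `partition`, its `modularity`, and
#'   `merged` (whether any merge was applied).
#' @export
agglomerate_modules <- function(net, part, tolerance = modularity_tolerance()) {
  check_net_part(net, part)
  W <- net$weights
  ag <- agglomerate_core(W, rowSums(W), colSums(W), sum(W),
                         part$row_modules, part$col_modules, tolerance)
  list(partition = canonicalize(bip_partition(ag$g, ag$h)),
       modularity = ag$q, merged = ag$merged)
}

#' LPAwb+: weighted modularity maximization by label propagation
#'
#' Alternates the label-propagation stage and the agglomeration stage until
#' neither can increase modularity beyond the tolerance. On binary input the
#' marginal totals are the node degrees and the procedure is the binary
#' label-propagation algorithm it generalizes.
#'
#' @param net A `bipartite_network` with positive total weight (clean it
#'   first with [clean_network()] if it may contain empty rows/columns).
#' @param seed Optional integer seed making the run fully reproducible.
#' @param init Optional starting `bip_partition`; by default the unique-label
#'   initialization of [initialize_labels()].
#' @param tolerance Minimum modularity gain counted as an improvement.
#' @return An `optimization_result`: `partition`, `modularity`, `n_modules`,
#'   the per-phase modularity `trace`, `algorithm` and `seed`.
#' @export
#' @examples
#' net <- bipartite_network(rbind(c(3, 2, 0, 0), c(2, 3, 0, 0),
#'                                c(0, 0, 3, 2), c(0, 0, 2, 3)))
#' lpawb_plus(net, seed = 1)
lpawb_plus <- function(net, seed = NULL, init = NULL,
                       tolerance = modularity_tolerance()) {
  stopifnot(inherits(net, "bipartite_network"))
  d <- dim(net)
  if (is.null(init)) {
    init <- initialize_labels(net, "unique")
  }
  if (length(init$row_modules) != d[1L] || length(init$col_modules) != d[2L]) {
    stop("init partition dimensions do not match the network", call. = FALSE)
  }
  res <- with_seed(seed, lpawb_core(net$weights, init$row_modules,
                                    init$col_modules, tolerance))
  make_result(net, res$g, res$h, res$q, res$trace, "LPAwb+", seed)
}

#' DIRTLPAwb+: restart sweep over random label initializations
#'
#' Runs [lpawb_plus()] once from the unique-label start to fix an upper
#' limit on the number of modules, then re-runs it `reps` times for every
#' label-pool size mu between `min(min_modules, limit)` and that limit, each
#' time from labels drawn uniformly at random from mu values on both node
#' classes. The best partition over all runs is returned, so the result can
#' never score below the plain LPAwb+ run.
#'
#' @inheritParams lpawb_plus
#' @param reps Number of restarts per label-pool size (default 10).
#' @param min_modules Smallest label-pool size to sweep from (default 4);
#'   merging may still produce fewer modules than this.
#' @return An `optimization_result`; `$restarts` records the label-pool
#'   size, repetition and modularity of every restart.
#' @export
dirtlpawb_plus <- function(net, reps = 10, min_modules = 4, seed = NULL,
                           tolerance = modularity_tolerance()) {
  stopifnot(inherits(net, "bipartite_network"))
  if (reps < 1) {
    stop("`reps` must be at least 1", call. = FALSE)
  }
  if (min_modules < 1) {
    stop("`min_modules` must be at least 1", call. = FALSE)
  }
  d <- dim(net)
  W <- net$weights
  with_seed(seed, {
    init <- unique_init_labels(d[1L], d[2L])
    base <- lpawb_core(W, init$g, init$h, tolerance)
    best <- base
    limit <- length(unique(c(base$g, base$h)))
    lo <- min(min_modules, limit)
    mus <- seq.int(lo, limit)
    restarts <- data.frame(
      mu = rep(mus, each = reps),
      rep = rep(seq_len(reps), length(mus)),
      modularity = NA_real_
    )
    k <- 0L
    for (mu in mus) {
      for (i in seq_len(reps)) {
        g0 <- sample.int(mu, d[1L], replace = TRUE)
        h0 <- sample.int(mu, d[2L], replace = TRUE)
        run <- lpawb_core(W, g0, h0, tolerance)
        k <- k + 1L
        restarts$modularity[k] <- run$q
        if (run$q > best$q + tolerance) {
          best <- run
        }
      }
    }
    make_result(net, best$g, best$h, best$q, best$trace, "DIRTLPAwb+", seed,
                restarts = restarts)
  })
}
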