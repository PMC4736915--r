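#' Benchmark recovery indicators against a planted partition
#'
#' The three indicators used to score module recovery on synthetic networks:
#' the ratio of detected to planted module counts, the ratio of detected to
#' planted modularity, and the NMI between the detected and planted
#' partitions. The planted modularity is evaluated on the network as
#' analysed (i.e. after any noise rewiring), so the modularity ratio can
#' exceed 1 when noise has made the planted labels suboptimal. Perfect
#' recovery gives (1, 1, 1).
#'
#' @param planted A `planted_network`.
#' @param result An `optimization_result` computed on `planted$network`.
#' @return Named numeric vector `c(module_ratio, modularity_ratio, nmi)`;
#'   the modularity ratio is `NA` if the planted partition scores zero.
#' @export
benchmark_indicators <- function(planted, result) {
  stopifnot(inherits(planted, "planted_network"),
            inherits(result, "optimization_result"))
  q_planted <- weighted_modularity(planted$network, planted$partition)
  q_ratio <- if (abs(q_planted) <= modularity_tolerance()) {
    NA_real_
  } else {
    result$modularity / q_planted
  }
  c(
    module_ratio = result$n_modules / n_modules(planted$partition),
    modularity_ratio = q_ratio,
    nmi = nmi(result$partition, planted$partition)
  )
}

run_algorithm <- function(net, algorithm, seed, ...) {
  fun <- switch(
    algorithm,
    "lpawb+" = lpawb_plus,
    "dirtlpawb+" = dirtlpawb_plus,
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
  args <- list(...)
  args <- args[names(args) %in% names(formals(fun))]
  do.call(fun, c(list(net, seed = seed), args))
}

#' Repeated seeded runs of a maximization algorithm
#'
#' The repeated-run protocol used to assess a stochastic maximizer on one
#' network: the algorithm is run `n_runs` times with seeds
#' `base_seed .. base_seed + n_runs - 1`, and all modularity scores are kept
#' together with every distinct best partition (distinct up to module
#' relabelling; several runs may tie at the maximum with different
#' structures).
#'
#' @param net A `bipartite_network`.
#' @param algorithm `"dirtlpawb+"` (default) or `"lpawb+"`.
#' @param n_runs Number of runs (default 100).
#' @param base_seed First seed.
#' @param ... Further arguments passed to the algorithm (e.g. `reps`).
#' @return An object of class `repeated_runs`: per-run `modularity` and
#'   `n_modules`, `max_modularity`, `median_modularity`, `modules_at_max`,
#'   and `best_partitions` (list of distinct `bip_partition`s at the max).
#' @export
repeated_runs <- function(net, algorithm = c("dirtlpawb+", "lpawb+"),
                          n_runs = 100, base_seed = 1, ...) {
  stopifnot(inherits(net, "bipartite_network"))
  algorithm <- match.arg(algorithm)
  if (n_runs < 1) {
    stop("`n_runs` must be at least 1", call. = FALSE)
  }
  seeds <- base_seed + seq_len(n_runs) - 1
  qs <- numeric(n_runs)
  mods <- integer(n_runs)
  results <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    res <- run_algorithm(net, algorithm, seeds[i], ...)
    qs[i] <- res$modularity
    mods[i] <- res$n_modules
    results[[i]] <- res
  }
  tol <- modularity_tolerance()
  at_max <- which(qs >= max(qs) - tol)
  sigs <- vapply(results[at_max],
                 function(r) partition_signature(r$partition), character(1))
  best <- lapply(results[at_max[!duplicated(sigs)]],
                 function(r) r$partition)
  structure(
    list(
      algorithm = algorithm,
      seeds = seeds,
      modularity = qs,
      n_modules = mods,
      max_modularity = max(qs),
      median_modularity = stats::median(qs),
      modules_at_max = mods[which.max(qs)],
      best_partitions = best
    ),
    class = "repeated_runs"
  )
}

#' @export
print.repeated_runs <- function(x, ...) {
  cat(
    "<repeated_runs> ", x$algorithm, ", ", length(x$modularity), " runs: ",
    "max Q = ", format(x$max_modularity),
    " (", x$modules_at_max, " modules, ",
    length(x$best_partitions), " distinct best partition(s)), ",
    "median Q = ", format(x$median_modularity), "\n",
    sep = ""
  )
  invisible(x)
}

#' Contrast the binary and weighted representations of one network
#'
#' Optimizes modularity separately on the binarized and on the weighted
#' representation of the network (repeated seeded runs each), then compares
#' the two best partitions: their NMI over all r + c nodes, and the change
#' in normalized modularity `delta_q_norm = Qnorm_weighted - Qnorm_binary`.
#' On an already-binary network the two representations coincide, so
#' NMI = 1 and `delta_q_norm` = 0.
#'
#' @inheritParams repeated_runs
#' @return A list: `binary` and `weighted` (the two `repeated_runs`
#'   objects), `q_norm_binary`, `q_norm_weighted`, `delta_q_norm` and `nmi`.
#' @export
binary_vs_weighted <- function(net, algorithm = c("dirtlpawb+", "lpawb+"),
                               n_runs = 100, base_seed = 1, ...) {
  stopifnot(inherits(net, "bipartite_network"))
  algorithm <- match.arg(algorithm)
  bnet <- binarize(net)
  rb <- repeated_runs(bnet, algorithm, n_runs = n_runs, base_seed = base_seed, ...)
  rw <- repeated_runs(net, algorithm, n_runs = n_runs, base_seed = base_seed, ...)
  pb <- rb$best_partitions[[1L]]
  pw <- rw$best_partitions[[1L]]
  qnb <- normalized_modularity(bnet, pb)
  qnw <- normalized_modularity(net, pw)
  list(
    binary = rb,
    weighted = rw,
    q_norm_binary = qnb,
    q_norm_weighted = qnw,
    delta_q_norm = qnw - qnb,
    nmi = nmi(pw, pb)
  )
}

#' Cross-algorithm, cross-representation comparison report
#'
#' Runs the repeated-run protocol for every requested algorithm on both the
#' binary and the weighted representation of a network and assembles the
#' summary used for cross-method comparison: per-cell maximum and median
#' modularity, module count at the maximum, the number of distinct best
#' partitions, a symmetric NMI table between all best partitions, and the
#' per-algorithm change in normalized modularity between representations.
#'
#' @inheritParams repeated_runs
#' @param algorithms Character vector of algorithms to compare.
#' @return An object of class `comparison_report` with `summary` (data
#'   frame), `nmi` (matrix), `delta_q_norm` (named vector) and `cells`
#'   (the underlying `repeated_runs` objects).
#' @export
comparison_report <- function(net, algorithms = c("lpawb+", "dirtlpawb+"),
                              n_runs = 100, base_seed = 1, ...) {
  stopifnot(inherits(net, "bipartite_network"))
  reps <- c("binary", "weighted")
  cells <- list()
  summary <- NULL
  for (alg in algorithms) {
    for (repr in reps) {
      use_net <- if (repr == "binary") binarize(net) else net
      cell <- repeated_runs(use_net, alg, n_runs = n_runs,
                            base_seed = base_seed, ...)
      key <- paste(alg, repr, sep = ".")
      cells[[key]] <- cell
      summary <- rbind(summary, data.frame(
        algorithm = alg,
        representation = repr,
        max_modularity = cell$max_modularity,
        median_modularity = cell$median_modularity,
        modules_at_max = cell$modules_at_max,
        n_best_partitions = length(cell$best_partitions),
        stringsAsFactors = FALSE
      ))
    }
  }
  keys <- names(cells)
  nm <- matrix(NA_real_, length(keys), length(keys),
               dimnames = list(keys, keys))
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      nm[i, j] <- nmi(cells[[i]]$best_partitions[[1L]],
                      cells[[j]]$best_partitions[[1L]])
    }
  }
  dqn <- vapply(algorithms, function(alg) {
    qb <- normalized_modularity(binarize(net),
                                cells[[paste(alg, "binary", sep = ".")]]$best_partitions[[1L]])
    qw <- normalized_modularity(net,
                                cells[[paste(alg, "weighted", sep = ".")]]$best_partitions[[1L]])
    qw - qb
  }, numeric(1))
  structure(
    list(summary = summary, nmi = nm, delta_q_norm = dqn, cells = cells,
         n_runs = n_runs, base_seed = base_seed),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$n_runs, " runs per cell\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write / read a comparison report
#'
#' `write_report()` serializes a `comparison_report` to a TSV summary table
#' plus a JSON file holding the full content (per-run modularity scores,
#' best partition label vectors, NMI table); `read_report()` restores the
#' serializable content from the JSON. The round trip is lossless for every
#' serialized field.
#'
#' @param report A `comparison_report`.
#' @param tsv,json Output paths.
#' @return `write_report()` returns the paths invisibly; `read_report()`
#'   a `comparison_report`.
#' @export
write_report <- function(report, tsv, json) {
  stopifnot(inherits(report, "comparison_report"))
  utils::write.table(report$summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  payload <- list(
    summary = report$summary,
    nmi = report$nmi,
    delta_q_norm = as.list(report$delta_q_norm),
    n_runs = report$n_runs,
    base_seed = report$base_seed,
    cells = lapply(report$cells, function(cell) {
      list(
        algorithm = cell$algorithm,
        seeds = cell$seeds,
        modularity = cell$modularity,
        n_modules = cell$n_modules,
        best_partitions = lapply(cell$best_partitions, function(p) {
          list(row_modules = p$row_modules, col_modules = p$col_modules)
        })
      )
    })
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_report
#' @param path Path to a JSON file written by `write_report()`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- lapply(payload$cells, function(cell) {
    bp <- cell$best_partitions
    if (is.data.frame(bp)) {
      bp <- lapply(seq_len(nrow(bp)), function(i) {
        bip_partition(unlist(bp$row_modules[i]), unlist(bp$col_modules[i]))
      })
    } else {
      bp <- lapply(bp, function(p) {
        bip_partition(unlist(p$row_modules), unlist(p$col_modules))
      })
    }
    structure(
      list(
        algorithm = cell$algorithm,
        seeds = cell$seeds,
        modularity = cell$modularity,
        n_modules = cell$n_modules,
        max_modularity = max(cell$modularity),
        median_modularity = stats::median(cell$modularity),
        modules_at_max = cell$n_modules[which.max(cell$modularity)],
        best_partitions = bp
      ),
      class = "repeated_runs"
    )
  })
  nm <- as.matrix(payload$nmi)
  dimnames(nm) <- list(names(cells), names(cells))
  structure(
    list(
      summary = payload$summary,
      nmi = nm,
      delta_q_norm = unlist(payload$delta_q_norm),
      cells = cells,
      n_runs = payload$n_runs,
      base_seed = payload$base_seed
    ),
    class = "comparison_report"
  )
}
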