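#' Specification of a planted-partition synthetic network
#'
#' Describes one synthetic modular bipartite network: its dimensions, the
#' number of planted modules, the negative-binomial edge-weight distribution
#' inside modules (parameterized by dispersion `size` and mean `mu`, with
#' variance \eqn{\mu + \mu^2/size}), the proportion of interactions to rewire
#' as noise, and the seed. The defaults mirror the benchmark conditions the
#' package's evaluation uses: 30 x 50 networks with 2 or 10 modules, weight
#' mean 4 and dispersion 0.5 (sparser, lower connectance) or 2.5 (denser).
#'
#' @param n_rows,n_cols Network dimensions (defaults 30 and 50).
#' @param n_modules Number of planted modules (at most min(n_rows, n_cols)).
#' @param nb_size Negative-binomial dispersion of within-module weights.
#' @param nb_mean Negative-binomial mean of within-module weights.
#' @param noise Proportion of interactions to rewire, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 30, n_cols = 50, n_modules = 2,
                           nb_size = 2.5, nb_mean = 4, noise = 0, seed = NULL) {
  if (n_modules < 1 || n_modules > min(n_rows, n_cols)) {
    stop("`n_modules` must be between 1 and min(n_rows, n_cols)", call. = FALSE)
  }
  if (noise < 0 || noise > 1) {
    stop("`noise` must be in [0, 1]", call. = FALSE)
  }
  if (nb_size <= 0 || nb_mean <= 0) {
    stop("negative-binomial parameters must be positive", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_modules = n_modules,
         nb_size = nb_size, nb_mean = nb_mean, noise = noise, seed = seed),
    class = "synthetic_spec"
  )
}

# n_blocks contiguous blocks of total length n, each of size >= 1. Sizes are
# multinomial (one guaranteed node per block, the rest assigned uniformly at
# random), so they differ between realizations while extreme imbalance --
# under which the planted partition would not even be the modularity optimum
# of a noiseless network -- stays rare.
random_blocks <- function(n, n_blocks) {
  extra <- if (n > n_blocks) {
    tabulate(sample.int(n_blocks, n - n_blocks, replace = TRUE), n_blocks)
  } else {
    integer(n_blocks)
  }
  rep.int(seq_len(n_blocks), 1L + extra)
}

#' Generate a perfectly modular planted-partition network
#'
#' Rows and columns are each cut into `n_modules` contiguous blocks at random
#' breakpoints (every block keeps at least one node), so module sizes vary
#' between realizations. Every cell inside a module receives an independent
#' negative-binomial weight; all between-module cells are zero, so under the
#' planted partition every interaction is within-module. Zero draws inside
#' modules are allowed (they make the sparser treatments genuinely sparse),
#' but a row or column left with no interactions at all is redrawn so the
#' network stays clean at exactly the requested dimensions.
#'
#' @param spec A `synthetic_spec`. Its `noise` field is not applied here;
#'   see [rewire_noise()].
#' @return A `planted_network`: list with the `network`, the ground-truth
#'   `partition`, the realized `noise` (0 here) and the `spec`.
#' @export
#' @examples
#' pn <- plant_modules(synthetic_spec(n_modules = 2, seed = 1))
#' realized_modularity(pn$network, pn$partition) # 1: perfectly modular
plant_modules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    g <- random_blocks(spec$n_rows, spec$n_modules)
    h <- random_blocks(spec$n_cols, spec$n_modules)
    W <- matrix(0, spec$n_rows, spec$n_cols)
    inside <- outer(g, h, "==")
    W[inside] <- stats::rnbinom(sum(inside), size = spec$nb_size, mu = spec$nb_mean)
    for (iter in seq_len(10000L)) {
      zr <- which(rowSums(W) == 0)
      zc <- which(colSums(W) == 0)
      if (length(zr) == 0L && length(zc) == 0L) break
      for (i in zr) {
        cells <- which(inside[i, ])
        W[i, cells] <- stats::rnbinom(length(cells), size = spec$nb_size,
                                      mu = spec$nb_mean)
      }
      for (j in zc) {
        cells <- which(inside[, j])
        W[cells, j] <- stats::rnbinom(length(cells), size = spec$nb_size,
                                      mu = spec$nb_mean)
      }
    }
    structure(
      list(
        network = bipartite_network(W),
        partition = bip_partition(g, h),
        noise = 0,
        spec = spec
      ),
      class = "planted_network"
    )
  })
}

#' @export
print.planted_network <- function(x, ...) {
  d <- dim(x$network)
  cat(
    "<planted_network> ", d[1L], " x ", d[2L], ", ",
    n_modules(x$partition), " planted module(s), noise = ", x$noise, "\n",
    sep = ""
  )
  invisible(x)
}

#' Perturb a planted network by rewiring interactions
#'
#' Degrades modular structure by relocating a proportion of the
#' interactions: `ceiling(noise * n_positive)` positive cells are chosen
#' uniformly without replacement and each cell's full weight is moved to a
#' uniformly chosen currently-zero cell, so node connections change while
#' the total weight M is conserved exactly. If no zero cell is available a
#' move is skipped with a warning. The planted partition is retained for
#' scoring recovery against the ground truth.
#'
#' @param pn A `planted_network`.
#' @param noise Proportion of positive cells to relocate, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A `planted_network` with perturbed weights and updated `noise`.
#' @export
rewire_noise <- function(pn, noise, seed = NULL) {
  stopifnot(inherits(pn, "planted_network"))
  if (noise < 0 || noise > 1) {
    stop("`noise` must be in [0, 1]", call. = FALSE)
  }
  W <- pn$network$weights
  pos <- which(W > 0)
  n_move <- ceiling(noise * length(pos))
  if (n_move == 0L) {
    out <- pn
    out$noise <- noise
    return(out)
  }
  with_seed(seed, {
    sources <- pos[sample.int(length(pos), n_move)]
    moved <- 0L
    for (s in sources) {
      zeros <- which(W == 0)
      if (length(zeros) == 0L) {
        warning("no zero cell available; rewiring move skipped")
        next
      }
      dest <- zeros[sample.int(length(zeros), 1L)]
      W[dest] <- W[dest] + W[s]
      W[s] <- 0
      moved <- moved + 1L
    }
    out <- pn
    out$network <- bipartite_network(W)
    out$noise <- noise
    out$realized_moves <- moved
    out
  })
}

#' Generate the full synthetic benchmark ensemble
#'
#' Reproduces the benchmark design used throughout the package's evaluation:
#' four treatments (2 or 10 planted modules crossed with negative-binomial
#' dispersion 0.5 or 2.5, mean 4), ten initial perfectly modular 30 x 50
#' networks per treatment, and, for each initial network, five replicates at
#' each of four noise levels (0, 0.01, 0.25, 0.5) — 800 networks in all.
#' Every element carries its provenance (treatment, initial-network id,
#' noise, replicate, seed), and the same `base_seed` always regenerates the
#' identical ensemble.
#'
#' @param base_seed Integer seed from which all per-network seeds derive.
#' @param n_initial Initial networks per treatment (default 10).
#' @param n_replicates Replicates per noise level (default 5).
#' @param noise_levels Noise proportions (default `c(0, 0.01, 0.25, 0.5)`).
#' @return A list of `planted_network` objects (length 800 at the defaults).
#' @export
generate_ensemble <- function(base_seed = 1, n_initial = 10, n_replicates = 5,
                              noise_levels = c(0, 0.01, 0.25, 0.5)) {
  treatments <- expand.grid(n_modules = c(2, 10), nb_size = c(0.5, 2.5))
  out <- vector("list", nrow(treatments) * n_initial * length(noise_levels) *
                  n_replicates)
  idx <- 0L
  seed_counter <- as.integer(base_seed)
  for (t in seq_len(nrow(treatments))) {
    for (i in seq_len(n_initial)) {
      seed_counter <- seed_counter + 1L
      spec <- synthetic_spec(
        n_modules = treatments$n_modules[t],
        nb_size = treatments$nb_size[t],
        seed = seed_counter
      )
      pn0 <- plant_modules(spec)
      for (nz in noise_levels) {
        for (rep in seq_len(n_replicates)) {
          seed_counter <- seed_counter + 1L
          pn <- rewire_noise(pn0, nz, seed = seed_counter)
          pn$provenance <- list(
            treatment = sprintf("modules%d_size%g", treatments$n_modules[t],
                                treatments$nb_size[t]),
            initial_id = i,
            noise = nz,
            replicate = rep,
            seed = seed_counter
          )
          idx <- idx + 1L
          out[[idx]] <- pn
        }
      }
    }
  }
  out
}
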