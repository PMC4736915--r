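# Independent oracles used across the suite. These deliberately avoid the
# package's aggregate/trace code paths: modularity is evaluated by the
# explicit double sum over node pairs, and maxima by exhaustive enumeration
# of label assignments.

rand_net <- function(r, c, weights = 0:2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    W <- matrix(sample(weights, r * c, replace = TRUE), r, c)
    if (sum(W) > 0) break
  }
  bipartite_network(W)
}

# Q by the literal double sum, one pair at a time.
oracle_modularity <- function(W, g, h) {
  M <- sum(W)
  y <- rowSums(W)
  z <- colSums(W)
  q <- 0
  for (u in seq_len(nrow(W))) {
    for (v in seq_len(ncol(W))) {
      if (g[u] == h[v]) {
        q <- q + W[u, v] - y[u] * z[v] / M
      }
    }
  }
  as.numeric(q / M)
}

# Independent re-simulation of the noise rewiring: pick ceiling(noise * n_pos)
# positive cells and relocate each one's weight to a uniform currently-zero
# cell, sequentially. Written without package code.
oracle_rewire <- function(W, noise, seed) {
  set.seed(seed)
  pos <- which(W > 0)
  n_move <- ceiling(noise * length(pos))
  if (n_move == 0) return(W)
  sources <- pos[sample.int(length(pos), n_move)]
  for (s in sources) {
    zeros <- which(W == 0)
    if (length(zeros) == 0) next
    dest <- zeros[sample.int(length(zeros), 1)]
    W[dest] <- W[dest] + W[s]
    W[s] <- 0
  }
  W
}

# Exhaustive maximum of Q over every joint label assignment with at most
# min(r, c) modules. Only feasible for tiny matrices.
oracle_max_modularity <- function(W) {
  r <- nrow(W)
  c <- ncol(W)
  K <- min(r, c)
  gs <- as.matrix(expand.grid(rep(list(seq_len(K)), r)))
  hs <- as.matrix(expand.grid(rep(list(seq_len(K)), c)))
  best <- -Inf
  for (i in seq_len(nrow(gs))) {
    for (j in seq_len(nrow(hs))) {
      q <- oracle_modularity(W, gs[i, ], hs[j, ])
      if (q > best) best <- q
    }
  }
  best
}

random_partition <- function(net, k = 3) {
  d <- dim(net)
  bip_partition(sample.int(k, d[1L], replace = TRUE),
                sample.int(k, d[2L], replace = TRUE))
}

partition_sig <- function(p) bipartmod:::partition_signature(p)
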