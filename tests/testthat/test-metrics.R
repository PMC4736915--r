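test_that("hand-evaluated modularity values are reproduced", {
  # 2x2 identity, diagonal partition: Q = (1/2) * 2 * (1 - 1*1/2) = 0.5
  net <- bipartite_network(diag(2))
  diag2 <- bip_partition(1:2, 1:2)
  expect_equal(weighted_modularity(net, diag2), 0.5)
  expect_equal(max_modularity(net, diag2), 0.5)
  expect_equal(normalized_modularity(net, diag2), 1)
  # 3x3 identity, diagonal partition: Q_B = 3 * (1/3) * (1 - 1/3) = 2/3
  net3 <- bipartite_network(diag(3))
  expect_equal(binary_modularity(net3, bip_partition(1:3, 1:3)), 2 / 3)
})

test_that("the single-module partition always scores zero", {
  set.seed(3)
  for (k in 1:10) {
    net <- rand_net(sample(2:6, 1), sample(2:6, 1))
    one <- bip_partition(rep(1, nrow(net$weights)), rep(1, ncol(net$weights)))
    expect_equal(weighted_modularity(net, one), 0)
    expect_equal(max_modularity(net, one), 0)
    expect_identical(normalized_modularity(net, one), NA_real_)
  }
})

test_that("double-sum and trace evaluations agree to 1e-12", {
  set.seed(4)
  for (k in 1:200) {
    r <- sample(2:6, 1)
    c <- sample(2:6, 1)
    W <- matrix(stats::rexp(r * c) * stats::rbinom(r * c, 1, 0.6), r, c)
    if (sum(W) == 0) next
    net <- bipartite_network(W)
    p <- random_partition(net)
    expect_equal(weighted_modularity(net, p, "trace"),
                 weighted_modularity(net, p, "sum"),
                 tolerance = 1e-12)
    expect_equal(weighted_modularity(net, p, "sum"),
                 oracle_modularity(W, p$row_modules, p$col_modules),
                 tolerance = 1e-12)
  }
})

test_that("weighted modularity of a 0/1 matrix equals binary modularity exactly", {
  set.seed(5)
  for (k in 1:25) {
    net <- rand_net(sample(2:6, 1), sample(2:6, 1), weights = 0:1)
    p <- random_partition(net)
    expect_identical(weighted_modularity(net, p), binary_modularity(net, p))
  }
})

test_that("all metrics are invariant under module relabelling", {
  set.seed(6)
  for (k in 1:20) {
    net <- rand_net(4, 5, weights = 0:3)
    p <- random_partition(net, k = 4)
    codes <- sort(unique(c(p$row_modules, p$col_modules)))
    perm <- sample(codes)
    remap <- function(x) perm[match(x, codes)]
    p2 <- bip_partition(remap(p$row_modules), remap(p$col_modules))
    expect_identical(weighted_modularity(net, p), weighted_modularity(net, p2))
    expect_identical(max_modularity(net, p), max_modularity(net, p2))
    expect_identical(realized_modularity(net, p), realized_modularity(net, p2))
    expect_identical(nmi(p, p2), 1)
  }
})

test_that("Q never exceeds Q_max and realized modularity stays in [-1, 1]", {
  set.seed(7)
  for (k in 1:30) {
    net <- rand_net(sample(2:6, 1), sample(2:6, 1))
    p <- random_partition(net)
    expect_lte(weighted_modularity(net, p), max_modularity(net, p) + 1e-12)
    qr <- realized_modularity(net, p)
    expect_gte(qr, -1)
    expect_lte(qr, 1)
  }
})

test_that("realized modularity matches its hand-evaluated cases", {
  # all weight within modules
  block <- bipartite_network(rbind(c(2, 0), c(0, 5)))
  expect_equal(realized_modularity(block, bip_partition(1:2, 1:2)), 1)
  # half the weight within modules
  even <- bipartite_network(matrix(1, 2, 2))
  expect_equal(realized_modularity(even, bip_partition(1:2, 1:2)), 0)
  # 2x2 [[3,1],[1,3]] diagonal partition: 2 * (6/8) - 1 = 0.5
  net <- bipartite_network(rbind(c(3, 1), c(1, 3)))
  expect_equal(realized_modularity(net, bip_partition(1:2, 1:2)), 0.5)
})

test_that("errors are raised for dimension mismatches and zero-weight networks", {
  net <- bipartite_network(diag(2))
  expect_error(weighted_modularity(net, bip_partition(1:3, 1:2)), "dimensions")
  zero <- bipartite_network(matrix(0, 2, 2))
  expect_error(weighted_modularity(zero, bip_partition(1:2, 1:2)), "zero total")
  expect_error(realized_modularity(zero, bip_partition(1:2, 1:2)), "zero total")
})

test_that("NMI is 1 on itself, 0 against the single-module partition", {
  set.seed(8)
  p <- bip_partition(c(1, 1, 2, 3), c(1, 2, 3, 3, 2))
  expect_equal(nmi(p, p), 1)
  one <- bip_partition(rep(1, 4), rep(1, 5))
  expect_equal(nmi(p, one), 0)
  expect_equal(nmi(one, one), 1) # degenerate 0/0 case: identical structures
})

test_that("NMI is symmetric, bounded and base-invariant", {
  set.seed(9)
  for (k in 1:25) {
    r <- sample(3:7, 1)
    c <- sample(3:7, 1)
    a <- bip_partition(sample.int(3, r, TRUE), sample.int(3, c, TRUE))
    b <- bip_partition(sample.int(4, r, TRUE), sample.int(4, c, TRUE))
    v <- nmi(a, b)
    expect_equal(v, nmi(b, a))
    expect_gte(v, 0)
    expect_lte(v, 1 + 1e-12)
    expect_equal(v, nmi(a, b, base = 2), tolerance = 1e-12)
  }
  expect_error(nmi(bip_partition(1:2, 1:2), bip_partition(1:3, 1:2)),
               "node set")
})

test_that("NMI is invariant to which node class carries which labels", {
  # identical partitions written with different label alphabets
  a <- bip_partition(c("x", "y", "y"), c("x", "y"))
  b <- bip_partition(c(10, 20, 20), c(10, 20))
  expect_equal(nmi(a, b), 1)
})
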