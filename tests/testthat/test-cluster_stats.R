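test_that("delta_power equals the textbook pooled-variance t statistic", {
  # spec-style example
  d <- delta_power(matrix(c(3, 4, 5, 6), 1), matrix(c(1, 2, 3, 4), 1))
  expect_equal(drop(d$values), 2 / (sqrt(5 / 3) * sqrt(0.5)),
               tolerance = 1e-12)

  # identical samples -> 0; scale invariance
  expect_equal(drop(delta_power(matrix(1:3, 1), matrix(1:3, 1))$values), 0)
  p <- matrix(rnorm(8, 10), 2); b <- matrix(rnorm(8, 9), 2)
  expect_equal(delta_power(3.7 * p, 3.7 * b)$values,
               delta_power(p, b)$values, tolerance = 1e-12)

  # 100 random fixtures against an independently coded oracle
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1); E <- sample(1:6, 1)
    post <- matrix(rnorm(E * n1, sd = runif(1, 0.5, 3)), E)
    base <- matrix(rnorm(E * n2, sd = runif(1, 0.5, 3)), E)
    got <- delta_power(post, base)$values
    want <- vapply(seq_len(E), function(e)
      oracle_pooled_t(post[e, ], base[e, ]), 0)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("delta_power options and edge cases behave as specified", {
  post <- matrix(rnorm(12, sd = 2), 2); base <- matrix(rnorm(16), 2)
  # welch switch agrees with t.test
  w <- delta_power(post, base, var_type = "welch")$values
  p <- delta_power(post, base)$values
  for (e in 1:2) {
    expect_equal(w[e], unname(t.test(post[e, ], base[e, ])$statistic),
                 tolerance = 1e-12)
    expect_equal(p[e], unname(t.test(post[e, ], base[e, ],
                                     var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  # antisymmetry under swapping the two samples
  expect_equal(delta_power(base, post)$values,
               -delta_power(post, base)$values, tolerance = 1e-12)
  # degenerate variance
  expect_error(delta_power(matrix(2, 1, 3), matrix(1, 1, 3)),
               "degenerate variance")
  expect_equal(drop(delta_power(matrix(1, 1, 3), matrix(1, 1, 3))$values), 0)
  # baseline broadcast over the time dimension
  pt <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  bt <- matrix(rnorm(2 * 6), 2, 6)
  d <- delta_power(pt, bt)
  expect_equal(dim(d$values), c(2, 4))
  expect_equal(d$values[2, 3],
               oracle_pooled_t(pt[2, 3, ], bt[2, ]), tolerance = 1e-12)
})

test_that("pool_blocks averages element-wise on matching axes", {
  a <- array(rnorm(12), c(3, 4)); b <- array(rnorm(12), c(3, 4))
  expect_equal(pool_blocks(a, a), a)
  expect_equal(pool_blocks(a, -a), array(0, c(3, 4)))
  expect_equal(pool_blocks(array(2, c(2, 2)), array(4, c(2, 2))),
               array(3, c(2, 2)))
  expect_error(pool_blocks(a, array(0, c(4, 3))), "mismatch")
})

test_that("cluster permutation p equals exhaustive sign-flip enumeration", {
  # 4 participants, 3-unit chain; hand-built paired maps
  A <- rbind(c(5.0, 5.5, 0.2),
             c(4.2, 4.8, -0.1),
             c(5.1, 4.0, 0.3),
             c(3.9, 5.2, 0.0))
  B <- matrix(0, 4, 3)
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  spec <- cluster_test_spec(n_permutations = 1000, seed = 1)
  res <- cluster_permutation_test(
    lapply(1:4, function(i) A[i, ]), lapply(1:4, function(i) B[i, ]),
    spec, adj)
  expect_true(res$exhaustive)
  expect_equal(length(res$perm_max), 16)
  expect_length(res$clusters, 1)
  expect_identical(res$clusters[[1]]$members, c(1L, 2L))

  # oracle: explicit enumeration, independently coded with plain loops
  D <- A - B
  tcrit <- qt(0.975, 3)
  enum_max <- c()
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1),
                       s4 = c(1, -1))
  for (r in seq_len(nrow(signs))) {
    Dp <- D * as.numeric(signs[r, ])
    tv <- apply(Dp, 2, function(x) mean(x) / (sd(x) / 2))
    best <- 0
    for (sgn in c(1, -1)) {
      sup <- which(sgn * tv > tcrit)
      # chain components among suprathreshold units
      comps <- split(sup, cumsum(c(1, diff(sup) != 1)))
      for (cp in comps)
        if (length(cp) >= 2) best <- max(best, abs(sum(tv[cp])))
    }
    enum_max[r] <- best
  }
  obs <- res$clusters[[1]]$mass
  expect_equal(res$clusters[[1]]$p, mean(enum_max >= abs(obs)))
  expect_equal(sort(res$perm_max), sort(enum_max), tolerance = 1e-12)
})

test_that("identical conditions yield an empty cluster list", {
  A <- lapply(1:4, function(i) rnorm(5, i))
  res <- cluster_permutation_test(A, A,
                                  cluster_test_spec(n_permutations = 50,
                                                    seed = 2),
                                  grid_adjacency(c(5, 1)))
  expect_length(res$clusters, 0)
  expect_length(significant_clusters(res), 0)
})

test_that("condition exchange flips cluster signs and preserves p", {
  set.seed(31)
  n <- 6
  A <- lapply(1:n, function(i) c(rnorm(4, 3), rnorm(4)))
  B <- lapply(1:n, function(i) rnorm(8))
  adj <- grid_adjacency(c(8, 1))
  spec <- cluster_test_spec(n_permutations = 200, seed = 3)
  r1 <- cluster_permutation_test(A, B, spec, adj)
  r2 <- cluster_permutation_test(B, A, spec, adj)
  expect_equal(length(r1$clusters), length(r2$clusters))
  for (i in seq_along(r1$clusters)) {
    expect_equal(r1$clusters[[i]]$mass, -r2$clusters[[i]]$mass)
    expect_identical(r1$clusters[[i]]$members, r2$clusters[[i]]$members)
    expect_equal(r1$clusters[[i]]$p, r2$clusters[[i]]$p)
  }
})

test_that("suprathreshold singletons are dropped by the adjacency rule", {
  # strong effect on unit 1 only; unit 1 is isolated from units 2-3
  A <- lapply(1:5, function(i) c(6 + rnorm(1, sd = 0.1), 0, 0))
  B <- lapply(1:5, function(i) rnorm(3, sd = 0.1))
  adj <- matrix(FALSE, 3, 3); adj[2, 3] <- adj[3, 2] <- TRUE
  res <- cluster_permutation_test(A, B,
                                  cluster_test_spec(n_permutations = 100,
                                                    seed = 4), adj)
  expect_length(res$clusters, 0)
  expect_gt(max(abs(res$t_obs)), qt(0.975, 4))
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(7)
  n <- 11
  A <- lapply(1:n, function(i) c(rnorm(3, 1.2), rnorm(3)))
  B <- lapply(1:n, function(i) rnorm(6))
  adj <- grid_adjacency(c(6, 1))
  ex <- cluster_permutation_test(A, B,
          cluster_test_spec(n_permutations = 2048, seed = 5), adj)
  mc <- cluster_permutation_test(A, B,
          cluster_test_spec(n_permutations = 2000, seed = 5), adj)
  expect_true(ex$exhaustive); expect_false(mc$exhaustive)
  p_ex <- ex$clusters[[1]]$p; p_mc <- mc$clusters[[1]]$p
  expect_lt(abs(p_ex - p_mc),
            0.02 + 3 * sqrt(p_ex * (1 - p_ex) / 2000))
})

test_that("region split runs per region and errors on empty intersections", {
  n <- 5
  mk <- function(mu) lapply(1:n, function(i)
    array(rnorm(4 * 3 * 4, mu), c(4, 3, 4)))
  labels <- c("somatosensory", "somatosensory", "frontal", "frontal")
  spec <- cluster_test_spec(n_permutations = 64, seed = 6)
  res <- region_split_test(1:4, labels, mk(0.5), mk(0), spec)
  expect_named(res, c("somatosensory", "frontal"))
  expect_s3_class(res$somatosensory, "cluster_test")
  expect_error(
    region_split_test(1:2, labels, mk(0.5), mk(0), spec),
    "frontal")
})

test_that("block contrast reduces to the closed-form rank-sum statistic", {
  # hand-built per-block spatial maps for 4 participants, 6 cluster units
  set.seed(8)
  n <- 4; units <- 1:6
  mk_block <- function(shift) list(
    tacs = lapply(1:n, function(i) rnorm(6, shift, 0.3) + 0.2 * i),
    control = lapply(1:n, function(i) rnorm(6, 0, 0.3)))
  maps <- list(train10 = mk_block(2), train30 = mk_block(0.8))
  bc <- block_contrast(units, maps)

  tvals <- lapply(maps, function(m) {
    D <- sapply(1:6, function(u)
      sapply(1:n, function(i) m$tacs[[i]][u] - m$control[[i]][u]))
    apply(D, 2, function(d) mean(d) / (sd(d) / sqrt(n)))
  })
  # closed-form Mann-Whitney U from pairwise comparisons
  U <- sum(outer(tvals[[1]], tvals[[2]], ">")) +
    0.5 * sum(outer(tvals[[1]], tvals[[2]], "=="))
  expect_equal(bc$statistic, U)
  expect_equal(bc$p, wilcox.test(tvals[[1]], tvals[[2]])$p.value)

  # identical blocks -> maximal p; full separation -> minimal exact p
  same <- list(train10 = maps$train10, train30 = maps$train10)
  expect_equal(block_contrast(units, same)$p, 1)
  sep <- list(train10 = mk_block(50), train30 = mk_block(0))
  expect_equal(block_contrast(units, sep)$statistic, 36)
  expect_equal(block_contrast(units, sep)$p, 2 / choose(12, 6),
               tolerance = 1e-12)
  expect_error(block_contrast(1L, maps), "fewer than 2")
})
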