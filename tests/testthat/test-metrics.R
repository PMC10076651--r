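test_that("expected influence is the signed row sum of edge weights", {
  w0 <- weights_from_edges(4, data.frame(i = integer(0), j = integer(0),
                                         w = numeric(0)))
  expect_equal(expected_influence(w0), rep(0, 4), ignore_attr = TRUE)

  # chain V1 -0.45- V2 -0.35- V3: middle node sums both
  chain <- weights_from_edges(3, data.frame(i = c(1, 2), j = c(2, 3),
                                            w = c(0.45, 0.35)))
  expect_equal(expected_influence(chain),
               c(V1 = 0.45, V2 = 0.80, V3 = 0.35))

  # adding a negative edge lowers both endpoints by its magnitude
  chain2 <- chain
  chain2[1, 3] <- chain2[3, 1] <- -0.2
  expect_equal(expected_influence(chain2) - expected_influence(chain),
               c(V1 = -0.2, V2 = 0, V3 = -0.2))
})

test_that("bridge expected influence obeys the partition identities", {
  set.seed(71)
  w <- matrix(rnorm(100), 10, 10)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  colnames(w) <- rownames(w) <- paste0("V", 1:10)
  groups <- rep(c("x", "y"), each = 5)

  expect_equal(bridge_expected_influence(w, rep("one", 10)),
               rep(0, 10), ignore_attr = TRUE)

  single <- weights_from_edges(6, data.frame(i = 2, j = 5, w = 0.10))
  bei <- bridge_expected_influence(single, rep(c("g1", "g2"), each = 3))
  expect_equal(unname(bei), c(0, 0.10, 0, 0, 0.10, 0))

  # BEI + within-group sum = EI, to machine precision
  bei_full <- bridge_expected_influence(w, groups)
  within <- sapply(1:10, function(i) sum(w[i, groups == groups[i]]))
  expect_equal(bei_full + within, expected_influence(w), ignore_attr = TRUE)
})

test_that("predictability matches an independent per-node regression oracle", {
  single <- weights_from_edges(3, data.frame(i = 1, j = 2, w = 0.5))
  x <- matrix(rnorm(300), 100, 3)
  x[, 2] <- x[, 1]  # node 2 is a copy of its sole neighbour
  pr <- predictability(x, single)
  expect_gte(pr[[2]], 0.99)
  expect_equal(pr[[3]], 0)  # no neighbours

  cfg <- small_generator(seed = 72, n = 2000)
  sim <- simulate_survey(cfg)
  z <- npn_transform(sim$responses)
  m <- estimate_network(sim$responses)
  pr <- predictability(z, m)
  oracle <- vapply(seq_len(ncol(z)), function(j) {
    nb <- which(m$weights[j, ] != 0)
    if (length(nb) == 0) return(0)
    xx <- cbind(1, z[, nb, drop = FALSE])
    beta <- solve(crossprod(xx), crossprod(xx, z[, j]))
    res <- z[, j] - xx %*% beta
    max(0, 1 - sum(res^2) / sum((z[, j] - mean(z[, j]))^2))
  }, numeric(1))
  expect_lt(abs(mean(pr) - mean(oracle)), 0.1)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("walktrap splits two cliques and never merges disconnected parts", {
  cm <- walktrap_communities(two_cliques())
  expect_equal(cm$n_communities, 2)
  expect_equal(length(unique(cm$membership[1:4])), 1)
  expect_equal(length(unique(cm$membership[5:8])), 1)

  disc <- two_cliques(weak = 0)  # two components
  cm2 <- walktrap_communities(disc)
  expect_true(all(cm2$membership[1:4] != cm2$membership[5:8]))

  iso <- weights_from_edges(4, data.frame(i = 1, j = 2, w = 0.5))
  expect_warning(cm3 <- walktrap_communities(iso), "singleton")
  expect_equal(length(unique(cm3$membership[3:4])), 2)
})

test_that("walktrap partitions reach the brute-force modularity optimum", {
  g1 <- two_cliques()
  set.seed(73)
  g2 <- weights_from_edges(7, data.frame(
    i = c(1, 1, 2, 4, 4, 5, 6, 3),
    j = c(2, 3, 3, 5, 6, 6, 7, 4),
    w = c(0.9, 0.8, 0.7, 0.8, 0.9, 0.6, 0.7, 0.1)
  ))
  for (w in list(g1, g2)) {
    cm <- walktrap_communities(w)
    expect_gte(modularity_manual(w, cm$membership),
               0.95 * brute_force_max_modularity(w))
  }
})

test_that("centrality table assembles z-scored indices", {
  cfg <- small_generator(seed = 74, n = 500)
  sim <- simulate_survey(cfg)
  m <- estimate_network(sim$responses)
  z <- npn_transform(sim$responses)
  cm <- walktrap_communities(m)
  ct <- centrality_table(m, z, groups = rep(c("a", "b"), each = 4),
                         communities = cm)
  expect_equal(mean(ct$z_ei), 0, tolerance = 1e-12)
  expect_equal(sd(ct$z_ei), 1, tolerance = 1e-12)
  expect_equal(mean(ct$z_bei), 0, tolerance = 1e-12)
  expect_equal(ct$expected_influence, unname(expected_influence(m)))
})
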