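test_that("build_precision realizes the requested block and bridge structure", {
  # independence: zero within-block magnitude, no bridges
  cfg0 <- generator_config(
    n_respondents = 50,
    blocks = data.frame(label = c("a", "b"), size = c(3L, 3L), rho = c(0, 0)),
    bridge_edges = NULL, item_levels = 4L, seed = 1
  )
  spec0 <- build_precision(cfg0)
  expect_equal(spec0$theta, diag(6))
  expect_true(all(spec0$true_partials == 0))

  # 2 nodes, one planted partial correlation 0.5: inverting
  # w = -theta12/sqrt(theta11*theta22) under unit diagonal gives theta12 = -0.5
  cfg2 <- generator_config(
    n_respondents = 50,
    blocks = data.frame(label = "a", size = 2L, rho = 0.5),
    bridge_edges = NULL, item_levels = 4L, seed = 1
  )
  spec2 <- build_precision(cfg2)
  expect_equal(spec2$theta[1, 2], -0.5)
  expect_equal(spec2$true_partials[1, 2], 0.5)
  expect_equal(diag(spec2$true_partials), c(0, 0))

  # default 5-block layout: 35 x 35, cross-block entries zero except bridges
  cfg <- generator_config(seed = 1)
  spec <- build_precision(cfg)
  expect_equal(dim(spec$theta), c(35, 35))
  expect_gt(min(eigen(spec$theta, symmetric = TRUE, only.values = TRUE)$values), 0)
  cross <- outer(cfg$block_id, cfg$block_id, "!=")
  bridge_mask <- matrix(FALSE, 35, 35)
  for (r in seq_len(nrow(cfg$bridge_edges))) {
    bridge_mask[cfg$bridge_edges$i[r], cfg$bridge_edges$j[r]] <- TRUE
    bridge_mask[cfg$bridge_edges$j[r], cfg$bridge_edges$i[r]] <- TRUE
  }
  expect_true(all(spec$theta[cross & !bridge_mask] == 0))
  expect_equal(sum(spec$theta[cross & bridge_mask] != 0), 6)
})

test_that("infeasible precision requests are rejected with a diagnostic", {
  cfg <- generator_config(
    n_respondents = 50,
    blocks = data.frame(label = "a", size = 10L, rho = 0.2),  # 9*0.2 > 1
    bridge_edges = NULL, item_levels = 4L, seed = 1
  )
  expect_error(build_precision(cfg), "diagonally dominant")
  expect_error(generator_config(
    n_respondents = 50,
    blocks = data.frame(label = "a", size = 4L, rho = 0.1),
    bridge_edges = data.frame(i = 1L, j = 2L, rho = 0.1),  # same block
    item_levels = 4L, seed = 1
  ), "distinct blocks")
})

test_that("sampling is reproducible and respects the marginal thresholds", {
  cfg <- generator_config(
    n_respondents = 10000,
    blocks = data.frame(label = c("a", "b"), size = c(2L, 2L), rho = c(0, 0)),
    bridge_edges = NULL, item_levels = 4L,
    marginal_probs = list(rep(0.25, 4)), seed = 42
  )
  spec <- build_precision(cfg)
  x <- sample_responses(spec, cfg)
  expect_equal(dim(x), c(10000, 4))
  for (j in 1:4) {
    freq <- tabulate(x[, j], nbins = 4) / 10000
    expect_true(all(abs(freq - 0.25) < 0.02))
  }
  x2 <- sample_responses(spec, cfg)
  expect_identical(unclass(x), unclass(x2))
})

test_that("reverse keying flips recorded codes and is an involution", {
  cfg <- generator_config(
    n_respondents = 200,
    blocks = data.frame(label = "a", size = 3L, rho = 0.1),
    bridge_edges = NULL, item_levels = 4L, reverse_keyed = 2L, seed = 9
  )
  spec <- build_precision(cfg)
  x <- sample_responses(spec, cfg)
  cfg_plain <- cfg; cfg_plain$reverse_keyed <- integer(0)
  x_plain <- sample_responses(spec, cfg_plain)
  expect_identical(x[, 2], 5L - x_plain[, 2])
  expect_identical(x[, c(1, 3)], x_plain[, c(1, 3)])
  twice <- reverse_key(reverse_key(unclass(x), 2L, 1L, 4L), 2L, 1L, 4L)
  expect_identical(twice, unclass(x))
})

test_that("planted dependence dominates null pairs in the sample correlations", {
  cfg <- generator_config(
    n_respondents = 5000,
    blocks = data.frame(label = c("a", "b"), size = c(2L, 4L), rho = c(0.4, 0)),
    bridge_edges = NULL, item_levels = 4L, seed = 3
  )
  sim <- simulate_survey(cfg)
  r <- cor(unclass(sim$responses))
  planted <- r[1, 2]
  nulls <- abs(r[upper.tri(r)])
  nulls <- nulls[nulls != abs(planted)]
  expect_gt(planted, 0)
  expect_gt(planted, max(nulls))
  # latent covariance round-trip: solve(theta) really is the inverse
  expect_equal(solve(sim$truth$theta) %*% sim$truth$theta, diag(6),
               tolerance = 1e-10)
})

test_that("independent items yield a near-empty estimated network", {
  cfg <- generator_config(
    n_respondents = 2000,
    blocks = data.frame(label = "a", size = 10L, rho = 0),
    bridge_edges = NULL, item_levels = 4L, seed = 8
  )
  sim <- simulate_survey(cfg)
  m <- suppressWarnings(estimate_network(sim$responses))
  density <- mean(edge_support(m$weights))
  expect_lte(density, 0.05)
})

test_that("survey round-trips through CSV with the truth sidecar", {
  cfg <- small_generator(seed = 4, n = 60)
  sim <- simulate_survey(cfg)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_survey(sim, csv, js)
  back <- read_responses(csv)
  # CSV keeps values and names, not the generator's bookkeeping attributes
  orig <- unclass(sim$responses)
  attributes(orig) <- attributes(orig)[c("dim", "dimnames")]
  expect_identical(unname(back), unname(orig))
  expect_identical(colnames(back), cfg$labels)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$theta, sim$truth$theta, tolerance = 1e-12)
})
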