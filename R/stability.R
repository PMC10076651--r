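# Re-estimate the network on a row subset, redrawing (capped) if a resample
# produces a constant column that the nonparanormal transform cannot handle.
resample_network <- function(x, rows, gamma, max_redraw = 25, replace = TRUE) {
  n <- nrow(x)
  redraws <- 0
  repeat {
    xb <- x[rows, , drop = FALSE]
    ok <- all(apply(xb, 2, function(col) length(unique(col)) > 1))
    if (ok) return(list(model = estimate_network(xb, gamma = gamma),
                        redraws = redraws))
    redraws <- redraws + 1
    if (redraws > max_redraw) {
      stop("resampling kept producing constant columns (", redraws, " redraws)")
    }
    rows <- sample.int(n, length(rows), replace = replace)
  }
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples respondents with replacement and re-runs the full estimation
#' (nonparanormal transform, correlations, EBIC-selected glasso) per
#' resample; reports percentile 95% confidence intervals per edge and keeps
#' the bootstrap draws of edge weights and node expected influence for
#' difference tests.
#'
#' @param x item response matrix.
#' @param nboot number of bootstrap resamples (values below 1000 warn;
#'   below 100 are rejected).
#' @param seed integer seed.
#' @param gamma EBIC hyperparameter for each re-estimation.
#' @return object of class `bootstrap_summary`: `edges` (data.frame: pair,
#'   point estimate, bootstrap mean, 2.5%/97.5% quantiles), `edge_samples`
#'   (nboot x n_pairs), `ei_samples` (nboot x p), `model` (full-sample fit),
#'   `nboot`, `seed`.
#' @export
bootstrap_edges <- function(x, nboot = 1000, seed = 1, gamma = 0.5) {
  x <- as.matrix(x)
  if (nboot < 100) stop("nboot must be at least 100")
  if (nboot < 1000) warning("nboot below 1000; confidence intervals will be rough")
  n <- nrow(x)
  model <- estimate_network(x, gamma = gamma)
  p <- length(model$labels)
  ut <- upper.tri(model$weights)
  pair_idx <- which(ut, arr.ind = TRUE)
  pair_names <- paste(model$labels[pair_idx[, 1]], model$labels[pair_idx[, 2]],
                      sep = "--")
  set.seed(seed)
  edge_samples <- matrix(NA_real_, nboot, nrow(pair_idx),
                         dimnames = list(NULL, pair_names))
  ei_samples <- matrix(NA_real_, nboot, p, dimnames = list(NULL, model$labels))
  redraws <- 0
  for (b in seq_len(nboot)) {
    rows <- sample.int(n, n, replace = TRUE)
    fit <- resample_network(x, rows, gamma)
    redraws <- redraws + fit$redraws
    edge_samples[b, ] <- fit$model$weights[ut]
    ei_samples[b, ] <- expected_influence(fit$model)
  }
  qs <- apply(edge_samples, 2, stats::quantile, probs = c(0.025, 0.975))
  edges <- data.frame(
    node_i = model$labels[pair_idx[, 1]],
    node_j = model$labels[pair_idx[, 2]],
    estimate = model$weights[ut],
    boot_mean = colMeans(edge_samples),
    ci_lower = qs[1, ],
    ci_upper = qs[2, ],
    row.names = NULL
  )
  structure(list(edges = edges, edge_samples = edge_samples,
                 ei_samples = ei_samples, model = model,
                 nboot = nboot, seed = seed, redraws = redraws),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Edge-weight bootstrap:", x$nboot, "resamples,",
      nrow(x$edges), "edges\n")
  cov0 <- mean(x$edges$ci_lower <= 0 & x$edges$ci_upper >= 0)
  cat(sprintf("95%% CIs containing 0: %.1f%%\n", 100 * cov0))
  invisible(x)
}

#' Bootstrapped difference test
#'
#' Two edges (or two nodes' expected influences) differ significantly when
#' the 95% percentile interval of their bootstrapped pairwise difference
#' excludes zero.
#'
#' @param summary a [bootstrap_edges()] result.
#' @param a,b identifiers of the two quantities: edge names
#'   (`"node1--node2"`) or node labels, matching `what`.
#' @param what `"edge"` or `"ei"`.
#' @return list with `significant` (logical), `difference` (point estimate
#'   a - b), `ci` (2.5%/97.5% bootstrap quantiles of the difference).
#' @export
difference_test <- function(summary, a, b, what = c("edge", "ei")) {
  what <- match.arg(what)
  stopifnot(inherits(summary, "bootstrap_summary"))
  samples <- if (what == "edge") summary$edge_samples else summary$ei_samples
  for (nm in c(a, b)) {
    if (!nm %in% colnames(samples)) stop("unknown ", what, ": ", nm)
  }
  d <- samples[, a] - samples[, b]
  ci <- stats::quantile(d, c(0.025, 0.975))
  point <- if (what == "edge") {
    e <- summary$edges
    key <- paste(e$node_i, e$node_j, sep = "--")
    e$estimate[match(a, key)] - e$estimate[match(b, key)]
  } else {
    ei <- expected_influence(summary$model)
    ei[a] - ei[b]
  }
  list(significant = (ci[1] > 0 || ci[2] < 0) && a != b,
       difference = unname(point), ci = unname(ci))
}

#' Case-dropping bootstrap and the correlation-stability coefficient
#'
#' For each drop proportion in `grid`, repeatedly re-estimates the network
#' on the retained random subsample and correlates the subsample centrality
#' vector with the full-sample one. The CS coefficient is the largest drop
#' proportion at which at least 95% of those correlations stay at or above
#' 0.70 (0 if none does). Values of 0.25 and 0.50 are the conventional
#' acceptability and preference thresholds.
#'
#' @param x item response matrix.
#' @param statistic `"ei"` (expected influence) or `"bei"` (bridge expected
#'   influence under the two-construct split).
#' @param nboot total resamples, split evenly over the grid.
#' @param grid drop proportions, strictly inside (0, 1).
#' @param seed integer seed.
#' @param gamma EBIC hyperparameter.
#' @param cor_method correlation between subsample and full-sample
#'   centralities (`"pearson"` default, `"spearman"` optional).
#' @param cor_floor,coverage the CS rule: `coverage` of correlations must
#'   reach `cor_floor`.
#' @return object of class `cs_result`: `cs_coefficient`, `grid`,
#'   `correlations` (list of per-proportion correlation vectors),
#'   `prop_above` (share of correlations >= `cor_floor` per proportion).
#' @export
case_dropping_cs <- function(x, statistic = c("ei", "bei"), nboot = 2000,
                             grid = seq(0.1, 0.9, by = 0.1), seed = 1,
                             gamma = 0.5, cor_method = c("pearson", "spearman"),
                             cor_floor = 0.70, coverage = 0.95) {
  statistic <- match.arg(statistic)
  cor_method <- match.arg(cor_method)
  x <- as.matrix(x)
  if (any(grid <= 0 | grid >= 1)) stop("grid proportions must lie in (0, 1)")
  grid <- sort(grid)
  n <- nrow(x)
  p <- ncol(x)
  full <- estimate_network(x, gamma = gamma)
  groups <- construct_groups(full$labels)
  stat_fun <- function(model) {
    if (statistic == "ei") expected_influence(model)
    else bridge_expected_influence(model, groups)
  }
  full_stat <- stat_fun(full)
  per_prop <- max(1, floor(nboot / length(grid)))
  set.seed(seed)
  correlations <- vector("list", length(grid))
  names(correlations) <- paste0("drop_", grid)
  for (gidx in seq_along(grid)) {
    keep_n <- round(n * (1 - grid[gidx]))
    if (keep_n <= p) {
      warning("drop proportion ", grid[gidx], " leaves ", keep_n,
              " rows (fewer than ", p + 1, "); skipped")
      correlations[[gidx]] <- rep(NA_real_, per_prop)
      next
    }
    cors <- numeric(per_prop)
    for (b in seq_len(per_prop)) {
      rows <- sample.int(n, keep_n, replace = FALSE)
      fit <- resample_network(x, rows, gamma, replace = FALSE)
      cors[b] <- suppressWarnings(
        stats::cor(stat_fun(fit$model), full_stat, method = cor_method))
    }
    correlations[[gidx]] <- cors
  }
  prop_above <- vapply(correlations, function(cv) {
    mean(!is.na(cv) & cv >= cor_floor)
  }, numeric(1))
  ok <- which(prop_above >= coverage)
  cs <- if (length(ok) > 0) max(grid[ok]) else 0
  structure(list(cs_coefficient = cs, grid = grid, statistic = statistic,
                 correlations = correlations, prop_above = prop_above,
                 nboot_per_prop = per_prop, seed = seed,
                 cor_floor = cor_floor, coverage = coverage),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat("Case-dropping bootstrap (", x$statistic, "): CS = ",
      x$cs_coefficient, "\n", sep = "")
  print(round(x$prop_above, 3))
  invisible(x)
}
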