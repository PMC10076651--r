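#' Global strength of a network
#'
#' Sum of absolute edge weights over unordered node pairs.
#'
#' @param model `network_model` or weight matrix.
#' @return scalar.
#' @export
global_strength <- function(model) {
  w <- as_weight_matrix(model)
  sum(abs(w[upper.tri(w)]))
}

nct_stats <- function(xa, xb, gamma) {
  ma <- estimate_network(xa, gamma = gamma)
  mb <- estimate_network(xb, gamma = gamma)
  dw <- ma$weights - mb$weights
  list(m = max(abs(dw[upper.tri(dw)])),
       gs_a = global_strength(ma), gs_b = global_strength(mb),
       edge_diff = abs(dw[upper.tri(dw)]),
       model_a = ma, model_b = mb)
}

#' Permutation network comparison test
#'
#' Compares two groups' networks on (i) network structure, the maximum
#' absolute edge difference `M = max |w_A - w_B|`, and (ii) global strength,
#' `S = |GS(A) - GS(B)|`. The null distribution pools the respondents,
#' permutes group labels at the original group sizes and re-runs the full
#' estimation (nonparanormal transform included) for both permuted groups.
#' P-values use the add-one rule `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#' Per-edge two-sided permutation tests are corrected with Holm's step-down
#' procedure.
#'
#' @param xa,xb item response matrices for the two groups (identical
#'   columns).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @param gamma EBIC hyperparameter for every estimation.
#' @param edge_tests whether to run the per-edge invariance tests.
#' @return object of class `nct_result`: `m_statistic`, `s_statistic`,
#'   `global_strength` (per group), `p_value_m`, `p_value_s`, `edges`
#'   (data.frame with per-edge observed differences, raw and Holm-adjusted
#'   p-values; `NULL` if `edge_tests = FALSE`), `n_permutations`, `seed`,
#'   plus both observed models.
#' @export
compare_networks <- function(xa, xb, n_perm = 1000, seed = 1, gamma = 0.5,
                             edge_tests = TRUE) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (ncol(xa) != ncol(xb) ||
      !identical(colnames(xa), colnames(xb))) {
    stop("both groups must measure the identical item set")
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  p <- ncol(xa)
  if (min(nrow(xa), nrow(xb)) < 3 * p) {
    warning("a group has fewer than 3 x p respondents; comparison unstable")
  }
  obs <- nct_stats(xa, xb, gamma)
  s_obs <- abs(obs$gs_a - obs$gs_b)
  # canonical row order makes the null distribution (and hence the p-values)
  # invariant to which group is passed first
  pooled <- rbind(xa, xb)
  pooled <- pooled[do.call(order, as.data.frame(pooled)), , drop = FALSE]
  nsmall <- min(nrow(xa), nrow(xb)); ntot <- nrow(pooled)
  set.seed(seed)
  m_null <- numeric(n_perm)
  s_null <- numeric(n_perm)
  edge_ge <- if (edge_tests) numeric(length(obs$edge_diff)) else NULL
  for (b in seq_len(n_perm)) {
    idx <- sample.int(ntot, nsmall)
    perm <- nct_stats(pooled[idx, , drop = FALSE],
                      pooled[-idx, , drop = FALSE], gamma)
    m_null[b] <- perm$m
    s_null[b] <- abs(perm$gs_a - perm$gs_b)
    if (edge_tests) edge_ge <- edge_ge + (perm$edge_diff >= obs$edge_diff)
  }
  p_m <- (1 + sum(m_null >= obs$m)) / (1 + n_perm)
  p_s <- (1 + sum(s_null >= s_obs)) / (1 + n_perm)
  edges <- NULL
  if (edge_tests) {
    labels <- obs$model_a$labels
    ut <- which(upper.tri(obs$model_a$weights), arr.ind = TRUE)
    p_raw <- (1 + edge_ge) / (1 + n_perm)
    edges <- data.frame(
      node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
      diff = obs$model_a$weights[upper.tri(obs$model_a$weights)] -
        obs$model_b$weights[upper.tri(obs$model_b$weights)],
      p_raw = p_raw,
      p_holm = stats::p.adjust(p_raw, method = "holm"),
      row.names = NULL
    )
  }
  structure(list(
    m_statistic = obs$m,
    s_statistic = s_obs,
    global_strength = c(group_a = obs$gs_a, group_b = obs$gs_b),
    p_value_m = p_m,
    p_value_s = p_s,
    edges = edges,
    n_permutations = n_perm,
    seed = seed,
    model_a = obs$model_a,
    model_b = obs$model_b
  ), class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("Network comparison test (%d permutations)\n", x$n_permutations))
  cat(sprintf("  Network variance (M) = %.2f, p = %.2f\n",
              x$m_statistic, x$p_value_m))
  cat(sprintf("  Global strength variance (S) = %.2f, p = %.2f\n",
              x$s_statistic, x$p_value_s))
  cat(sprintf("  Global strength: group A %.2f, group B %.2f\n",
              x$global_strength[1], x$global_strength[2]))
  if (!is.null(x$edges)) {
    sig <- sum(x$edges$p_holm < 0.05)
    cat("  Edges significant after Holm correction:", sig, "\n")
  }
  invisible(x)
}

#' Split a response table by a grouping variable and compare the networks
#'
#' Convenience wrapper for config-driven subgroup comparisons (for example
#' gender, an age split, education, professional title, or length of
#' service).
#'
#' @param x item response matrix.
#' @param group vector with exactly two distinct values, one per row of `x`.
#' @param ... passed to [compare_networks()].
#' @return an `nct_result`.
#' @export
compare_by_group <- function(x, group, ...) {
  x <- as.matrix(x)
  stopifnot(length(group) == nrow(x))
  lev <- unique(group)
  if (length(lev) != 2) stop("grouping variable must have exactly 2 levels")
  compare_networks(x[group == lev[1], , drop = FALSE],
                   x[group == lev[2], , drop = FALSE], ...)
}
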