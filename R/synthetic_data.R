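#' Configuration for the synthetic questionnaire generator
#'
#' Describes an ordinal item-response dataset generated from a latent
#' multivariate Gaussian whose precision matrix has planted block (community)
#' structure plus a small set of cross-block "bridge" edges. The default
#' configuration mirrors a burnout + depression survey: 15 burnout items
#' (three subscales: emotional exhaustion, depersonalization, reduced
#' professional efficacy) scored 0-6, and 20 depression items scored 1-4
#' falling into two latent clusters, with three weak bridge edges connecting
#' the constructs.
#'
#' @param n_respondents number of rows to simulate.
#' @param blocks data.frame with columns `label`, `size`, `rho`: one row per
#'   community; `rho` is the partial correlation planted on every within-block
#'   pair.
#' @param bridge_edges data.frame with columns `i`, `j`, `rho` giving node
#'   indices (in the concatenated block order) and the planted cross-block
#'   partial correlation. May have zero rows.
#' @param item_levels integer vector, number of ordinal categories per item
#'   (recycled across nodes if length 1).
#' @param marginal_probs list of per-item category probability vectors, or a
#'   single vector recycled over items with the same number of levels. The
#'   default is right-skewed (most mass in low categories), matching the
#'   response profile typical of burnout/depression items.
#' @param reverse_keyed integer indices of items whose recorded codes are
#'   flipped (`max + min - x`) after discretization.
#' @param seed integer seed driving all randomness for this configuration.
#'
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 1322,
                             blocks = default_blocks(),
                             bridge_edges = default_bridges(),
                             item_levels = NULL,
                             marginal_probs = NULL,
                             reverse_keyed = integer(0),
                             seed = 1L) {
  stopifnot(is.data.frame(blocks), all(c("label", "size", "rho") %in% names(blocks)))
  if (!is.data.frame(bridge_edges)) {
    bridge_edges <- data.frame(i = integer(0), j = integer(0), rho = numeric(0))
  }
  if (n_respondents < 1) stop("n_respondents must be a positive integer")
  p <- sum(blocks$size)
  labels <- default_item_labels(blocks)
  if (is.null(item_levels)) {
    # 7 categories (0-6) for MBI-style items, 4 (1-4) for SDS-style ones
    item_levels <- ifelse(grepl("^MBI", labels), 7L, 4L)
  }
  item_levels <- as.integer(rep_len(item_levels, p))
  if (any(item_levels < 2)) stop("every item needs at least 2 categories")
  if (is.null(marginal_probs)) {
    marginal_probs <- lapply(item_levels, default_marginal)
  } else if (!is.list(marginal_probs)) {
    marginal_probs <- rep_len(list(marginal_probs), p)
  } else {
    marginal_probs <- rep_len(marginal_probs, p)
  }
  for (i in seq_len(p)) {
    pr <- marginal_probs[[i]]
    if (length(pr) != item_levels[i]) {
      stop("marginal_probs[[", i, "]] must have ", item_levels[i], " entries")
    }
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      stop("marginal_probs[[", i, "]] must be a probability vector")
    }
  }
  # item score origin: 0 for 7-level (MBI convention), 1 for 4-level (SDS)
  item_min <- ifelse(item_levels == 7L, 0L, 1L)
  block_id <- rep(seq_len(nrow(blocks)), blocks$size)
  if (nrow(bridge_edges) > 0) {
    if (any(bridge_edges$i < 1 | bridge_edges$j < 1 |
            bridge_edges$i > p | bridge_edges$j > p)) {
      stop("bridge edge index out of range")
    }
    if (any(block_id[bridge_edges$i] == block_id[bridge_edges$j])) {
      stop("bridge edges must span two distinct blocks")
    }
  }
  reverse_keyed <- as.integer(reverse_keyed)
  if (any(reverse_keyed < 1 | reverse_keyed > p)) stop("reverse_keyed index out of range")
  structure(list(
    n_respondents = as.integer(n_respondents),
    blocks = blocks,
    bridge_edges = bridge_edges,
    item_levels = item_levels,
    item_min = item_min,
    marginal_probs = marginal_probs,
    reverse_keyed = reverse_keyed,
    labels = labels,
    block_id = block_id,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default community layout: three burnout subscales and two depression clusters
#'
#' Block sizes follow the instruments (5 + 4 + 6 burnout items, two 10-item
#' depression clusters). Within-block partial correlations are 0.15 for the
#' small burnout blocks and 0.09 for the 10-node depression blocks, the
#' strongest equicorrelated values compatible with a diagonally dominant
#' precision matrix once bridge edges are added.
#'
#' @return data.frame with columns `label`, `size`, `rho`.
#' @export
default_blocks <- function() {
  data.frame(
    label = c("emotional_exhaustion", "depersonalization",
              "reduced_professional_efficacy",
              "depression_negative", "depression_positive"),
    size = c(5L, 4L, 6L, 10L, 10L),
    rho = c(0.15, 0.15, 0.15, 0.09, 0.09),
    stringsAsFactors = FALSE
  )
}

# Item labels MBI-1..MBI-15 then D1..D20; depression cluster membership follows
# the negative-description {1,3,4,7,8,9,10,13,15,19} / positive-description
# {2,5,6,11,12,14,16,17,18,20} split, so D items are interleaved across the
# two blocks rather than consecutive.
default_item_labels <- function(blocks) {
  if (identical(blocks$size, c(5L, 4L, 6L, 10L, 10L))) {
    d_neg <- c(1L, 3L, 4L, 7L, 8L, 9L, 10L, 13L, 15L, 19L)
    d_pos <- c(2L, 5L, 6L, 11L, 12L, 14L, 16L, 17L, 18L, 20L)
    c(paste0("MBI-", 1:15), paste0("D", d_neg), paste0("D", d_pos))
  } else {
    unlist(lapply(seq_len(nrow(blocks)), function(b) {
      paste0(abbreviate(blocks$label[b], 3), "-", seq_len(blocks$size[b]))
    }), use.names = FALSE)
  }
}

#' Default bridge edges between the burnout and depression constructs
#'
#' Three weak cross-construct connections with partial correlations 0.10,
#' 0.07 and 0.07: D17 with MBI-14, D14 with MBI-13 and D1 with MBI-7 — the
#' magnitude range typical of cross-disorder edges in symptom networks.
#'
#' @return data.frame with columns `i`, `j`, `rho` (indices in default order).
#' @export
default_bridges <- function() {
  labels <- default_item_labels(default_blocks())
  idx <- function(x) match(x, labels)
  data.frame(
    i = idx(c("D17", "D14", "D1")),
    j = idx(c("MBI-14", "MBI-13", "MBI-7")),
    rho = c(0.10, 0.07, 0.07)
  )
}

# Right-skewed default category probabilities (geometric-ish decay).
default_marginal <- function(k) {
  if (k == 7L) {
    pr <- c(0.28, 0.22, 0.17, 0.12, 0.09, 0.07, 0.05)
  } else if (k == 4L) {
    pr <- c(0.45, 0.30, 0.15, 0.10)
  } else {
    pr <- 0.6^(seq_len(k) - 1)
  }
  pr / sum(pr)
}

#' Build the planted precision matrix for a generator configuration
#'
#' Constructs a unit-diagonal precision matrix Theta with
#' `Theta[i, j] = -rho` for every within-block pair (at the block's `rho`)
#' and for every listed bridge edge; all other off-diagonal entries are
#' exactly zero. Positive definiteness is enforced through a strict
#' diagonal-dominance check, which fails with a diagnostic naming the worst
#' node if the requested magnitudes are too large.
#'
#' @param config a [generator_config()].
#' @return object of class `precision_spec` with elements `theta` (the
#'   precision matrix), `true_partials` (implied partial correlations, zero
#'   diagonal), `labels`, `block_id`.
#' @export
build_precision <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- length(config$labels)
  theta <- diag(p)
  bid <- config$block_id
  for (b in seq_len(nrow(config$blocks))) {
    nodes <- which(bid == b)
    rho <- config$blocks$rho[b]
    if (length(nodes) > 1 && rho != 0) {
      theta[nodes, nodes] <- -rho
      diag(theta)[nodes] <- 1
    }
  }
  be <- config$bridge_edges
  for (e in seq_len(nrow(be))) {
    theta[be$i[e], be$j[e]] <- -be$rho[e]
    theta[be$j[e], be$i[e]] <- -be$rho[e]
  }
  off <- rowSums(abs(theta)) - abs(diag(theta))
  if (any(off >= diag(theta))) {
    worst <- which.max(off - diag(theta))
    stop("requested precision matrix is not diagonally dominant at node ",
         config$labels[worst], " (off-diagonal mass ", round(off[worst], 3),
         "); reduce within-block or bridge partial correlations")
  }
  partials <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(partials) <- 0
  structure(list(theta = theta, true_partials = partials,
                 labels = config$labels, block_id = config$block_id),
            class = "precision_spec")
}

#' @export
print.precision_spec <- function(x, ...) {
  p <- nrow(x$theta)
  nz <- sum(x$true_partials[upper.tri(x$true_partials)] != 0)
  cat("Planted precision spec:", p, "nodes,", nz, "true edges,",
      length(unique(x$block_id)), "blocks\n")
  invisible(x)
}

#' Sample ordinal item responses from a planted Gaussian graphical model
#'
#' Draws latent vectors from the multivariate normal with covariance
#' `solve(theta)` (rescaled to unit marginal variances, which leaves partial
#' correlations untouched), then discretizes each margin at the
#' standard-normal quantiles of the item's cumulative category probabilities,
#' and finally flips reverse-keyed items. Categories whose probability is
#' zero are merged into their neighbour with a warning.
#'
#' @param spec a [build_precision()] result.
#' @param config the matching [generator_config()].
#' @return an `item_response_table`: integer matrix `n x p` with item labels
#'   as column names and attributes `item_levels`, `item_min`,
#'   `reverse_keyed`, `block_id`.
#' @export
sample_responses <- function(spec, config) {
  stopifnot(inherits(spec, "precision_spec"), inherits(config, "generator_config"))
  p <- length(config$labels)
  n <- config$n_respondents
  sigma <- solve(spec$theta)
  d <- sqrt(diag(sigma))
  sigma <- sigma / (d %o% d)   # unit-variance margins; partials invariant
  set.seed(config$seed)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
  x <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    pr <- config$marginal_probs[[j]]
    if (any(pr == 0)) {
      warning("item ", config$labels[j],
              ": empty categories merged with neighbours")
      pr <- pr[pr > 0]
    }
    cuts <- stats::qnorm(cumsum(pr)[-length(pr)])
    x[, j] <- config$item_min[j] +
      as.integer(findInterval(z[, j], cuts))
  }
  for (j in config$reverse_keyed) {
    lo <- config$item_min[j]
    hi <- lo + config$item_levels[j] - 1L
    x[, j] <- lo + hi - x[, j]
  }
  colnames(x) <- config$labels
  structure(x, class = c("item_response_table", "matrix", "array"),
            item_levels = config$item_levels, item_min = config$item_min,
            reverse_keyed = config$reverse_keyed, block_id = config$block_id)
}

#' Simulate a full synthetic survey dataset
#'
#' Convenience wrapper: builds the precision matrix and samples responses.
#'
#' @inheritParams sample_responses
#' @param config a [generator_config()].
#' @return list with elements `responses` (item_response_table) and `truth`
#'   (precision_spec).
#' @export
simulate_survey <- function(config = generator_config()) {
  spec <- build_precision(config)
  list(responses = sample_responses(spec, config), truth = spec)
}

#' Apply (or undo) reverse keying to selected columns
#'
#' Reverse keying maps a response `x` on `[lo, hi]` to `lo + hi - x`; the map
#' is its own inverse.
#'
#' @param x item response matrix.
#' @param items column indices to flip.
#' @param lo,hi response range per flipped item (recycled).
#' @return the matrix with the selected columns recoded.
#' @export
reverse_key <- function(x, items, lo, hi) {
  lo <- rep_len(lo, length(items)); hi <- rep_len(hi, length(items))
  for (k in seq_along(items)) {
    j <- items[k]
    x[, j] <- lo[k] + hi[k] - x[, j]
  }
  x
}

#' Write a simulated dataset to disk
#'
#' The responses go to CSV (header = item labels, integer cells); the planted
#' truth goes to a JSON sidecar holding the precision matrix, the implied
#' partial correlations and the block assignment, for recovery testing.
#'
#' @param sim result of [simulate_survey()].
#' @param csv path for the response table.
#' @param truth_json optional path for the truth sidecar.
#' @return invisibly, the paths written.
#' @export
write_survey <- function(sim, csv, truth_json = NULL) {
  utils::write.csv(as.data.frame(unclass(sim$responses)), csv, row.names = FALSE)
  if (!is.null(truth_json)) {
    jsonlite::write_json(list(
      labels = sim$truth$labels,
      block_id = sim$truth$block_id,
      theta = sim$truth$theta,
      true_partials = sim$truth$true_partials
    ), truth_json, digits = NA, auto_unbox = TRUE)
  }
  invisible(c(csv = csv, truth_json = truth_json))
}

#' Read an item-response table from CSV
#'
#' @param path CSV file with one row per respondent, item labels as header.
#' @return integer matrix with item labels as column names.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}
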