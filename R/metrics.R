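as_weight_matrix <- function(model) {
  if (inherits(model, "network_model")) model$weights else {
    w <- as.matrix(model)
    stopifnot(nrow(w) == ncol(w))
    w
  }
}

#' Expected influence centrality
#'
#' One-step expected influence of node i: the sum of its signed edge
#' weights, `EI_i = sum_{j != i} w_ij`.
#'
#' @param model `network_model` or weight matrix.
#' @return named numeric vector.
#' @export
expected_influence <- function(model) {
  w <- as_weight_matrix(model)
  diag(w) <- 0
  rowSums(w)
}

#' Bridge expected influence centrality
#'
#' Sum of a node's signed edge weights to nodes outside its own group,
#' `BEI_i = sum_{j: g(j) != g(i)} w_ij`. The grouping is typically the
#' two-construct split (depression items vs burnout items); empirical
#' communities from [walktrap_communities()] can be passed instead.
#'
#' @param model `network_model` or weight matrix.
#' @param groups vector of group labels, one per node, or a
#'   `community_assignment`.
#' @return named numeric vector.
#' @export
bridge_expected_influence <- function(model, groups) {
  w <- as_weight_matrix(model)
  diag(w) <- 0
  if (inherits(groups, "community_assignment")) groups <- groups$membership
  if (length(groups) != nrow(w)) stop("groups must cover every node")
  cross <- outer(groups, groups, FUN = "!=")
  rowSums(w * cross)
}

#' Two-construct node grouping from item labels
#'
#' Assigns `"burnout"` to MBI items and `"depression"` to the rest, the
#' fixed split used for bridge centrality.
#'
#' @param labels character vector of node labels.
#' @return character vector of group labels.
#' @export
construct_groups <- function(labels) {
  ifelse(grepl("^MBI", labels), "burnout", "depression")
}

#' Node predictability
#'
#' Proportion of a node's variance explained by its network neighbours:
#' each (transformed) node is regressed by ordinary least squares on the
#' nodes it shares a nonzero edge with, and the R-squared is reported,
#' floored at 0. Nodes without neighbours get 0. With `neighbors = "all"`
#' every other node enters the regression (nodewise mode).
#'
#' @param x numeric data matrix (same columns as the model's nodes),
#'   typically the nonparanormal-transformed responses.
#' @param model `network_model` or weight matrix defining adjacency.
#' @param neighbors `"network"` (default) to use the model's nonzero edges,
#'   `"all"` for all other nodes.
#' @return named numeric vector of R-squared values in `[0, 1]`.
#' @export
predictability <- function(x, model, neighbors = c("network", "all")) {
  neighbors <- match.arg(neighbors)
  w <- as_weight_matrix(model)
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(nrow(w) == p)
  out <- numeric(p)
  for (j in seq_len(p)) {
    nb <- if (neighbors == "all") setdiff(seq_len(p), j) else which(w[j, ] != 0)
    if (length(nb) == 0) { out[j] <- 0; next }
    if (nrow(x) <= length(nb) + 1) {
      stop("not enough rows to regress node ", j, " on its ", length(nb),
           " neighbours")
    }
    fit <- stats::lm.fit(cbind(1, x[, nb, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    out[j] <- max(0, 1 - rss / tss)
  }
  names(out) <- colnames(w)
  out
}

#' Walktrap community detection
#'
#' Runs the Walktrap algorithm (short random walks as node distances,
#' agglomerative merging, dendrogram cut at maximum modularity) on the
#' network. Edge weights enter as absolute values: the random-walk
#' transition matrix is undefined for signed graphs, so connection strength
#' is what drives the walk. Isolated nodes become singleton communities
#' with a warning.
#'
#' @param model `network_model` or weight matrix.
#' @param steps random-walk length (default 4).
#' @return object of class `community_assignment`: `membership` (integer
#'   labels, contiguous from 1), `n_communities`, `modularity` (of the
#'   chosen partition on the absolute-weight graph), `labels`.
#' @export
walktrap_communities <- function(model, steps = 4) {
  w <- as_weight_matrix(model)
  labels <- colnames(w)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(w)))
  aw <- abs(w)
  diag(aw) <- 0
  if (all(aw == 0)) stop("walktrap needs at least one edge")
  iso <- which(rowSums(aw) == 0)
  if (length(iso) > 0) {
    warning(length(iso), " isolated node(s) become singleton communities")
  }
  g <- igraph::graph_from_adjacency_matrix(aw, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- integer(ncol(w))
  keep <- setdiff(seq_len(ncol(w)), iso)
  sub <- igraph::induced_subgraph(g, keep)
  wt <- igraph::cluster_walktrap(sub, steps = steps)
  memb[keep] <- as.integer(igraph::membership(wt))
  if (length(iso) > 0) memb[iso] <- max(memb) + seq_along(iso)
  memb <- match(memb, unique(memb))  # contiguous labels
  structure(list(
    membership = stats::setNames(memb, labels),
    n_communities = length(unique(memb)),
    modularity = igraph::modularity(g, memb,
                                    weights = igraph::E(g)$weight),
    labels = labels,
    steps = steps,
    weights_used = "absolute"
  ), class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat("Walktrap communities:", x$n_communities, "communities, modularity",
      sprintf("%.4f", x$modularity), "\n")
  print(split(x$labels, x$membership))
  invisible(x)
}

#' Centrality table for a network model
#'
#' Collects expected influence, bridge expected influence, predictability
#' and their z-scored versions (z-scored across nodes) into one table.
#'
#' @param model `network_model`.
#' @param x data matrix used for predictability (transformed responses);
#'   if `NULL`, predictability is `NA`.
#' @param groups grouping for bridge centrality; defaults to the
#'   two-construct split derived from node labels.
#' @param communities optional `community_assignment` to attach.
#' @return data.frame with columns `node`, `community`, `expected_influence`,
#'   `bridge_expected_influence`, `predictability`, `z_ei`, `z_bei`.
#' @export
centrality_table <- function(model, x = NULL,
                             groups = construct_groups(model$labels),
                             communities = NULL) {
  ei <- expected_influence(model)
  bei <- bridge_expected_influence(model, groups)
  pred <- if (is.null(x)) rep(NA_real_, length(ei)) else predictability(x, model)
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  data.frame(
    node = model$labels,
    community = if (is.null(communities)) NA_integer_ else
      as.integer(communities$membership),
    group = groups,
    expected_influence = as.numeric(ei),
    bridge_expected_influence = as.numeric(bei),
    predictability = as.numeric(pred),
    z_ei = zs(as.numeric(ei)),
    z_bei = zs(as.numeric(bei)),
    row.names = NULL
  )
}
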