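#' Product-moment correlation matrix for network estimation
#'
#' Computes the Pearson correlation matrix of the (typically nonparanormal-
#' transformed) item columns, forces exact symmetry and a unit diagonal, and
#' floors negative eigenvalues if sampling noise makes the matrix indefinite
#' (recorded in the `eigen_floored` attribute).
#'
#' @param x numeric matrix, respondents by items.
#' @return correlation matrix with attributes `n` (rows used) and
#'   `eigen_floored`.
#' @export
item_correlations <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) warning("fewer respondents than items; correlations unstable")
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  floored <- FALSE
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    e <- eigen(r, symmetric = TRUE)
    vals <- pmax(e$values, 1e-8)
    r <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(r))
    r <- r / (d %o% d)
    diag(r) <- 1
    floored <- TRUE
  }
  attr(r, "n") <- n
  attr(r, "eigen_floored") <- floored
  r
}

#' Graphical lasso at a single penalty
#'
#' L1-penalized maximum-likelihood precision estimation: maximizes
#' `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' (diagonal unpenalized) by blockwise coordinate descent. Entries shrunk to
#' zero are exact zeros.
#'
#' @param S correlation (or covariance) matrix, positive semidefinite.
#' @param lambda nonnegative penalty.
#' @param maxit maximum outer sweeps.
#' @param tol convergence tolerance, relative to the mean absolute
#'   off-diagonal of `S`.
#' @return list with `theta` (precision matrix), `w` (estimated covariance),
#'   `niter`, `converged`.
#' @export
glasso_fit <- function(S, lambda, maxit = 200, tol = 1e-4) {
  if (lambda < 0) stop("lambda must be nonnegative")
  S <- unclass(as.matrix(S))
  fit <- .glasso_cpp(S, lambda, as.integer(maxit), tol)
  if (!fit$converged) {
    warning("graphical lasso did not converge at lambda = ",
            signif(lambda, 4), " after ", fit$niter, " sweeps")
  }
  fit
}

#' Convert a precision matrix to partial correlations
#'
#' `w_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`, zero diagonal. Entries
#' with absolute value below `zero_tol` are set to exactly zero so edge
#' counts reflect genuine support.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @param zero_tol magnitude below which a weight counts as an absent edge.
#' @return symmetric zero-diagonal weight matrix.
#' @export
precision_to_partials <- function(theta, zero_tol = 1e-8) {
  d <- sqrt(diag(theta))
  w <- -theta / (d %o% d)
  diag(w) <- 0
  w[abs(w) < zero_tol] <- 0
  (w + t(w)) / 2
}

ebic_value <- function(theta, S, n, gamma, zero_tol = 1e-8) {
  p <- nrow(S)
  w <- precision_to_partials(theta, zero_tol)
  E <- sum(w[upper.tri(w)] != 0)
  loglik <- (n / 2) * (2 * sum(log(diag(chol(theta)))) - sum(S * theta))
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

#' Estimate a sparse partial-correlation network via EBIC-selected glasso
#'
#' Fits the graphical lasso along a descending penalty path (100 log-spaced
#' values from the largest absolute off-diagonal correlation down to 1% of
#' it by default) and selects the penalty minimizing the extended BIC,
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)` with `E` the number of
#' nonzero edges. `gamma = 0.5` gives the conventional conservative
#' selection; `gamma = 0` reduces to the ordinary BIC.
#'
#' @param S correlation matrix from [item_correlations()].
#' @param n sample size behind `S` (defaults to its `n` attribute).
#' @param gamma EBIC hyperparameter, nonnegative.
#' @param lambda_path optional descending vector of penalties.
#' @param nlambda,lambda_min_ratio path construction parameters when
#'   `lambda_path` is not given.
#' @param zero_tol magnitude below which a partial correlation is an absent
#'   edge.
#' @param labels node labels (defaults to the column names of `S`).
#' @return object of class `network_model`: `weights` (partial correlation
#'   matrix), `precision`, `lambda_selected`, `gamma`, `lambda_path`,
#'   `ebic_path`, `edge_counts`, `labels`, `n`.
#' @export
ebic_glasso <- function(S, n = attr(S, "n"), gamma = 0.5, lambda_path = NULL,
                        nlambda = 100, lambda_min_ratio = 0.01,
                        zero_tol = 1e-8, labels = colnames(S)) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (is.null(n)) stop("sample size n is required for EBIC")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (is.null(lambda_path)) {
    lam_max <- max(abs(S[upper.tri(S)]))
    if (lam_max <= 0) lam_max <- 1e-4  # independence: any penalty empties the path
    lambda_path <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                           length.out = nlambda))
  }
  if (length(lambda_path) < 2) stop("penalty path needs at least 2 values")
  if (is.unsorted(rev(lambda_path), strictly = FALSE)) {
    stop("lambda_path must be descending")
  }
  path <- .glasso_path_cpp(unclass(S), lambda_path, 200L, 1e-4)
  nl <- length(lambda_path)
  ebic <- numeric(nl)
  edges <- integer(nl)
  for (i in seq_len(nl)) {
    th <- path$thetas[[i]]
    w <- precision_to_partials(th, zero_tol)
    edges[i] <- sum(w[upper.tri(w)] != 0)
    ebic[i] <- ebic_value(th, S, n, gamma, zero_tol)
  }
  best <- which.min(ebic)
  theta <- path$thetas[[best]]
  weights <- precision_to_partials(theta, zero_tol)
  dimnames(weights) <- list(labels, labels)
  if (all(edges == 0)) warning("selected network is empty along the whole path")
  structure(list(
    weights = weights,
    precision = theta,
    lambda_selected = lambda_path[best],
    gamma = gamma,
    lambda_path = lambda_path,
    ebic_path = ebic,
    edge_counts = edges,
    labels = labels,
    n = n
  ), class = "network_model")
}

#' One-call network estimation from raw item responses
#'
#' Chains the default pipeline: nonparanormal transform, product-moment
#' correlations, EBIC-selected graphical lasso.
#'
#' @param x item response matrix (respondents by items).
#' @param gamma EBIC hyperparameter.
#' @param ... passed to [ebic_glasso()].
#' @return a `network_model`.
#' @export
estimate_network <- function(x, gamma = 0.5, ...) {
  z <- npn_transform(x)
  S <- item_correlations(z)
  ebic_glasso(S, gamma = gamma, labels = colnames(as.matrix(x)), ...)
}

#' @export
print.network_model <- function(x, ...) {
  p <- length(x$labels)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  pot <- p * (p - 1) / 2
  cat("Partial-correlation network: ", p, " nodes, ", ne, "/", pot,
      " edges (density ", sprintf("%.4f", ne / pot), ")\n",
      "lambda = ", signif(x$lambda_selected, 4),
      ", gamma = ", x$gamma, ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Extract the edge list of a network model
#'
#' @param model a `network_model` (or plain weight matrix).
#' @return data.frame (`node_i`, `node_j`, `weight`) sorted by decreasing
#'   absolute weight; zero-weight pairs omitted.
#' @export
edge_list <- function(model) {
  w <- if (inherits(model, "network_model")) model$weights else as.matrix(model)
  labels <- colnames(w)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(w)))
  ut <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  out <- data.frame(node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
                    weight = w[ut])
  out[order(-abs(out$weight)), , drop = FALSE]
}
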