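#' Nonparanormal (Gaussian copula) marginal transformation
#'
#' Maps each column through its shrunken empirical CDF followed by the
#' standard-normal quantile function: mid-ranks `r_i / (n + 1)` are
#' winsorized to `[delta_n, 1 - delta_n]` with
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, passed through `qnorm`, and
#' rescaled to unit sample variance. The transform is monotone per column
#' (ties keep identical values via mid-ranks) and makes heavily skewed
#' ordinal margins approximately standard normal, which is what the Gaussian
#' graphical model downstream assumes.
#'
#' @param x numeric matrix or data.frame, respondents by items.
#' @return numeric matrix of the same dimensions with attribute
#'   `winsor_bound` = `delta_n`.
#' @export
npn_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("nonparanormal transform needs at least 10 rows")
  const <- which(apply(x, 2, function(col) length(unique(col)) < 2))
  if (length(const) > 0) {
    nm <- colnames(x)[const[1]]
    stop("constant column cannot be transformed: ",
         if (is.null(nm)) const[1] else nm)
  }
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- apply(x, 2, function(col) {
    u <- rank(col, ties.method = "average") / (n + 1)
    u <- pmin(pmax(u, delta), 1 - delta)
    z <- stats::qnorm(u)
    z / stats::sd(z)
  })
  dimnames(out) <- dimnames(x)
  attr(out, "winsor_bound") <- delta
  out
}

# Steiger-type test for two dependent overlapping correlations r(i,k) vs
# r(j,k), with the mean correlation back-transformed from the average Fisher
# z (the Hittner variant). Returns the two-sided p-value.
dependent_cor_test <- function(r_ik, r_jk, r_ij, n) {
  z1 <- atanh(r_ik)
  z2 <- atanh(r_jk)
  if (isTRUE(all.equal(z1, z2))) return(1)  # identical profiles: no difference
  rm <- tanh((z1 + z2) / 2)
  cov_num <- r_ij * (1 - 2 * rm^2) - 0.5 * rm^2 * (1 - 2 * rm^2 - r_ij^2)
  c_val <- min(cov_num / (1 - rm^2)^2, 1 - 1e-12)
  z_stat <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - c_val)))
  2 * stats::pnorm(-abs(z_stat))
}

#' Screen for redundant item pairs (goldbricker-style)
#'
#' For each candidate pair of items whose zero-order correlation exceeds
#' `cor_min`, every third item k yields a dependent-correlations test of
#' whether `cor(i, k)` and `cor(j, k)` differ (Steiger's z with the
#' back-transformed mean correlation, two-sided at level `alpha`). A pair is
#' flagged as redundant when the proportion of significantly different
#' third-party correlations is below `threshold`: the two items relate to the
#' rest of the network interchangeably. Flagged pairs are reported, never
#' dropped automatically.
#'
#' @param x numeric matrix, respondents by items (raw responses by
#'   convention).
#' @param threshold proportion cutoff below which a pair counts as redundant
#'   (default 0.25).
#' @param alpha significance level of each dependent-correlations test
#'   (default 0.05).
#' @param cor_min minimum absolute zero-order correlation for a pair to be
#'   considered a redundancy candidate (default 0.5).
#' @return object of class `redundancy_report`: data.frame of candidate pairs
#'   with their proportion of significant differences and a `redundant` flag,
#'   plus the parameters as attributes.
#' @export
find_redundant_pairs <- function(x, threshold = 0.25, alpha = 0.05,
                                 cor_min = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (p < 3) stop("redundancy screening needs at least 3 items")
  if (n < 10) stop("too few rows for the dependent-correlations test")
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  r <- stats::cor(x)
  res <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (abs(r[i, j]) < cor_min) next
      ks <- setdiff(seq_len(p), c(i, j))
      pv <- vapply(ks, function(k) {
        dependent_cor_test(r[i, k], r[j, k], r[i, j], n)
      }, numeric(1))
      prop <- mean(pv < alpha)
      res[[length(res) + 1]] <- data.frame(
        item_i = labels[i], item_j = labels[j],
        zero_order_cor = r[i, j],
        prop_significant = prop,
        redundant = prop < threshold
      )
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else {
    data.frame(item_i = character(0), item_j = character(0),
               zero_order_cor = numeric(0), prop_significant = numeric(0),
               redundant = logical(0))
  }
  structure(out, class = c("redundancy_report", "data.frame"),
            threshold = threshold, alpha = alpha, cor_min = cor_min)
}

#' @export
print.redundancy_report <- function(x, ...) {
  nf <- sum(x$redundant)
  cat("Redundancy screen: ", nrow(x), " candidate pair(s), ", nf,
      " flagged (threshold = ", attr(x, "threshold"),
      ", alpha = ", attr(x, "alpha"), ")\n", sep = "")
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}
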