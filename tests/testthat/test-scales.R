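test_that("MBI-GS subscale scoring applies the printed severity cutoffs", {
  # build rows with prescribed subscale sums (items 1-5 EE, 6-9 DP, 10-15 RPE)
  row_with <- function(ee, dp, rpe) {
    spread <- function(total, k, cap = 6) {
      v <- rep(total %/% k, k)
      extra <- total - sum(v)
      if (extra > 0) v[seq_len(extra)] <- v[seq_len(extra)] + 1
      stopifnot(all(v <= cap), sum(v) == total)
      v
    }
    c(spread(ee, 5), spread(dp, 4), spread(rpe, 6))
  }
  cases <- rbind(
    row_with(16, 0, 0), row_with(11, 0, 0), row_with(15, 0, 0),
    row_with(10, 0, 0),
    row_with(0, 12, 0), row_with(0, 13, 0), row_with(0, 8, 0),
    row_with(0, 7, 0),
    row_with(0, 0, 22), row_with(0, 0, 23), row_with(0, 0, 18),
    row_with(0, 0, 17),
    row_with(0, 0, 0)
  )
  sc <- score_mbi(cases)
  expect_equal(as.character(sc$ee_severity[1:4]),
               c("severe", "moderate", "moderate", "mild"))
  expect_equal(as.character(sc$dp_severity[5:8]),
               c("moderate", "severe", "moderate", "mild"))
  expect_equal(as.character(sc$rpe_severity[9:12]),
               c("moderate", "severe", "moderate", "mild"))
  expect_equal(unlist(sc[13, c(1, 3, 5)], use.names = FALSE), c(0, 0, 0))
  expect_equal(as.character(unlist(sc[13, c(2, 4, 6)])),
               rep("mild", 3))
  expect_error(score_mbi(rep(7, 15)), "out of range")
  expect_error(score_mbi(rep(1, 14)), "expected 15")
})

test_that("SDS raw-to-standard conversion reproduces every printed anchor", {
  expect_identical(sds_standard_score(c(20L, 40L, 48L, 56L)),
                   c(25L, 50L, 60L, 70L))
  # band edges: 47 is the top of mild-to-moderate, 55 of moderate-to-severe
  expect_identical(sds_standard_score(c(41L, 47L, 55L, 80L)),
                   c(51L, 58L, 68L, 100L))
  expect_error(sds_standard_score(19), "20-80")
})

test_that("SDS scoring reverse-keys ten items and bands the standard score", {
  # all items at the keyed minimum: raw 20, standard 25, normal
  lo <- rep(1, 20); lo[sds_reverse_items()] <- 4
  sc <- score_sds(lo)
  expect_equal(sc$raw, 20L)
  expect_equal(sc$standard, 25L)
  expect_equal(as.character(sc$severity), "normal")

  # raw 40 -> standard 50 (mild_to_moderate); raw 56 -> standard 70 (severe)
  make_raw <- function(target) {
    # keyed item scores summing to target, spread over 20 items in 1-4
    v <- rep(1L, 20)
    extra <- target - 20
    i <- 1
    while (extra > 0) {
      add <- min(3L, extra)
      v[i] <- v[i] + add
      extra <- extra - add
      i <- i + 1
    }
    v[sds_reverse_items()] <- 5L - v[sds_reverse_items()]
    v
  }
  sc40 <- score_sds(make_raw(40))
  expect_equal(sc40$raw, 40L)
  expect_equal(sc40$standard, 50L)
  expect_equal(as.character(sc40$severity), "mild_to_moderate")
  sc56 <- score_sds(make_raw(56))
  expect_equal(sc56$standard, 70L)
  expect_equal(as.character(sc56$severity), "severe")
  sc48 <- score_sds(make_raw(48))
  expect_equal(sc48$standard, 60L)
  expect_equal(as.character(sc48$severity), "moderate_to_severe")

  expect_error(score_sds(rep(5, 20)), "out of range")
  expect_error(score_sds(rep(2, 20), reverse_keyed = 1:3), "reverse-keyed")
})

test_that("scoring is permutation-invariant over respondents", {
  set.seed(11)
  x_mbi <- matrix(sample(0:6, 20 * 15, replace = TRUE), 20, 15)
  x_sds <- matrix(sample(1:4, 20 * 20, replace = TRUE), 20, 20)
  perm <- sample(20)
  expect_equal(score_mbi(x_mbi)[perm, ],
               score_mbi(x_mbi[perm, ]), ignore_attr = TRUE)
  expect_equal(score_sds(x_sds)[perm, ],
               score_sds(x_sds[perm, ]), ignore_attr = TRUE)
})

test_that("cohort summary counts threshold exceedances exactly", {
  set.seed(21)
  n <- 1322
  x_mbi <- matrix(sample(0:6, n * 15, replace = TRUE), n, 15)
  x_sds <- matrix(sample(1:4, n * 20, replace = TRUE), n, 20)
  mbi <- score_mbi(x_mbi); sds <- score_sds(x_sds)
  cs <- cohort_summary(mbi, sds)
  # brute-force tally oracle
  expect_equal(cs$count, c(sum(mbi$emotional_exhaustion > 10),
                           sum(mbi$depersonalization > 7),
                           sum(mbi$reduced_professional_efficacy > 17),
                           sum(sds$standard > 62),
                           sum(sds$standard > 52)))
  expect_equal(cs$percent, round(100 * cs$count / n, 2))
  # the published male share: 375 of 1,322 is 28.37%
  expect_equal(round(100 * 375 / 1322, 2), 28.37)

  # single respondent below every threshold
  one <- cohort_summary(score_mbi(rep(0, 15)),
                        score_sds({v <- rep(1, 20)
                                   v[sds_reverse_items()] <- 4; v}))
  expect_equal(one$count, rep(0L, 5))
  expect_equal(one$percent, rep(0, 5))
})

test_that("cronbach alpha is 1 for duplicated items and near 0 for noise", {
  set.seed(5)
  base <- rnorm(200)
  expect_equal(cronbach_alpha(cbind(base, base, base)), 1)
  noise <- matrix(rnorm(200 * 10), 200, 10)
  expect_lt(abs(cronbach_alpha(noise)), 0.35)
})
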