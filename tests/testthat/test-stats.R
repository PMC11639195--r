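test_that("one-way ANOVA matches textbook hand computation", {
  a <- oneWayAnova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4)))
  # between MS = 1.5 (k-1 = 1), within MS = 4/4 = 1 -> F = 1.5
  expect_equal(a$F, 1.5, tolerance = 1e-12)
  expect_equal(a$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: exact limit
  same <- oneWayAnova(list(a = c(2, 3, 4), b = c(2, 3, 4), c = c(2, 3, 4)))
  expect_identical(same$F, 0)
  expect_identical(same$p, 1)

  expect_error(oneWayAnova(list(a = 1, b = c(1, 2))), "2 values")
})

test_that("analytic ANOVA p agrees with a permutation oracle", {
  set.seed(61)
  groups <- list(a = c(3.1, 4.2, 2.8, 3.9, 3.5),
                 b = c(4.0, 4.8, 3.7, 4.4, 5.1),
                 c = c(3.3, 3.0, 4.1, 3.6, 2.9))
  res <- oneWayAnova(groups)
  vals <- unlist(groups)
  lab <- rep(names(groups), lengths(groups))
  fstat <- function(v, l) {
    gm <- tapply(v, l, mean); n <- tapply(v, l, length)
    ssb <- sum(n * (gm - mean(v))^2) / (length(gm) - 1)
    ssw <- sum((v - gm[l])^2) / (length(v) - length(gm))
    ssb / ssw
  }
  f0 <- fstat(vals, lab)
  expect_equal(f0, res$F, tolerance = 1e-10)
  perm <- replicate(1e4, fstat(vals, sample(lab)))
  expect_lt(abs(mean(perm >= f0) - res$p), 0.02)
})

test_that("Tukey HSD matches the studentized-range formula", {
  set.seed(62)
  groups <- list(a = rnorm(6, 10), b = rnorm(6, 11), c = rnorm(6, 14))
  tk <- tukeyHsd(groups)
  # direct evaluation: q = |diff| / sqrt(MSW / n), p = ptukey(q, k, df)
  vals <- unlist(groups); lab <- rep(names(groups), lengths(groups))
  gm <- tapply(vals, lab, mean)
  msw <- sum((vals - gm[lab])^2) / (length(vals) - 3)
  for (r in seq_len(nrow(tk))) {
    pr <- strsplit(tk$pair[r], "-")[[1]]
    q <- abs(gm[pr[1]] - gm[pr[2]]) / sqrt(msw / 6)
    expect_equal(tk$pAdj[r],
                 as.numeric(ptukey(q, 3, length(vals) - 3,
                                   lower.tail = FALSE)),
                 tolerance = 1e-8)
  }

  # extreme separation: the shifted group is significant against all
  sep <- tukeyHsd(list(a = rnorm(5, 0, 0.01), b = rnorm(5, 0, 0.01),
                       c = rnorm(5, 100, 0.01)))
  cIdx <- grepl("c", sep$pair)
  expect_true(all(sep$significant[cIdx]))
  expect_false(any(sep$significant[!cIdx]))

  # identical groups: nothing flagged
  none <- tukeyHsd(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_false(any(none$significant))
})
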