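test_that("composite delay embedding has the stated count, order and errors", {
  # n=1, M=2, tau=1, N=10: 8 vectors of dimension 2
  x <- seq_len(10) / 10
  E <- embed_delay(x, M = 2L, tau = 1L)
  expect_equal(dim(E), c(8L, 2L))
  expect_equal(E[1, ], c(x[1], x[2]))
  # n=2, M=(2,2), tau=(1,1), N=100: 98 vectors of dimension 4
  set.seed(8)
  seg <- matrix(rnorm(200), 100, 2)
  E2 <- embed_delay(seg, M = c(2L, 2L), tau = c(1L, 1L))
  expect_equal(dim(E2), c(98L, 4L))
  # channel-by-channel element order per the composite delay vector
  expect_equal(E2[5, ], c(seg[5, 1], seg[6, 1], seg[5, 2], seg[6, 2]))
  # univariate case equals an independent Takens loop
  E3 <- embed_delay(x, M = 3L, tau = 2L)
  expect_equal(unname(E3), oracle_embed_uni(x, 3L, 2L, 10L - 6L))
  expect_error(embed_delay(x[1:4], M = 3L, tau = 2L), "too short")
})

test_that("msampen equals exhaustive enumeration on random multichannel segments", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:3, 1)
    N <- sample(25:60, 1)
    seg <- matrix(rnorm(N * n), N, n)
    if (rep %% 3 == 0) seg <- round(seg, 1)  # exercise distance ties
    M <- sample(1:3, n, replace = TRUE)
    tau <- sample(1:2, n, replace = TRUE)
    r <- runif(1, 0.1, if (rep %% 4 == 0) 4 else 1.2) * mean(apply(seg, 2, sd))
    want <- oracle_msampen(seg, M, tau, r)
    got <- msampen(seg, M, tau, r)
    expect_equal(got$B_m, want$B_m, tolerance = 1e-14)
    expect_equal(got$B_m1, want$B_m1, tolerance = 1e-14)
    if (is.finite(want$value)) expect_equal(got$value, want$value, tolerance = 1e-12)
  }
})

test_that("univariate msampen reduces to classic sample entropy", {
  x <- logistic_map(200)
  r <- 0.2 * sd(x)
  got <- msampen(x, M = 2L, tau = 1L, r = r)
  expect_equal(got$value, oracle_sampen_uni(x, 2L, 1L, r), tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:10) {
    y <- rnorm(120)
    ry <- runif(1, 0.15, 0.4) * sd(y)
    expect_equal(msampen(y, 2L, 1L, ry)$value,
                 oracle_sampen_uni(y, 2L, 1L, ry), tolerance = 1e-12)
  }
})

test_that("msampen handles constants, is monotone in r, and is channel-permutation symmetric", {
  cst <- matrix(1.5, 60, 2)
  e <- msampen(cst, 2L, 1L, r = 0.3)
  expect_true(e$defined)
  expect_identical(e$value, 0)  # -ln(1/1)
  expect_equal(e$B_m, 1); expect_equal(e$B_m1, 1)

  # monotone in r across moderate tolerances (away from the near-zero-match
  # regime, where the m+1 candidate set's same-origin pairs can dominate)
  set.seed(13)
  seg <- matrix(rnorm(600), 300, 2)
  rs <- c(0.25, 0.4, 0.6, 0.8, 1.2) * sum(apply(seg, 2, sd))
  vals <- vapply(rs, function(r) msampen(seg, 2L, 1L, r)$value, numeric(1))
  expect_true(all(is.finite(vals)))
  expect_true(all(diff(vals) <= 1e-12))

  seg3 <- matrix(rnorm(300), 100, 3)
  perm <- c(3, 1, 2)
  e1 <- msampen(seg3, c(2L, 3L, 2L), c(1L, 1L, 2L), r = 0.8)
  e2 <- msampen(seg3[, perm], c(2L, 3L, 2L)[perm], c(1L, 1L, 2L)[perm], r = 0.8)
  expect_equal(e1$value, e2$value, tolerance = 1e-14)
})

test_that("msampen is non-negative in the analysis regime and flags zero-match segments", {
  # under the summed-SD tolerance convention on realistic segment lengths,
  # conditional match probabilities are well below 1 and MSampEn >= 0
  set.seed(14)
  for (rep in 1:15) {
    n <- sample(2:3, 1)
    seg <- matrix(rnorm(400 * n), 400, n)
    e <- msampen(seg, 2L, 1L, r = 0.2 * sum(apply(seg, 2, sd)))
    expect_true(e$defined)
    expect_gte(e$value, 0)
    expect_lte(e$B_m1, e$B_m + 1e-15)
  }
  # tolerance of zero on continuous data: no matches -> flagged, not numeric
  seg <- matrix(rnorm(50 * 2), 50, 2)
  e0 <- msampen(seg, 2L, 1L, r = 0)
  expect_false(e0$defined)
  expect_true(is.na(e0$value))
})

test_that("tolerance follows the raw-SD-sum rule", {
  set.seed(15)
  a <- rnorm(500); a <- (a - mean(a)) / sd(a)        # SD exactly 1
  b <- a * 3                                          # SD exactly 3
  expect_equal(tolerance_from_raw(cbind(a, b)), 0.8)
  expect_equal(tolerance_from_raw(a), 0.2)
  seg <- matrix(rnorm(200), 100, 2)
  expect_equal(tolerance_from_raw(seg * 5), 5 * tolerance_from_raw(seg))
  expect_warning(r0 <- tolerance_from_raw(matrix(2, 10, 2)), "constant")
  expect_identical(r0, 0)
})

test_that("mmse_curve computes r once from the raw segment and spans all scales", {
  set.seed(16)
  x <- multichannel_signal(matrix(rnorm(700 * 3), 700, 3), 100, paste0("c", 1:3))
  dec <- memd(x, n_directions = 32L, max_modes = 6L)
  sc <- cumulative_scales(dec, min(7L, length(dec$imfs) + 1L))
  raw <- unclass(x)
  curve <- mmse_curve(raw, sc)
  expect_s3_class(curve, "mmse_curve")
  expect_identical(nrow(curve), length(sc))
  expect_identical(curve$scale, seq_along(sc))
  # the tolerance comes from the raw segment, not from any scale
  expect_equal(attr(curve, "r"), tolerance_from_raw(raw))
  # consistency: a raw segment passed as its own single scale, univariate
  v <- raw[, 1, drop = FALSE]
  c1 <- mmse_curve(v, list(v))
  expect_equal(c1$value, msampen(v, 2L, 1L, tolerance_from_raw(v))$value)
  expect_error(mmse_curve(raw[1:100, ], sc), "same samples")
})
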