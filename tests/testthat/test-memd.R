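test_that("projection is the per-sample inner product", {
  set.seed(7)
  x <- multichannel_signal(matrix(rnorm(200 * 4), 200, 4), 100,
                           paste0("c", 1:4))
  # axis-aligned basis vector returns the channel unchanged
  expect_equal(project_signal(x, c(0, 1, 0, 0)), unclass(x)[, 2])
  # two identical channels along (1,1)/sqrt(2) give sqrt(2) x channel
  y <- multichannel_signal(cbind(unclass(x)[, 1], unclass(x)[, 1]), 100, c("a", "b"))
  expect_equal(project_signal(y, c(1, 1) / sqrt(2)), sqrt(2) * unclass(x)[, 1])
  # random direction equals an element-wise loop
  d <- rnorm(4); d <- d / sqrt(sum(d^2))
  manual <- vapply(seq_len(200), function(t) sum(unclass(x)[t, ] * d), numeric(1))
  expect_equal(project_signal(x, d), manual)
  expect_error(project_signal(x, c(1, 0)), "channels")
})

test_that("local mean of a constant signal is that constant; pure tones average near zero", {
  dirs <- generate_directions(2L, 16L)
  cst <- matrix(c(rep(2, 300), rep(-1, 300)), 300, 2)
  # constant projections have no strict maxima -> monotonic-residual signal
  em <- envelope_local_mean(cst, dirs)
  expect_identical(em$n_valid, 0L)

  # 2-channel sinusoids, 20 periods: interior local mean is small
  t <- seq_len(2000)
  sig <- cbind(sin(2 * pi * 20 * t / 2000), cos(2 * pi * 20 * t / 2000))
  em <- envelope_local_mean(sig, generate_directions(2L, 64L))
  expect_gt(em$n_valid, 0L)
  interior <- 200:1800
  expect_lt(max(abs(em$mean[interior, ])), 0.05)
})

test_that("sifting: telescoping identity, single-iteration limit, tone recovery", {
  x <- tone_pair_signal()
  dirs <- generate_directions(2L, 64L)
  s <- sift_mode(unclass(x), dirs)
  expect_equal(s$mode + s$remainder, unclass(unclass(x)), tolerance = 1e-12)
  # infinite threshold stops after exactly one iteration with d = v - m
  s1 <- sift_mode(unclass(x), dirs, sd_threshold = Inf)
  expect_identical(s1$n_sift, 1L)
  em <- envelope_local_mean(unclass(x), dirs)
  expect_equal(s1$mode, unclass(x) - em$mean)
  # first mode tracks the fast tone
  t <- seq(0.01, 30, by = 0.01)
  expect_gt(abs(cor(s$mode[, 1], sin(2 * pi * 4 * t))), 0.99)
})

test_that("memd reconstructs, aligns modes, and separates a 4 Hz / 0.5 Hz pair", {
  x <- tone_pair_signal()
  dec <- memd(x)
  expect_lt(reconstruction_relerr(dec, x), 1e-10)
  dims <- vapply(c(dec$imfs, list(dec$residual)), ncol, integer(1))
  expect_true(all(dims == 2L))
  t <- seq(0.01, 30, by = 0.01)
  expect_gt(abs(cor(dec$imfs[[1]][, 1], sin(2 * pi * 4 * t))), 0.95)
  low_cors <- vapply(dec$imfs, function(m) abs(cor(m[, 1], sin(2 * pi * 0.5 * t))),
                     numeric(1))
  expect_gt(max(low_cors), 0.95)
  expect_gt(which.max(low_cors), 1L)
})

test_that("memd validates input and routes univariate signals to classic EMD", {
  bad <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(memd(bad), "finite")
  # univariate tone pair: classic EMD recovers both components
  t <- seq(0.01, 30, by = 0.01)
  u <- matrix(sin(2 * pi * 4 * t) + sin(2 * pi * 0.5 * t), ncol = 1)
  dec <- memd(u, max_modes = 5)
  expect_gt(length(dec$imfs), 1L)
  expect_gt(abs(cor(dec$imfs[[1]][, 1], sin(2 * pi * 4 * t))), 0.95)
  low <- vapply(dec$imfs, function(m) abs(cor(m[, 1], sin(2 * pi * 0.5 * t))), numeric(1))
  expect_gt(max(low), 0.95)
  expect_lt(reconstruction_relerr(dec, u), 1e-10)
})

test_that("noise augmentation appends seeded channels at EMG-comparable scale", {
  set.seed(3)
  x <- multichannel_signal(matrix(rnorm(500 * 16, sd = 2), 500, 16), 1000,
                           c(default_muscle_map()$left, default_muscle_map()$right))
  x22 <- add_noise_channels(x, 6L, seed = 9)
  expect_identical(n_channels(x22), 22L)
  expect_identical(unclass(x22)[, 1:16], unclass(x)[, ])
  # identical seed reproduces bit-identical noise; n_noise = 0 is a no-op
  expect_identical(unclass(add_noise_channels(x, 6L, seed = 9)), unclass(x22))
  expect_identical(add_noise_channels(x, 0L, seed = 9), x)
  # noise amplitude tracks the mean channel SD
  expect_equal(mean(apply(unclass(x22)[, 17:22], 2, sd)),
               mean(apply(unclass(x), 2, sd)), tolerance = 0.1)
})

test_that("stripping noise channels preserves modes and reconstruction", {
  set.seed(4)
  x <- multichannel_signal(matrix(rnorm(600 * 4), 600, 4), 100, paste0("c", 1:4))
  x6 <- add_noise_channels(x, 2L, seed = 5)
  dec <- memd(x6, n_directions = 32L, max_modes = 4L)
  dec4 <- strip_noise_channels(dec, 2L)
  expect_identical(ncol(dec4$residual), 4L)
  expect_identical(length(dec4$imfs), length(dec$imfs))
  expect_identical(dec4$labels, channel_labels(x))
  rec <- Reduce(`+`, c(dec4$imfs, list(dec4$residual)))
  expect_lt(norm(rec - unclass(x), "F") / norm(unclass(x), "F"), 1e-10)
  expect_identical(strip_noise_channels(dec, 0L), dec)
  expect_error(strip_noise_channels(dec, 6L), "cannot strip")
})

test_that("cumulative scales telescope exactly and bracket the signal", {
  set.seed(5)
  x <- multichannel_signal(matrix(rnorm(800 * 3), 800, 3), 100, paste0("c", 1:3))
  dec <- memd(x, n_directions = 32L, max_modes = 4L)
  sc <- cumulative_scales(dec)
  expect_length(sc, length(dec$imfs) + 1L)
  # scale 1 reconstructs the input
  expect_lt(norm(unclass(sc[[1]]) - unclass(x), "F") / norm(unclass(x), "F"), 1e-10)
  # last scale is the residual alone
  expect_equal(unclass(sc[[length(sc)]])[, ], dec$residual[, ])
  # bit-level telescoping: scale_n == scale_{n+1} + imf_n
  for (i in seq_along(dec$imfs)) {
    expect_identical(as.vector(sc[[i]]),
                     as.vector(unclass(sc[[i + 1L]]) + dec$imfs[[i]]))
  }
  expect_error(cumulative_scales(dec, 0L), ">= 1")
  expect_error(cumulative_scales(dec, length(dec$imfs) + 2L), "exceeds")
})

test_that("memd reconstruction and alignment hold on random multichannel signals", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    T_len <- sample(300:600, 1)
    x <- multichannel_signal(matrix(rnorm(T_len * n), T_len, n), 100,
                             paste0("c", seq_len(n)))
    dec <- memd(x, n_directions = 32L, max_modes = 5L)
    expect_lt(reconstruction_relerr(dec, x), 1e-10)
    expect_true(all(vapply(dec$imfs, ncol, integer(1)) == n))
  }
})
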