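test_that("accelerometer peak detection obeys threshold and spacing rules", {
  # constant signal: zero peaks, not an error
  expect_length(detect_acc_peaks(rep(1, 200), 100)$indices, 0L)
  expect_length(detect_acc_peaks(numeric(0), 100)$indices, 0L)

  # two impulses 0.1 s apart with min spacing 0.4 s: only the larger survives
  acc <- rnorm(500, sd = 0.01)
  acc[101] <- 1; acc[111] <- 0.8
  pk <- detect_acc_peaks(acc, 100, min_interval_s = 0.4)
  expect_identical(pk$indices, 100L)  # 0-based

  # synthetic strikes + noise are recovered within +/- 2 samples
  set.seed(21)
  t <- (0:999) / 100
  truth_s <- seq(0.5, 9.5, by = 1.1)
  a <- rowSums(sapply(truth_s, function(s) exp(-0.5 * ((t - s) / 0.03)^2))) +
    rnorm(1000, sd = 0.05)
  pk <- detect_acc_peaks(a, 100)
  expect_identical(length(pk$indices), length(truth_s))
  expect_true(all(abs(pk$indices - round(truth_s * 100)) <= 2))
})

test_that("gait cycles follow the ipsilateral/contralateral strike rule", {
  left <- heel_strikes(c(100L, 200L), 100, "left")
  right <- heel_strikes(150L, 100, "right")
  cyc <- build_gait_cycles(left, right, emg_rate = 1000)
  expect_identical(nrow(cyc), 1L)
  expect_identical(cyc$start, 1000L)
  expect_identical(cyc$stance_end, 1500L)
  expect_identical(cyc$end, 2000L)
  expect_identical(cyc$side, "left")

  # strike pair without an intervening contralateral strike is dropped
  left2 <- heel_strikes(c(100L, 200L, 300L), 100, "left")
  cyc2 <- build_gait_cycles(left2, right, 1000)
  expect_identical(nrow(cyc2), 1L)
  expect_identical(attr(cyc2, "n_dropped"), 1L)

  # two intervening contralateral strikes also invalidate the pair
  right2 <- heel_strikes(c(120L, 180L), 100, "right")
  cyc3 <- build_gait_cycles(left, right2, 1000)
  expect_identical(nrow(cyc3), 0L)

  # duration bounds: a 0.3 s "cycle" is rejected
  fast <- build_gait_cycles(heel_strikes(c(100L, 130L), 100, "left"),
                            heel_strikes(115L, 100, "right"), 1000)
  expect_identical(nrow(fast), 0L)
  expect_error(build_gait_cycles(left, heel_strikes(integer(0), 100), 1000),
               "non-empty")
})

test_that("segment extraction partitions the cycle and validates labels", {
  set.seed(22)
  labs <- c(default_muscle_map()$left, default_muscle_map()$right)
  emg <- multichannel_signal(matrix(rnorm(3000 * 16), 3000, 16), 1000, labs)
  cyc <- tibble::tibble(side = "left", start = 1000L,
                        stance_end = 1600L, end = 2100L)
  full <- extract_segment(emg, cyc, "full")
  stance <- extract_segment(emg, cyc, "stance")
  swing <- extract_segment(emg, cyc, "swing")
  expect_identical(nrow(full), nrow(stance) + nrow(swing))
  expect_identical(ncol(full), 16L)
  expect_equal(full, rbind(stance, swing))
  sub <- extract_segment(emg, cyc, "full", channels = c("L_TA", "L_SO", "L_LG"))
  expect_identical(ncol(sub), 3L)
  expect_error(extract_segment(emg, cyc, "full", channels = "L_XX"),
               "valid labels")
  bad <- tibble::tibble(side = "left", start = 2500L, stance_end = 2900L, end = 3500L)
  expect_error(extract_segment(emg, bad, "full"), "bounds")
})

test_that("artifact rejection drops exactly the spiked cycle", {
  set.seed(23)
  labs <- paste0("c", 1:4)
  m <- matrix(rnorm(5000 * 4), 5000, 4)
  cyc <- tibble::tibble(side = rep("left", 4),
                        start = c(0L, 1000L, 2000L, 3000L),
                        stance_end = c(600L, 1600L, 2600L, 3600L),
                        end = c(1000L, 2000L, 3000L, 4000L))
  emg_clean <- multichannel_signal(m, 1000, labs)
  # infinite threshold: identity
  kept <- reject_artifact_cycles(emg_clean, cyc, z_threshold = Inf)
  expect_identical(nrow(kept), 4L)
  # inject a 50-SD spike into cycle 3
  m2 <- m
  m2[2500, 2] <- 50 * sd(m[, 2])
  kept2 <- reject_artifact_cycles(multichannel_signal(m2, 1000, labs), cyc, 8)
  expect_identical(nrow(kept2), 3L)
  expect_false(2000L %in% kept2$start)
  expect_identical(attr(kept2, "n_rejected"), 1L)
})

test_that("segmentation recovers ground-truth cycles from generator output", {
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    sub <- generate_subject(subject_profile("control", n_cycles = 8, seed = seed))
    pkL <- detect_acc_peaks(as.vector(unclass(sub$acc_left)), 100, side = "left")
    pkR <- detect_acc_peaks(as.vector(unclass(sub$acc_right)), 100, side = "right")
    cyc <- rbind(build_gait_cycles(pkL, pkR, 1000),
                 build_gait_cycles(pkR, pkL, 1000))
    truth <- sub$truth$cycles
    total <- total + nrow(truth)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      match <- cyc[cyc$side == tr$side &
                   abs(cyc$start - tr$start) <= 20 &
                   abs(cyc$end - tr$end) <= 20 &
                   abs(cyc$stance_end - tr$stance_end) <= 20, ]
      if (nrow(match) == 1L) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("cycles are ordered, non-overlapping, and stance/swing partition each cycle", {
  sub <- generate_subject(subject_profile("spastic", n_cycles = 10, seed = 31))
  pkL <- detect_acc_peaks(as.vector(unclass(sub$acc_left)), 100, side = "left")
  pkR <- detect_acc_peaks(as.vector(unclass(sub$acc_right)), 100, side = "right")
  for (pair in list(list(pkL, pkR), list(pkR, pkL))) {
    cyc <- build_gait_cycles(pair[[1]], pair[[2]], 1000)
    expect_true(all(cyc$start < cyc$stance_end))
    expect_true(all(cyc$stance_end < cyc$end))
    expect_true(all(diff(cyc$start) > 0))
    expect_true(all(head(cyc$end, -1) <= tail(cyc$start, -1) + 1))
  }
})
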