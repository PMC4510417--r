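#' Canonical lower-limb EMG montage
#'
#' Eight muscles per leg: five thigh muscles — vastus lateralis (VL), rectus
#' femoris (RF), semitendinosus (SE), biceps femoris (BF), tensor fasciae
#' latae (TF) — and three lower-leg muscles — tibialis anterior (TA), soleus
#' (SO), lateral gastrocnemius (LG). Channel labels prefix the side, e.g.
#' `L_VL`, `R_TA`.
#'
#' @return `default_muscles()`: the 8 muscle abbreviations;
#'   `default_muscle_map()`: a list with elements `left` and `right` of 8
#'   channel labels each.
#' @export
default_muscles <- function() c("VL", "RF", "SE", "BF", "TF", "TA", "SO", "LG")

#' @rdname default_muscles
#' @export
default_muscle_map <- function() {
  m <- default_muscles()
  list(left = paste0("L_", m), right = paste0("R_", m))
}

thigh_muscles <- function() c("VL", "RF", "SE", "BF", "TF")
lower_leg_muscles <- function() c("TA", "SO", "LG")

# textbook activation windows as phase fractions of the gait cycle
# (heel strike at phase 0; windows may wrap past 1)
default_activation_windows <- function() {
  list(
    VL = c(0.92, 0.25),  # loading response / early stance
    RF = c(0.92, 0.20),
    SE = c(0.75, 0.05),  # terminal swing / heel strike (hamstrings)
    BF = c(0.75, 0.05),
    TF = c(0.95, 0.30),
    TA = c(0.55, 0.08),  # swing clearance + heel strike
    SO = c(0.15, 0.55),  # mid-to-late stance push-off
    LG = c(0.15, 0.55)
  )
}

#' Synthetic subject profile
#'
#' Parameterizes one simulated walker: cadence, per-muscle activation
#' windows and burst amplitudes, and a shared-drive coupling knob. Group
#' presets emulate the mechanisms thought to alter coactivation complexity:
#' `"control"` — moderate physiological coupling across all 8 muscles of each
#' leg; `"spastic"` — strong shared drive across the thigh muscles and
#' stance-widened thigh activation windows (over-activation / abnormal
#' synchronization); `"paretic"` — attenuated lower-leg amplitudes (default
#' x 0.3) with the lower-leg muscles decoupled from the shared drive
#' (insufficient motor output, loss of couplings).
#'
#' @param group `"control"`, `"spastic"` or `"paretic"`.
#' @param n_cycles number of gait cycles to simulate (default 12).
#' @param cadence_s mean gait-cycle duration in seconds (default 1.1,
#'   self-selected child walking pace).
#' @param cadence_jitter_s SD of per-cycle duration jitter (default 0.05).
#' @param rho coupling strength in `[0, 1]`: carriers of the coupled muscle
#'   subset mix a per-leg shared drive with weight `sqrt(rho)` so their
#'   pairwise correlation equals `rho`.
#' @param coupled_muscles muscle abbreviations sharing the drive.
#' @param amplitude named per-muscle burst amplitudes (arbitrary units).
#' @param windows named list of `(start, end)` activation phase fractions.
#' @param seed integer RNG seed for this subject.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(group = c("control", "spastic", "paretic"),
                            n_cycles = 12L,
                            cadence_s = 1.1, cadence_jitter_s = 0.05,
                            rho = NULL, coupled_muscles = NULL,
                            amplitude = NULL, windows = NULL,
                            seed = 1L) {
  group <- match.arg(group)
  muscles <- default_muscles()
  if (is.null(windows)) {
    windows <- default_activation_windows()
    if (group == "spastic") {
      for (m in thigh_muscles()) {
        w <- windows[[m]]
        w[2] <- (w[2] + 0.15) %% 1  # widen into stance
        windows[[m]] <- w
      }
    }
  }
  if (is.null(amplitude)) {
    amplitude <- setNames(rep(1, 8), muscles)
    if (group == "paretic") amplitude[lower_leg_muscles()] <- 0.3
  }
  if (is.null(rho))
    rho <- switch(group, control = 0.3, spastic = 0.85, paretic = 0.3)
  if (is.null(coupled_muscles))
    coupled_muscles <- switch(group,
      control = muscles, spastic = thigh_muscles(), paretic = thigh_muscles())
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  for (m in muscles) {
    w <- windows[[m]]
    if (is.null(w) || length(w) != 2 || any(w < 0) || any(w >= 1))
      stop("activation window for ", m, " must be two phase fractions in [0, 1)")
  }
  if (any(amplitude < 0)) stop("burst amplitudes must be >= 0")
  structure(list(group = group, n_cycles = as.integer(n_cycles),
                 cadence_s = cadence_s, cadence_jitter_s = cadence_jitter_s,
                 rho = rho, coupled_muscles = coupled_muscles,
                 amplitude = amplitude, windows = windows,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' Band-limited Gaussian noise
#'
#' Gaussian white noise band-pass filtered to the surface-EMG band with a
#' 4th-order zero-phase Butterworth filter and scaled to unit variance: the
#' generator's EMG carrier process, also useful on its own as a broadband
#' synthetic EMG stand-in. Draws from the current RNG stream.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 20 and 450).
#' @return Numeric vector of length `n` with unit SD.
#' @export
band_limited_noise <- function(n, rate, low = 20, high = 450) {
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n + 2000))[1001:(n + 1000)]
  x / sd(x)
}

# soft dynamic-range limit emulating the recording front-end: amplitudes are
# compressed smoothly and never exceed `limit` carrier SDs
soft_limit <- function(x, limit = 3.5) limit * tanh(x / limit)

# smooth activation envelope over phase in [0,1): tonic baseline plus a Hann
# burst on the (possibly wrapping) activation window, peak normalized to 1
activation_envelope <- function(phase, window, baseline = 0.25) {
  a <- window[1]; b <- window[2]
  width <- (b - a) %% 1
  if (width == 0) width <- 1
  u <- ((phase - a) %% 1) / width
  inside <- u >= 0 & u <= 1
  baseline + (1 - baseline) * ifelse(inside, 0.5 - 0.5 * cos(2 * pi * u), 0)
}

#' Generate one synthetic gait-EMG subject
#'
#' Simulates a 16-channel surface EMG recording at 1 kHz plus bilateral
#' single-axis accelerometer traces at 100 Hz for one walking subject. Each
#' muscle's EMG is a smooth phase-locked activation envelope (tonic baseline
#' plus a Hann burst over the muscle's activation window) multiplying a
#' band-limited (20-450 Hz) Gaussian carrier; carriers of the profile's
#' coupled muscle subset mix a per-leg shared drive with weight
#' `sqrt(rho)`, and are soft-limited at 3.5 carrier SDs, emulating the
#' finite dynamic range of a recording front-end. The legs alternate half a
#' cycle out of phase. Each
#' accelerometer trace carries a smoothed impulse at every ipsilateral heel
#' strike plus measurement noise. Fully seeded and reproducible.
#'
#' @param profile a [subject_profile()].
#' @param emg_rate,acc_rate sampling rates in Hz (defaults 1000 and 100).
#' @return An object of class `sim_subject`: list with `emg` (16-channel
#'   [multichannel_signal()]), `acc_left`, `acc_right` (1-channel
#'   `mc_signal`s), and `truth` — ground truth containing heel-strike times
#'   per side (seconds), the true cycles table (EMG-rate indices), per-channel
#'   envelope traces and the coupling configuration.
#' @export
generate_subject <- function(profile, emg_rate = 1000, acc_rate = 100) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed_local(profile$seed, generate_subject_impl(profile, emg_rate, acc_rate))
}

generate_subject_impl <- function(profile, emg_rate, acc_rate) {
  nc <- profile$n_cycles
  durs <- pmax(0.6, rnorm(nc, profile$cadence_s, profile$cadence_jitter_s))
  lead_s <- 0.5
  strikes_left <- lead_s + c(0, cumsum(durs))            # n_cycles + 1 strikes
  strikes_right <- c(strikes_left[seq_len(nc)] + 0.5 * durs,
                     strikes_left[nc + 1L] + 0.5 * mean(durs))
  total_s <- strikes_right[nc + 1L] + 0.5
  T_emg <- ceiling(total_s * emg_rate)
  t_emg <- (seq_len(T_emg) - 1) / emg_rate

  phase_left <- phase_from_strikes(t_emg, strikes_left)
  phase_right <- phase_from_strikes(t_emg, strikes_right)

  muscles <- default_muscles()
  map <- default_muscle_map()
  labels <- c(map$left, map$right)
  emg <- matrix(0, T_emg, 16L)
  env_mat <- matrix(0, T_emg, 16L)
  colnames(env_mat) <- labels
  coupling <- matrix(0, 16L, 16L, dimnames = list(labels, labels))
  diag(coupling) <- 1

  col <- 0L
  for (side in c("left", "right")) {
    phase <- if (side == "left") phase_left else phase_right
    drive <- band_limited_noise(T_emg, emg_rate)
    coupled <- paste0(ifelse(side == "left", "L_", "R_"), profile$coupled_muscles)
    for (m in muscles) {
      col <- col + 1L
      lab <- labels[col]
      own <- band_limited_noise(T_emg, emg_rate)
      carrier <- soft_limit(if (lab %in% coupled)
        sqrt(1 - profile$rho) * own + sqrt(profile$rho) * drive else own)
      env <- profile$amplitude[[m]] *
        activation_envelope(phase, profile$windows[[m]])
      env[is.na(phase)] <- profile$amplitude[[m]] * 0.25  # tonic outside cycles
      env_mat[, col] <- env
      emg[, col] <- env * carrier +
        rnorm(T_emg, sd = 0.02 * max(profile$amplitude[[m]], 1e-3))
    }
    ii <- match(coupled, labels)
    coupling[ii, ii] <- profile$rho
    diag(coupling) <- 1
  }

  T_acc <- ceiling(total_s * acc_rate)
  t_acc <- (seq_len(T_acc) - 1) / acc_rate
  acc_left <- acc_trace(t_acc, strikes_left)
  acc_right <- acc_trace(t_acc, strikes_right)

  true_cycles <- true_cycle_table(strikes_left, strikes_right, emg_rate)

  list(
    emg = multichannel_signal(emg, emg_rate, labels),
    acc_left = multichannel_signal(matrix(acc_left, ncol = 1), acc_rate, "L_ACC"),
    acc_right = multichannel_signal(matrix(acc_right, ncol = 1), acc_rate, "R_ACC"),
    truth = list(strikes_left = strikes_left, strikes_right = strikes_right,
                 cycles = true_cycles, envelopes = env_mat,
                 coupling = coupling, rho = profile$rho,
                 coupled_muscles = profile$coupled_muscles)
  ) |> structure(class = "sim_subject")
}

# cycle phase in [0, 1) between consecutive strikes; NA outside
phase_from_strikes <- function(t, strikes) {
  k <- findInterval(t, strikes)
  ok <- k >= 1 & k < length(strikes)
  phase <- rep(NA_real_, length(t))
  kk <- k[ok]
  phase[ok] <- (t[ok] - strikes[kk]) / (strikes[kk + 1L] - strikes[kk])
  phase
}

acc_trace <- function(t, strikes, bump_sd_s = 0.03, noise_sd = 0.05) {
  a <- numeric(length(t))
  for (s in strikes) a <- a + exp(-0.5 * ((t - s) / bump_sd_s)^2)
  a + rnorm(length(t), sd = noise_sd)
}

true_cycle_table <- function(sl, sr, emg_rate) {
  build_true <- function(ipsi, contra, side) {
    rows <- lapply(seq_len(length(ipsi) - 1L), function(k) {
      q <- contra[contra > ipsi[k] & contra < ipsi[k + 1L]]
      if (length(q) != 1L) return(NULL)
      tibble::tibble(side = side,
                     start = as.integer(round(ipsi[k] * emg_rate)),
                     stance_end = as.integer(round(q * emg_rate)),
                     end = as.integer(round(ipsi[k + 1L] * emg_rate)))
    })
    dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(build_true(sl, sr, "left"), build_true(sr, sl, "right"))
}

#' Generate a synthetic cohort
#'
#' Builds `sum(n_per_group)` subjects with per-group profiles, all randomness
#' flowing from one master seed: per-subject seeds are drawn once from the
#' master-seeded stream, so the cohort is bit-reproducible. Optionally writes
#' each subject's signals to a directory tree of columnar text files.
#'
#' @param n_per_group named integer vector, e.g.
#'   `c(control = 4, spastic = 3)`; names must be profile groups.
#' @param master_seed integer master seed.
#' @param dir optional output directory; when given, per-subject
#'   subdirectories with `emg.tsv`, `acc_left.tsv`, `acc_right.tsv` and a
#'   `groups.tsv` map are written.
#' @param ... passed to [subject_profile()] (e.g. `n_cycles`).
#' @return A tibble of class `gait_cohort` with columns `subject`, `group`,
#'   and list-columns `emg`, `acc_left`, `acc_right`, `truth`.
#' @export
make_cohort <- function(n_per_group, master_seed = 1L, dir = NULL, ...) {
  stopifnot(length(n_per_group) >= 1, !is.null(names(n_per_group)),
            all(n_per_group >= 1))
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  seeds <- with_seed_local(master_seed, sample.int(.Machine$integer.max, n))
  subjects <- sprintf("S%02d", seq_len(n))
  sims <- purrr::map2(groups, seeds, function(g, s)
    generate_subject(subject_profile(group = g, seed = s, ...)))
  out <- tibble::tibble(
    subject = subjects, group = groups,
    emg = purrr::map(sims, "emg"),
    acc_left = purrr::map(sims, "acc_left"),
    acc_right = purrr::map(sims, "acc_right"),
    truth = purrr::map(sims, "truth")
  )
  class(out) <- c("gait_cohort", class(out))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      sub <- file.path(dir, subjects[i])
      dir.create(sub, showWarnings = FALSE)
      write_signal(out$emg[[i]], file.path(sub, "emg.tsv"))
      write_signal(out$acc_left[[i]], file.path(sub, "acc_left.tsv"))
      write_signal(out$acc_right[[i]], file.path(sub, "acc_right.tsv"))
    }
    utils::write.table(data.frame(subject = subjects, group = groups),
                       file.path(dir, "groups.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
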