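#' Enumerate the 14 muscle-combination analysis schemes
#'
#' The coactivation analysis examines 14 (muscle subset, side, segment)
#' configurations drawn from four data-organization strategies:
#' \describe{
#'   \item{strategy 1}{all 8 muscles of one leg over the entire gait cycle
#'     (2 schemes: left, right);}
#'   \item{strategy 2}{all 8 muscles of one leg over one gait phase
#'     (4 schemes: left/right x stance/swing);}
#'   \item{strategy 3}{the 3 lower-leg muscles (TA, SO, LG) of one leg over
#'     one gait phase (4 schemes);}
#'   \item{strategy 4}{the 5 thigh muscles (VL, RF, SE, BF, TF) of one leg
#'     over one gait phase (4 schemes).}
#' }
#' Ordering is deterministic by (strategy, side, segment), so the channel
#' counts over the 14 schemes read (8,8, 8,8,8,8, 3,3,3,3, 5,5,5,5).
#'
#' @param muscle_map list with `left` and `right` character vectors of the 8
#'   per-leg channel labels, ordered as [default_muscles()]; default
#'   [default_muscle_map()].
#' @return A tibble of class `scheme_set` with columns `scheme_id`,
#'   `strategy`, `side`, `segment`, `muscle_set`, `n_channels` and the
#'   list-column `channels` of resolved labels.
#' @examples
#' enumerate_schemes()
#' @export
enumerate_schemes <- function(muscle_map = default_muscle_map()) {
  muscles <- default_muscles()
  for (s in c("left", "right")) {
    if (is.null(muscle_map[[s]]) || length(muscle_map[[s]]) != 8L)
      stop("`muscle_map$", s, "` must hold the 8 per-leg channel labels")
  }
  pick <- function(side, set) {
    idx <- match(switch(set, all8 = muscles, lower3 = lower_leg_muscles(),
                        thigh5 = thigh_muscles()), muscles)
    muscle_map[[side]][idx]
  }
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(strategy = 1L, side = c("left", "right"),
                       segment = "full", muscle_set = "all8"),
    tidyr::expand_grid(strategy = 2L, side = c("left", "right"),
                       segment = c("stance", "swing"), muscle_set = "all8"),
    tidyr::expand_grid(strategy = 3L, side = c("left", "right"),
                       segment = c("stance", "swing"), muscle_set = "lower3"),
    tidyr::expand_grid(strategy = 4L, side = c("left", "right"),
                       segment = c("stance", "swing"), muscle_set = "thigh5")
  )
  grid <- dplyr::arrange(grid, .data$strategy, .data$side, .data$segment)
  out <- dplyr::mutate(grid,
    scheme_id = dplyr::row_number(),
    channels = purrr::map2(.data$side, .data$muscle_set, pick),
    n_channels = lengths(.data$channels), .before = 1)
  out <- dplyr::relocate(out, "scheme_id", "strategy", "side", "segment",
                         "muscle_set", "n_channels", "channels")
  class(out) <- c("scheme_set", class(out))
  out
}

#' Average per-cycle MMSE curves into a subject curve
#'
#' Per-scale arithmetic mean over a subject's cycle-level curves. Undefined
#' (flagged) entropy values are excluded pairwise; a scale where every cycle
#' is undefined stays flagged. The number of contributing cycles per scale is
#' recorded.
#'
#' @param cycle_curves tibble with columns `scale`, `value`, `defined` and a
#'   cycle identifier (any other columns are ignored); typically the
#'   row-bound [mmse_curve()] results of one subject under one scheme.
#' @return Tibble with columns `scale`, `value`, `defined`, `n_contributing`.
#' @export
subject_curve <- function(cycle_curves) {
  stopifnot(all(c("scale", "value", "defined") %in% names(cycle_curves)))
  if (nrow(cycle_curves) == 0L) stop("need at least one cycle curve")
  cycle_curves |>
    dplyr::group_by(.data$scale) |>
    dplyr::summarise(
      n_contributing = sum(.data$defined),
      value = if (any(.data$defined)) mean(.data$value[.data$defined]) else NA_real_,
      defined = any(.data$defined),
      .groups = "drop"
    ) |>
    dplyr::relocate("scale", "value", "defined", "n_contributing")
}

#' Group mean and SD of subject MMSE curves
#'
#' @param subject_curves tibble with columns `subject`, `group`, `scale`,
#'   `value` (one row per subject x scale, e.g. from [run_analysis()]).
#' @return Tibble with per-group, per-scale `mean`, `sd` and `n_subjects`.
#'   Singleton groups get `sd = NA` (flagged undefined).
#' @export
group_summary <- function(subject_curves) {
  stopifnot(all(c("subject", "group", "scale", "value") %in% names(subject_curves)))
  subject_curves |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("scheme_id", "group", "scale")))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2L) sd(.data$value) else NA_real_,
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
}

#' Analysis configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default.
#' Unknown keys are rejected.
#'
#' @param ... overrides of: `n_directions` (64), `max_modes` (6), `n_noise`
#'   (6), `sd_threshold` (0.2), `max_sift` (15), `m` (2), `tau` (1),
#'   `r_factor` (0.2), `min_interval_s` (0.4), `prominence_factor` (2),
#'   `min_duration_s` (0.5), `max_duration_s` (4), `z_threshold` (8),
#'   `max_cycles` (Inf, per side), `mode` ("concat" or "per_subject"),
#'   `seed` (1).
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    n_directions = 64L, max_modes = 6L, n_noise = 6L,
    sd_threshold = 0.2, max_sift = 15L,
    m = 2L, tau = 1L, r_factor = 0.2,
    min_interval_s = 0.4, prominence_factor = 2,
    min_duration_s = 0.5, max_duration_s = 4,
    z_threshold = 8, max_cycles = Inf,
    mode = "concat", seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!cfg$mode %in% c("concat", "per_subject"))
    stop("`mode` must be \"concat\" or \"per_subject\"")
  structure(cfg, class = "analysis_config")
}

#' Run the full coactivation-complexity analysis
#'
#' End-to-end pipeline over a cohort: per subject, heel strikes are detected
#' in both accelerometer traces, gait cycles built per side, artifact cycles
#' rejected and the contiguous analysis span (first retained cycle start to
#' last retained cycle end) extracted. In `"concat"` mode the spans of all
#' subjects are concatenated and decomposed by one noise-assisted MEMD run
#' (the alignment guarantee across cycles, muscles and subjects); in
#' `"per_subject"` mode each subject is decomposed separately. The noise
#' channels are stripped, cumulative scales formed, and for every scheme and
#' every cycle of the scheme's side an MMSE curve is computed from the
#' sliced scales with the tolerance taken from the matching raw EMG slice.
#' Cycle curves are averaged into subject curves and summarized per group.
#'
#' @param cohort a [make_cohort()] tibble (columns `subject`, `group`, `emg`,
#'   `acc_left`, `acc_right`).
#' @param schemes a [enumerate_schemes()] table (default: all 14).
#' @param config an [analysis_config()].
#' @return An object of class `mmse_analysis`: list with tibbles
#'   `curves_cycle`, `curves_subject`, `summary_group`, plus `cycles`,
#'   `config` and `log`.
#' @export
run_analysis <- function(cohort, schemes = enumerate_schemes(),
                         config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  needed <- c("subject", "group", "emg", "acc_left", "acc_right")
  stopifnot(all(needed %in% names(cohort)))
  n_sub <- nrow(cohort)
  log <- character(0)

  # --- segmentation per subject ------------------------------------------
  seg <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    emg <- cohort$emg[[i]]
    acc_rate <- signal_rate(cohort$acc_left[[i]])
    pk <- list(
      left = detect_acc_peaks(as.vector(unclass(cohort$acc_left[[i]])), acc_rate,
                              config$min_interval_s, config$prominence_factor, "left"),
      right = detect_acc_peaks(as.vector(unclass(cohort$acc_right[[i]])), acc_rate,
                               config$min_interval_s, config$prominence_factor, "right"))
    cyc <- dplyr::bind_rows(
      build_gait_cycles(pk$left, pk$right, signal_rate(emg),
                        config$min_duration_s, config$max_duration_s),
      build_gait_cycles(pk$right, pk$left, signal_rate(emg),
                        config$min_duration_s, config$max_duration_s))
    cyc <- reject_artifact_cycles(emg, cyc, config$z_threshold)
    if (is.finite(config$max_cycles))
      cyc <- cyc |> dplyr::group_by(.data$side) |>
        dplyr::slice_head(n = as.integer(config$max_cycles)) |> dplyr::ungroup()
    if (nrow(cyc) == 0L)
      stop("subject ", cohort$subject[i], ": no usable gait cycles")
    span0 <- min(cyc$start); span1 <- max(cyc$end)
    seg[[i]] <- list(cycles = cyc, span = c(span0, span1))
    log <- c(log, sprintf("subject %s: %d cycles retained (%d artifact-rejected), span [%d, %d)",
                          cohort$subject[i], nrow(cyc),
                          attr(cyc, "n_rejected") %||% 0L, span0, span1))
  }

  # --- decomposition ------------------------------------------------------
  slice_block <- function(i) {
    emg <- cohort$emg[[i]]
    sp <- seg[[i]]$span
    unclass(emg)[(sp[1] + 1L):sp[2], , drop = FALSE]
  }
  labels <- channel_labels(cohort$emg[[1]])
  rate <- signal_rate(cohort$emg[[1]])
  scales_of <- function(block_mat, seed) {
    x <- multichannel_signal(block_mat, rate, labels)
    xn <- add_noise_channels(x, config$n_noise, seed = seed)
    dec <- memd(xn, n_directions = config$n_directions,
                max_modes = config$max_modes,
                sd_threshold = config$sd_threshold, max_sift = config$max_sift)
    dec <- strip_noise_channels(dec, config$n_noise)
    cumulative_scales(dec, min(length(dec$imfs) + 1L, config$max_modes + 1L))
  }

  if (config$mode == "concat") {
    blocks <- lapply(seq_len(n_sub), slice_block)
    offs <- cumsum(c(0L, vapply(blocks, nrow, integer(1))))[seq_len(n_sub)]
    scales_all <- scales_of(do.call(rbind, blocks), config$seed)
    subject_scales <- function(i) {
      sp <- seg[[i]]$span
      rows <- (offs[i] + 1L):(offs[i] + (sp[2] - sp[1]))
      lapply(scales_all, function(s) s[rows, , drop = FALSE])
    }
    log <- c(log, sprintf("concat MEMD: %d samples x %d+%d channels, %d scales",
                          sum(vapply(blocks, nrow, integer(1))), length(labels),
                          config$n_noise, length(scales_all)))
  } else {
    per <- lapply(seq_len(n_sub), function(i)
      scales_of(slice_block(i), config$seed + i))
    subject_scales <- function(i) per[[i]]
    log <- c(log, sprintf("per-subject MEMD on %d subjects", n_sub))
  }

  # --- per-cycle MMSE curves over the 14 schemes -------------------------
  curve_rows <- list()
  for (i in seq_len(n_sub)) {
    emg <- cohort$emg[[i]]
    sp <- seg[[i]]$span
    sscales <- subject_scales(i)
    cyc <- seg[[i]]$cycles
    for (s in seq_len(nrow(schemes))) {
      sch <- schemes[s, ]
      chans <- sch$channels[[1]]
      ch_idx <- match(chans, labels)
      side_cyc <- cyc[cyc$side == sch$side, ]
      for (cidx in seq_len(nrow(side_cyc))) {
        cy <- side_cyc[cidx, ]
        rows <- switch(sch$segment,
          full = (cy$start + 1L):cy$end,
          stance = (cy$start + 1L):cy$stance_end,
          swing = (cy$stance_end + 1L):cy$end) - sp[1]
        raw <- unclass(emg)[rows + sp[1], ch_idx, drop = FALSE]
        sc <- lapply(sscales, function(m) m[rows, ch_idx, drop = FALSE])
        curve <- mmse_curve(raw, sc, M = config$m, tau = config$tau,
                            r_factor = config$r_factor)
        curve_rows[[length(curve_rows) + 1L]] <- dplyr::mutate(
          tibble::as_tibble(curve),
          scheme_id = sch$scheme_id, strategy = sch$strategy,
          side = sch$side, segment = sch$segment, muscle_set = sch$muscle_set,
          subject = cohort$subject[i], group = cohort$group[i],
          cycle = cidx, .before = 1)
      }
    }
  }
  curves_cycle <- dplyr::bind_rows(curve_rows)

  curves_subject <- curves_cycle |>
    dplyr::group_by(.data$scheme_id, .data$strategy, .data$side, .data$segment,
                    .data$muscle_set, .data$subject, .data$group) |>
    dplyr::group_modify(~ subject_curve(.x)) |>
    dplyr::ungroup()

  summary_group <- group_summary(curves_subject)

  n_undef <- sum(!curves_cycle$defined)
  if (n_undef > 0)
    log <- c(log, sprintf("%d of %d cycle-scale entropy values undefined (zero matches)",
                          n_undef, nrow(curves_cycle)))

  structure(list(curves_cycle = curves_cycle, curves_subject = curves_subject,
                 summary_group = summary_group,
                 cycles = dplyr::bind_rows(lapply(seq_len(n_sub), function(i)
                   dplyr::mutate(seg[[i]]$cycles, subject = cohort$subject[i]))),
                 config = config, log = log),
            class = "mmse_analysis")
}

#' @export
print.mmse_analysis <- function(x, ...) {
  cc <- x$curves_cycle
  cs <- x$curves_subject
  cat(sprintf("<mmse_analysis> %d cycle curves, %d subject curves, %d schemes, mode=%s\n",
              length(unique(paste(cc$scheme_id, cc$subject, cc$cycle))),
              length(unique(paste(cs$scheme_id, cs$subject))),
              length(unique(cc$scheme_id)), x$config$mode))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
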