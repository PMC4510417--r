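#' Two-way repeated-measures ANOVA on subject MMSE curves
#'
#' Standard mixed-design ANOVA with scale factor (within-subjects, typically
#' 7 levels) and subject group (between-subjects) for one analysis scheme:
#' F, degrees of freedom and p for the group effect, the scale effect and
#' their interaction. Within-subject effects additionally report the
#' Greenhouse-Geisser sphericity correction (epsilon and adjusted p)
#' alongside the uncorrected values. Subjects with any flagged/missing scale
#' are excluded listwise (their count is recorded). When an effect's sum of
#' squares is exactly zero its F ratio is reported as 0.
#'
#' @param subject_curves tibble with columns `subject`, `group`, `scale`,
#'   `value` (one row per subject x scale), e.g. `curves_subject` from
#'   [run_analysis()] filtered to one scheme.
#' @param alpha significance level carried into the result (default 0.05).
#' @return An object of class `rm_anova`: list with `effects` (tibble: one
#'   row per effect with `F`, `df1`, `df2`, `p`, `gg_epsilon`, `p_gg`),
#'   `n_subjects`, `n_excluded`, `alpha`, `groups`, `n_scales`.
#' @export
rm_anova <- function(subject_curves, alpha = 0.05) {
  stopifnot(all(c("subject", "group", "scale", "value") %in% names(subject_curves)))
  d <- subject_curves
  scales <- sort(unique(d$scale))
  S <- length(scales)
  wide <- d |>
    dplyr::select("subject", "group", "scale", "value") |>
    tidyr::pivot_wider(names_from = "scale", values_from = "value")
  complete <- stats::complete.cases(wide)
  n_excluded <- sum(!complete)
  wide <- wide[complete, ]
  groups <- unique(wide$group)
  if (length(groups) < 2L)
    warning("fewer than 2 groups: between-subjects effect omitted")
  if (any(table(wide$group) < 2L))
    stop("need at least 2 complete subjects per group")

  Y <- as.matrix(wide[, as.character(scales)])
  grp <- factor(wide$group)
  idata <- data.frame(scale = factor(scales))

  if (length(groups) >= 2L) {
    mlm <- stats::lm(Y ~ grp)
    av <- car::Anova(mlm, idata = idata, idesign = ~scale, type = 3)
    terms_map <- c(group = "grp", scale = "scale", `group:scale` = "grp:scale")
  } else {
    mlm <- stats::lm(Y ~ 1)
    av <- car::Anova(mlm, idata = idata, idesign = ~scale, type = 3)
    terms_map <- c(scale = "scale")
  }
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  pa <- s$pval.adjustments

  # an effect whose sum of squares vanishes (relative to the whole
  # decomposition) has no variance to test: report F = 0, p = 1 instead of
  # the indeterminate 0/0 ratio
  ss_scale <- sum(abs(ut[, "Sum Sq"])) + sum(abs(ut[, "Error SS"]))
  eff <- lapply(names(terms_map), function(nm) {
    row <- ut[terms_map[[nm]], ]
    zero_ss <- is.finite(row["Sum Sq"]) && row["Sum Sq"] <= 1e-10 * ss_scale
    Fv <- unname(row["F value"]); pv <- unname(row["Pr(>F)"])
    if (zero_ss) { Fv <- 0; pv <- 1 }
    gg_eps <- NA_real_; p_gg <- NA_real_
    if (!is.null(pa) && terms_map[[nm]] %in% rownames(pa)) {
      gg_eps <- unname(pa[terms_map[[nm]], "GG eps"])
      p_gg <- unname(pa[terms_map[[nm]], "Pr(>F[GG])"])
      if (zero_ss) p_gg <- 1
    }
    tibble::tibble(effect = nm, F = Fv, df1 = unname(row["num Df"]),
                   df2 = unname(row["den Df"]), p = pv,
                   gg_epsilon = gg_eps, p_gg = p_gg)
  })
  structure(list(effects = dplyr::bind_rows(eff),
                 n_subjects = nrow(wide), n_excluded = n_excluded,
                 alpha = alpha, groups = as.character(groups),
                 n_scales = S),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA: %d subjects (%d excluded), %d scales, groups: %s\n",
              x$n_subjects, x$n_excluded, x$n_scales,
              paste(x$groups, collapse = ", ")))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' @rdname rm_anova
#' @param x an `rm_anova` object.
#' @param ... unused.
#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_excluded = x$n_excluded,
                 n_groups = length(x$groups), n_scales = x$n_scales,
                 alpha = x$alpha)
}

#' Bonferroni-corrected pairwise group comparisons
#'
#' Post-hoc pairwise two-sample t tests between groups at one scale, with the
#' Bonferroni correction `p_adj = min(1, p * n_comparisons)`.
#'
#' @param values numeric vector of per-subject values at one scale.
#' @param groups group label per value.
#' @param alpha significance level (default 0.05).
#' @return Tibble with one row per group pair: `group1`, `group2`,
#'   `estimate` (mean difference), `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
posthoc_bonferroni <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) < 2L) stop("need at least 2 groups for pairwise comparisons")
  pairs <- utils::combn(gs, 2L, simplify = FALSE)
  n_comp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    if (sd(c(a - mean(a), b - mean(b))) == 0) {
      # identical-within-group degenerate case: no evidence of difference
      tt <- list(estimate = mean(a) - mean(b), statistic = NA_real_,
                 parameter = NA_real_,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      ht <- t.test(a, b)
      tt <- list(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                 statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   estimate = tt$estimate, t = tt$statistic,
                   df = tt$parameter, p = tt$p.value,
                   p_adj = min(1, tt$p.value * n_comp))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, significant = .data$p_adj < alpha)
}
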