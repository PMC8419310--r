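#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino's Z of
#' `sqrt(b1)`) and the transformed sample kurtosis (the Anscombe-Glynn Z
#' of `b2`) into `K^2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom.  Requires `n >= 8` (the
#' kurtosis transform is undefined below that).
#'
#' @param x numeric vector.
#' @return list with `statistic` (K^2), `p.value`, `z_skew`, `z_kurt`,
#'   `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance sample", call. = FALSE)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb <- (6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9))) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + (8 / sb) * (2 / sb + sqrt(1 + 4 / sb^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
               ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z_skew^2 + z_kurt^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality-gated paired comparison
#'
#' Tests both groups with [dagostino_pearson()]; if both pass at
#' `alpha_norm`, a two-sided paired t-test is used, otherwise the
#' two-sided Wilcoxon matched-pairs signed-rank test (zero differences
#' dropped; exact distribution when `n <= 25` and there are no rank ties,
#' mid-rank normal approximation with continuity correction otherwise —
#' the behaviour of [stats::wilcox.test()]).  With fewer than 8 pairs the
#' normality gate cannot run; the Wilcoxon branch is used with a warning.
#'
#' @param group1,group2 paired observations, same length and order.
#' @param alpha_norm significance level of the normality gate.
#' @return a `paired_test` object.
#' @export
paired_compare <- function(group1, group2, alpha_norm = 0.05) {
  if (length(group1) != length(group2))
    stop("paired groups must have equal length", call. = FALSE)
  ok <- is.finite(group1) & is.finite(group2)
  g1 <- group1[ok]; g2 <- group2[ok]
  n <- length(g1)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)

  p1 <- p2 <- NA_real_
  if (n >= 8L) {
    p1 <- tryCatch(dagostino_pearson(g1)$p.value, error = function(e) NA_real_)
    p2 <- tryCatch(dagostino_pearson(g2)$p.value, error = function(e) NA_real_)
    use_t <- is.finite(p1) && is.finite(p2) && p1 >= alpha_norm && p2 >= alpha_norm
  } else {
    warning("fewer than 8 pairs: normality gate skipped, Wilcoxon used")
    use_t <- FALSE
  }

  d <- g2 - g1
  if (all(d == 0)) {
    res <- structure(list(test_used = "degenerate", statistic = NA_real_,
                          p_value = NA_real_, n = n,
                          normality_p = c(group1 = p1, group2 = p2),
                          mean1 = mean(g1), sd1 = sd(g1),
                          mean2 = mean(g2), sd2 = sd(g2),
                          note = "all paired differences are zero"),
                     class = "paired_test")
    return(res)
  }
  if (use_t) {
    tt <- stats::t.test(g2, g1, paired = TRUE)
    test_used <- "paired_t"; stat <- unname(tt$statistic); p <- tt$p.value
    note <- NULL
  } else {
    nz <- sum(d != 0)
    wt <- suppressWarnings(stats::wilcox.test(g2, g1, paired = TRUE,
                                              exact = nz <= 25, correct = TRUE))
    test_used <- "wilcoxon_signed_rank"; stat <- unname(wt$statistic); p <- wt$p.value
    note <- if (nz < n) sprintf("%d zero difference(s) dropped", n - nz) else NULL
  }
  structure(list(test_used = test_used, statistic = stat, p_value = p, n = n,
                 normality_p = c(group1 = p1, group2 = p2),
                 mean1 = mean(g1), sd1 = sd(g1),
                 mean2 = mean(g2), sd2 = sd(g2), note = note),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired comparison (n = %d): %s\n", x$n, x$test_used))
  cat(sprintf("  group1 %.3f +/- %.3f, group2 %.3f +/- %.3f\n",
              x$mean1, x$sd1, x$mean2, x$sd2))
  if (all(is.finite(x$normality_p)))
    cat(sprintf("  normality p: %.3f / %.3f\n",
                x$normality_p[1], x$normality_p[2]))
  cat(sprintf("  statistic %.3f, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Regional mean of a parameter map
#'
#' Arithmetic mean of the selected metric over `mask`, intersected with
#' the map's validity mask; ventricle pixels are never included (shear
#' waves do not propagate in fluid-filled spaces).
#'
#' @param maps an `mre_maps` object from [invert()].
#' @param mask logical array.
#' @param metric `"c"` or `"phi"`.
#' @param ventricles optional logical array to exclude.
#' @param animal_id,region_tag,timepoint metadata carried into the result
#'   (and into error messages).
#' @return a `region_sample` list with `value` and `n_valid_px`.
#' @export
regional_mean <- function(maps, mask, metric = c("c", "phi"),
                          ventricles = NULL, animal_id = "", region_tag = "",
                          timepoint = "") {
  metric <- match.arg(metric)
  sel <- mask & maps$valid
  if (!is.null(ventricles)) sel <- sel & !ventricles
  vals <- (if (metric == "c") maps$c_map else maps$phi_map)[sel]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop(sprintf("empty region: no valid pixels in '%s' for %s (%s)",
                 region_tag, animal_id, timepoint), call. = FALSE)
  list(animal_id = animal_id, region_tag = region_tag, timepoint = timepoint,
       metric = metric, value = mean(vals), n_valid_px = length(vals))
}

#' Percent change between two paired regional samples
#'
#' `100 * (eae - baseline) / baseline`; both samples must refer to the
#' same animal, region and metric.
#'
#' @param baseline,eae `region_sample` lists from [regional_mean()].
#' @return numeric percent change.
#' @export
percent_change <- function(baseline, eae) {
  for (f in c("animal_id", "region_tag", "metric"))
    if (!identical(baseline[[f]], eae[[f]]))
      stop(sprintf("baseline and follow-up samples differ in %s", f), call. = FALSE)
  if (!is.finite(baseline$value) || baseline$value <= 0)
    stop("baseline value must be positive", call. = FALSE)
  100 * (eae$value - baseline$value) / baseline$value
}

#' Voxelwise percent-change map between two parameter-map sets
#'
#' `100 * (eae - baseline) / baseline` per voxel on the joint validity
#' mask; voxels with non-positive baseline are invalid.
#'
#' @param maps_baseline,maps_eae `mre_maps` objects on one grid.
#' @param metric `"c"` or `"phi"`.
#' @return numeric array (percent; `NA` where invalid).
#' @export
percent_change_map <- function(maps_baseline, maps_eae, metric = c("c", "phi")) {
  metric <- match.arg(metric)
  if (!identical(dim(maps_baseline$c_map), dim(maps_eae$c_map)))
    stop("maps must share a grid", call. = FALSE)
  b <- if (metric == "c") maps_baseline$c_map else maps_baseline$phi_map
  e <- if (metric == "c") maps_eae$c_map else maps_eae$phi_map
  valid <- maps_baseline$valid & maps_eae$valid & is.finite(b) & b > 0
  out <- 100 * (e - b) / b
  out[!valid] <- NA_real_
  out
}

#' Invert and mask every session of a cohort
#'
#' Runs the inversion on both timepoints of every animal, derives the
#' final lesion mask set from the EAE contrast pairs, and extracts the
#' regional samples for the standard regions (`whole_brain`, `gd`,
#' `vsop`, `non_gd`, `non_vsop`) and both metrics.  Animals lacking a
#' region (e.g. no VSOP focus present, or no valid pixels) simply carry
#' no rows for it; droppage is reported by [lesion_vs_rest()] and
#' [summarize_cohort()].
#'
#' @param cohort an [make_cohort()] object.
#' @param config an [inversion_config()].
#' @param gd_threshold,vsop_ratio_threshold,vsop_dilate_px,min_size_px
#'   mask-pipeline settings (see [derive_lesion_masks()]).
#' @return a `cohort_analysis` object: per-animal `maps` (baseline/eae),
#'   `masks`, and a long-format `samples` data.frame.
#' @export
analyze_cohort <- function(cohort, config = inversion_config(),
                           gd_threshold = 15, vsop_ratio_threshold = 0.8,
                           vsop_dilate_px = 2L, min_size_px = 5L) {
  stopifnot(inherits(cohort, "mre_cohort"))
  per_animal <- list()
  rows <- list()
  for (se in cohort$sessions) {
    maps_b <- invert(se$baseline$wavefield, config)
    maps_e <- invert(se$eae$wavefield, config)
    # paired analysis on common support: both timepoints contribute the
    # same pixel set to every regional mean
    joint <- maps_b$valid & maps_e$valid
    maps_b$valid <- joint; maps_e$valid <- joint
    ph <- se$eae$phantom
    masks <- derive_lesion_masks(se$eae$gd_pair, se$eae$vsop_pair,
                                 ph$ventricles, ph$brain,
                                 gd_threshold, vsop_ratio_threshold,
                                 vsop_dilate_px, min_size_px)
    # exclude the partial-volume ring around the ventricles as well:
    # the inversion's smoothing kernel straddles the fluid interface there
    vent_ring <- dilate_mask(ph$ventricles, config$edge_margin_px)
    tissue <- ph$brain & !vent_ring
    regions <- list(whole_brain = tissue,
                    gd = masks$gd & tissue, vsop = masks$vsop & tissue,
                    non_gd = tissue & !masks$gd,
                    non_vsop = tissue & !masks$vsop)
    for (rg in names(regions)) {
      if (!any(regions[[rg]])) next
      for (met in c("c", "phi")) {
        for (tp in c("baseline", "eae")) {
          mp <- if (tp == "baseline") maps_b else maps_e
          smp <- tryCatch(
            regional_mean(mp, regions[[rg]], met, ventricles = ph$ventricles,
                          animal_id = se$id, region_tag = rg, timepoint = tp),
            error = function(e) NULL)
          if (!is.null(smp))
            rows[[length(rows) + 1L]] <- as.data.frame(smp, stringsAsFactors = FALSE)
        }
      }
    }
    per_animal[[se$id]] <- list(maps = list(baseline = maps_b, eae = maps_e),
                                masks = masks, truth = se$truth)
  }
  samples <- do.call(rbind, rows)
  structure(list(animals = per_animal, samples = samples,
                 spec = cohort$spec, config = config),
            class = "cohort_analysis")
}

# wide table of paired values for one region/metric; drops animals
# missing either timepoint
.paired_values <- function(samples, region_tag, metric) {
  s <- samples[samples$region_tag == region_tag & samples$metric == metric, ]
  b <- s[s$timepoint == "baseline", c("animal_id", "value")]
  e <- s[s$timepoint == "eae", c("animal_id", "value")]
  m <- merge(b, e, by = "animal_id", suffixes = c("_baseline", "_eae"))
  m[order(m$animal_id), ]
}

#' Compare lesion percent change against the rest of the brain
#'
#' Per animal, the percent change of the regional mean inside the lesion
#' class and inside its complement (brain minus that lesion class minus
#' ventricles), compared across animals with [paired_compare()].  Animals
#' missing the lesion region are dropped and reported.
#'
#' @param analysis a [analyze_cohort()] object.
#' @param region_tag `"vsop"` or `"gd"`.
#' @param metric `"c"` or `"phi"`.
#' @param alpha_norm normality-gate level.
#' @return list with `lesion_pct`, `rest_pct` (named per animal), the
#'   `paired_test`, and `n_dropped`.
#' @export
lesion_vs_rest <- function(analysis, region_tag = c("vsop", "gd"),
                           metric = c("c", "phi"), alpha_norm = 0.05) {
  region_tag <- match.arg(region_tag)
  metric <- match.arg(metric)
  rest_tag <- paste0("non_", region_tag)
  les <- .paired_values(analysis$samples, region_tag, metric)
  rst <- .paired_values(analysis$samples, rest_tag, metric)
  common <- intersect(les$animal_id, rst$animal_id)
  n_all <- length(unique(analysis$samples$animal_id))
  if (length(common) < 2L)
    stop("fewer than 2 animals carry region '", region_tag,
         "': paired contrast undefined", call. = FALSE)
  if (length(common) < n_all)
    message(sprintf("lesion_vs_rest: %d animal(s) without '%s' region dropped",
                    n_all - length(common), region_tag))
  les <- les[les$animal_id %in% common, ]
  rst <- rst[rst$animal_id %in% common, ]
  lesion_pct <- 100 * (les$value_eae - les$value_baseline) / les$value_baseline
  rest_pct <- 100 * (rst$value_eae - rst$value_baseline) / rst$value_baseline
  names(lesion_pct) <- les$animal_id; names(rest_pct) <- rst$animal_id
  list(lesion_pct = lesion_pct, rest_pct = rest_pct,
       test = paired_compare(rest_pct, lesion_pct, alpha_norm),
       n = length(common), n_dropped = n_all - length(common))
}

#' Cohort summary table
#'
#' One row per (region, metric): baseline and EAE group mean +/- sd of
#' the regional means, the mean per-animal percent change, and the
#' normality-gated paired test.
#'
#' @param analysis a [analyze_cohort()] object.
#' @param alpha_norm normality-gate level.
#' @return a `cohort_summary` data.frame.
#' @export
summarize_cohort <- function(analysis, alpha_norm = 0.05) {
  out <- list()
  for (rg in unique(analysis$samples$region_tag)) {
    for (met in c("c", "phi")) {
      w <- .paired_values(analysis$samples, rg, met)
      if (nrow(w) < 2L) next
      pct <- 100 * (w$value_eae - w$value_baseline) / w$value_baseline
      tst <- tryCatch(paired_compare(w$value_baseline, w$value_eae, alpha_norm),
                      error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        region = rg, metric = met, n = nrow(w),
        baseline_mean = mean(w$value_baseline), baseline_sd = sd(w$value_baseline),
        eae_mean = mean(w$value_eae), eae_sd = sd(w$value_eae),
        pct_change_mean = mean(pct), pct_change_sd = sd(pct),
        test_used = if (is.null(tst)) NA_character_ else tst$test_used,
        p_value = if (is.null(tst)) NA_real_ else tst$p_value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cohort_summary", "data.frame")
  res
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (regional means, paired baseline vs EAE)\n")
  df <- as.data.frame(x)
  df$baseline <- sprintf("%.3f +/- %.3f", df$baseline_mean, df$baseline_sd)
  df$eae <- sprintf("%.3f +/- %.3f", df$eae_mean, df$eae_sd)
  df$pct <- sprintf("%+.2f%%", df$pct_change_mean)
  df$p <- signif(df$p_value, 3)
  print(df[, c("region", "metric", "n", "baseline", "eae", "pct", "test_used", "p")],
        row.names = FALSE)
  invisible(x)
}
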