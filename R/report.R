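#' Render summary figures and a markdown report for a pipeline run
#'
#' Produces deterministic PNG figures — incidence maps (color scale
#' spanning 0-100% of animals), baseline-vs-EAE box plots per region and
#' metric, and a representative voxelwise percent-change map — plus a
#' `report.md` embedding the run's configuration hash.  No analysis logic
#' lives here; everything is read from the result object.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (defaults to the run directory).
#' @return character vector of written files, invisibly.
#' @export
render_report <- function(result, dir = result$out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  missing <- character()

  pal <- grDevices::hcl.colors(64, "viridis")
  img_slice <- function(a, s) t(matrix(a[s, , ], dim(a)[2], dim(a)[3]))[, rev(seq_len(dim(a)[2]))]

  # incidence maps, colorbar fixed to 0..100%
  for (mod in c("gd", "vsop")) {
    inc <- result$incidence[[mod]]
    if (is.null(inc)) { missing <- c(missing, paste0("incidence_", mod)); next }
    f <- file.path(dir, sprintf("fig_incidence_%s.png", mod))
    grDevices::png(f, 900, 400)
    pop <- which(apply(inc$percent, 1, max) > 0)
    s <- if (length(pop)) pop[ceiling(length(pop) / 2)] else 1L
    graphics::par(mar = c(2, 2, 3, 6))
    graphics::image(img_slice(inc$percent, s), zlim = c(0, 100), col = pal,
                    axes = FALSE,
                    main = sprintf("%s incidence (%% of %d animals), atlas slice %d",
                                   toupper(mod), inc$n_animals, s))
    # simple vertical colorbar
    xs <- grDevices::dev.size("px")
    graphics::par(new = TRUE, mar = c(2, 0, 3, 1), fig = c(0.92, 1, 0, 1))
    graphics::image(t(matrix(seq(0, 100, length.out = 64))), col = pal,
                    axes = FALSE)
    graphics::axis(4, at = c(0, 0.5, 1), labels = c("0", "50", "100%"))
    grDevices::dev.off()
    written <- c(written, f)
  }

  # group box plots, one panel per (region, metric)
  if (!is.null(result$analysis$samples)) {
    smp <- result$analysis$samples
    regions <- unique(smp$region_tag)
    f <- file.path(dir, "fig_group_comparisons.png")
    grDevices::png(f, 300 * length(regions), 620)
    graphics::par(mfrow = c(2, length(regions)), mar = c(3, 4, 3, 1))
    for (met in c("c", "phi")) {
      for (rg in regions) {
        w <- .paired_values(smp, rg, met)
        if (nrow(w) < 2) { graphics::plot.new(); next }
        graphics::boxplot(list(baseline = w$value_baseline, EAE = w$value_eae),
                          main = sprintf("%s: %s", rg, met),
                          ylab = if (met == "c") "c (m/s)" else "phi (rad)")
        graphics::stripchart(list(w$value_baseline, w$value_eae), vertical = TRUE,
                             add = TRUE, pch = 16, col = "#00000055", method = "jitter")
      }
    }
    grDevices::dev.off()
    written <- c(written, f)
  } else missing <- c(missing, "samples")

  # representative percent-change maps
  a1 <- result$analysis$animals[[1]]
  if (!is.null(a1)) {
    f <- file.path(dir, "fig_percent_change_maps.png")
    grDevices::png(f, 900, 400)
    graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
    for (met in c("c", "phi")) {
      pcm <- percent_change_map(a1$maps$baseline, a1$maps$eae, met)
      s <- ceiling(dim(pcm)[1] / 2)
      graphics::image(img_slice(pcm, s), col = grDevices::hcl.colors(64, "Blue-Red 3"),
                      zlim = c(-40, 40), axes = FALSE,
                      main = sprintf("%% change, %s-map (slice %d)", met, s))
    }
    grDevices::dev.off()
    written <- c(written, f)
  }

  # markdown report
  rp <- file.path(dir, "report.md")
  lines <- c("# Multifrequency MRE cohort report", "",
             sprintf("- config hash: `%s`", result$provenance$config_hash),
             sprintf("- seed: %d; animals: %d", result$provenance$seed,
                     result$provenance$n_animals),
             sprintf("- package: tomomre %s", result$provenance$package_version), "")
  if (!is.null(result$summary)) {
    s <- as.data.frame(result$summary)
    lines <- c(lines, "## Regional comparisons", "",
               "| region | metric | n | baseline | EAE | % change | test | p |",
               "|---|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %.3f ± %.3f | %.3f ± %.3f | %+.2f | %s | %.4g |",
                       s$region, s$metric, s$n, s$baseline_mean, s$baseline_sd,
                       s$eae_mean, s$eae_sd, s$pct_change_mean, s$test_used, s$p_value))
  }
  if (!is.null(result$stats_error))
    lines <- c(lines, "", sprintf("**Statistics stage failed:** %s", result$stats_error))
  if (length(missing))
    lines <- c(lines, "", sprintf("Missing inputs: %s", paste(missing, collapse = ", ")))
  writeLines(lines, rp)
  written <- c(written, rp)
  invisible(written)
}
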