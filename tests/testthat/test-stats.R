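# Frozen oracle values for the D'Agostino-Pearson omnibus test, computed
# independently with scipy.stats (normaltest / skewtest / kurtosistest).
test_that("D'Agostino-Pearson statistic matches the independent oracle", {
  v1 <- c(2.3, 3.1, 2.8, 3.5, 2.9, 3.2, 2.7, 3.0, 3.3, 2.6, 3.4, 2.95, 3.05,
          2.85, 3.15, 2.75, 3.25, 2.65, 3.45)
  r1 <- dagostino_pearson(v1)
  expect_equal(r1$statistic, 0.3187923316074253, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.8526584979099344, tolerance = 1e-10)
  expect_equal(r1$z_skew, -0.5393845678904953, tolerance = 1e-10)
  expect_equal(r1$z_kurt, -0.16690302432553178, tolerance = 1e-10)

  v2 <- exp(c(0.1, 0.5, -0.3, 1.2, 0.8, -0.7, 2.1, 0.3, -0.2, 0.9, 1.5, 0.05,
              -0.55, 0.45, 1.9, 0.25, -0.95, 0.65, 1.1))
  r2 <- dagostino_pearson(v2)
  expect_equal(r2$statistic, 13.57692277892787, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.001126700995248597, tolerance = 1e-10)

  v3 <- c(1.2, 1.9, 2.4, 2.5, 3.1, 3.3, 3.6, 4.0, 4.4, 5.2, 6.8, 9.5)
  r3 <- dagostino_pearson(v3)
  expect_equal(r3$statistic, 6.683398527158108, tolerance = 1e-10)
  expect_equal(r3$p.value, 0.03537679212307232, tolerance = 1e-10)
  expect_equal(r3$z_skew, 2.092069888552601, tolerance = 1e-10)
  expect_equal(r3$z_kurt, 1.5187633484416247, tolerance = 1e-10)
  # exactly symmetric data: the skewness transform is identically zero
  expect_equal(dagostino_pearson(as.numeric(1:12))$z_skew, 0)

  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("the normality gate selects the right branch", {
  set.seed(314)
  picks_t <- vapply(1:40, function(i) {
    g1 <- rnorm(19); g2 <- g1 + 0.5 + rnorm(19, 0, 0.3)
    paired_compare(g1, g2)$test_used == "paired_t"
  }, logical(1))
  expect_gt(mean(picks_t), 0.8)  # approx (1 - alpha)^2 = 0.90 for Normal data

  picks_w <- vapply(1:40, function(i) {
    g1 <- exp(rnorm(19, 0, 1.3)); g2 <- exp(rnorm(19, 0, 1.3))
    paired_compare(g1, g2)$test_used == "wilcoxon_signed_rank"
  }, logical(1))
  expect_gt(mean(picks_w), 0.8)  # strongly skewed data fail the gate
})

test_that("small samples and degenerate differences are handled explicitly", {
  expect_warning(res <- paired_compare(c(1, 2, 3, 4), c(2, 3, 4, 6)),
                 "fewer than 8")
  expect_identical(res$test_used, "wilcoxon_signed_rank")
  r0 <- suppressWarnings(paired_compare(1:10 * 1.0, 1:10 * 1.0))
  expect_identical(r0$test_used, "degenerate")
  expect_true(is.na(r0$p_value))
  expect_error(paired_compare(1:5, 1:4), "equal length")
})

test_that("regional means follow mask arithmetic and report empty regions", {
  dims <- c(1, 4, 4)
  maps <- structure(list(c_map = array(3.0, dims), phi_map = array(0.7, dims),
                         valid = array(TRUE, dims),
                         pixel_spacing_mm = c(0.8, 0.18, 0.18)),
                    class = "mre_maps")
  mask <- array(TRUE, dims)
  expect_equal(regional_mean(maps, mask, "c")$value, 3.0)
  maps$c_map[1, 1, 1] <- 2.0; maps$c_map[1, 1, 2] <- 4.0
  two <- array(FALSE, dims); two[1, 1, 1:2] <- TRUE
  smp <- regional_mean(maps, two, "c")
  expect_equal(smp$value, 3.0)
  expect_equal(smp$n_valid_px, 2L)
  # invariant to adding invalid pixels to the mask
  maps$valid[1, 4, 4] <- FALSE
  three <- two; three[1, 4, 4] <- TRUE
  expect_equal(regional_mean(maps, three, "c")$value, 3.0)
  none <- array(FALSE, dims)
  expect_error(regional_mean(maps, none, "c", animal_id = "m07",
                             region_tag = "vsop"),
               "m07")
})

test_that("percent change arithmetic and metadata guards", {
  b <- list(animal_id = "a1", region_tag = "vsop", timepoint = "baseline",
            metric = "c", value = 3.0, n_valid_px = 10L)
  e <- b; e$timepoint <- "eae"; e$value <- 2.49
  expect_equal(percent_change(b, e), -17.0)
  same <- b; same$timepoint <- "eae"
  expect_equal(percent_change(b, same), 0)
  wrong <- e; wrong$region_tag <- "gd"
  expect_error(percent_change(b, wrong), "region_tag")
  bneg <- b; bneg$value <- 0
  expect_error(percent_change(bneg, e), "positive")
})

test_that("voxelwise percent-change maps respect joint validity", {
  dims <- c(1, 3, 3)
  mk <- function(v) structure(list(c_map = array(v, dims),
                                   phi_map = array(0.7, dims),
                                   valid = array(TRUE, dims)),
                              class = "mre_maps")
  expect_true(all(percent_change_map(mk(3), mk(3)) == 0))
  expect_true(all(abs(percent_change_map(mk(3), mk(2.7)) + 10) < 1e-9))
  a <- mk(3); a$valid[1, 1, 1] <- FALSE
  expect_true(is.na(percent_change_map(a, mk(2.7))[1, 1, 1]))
})

test_that("lesion-vs-rest drops animals without the region and needs two", {
  mkrow <- function(id, rg, tp, v)
    data.frame(animal_id = id, region_tag = rg, timepoint = tp, metric = "c",
               value = v, n_valid_px = 10L)
  smp <- rbind(mkrow("a1", "vsop", "baseline", 3.0), mkrow("a1", "vsop", "eae", 2.5),
               mkrow("a1", "non_vsop", "baseline", 3.1), mkrow("a1", "non_vsop", "eae", 2.9),
               mkrow("a2", "non_vsop", "baseline", 3.0), mkrow("a2", "non_vsop", "eae", 2.8))
  fake <- structure(list(samples = smp), class = "cohort_analysis")
  expect_error(lesion_vs_rest(fake, "vsop", "c"), "fewer than 2")
  smp2 <- rbind(smp, mkrow("a2", "vsop", "baseline", 3.0), mkrow("a2", "vsop", "eae", 2.4),
                mkrow("a3", "non_vsop", "baseline", 3.0), mkrow("a3", "non_vsop", "eae", 2.9))
  fake2 <- structure(list(samples = smp2), class = "cohort_analysis")
  expect_message(res <- suppressWarnings(lesion_vs_rest(fake2, "vsop", "c")),
                 "dropped")
  expect_equal(res$n, 2L)
  expect_equal(res$n_dropped, 1L)
  expect_equal(unname(res$lesion_pct["a1"]), 100 * (2.5 - 3.0) / 3.0)
})

test_that("cohort summary has one row per region and metric", {
  mkrows <- function(id, rg, met, b, e)
    data.frame(animal_id = id, region_tag = rg, timepoint = c("baseline", "eae"),
               metric = met, value = c(b, e), n_valid_px = 10L)
  smp <- do.call(rbind, c(
    lapply(sprintf("a%d", 1:9), function(id) mkrows(id, "whole_brain", "c", 3 + runif(1, -.1, .1), 2.9)),
    lapply(sprintf("a%d", 1:9), function(id) mkrows(id, "whole_brain", "phi", 0.69, 0.70)),
    lapply(sprintf("a%d", 1:9), function(id) mkrows(id, "gd", "c", 3.3, 3.0))))
  fake <- structure(list(samples = smp), class = "cohort_analysis")
  tab <- suppressWarnings(summarize_cohort(fake))
  expect_equal(nrow(tab), 3L)  # (whole_brain x c, phi) + (gd x c)
  expect_true(all(c("baseline_mean", "eae_sd", "pct_change_mean", "test_used",
                    "p_value") %in% names(tab)))
  wbphi <- tab[tab$region == "whole_brain" & tab$metric == "phi", ]
  expect_equal(wbphi$baseline_sd, 0)
  expect_equal(wbphi$pct_change_mean, 100 * (0.70 - 0.69) / 0.69)
})
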