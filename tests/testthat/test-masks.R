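test_that("percent-change SI map implements enhancement arithmetic", {
  dims <- c(1, 4, 4)
  brain <- array(TRUE, dims)
  pre <- array(100, dims); post <- array(120, dims)
  pair <- list(pre = pre, post = post, brain = brain)
  expect_true(all(percent_change_si(pair) == 20))
  pair$post <- pair$pre
  expect_true(all(percent_change_si(pair) == 0))
  # zero pre-contrast SI is flagged invalid, not propagated
  pair$pre[1, 2, 2] <- 0
  expect_true(is.na(percent_change_si(pair)[1, 2, 2]))
  # outside brain undefined
  pair$pre[1, 2, 2] <- 100; pair$brain[1, 1, 1] <- FALSE
  expect_true(is.na(percent_change_si(pair)[1, 1, 1]))
  expect_error(percent_change_si(list(pre = pre, post = array(1, c(1, 2, 2)))),
               "share a grid")
})

test_that("threshold masks match noiseless truth and drop small components", {
  ph <- make_phantom(phantom_spec(grid_shape = c(1, 60, 90)))
  gd_pair <- simulate_contrast_pair(ph, "t1_gbca", 30, noise_sigma = 0)
  gd <- gd_mask_from_change(percent_change_si(gd_pair), threshold = 15)
  expect_identical(unname(gd), unname(ph$gd_contrast))
  vs_pair <- simulate_contrast_pair(ph, "t2star_vsop", 40, noise_sigma = 0)
  vs <- vsop_mask_from_hypointensity(vs_pair, 0.8)
  expect_identical(unname(vs), unname(ph$vsop_contrast))
  # uniform zero map -> empty; lone suprathreshold pixel removed at min size 5
  zmap <- array(0, c(1, 10, 10))
  expect_equal(sum(gd_mask_from_change(zmap, 15)), 0)
  zmap[1, 5, 5] <- 30
  expect_equal(sum(gd_mask_from_change(zmap, 15, min_size_px = 5)), 0)
  expect_equal(sum(gd_mask_from_change(zmap, 15, min_size_px = 1)), 1)
  # an unattainable hypointensity bound gives an empty mask
  expect_error(vsop_mask_from_hypointensity(vs_pair, 1.0), "0, 1")
  expect_equal(sum(vsop_mask_from_hypointensity(vs_pair, 0)), 0)
  expect_error(gd_mask_from_change(zmap, 0), "> 0")
})

test_that("two dilations of a pixel give the 13-pixel L1 ball (brute force)", {
  m <- array(FALSE, c(1, 15, 15)); m[1, 8, 8] <- TRUE
  d2 <- dilate_mask(m, 2)
  ball <- array(FALSE, c(1, 15, 15))
  for (r in 1:15) for (cc in 1:15)
    ball[1, r, cc] <- abs(r - 8) + abs(cc - 8) <= 2
  expect_identical(d2, ball)
  expect_equal(sum(d2), 13)
  expect_identical(dilate_mask(m, 0), m)
  expect_equal(formals(dilate_mask)$pixels, 2L)  # protocol default
})

test_that("dilation is monotone", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_mask(c(2, 20, 25), p = 0.1)
    d1 <- dilate_mask(m, 1); d2 <- dilate_mask(m, 2)
    expect_true(all(d1[m]))
    expect_true(all(d2[d1]))
  }
})

test_that("mutual exclusion and ventricle removal follow set algebra", {
  dims <- c(1, 8, 8)
  brain <- array(TRUE, dims)
  vent <- array(FALSE, dims)
  gd <- array(FALSE, dims); gd[1, 2, 2] <- gd[1, 2, 3] <- TRUE     # {a, b}
  vs <- array(FALSE, dims); vs[1, 2, 3] <- vs[1, 2, 4] <- TRUE     # {b, c}
  out <- make_exclusive(lesion_mask_set(gd, vs, vent, brain, "dilated"))
  expect_identical(idx_set(out$gd), idx_set(gd & !vs))
  expect_identical(idx_set(out$vsop), idx_set(vs & !gd))
  expect_identical(out$state, "final")
  # disjoint masks unchanged; contained mask emptied
  vs2 <- array(FALSE, dims); vs2[1, 6, 6] <- TRUE
  out2 <- make_exclusive(lesion_mask_set(gd, vs2, vent, brain, "dilated"))
  expect_identical(out2$gd, gd); expect_identical(out2$vsop, vs2)
  inside <- array(FALSE, dims); inside[1, 2, 2] <- TRUE
  out3 <- make_exclusive(lesion_mask_set(gd, inside, vent, brain, "dilated"))
  expect_equal(sum(out3$vsop), 0)
  expect_identical(idx_set(out3$gd), idx_set(gd & !inside))
  # state machine: raw sets must be dilated first; final invariants enforced
  expect_error(make_exclusive(lesion_mask_set(gd, vs, vent, brain, "raw")),
               "dilated")
  expect_error(lesion_mask_set(gd, gd, vent, brain, "final"), "disjoint")
})

test_that("exclusivity and ventricle-freeness hold on randomized masks", {
  set.seed(7)
  for (i in 1:50) {
    dims <- c(2, 15, 20)
    brain <- random_mask(dims, 0.9)
    out <- make_exclusive(lesion_mask_set(random_mask(dims), random_mask(dims),
                                          random_mask(dims, 0.1), brain,
                                          "dilated"))
    expect_equal(sum(out$gd & out$vsop), 0)
    expect_equal(sum((out$gd | out$vsop) & out$ventricles), 0)
    expect_true(all(brain[out$gd]) && all(brain[out$vsop]))
  }
})

test_that("slice resampling preserves identity, constants and the atlas mapping", {
  img <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  # identity: same slice count over the same physical span
  same <- resample_slices(img, 3, "nearest", src_spacing_mm = 0.8,
                          target_span_mm = 2.4)
  expect_equal(same, img)
  cst <- resample_slices(array(2.5, c(3, 4, 5)), 15, "linear",
                         src_spacing_mm = 0.8, target_span_mm = 2.4)
  expect_true(all(cst[!is.na(cst)] == 2.5))
  # 7 slices x 0.8 mm onto the 215-slice atlas -> approx 58 populated slices
  out <- resample_slices(array(1.0, c(7, 2, 2)), 215, "nearest")
  populated <- sum(apply(out, 1, function(s) any(!is.na(s))))
  expect_true(abs(populated - 58) <= 1)
  # masks stay logical under nearest, and reject linear
  msk <- array(TRUE, c(7, 2, 2))
  expect_type(resample_slices(msk, 215, "nearest"), "logical")
  expect_error(resample_slices(msk, 215, "linear"), "nearest")
})

test_that("incidence maps count animals exactly", {
  dims <- c(1, 5, 5)
  masks <- list(array(FALSE, dims), array(FALSE, dims),
                array(FALSE, dims), array(FALSE, dims))
  for (i in 1:2) masks[[i]][1, 3, 3] <- TRUE   # present in 2 of 4
  for (i in 1:4) masks[[i]][1, 1, 1] <- TRUE   # present in all
  inc <- incidence_map(masks, "gd")
  expect_equal(inc$percent[1, 3, 3], 50)
  expect_equal(inc$percent[1, 1, 1], 100)
  expect_equal(inc$percent[1, 5, 5], 0)
  expect_error(incidence_map(list(masks[[1]], array(FALSE, c(1, 2, 2)))),
               "share a grid")
  # exact agreement with brute-force counting on random cohorts
  set.seed(11)
  for (r in 1:20) {
    ms <- lapply(1:7, function(i) random_mask(c(2, 6, 8)))
    inc <- incidence_map(ms, "vsop")
    brute <- Reduce(`+`, lapply(ms, function(m) m * 1)) / 7 * 100
    expect_equal(inc$percent, brute)
    expect_true(all(inc$percent >= 0 & inc$percent <= 100))
  }
})

test_that("regional incidence tabulates intersecting animals per label", {
  dims <- c(1, 6, 6)
  atlas <- array(0L, dims); atlas[1, 1:3, ] <- 1L; atlas[1, 4:6, ] <- 2L
  key <- c(upper = 1L, lower = 2L)
  masks <- lapply(1:19, function(i) array(FALSE, dims))
  for (i in 1:15) masks[[i]][1, 2, 2] <- TRUE  # 15 of 19 intersect 'upper'
  tab <- regional_incidence(masks, atlas, key)
  expect_equal(round(tab$incidence_pct[tab$region == "upper"], 1), 78.9)
  expect_equal(tab$incidence_pct[tab$region == "lower"], 0)
  all_in <- lapply(1:4, function(i) array(TRUE, dims))
  expect_true(all(regional_incidence(all_in, atlas, key)$incidence_pct == 100))
  expect_error(regional_incidence(masks, atlas, c(foo = 9L)), "unknown label")
})
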