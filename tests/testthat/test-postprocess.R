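test_that("duplicate removal keeps the sharpest member of each group", {
  # hand-worked toy: two same-frame rows 5 nm apart, uncertainties 10 / 15
  tab <- toy_table(frame = c(0L, 0L), x = c(0, 5), y = c(0, 0),
                   uncertainty = c(10, 15))
  out <- remove_duplicates(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$uncertainty, 10)

  # same position in different frames: step 1 is intra-frame only
  tf <- toy_table(frame = c(0L, 1L), x = c(0, 0), y = c(0, 0))
  expect_equal(nrow(remove_duplicates(tf)), 2L)

  expect_equal(nrow(remove_duplicates(empty_table())), 0L)

  # transitive grouping: chain of three rows, pairwise 8 nm, radius 10
  chain <- toy_table(frame = 0L, x = c(0, 8, 16), y = c(0, 0, 0),
                     uncertainty = c(12, 11, 13))
  out2 <- remove_duplicates(chain, filter_params(duplicate_radius = 10))
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$uncertainty, 11)
})

test_that("uncertainty filter is strict: the boundary value survives", {
  tab <- toy_table(frame = 0:2, x = c(0, 100, 200), y = 0,
                   uncertainty = c(15, 20, 25))
  out <- filter_uncertainty(tab)
  expect_equal(sort(out$uncertainty), c(15, 20))

  all_ok <- toy_table(frame = 0:1, x = c(0, 50), y = 0, uncertainty = 18)
  expect_equal(nrow(filter_uncertainty(all_ok)), 2L)

  none <- toy_table(frame = 0:1, x = c(0, 50), y = 0, uncertainty = 30)
  expect_equal(nrow(filter_uncertainty(none)), 0L)
})

test_that("density filter counts neighbors on the pre-filter set", {
  # triangle 30 nm on a side: each row has 2 neighbors in 50 nm -> all kept
  tri <- toy_table(frame = 0:2, x = c(0, 30, 15), y = c(0, 0, 26))
  expect_equal(nrow(density_filter(tri)), 3L)

  # an isolated row 200 nm away is removed
  iso <- toy_table(frame = 0:3, x = c(0, 30, 15, 230), y = c(0, 0, 26, 0))
  expect_equal(nrow(density_filter(iso)), 3L)

  # a pair 30 nm apart has only 1 neighbor each -> both removed
  pair <- toy_table(frame = 0:1, x = c(0, 30), y = 0)
  expect_equal(nrow(density_filter(pair)), 0L)
})

test_that("blink merging pools chains by inverse-variance weights", {
  # same molecule in frames 3, 4, 5 within 8 nm -> one record
  tab <- toy_table(frame = 3:5, x = c(0, 6, 3), y = c(0, 2, 7),
                   uncertainty = c(10, 10, 10))
  out <- merge_blinks(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$frame, 3L)
  # equal weights: plain mean; combined sigma = sigma / sqrt(3)
  expect_equal(out$x, 3)
  expect_equal(out$uncertainty, 10 / sqrt(3))

  # two molecules 100 nm apart blinking in the same frames stay separate
  two <- toy_table(frame = c(0L, 0L, 1L, 1L), x = c(0, 100, 2, 98),
                   y = 0, uncertainty = 8)
  expect_equal(nrow(merge_blinks(two)), 2L)

  # equal-sigma pair at (0,0) and (10,0): merged position (5, 0)
  sym <- toy_table(frame = 0:1, x = c(0, 10), y = c(0, 0), uncertainty = 10)
  m <- merge_blinks(sym)
  expect_equal(m$x, 5)
  expect_equal(m$y, 0)

  # sum of inverse variances is conserved within a chain
  mix <- toy_table(frame = 0:1, x = c(0, 5), y = 0, uncertainty = c(5, 10))
  mm <- merge_blinks(mix)
  expect_equal(1 / mm$uncertainty^2, 1 / 25 + 1 / 100)

  # a gap of one dark frame breaks the chain at the default gap 0
  gap <- toy_table(frame = c(0L, 2L), x = c(0, 4), y = 0, uncertainty = 10)
  expect_equal(nrow(merge_blinks(gap)), 2L)
  expect_equal(nrow(merge_blinks(gap, filter_params(merge_max_gap_frames = 1))),
               1L)
})

test_that("drift estimation recovers an injected linear path", {
  r <- region(0, 0, 3000, 3000)

  # static beads, zero noise: offsets identically zero
  still <- add_fiducials(empty_table(), r, 2, 100, loc_sigma = 0,
                         channels = "647", seed = 1)
  est0 <- estimate_drift(still)
  expect_equal(max(abs(c(est0$dx, est0$dy))), 0)

  # 0.5 nm/frame drift, 2 beads, sigma 2 nm, 500 frames: RMS error < 1 nm
  beads <- add_fiducials(empty_table(), r, 2, 500, loc_sigma = 2,
                         channels = "647", seed = 2)
  path <- drift_path_linear(500, 0.5, -0.2)
  est <- estimate_drift(apply_drift(beads, path))
  rms <- sqrt(mean((est$dx - path$dx)^2 + (est$dy - path$dy)^2))
  expect_lt(rms, 1)

  # averaging two beads beats one bead (variance oracle), on average
  err_for <- function(n_beads, seed) {
    b <- add_fiducials(empty_table(), r, n_beads, 300, loc_sigma = 3,
                       channels = "647", seed = seed)
    p <- drift_path_linear(300, 0.3, 0.1)
    e <- estimate_drift(apply_drift(b, p))
    mean((e$dx - p$dx)^2 + (e$dy - p$dy)^2)
  }
  err1 <- mean(vapply(1:6, function(s) err_for(1, s), numeric(1)))
  err2 <- mean(vapply(1:6, function(s) err_for(2, 100 + s), numeric(1)))
  expect_lt(err2, err1)

  expect_error(estimate_drift(toy_table(0L, 0, 0)), "fiducial")
})

test_that("drift correction inverts injection and touches nothing else", {
  set.seed(3)
  tab <- toy_table(frame = sample(0:99, 40, replace = TRUE),
                   x = runif(40, 0, 3000), y = runif(40, 0, 3000),
                   uncertainty = runif(40, 5, 15))
  path <- drift_path_random_walk(100, 0.5, seed = 4)
  back <- apply_drift_correction(apply_drift(tab, path), path)
  expect_equal(back$x, tab$x, tolerance = 1e-12)
  expect_equal(back$y, tab$y, tolerance = 1e-12)
  expect_identical(back$frame, tab$frame)
  expect_identical(back$uncertainty, tab$uncertainty)

  zero <- drift_path(rep(0, 100), rep(0, 100))
  expect_equal(apply_drift_correction(tab, zero), tab)
  expect_error(apply_drift_correction(tab, drift_path_linear(10, 1)),
               "cover frame")
})

test_that("registration recovers identity, translation and a known warp", {
  beads <- grid_bead_table(n_frames = 6000, loc_sigma = 2, seed = 5)
  fixed <- beads[beads$channel == "647", ]

  ident <- fit_registration(fixed, fixed, degree = 1)
  expect_equal(ident$coef_x, c(0, 1, 0), tolerance = 1e-8)
  expect_equal(ident$coef_y, c(0, 0, 1), tolerance = 1e-8)
  expect_lt(ident$rms_residual, 1e-8)

  # pure translation: recovered up to centroid noise (sigma / sqrt(frames))
  shift <- channel_warp(c(30, 1, 0), c(-10, 0, 1), 1)
  warped <- apply_channel_warp(beads, shift, "488")
  tr <- fit_registration(warped[warped$channel == "488", ],
                         warped[warped$channel == "647", ], degree = 1)
  expect_equal(tr$coef_x, c(-30, 1, 0), tolerance = 0.01)
  expect_equal(tr$coef_y, c(10, 0, 1), tolerance = 0.01)
  expect_lt(tr$rms_residual, 3 * 2 / sqrt(6000))

  # injected degree-2 warp: each coefficient recovered within 1 %
  w2 <- test_warp2()
  warped2 <- apply_channel_warp(beads, w2, "488")
  # fit the forward map 647 -> warped 488 to compare against known coefs
  fit2 <- fit_registration(warped2[warped2$channel == "647", ],
                           warped2[warped2$channel == "488", ], degree = 2)
  expect_lt(max(abs(fit2$coef_x - w2$coef_x) / abs(w2$coef_x)), 0.01)
  expect_lt(max(abs(fit2$coef_y - w2$coef_y) / abs(w2$coef_y)), 0.01)

  # applying the fitted inverse registration restores coordinates within
  # 2 rms of the per-localization noise scale
  reg <- fit_registration(warped2[warped2$channel == "488", ],
                          warped2[warped2$channel == "647", ], degree = 2)
  restored <- apply_registration(warped2, reg, "488")
  res <- sqrt((restored$x - beads$x)^2 + (restored$y - beads$y)^2)
  expect_lt(stats::median(res[restored$channel == "488"]),
            max(2 * reg$rms_residual, 0.5))

  expect_error(fit_registration(fixed[1, ], fixed[1, ], degree = 2),
               "matched fiducials")
  line <- cbind(seq(0, 900, 100), seq(0, 900, 100))
  expect_error(fit_registration(line, line, degree = 2), "degenerate")
})

test_that("the full chain recovers molecule counts on a sparse field", {
  r <- region(0, 0, 4000, 4000)
  f <- generate_csr(r, 200, seed = 11)
  tab <- simulate_localizations(f, blink_model(3, 5, 0, 300), seed = 12)
  params <- filter_params(density_radius = 300, density_min_neighbors = 2,
                          merge_max_gap_frames = 300)
  out <- run_postprocess(tab, params, verbose = FALSE)
  expect_lt(abs(nrow(out) - 200) / 200, 0.05)
  lg <- attr(out, "log")
  expect_true(all(c("remove_duplicates", "merge_blinks") %in% lg$step))
})

test_that("the printed step order is the one executed", {
  # A and B are same-frame duplicates 5 nm apart; D sits 45 nm from A.
  # Printed order (duplicates before density) leaves A and D with a single
  # neighbor each, so the density filter removes everything; running the
  # density filter first would keep all three rows.
  tab <- toy_table(frame = c(0L, 0L, 0L), x = c(0, 5, 0), y = c(0, 0, 45),
                   uncertainty = c(10, 15, 10))
  params <- filter_params(density_min_neighbors = 2, density_radius = 50)
  ours <- run_postprocess(tab, params, verbose = FALSE)
  expect_equal(nrow(ours), 0L)
  permuted <- merge_blinks(remove_duplicates(density_filter(tab, params),
                                             params), params)
  expect_gt(nrow(permuted), 0L)
})

test_that("filters are contractive pure functions", {
  set.seed(13)
  tab <- toy_table(frame = sample(0:20, 80, replace = TRUE),
                   x = runif(80, 0, 1000), y = runif(80, 0, 1000),
                   uncertainty = runif(80, 5, 30))
  for (fn in list(remove_duplicates, filter_uncertainty, density_filter)) {
    a <- fn(tab, filter_params())
    b <- fn(tab, filter_params())
    expect_identical(a, b)
    expect_lte(nrow(a), nrow(tab))
  }
})
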