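test_that("CSR generator matches uniform moments and handles edge cases", {
  r <- region(0, 0, 3000, 3000)
  expect_equal(nrow(generate_csr(r, 0)), 0L)
  expect_error(generate_csr(r, -1), "non-negative")

  f <- generate_csr(r, 500, seed = 7)
  expect_true(all(in_region(r, f$x, f$y)))
  # closed-form uniform moments: mean = 1500, SE = width / sqrt(12 n)
  se <- 3000 / sqrt(12 * 500)
  expect_lt(abs(mean(f$x) - 1500), 3 * se)
  expect_lt(abs(mean(f$y) - 1500), 3 * se)
})

test_that("generators are bit-for-bit reproducible and leave the RNG alone", {
  r <- region(0, 0, 3000, 3000)
  set.seed(99)
  before <- .Random.seed
  f1 <- generate_cluster_field(r, cluster_field_params(10, 20, 50, 0.2),
                               seed = 5)
  expect_identical(before, .Random.seed)
  f2 <- generate_cluster_field(r, cluster_field_params(10, 20, 50, 0.2),
                               seed = 5)
  expect_identical(f1, f2)
  t1 <- simulate_localizations(f1, blink_model(3, 8, 3, 500), seed = 6)
  t2 <- simulate_localizations(f1, blink_model(3, 8, 3, 500), seed = 6)
  expect_identical(t1, t2)
})

test_that("cluster fields concentrate around their centers", {
  r <- region(0, 0, 3000, 3000)
  f <- generate_cluster_field(r, cluster_field_params(1, 100, 20, 0),
                              seed = 3, wrap = FALSE)
  ctr <- c(mean(f$x), mean(f$y))
  d <- sqrt((f$x - ctr[1])^2 + (f$y - ctr[2])^2)
  expect_true(all(d < 5 * 20))
  expect_true(all(f$cluster_id == 1L))
})

test_that("fully-background cluster field is indistinguishable from CSR", {
  r <- region(0, 0, 3000, 3000)
  vals <- vapply(1:5, function(s) {
    f <- generate_cluster_field(r, cluster_field_params(30, 50, 60, 1),
                                seed = s)
    hopkins_index(f, r, m = 100, n_iterations = 30,
                  seed = 100 + s)$value
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.03)
})

test_that("coupling places species B on species A by construction", {
  r <- region(0, 0, 3000, 3000)
  a <- generate_csr(r, 400, seed = 1, species = "647")
  pb <- cluster_field_params(20, 20, 40, 1)
  expect_error(couple_fields(a, pb, 1.5), "\\[0, 1\\]")

  b0 <- couple_fields(a, pb, coupling_fraction = 0, seed = 2)
  expect_true(all(is.na(b0$coupled_to)))

  b1 <- couple_fields(a, pb, coupling_fraction = 1, coupling_jitter = 0,
                      seed = 3)
  expect_true(all(!is.na(b1$coupled_to)))
  # every B position equals the position of its recorded A partner
  idx <- match(b1$coupled_to, a$molecule_id)
  expect_equal(b1$x, a$x[idx], tolerance = 1e-12)
  expect_equal(b1$y, a$y[idx], tolerance = 1e-12)
})

test_that("blink simulation reproduces the geometric appearance model", {
  r <- region(0, 0, 3000, 3000)
  f <- generate_csr(r, 200, seed = 4)

  one <- simulate_localizations(f, blink_model(1, 10, 0, 100), seed = 5)
  expect_equal(nrow(one), 200L)
  expect_equal(sort(unique(one$molecule_id)), 1:200)

  f100 <- generate_csr(r, 100, seed = 8)
  many <- simulate_localizations(f100, blink_model(3, 10, 3, 5000), seed = 5)
  # geometric-sum oracle: mean 3 per molecule, var (1-p)/p^2 = 6
  sd_total <- sqrt(100 * 6)
  expect_lt(abs(nrow(many) - 300), 3 * sd_total)
  # blinks of one molecule land in distinct frames
  expect_false(any(duplicated(many[, c("molecule_id", "frame")])))

  clean <- simulate_localizations(f, blink_model(2, 0, 0, 100), seed = 6)
  idx <- match(clean$molecule_id, f$molecule_id)
  expect_equal(clean$x, f$x[idx])
  expect_equal(clean$y, f$y[idx])
})

test_that("drift injection shifts frames as constructed and round-trips", {
  tab <- toy_table(frame = c(0L, 50L, 99L), x = c(100, 200, 300),
                   y = c(100, 200, 300))
  zero <- drift_path(rep(0, 100), rep(0, 100))
  expect_equal(apply_drift(tab, zero)$x, tab$x)

  lin <- drift_path_linear(100, 1, 0)
  shifted <- apply_drift(tab, lin)
  expect_equal(shifted$x, tab$x + c(0, 50, 99))
  expect_equal(shifted$y, tab$y)

  neg <- drift_path(-lin$dx, -lin$dy)
  back <- apply_drift(apply_drift(tab, lin), neg)
  expect_equal(back$x, tab$x, tolerance = 1e-12)

  short <- drift_path_linear(50, 1, 0)
  expect_error(apply_drift(tab, short), "cover frame")
})

test_that("fiducial rows are added per frame and channel", {
  r <- region(0, 0, 3000, 3000)
  expect_identical(nrow(add_fiducials(empty_table(), r, 0, 100)), 0L)

  tab <- add_fiducials(empty_table(), r, 2, 100, loc_sigma = 2,
                       channels = c("647", "488"), seed = 1)
  expect_equal(nrow(tab), 400L)
  expect_true(all(tab$is_fiducial))
  expect_setequal(unique(tab$channel), c("647", "488"))

  still <- add_fiducials(empty_table(), r, 1, 50, loc_sigma = 0,
                         channels = "647", seed = 2)
  expect_equal(length(unique(still$x)), 1L)
  expect_equal(length(unique(still$y)), 1L)
})

test_that("channel warps transform only the named channel", {
  tab <- toy_table(frame = 0L, x = c(100, 200), y = c(50, 60),
                   channel = c("647", "488"))
  ident <- channel_warp(c(0, 1, 0), c(0, 0, 1), 1)
  expect_equal(apply_channel_warp(tab, ident, "488"), tab)

  shift <- channel_warp(c(30, 1, 0), c(-10, 0, 1), 1)
  out <- apply_channel_warp(tab, shift, "488")
  expect_equal(out$x, c(100, 230))
  expect_equal(out$y, c(50, 50))

  expect_error(apply_channel_warp(tab, shift, "561"), "not present")
})

test_that("near-identity warps invert to sub-0.1 nm by iteration", {
  w <- channel_warp(c(25, 1.001, 2e-4, 1e-7, -5e-8, 8e-8),
                    c(-12, 3e-4, 0.999, -6e-8, 1e-7, 4e-8), 2)
  x <- runif(50, 0, 3000)
  y <- runif(50, 0, 3000)
  fwd <- smlmpipe:::.warp_xy(w, x, y)
  inv <- invert_warp(w, fwd$x, fwd$y, tol = 1e-3)
  expect_lt(max(abs(inv$x - x)), 0.1)
  expect_lt(max(abs(inv$y - y)), 0.1)
})

test_that("Brownian tracks match the closed-form increment variance", {
  frozen <- simulate_brownian_tracks(brownian_params(0, 0.05, 50, 0), 3,
                                     seed = 1)
  for (tr in frozen) {
    expect_equal(length(unique(tr$x)), 1L)
    expect_equal(length(unique(tr$y)), 1L)
  }

  p <- brownian_params(0.02, 0.05, 100, 0)
  tracks <- simulate_brownian_tracks(p, 200, seed = 2)
  steps <- unlist(lapply(tracks, function(tr) c(diff(tr$x), diff(tr$y))))
  v_hat <- mean(steps^2) # per-axis increment variance, nm^2
  v_true <- 2 * p$D_true * p$dt * 1e6
  se <- sqrt(2 / length(steps)) * v_true
  expect_lt(abs(v_hat - v_true), 3 * se)

  # ensemble MSD at lag 1 ~ 4 D dt
  msd1 <- mean(vapply(tracks, function(tr) {
    mean((diff(tr$x))^2 + (diff(tr$y))^2)
  }, numeric(1)))
  expect_lt(abs(msd1 - 4 * p$D_true * p$dt * 1e6),
            3 * sqrt(2 / length(steps)) * 2 * v_true)
})
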