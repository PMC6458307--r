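test_that("Hopkins index is calibrated at 0.5 under CSR and bounded", {
  r <- region(0, 0, 3000, 3000)
  vals <- vapply(1:10, function(s) {
    f <- generate_csr(r, 2000, seed = s)
    h <- hopkins_index(f, r, m = 100, n_iterations = 30, seed = 1000 + s)
    expect_true(all(h$per_iteration >= 0 & h$per_iteration <= 1))
    expect_equal(h$value, mean(h$per_iteration))
    h$value
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("Hopkins hits its degenerate and regular limits", {
  r <- region(0, 0, 3000, 3000)
  # all points coincident: w_i = 0 exactly, value = 1
  co <- cbind(rep(1500, 300), rep(1500, 300))
  expect_equal(hopkins_index(co, r, m = 100, n_iterations = 5,
                             seed = 1)$value, 1)

  # regular lattice: more regular than random, value < 0.5
  g <- seq(75, 2925, length.out = 20)
  lattice <- as.matrix(expand.grid(g, g))
  expect_lt(hopkins_index(lattice, r, m = 100, n_iterations = 30,
                          seed = 2)$value, 0.5)

  expect_error(hopkins_index(co[1:10, ], r, m = 100), "at least")
})

test_that("Hopkins increases with the clustered fraction", {
  r <- region(0, 0, 3000, 3000)
  mean_hopkins <- function(bg) {
    mean(vapply(1:5, function(s) {
      f <- generate_cluster_field(r, cluster_field_params(30, 40, 50, bg),
                                  seed = 37 * s + bg * 1000)
      hopkins_index(f, r, m = 100, n_iterations = 20, seed = s)$value
    }, numeric(1)))
  }
  h <- vapply(c(1, 0.5, 0), mean_hopkins, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("Ripley curves satisfy their structural invariants", {
  r <- region(0, 0, 3000, 3000)
  f <- generate_cluster_field(r, cluster_field_params(30, 50, 60, 0.1),
                              seed = 5)
  rc <- ripley_curve(f, r, r_max = 500, n_r = 50)
  expect_equal(rc$K[1], 0)
  expect_equal(rc$H[1], 0)
  expect_true(all(diff(rc$K) >= 0))
  expect_equal(rc$L, sqrt(rc$K / pi))
  expect_equal(rc$peak_height, max(rc$H))
  expect_equal(rc$peak_radius, rc$r[which.max(rc$H)])
  expect_error(ripley_curve(f, r, r_max = 2000), "half")
  expect_error(ripley_curve(f[1, , drop = FALSE], r, 500), "at least 2")
})

test_that("toroidal CSR Ripley H is unbiased around zero", {
  r <- region(0, 0, 3000, 3000)
  H <- sapply(1:40, function(s) {
    ripley_curve(generate_csr(r, 800, seed = s), r, 500, 25)$H
  })
  m <- rowMeans(H)[-1]
  se <- apply(H, 1, sd)[-1] / sqrt(ncol(H))
  expect_true(all(abs(m) < 3.5 * se + 1e-9))
})

test_that("empirical K of a Thomas field matches the closed form", {
  r <- region(0, 0, 3000, 3000)
  Ks <- sapply(1:20, function(s) {
    f <- generate_cluster_field(r, cluster_field_params(30, 50, 60, 0.1),
                                seed = 200 + s)
    ripley_curve(f, r, 500, 25)$K
  })
  rr <- seq(0, 500, length.out = 25)
  theory <- thomas_k_theoretical(rr, 30, r, 60, 0.1)
  lo <- apply(Ks, 1, quantile, 0.025)
  hi <- apply(Ks, 1, quantile, 0.975)
  expect_true(all(theory >= lo - 1e-9 & theory <= hi + 1e-9))
})

test_that("isotropic edge correction is unbiased for CSR in a rectangle", {
  r <- region(0, 0, 3000, 3000)
  Ks <- sapply(1:10, function(s) {
    ripley_curve(generate_csr(r, 600, seed = 50 + s), r, 500, 25,
                 edge_correction = "isotropic")$K
  })
  rr <- seq(0, 500, length.out = 25)
  m <- rowMeans(Ks)
  idx <- rr >= 200
  expect_lt(max(abs(m[idx] - pi * rr[idx]^2) / (pi * rr[idx]^2)), 0.1)
})

test_that("H peak radius grows with cluster spread", {
  r <- region(0, 0, 3000, 3000)
  peak_at <- function(sig) {
    mean(vapply(1:5, function(s) {
      f <- generate_cluster_field(r, cluster_field_params(30, 50, sig, 0),
                                  seed = 300 + 7 * s + sig)
      ripley_curve(f, r, 700, 70)$peak_radius
    }, numeric(1)))
  }
  peaks <- vapply(c(30, 60, 120), peak_at, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("DBSCAN agrees with the exhaustive density-connectivity oracle", {
  # a hand-sized instance with two clusters, a border point and noise
  xy <- rbind(c(0, 0), c(10, 0), c(5, 8), c(4, 4), c(18, 0),
              c(100, 100), c(108, 100), c(104, 106), c(103, 103),
              c(200, 0), c(60, 50), c(140, 140))
  cs <- dbscan_clusters(xy, eps = 12, min_pts = 4)
  expect_identical(cs$labels, oracle_dbscan(xy, 12, 4))

  # all points pairwise farther than eps: everything is noise
  far <- cbind(seq(0, 900, 100), 0)
  expect_true(all(is.na(dbscan_clusters(far, eps = 50,
                                        min_pts = 2)$labels)))

  # randomized sweep against the oracle
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:15, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    eps <- runif(1, 10, 40)
    mp <- sample(2:4, 1)
    expect_identical(dbscan_clusters(pts, eps, mp)$labels,
                     oracle_dbscan(pts, eps, mp),
                     info = sprintf("instance %d", i))
  }
})

test_that("cluster summaries respect the density = size/diameter identity", {
  set.seed(8)
  r <- region(0, 0, 3000, 3000)
  f <- generate_cluster_field(r, cluster_field_params(15, 40, 40, 0.1),
                              seed = 9)
  cs <- dbscan_clusters(f, eps = 50, min_pts = 10)
  expect_gt(nrow(cs$clusters), 0)
  expect_equal(cs$clusters$density,
               cs$clusters$size / cs$clusters$diameter)
  # every labelled point belongs to a reported cluster
  expect_setequal(unique(cs$labels[!is.na(cs$labels)]), cs$clusters$label)

  expect_equal(mean_cluster_density(cs),
               mean(cs$clusters$density))
})

test_that("mean cluster density follows its arithmetic contract", {
  fake <- structure(list(
    labels = c(1L, 1L, 2L, 2L),
    clusters = data.frame(label = 1:2, size = c(10L, 30L),
                          diameter = c(100, 100),
                          density = c(0.1, 0.3)),
    params = list()), class = "cluster_set")
  expect_equal(mean_cluster_density(fake), 0.2)

  none <- structure(list(labels = rep(NA_integer_, 3),
                         clusters = data.frame(label = integer(0),
                                               size = integer(0),
                                               diameter = numeric(0),
                                               density = numeric(0)),
                         params = list()), class = "cluster_set")
  expect_warning(v <- mean_cluster_density(none), "undefined")
  expect_true(is.na(v))
})

test_that("denser clusters raise the mean DBSCAN density", {
  r <- region(0, 0, 3000, 3000)
  dens_at <- function(mu) {
    mean(vapply(1:5, function(s) {
      f <- generate_cluster_field(r, cluster_field_params(25, mu, 40, 0.1),
                                  seed = 400 + 13 * s + mu)
      suppressWarnings(
        mean_cluster_density(dbscan_clusters(f, eps = 50, min_pts = 10)))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(dens_at(20), dens_at(40))
})

test_that("Getis analysis is calibrated on CSR and finds a planted cluster", {
  r <- region(0, 0, 3000, 3000)
  # null calibration: flagged fraction at the 95 % threshold stays <= 6 %
  fracs <- vapply(1:300, function(s) {
    f <- generate_csr(r, 200, seed = 4000 + s)
    g <- getis_clusters(f, r, d = 150, n_null = 20, seed = 5000 + s)
    mean(g$flagged)
  }, numeric(1))
  expect_lte(mean(fracs), 0.06)

  # a single tight cluster on sparse background forms one component whose
  # diameter is within a factor 2 of the 4 sigma spread
  set.seed(21)
  clus <- cbind(rnorm(80, 1500, 50), rnorm(80, 1500, 50))
  bg <- cbind(runif(40, 0, 3000), runif(40, 0, 3000))
  g2 <- getis_clusters(rbind(clus, bg), r, d = 100, n_null = 50, seed = 22)
  expect_gte(nrow(g2$clusters), 1)
  main <- g2$clusters[which.max(g2$clusters$size), ]
  expect_gt(main$diameter, 100) # >= (4 sigma)/2
  expect_lt(main$diameter, 400) # <= (4 sigma)*2

  # a uniform lattice has no locally clustered points
  gr <- seq(75, 2925, length.out = 20)
  lattice <- as.matrix(expand.grid(gr, gr))
  g3 <- getis_clusters(lattice, r, d = 225, n_null = 50, seed = 23)
  expect_equal(sum(g3$flagged), 0L)
})
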