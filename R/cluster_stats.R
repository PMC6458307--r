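#' Hopkins index of clustering tendency
#'
#' Compares nearest-neighbor distances from `m` uniform test locations with
#' nearest-other-neighbor distances from `m` sampled data points, using
#' squared distances (the standard 2-D form): per iteration the statistic
#' is `sum(u_i^2) / (sum(u_i^2) + sum(w_i^2))` and the result is the mean
#' over iterations. Under complete spatial randomness the expectation is
#' 0.5; values near 1 indicate clustering, values below 0.5 regularity.
#'
#' @param points A point set (matrix or data frame with x/y columns, in nm).
#' @param region The [region()] the points live on (test locations are
#'   drawn uniformly from it).
#' @param m Sample size per iteration; default `min(floor(0.1 * n), 100)`.
#'   The data must contain at least `2 * m` points.
#' @param n_iterations Number of resampling iterations.
#' @param seed Optional integer seed.
#' @param subsample_n Optionally subsample the data to this many points
#'   before analysis (off by default).
#' @return A `hopkins_result`: list with `value`, `per_iteration`, `m`,
#'   `n_iterations`, `n_points`.
#' @examples
#' f <- generate_csr(region(), 500, seed = 1)
#' hopkins_index(f, region(), n_iterations = 20, seed = 2)$value
#' @export
hopkins_index <- function(points, region, m = NULL, n_iterations = 100,
                          seed = NULL, subsample_n = NULL) {
  stopifnot(inherits(region, "region"))
  xy <- .as_xy(points)
  .with_seed(seed, {
    if (!is.null(subsample_n) && nrow(xy) > subsample_n) {
      xy <- xy[sample.int(nrow(xy), subsample_n), , drop = FALSE]
    }
    n <- nrow(xy)
    if (is.null(m)) m <- max(1L, min(floor(0.1 * n), 100L))
    m <- as.integer(m)
    if (n < 2L * m) {
      stop(sprintf("need at least 2*m = %d points, got %d", 2L * m, n),
           call. = FALSE)
    }
    vals <- vapply(seq_len(n_iterations), function(it) {
      tx <- region$x0 + stats::runif(m) * region$width
      ty <- region$y0 + stats::runif(m) * region$height
      u <- .nearest_dist(tx, ty, xy)
      s <- sample.int(n, m)
      w <- .nearest_dist(xy[s, 1], xy[s, 2], xy, exclude = s)
      su <- sum(u^2)
      su / (su + sum(w^2))
    }, numeric(1))
    structure(
      list(value = mean(vals), per_iteration = vals, m = m,
           n_iterations = as.integer(n_iterations), n_points = n),
      class = "hopkins_result"
    )
  })
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins index: %.4f (m = %d, %d iterations, n = %d)\n",
              x$value, x$m, x$n_iterations, x$n_points))
  invisible(x)
}

#' Ripley's K, L and H functions with peak extraction
#'
#' `K(r) = (area / n^2) * sum_{i != j} w_ij * 1[d_ij <= r]`,
#' `L(r) = sqrt(K/pi)`, `H(r) = L(r) - r`. Under CSR, H is zero in
#' expectation; a positive peak indicates clustering, its radius the
#' characteristic cluster scale. Two edge corrections are available:
#' `"toroidal"` (wrapped distances, `w_ij = 1`; exact for fields generated
#' on the torus, the default for synthetic work) and `"isotropic"`
#' (Ripley's circle-arc weight for points observed in a rectangle, for
#' real ROIs).
#'
#' @param points A point set in nm.
#' @param region The observation [region()].
#' @param r_max Largest radius evaluated, nm; must not exceed half the
#'   shorter region side.
#' @param n_r Number of grid radii (the grid is `seq(0, r_max, length.out
#'   = n_r)`; `K(0) = 0`).
#' @param edge_correction `"toroidal"` or `"isotropic"`.
#' @return A `ripley_curve`: list with `r`, `K`, `L`, `H`, `peak_height`,
#'   `peak_radius`, `edge_correction`, `n_points`.
#' @export
ripley_curve <- function(points, region, r_max = 500, n_r = 50,
                         edge_correction = c("toroidal", "isotropic")) {
  stopifnot(inherits(region, "region"))
  edge_correction <- match.arg(edge_correction)
  xy <- .as_xy(points)
  n <- nrow(xy)
  if (n < 2L) stop("Ripley's K needs at least 2 points", call. = FALSE)
  if (r_max > min(region$width, region$height) / 2) {
    stop("r_max must not exceed half the shorter region side", call. = FALSE)
  }
  r <- seq(0, r_max, length.out = n_r)
  area <- region_area(region)
  # pairwise distances (ordered pairs i != j), chunked
  dvec <- numeric(0)
  wvec <- numeric(0)
  chunk <- max(1L, floor(2^21 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx <- abs(outer(xy[idx, 1], xy[, 1], "-"))
    dy <- abs(outer(xy[idx, 2], xy[, 2], "-"))
    if (edge_correction == "toroidal") {
      dx <- pmin(dx, region$width - dx)
      dy <- pmin(dy, region$height - dy)
    }
    dmat <- sqrt(dx^2 + dy^2)
    dmat[cbind(seq_along(idx), idx)] <- Inf # drop self pairs
    keep <- dmat <= r_max
    d_chunk <- dmat[keep]
    if (edge_correction == "isotropic") {
      ex <- pmin(xy[idx, 1] - region$x0, region$x0 + region$width - xy[idx, 1])
      ey <- pmin(xy[idx, 2] - region$y0, region$y0 + region$height - xy[idx, 2])
      exm <- matrix(ex, nrow = length(idx), ncol = n)
      eym <- matrix(ey, nrow = length(idx), ncol = n)
      w_chunk <- .isotropic_weight(d_chunk, exm[keep], eym[keep])
    } else {
      w_chunk <- rep(1, length(d_chunk))
    }
    dvec <- c(dvec, d_chunk)
    wvec <- c(wvec, w_chunk)
  }
  ord <- order(dvec)
  cw <- c(0, cumsum(wvec[ord]))
  counts <- cw[findInterval(r, dvec[ord]) + 1L]
  K <- area / n^2 * counts
  L <- sqrt(K / pi)
  H <- L - r
  peak_idx <- which.max(H)
  structure(
    list(r = r, K = K, L = L, H = H,
         peak_height = H[peak_idx], peak_radius = r[peak_idx],
         edge_correction = edge_correction, n_points = n),
    class = "ripley_curve"
  )
}

# Ripley isotropic edge weight for a rectangle: 1 / (fraction of the circle
# of radius d around point i lying inside the region). Valid for
# d <= min(side)/2 (enforced by ripley_curve), where at most the nearest
# edge per axis and one corner can intersect the circle.
.isotropic_weight <- function(d, ex, ey) {
  out <- numeric(length(d))
  ax <- ifelse(ex < d, 2 * acos(pmin(ex / d, 1)), 0)
  ay <- ifelse(ey < d, 2 * acos(pmin(ey / d, 1)), 0)
  overlap <- pmax(ax / 2 + ay / 2 - pi / 2, 0)
  corner <- ex^2 + ey^2 < d^2
  outside <- ax + ay - ifelse(corner, overlap, 0)
  frac <- 1 - outside / (2 * pi)
  1 / pmax(frac, 1e-6)
}

#' Closed-form Ripley K of a Thomas process (with uniform background)
#'
#' For a Thomas process with cluster intensity `kappa` (clusters per unit
#' area) and Gaussian spread `sigma`,
#' `K(r) = pi r^2 + (1/kappa) (1 - exp(-r^2 / (4 sigma^2)))`. When a
#' fraction `background_fraction` of molecules is an independent uniform
#' background, the field is a superposition and the excess term scales by
#' `(1 - background_fraction)^2`.
#'
#' @param r Radii, nm.
#' @param n_clusters,region Cluster count and region defining
#'   `kappa = n_clusters / area`.
#' @param cluster_sigma Gaussian cluster spread, nm.
#' @param background_fraction Uniform background share in `[0, 1)`.
#' @return Numeric vector `K(r)` in nm^2.
#' @export
thomas_k_theoretical <- function(r, n_clusters, region, cluster_sigma,
                                 background_fraction = 0) {
  stopifnot(inherits(region, "region"), n_clusters > 0,
            background_fraction >= 0, background_fraction < 1)
  kappa <- n_clusters / region_area(region)
  pi * r^2 + (1 - background_fraction)^2 / kappa *
    (1 - exp(-r^2 / (4 * cluster_sigma^2)))
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf(
    "Ripley curve (%s correction, n = %d): H peak %.1f nm at r = %.1f nm\n",
    x$edge_correction, x$n_points, x$peak_height, x$peak_radius))
  invisible(x)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r, x$H, type = "l", xlab = "r (nm)", ylab = "H(r) (nm)",
                 ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::points(x$peak_radius, x$peak_height, pch = 19)
  invisible(x)
}

#' DBSCAN nanocluster segmentation
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts` points
#' (including itself) within `eps`; clusters are the density-connected
#' components; non-core points within `eps` of a core are border points and
#' join the cluster of their nearest core (ties broken by lowest index, so
#' labels are deterministic); everything else is noise (`NA` label).
#' Per-cluster diameter is the maximum pairwise distance and the relative
#' cluster density is `size / diameter` (molecules per nm) -- the summary
#' used to compare nanocluster packing between conditions.
#'
#' @param points A point set in nm.
#' @param eps Neighborhood radius, nm (> 0).
#' @param min_pts Core-point threshold, >= 2 (count includes self).
#' @return A `cluster_set`: list with `labels` (integer or `NA` per point),
#'   `clusters` (data frame `label`, `size`, `diameter`, `density`),
#'   `params`.
#' @export
dbscan_clusters <- function(points, eps = 50, min_pts = 10) {
  stopifnot(eps > 0, min_pts >= 2)
  xy <- .as_xy(points)
  n <- nrow(xy)
  labels <- rep(NA_integer_, n)
  if (n == 0L) {
    return(.new_cluster_set(xy, labels, list(eps = eps, min_pts = min_pts)))
  }
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  within <- d2 <= eps^2
  n_in <- rowSums(within) # includes self
  core <- n_in >= min_pts
  if (any(core)) {
    core_idx <- which(core)
    comp <- .components(within[core_idx, core_idx, drop = FALSE])
    labels[core_idx] <- comp
    # border points: nearest core within eps, ties to lowest core index
    border <- which(!core)
    for (i in border) {
      cand <- core_idx[within[i, core_idx]]
      if (length(cand)) {
        labels[i] <- labels[cand[which.min(d2[i, cand])]]
      }
    }
    # renumber clusters by first appearance
    labels <- match(labels, unique(labels[!is.na(labels)]))
  }
  .new_cluster_set(xy, labels, list(eps = eps, min_pts = min_pts))
}

# Build the per-cluster summary shared by DBSCAN and Getis clustering.
.new_cluster_set <- function(xy, labels, params) {
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids)) {
    clusters <- do.call(rbind, lapply(ids, function(l) {
      pts <- xy[which(labels == l), , drop = FALSE]
      dia <- if (nrow(pts) > 1) max(stats::dist(pts)) else 0
      data.frame(label = l, size = nrow(pts), diameter = dia,
                 density = if (dia > 0) nrow(pts) / dia else NA_real_)
    }))
  } else {
    clusters <- data.frame(label = integer(0), size = integer(0),
                           diameter = numeric(0), density = numeric(0))
  }
  structure(list(labels = labels, clusters = clusters, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d of %d points clustered\n",
              nrow(x$clusters), sum(!is.na(x$labels)), length(x$labels)))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Mean relative cluster density of a cluster set
#'
#' The unweighted mean of per-cluster `size / diameter` values -- the
#' one-number-per-ROI summary used to compare conditions. With no clusters
#' the result is `NA` with a warning (an undefined-result signal, not an
#' error).
#'
#' @param cluster_set A `cluster_set` from [dbscan_clusters()].
#' @return Mean density in molecules per nm, or `NA_real_`.
#' @export
mean_cluster_density <- function(cluster_set) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  cl <- cluster_set$clusters
  cl <- cl[is.finite(cl$density), , drop = FALSE]
  if (nrow(cl) == 0L) {
    warning("no clusters: mean cluster density is undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(cl$density)
}

#' Getis-type local clustering analysis
#'
#' Each point receives the normalized local statistic
#' `G_i(d) = (count within d, self excluded) / (n - 1) / (pi d^2 / area)`
#' -- the ratio of the local neighbor share to its expectation under
#' complete spatial randomness. Points whose `G_i` exceeds the 95th
#' percentile of a Monte-Carlo CSR null (same `n`, same region) are
#' flagged as locally clustered; flagged points within `d` of each other
#' are linked into connected components, and components of two or more
#' points are reported as clusters with DBSCAN-style diameters. The mean
#' component diameter is the per-ROI summary.
#'
#' @param points A point set in nm.
#' @param region The observation [region()].
#' @param d Neighborhood distance, nm (> 0).
#' @param n_null Number of CSR simulations pooled for the null threshold.
#' @param threshold_quantile Null quantile above which a point is flagged.
#' @param seed Optional integer seed for the null simulations.
#' @return A `getis_result`: list with `G`, `flagged`, `threshold`,
#'   `labels`, `clusters`, `mean_diameter`, `params`.
#' @export
getis_clusters <- function(points, region, d = 50, n_null = 100,
                           threshold_quantile = 0.95, seed = NULL) {
  stopifnot(inherits(region, "region"), d > 0, n_null >= 1)
  xy <- .as_xy(points)
  n <- nrow(xy)
  if (n < 2L) stop("Getis analysis needs at least 2 points", call. = FALSE)
  area <- region_area(region)
  expected <- pi * d^2 / area
  g_of <- function(pts) {
    .count_neighbors(pts, d) / (nrow(pts) - 1) / expected
  }
  G <- g_of(xy)
  null_G <- .with_seed(seed, {
    unlist(lapply(seq_len(n_null), function(i) {
      sim <- cbind(region$x0 + stats::runif(n) * region$width,
                   region$y0 + stats::runif(n) * region$height)
      g_of(sim)
    }))
  })
  threshold <- stats::quantile(null_G, threshold_quantile, names = FALSE)
  flagged <- G > threshold
  labels <- rep(NA_integer_, n)
  if (sum(flagged) >= 2L) {
    fi <- which(flagged)
    d2 <- outer(xy[fi, 1], xy[fi, 1], "-")^2 +
          outer(xy[fi, 2], xy[fi, 2], "-")^2
    comp <- .components(d2 <= d^2)
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes >= 2])
    comp[!comp %in% big] <- NA_integer_
    labels[fi] <- match(comp, sort(unique(comp[!is.na(comp)])))
  }
  cs <- .new_cluster_set(xy, labels,
                         list(d = d, n_null = n_null,
                              threshold_quantile = threshold_quantile))
  structure(
    list(G = G, flagged = flagged, threshold = threshold,
         labels = labels, clusters = cs$clusters,
         mean_diameter = if (nrow(cs$clusters)) mean(cs$clusters$diameter)
                         else NA_real_,
         params = cs$params),
    class = "getis_result"
  )
}

#' @export
print.getis_result <- function(x, ...) {
  cat(sprintf(
    "<getis_result> %d/%d points flagged (threshold G > %.3f), %d component(s), mean diameter %.1f nm\n",
    sum(x$flagged), length(x$flagged), x$threshold, nrow(x$clusters),
    x$mean_diameter))
  invisible(x)
}
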