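# Shared fixtures and independent oracles, built in code at test time.

# Quick localization table from bare vectors.
toy_table <- function(frame, x, y, uncertainty = 10, channel = "647", ...) {
  localization_table(frame = frame, x = x, y = y,
                     uncertainty = uncertainty, channel = channel, ...)
}

# An empty table to seed add_fiducials etc.
empty_table <- function() {
  localization_table(frame = integer(0), x = numeric(0), y = numeric(0))
}

# Independent brute-force DBSCAN oracle: cores by exhaustive counting,
# cluster membership by transitive closure of the core adjacency matrix
# (boolean matrix powers), border points to the nearest core within eps.
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  labels <- rep(NA_integer_, n)
  if (n == 0L) return(labels)
  d <- as.matrix(stats::dist(xy))
  within <- d <= eps
  core <- rowSums(within) >= min_pts # includes self (diagonal TRUE)
  ci <- which(core)
  if (length(ci)) {
    reach <- within[ci, ci, drop = FALSE]
    diag(reach) <- TRUE
    repeat {
      nxt <- reach | ((reach %*% reach) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp <- integer(length(ci))
    next_label <- 0L
    for (i in seq_along(ci)) {
      if (comp[i] == 0L) {
        next_label <- next_label + 1L
        comp[reach[i, ]] <- next_label
      }
    }
    labels[ci] <- comp
    for (i in which(!core)) {
      cand <- ci[within[i, ci]]
      if (length(cand)) labels[i] <- labels[cand[which.min(d[i, cand])]]
    }
    labels <- match(labels, unique(labels[!is.na(labels)]))
  }
  labels
}

# A full-length two-channel bead acquisition with the beads spread over the
# field of view (as a well-prepared fiducial sample gives): 16 beads on a
# jittered-free grid, localized in every frame of both channels.
grid_bead_table <- function(n_frames = 6000, loc_sigma = 2, seed = 1) {
  g <- seq(300, 2700, length.out = 4)
  ctr <- as.matrix(expand.grid(g, g))
  nb <- nrow(ctr)
  smlmpipe:::.with_seed(seed, {
    rows <- nb * n_frames * 2L
    bead <- rep(rep(seq_len(nb), each = n_frames), 2)
    localization_table(
      frame = rep(rep(seq_len(n_frames) - 1L, nb), 2),
      x = ctr[bead, 1] + stats::rnorm(rows, sd = loc_sigma),
      y = ctr[bead, 2] + stats::rnorm(rows, sd = loc_sigma),
      uncertainty = loc_sigma,
      channel = rep(c("647", "488"), each = nb * n_frames),
      is_fiducial = TRUE)
  })
}

# Realistic degree-2 channel misalignment used in registration tests: tens
# of nm of offset, slight scale error, shear, and curvature.
test_warp2 <- function() {
  channel_warp(c(40, 1.01, 0.02, 2e-5, -1.5e-5, 1.8e-5),
               c(-30, 0.018, 0.99, -1.5e-5, 2e-5, 1.2e-5), 2)
}

# Study-condition field for the identical-channel CBC calibration: tight
# clusters (sigma 20 nm, ~25 molecules each, no background, no torus
# wrapping) so that every localization has a same-species neighbor within
# the 80 nm search radius.
cbc_calibration_field <- function(seed) {
  generate_cluster_field(region(0, 0, 3000, 3000),
                         cluster_field_params(20, 25, 20, 0),
                         seed = seed, wrap = FALSE)
}
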