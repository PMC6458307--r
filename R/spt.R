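#' Construct a single-particle trajectory
#'
#' @param frame Strictly increasing integer frame indices.
#' @param x,y Observed positions in nm.
#' @param dt Frame interval in seconds (0.05 s = 20 frames/s).
#' @param true_x,true_y Optional noise-free ground-truth positions.
#' @param molecule_id Optional ground-truth identity.
#' @return A data frame of class `trajectory` with `dt` attribute.
#' @export
trajectory <- function(frame, x, y, dt = 0.05, true_x = NULL, true_y = NULL,
                       molecule_id = NA_integer_) {
  stopifnot(length(frame) >= 2, all(diff(frame) > 0), dt > 0)
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y))
  if (!is.null(true_x)) df$true_x <- as.numeric(true_x)
  if (!is.null(true_y)) df$true_y <- as.numeric(true_y)
  df$molecule_id <- rep_len(as.integer(molecule_id), nrow(df))
  attr(df, "dt") <- dt
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame greedy mutual-nearest-neighbor assignment: a detection in
#' frame `f` continues the track of a detection in frame `f - 1` iff each
#' is the other's nearest neighbor and their distance is at most
#' `max_disp`. Unmatched detections start new tracks; there is no gap
#' closing (a missed frame ends the track), and tracks shorter than
#' `min_length` frames are discarded -- short tracks give hopelessly noisy
#' diffusion estimates.
#'
#' @param detections A data frame with columns `frame`, `x`, `y` (nm) and
#'   optionally `molecule_id` for ground-truth audits.
#' @param max_disp Maximum frame-to-frame displacement, nm.
#' @param min_length Minimum track length in frames.
#' @param dt Frame interval in seconds attached to the trajectories.
#' @return A list of `trajectory` objects.
#' @export
link_tracks <- function(detections, max_disp, min_length = 10, dt = 0.05) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)),
            max_disp > 0, min_length >= 2)
  if (!"molecule_id" %in% names(detections)) {
    detections$molecule_id <- NA_integer_
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)
  track_of <- integer(nrow(det)) # track id per detection
  n_tracks <- 0L
  prev_rows <- integer(0)
  prev_frame <- NA_integer_
  for (f in frames) {
    rows <- by_frame[[as.character(f)]]
    assigned <- rep(FALSE, length(rows))
    if (length(prev_rows) && !is.na(prev_frame) && f == prev_frame + 1L) {
      d <- sqrt(outer(det$x[prev_rows], det$x[rows], "-")^2 +
                outer(det$y[prev_rows], det$y[rows], "-")^2)
      # mutual nearest neighbors within max_disp
      nn_fwd <- apply(d, 1, which.min)
      nn_bwd <- apply(d, 2, which.min)
      for (i in seq_along(prev_rows)) {
        j <- nn_fwd[i]
        if (nn_bwd[j] == i && d[i, j] <= max_disp) {
          track_of[rows[j]] <- track_of[prev_rows[i]]
          assigned[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned)) {
      n_tracks <- n_tracks + 1L
      track_of[rows[j]] <- n_tracks
    }
    prev_rows <- rows
    prev_frame <- f
  }
  out <- list()
  for (tid in seq_len(n_tracks)) {
    rows <- which(track_of == tid)
    if (length(rows) < min_length) next
    out[[length(out) + 1L]] <- trajectory(
      frame = det$frame[rows], x = det$x[rows], y = det$y[rows], dt = dt,
      molecule_id = det$molecule_id[rows][1]
    )
  }
  out
}

#' Time-averaged mean squared displacement of a trajectory
#'
#' `MSD(tau * dt)` is the mean over all (overlapping) position pairs
#' separated by lag `tau` of the squared displacement, for
#' `tau = 1 .. floor(length/2)` (longer lags average too few pairs to be
#' useful).
#'
#' @param traj A `trajectory`.
#' @param max_lag Optional cap on the largest lag computed.
#' @return A data frame with columns `lag`, `tau_s` (seconds) and `msd`
#'   (nm^2); the zero-lag MSD is 0 by definition and not included.
#' @export
compute_msd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  dt <- attr(traj, "dt")
  lags <- seq_len(floor(n / 2))
  if (!is.null(max_lag)) lags <- lags[lags <= max_lag]
  msd <- vapply(lags, function(tau) {
    dx <- traj$x[(tau + 1):n] - traj$x[1:(n - tau)]
    dy <- traj$y[(tau + 1):n] - traj$y[1:(n - tau)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = lags, tau_s = lags * dt, msd = msd)
}

#' Estimate a diffusion coefficient from a trajectory
#'
#' Ordinary least squares through the first `n_points_fit` MSD lags with a
#' free intercept; in 2-D, `D = slope / 4`. The free intercept absorbs the
#' static localization error (expected intercept `4 * sigma_loc^2`), so
#' the error magnitude need not be known. Slopes that come out
#' non-positive are floored at `D = 1e-6` um^2/s and flagged.
#'
#' @param traj A `trajectory` of at least `2 * n_points_fit` frames.
#' @param n_points_fit Number of MSD lags in the fit (>= 2).
#' @return A `diffusion_estimate`: list with `D` (um^2/s),
#'   `intercept` (um^2), `msd` (the fitted lags), `n_points_fit`,
#'   `n_frames`, `flagged`; or `NULL` (a skip signal) when the track is
#'   too short.
#' @export
estimate_diffusion <- function(traj, n_points_fit = 4) {
  stopifnot(inherits(traj, "trajectory"), n_points_fit >= 2)
  if (floor(nrow(traj) / 2) < n_points_fit) return(NULL)
  m <- compute_msd(traj, max_lag = n_points_fit)
  fit <- stats::lm.fit(cbind(1, m$tau_s), m$msd)
  slope_nm2 <- fit$coefficients[2]
  flagged <- !is.finite(slope_nm2) || slope_nm2 <= 0
  D <- if (flagged) 1e-6 else slope_nm2 / 4 / 1e6 # nm^2/s -> um^2/s
  structure(
    list(D = unname(D), intercept = unname(fit$coefficients[1]) / 1e6,
         msd = m, n_points_fit = as.integer(n_points_fit),
         n_frames = nrow(traj), flagged = flagged),
    class = "diffusion_estimate"
  )
}

#' Diffusion estimates for a list of trajectories
#'
#' @param tracks A list of `trajectory` objects.
#' @param n_points_fit Passed to [estimate_diffusion()].
#' @return A data frame with one row per usable track: `track`,
#'   `D_um2_per_s`, `intercept_um2`, `n_frames`, `flagged`.
#' @export
estimate_diffusion_tracks <- function(tracks, n_points_fit = 4) {
  rows <- lapply(seq_along(tracks), function(i) {
    est <- estimate_diffusion(tracks[[i]], n_points_fit)
    if (is.null(est)) return(NULL)
    data.frame(track = i, D_um2_per_s = est$D,
               intercept_um2 = est$intercept,
               n_frames = est$n_frames, flagged = est$flagged)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(track = integer(0), D_um2_per_s = numeric(0),
                      intercept_um2 = numeric(0), n_frames = integer(0),
                      flagged = logical(0))
  }
  out
}

#' Population summary of diffusion estimates
#'
#' @param estimates A numeric vector of per-track diffusion coefficients,
#'   or the data frame returned by [estimate_diffusion_tracks()].
#' @param n_bins Number of log-spaced bins of the cumulative curve.
#' @return A list with `median_D` (um^2/s) and `cdf` (data frame `D`,
#'   `cumulative_probability`; monotone non-decreasing, ending at 1).
#' @export
population_summary <- function(estimates, n_bins = 50) {
  D <- if (is.data.frame(estimates)) estimates$D_um2_per_s
       else as.numeric(estimates)
  if (length(D) == 0L) stop("need at least one estimate", call. = FALSE)
  lo <- max(min(D), 1e-7)
  hi <- max(D)
  grid <- if (hi > lo) 10^seq(log10(lo), log10(hi), length.out = n_bins)
          else hi
  cdf <- vapply(grid, function(g) mean(D <= g), numeric(1))
  cdf[length(cdf)] <- 1
  list(median_D = stats::median(D),
       cdf = data.frame(D = grid, cumulative_probability = cdf))
}
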