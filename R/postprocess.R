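#' Post-processing filter parameters
#'
#' Defaults follow common dSTORM practice for membrane-receptor imaging:
#' localizations with uncertainty above 20 nm are discarded, a localization
#' needs at least two neighbors within 50 nm to survive the density filter,
#' and re-appearances of a molecule within 20 nm in consecutive frames are
#' merged.
#'
#' @param duplicate_radius `"uncertainty"` (pair radius = the larger of the
#'   two uncertainties) or a fixed radius in nm, for same-frame duplicate
#'   removal.
#' @param max_uncertainty Uncertainty cutoff in nm; rows strictly above it
#'   are eliminated (the boundary value is kept).
#' @param density_radius Neighborhood radius of the density filter, nm
#'   (closed ball).
#' @param density_min_neighbors Minimum number of neighbors (self excluded).
#' @param merge_radius Linking radius of blink merging, nm.
#' @param merge_max_gap_frames Maximum number of dark frames a merged chain
#'   may skip; 0 links consecutive frames only.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(duplicate_radius = "uncertainty",
                          max_uncertainty = 20,
                          density_radius = 50,
                          density_min_neighbors = 2,
                          merge_radius = 20,
                          merge_max_gap_frames = 0) {
  if (!identical(duplicate_radius, "uncertainty")) {
    stopifnot(is.numeric(duplicate_radius), duplicate_radius > 0)
  }
  stopifnot(max_uncertainty > 0, density_radius > 0,
            density_min_neighbors >= 1, merge_radius > 0,
            merge_max_gap_frames >= 0)
  structure(
    list(duplicate_radius = duplicate_radius,
         max_uncertainty = max_uncertainty,
         density_radius = density_radius,
         density_min_neighbors = as.integer(density_min_neighbors),
         merge_radius = merge_radius,
         merge_max_gap_frames = as.integer(merge_max_gap_frames)),
    class = "filter_params"
  )
}

# Split a table into the rows the filters act on and the fiducial rows that
# pass through untouched (they are still needed for drift estimation).
.split_fiducials <- function(table) {
  fid <- table$is_fiducial
  list(data = table[!fid, , drop = FALSE], fid = table[fid, , drop = FALSE])
}

#' Remove same-frame duplicate localizations
#'
#' Multi-emitter fitting can report one molecule several times in a single
#' frame. Within each frame and channel, localizations closer than the
#' duplicate radius (in `"uncertainty"` mode, the larger of the pair's
#' uncertainties) are grouped transitively and each group is replaced by
#' its member with the smallest uncertainty (ties broken by lowest id);
#' duplicate removal is a removal step, not an averaging step. Fiducial
#' rows are untouched.
#'
#' @param table A localization table.
#' @param params A [filter_params()].
#' @return The deduplicated table.
#' @export
remove_duplicates <- function(table, params = filter_params()) {
  table <- .validate_loc_table(table)
  if (nrow(table) == 0L) return(table)
  parts <- .split_fiducials(table)
  d <- parts$data
  keep <- logical(nrow(d))
  for (key in split(seq_len(nrow(d)), list(d$frame, d$channel), drop = TRUE)) {
    if (length(key) == 1L) {
      keep[key] <- TRUE
      next
    }
    dx <- outer(d$x[key], d$x[key], "-")
    dy <- outer(d$y[key], d$y[key], "-")
    dist <- sqrt(dx^2 + dy^2)
    if (identical(params$duplicate_radius, "uncertainty")) {
      rad <- outer(d$uncertainty[key], d$uncertainty[key], pmax)
    } else {
      rad <- params$duplicate_radius
    }
    adj <- dist < rad
    diag(adj) <- TRUE
    comp <- .components(adj)
    for (c_id in unique(comp)) {
      members <- key[comp == c_id]
      best <- members[order(d$uncertainty[members], d$id[members])][1]
      keep[best] <- TRUE
    }
  }
  out <- rbind(d[keep, , drop = FALSE], parts$fid)
  rownames(out) <- NULL
  .validate_loc_table(out)
}

#' Filter localizations by uncertainty
#'
#' Rows with uncertainty strictly greater than `max_uncertainty` are
#' eliminated; the boundary value is kept. Fiducial rows pass through.
#'
#' @inheritParams remove_duplicates
#' @export
filter_uncertainty <- function(table, params = filter_params()) {
  table <- .validate_loc_table(table)
  if (nrow(table) == 0L) return(table)
  drop <- !table$is_fiducial & table$uncertainty > params$max_uncertainty
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  .validate_loc_table(out)
}

#' Density filter: drop isolated localizations
#'
#' Per channel, a row is kept iff at least `density_min_neighbors` other
#' rows lie within `density_radius` (closed ball, self excluded). Counts
#' are taken on the pre-filter set in a single pass -- removals do not
#' cascade. Fiducial rows pass through.
#'
#' @inheritParams remove_duplicates
#' @export
density_filter <- function(table, params = filter_params()) {
  table <- .validate_loc_table(table)
  if (nrow(table) == 0L) return(table)
  parts <- .split_fiducials(table)
  d <- parts$data
  keep <- logical(nrow(d))
  for (idx in split(seq_len(nrow(d)), d$channel, drop = TRUE)) {
    counts <- .count_neighbors(cbind(d$x[idx], d$y[idx]),
                               params$density_radius)
    keep[idx] <- counts >= params$density_min_neighbors
  }
  out <- rbind(d[keep, , drop = FALSE], parts$fid)
  rownames(out) <- NULL
  .validate_loc_table(out)
}

#' Estimate stage drift from fiducial beads
#'
#' Fiducial rows are grouped into per-channel bead traces (each row is
#' assigned to the nearest bead seed taken from the earliest frame). Each
#' trace's displacement is measured relative to its own mean position --
#' not its noisy first observation -- the traces are averaged per frame,
#' smoothed with a centered moving average, missing frames are interpolated
#' linearly, and the path is re-zeroed at frame 0.
#'
#' @param table A localization table containing fiducial-flagged rows.
#' @param smooth_window Moving-average window in frames.
#' @param anchor_window Number of initial frames whose linear fit pins the
#'   path to (0, 0) at frame 0; a local fit averages away the reference
#'   noise that anchoring on the raw frame-0 bead positions would inject.
#' @param frames Frames the estimate must cover (default: every frame
#'   present in `table`).
#' @return A `drift_estimate`: data frame `frame`, `dx`, `dy` with
#'   attributes `n_fiducials` and `smooth_window`.
#' @export
estimate_drift <- function(table, smooth_window = 10, anchor_window = 150,
                           frames = NULL) {
  table <- .validate_loc_table(table)
  fid <- table[table$is_fiducial, , drop = FALSE]
  if (nrow(fid) == 0L) {
    stop(paste("no fiducial rows in table: fiducial markers are required",
               "(cross-correlation drift correction is not supported)"),
         call. = FALSE)
  }
  if (is.null(frames)) frames <- sort(unique(table$frame))
  traces <- list()
  for (ch in unique(fid$channel)) {
    f <- fid[fid$channel == ch, , drop = FALSE]
    seeds <- f[f$frame == min(f$frame), , drop = FALSE]
    d2 <- outer(f$x, seeds$x, "-")^2 + outer(f$y, seeds$y, "-")^2
    bead <- max.col(-d2, ties.method = "first")
    for (b in unique(bead)) {
      traces[[length(traces) + 1L]] <- f[bead == b, c("frame", "x", "y")]
    }
  }
  all_frames <- seq(min(frames), max(frames))
  acc_x <- acc_y <- matrix(NA_real_, nrow = length(all_frames),
                           ncol = length(traces))
  for (j in seq_along(traces)) {
    tr <- traces[[j]]
    agg <- stats::aggregate(cbind(x, y) ~ frame, data = tr, FUN = mean)
    row <- match(agg$frame, all_frames)
    acc_x[row, j] <- agg$x - mean(agg$x)
    acc_y[row, j] <- agg$y - mean(agg$y)
  }
  dx <- rowMeans(acc_x, na.rm = TRUE)
  dy <- rowMeans(acc_y, na.rm = TRUE)
  fill <- function(v) {
    if (anyNA(v)) {
      v <- stats::approx(all_frames[!is.na(v)], v[!is.na(v)],
                         xout = all_frames, rule = 2)$y
    }
    v
  }
  dx <- .moving_average(fill(dx), smooth_window)
  dy <- .moving_average(fill(dy), smooth_window)
  # pin frame 0 to (0, 0) via the intercept of a local linear fit, which is
  # unbiased for slowly varying drift and far less noisy than the raw
  # frame-0 value
  ref <- match(min(frames), all_frames)
  k <- min(length(all_frames), max(anchor_window, 2L))
  aw <- ref:(ref + k - 1L)
  t_rel <- all_frames[aw] - all_frames[ref]
  fit_x <- stats::lm.fit(cbind(1, t_rel), dx[aw])$coefficients[1]
  fit_y <- stats::lm.fit(cbind(1, t_rel), dy[aw])$coefficients[1]
  est <- data.frame(frame = all_frames, dx = dx - fit_x, dy = dy - fit_y)
  est$dx[ref] <- 0
  est$dy[ref] <- 0
  attr(est, "n_fiducials") <- length(traces)
  attr(est, "smooth_window") <- smooth_window
  class(est) <- c("drift_estimate", "drift_path", "data.frame")
  est
}

#' Subtract a drift path from a localization table
#'
#' The inverse of [apply_drift()]: each row's coordinates minus its frame's
#' offset. Uncertainties and frames are unchanged.
#'
#' @param table A localization table.
#' @param drift A `drift_path` or `drift_estimate` covering all frames
#'   present.
#' @export
apply_drift_correction <- function(table, drift) {
  table <- .validate_loc_table(table)
  stopifnot(inherits(drift, "drift_path"))
  if (nrow(table) == 0L) return(table)
  idx <- match(table$frame, drift$frame)
  if (anyNA(idx)) {
    stop("drift estimate does not cover frame(s): ",
         paste(utils::head(sort(unique(table$frame[is.na(idx)])), 5),
               collapse = ", "),
         call. = FALSE)
  }
  table$x <- table$x - drift$dx[idx]
  table$y <- table$y - drift$dy[idx]
  table
}

#' Merge repeated blinks of a molecule across frames
#'
#' Localizations of the same channel appearing within `merge_radius` of an
#' active chain's running centroid in consecutive frames (or within
#' `merge_max_gap_frames` dark frames) are linked greedily in frame order.
#' Each chain is replaced by a single record at the inverse-variance
#' (1/sigma^2) weighted mean position, with combined uncertainty
#' `1/sigma_c^2 = sum(1/sigma_i^2)`, the chain's first frame, and summed
#' intensity. Fiducial rows pass through.
#'
#' @inheritParams remove_duplicates
#' @export
merge_blinks <- function(table, params = filter_params()) {
  table <- .validate_loc_table(table)
  if (nrow(table) == 0L) return(table)
  parts <- .split_fiducials(table)
  d <- parts$data
  merged <- list()
  for (idx in split(seq_len(nrow(d)), d$channel, drop = TRUE)) {
    sub <- d[idx, , drop = FALSE]
    sub <- sub[order(sub$frame, sub$id), , drop = FALSE]
    # active chains: running inverse-variance sums
    ch_x <- ch_y <- ch_w <- ch_int <- numeric(0)
    ch_last <- ch_first <- integer(0)
    ch_mol <- integer(0)
    ch_n <- integer(0)
    done <- list()
    close_chain <- function(j) {
      done[[length(done) + 1L]] <<- data.frame(
        frame = ch_first[j], x = ch_x[j] / ch_w[j], y = ch_y[j] / ch_w[j],
        uncertainty = 1 / sqrt(ch_w[j]), intensity = ch_int[j],
        channel = sub$channel[1], is_fiducial = FALSE,
        molecule_id = ch_mol[j]
      )
    }
    max_diff <- 1L + params$merge_max_gap_frames
    for (i in seq_len(nrow(sub))) {
      f <- sub$frame[i]
      # finalize chains that can no longer be extended
      expired <- which(f - ch_last > max_diff)
      if (length(expired)) {
        for (j in expired) close_chain(j)
        keep <- setdiff(seq_along(ch_w), expired)
        ch_x <- ch_x[keep]; ch_y <- ch_y[keep]; ch_w <- ch_w[keep]
        ch_int <- ch_int[keep]; ch_last <- ch_last[keep]
        ch_first <- ch_first[keep]; ch_mol <- ch_mol[keep]; ch_n <- ch_n[keep]
      }
      w_i <- 1 / max(sub$uncertainty[i], 1e-9)^2
      target <- NA_integer_
      if (length(ch_w)) {
        open <- which(ch_last < f & f - ch_last <= max_diff)
        if (length(open)) {
          dd <- sqrt((ch_x[open] / ch_w[open] - sub$x[i])^2 +
                     (ch_y[open] / ch_w[open] - sub$y[i])^2)
          ok <- which(dd <= params$merge_radius)
          if (length(ok)) target <- open[ok[which.min(dd[ok])]]
        }
      }
      if (is.na(target)) {
        ch_x <- c(ch_x, sub$x[i] * w_i); ch_y <- c(ch_y, sub$y[i] * w_i)
        ch_w <- c(ch_w, w_i)
        ch_int <- c(ch_int, ifelse(is.na(sub$intensity[i]), 0,
                                   sub$intensity[i]))
        ch_last <- c(ch_last, f); ch_first <- c(ch_first, f)
        ch_mol <- c(ch_mol, sub$molecule_id[i]); ch_n <- c(ch_n, 1L)
      } else {
        ch_x[target] <- ch_x[target] + sub$x[i] * w_i
        ch_y[target] <- ch_y[target] + sub$y[i] * w_i
        ch_w[target] <- ch_w[target] + w_i
        ch_int[target] <- ch_int[target] +
          ifelse(is.na(sub$intensity[i]), 0, sub$intensity[i])
        ch_last[target] <- f
        ch_n[target] <- ch_n[target] + 1L
      }
    }
    for (j in seq_along(ch_w)) close_chain(j)
    merged[[length(merged) + 1L]] <- do.call(rbind, done)
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$frame), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  if (nrow(parts$fid)) out <- .bind_loc_tables(out, parts$fid)
  rownames(out) <- NULL
  .validate_loc_table(out)
}

#' Fit a polynomial channel registration from fiducial beads
#'
#' Beads are collapsed to per-bead centroids in each channel (grouping as
#' in [estimate_drift()]), matched moving-to-fixed by nearest centroid, and
#' a least-squares bivariate polynomial `moving -> fixed` of the requested
#' degree is fitted per axis. Inputs may be localization tables (fiducial
#' rows are used; all rows if none are flagged) or plain data frames /
#' matrices of centroid coordinates.
#'
#' @param fiducials_moving,fiducials_fixed Bead localizations (or centroid
#'   coordinates) of the channel to be transformed and of the reference
#'   channel.
#' @param degree Polynomial degree, 1 (affine) or 2.
#' @return A `poly_transform`: list with `degree`, `coef_x`, `coef_y`,
#'   `rms_residual` (nm) and `n_fiducials`.
#' @export
fit_registration <- function(fiducials_moving, fiducials_fixed, degree = 1) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("'degree' must be 1 or 2", call. = FALSE)
  mov <- .bead_centroids(fiducials_moving)
  fix <- .bead_centroids(fiducials_fixed)
  need <- .n_poly_terms(degree)
  if (nrow(mov) < need || nrow(fix) < need) {
    stop(sprintf("registration of degree %d needs >= %d matched fiducials",
                 degree, need), call. = FALSE)
  }
  # match each moving bead to its nearest fixed bead
  d2 <- outer(mov[, 1], fix[, 1], "-")^2 + outer(mov[, 2], fix[, 2], "-")^2
  match_idx <- max.col(-d2, ties.method = "first")
  fx <- fix[match_idx, 1]
  fy <- fix[match_idx, 2]
  basis <- .poly_basis(mov[, 1], mov[, 2], degree)
  qrb <- qr(basis)
  if (qrb$rank < ncol(basis)) {
    stop("fiducial geometry is degenerate (e.g. collinear beads) for the ",
         "requested degree", call. = FALSE)
  }
  coef_x <- qr.coef(qrb, fx)
  coef_y <- qr.coef(qrb, fy)
  res <- cbind(fx - basis %*% coef_x, fy - basis %*% coef_y)
  structure(
    list(degree = degree, coef_x = as.numeric(coef_x),
         coef_y = as.numeric(coef_y),
         rms_residual = sqrt(mean(res^2)),
         n_fiducials = nrow(mov)),
    class = "poly_transform"
  )
}

# Per-bead centroids of a set of fiducial localizations (any channel mix
# collapses per channel caller-side).
.bead_centroids <- function(obj) {
  if (is.matrix(obj)) return(cbind(obj[, 1], obj[, 2]))
  stopifnot(is.data.frame(obj))
  if ("is_fiducial" %in% names(obj) && any(obj$is_fiducial)) {
    obj <- obj[obj$is_fiducial, , drop = FALSE]
  }
  xy <- .as_xy(obj)
  if (!"frame" %in% names(obj) || length(unique(obj$frame)) == 1L) {
    return(xy)
  }
  seeds <- xy[obj$frame == min(obj$frame), , drop = FALSE]
  d2 <- outer(xy[, 1], seeds[, 1], "-")^2 + outer(xy[, 2], seeds[, 2], "-")^2
  bead <- max.col(-d2, ties.method = "first")
  t(sapply(sort(unique(bead)), function(b) colMeans(xy[bead == b, , drop = FALSE])))
}

#' Apply a fitted registration to one channel
#'
#' @param table A localization table.
#' @param transform A `poly_transform` from [fit_registration()].
#' @param channel Channel whose coordinates are transformed; other channels
#'   are untouched. Unknown channel is an error.
#' @export
apply_registration <- function(table, transform, channel) {
  stopifnot(inherits(transform, "poly_transform"))
  warp <- channel_warp(transform$coef_x, transform$coef_y, transform$degree)
  apply_channel_warp(table, warp, channel)
}

#' Run the full post-processing chain
#'
#' Executes, in order: channel registration (when a transform is given),
#' then (1) same-frame duplicate removal, (2) uncertainty filtering,
#' (3) density filtering, (4) drift correction (using `drift` when given,
#' otherwise estimated from fiducial rows when present), and (5) blink
#' merging. Per-step row counts are logged to stderr as
#' `step=<name> rows_in=<n> rows_out=<m>` and kept in the `"log"`
#' attribute of the result.
#'
#' @param table A localization table.
#' @param params A [filter_params()].
#' @param drift Optional drift path to subtract; `NULL` estimates one from
#'   fiducials (or skips step 4 when the table has none).
#' @param transform Optional `poly_transform` applied to `register_channel`
#'   before step 1.
#' @param register_channel Channel the registration maps onto the
#'   reference channel (default `"488"`).
#' @param drop_fiducials Remove fiducial rows from the final table.
#' @param verbose Emit per-step log lines via [message()].
#' @return The processed table with a `"log"` attribute (data frame of
#'   `step`, `rows_in`, `rows_out`).
#' @export
run_postprocess <- function(table, params = filter_params(), drift = NULL,
                            transform = NULL, register_channel = "488",
                            drop_fiducials = TRUE, verbose = TRUE) {
  table <- .validate_loc_table(table)
  log <- data.frame(step = character(0), rows_in = integer(0),
                    rows_out = integer(0))
  note <- function(step, nin, nout) {
    if (verbose) message(sprintf("step=%s rows_in=%d rows_out=%d",
                                 step, nin, nout))
    log[nrow(log) + 1L, ] <<- list(step, nin, nout)
  }
  if (!is.null(transform)) {
    n0 <- nrow(table)
    table <- apply_registration(table, transform, register_channel)
    note("registration", n0, nrow(table))
  }
  n0 <- nrow(table); table <- remove_duplicates(table, params)
  note("remove_duplicates", n0, nrow(table))
  n0 <- nrow(table); table <- filter_uncertainty(table, params)
  note("filter_uncertainty", n0, nrow(table))
  n0 <- nrow(table); table <- density_filter(table, params)
  note("density_filter", n0, nrow(table))
  if (is.null(drift) && any(table$is_fiducial)) {
    drift <- estimate_drift(table)
  }
  if (!is.null(drift)) {
    n0 <- nrow(table); table <- apply_drift_correction(table, drift)
    note("drift_correction", n0, nrow(table))
  } else {
    note("drift_correction_skipped", nrow(table), nrow(table))
  }
  n0 <- nrow(table); table <- merge_blinks(table, params)
  note("merge_blinks", n0, nrow(table))
  if (drop_fiducials && any(table$is_fiducial)) {
    n0 <- nrow(table)
    table <- table[!table$is_fiducial, , drop = FALSE]
    rownames(table) <- NULL
    table <- .validate_loc_table(table)
    note("drop_fiducials", n0, nrow(table))
  }
  attr(table, "log") <- log
  table
}
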