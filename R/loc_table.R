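#' Construct a localization table
#'
#' The localization table is the pipeline's lingua franca: one row per
#' detected blink with its frame, coordinates (nm), localization
#' uncertainty (nm), photon count, channel label, fiducial flag, and --
#' for synthetic data -- the ground-truth molecule identity.
#'
#' @param frame Integer frame indices (0-based, >= 0).
#' @param x,y Coordinates in nm (finite).
#' @param uncertainty Per-blink localization uncertainty in nm (>= 0).
#' @param intensity Photon counts (optional; `NA` when unknown).
#' @param channel Channel labels (free strings such as `"647"`, `"488"`).
#' @param is_fiducial Logical fiducial-bead flag.
#' @param molecule_id Ground-truth molecule id or `NA`.
#' @param id Unique row ids; generated when omitted.
#' @return A data frame of class `loc_table`.
#' @export
localization_table <- function(frame, x, y, uncertainty = 0,
                               intensity = NA_real_, channel = "647",
                               is_fiducial = FALSE,
                               molecule_id = NA_integer_, id = NULL) {
  n <- max(length(frame), length(x), length(y))
  df <- data.frame(
    id = if (is.null(id)) seq_len(n) else as.integer(id),
    frame = rep_len(as.integer(frame), n),
    x = rep_len(as.numeric(x), n),
    y = rep_len(as.numeric(y), n),
    uncertainty = rep_len(as.numeric(uncertainty), n),
    intensity = rep_len(as.numeric(intensity), n),
    channel = rep_len(as.character(channel), n),
    is_fiducial = rep_len(as.logical(is_fiducial), n),
    molecule_id = rep_len(as.integer(molecule_id), n),
    stringsAsFactors = FALSE
  )
  .validate_loc_table(df)
}

# Check invariants and restore the loc_table class; accepts any data frame
# holding at least the mandatory columns.
.validate_loc_table <- function(table) {
  stopifnot(is.data.frame(table))
  needed <- c("frame", "x", "y")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"id" %in% names(table)) table$id <- seq_len(nrow(table))
  if (!"uncertainty" %in% names(table)) table$uncertainty <- 0
  if (!"intensity" %in% names(table)) table$intensity <- NA_real_
  if (!"channel" %in% names(table)) table$channel <- "647"
  if (!"is_fiducial" %in% names(table)) table$is_fiducial <- FALSE
  if (!"molecule_id" %in% names(table)) table$molecule_id <- NA_integer_
  if (nrow(table)) {
    if (anyDuplicated(table$id)) stop("row ids must be unique", call. = FALSE)
    if (any(table$frame < 0)) stop("frames must be >= 0", call. = FALSE)
    if (any(!is.finite(table$x)) || any(!is.finite(table$y))) {
      stop("coordinates must be finite", call. = FALSE)
    }
    if (any(table$uncertainty < 0, na.rm = TRUE)) {
      stop("uncertainties must be >= 0", call. = FALSE)
    }
  }
  if (!inherits(table, "loc_table")) {
    class(table) <- c("loc_table", class(table))
  }
  table
}

# rbind two loc tables, renumbering ids to stay unique.
.bind_loc_tables <- function(a, b) {
  cols <- c("id", "frame", "x", "y", "uncertainty", "intensity", "channel",
            "is_fiducial", "molecule_id")
  out <- rbind(as.data.frame(a)[cols], as.data.frame(b)[cols])
  out$id <- seq_len(nrow(out))
  .validate_loc_table(out)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf(
    "<loc_table> %d localizations, %d frame(s), channel(s): %s%s\n",
    nrow(x), length(unique(x$frame)),
    paste(unique(x$channel), collapse = ", "),
    if (any(x$is_fiducial)) sprintf(" (%d fiducial rows)", sum(x$is_fiducial))
    else ""
  ))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# ThunderSTORM-dialect header mapping: file header token -> internal column.
.ts_dialect <- c(
  "id" = "id",
  "frame" = "frame",
  "x [nm]" = "x",
  "y [nm]" = "y",
  "uncertainty [nm]" = "uncertainty",
  "uncertainty_xy [nm]" = "uncertainty",
  "intensity [photon]" = "intensity",
  "channel" = "channel",
  "is_fiducial" = "is_fiducial",
  "molecule_id" = "molecule_id"
)

#' Read a localization table from a ThunderSTORM-style CSV
#'
#' Columns are mapped by header name; the dialect accepts the tokens
#' `"frame"`, `"x [nm]"`, `"y [nm]"`, `"uncertainty [nm]"`, optionally
#' `"intensity [photon]"`, plus the artifact columns `"channel"`,
#' `"is_fiducial"` and `"molecule_id"`. Unknown extra columns are kept
#' verbatim. A file lacking frame/x/y raises a format error naming the
#' missing column; a non-numeric cell raises a parse error with its row
#' number.
#'
#' @param path Path to an existing CSV file.
#' @return A `loc_table`.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  known <- names(.ts_dialect)[names(.ts_dialect) %in% names(raw)]
  need <- c("frame", "x [nm]", "y [nm]")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("localization file is missing required column(s): ",
         paste(sprintf("'%s'", miss), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (tok in known) {
    col <- .ts_dialect[[tok]]
    v <- raw[[tok]]
    if (col %in% c("frame", "x", "y", "uncertainty", "intensity",
                   "molecule_id")) {
      blank <- is.na(v) | v == ""
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!blank & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                     v[bad[1]], tok, bad[1]), call. = FALSE)
      }
      out[[col]] <- if (col %in% c("frame", "molecule_id")) as.integer(num)
                    else num
    } else if (col == "is_fiducial") {
      out[[col]] <- as.logical(v)
    } else {
      out[[col]] <- v
    }
  }
  extra <- setdiff(names(raw), names(.ts_dialect))
  for (tok in extra) out[[tok]] <- raw[[tok]]
  .validate_loc_table(out)
}

#' Write a localization table as ThunderSTORM-style CSV
#'
#' Column order is fixed and nm values are written with two decimals (well
#' below localization uncertainty), so two writes of the same table are
#' byte-identical and files diff cleanly.
#'
#' @param table A localization table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_localizations <- function(table, path) {
  table <- .validate_loc_table(table)
  fmt2 <- function(v) ifelse(is.na(v), "", sprintf("%.2f", v))
  df <- data.frame(
    "id" = table$id,
    "frame" = table$frame,
    "x [nm]" = fmt2(table$x),
    "y [nm]" = fmt2(table$y),
    "uncertainty [nm]" = fmt2(table$uncertainty),
    "intensity [photon]" = fmt2(table$intensity),
    "channel" = table$channel,
    "is_fiducial" = table$is_fiducial,
    "molecule_id" = ifelse(is.na(table$molecule_id), "",
                           as.character(table$molecule_id)),
    check.names = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Select a centered square region of interest
#'
#' Determinizes the "square ROI in the middle of the cell" step: the ROI is
#' the square of side `roi_size` centered on the centroid of the
#' non-fiducial localizations. Because the centroid of the retained subset
#' can differ slightly from the centroid of the full table, the centering
#' is iterated to a fixed point (centroid of the rows currently inside the
#' box becomes the new box center) so that re-selecting from the returned
#' table reproduces it exactly. A manual `center` overrides the automatic
#' placement.
#'
#' @param table A nonempty localization table.
#' @param roi_size ROI side length in nm (default 3000, i.e. 3 x 3 um).
#' @param center Optional `c(x, y)` center in table coordinates; skips the
#'   centroid iteration.
#' @param max_iter Cap on centroid iterations.
#' @return A list with `table` (rows inside the half-open ROI, coordinates
#'   re-expressed relative to the ROI origin), `region` (the origin-based
#'   [region()] to use in downstream statistics), and `center` (the ROI
#'   center in the original coordinates).
#' @export
select_center_roi <- function(table, roi_size = 3000, center = NULL,
                              max_iter = 100L) {
  table <- .validate_loc_table(table)
  if (nrow(table) == 0L) stop("cannot place an ROI on an empty table",
                              call. = FALSE)
  half <- roi_size / 2
  pts <- table[!table$is_fiducial, , drop = FALSE]
  if (nrow(pts) == 0L) pts <- table
  if (is.null(center)) {
    center <- c(mean(pts$x), mean(pts$y))
    prev_keep <- NULL
    for (i in seq_len(max_iter)) {
      keep <- which(pts$x >= center[1] - half & pts$x < center[1] + half &
                    pts$y >= center[2] - half & pts$y < center[2] + half)
      if (length(keep) == 0L) break
      if (!is.null(prev_keep) && identical(keep, prev_keep)) break
      prev_keep <- keep
      center <- c(mean(pts$x[keep]), mean(pts$y[keep]))
    }
  }
  roi <- region(center[1] - half, center[2] - half, roi_size, roi_size)
  inside <- in_region(roi, table$x, table$y)
  out <- table[inside, , drop = FALSE]
  out$x <- out$x - roi$x0
  out$y <- out$y - roi$y0
  rownames(out) <- NULL
  list(table = .validate_loc_table(out),
       region = region(0, 0, roi_size, roi_size),
       center = center)
}
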