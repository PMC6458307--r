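#' Build a pipeline scenario configuration
#'
#' A scenario bundles every parameter of the simulate -> post-process ->
#' analyze chain. Values default to the standard analysis settings
#' (20 nm uncertainty cutoff, 2 neighbors in 50 nm, 20 nm merge radius,
#' 3 x 3 um ROI, 80 nm CBC search radius, 20 frames/s tracking); the
#' synthetic-field defaults emulate a nanoclustered receptor pair on a
#' cell-sized membrane patch. Any entry can be overridden by name.
#'
#' @param scenario Scenario name (used in file names).
#' @param seed Integer master seed; every stochastic stage derives its own
#'   child seed from it, so a config file alone regenerates every output.
#' @param ... Named overrides of the default entries (unknown names are an
#'   error).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "baseline", seed = 1, ...) {
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    n_replicates = 1L,
    # simulation field (nm)
    sim_width = 4000, sim_height = 4000,
    # species A (reference channel, "647")
    a_n_clusters = 60, a_molecules_per_cluster = 30,
    a_cluster_sigma = 60, a_background_fraction = 0.2,
    # species B ("488") and its coupling to A
    b_n_clusters = 60, b_molecules_per_cluster = 25,
    b_cluster_sigma = 60, b_background_fraction = 0.3,
    coupling_fraction = 0.2, coupling_jitter = 20,
    # blinking / acquisition
    mean_blinks = 3, loc_sigma_mean = 8, loc_sigma_spread = 3,
    n_frames = 2000L,
    # drift, fiducials, channel misalignment
    drift_step_sd = 0.1, n_fiducials = 3L, fiducial_sigma = 2,
    warp_dx = 30, warp_dy = -10,
    # post-processing
    max_uncertainty = 20, density_radius = 50, density_min_neighbors = 2L,
    merge_radius = 20, merge_max_gap_frames = 0L,
    registration_degree = 1L,
    # analysis
    roi_size = 3000,
    hopkins_m = 100L, hopkins_iterations = 100L,
    ripley_r_max = 500, ripley_n_r = 50,
    dbscan_eps = 50, dbscan_min_pts = 10L,
    getis_d = 50, getis_n_null = 50L,
    cbc_r_max = 80, cbc_n_bins = 10L,
    # single-particle tracking
    spt_D_true = 0.02, spt_dt = 0.05, spt_n_steps = 200L,
    spt_loc_error = 20, spt_n_tracks = 60L,
    spt_region_size = 10000, # sparse labeling over a cell-scale field
    spt_max_disp = 500, spt_min_length = 10L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a scenario configuration file
#'
#' Scenario files are flat YAML key-value mappings; the round trip through
#' file is lossless, so a config file alone suffices to regenerate a run.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns the path invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(vals[c("scenario", "seed")],
            vals[setdiff(names(vals), c("scenario", "seed"))]))
}

# One simulated + analyzed replicate; returns the summary rows.
.run_replicate <- function(cfg, seed, out_dir, write_tables = TRUE,
                           verbose = FALSE) {
  sim_region <- region(0, 0, cfg$sim_width, cfg$sim_height)
  field_a <- generate_cluster_field(
    sim_region,
    cluster_field_params(cfg$a_n_clusters, cfg$a_molecules_per_cluster,
                         cfg$a_cluster_sigma, cfg$a_background_fraction),
    seed = .child_seed(seed, 1), species = "647")
  field_b <- couple_fields(
    field_a,
    cluster_field_params(cfg$b_n_clusters, cfg$b_molecules_per_cluster,
                         cfg$b_cluster_sigma, cfg$b_background_fraction),
    coupling_fraction = cfg$coupling_fraction,
    coupling_jitter = cfg$coupling_jitter,
    seed = .child_seed(seed, 2), species = "488")
  blink <- blink_model(cfg$mean_blinks, cfg$loc_sigma_mean,
                       cfg$loc_sigma_spread, cfg$n_frames)
  tab <- .bind_loc_tables(
    simulate_localizations(field_a, blink, seed = .child_seed(seed, 3)),
    simulate_localizations(field_b, blink, seed = .child_seed(seed, 4)))
  tab <- add_fiducials(tab, sim_region, cfg$n_fiducials, cfg$n_frames,
                       cfg$fiducial_sigma, seed = .child_seed(seed, 5))
  warp <- channel_warp(c(cfg$warp_dx, 1, 0), c(cfg$warp_dy, 0, 1), 1)
  tab <- apply_channel_warp(tab, warp, "488")
  drift <- drift_path_random_walk(cfg$n_frames, cfg$drift_step_sd,
                                  seed = .child_seed(seed, 6))
  tab <- apply_drift(tab, drift)
  if (write_tables) {
    write_emitter_field(field_a, file.path(out_dir, "ground_truth_647.csv"))
    write_emitter_field(field_b, file.path(out_dir, "ground_truth_488.csv"))
    write_localizations(tab, file.path(out_dir, "localizations_raw.csv"))
  }
  # post-process: register 488 onto 647 using fiducials, then steps 1-5
  fid <- tab[tab$is_fiducial, , drop = FALSE]
  transform <- fit_registration(fid[fid$channel == "488", , drop = FALSE],
                                fid[fid$channel == "647", , drop = FALSE],
                                degree = cfg$registration_degree)
  params <- filter_params(max_uncertainty = cfg$max_uncertainty,
                          density_radius = cfg$density_radius,
                          density_min_neighbors = cfg$density_min_neighbors,
                          merge_radius = cfg$merge_radius,
                          merge_max_gap_frames = cfg$merge_max_gap_frames)
  clean <- run_postprocess(tab, params, transform = transform,
                           register_channel = "488", verbose = verbose)
  if (write_tables) {
    write_localizations(clean, file.path(out_dir, "localizations_clean.csv"))
  }
  roi <- select_center_roi(clean, cfg$roi_size)
  stats_rows <- list()
  add_row <- function(statistic, channel, value) {
    stats_rows[[length(stats_rows) + 1L]] <<-
      data.frame(statistic = statistic, channel = channel, value = value)
  }
  pts <- list(
    "647" = roi$table[roi$table$channel == "647", c("x", "y")],
    "488" = roi$table[roi$table$channel == "488", c("x", "y")]
  )
  for (ch in names(pts)) {
    p <- pts[[ch]]
    if (nrow(p) < 2L * cfg$hopkins_m) next
    hop <- hopkins_index(p, roi$region, m = cfg$hopkins_m,
                         n_iterations = cfg$hopkins_iterations,
                         seed = .child_seed(seed, 10))
    add_row("hopkins", ch, hop$value)
    rip <- ripley_curve(p, roi$region, r_max = cfg$ripley_r_max,
                        n_r = cfg$ripley_n_r)
    add_row("ripley_h_peak_height", ch, rip$peak_height)
    add_row("ripley_h_peak_radius", ch, rip$peak_radius)
    db <- dbscan_clusters(p, eps = cfg$dbscan_eps,
                          min_pts = cfg$dbscan_min_pts)
    add_row("dbscan_mean_density", ch,
            suppressWarnings(mean_cluster_density(db)))
    get <- getis_clusters(p, roi$region, d = cfg$getis_d,
                          n_null = cfg$getis_n_null,
                          seed = .child_seed(seed, 11))
    add_row("getis_mean_diameter", ch, get$mean_diameter)
  }
  cbc_ab <- cbc_values(pts[["647"]], pts[["488"]],
                       r_max = cfg$cbc_r_max, n_bins = cfg$cbc_n_bins)
  cbc_ba <- cbc_values(pts[["488"]], pts[["647"]],
                       r_max = cfg$cbc_r_max, n_bins = cfg$cbc_n_bins)
  add_row("cbc_median", "647vs488", cbc_ab$median)
  add_row("cbc_median", "488vs647", cbc_ba$median)
  # SPT is a separate acquisition mode; simulated per replicate
  tracks_true <- simulate_brownian_tracks(
    brownian_params(cfg$spt_D_true, cfg$spt_dt, cfg$spt_n_steps,
                    cfg$spt_loc_error),
    n_tracks = cfg$spt_n_tracks, seed = .child_seed(seed, 12),
    region = region(0, 0, cfg$spt_region_size, cfg$spt_region_size))
  linked <- link_tracks(tracks_to_detections(tracks_true),
                        max_disp = cfg$spt_max_disp,
                        min_length = cfg$spt_min_length, dt = cfg$spt_dt)
  est <- estimate_diffusion_tracks(linked)
  add_row("spt_median_D", "tracking", population_summary(est)$median_D)
  add_row("spt_n_tracks", "tracking", nrow(est))
  do.call(rbind, stats_rows)
}

#' Run a scenario end-to-end
#'
#' Simulates the configured two-color field, post-processes the blinking
#' localization table, selects the central ROI and computes the full
#' statistic panel (Hopkins, Ripley H peak, DBSCAN mean density, Getis
#' mean diameter, CBC medians in both directions, SPT median diffusion
#' coefficient), optionally over several replicates with derived seeds.
#' All tables and the summary are written under `out_dir`; the same config
#' and seed give byte-identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `config$seed`.
#' @param verbose Log post-processing row counts.
#' @return A `scenario_report`: list with `scenario`, `seed`, `summary`
#'   (data frame `replicate`, `statistic`, `channel`, `value`) and
#'   `out_dir`.
#' @export
run_scenario <- function(config, out_dir = tempfile("scenario_"),
                         seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    rep_dir <- if (config$n_replicates > 1L) {
      d <- file.path(out_dir, sprintf("replicate_%02d", r))
      dir.create(d, showWarnings = FALSE)
      d
    } else out_dir
    rows <- .run_replicate(config, .child_seed(config$seed, 100 + r),
                           rep_dir, verbose = verbose)
    cbind(replicate = r, rows)
  })
  summary <- do.call(rbind, reps)
  sum_path <- file.path(out_dir, "summary.csv")
  out <- summary
  out$value <- sprintf("%.6g", out$value)
  con <- file(sum_path, open = "wb")
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  structure(list(scenario = config$scenario, seed = config$seed,
                 summary = summary, out_dir = out_dir),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> '%s' (seed %d)\n", x$scenario, x$seed))
  print(x$summary)
  invisible(x)
}

#' Compare two scenario reports statistic by statistic
#'
#' Aggregates each statistic over replicates (median and interquartile
#' range) and reports per-statistic differences and ratios between the two
#' conditions. No hypothesis testing is performed.
#'
#' @param report_a,report_b `scenario_report` objects (or their `summary`
#'   data frames) holding the same set of statistics; mismatched
#'   statistics are an error listing the asymmetric keys.
#' @return A data frame with one row per (statistic, channel):
#'   `median_a`, `iqr_a`, `median_b`, `iqr_b`, `difference` (b - a),
#'   `ratio` (b / a).
#' @export
compare_conditions <- function(report_a, report_b) {
  get_summary <- function(r) {
    if (inherits(r, "scenario_report")) r$summary else r
  }
  a <- get_summary(report_a)
  b <- get_summary(report_b)
  key <- function(s) paste(s$statistic, s$channel, sep = "|")
  ka <- sort(unique(key(a)))
  kb <- sort(unique(key(b)))
  if (!identical(ka, kb)) {
    stop("reports hold different statistics: ",
         paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", "),
         call. = FALSE)
  }
  agg <- function(s) {
    sp <- split(s$value, key(s))
    data.frame(key = names(sp),
               median = vapply(sp, stats::median, numeric(1), na.rm = TRUE),
               iqr = vapply(sp, stats::IQR, numeric(1), na.rm = TRUE))
  }
  aa <- agg(a)
  bb <- agg(b)
  bb <- bb[match(aa$key, bb$key), ]
  parts <- do.call(rbind, strsplit(aa$key, "|", fixed = TRUE))
  out <- data.frame(
    statistic = parts[, 1], channel = parts[, 2],
    median_a = aa$median, iqr_a = aa$iqr,
    median_b = bb$median, iqr_b = bb$iqr,
    difference = bb$median - aa$median,
    ratio = bb$median / aa$median
  )
  rownames(out) <- NULL
  out
}
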