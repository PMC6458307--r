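# smlmpipe

Analysis pipeline for two-color single-molecule localization microscopy
(dSTORM) of membrane receptors — built around the question of how
receptors such as the inhibitory co-receptor CD22 and the IgM B-cell
receptor organize into nanoclusters on the cell surface, and how strongly
the two species associate.

The package takes ThunderSTORM-style localization tables (one row per
detected blink: frame, x/y in nm, uncertainty, intensity, channel) and
provides, as composable R functions:

* **Post-processing** — the standard five-step chain: same-frame duplicate
  removal, uncertainty filtering (> 20 nm eliminated), density filtering
  (≥ 2 neighbors within 50 nm), fiducial-based drift correction, and
  merging of re-appearing molecules within 20 nm; plus polynomial
  channel registration fitted on fiducial beads.
* **Cluster statistics** — Hopkins index of clustering tendency (0.5 under
  complete spatial randomness), Ripley's K/L/H with peak extraction
  (`H(r) = sqrt(K(r)/pi) − r`), DBSCAN nanocluster segmentation with
  relative cluster density (molecules per nm of cluster diameter), and a
  Getis-type local statistic with Monte-Carlo CSR thresholding.
* **Coordinate-based colocalization (CBC)** — per-localization values
  `C_i = S_i · exp(−E_i / r_max)` in [−1, +1], where `S_i` is the Spearman
  correlation of the same-species and cross-species radial density
  gradients and `E_i` the nearest cross-species distance (80 nm search
  radius by default).
* **Single-particle tracking** — mutual-nearest-neighbor track linking,
  time-averaged MSD, and per-track diffusion coefficients `D = slope/4`
  from an ordinary least-squares fit through the first four MSD lags with
  a free intercept (which absorbs localization error).
* **Synthetic data** — a ground-truth generator (Thomas cluster process
  with uniform background, cross-species coupling, geometric blinking,
  log-normal localization uncertainty, stage drift, fiducial beads,
  polynomial channel misalignment, 2-D Brownian trajectories) so that
  every stage is testable against known truth without raw image data.

## Worked example

Simulate a clustered receptor field, quantify it, and run a whole scenario
end to end:

```r
library(smlmpipe)

roi   <- region(0, 0, 3000, 3000)               # a 3 x 3 um analysis window
field <- generate_cluster_field(roi, cluster_field_params(
           n_clusters = 30, molecules_per_cluster_mean = 50,
           cluster_sigma = 60, background_fraction = 0.1), seed = 1)

hopkins_index(field, roi, seed = 2)
#> Hopkins index: 0.8632 (m = 100, 100 iterations, n = 1676)
ripley_curve(field, roi)
#> Ripley curve (toroidal correction, n = 1676): H peak 135.8 nm at r = 163.3 nm
```

A Hopkins index of 0.86 (vs. 0.5 for a random field) and an H-function
peak near 160 nm say: this field is strongly clustered, with a
characteristic nanocluster scale of roughly 160 nm.

The full pipeline — simulate two coupled channels with blinking, drift,
fiducials and channel misalignment; register, filter, merge; then compute
the statistic panel:

```r
rep <- run_scenario(pipeline_config(scenario = "baseline", seed = 7),
                    out_dir = "demo_out")
rep$summary
#>  replicate            statistic  channel        value
#>          1              hopkins      647   0.98560920
#>          1 ripley_h_peak_height      647 112.03952001
#>          1 ripley_h_peak_radius      647 153.06122449
#>          1  dbscan_mean_density      647   0.30857138
#>          1  getis_mean_diameter      647 170.20189164
#>          1              hopkins      488   0.98354656
#>          1 ripley_h_peak_height      488  78.07829813
#>          1 ripley_h_peak_radius      488 142.85714286
#>          1  dbscan_mean_density      488   0.24814995
#>          1  getis_mean_diameter      488 103.11899690
#>          1           cbc_median 647vs488   0.00000000
#>          1           cbc_median 488vs647   0.00000000
#>          1         spt_median_D tracking   0.01910327
#>          1         spt_n_tracks tracking 109.00000000
```

Reading the panel: both channels are strongly clustered (Hopkins ≈ 0.99 on
blink-level data), with H-peak radii of ~140–150 nm and a higher
nanocluster density in the 647 channel; the CBC medians sit at 0 because
the scenario's cross-species coupling is weak (20 % at 20 nm jitter), and
the recovered median diffusion coefficient, 0.019 µm²/s, matches the
simulated ground truth of 0.02 µm²/s. `demo_out/` holds the ground-truth
fields, raw and post-processed localization tables, the config, and the
summary; the same config and seed reproduce it byte for byte.

`compare_conditions(rep_a, rep_b)` tabulates per-statistic differences and
ratios between two scenarios (e.g. a baseline vs. a strongly coupled
condition).

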