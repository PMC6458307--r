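#' Coordinate-based colocalization (CBC)
#'
#' For every localization `i` of species A the radial density gradients of
#' its own species and of species B are compared. Over the bin radii
#' `r_k = k * r_max / n_bins` (`k = 1..n_bins`; the `r = 0` bin is excluded
#' because of the `1/r^2` normalization):
#'
#' \deqn{D_{AA,i}(r_k) = \frac{N_{AA,i}(r_k)}{N_{AA,i}(r_{max})}
#'       \cdot \frac{r_{max}^2}{r_k^2}}
#'
#' and `D_AB` analogously from the cross-species counts. `S_i` is the
#' Spearman rank correlation (average ranks for ties) of the two gradient
#' vectors, `E_i` the distance to the nearest B localization, and the
#' colocalization value `C_i = S_i * exp(-E_i / r_max)`, in `[-1, +1]`:
#' +1 for perfectly colocalized, -1 for perfectly segregated molecules.
#'
#' Conventions: same-species counts exclude the localization itself;
#' cross-species counts exclude zero-distance coincident points (they
#' represent the same underlying emitter, and excluding them makes the
#' identical-channel calibration return exactly +1) while `E_i` still
#' counts them, so coincidence gives the full weight `exp(0) = 1`. When a
#' gradient vector is degenerate (no same-species or no cross-species
#' neighbor within `r_max`, or a constant vector) the rank correlation is
#' undefined; such points are flagged and assigned `C_i = 0`, encoding "no
#' colocalization information".
#'
#' @param points_a Localizations of the reference species (the species the
#'   per-localization values are attributed to), as a point set in nm.
#' @param points_b Localizations of the other species.
#' @param r_max Search radius in nm (default 80, the scale of IgM
#'   nanocluster radii).
#' @param n_bins Number of radial bins (>= 3 for a meaningful rank
#'   correlation).
#' @return A `cbc_result`: list with `values` (data frame `x`, `y`, `S`,
#'   `E`, `C`, `degenerate`), `median`, `histogram` (20 bins of width 0.1
#'   on `[-1, 1]`, fractions summing to 1), and `params`. Compute the
#'   symmetric direction by swapping the arguments.
#' @export
cbc_values <- function(points_a, points_b, r_max = 80, n_bins = 10) {
  stopifnot(r_max > 0, n_bins >= 3)
  a <- .as_xy(points_a)
  b <- .as_xy(points_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both point sets must be nonempty", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  r_k <- r_max * seq_len(n_bins) / n_bins
  na <- nrow(a)
  counts_aa <- matrix(0L, na, n_bins)
  counts_ab <- matrix(0L, na, n_bins)
  E <- numeric(na)
  chunk <- max(1L, floor(2^21 / max(na, nrow(b))))
  for (start in seq(1L, na, by = chunk)) {
    idx <- start:min(start + chunk - 1L, na)
    daa <- sqrt(outer(a[idx, 1], a[, 1], "-")^2 +
                outer(a[idx, 2], a[, 2], "-")^2)
    daa[cbind(seq_along(idx), idx)] <- Inf # self excluded
    dab <- sqrt(outer(a[idx, 1], b[, 1], "-")^2 +
                outer(a[idx, 2], b[, 2], "-")^2)
    E[idx] <- apply(dab, 1, min)
    dab[dab == 0] <- Inf # coincident cross points: counted in E, not in bins
    for (k in seq_len(n_bins)) {
      counts_aa[idx, k] <- rowSums(daa <= r_k[k])
      counts_ab[idx, k] <- rowSums(dab <= r_k[k])
    }
  }
  norm <- matrix(r_max^2 / r_k^2, na, n_bins, byrow = TRUE)
  D_aa <- counts_aa / pmax(counts_aa[, n_bins], 1L) * norm
  D_ab <- counts_ab / pmax(counts_ab[, n_bins], 1L) * norm
  degenerate <- counts_aa[, n_bins] == 0L | counts_ab[, n_bins] == 0L
  S <- rep(NA_real_, na)
  ok <- which(!degenerate)
  if (length(ok)) {
    ra <- t(apply(D_aa[ok, , drop = FALSE], 1, rank))
    rb <- t(apply(D_ab[ok, , drop = FALSE], 1, rank))
    sa <- apply(ra, 1, stats::sd)
    sb <- apply(rb, 1, stats::sd)
    const <- sa == 0 | sb == 0
    degenerate[ok[const]] <- TRUE
    good <- ok[!const]
    if (length(good)) {
      ga <- ra[!const, , drop = FALSE]
      gb <- rb[!const, , drop = FALSE]
      ga <- ga - rowMeans(ga)
      gb <- gb - rowMeans(gb)
      S[good] <- rowSums(ga * gb) /
        sqrt(rowSums(ga^2) * rowSums(gb^2))
    }
  }
  C <- ifelse(degenerate, 0, S * exp(-E / r_max))
  values <- data.frame(x = a[, 1], y = a[, 2], S = S, E = E, C = C,
                       degenerate = degenerate)
  structure(
    list(values = values, median = stats::median(C),
         histogram = .cbc_histogram(C),
         params = list(r_max = r_max, n_bins = n_bins,
                       n_a = na, n_b = nrow(b))),
    class = "cbc_result"
  )
}

# 20 bins of width 0.1 on [-1, 1]; -1 falls in the first bin, +1 in the
# last.
.cbc_histogram <- function(C) {
  breaks <- seq(-1, 1, by = 0.1)
  h <- graphics::hist(pmin(pmax(C, -1), 1), breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(lower = utils::head(breaks, -1), upper = breaks[-1],
             fraction = h$counts / length(C))
}

#' Summarize a CBC result
#'
#' @param result A `cbc_result` from [cbc_values()].
#' @return A list with `median`, `histogram`, `fraction_at_plus1` (fraction
#'   in the topmost bin, `(0.9, 1]`) and `fraction_at_minus1` (fraction in
#'   the bottom bin, `[-1, -0.9]`).
#' @export
cbc_summary <- function(result) {
  stopifnot(inherits(result, "cbc_result"))
  h <- result$histogram
  list(median = result$median,
       histogram = h,
       fraction_at_plus1 = h$fraction[nrow(h)],
       fraction_at_minus1 = h$fraction[1])
}

#' @export
print.cbc_result <- function(x, ...) {
  cat(sprintf(
    "<cbc_result> %d localizations (r_max = %g nm, %d bins): median C = %.3f, %d degenerate\n",
    nrow(x$values), x$params$r_max, x$params$n_bins, x$median,
    sum(x$values$degenerate)))
  invisible(x)
}

#' @export
plot.cbc_result <- function(x, ...) {
  h <- x$histogram
  graphics::barplot(h$fraction, names.arg = sprintf("%.1f", h$upper),
                    xlab = "CBC value", ylab = "fraction of molecules", ...)
  invisible(x)
}
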