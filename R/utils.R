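# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards. seed = NULL means "use the current RNG stream".
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed, staying within the
# 32-bit integer range.
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + 7919L * k) %% .Machine$integer.max)
}

# Coerce the many point-set representations used in the package
# (2-column matrix, data.frame with x/y or x_nm/y_nm columns, emitter field,
# localization table) to a plain n x 2 matrix of nm coordinates.
.as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    return(cbind(x = as.numeric(points[, 1]), y = as.numeric(points[, 2])))
  }
  if (is.data.frame(points)) {
    xn <- intersect(c("x", "x_nm"), names(points))[1]
    yn <- intersect(c("y", "y_nm"), names(points))[1]
    if (is.na(xn) || is.na(yn)) {
      stop("point set needs x/y (or x_nm/y_nm) columns", call. = FALSE)
    }
    return(cbind(x = as.numeric(points[[xn]]), y = as.numeric(points[[yn]])))
  }
  stop("cannot interpret 'points' as a 2-D point set", call. = FALSE)
}

# Number of neighbors within `radius` (closed ball, self excluded) for each
# point, computed block-wise so large tables never materialize an n x n
# distance matrix.
.count_neighbors <- function(xy, radius, chunk = 1024L) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  counts <- integer(n)
  r2 <- radius * radius
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx2 <- outer(xy[idx, 1], xy[, 1], "-")^2
    dy2 <- outer(xy[idx, 2], xy[, 2], "-")^2
    counts[idx] <- as.integer(rowSums(dx2 + dy2 <= r2)) - 1L
  }
  counts
}

# For each query point, distance to the nearest point of `xy` (optionally
# excluding a matching index, for nearest-other-point queries).
.nearest_dist <- function(qx, qy, xy, exclude = NULL, chunk = 1024L) {
  nq <- length(qx)
  if (nrow(xy) == 0L) return(rep(Inf, nq))
  out <- numeric(nq)
  for (start in seq(1L, nq, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nq)
    d2 <- outer(qx[idx], xy[, 1], "-")^2 + outer(qy[idx], xy[, 2], "-")^2
    if (!is.null(exclude)) {
      d2[cbind(seq_along(idx), exclude[idx])] <- Inf
    }
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Connected components of an undirected adjacency matrix (logical, symmetric).
# Returns an integer component label per node, numbered by first appearance.
.components <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue) > 0L) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

# Centered moving average; near the edges the window shrinks symmetrically
# (so a linear ramp is reproduced without edge bias). `window` is the full
# width in samples.
.moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n <= 1L) return(x)
  half <- floor(window / 2)
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}
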