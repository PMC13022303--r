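#' Densify a polyline to a maximum point spacing
#'
#' Inserts interpolated points along every segment of an ordered polyline so
#' that consecutive points are at most `max_spacing` apart. Distance queries
#' against a boundary are made against the densified point set, so the
#' spacing bounds the discretisation error of a point-to-curve distance.
#'
#' @param x,y Numeric vectors of ordered vertex coordinates (pixel units).
#' @param max_spacing Maximum allowed spacing between consecutive points,
#'   in the same units as `x` and `y`. Default 0.5 px.
#' @param closed If `TRUE`, the segment from the last vertex back to the
#'   first is densified as well.
#' @return A list with numeric vectors `x` and `y`.
#' @export
densify_polyline <- function(x, y, max_spacing = 0.5, closed = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 1, max_spacing > 0)
  if (length(x) == 1L) return(list(x = x, y = y))
  if (closed) {
    x <- c(x, x[1L])
    y <- c(y, y[1L])
  }
  n <- length(x)
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  pieces_x <- vector("list", n - 1L)
  pieces_y <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    k <- max(1L, ceiling(seg_len[i] / max_spacing))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    pieces_x[[i]] <- x[i] + t * (x[i + 1L] - x[i])
    pieces_y[[i]] <- y[i] + t * (y[i + 1L] - y[i])
  }
  out_x <- c(unlist(pieces_x), x[n])
  out_y <- c(unlist(pieces_y), y[n])
  if (closed) {
    out_x <- out_x[-length(out_x)]
    out_y <- out_y[-length(out_y)]
  }
  list(x = out_x, y = out_y)
}

#' Exhaustive nearest-point distances (vectorised reference implementation)
#'
#' Pure-R all-pairs minimum Euclidean distance from each query point to a
#' reference point set, chunked to bound memory. This is the reference
#' ("oracle") path used by the synthetic-section generator to record true
#' boundary distances; the compiled kernel used by the pipeline is required
#' to agree with it exactly.
#'
#' @param px,py Query point coordinates.
#' @param qx,qy Reference point coordinates.
#' @param chunk Number of query points processed per block.
#' @return Numeric vector of minimum distances, one per query point.
#' @export
nearest_dist_exhaustive <- function(px, py, qx, qy, chunk = 2048L) {
  stopifnot(length(px) == length(py), length(qx) == length(qy))
  if (length(qx) == 0L) stop("reference point set is empty")
  n <- length(px)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx <- outer(px[idx], qx, "-")
    dy <- outer(py[idx], qy, "-")
    d2 <- dx * dx + dy * dy
    out[idx] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

# Compiled nearest-point distances; same contract as nearest_dist_exhaustive.
nearest_dist <- function(px, py, qx, qy) {
  .nearest_dist_cpp(as.numeric(px), as.numeric(py),
                    as.numeric(qx), as.numeric(qy))
}

# Ray-casting point-in-polygon test (even-odd rule), vectorised over points.
# Used to assert that apical contours face the lumen of their VZLS.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Seed-scoped RNG: run `expr` under `seed` without touching the caller's
# global RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
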