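#' Read and write rheometer force traces
#'
#' CSV with mandatory header `time_s, gap_mm, force_N`.
#'
#' @param path File path.
#' @param organoid_id Identifier attached to the trace on read.
#' @return `read_force_trace()` returns a `force_trace` data frame.
#' @export
read_force_trace <- function(path, organoid_id = basename(path)) {
  trace <- read.csv(path)
  need <- c("time_s", "gap_mm", "force_N")
  if (!all(need %in% names(trace)))
    stop("force-trace CSV must have header columns ",
         paste(need, collapse = ", "))
  class(trace) <- c("force_trace", "data.frame")
  attr(trace, "organoid_id") <- organoid_id
  trace
}

#' @rdname read_force_trace
#' @param trace A `force_trace` data frame.
#' @export
write_force_trace <- function(trace, path) {
  write.csv(trace[, c("time_s", "gap_mm", "force_N")], path,
            row.names = FALSE)
  invisible(path)
}

.validate_trace <- function(trace) {
  need <- c("time_s", "gap_mm", "force_N")
  if (!all(need %in% names(trace)))
    stop("trace must have columns ", paste(need, collapse = ", "))
  if (nrow(trace) < 2) stop("trace must contain at least 2 samples")
  if (is.unsorted(trace$time_s)) stop("time must be nondecreasing")
  if (any(trace$gap_mm <= 0)) stop("gap values must be positive")
  trace
}

#' Segment a compression recording into cycles
#'
#' The initial height X is the first recorded gap. A compression cycle is a
#' maximal run of samples in which the gap lies below the return band
#' `X * (1 - tolerance)`; cycles are the gap excursions between returns of
#' the gap to within the tolerance band of the initial height. Exactly
#' `n_expected` cycles must be found.
#'
#' @param trace A `force_trace` data frame.
#' @param n_expected Expected number of cycles (>= 1).
#' @param tolerance Gap-return tolerance as a fraction of the initial
#'   height (default 0.05).
#' @return A data frame with one row per cycle: `index`, `start`, `end`
#'   (sample indices, 1-based), `peak_force_N`, `min_gap_mm`.
#' @export
extract_cycles <- function(trace, n_expected, tolerance = 0.05) {
  .validate_trace(trace)
  if (n_expected < 1) stop("n_expected must be >= 1")
  X <- trace$gap_mm[1L]
  below <- trace$gap_mm < X * (1 - tolerance)
  if (!any(below))
    stop("no cycles: gap signal never leaves the tolerance band of the ",
         "initial height")
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  n_found <- length(runs)
  if (n_found != n_expected)
    stop("expected ", n_expected, " compression cycle(s) but found ",
         n_found)
  cycles <- data.frame(
    index = seq_len(n_found),
    start = starts[runs],
    end = ends[runs])
  cycles$peak_force_N <- vapply(seq_len(n_found), function(i)
    max(trace$force_N[cycles$start[i]:cycles$end[i]]), numeric(1))
  cycles$min_gap_mm <- vapply(seq_len(n_found), function(i)
    min(trace$gap_mm[cycles$start[i]:cycles$end[i]]), numeric(1))
  cycles
}

#' Mean maximum peak force over compression cycles
#'
#' Arithmetic mean of the per-cycle maximum forces.
#'
#' @param cycles Cycle table from [extract_cycles()], or a numeric vector
#'   of per-cycle peak forces.
#' @return Mean maximum peak force in newtons.
#' @export
mean_max_peak_force <- function(cycles) {
  peaks <- if (is.data.frame(cycles)) cycles$peak_force_N else cycles
  if (length(peaks) == 0) stop("no cycles supplied")
  mean(peaks)
}

#' Nominal stress of unconfined compression
#'
#' Applied force divided by the undeformed circular cross-section:
#' `sigma = F / (pi * (d / 2)^2)` with the diameter converted to metres, so
#' the result is in pascals. `nominal_stress_pa()` reports the integer
#' pascal value obtained by truncation toward zero.
#'
#' @param force_N Applied force in newtons (>= 0).
#' @param diameter_mm Organoid diameter in millimetres (> 0).
#' @return Nominal stress in Pa.
#' @export
nominal_stress <- function(force_N, diameter_mm) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  if (any(force_N < 0)) stop("force must be >= 0")
  r_m <- diameter_mm / 2 / 1000
  force_N / (pi * r_m^2)
}

#' @rdname nominal_stress
#' @export
nominal_stress_pa <- function(force_N, diameter_mm) {
  trunc(nominal_stress(force_N, diameter_mm))
}

#' Compressed height of an organoid
#'
#' In strain mode ("compressed by" a level) the compressed height is
#' `X * (1 - level)`; in residual mode ("compressed to" a level) it is
#' `X * level`. The two coincide at a level of 0.5.
#'
#' @param initial_mm Initial height X in mm (> 0).
#' @param level Compression level in (0, 1).
#' @param mode `"strain"` (default) or `"residual"`.
#' @return Compressed height in mm.
#' @export
compressed_height <- function(initial_mm, level,
                              mode = c("strain", "residual")) {
  mode <- match.arg(mode)
  if (any(initial_mm <= 0)) stop("initial height must be positive")
  if (any(level <= 0 | level >= 1)) stop("level must lie in (0, 1)")
  if (mode == "strain") initial_mm * (1 - level) else initial_mm * level
}

#' Cycle-to-cycle peak-force correlations across organoids
#'
#' Pearson correlation between the peak forces of each pair of compression
#' cycles across organoids, testing whether viscoelastic peak decay is
#' consistent from organoid to organoid.
#'
#' @param peaks Numeric matrix of peak forces, one row per organoid, one
#'   column per cycle (>= 3 organoids).
#' @return A list with symmetric matrices `r` (unit diagonal) and `p`
#'   (diagonal `NA`).
#' @export
cycle_peak_correlation <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 3) stop("need at least 3 organoids")
  if (ncol(peaks) < 2) stop("need at least 2 cycles")
  if (any(apply(peaks, 2, sd) == 0))
    stop("a cycle has zero variance across organoids; ",
         "correlation undefined")
  k <- ncol(peaks)
  r <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- cor.test(peaks[, i], peaks[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  dimnames(r) <- dimnames(p) <-
    list(paste0("cycle_", 1:k), paste0("cycle_", 1:k))
  list(r = r, p = p)
}

#' Regression of marker intensity on mean maximum peak force
#'
#' Ordinary least-squares fit of per-organoid mean marker intensity (e.g.
#' mean SOX2 level, whole-section or VZLS-restricted) on the mean maximum
#' peak force acting on each organoid, with a two-sided test of the slope.
#'
#' @param force Per-organoid mean maximum peak forces (>= 3 values with
#'   nonzero variance).
#' @param intensity Per-organoid mean intensities, same length.
#' @return A list with `slope`, `intercept`, `r_squared`, `p` (two-sided
#'   slope test), `ci` (95 percent slope confidence interval) and the `lm`
#'   fit.
#' @export
force_intensity_regression <- function(force, intensity) {
  stopifnot(length(force) == length(intensity))
  if (length(force) < 3) stop("need at least 3 paired observations")
  if (sd(force) == 0) stop("force values are constant; slope undefined")
  fit <- lm(intensity ~ force)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p = s$coefficients[2, 4],
       ci = unname(confint(fit)[2, ]),
       fit = fit)
}

#' Summarise one compression recording
#'
#' Runs cycle extraction, peak averaging and nominal-stress conversion for
#' one trace.
#'
#' @param trace A `force_trace`.
#' @param n_cycles Expected cycle count.
#' @param diameter_mm Organoid diameter for the stress conversion.
#' @param compression_level Compression level for bookkeeping.
#' @param mode Height convention, `"strain"` or `"residual"`.
#' @return A one-row data frame (`compression_summary`) plus per-cycle
#'   peaks in the `"cycles"` attribute.
#' @export
summarize_compression <- function(trace, n_cycles = 3L, diameter_mm = 3,
                                  compression_level = 0.5,
                                  mode = c("strain", "residual")) {
  mode <- match.arg(mode)
  cycles <- extract_cycles(trace, n_cycles)
  mmpf <- mean_max_peak_force(cycles)
  X <- trace$gap_mm[1L]
  out <- data.frame(
    organoid_id = attr(trace, "organoid_id") %||% NA_character_,
    n_cycles = n_cycles,
    mean_max_peak_N = mmpf,
    nominal_stress_Pa = nominal_stress(mmpf, diameter_mm),
    initial_height_mm = X,
    compressed_height_mm = compressed_height(X, compression_level, mode),
    compression_level = compression_level,
    diameter_mm = diameter_mm,
    mode = mode)
  attr(out, "cycles") <- cycles
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
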