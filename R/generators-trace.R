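#' Ground-truth parameters for a synthetic rheometer compression trace
#'
#' Defines a recording of cyclic unconfined compression: the gap (plate
#' height) starts at the organoid's initial height, ramps down to the
#' compressed height and back once per cycle, with short rest phases at the
#' initial height between cycles. The axial force rises with compression
#' depth and reaches its per-cycle maximum at the gap minimum; by default
#' peak forces decay across cycles, emulating viscoelastic relaxation.
#'
#' @param n_cycles Number of compression cycles (default 3).
#' @param peak_forces_N Positive per-cycle peak forces in newtons; length
#'   must equal `n_cycles`. Default `c(10, 8, 7) * 1e-3` (non-increasing).
#' @param cycle_duration_s Duration of one loading/unloading cycle in
#'   seconds (default 60: each cycle lasts roughly one minute).
#' @param initial_height_mm Organoid initial height X in mm; the first
#'   recorded gap.
#' @param compression_level Compression level in (0, 1); in strain mode the
#'   gap descends to `X * (1 - level)`.
#' @param noise_sd_N Gaussian force-noise SD in newtons.
#' @param seed Mandatory RNG seed.
#' @param dt_s Sampling interval (default 0.25 s).
#' @param rest_s Rest time at the initial height before, between and after
#'   cycles (default 5 s).
#' @return An object of class `trace_truth`.
#' @export
trace_truth <- function(n_cycles = 3L,
                        peak_forces_N = c(10, 8, 7) * 1e-3,
                        cycle_duration_s = 60,
                        initial_height_mm = 3,
                        compression_level = 0.5,
                        noise_sd_N = 0,
                        seed,
                        dt_s = 0.25,
                        rest_s = 5) {
  if (missing(seed)) stop("`seed` is a mandatory argument")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (length(peak_forces_N) != n_cycles)
    stop("peak_forces_N must have one entry per cycle")
  if (any(peak_forces_N <= 0)) stop("peak forces must be positive")
  if (compression_level <= 0 || compression_level >= 1)
    stop("compression_level must lie in (0, 1)")
  if (initial_height_mm <= 0 || cycle_duration_s <= 0 || dt_s <= 0)
    stop("heights and durations must be positive")
  if (noise_sd_N < 0) stop("noise_sd_N must be >= 0")
  structure(list(n_cycles = as.integer(n_cycles),
                 peak_forces_N = peak_forces_N,
                 cycle_duration_s = cycle_duration_s,
                 initial_height_mm = initial_height_mm,
                 compression_level = compression_level,
                 noise_sd_N = noise_sd_N,
                 seed = as.integer(seed),
                 dt_s = dt_s, rest_s = rest_s),
            class = "trace_truth")
}

#' Generate a synthetic rheometer force trace
#'
#' Produces a time-resolved recording (`time_s`, `gap_mm`, `force_N`) with
#' `n_cycles` triangular gap excursions from the initial height X down to
#' `X * (1 - compression_level)` and back. Force follows
#' `peak_i * depth^2`, where `depth` is the fractional compression depth
#' within the cycle, so each cycle's noiseless force maximum equals the
#' truth peak exactly (the sampling grid always hits the gap minimum).
#' Gaussian noise of SD `noise_sd_N` is added to the force channel.
#'
#' @param truth A [trace_truth()] object.
#' @param organoid_id Identifier attached to the trace.
#' @return A data frame of class `force_trace` with attribute `organoid_id`.
#' @export
gen_force_trace <- function(truth, organoid_id = "organoid_1") {
  stopifnot(inherits(truth, "trace_truth"))
  X <- truth$initial_height_mm
  Y <- X * (1 - truth$compression_level)
  half <- truth$cycle_duration_s / 2
  n_half <- max(2L, round(half / truth$dt_s))
  n_rest <- max(1L, round(truth$rest_s / truth$dt_s))
  down <- seq(X, Y, length.out = n_half + 1L)
  up <- seq(Y, X, length.out = n_half + 1L)[-1L]
  rest <- rep(X, n_rest)
  gap <- rest
  for (i in seq_len(truth$n_cycles)) gap <- c(gap, down, up, rest)
  depth <- (X - gap) / (X - Y)
  cycle_of <- integer(length(gap))
  pos <- n_rest
  for (i in seq_len(truth$n_cycles)) {
    len <- 2L * n_half + 1L
    cycle_of[(pos + 1L):(pos + len)] <- i
    pos <- pos + len + n_rest
  }
  force <- numeric(length(gap))
  in_cycle <- cycle_of > 0L
  force[in_cycle] <- truth$peak_forces_N[cycle_of[in_cycle]] *
    depth[in_cycle]^2
  force <- with_seed(truth$seed,
                     force + rnorm(length(force), 0, truth$noise_sd_N))
  trace <- data.frame(time_s = (seq_along(gap) - 1L) * truth$dt_s,
                      gap_mm = gap, force_N = force)
  class(trace) <- c("force_trace", "data.frame")
  attr(trace, "organoid_id") <- organoid_id
  trace
}
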