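#' Ground-truth parameters for a synthetic organoid section
#'
#' Defines the generative model for a labelled organoid section: one organoid
#' disc containing `n_vzls` ventricular-zone-like structures (VZLS) embedded
#' in a neuronal compartment (NC). Each VZLS is an annulus (apical contour =
#' inner, lumen-facing circle; basal contour = outer circle) or, with
#' `shape = "band"`, a straight-walled rectangle (apical contour = top edge).
#'
#' Per-pixel noiseless intensity is
#' `base * fc(condition) * (1 + gradient_slope * rho)` for positive VZLS
#' pixels, where `rho` is the relative apico-basal position recorded in the
#' truth table; NC positive pixels use `nc_factor * base * fc(condition)`;
#' non-positive pixels sit at `bg_factor * base`. Gaussian noise with
#' standard deviation `noise_sd` is added and the result clipped at zero.
#'
#' @param n_vzls Number of VZLS to place (>= 1).
#' @param fc_per_condition Named positive numeric vector of intensity
#'   multipliers per condition; must contain the reference condition
#'   `"uncompressed"` with multiplier exactly 1.
#' @param gradient_slope Intensity change per unit relative apico-basal
#'   position (0 = flat profile).
#' @param positive_fraction Fraction of in-tissue pixels drawn as
#'   marker-positive, in `[0, 1]`.
#' @param noise_sd Additive Gaussian intensity noise SD (>= 0).
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param seed Mandatory RNG seed; identical seed + parameters give
#'   bit-identical output.
#' @param width,height Canvas size in pixels (default 512 x 512, >= 64).
#' @param base_intensity Baseline positive-pixel intensity (arbitrary units).
#' @param nc_factor,bg_factor NC and background intensity levels as fractions
#'   of `base_intensity`.
#' @param shape `"annulus"` (default) or `"band"` (straight-walled VZLS).
#' @return An object of class `section_truth`.
#' @export
section_truth <- function(n_vzls = 3,
                          fc_per_condition = c(uncompressed = 1),
                          gradient_slope = 0,
                          positive_fraction = 1,
                          noise_sd = 0,
                          pixel_size_um = 2,
                          seed,
                          width = 512L, height = 512L,
                          base_intensity = 1000,
                          nc_factor = 0.5,
                          bg_factor = 0.08,
                          shape = c("annulus", "band")) {
  shape <- match.arg(shape)
  if (missing(seed)) stop("`seed` is a mandatory argument")
  if (n_vzls < 1) stop("n_vzls must be >= 1")
  if (width < 64 || height < 64) stop("canvas must be at least 64 x 64")
  if (is.null(names(fc_per_condition)) || any(names(fc_per_condition) == ""))
    stop("fc_per_condition must be a named vector")
  if (!"uncompressed" %in% names(fc_per_condition))
    stop("fc_per_condition must contain the reference condition 'uncompressed'")
  if (fc_per_condition[["uncompressed"]] != 1)
    stop("fold change of the reference condition 'uncompressed' must be 1.0")
  if (any(fc_per_condition <= 0)) stop("all intensity multipliers must be > 0")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(
    list(n_vzls = as.integer(n_vzls),
         fc_per_condition = fc_per_condition,
         gradient_slope = gradient_slope,
         positive_fraction = positive_fraction,
         noise_sd = noise_sd,
         pixel_size_um = pixel_size_um,
         seed = as.integer(seed),
         width = as.integer(width), height = as.integer(height),
         base_intensity = base_intensity,
         nc_factor = nc_factor, bg_factor = bg_factor,
         shape = shape),
    class = "section_truth")
}

# Sample a circle as an ordered polyline with ~0.4 px point spacing.
.circle_polyline <- function(cx, cy, r, spacing = 0.4) {
  n <- max(16L, ceiling(2 * pi * r / spacing))
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# Place annular VZLS inside the organoid disc by rejection sampling.
.place_annuli <- function(n_vzls, cx0, cy0, r_org, min_dim) {
  r_out_rng <- c(0.10, 0.16) * min_dim
  centers <- matrix(numeric(0), ncol = 2)
  r_outs <- numeric(0)
  attempts <- 0L
  while (nrow(centers) < n_vzls) {
    attempts <- attempts + 1L
    if (attempts > 5000L)
      stop("cannot fit ", n_vzls, " VZLS into a ", round(2 * r_org),
           " px organoid disc; reduce n_vzls or enlarge the canvas")
    r_out <- runif(1, r_out_rng[1], r_out_rng[2])
    rad <- runif(1, 0, max(0, r_org - r_out - 3))
    ang <- runif(1, 0, 2 * pi)
    cand <- c(cx0 + rad * cos(ang), cy0 + rad * sin(ang))
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (any(d < r_outs + r_out + 3)) next
    }
    centers <- rbind(centers, cand)
    r_outs <- c(r_outs, r_out)
  }
  list(centers = centers, r_out = r_outs, r_in = 0.45 * r_outs)
}

#' Generate a synthetic organoid section with ground truth
#'
#' Rasterises the geometry defined by a [section_truth()] onto the canvas,
#' draws per-pixel intensities for the requested condition, and returns the
#' intensity image, the section annotation (label map + boundary polylines),
#' and a per-pixel ground-truth table. Geometry, the positivity mask and the
#' noise stream all derive from `truth$seed`, so sections generated for
#' different conditions from the same truth share identical geometry.
#'
#' Recorded true boundary distances are exhaustive nearest-point distances
#' from each pixel centre to the densified (<= 0.5 px spacing) boundary
#' point sets, in micrometres; `rho = d_apical / (d_apical + d_basal)`.
#'
#' @param truth A [section_truth()] object.
#' @param condition Condition label; must be a name of
#'   `truth$fc_per_condition`.
#' @param compute_distances If `FALSE`, skip the (relatively costly)
#'   ground-truth boundary-distance computation; the truth table then
#'   carries `NA` distances and `rho`. Only allowed when
#'   `gradient_slope = 0`, since the intensity model needs `rho` otherwise.
#' @return A list of class `synthetic_section` with elements `intensity`
#'   (height x width matrix), `annotation` (a `section_annotation`), `truth`
#'   (per in-tissue pixel data frame) and `condition`.
#' @export
gen_section <- function(truth, condition = "uncompressed",
                        compute_distances = TRUE) {
  stopifnot(inherits(truth, "section_truth"))
  if (!compute_distances && truth$gradient_slope != 0)
    stop("compute_distances = FALSE requires gradient_slope = 0")
  if (!condition %in% names(truth$fc_per_condition))
    stop("condition '", condition, "' not present in fc_per_condition")
  fc <- truth$fc_per_condition[[condition]]
  w <- truth$width; h <- truth$height
  cx0 <- (w - 1) / 2; cy0 <- (h - 1) / 2
  r_org <- 0.46 * min(w, h)

  with_seed(truth$seed, {
    # --- geometry -----------------------------------------------------------
    if (truth$shape == "annulus") {
      geo <- .place_annuli(truth$n_vzls, cx0, cy0, r_org, min(w, h))
    } else {
      # straight-walled bands laid out on a grid
      bw <- floor(w / (truth$n_vzls + 1L))
      # band height commensurate with the default 10 apico-basal bins, so a
      # straight-walled VZLS fills relative bins with equal pixel counts
      bh <- 10L * floor((floor(h * 0.35) + 1L) / 10L) - 1L
      if (bw < 8 || bh < 8)
        stop("cannot fit ", truth$n_vzls, " band VZLS into the canvas")
      geo <- list(bands = lapply(seq_len(truth$n_vzls), function(i) {
        c0 <- floor((i - 0.5) * bw); c1 <- c0 + floor(0.6 * bw)
        r0 <- floor(h / 2 - bh / 2); r1 <- r0 + bh
        c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
      }))
    }

    # pixel centres: pixel (row, col), 0-based, sits at x = col, y = row
    cols <- matrix(rep(0:(w - 1), each = h), nrow = h)
    rows <- matrix(rep(0:(h - 1), times = w), nrow = h)
    d_org <- sqrt((cols - cx0)^2 + (rows - cy0)^2)
    label <- matrix(0L, nrow = h, ncol = w)
    label[d_org <= r_org] <- 1L  # NC by default inside the organoid disc

    boundaries <- list()
    outer_poly <- .circle_polyline(cx0, cy0, r_org)
    boundaries[[1]] <- data.frame(vzls_id = 0L, boundary = "outer",
                                  x_px = outer_poly$x, y_px = outer_poly$y)
    for (i in seq_len(truth$n_vzls)) {
      id <- i + 1L
      if (truth$shape == "annulus") {
        cc <- geo$centers[i, ]; ri <- geo$r_in[i]; ro <- geo$r_out[i]
        d <- sqrt((cols - cc[1])^2 + (rows - cc[2])^2)
        label[d >= ri & d <= ro] <- id
        label[d < ri] <- 0L  # lumen is not tissue
        ap <- .circle_polyline(cc[1], cc[2], ri)
        ba <- .circle_polyline(cc[1], cc[2], ro)
      } else {
        b <- geo$bands[[i]]
        sel <- rows >= b["r0"] & rows <= b["r1"] & cols >= b["c0"] & cols <= b["c1"]
        label[sel] <- id
        xs <- seq(b["c0"], b["c1"], by = 1)
        ap <- list(x = xs, y = rep(b["r0"], length(xs)))
        ba <- list(x = xs, y = rep(b["r1"], length(xs)))
      }
      boundaries[[length(boundaries) + 1L]] <-
        data.frame(vzls_id = id, boundary = "apical", x_px = ap$x, y_px = ap$y)
      boundaries[[length(boundaries) + 1L]] <-
        data.frame(vzls_id = id, boundary = "basal", x_px = ba$x, y_px = ba$y)
    }
    boundaries <- do.call(rbind, boundaries)

    annotation <- section_annotation(label, boundaries, truth$pixel_size_um)

    # --- ground-truth distances (exhaustive reference path) -----------------
    idx <- which(label > 0L)
    px_row <- rows[idx]; px_col <- cols[idx]
    vz <- label[idx]
    d_out <- d_ap <- d_ba <- rho <- rep(NA_real_, length(idx))
    if (compute_distances) {
      dens <- .densified_boundaries(annotation)
      d_out <- nearest_dist_exhaustive(px_col, px_row,
                                       dens$outer$x, dens$outer$y) *
        truth$pixel_size_um
      for (id in sort(unique(vz[vz >= 2L]))) {
        sel <- vz == id
        key <- as.character(id)
        d_ap[sel] <- nearest_dist_exhaustive(px_col[sel], px_row[sel],
                                             dens$apical[[key]]$x,
                                             dens$apical[[key]]$y) *
          truth$pixel_size_um
        d_ba[sel] <- nearest_dist_exhaustive(px_col[sel], px_row[sel],
                                             dens$basal[[key]]$x,
                                             dens$basal[[key]]$y) *
          truth$pixel_size_um
      }
      rho <- ifelse(d_ap + d_ba > 0, d_ap / (d_ap + d_ba), NA_real_)
    }

    # --- intensities --------------------------------------------------------
    positive <- runif(length(idx)) < truth$positive_fraction
    base <- truth$base_intensity
    noiseless <- rep(base * truth$bg_factor, length(idx))
    in_vz <- vz >= 2L
    grad <- if (truth$gradient_slope == 0) 1 else
      1 + truth$gradient_slope * rho[positive & in_vz]
    noiseless[positive & in_vz] <- base * fc * grad
    noiseless[positive & !in_vz] <- base * fc * truth$nc_factor
    noisy <- pmax(0, noiseless + rnorm(length(idx), 0, truth$noise_sd))

    intensity <- matrix(0, nrow = h, ncol = w)
    intensity[idx] <- noisy

    truth_tab <- data.frame(
      row = px_row, col = px_col,
      vzls_id = ifelse(in_vz, vz, 0L),
      compartment = ifelse(in_vz, paste0("VZLS_", vz), "NC"),
      positive = positive,
      d_apical_um = d_ap, d_basal_um = d_ba, d_outer_um = d_out,
      rho = rho,
      intensity_noiseless = noiseless,
      intensity = noisy)

    structure(list(intensity = intensity, annotation = annotation,
                   truth = truth_tab, condition = condition,
                   params = truth),
              class = "synthetic_section")
  })
}
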