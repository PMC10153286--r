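#' Shape descriptor for random colony outlines
#'
#' A four-parameter descriptor `d = (ns, rbar, rs, sigma_s)` controlling the
#' family of random, curvature-controlled colony boundaries: `ns` boundary
#' waves (Fourier modes), mean radius `rbar` (micrometres), dimensionless
#' radial fluctuation amplitude `rs`, and a circular Gaussian smoothing width
#' `sigma_s` expressed in angular samples.
#'
#' Setting `ns = 0` or `rs = 0` yields an exact circle of radius `rbar`.
#'
#' @param ns Integer number of boundary waves (>= 0).
#' @param rbar Mean colony radius in micrometres (> 0).
#' @param rs Radial fluctuation amplitude, dimensionless (>= 0).
#' @param sigma_s Gaussian smoothing width in angular samples (>= 0).
#' @return An object of class `shape_descriptor`.
#' @examples
#' shape_descriptor(ns = 4, rbar = 80, rs = 0.25, sigma_s = 3)
#' @export
shape_descriptor <- function(ns, rbar, rs, sigma_s) {
  stopifnot(is.numeric(ns), length(ns) == 1, ns >= 0, ns == round(ns))
  stopifnot(is.numeric(rbar), length(rbar) == 1, rbar > 0)
  stopifnot(is.numeric(rs), length(rs) == 1, rs >= 0)
  stopifnot(is.numeric(sigma_s), length(sigma_s) == 1, sigma_s >= 0)
  structure(
    list(ns = as.integer(ns), rbar = rbar, rs = rs, sigma_s = sigma_s),
    class = "shape_descriptor"
  )
}

#' @exportS3Method base::print
print.shape_descriptor <- function(x, ...) {
  cat(sprintf(
    "<shape_descriptor> ns=%d, rbar=%.1f um, rs=%.3f, sigma_s=%.1f samples\n",
    x$ns, x$rbar, x$rs, x$sigma_s
  ))
  invisible(x)
}

# Circular (wrap-around) Gaussian smoothing of a periodic signal.
# sigma is in samples; sigma = 0 returns the input unchanged.
smooth_circular <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- length(x)
  half <- min(k %/% 2, max(1L, ceiling(4 * sigma)))
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  idx <- outer(seq_len(k) - 1L, offs, `+`) %% k + 1L
  as.numeric(matrix(x[idx], nrow = k) %*% w)
}

#' Generate a random colony boundary profile
#'
#' Draws a closed polar curve `r(theta)` from the shape descriptor: a
#' truncated Fourier series with uniform random coefficients on `[-1, 1]`,
#' rescaled to unit maximum amplitude, multiplied onto the mean radius with
#' amplitude `rs`, circularly Gaussian-smoothed by `sigma_s` samples, and
#' finally rescaled so the enclosed area equals `pi * rbar^2` exactly.
#' Because the curve is single-valued in the polar angle it is simple
#' (non-self-intersecting) by construction; candidates whose fluctuation
#' drives the radius non-positive are rejected and redrawn from a
#' deterministic sub-seed, up to `max_retries` attempts.
#'
#' @param d A [shape_descriptor()].
#' @param seed Integer seed; the curve is a deterministic function of
#'   `(d, seed, k)`.
#' @param k Number of angular samples (>= 64), default 512.
#' @param max_retries Rejection-resampling cap, default 100.
#' @return An object of class `cell_profile`: list with `theta` (radians),
#'   `r` (micrometres), the descriptor and the seed.
#' @examples
#' prof <- generate_profile(shape_descriptor(5, 80, 0.25, 3), seed = 1)
#' range(prof$r)
#' @export
generate_profile <- function(d, seed, k = 512L, max_retries = 100L) {
  stopifnot(inherits(d, "shape_descriptor"))
  stopifnot(k >= 64)
  theta <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]

  if (d$ns == 0L || d$rs == 0) {
    r <- rep(d$rbar, k)
    return(structure(list(theta = theta, r = r, descriptor = d, seed = seed),
                     class = "cell_profile"))
  }

  for (retry in seq_len(max_retries)) {
    sub_seed <- (as.integer(seed) + 77003L * (retry - 1L)) %% .Machine$integer.max
    set.seed(sub_seed)
    a <- stats::runif(d$ns, -1, 1)
    b <- stats::runif(d$ns, -1, 1)
    f <- numeric(k)
    for (j in seq_len(d$ns)) {
      f <- f + a[j] * cos(j * theta) + b[j] * sin(j * theta)
    }
    amp <- max(abs(f))
    if (amp > 0) f <- f / amp
    r <- d$rbar * (1 + d$rs * f)
    if (min(r) <= 0) next
    r <- smooth_circular(r, d$sigma_s)
    if (min(r) <= 0) next
    # area renormalization: A = 0.5 * sum(r^2) * dtheta -> scale to pi*rbar^2
    area <- 0.5 * sum(r^2) * (2 * pi / k)
    r <- r * sqrt(pi * d$rbar^2 / area)
    return(structure(list(theta = theta, r = r, descriptor = d, seed = seed),
                     class = "cell_profile"))
  }
  stop(
    "generate_profile: could not draw a positive-radius boundary after ",
    max_retries, " attempts; reduce the fluctuation amplitude rs (",
    format(d$rs), ") relative to 1."
  )
}

#' @exportS3Method base::print
print.cell_profile <- function(x, ...) {
  cat(sprintf(
    "<cell_profile> K=%d samples, r in [%.1f, %.1f] um (rbar=%.1f)\n",
    length(x$r), min(x$r), max(x$r), x$descriptor$rbar
  ))
  invisible(x)
}

#' Binary cell-colony geometry
#'
#' Wraps an `n x n` binary indicator raster (1 inside the colony boundary, 0
#' outside) with its physical pixel size. The foreground must be non-empty,
#' contain only 0/1 values, and touch no image border.
#'
#' @param indicator Integer/numeric `n x n` matrix of 0/1 values. The first
#'   index runs along x, the second along y.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(indicator, pixel_size) {
  stopifnot(is.matrix(indicator), nrow(indicator) == ncol(indicator))
  stopifnot(all(indicator %in% c(0, 1)))
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0)
  n <- nrow(indicator)
  if (sum(indicator) == 0) stop("cell_geometry: empty indicator")
  if (any(indicator[1, ] == 1) || any(indicator[n, ] == 1) ||
      any(indicator[, 1] == 1) || any(indicator[, n] == 1)) {
    stop("cell_geometry: foreground touches the image border")
  }
  storage.mode(indicator) <- "double"
  structure(
    list(indicator = indicator, pixel_size = pixel_size, n = n),
    class = "cell_geometry"
  )
}

#' @exportS3Method base::print
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> %dx%d grid, pixel %.3g um, %d foreground px (rbar=%.1f um)\n",
    x$n, x$n, x$pixel_size, sum(x$indicator), average_radius(x)
  ))
  invisible(x)
}

# pixel-center coordinates (micrometres) relative to the grid centre
pixel_centers <- function(n, pixel_size) {
  (seq_len(n) - (n + 1) / 2) * pixel_size
}

#' Rasterize a boundary profile to a binary indicator
#'
#' A pixel is foreground iff its centre lies inside the closed curve. For the
#' star-shaped polar curves produced by [generate_profile()] the even-odd
#' point-in-polygon rule reduces to comparing the pixel-centre radius with the
#' (linearly interpolated) boundary radius at its polar angle, which is what
#' is implemented. No anti-aliasing is applied; the output is strictly binary.
#'
#' @param profile A `cell_profile`.
#' @param n Grid side length.
#' @param pixel_size Micrometres per pixel.
#' @return A [cell_geometry()]. Errors if the curve does not fit in the field
#'   of view with a 2-pixel margin.
#' @examples
#' prof <- generate_profile(shape_descriptor(0, 50, 0, 0), seed = 1)
#' g <- rasterize_profile(prof, n = 128, pixel_size = 2)
#' sum(g$indicator) * g$pixel_size^2 / pi  # ~ 50^2
#' @export
rasterize_profile <- function(profile, n, pixel_size) {
  stopifnot(inherits(profile, "cell_profile"))
  half_fov <- (n / 2 - 2) * pixel_size
  if (max(profile$r) > half_fov) {
    stop(
      "rasterize_profile: curve (max radius ", format(max(profile$r)),
      " um) exceeds the field of view with 2-pixel margin (", format(half_fov),
      " um); increase n or pixel_size."
    )
  }
  xs <- pixel_centers(n, pixel_size)
  px <- matrix(xs, n, n)
  py <- matrix(xs, n, n, byrow = TRUE)
  ang <- atan2(py, px) %% (2 * pi)
  rho <- sqrt(px^2 + py^2)
  # periodic linear interpolation of r(theta)
  k <- length(profile$r)
  pos <- ang / (2 * pi) * k          # in [0, k)
  i0 <- floor(pos)
  frac <- pos - i0
  i0 <- as.integer(i0) %% k + 1L
  i1 <- i0 %% k + 1L
  rb <- profile$r[i0] * (1 - frac) + profile$r[i1] * frac
  ind <- matrix(as.numeric(rho < rb), n, n)
  cell_geometry(ind, pixel_size)
}

#' Average colony radius from its footprint area
#'
#' The size of a colony is summarized by the radius of the circle with the
#' same area: `rbar = sqrt(S_cell / pi)` where `S_cell` is the foreground
#' area in square micrometres.
#'
#' @param g A [cell_geometry()].
#' @return Average radius in micrometres.
#' @export
average_radius <- function(g) {
  stopifnot(inherits(g, "cell_geometry"))
  s <- sum(g$indicator)
  if (s == 0) stop("average_radius: empty indicator")
  sqrt(s * g$pixel_size^2 / pi)
}

#' Signed boundary curvature of a profile
#'
#' Signed curvature of the closed polar curve, computed from the standard
#' polar formula `kappa = (r^2 + 2 r'^2 - r r'') / (r^2 + r'^2)^(3/2)` with
#' periodic central differences for the angular derivatives. Positive values
#' are convex outward; sign flips mark locally concave fluctuation valleys.
#'
#' @param profile A `cell_profile`.
#' @return Numeric vector of curvature (1/micrometre) per angular sample.
#' @examples
#' prof <- generate_profile(shape_descriptor(0, 50, 0, 0), seed = 1)
#' range(boundary_curvature(prof))  # 1/50 everywhere
#' @export
boundary_curvature <- function(profile) {
  stopifnot(inherits(profile, "cell_profile"))
  r <- profile$r
  k <- length(r)
  dt <- 2 * pi / k
  rp <- (r[c(2:k, 1)] - r[c(k, 1:(k - 1))]) / (2 * dt)
  rpp <- (r[c(2:k, 1)] - 2 * r + r[c(k, 1:(k - 1))]) / dt^2
  (r^2 + 2 * rp^2 - r * rpp) / (r^2 + rp^2)^1.5
}

#' Check that a closed curve is simple (non-self-intersecting)
#'
#' Brute-force segment-pair intersection test on the polygon obtained by
#' joining consecutive boundary samples. Used by the generator's invariant
#' tests; polar single-valued curves pass by construction.
#'
#' @param profile A `cell_profile`.
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_curve <- function(profile) {
  xs <- profile$r * cos(profile$theta)
  ys <- profile$r * sin(profile$theta)
  k <- length(xs)
  j <- c(2:k, 1L)
  ax <- xs; ay <- ys; bx <- xs[j]; by <- ys[j]
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (i in seq_len(k - 2L)) {
    # segments strictly after i+1, and skip the closing adjacency for i = 1
    rng <- (i + 2L):k
    if (i == 1L) rng <- rng[rng != k]
    d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[rng], ay[rng])
    d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[rng], by[rng])
    d3 <- cross2(ax[rng], ay[rng], bx[rng], by[rng], ax[i], ay[i])
    d4 <- cross2(ax[rng], ay[rng], bx[rng], by[rng], bx[i], by[i])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Connected-component check for a binary indicator
#'
#' @param indicator Binary matrix.
#' @return `TRUE` if the foreground forms one 4-connected component.
#' @keywords internal
single_component <- function(indicator) {
  cpp_n_components(indicator) == 1L
}

#' Default descriptor parameter ranges
#'
#' The sampling ranges used by [random_cell_geometry()] and the corpus
#' builder: `ns` in 2..8, `rbar` in 40..190 um, `rs` in 0..0.35, `sigma_s`
#' in 1..8 samples.
#'
#' @return Named list of 2-vectors (`ns`, `rbar`, `rs`, `sigma_s`).
#' @export
default_d_ranges <- function() {
  list(ns = c(2L, 8L), rbar = c(40, 190), rs = c(0, 0.35), sigma_s = c(1, 8))
}

#' Draw a random colony geometry
#'
#' Samples a shape descriptor uniformly from `d_ranges`, generates a profile,
#' and rasterizes it at a per-sample pixel size chosen so that the colony
#' diameter occupies `fill_fraction` of the field of view (fixed-fraction
#' framing: colonies of any physical size are representable at any grid
#' size). Candidates whose rasterization is not a single 4-connected
#' component are rejected and redrawn.
#'
#' @param seed Integer seed (deterministic output).
#' @param n Grid side length, default 128.
#' @param d_ranges Descriptor ranges, default [default_d_ranges()].
#' @param fill_fraction Fraction of the field spanned by the colony diameter
#'   (default 0.8).
#' @param k Angular samples for the profile.
#' @return List with elements `geometry` ([cell_geometry()]), `profile`, and
#'   `descriptor`.
#' @export
random_cell_geometry <- function(seed, n = 128L, d_ranges = default_d_ranges(),
                                 fill_fraction = 0.8, k = 512L) {
  for (retry in 0:99) {
    sub <- (as.integer(seed) + 104729L * retry) %% .Machine$integer.max
    set.seed(sub)
    d <- shape_descriptor(
      ns = sample(seq(d_ranges$ns[1], d_ranges$ns[2]), 1),
      rbar = stats::runif(1, d_ranges$rbar[1], d_ranges$rbar[2]),
      rs = stats::runif(1, d_ranges$rs[1], d_ranges$rs[2]),
      sigma_s = stats::runif(1, d_ranges$sigma_s[1], d_ranges$sigma_s[2])
    )
    prof <- generate_profile(d, seed = sub, k = k)
    pixel_size <- 2 * max(prof$r) / (fill_fraction * n)
    g <- rasterize_profile(prof, n = n, pixel_size = pixel_size)
    if (single_component(g$indicator)) {
      return(list(geometry = g, profile = prof, descriptor = d))
    }
  }
  stop("random_cell_geometry: no valid geometry after 100 attempts")
}

#' Write a geometry as a plain-text image plus metadata
#'
#' Stores the indicator as a PGM (portable graymap, values 0/255) alongside a
#' JSON sidecar holding the descriptor, seed and pixel size.
#'
#' @param g A [cell_geometry()].
#' @param path Output path for the PGM; the sidecar gets the extension
#'   `.json`.
#' @param meta Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(g, path, meta = list()) {
  stopifnot(inherits(g, "cell_geometry"))
  n <- g$n
  # PGM stores rows top-to-bottom; our second index is y (bottom-up)
  img <- t(g$indicator[, n:1]) * 255
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(n, n), "255"), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  sidecar <- c(list(pixel_size = g$pixel_size, n = n), meta)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
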