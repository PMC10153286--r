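#' Aggregated substrate/cell property record
#'
#' The conditioning record attached to every sample: the spatial substrate
#' stiffness field, the colony mean radius, the scalar contractility, and a
#' dimensionless cell-type scale (default 1). Scalars are min-max normalized
#' against declared ranges when encoded for the network; the encoding is
#' invertible.
#'
#' @param stiffness_field A [make_stiffness_field()] result.
#' @param mean_radius Colony mean radius, um.
#' @param contractility Active stress sigma_A, Pa.
#' @param alpha Cell-type contractility scale (default 1).
#' @return Object of class `property_tensor`.
#' @export
property_tensor <- function(stiffness_field, mean_radius, contractility,
                            alpha = 1) {
  stopifnot(inherits(stiffness_field, "stiffness_field"))
  stopifnot(is.finite(mean_radius), mean_radius > 0)
  stopifnot(is.finite(contractility), contractility >= 0)
  stopifnot(is.finite(alpha), alpha > 0)
  structure(
    list(stiffness_field = stiffness_field, mean_radius = mean_radius,
         contractility = contractility, alpha = alpha),
    class = "property_tensor"
  )
}

#' Default scalar normalization ranges
#'
#' Min-max ranges used to encode conditioning scalars into `[0, 1]`:
#' substrate stiffness 5-40 kPa (the simulated stiffness span), mean radius
#' 40-190 um (the representable colony sizes), contractility 0 to
#' `sigma_max`.
#'
#' @param params A [mechanics_params()] (supplies `sigma_max`).
#' @return Named list of 2-vectors `e_s`, `rbar`, `sigma_a`.
#' @export
default_ranges <- function(params = mechanics_params()) {
  list(e_s = c(5000, 40000), rbar = c(40, 190),
       sigma_a = c(0, params$sigma_max))
}

norm_scalar <- function(v, range) {
  pmin(1, pmax(0, (v - range[1]) / (range[2] - range[1])))
}

denorm_scalar <- function(v, range) {
  range[1] + v * (range[2] - range[1])
}

#' One (geometry, properties, traction) record
#'
#' @param geometry A [cell_geometry()].
#' @param properties A [property_tensor()].
#' @param traction A [traction_field()]; must vanish outside the footprint.
#' @param seed Integer provenance seed.
#' @param provenance `"simulation"` (this package generates only simulated
#'   samples) or `"experimental"` for externally ingested maps.
#' @param base_id Base sample identifier; augmented variants share it.
#' @return Object of class `tfm_sample`.
#' @export
tfm_sample <- function(geometry, properties, traction, seed,
                       provenance = "simulation", base_id = seed) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(properties, "property_tensor"),
            inherits(traction, "traction_field"))
  outside <- geometry$indicator == 0
  if (any(abs(traction$components[, , 1][outside]) > 0) ||
      any(abs(traction$components[, , 2][outside]) > 0)) {
    stop("tfm_sample: traction must be zero outside the colony footprint")
  }
  structure(
    list(geometry = geometry, properties = properties, traction = traction,
         seed = seed, provenance = provenance, base_id = base_id,
         augmented = "identity"),
    class = "tfm_sample"
  )
}

#' Simulate one corpus sample
#'
#' Draws a random colony geometry, a substrate stiffness field from the
#' requested patterning modes, runs the continuum solver, and packages the
#' result. Deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param n Grid side length (default 64).
#' @param d_ranges Descriptor ranges ([default_d_ranges()]).
#' @param stiffness_spec List: `modes` (subset of uniform/linear/circular),
#'   `e_range` (Pa), `gradient_range` (Pa/um, linear mode),
#'   `contrast_range` (circular mode inner/outer ratio bounds).
#' @param params [mechanics_params()].
#' @param fill_fraction Colony framing fraction (default 0.8).
#' @return A [tfm_sample()].
#' @export
simulate_sample <- function(seed, n = 64L, d_ranges = default_d_ranges(),
                            stiffness_spec = list(modes = "uniform",
                                                  e_range = c(5000, 40000)),
                            params = mechanics_params(),
                            fill_fraction = 0.8) {
  geo <- random_cell_geometry(seed, n = n, d_ranges = d_ranges,
                              fill_fraction = fill_fraction)
  g <- geo$geometry
  attr(g, "descriptor") <- geo$descriptor
  set.seed((as.integer(seed) + 524287L) %% .Machine$integer.max)
  modes <- stiffness_spec$modes %||% "uniform"
  er <- stiffness_spec$e_range %||% c(5000, 40000)
  mode <- if (length(modes) == 1) modes else sample(modes, 1)
  s <- switch(mode,
    uniform = make_stiffness_field("uniform", n, g$pixel_size,
                                   e0 = runif(1, er[1], er[2])),
    linear = {
      gr <- stiffness_spec$gradient_range %||% c(20, 100)
      e0 <- runif(1, er[1] + 0.3 * diff(er), er[2] - 0.3 * diff(er))
      gmax <- min(gr[2], 0.9 * (e0 - er[1] / 2) / (n * g$pixel_size / 2))
      make_stiffness_field("linear", n, g$pixel_size, e0 = e0,
                           gradient = runif(1, min(gr[1], gmax), gmax))
    },
    circular = {
      cr <- stiffness_spec$contrast_range %||% c(1.5, 4)
      e_lo <- runif(1, er[1], er[2] / cr[1])
      e_hi <- min(er[2], e_lo * runif(1, cr[1], cr[2]))
      swap <- runif(1) < 0.5
      make_stiffness_field("circular", n, g$pixel_size,
                           e_inner = if (swap) e_lo else e_hi,
                           e_outer = if (swap) e_hi else e_lo,
                           radius = runif(1, 0.3, 0.7) * average_radius(g),
                           edge_width = runif(1, 5, 15))
    },
    stop("simulate_sample: unknown stiffness mode ", mode)
  )
  tf <- solve_traction(g, s, params)
  ebar <- mean_stiffness(s, g)
  props <- property_tensor(s, mean_radius = average_radius(g),
                           contractility = contractility_law(ebar, params))
  tfm_sample(g, props, tf, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simulated training corpus
#'
#' Runs [simulate_sample()] for `count` independent sub-seeds, collects a
#' manifest (one row per sample: seed, descriptor, stiffness mode, footprint
#' mean stiffness, contractility, traction percentiles), and computes the
#' corpus traction normalization scale (99.5th percentile of pixel traction
#' magnitude over all footprints). Failed simulations are logged and
#' resampled from fresh sub-seeds; a failure rate above 5% aborts.
#'
#' @param count Number of samples (>= 1).
#' @param seed Master seed; each sample uses a deterministic sub-seed.
#' @param n Grid side length.
#' @param d_ranges,stiffness_spec,params,fill_fraction Passed to
#'   [simulate_sample()].
#' @param dir Optional directory: if given the corpus is persisted there via
#'   [write_corpus()].
#' @return Object of class `tfm_corpus`: list with `samples`, `manifest`
#'   (tibble), `traction_scale`, `ranges`, `params`, `n`.
#' @export
build_corpus <- function(count, seed = 1L, n = 64L,
                         d_ranges = default_d_ranges(),
                         stiffness_spec = list(modes = "uniform",
                                               e_range = c(5000, 40000)),
                         params = mechanics_params(),
                         fill_fraction = 0.8, dir = NULL) {
  stopifnot(count >= 1)
  samples <- vector("list", count)
  failures <- 0L
  i <- 1L
  attempt <- 0L
  while (i <= count) {
    sub <- (as.integer(seed) + 7919L * attempt) %% .Machine$integer.max
    attempt <- attempt + 1L
    s <- tryCatch(
      simulate_sample(sub, n = n, d_ranges = d_ranges,
                      stiffness_spec = stiffness_spec, params = params,
                      fill_fraction = fill_fraction),
      error = function(e) e
    )
    if (inherits(s, "error")) {
      failures <- failures + 1L
      message("build_corpus: simulation with sub-seed ", sub,
              " failed (", conditionMessage(s), "); resampling")
      if (failures > pmax(3, 0.05 * attempt)) {
        stop("build_corpus: simulation failure rate above 5% (", failures,
             "/", attempt, ")")
      }
      next
    }
    samples[[i]] <- s
    i <- i + 1L
  }

  manifest <- purrr::map_dfr(seq_along(samples), function(k) {
    s <- samples[[k]]
    d <- attr(s$geometry, "descriptor")
    mag <- traction_magnitude(s$traction)[s$geometry$indicator == 1]
    tibble::tibble(
      id = k,
      base_id = s$base_id,
      seed = s$seed,
      provenance = s$provenance,
      augmented = s$augmented,
      ns = if (is.null(d)) NA_integer_ else d$ns,
      rs = if (is.null(d)) NA_real_ else d$rs,
      sigma_s = if (is.null(d)) NA_real_ else d$sigma_s,
      rbar = s$properties$mean_radius,
      pixel_size = s$geometry$pixel_size,
      stiffness_mode = s$properties$stiffness_field$mode,
      ebar = mean_stiffness(s$properties$stiffness_field, s$geometry),
      gradient = s$properties$stiffness_field$gradient,
      sigma_a = s$properties$contractility,
      t_max = max(mag),
      t_p995 = as.numeric(quantile(mag, 0.995))
    )
  })

  all_mag <- unlist(purrr::map(samples, function(s) {
    traction_magnitude(s$traction)[s$geometry$indicator == 1]
  }))
  scale <- as.numeric(quantile(all_mag, 0.995))
  if (!is.finite(scale) || scale <= 0) scale <- max(all_mag, 1)

  corpus <- structure(
    list(samples = samples, manifest = manifest, traction_scale = scale,
         ranges = default_ranges(params), params = params, n = n,
         seed = as.integer(seed)),
    class = "tfm_corpus"
  )
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' @exportS3Method base::print
print.tfm_corpus <- function(x, ...) {
  cat(sprintf(
    "<tfm_corpus> %d samples, %dx%d grid, traction scale %.3g Pa\n",
    length(x$samples), x$n, x$n, x$traction_scale
  ))
  cat(" stiffness modes:",
      paste(unique(x$manifest$stiffness_mode), collapse = ", "), "\n")
  invisible(x)
}

#' Persist / load a corpus
#'
#' The sample tensors go into a single serialized container; the manifest is
#' additionally written as CSV and the normalization/configuration metadata
#' as JSON, so corpus statistics are reproducible from the manifest alone.
#'
#' @param corpus A [build_corpus()] result.
#' @param dir Directory (created if missing).
#' @return `dir` (write) or the corpus (read), invisibly/visibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "tfm_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(corpus$samples, file.path(dir, "samples.rds"))
  readr::write_csv(corpus$manifest, file.path(dir, "manifest.csv"))
  meta <- list(traction_scale = corpus$traction_scale, n = corpus$n,
               seed = corpus$seed, ranges = corpus$ranges,
               params = unclass(corpus$params))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  samples <- readRDS(file.path(dir, "samples.rds"))
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(samples = samples, manifest = tibble::as_tibble(manifest),
         traction_scale = meta$traction_scale,
         ranges = lapply(meta$ranges, as.numeric),
         params = do.call(mechanics_params, as.list(meta$params)),
         n = meta$n, seed = meta$seed),
    class = "tfm_corpus"
  )
}

#' Normalize a traction field to a dimensionless [-1, 1] tensor
#'
#' Divides both components by `scale` and clips to `[-1, 1]`; the clipped
#' fraction is reported so that an aggressive scale is visible. The default
#' corpus scale is the 99.5th percentile of footprint traction magnitude,
#' chosen over the maximum for robustness to solver edge spikes.
#'
#' @param tf A [traction_field()].
#' @param scale Positive scale in Pa.
#' @return List: `values` (n x n x 2 dimensionless), `scale`,
#'   `clip_fraction`, `pixel_size`.
#' @seealso [denormalize_traction()] for the inverse transform.
#' @export
normalize_traction <- function(tf, scale) {
  stopifnot(inherits(tf, "traction_field"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("normalize_traction: scale must be a positive number")
  }
  v <- tf$components / scale
  clipped <- mean(abs(v) > 1)
  v <- array(pmin(pmax(v, -1), 1), dim(tf$components))
  list(values = v, scale = scale, clip_fraction = clipped,
       pixel_size = tf$pixel_size)
}

#' Invert [normalize_traction()]
#'
#' @param values Dimensionless `n x n x 2` array.
#' @param scale Scale used to normalize, Pa.
#' @param pixel_size Micrometres per pixel.
#' @return A [traction_field()] in Pa.
#' @export
denormalize_traction <- function(values, scale, pixel_size) {
  traction_field(values * scale, pixel_size)
}

# ---- dihedral-4 augmentation -------------------------------------------

d4_ops <- c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")

#' Apply a dihedral-4 transform to a sample
#'
#' Rotates (by multiples of 90 degrees) or mirror-flips a sample: the
#' indicator and stiffness maps transform as images, the traction transforms
#' as a vector field (components permuted and negated consistently with the
#' spatial map), so force balance and the zero-outside-footprint invariant
#' are preserved bitwise. Augmentation is restricted to this group because
#' it is exact for binary masks and square-grid vector fields; arbitrary
#' angles are refused.
#'
#' @param s A [tfm_sample()].
#' @param op One of `"identity"`, `"rot90"`, `"rot180"`, `"rot270"`,
#'   `"flip_h"`, `"flip_v"` (rotations are counter-clockwise).
#' @return The transformed [tfm_sample()], sharing `base_id` with `s`.
#' @export
augment_sample <- function(s, op) {
  stopifnot(inherits(s, "tfm_sample"))
  if (is.numeric(op)) {
    stop("augment_sample: arbitrary-angle rotation is not supported; ",
         "use one of ", paste(d4_ops, collapse = ", "))
  }
  op <- match.arg(op, d4_ops)
  tx <- s$traction$components[, , 1]
  ty <- s$traction$components[, , 2]
  res <- d4_apply_field(s$geometry$indicator,
                        s$properties$stiffness_field$values, tx, ty, op)
  g2 <- cell_geometry(res$ind, s$geometry$pixel_size)
  sf <- s$properties$stiffness_field
  sf$values <- res$es
  props <- s$properties
  props$stiffness_field <- sf
  comp <- array(0, dim(s$traction$components))
  comp[, , 1] <- res$tx
  comp[, , 2] <- res$ty
  out <- tfm_sample(g2, props, traction_field(comp, s$traction$pixel_size),
                    seed = s$seed, provenance = s$provenance,
                    base_id = s$base_id)
  out$augmented <- op
  out
}

# core d4 action on (indicator, stiffness, traction components)
d4_apply_field <- function(ind, es, tx, ty, op) {
  n <- nrow(ind)
  r90 <- function(m) {
    # new[i, j] = old[j, n + 1 - i]  (counter-clockwise quarter turn)
    matrix(m[cbind(rep(seq_len(n), times = n),
                   rep(seq(n, 1), each = n))], n, n, byrow = TRUE)
  }
  switch(op,
    identity = list(ind = ind, es = es, tx = tx, ty = ty),
    rot90 = list(ind = r90(ind), es = r90(es),
                 tx = -r90(ty), ty = r90(tx)),
    rot180 = {
      f <- function(m) m[seq(n, 1), seq(n, 1)]
      list(ind = f(ind), es = f(es), tx = -f(tx), ty = -f(ty))
    },
    rot270 = {
      a <- d4_apply_field(ind, es, tx, ty, "rot180")
      d4_apply_field(a$ind, a$es, a$tx, a$ty, "rot90")
    },
    flip_h = list(ind = ind[seq(n, 1), ], es = es[seq(n, 1), ],
                  tx = -tx[seq(n, 1), ], ty = ty[seq(n, 1), ]),
    flip_v = list(ind = ind[, seq(n, 1)], es = es[, seq(n, 1)],
                  tx = tx[, seq(n, 1)], ty = -ty[, seq(n, 1)])
  )
}

#' Split a corpus into train/validation/test index sets
#'
#' Deterministic, disjoint, exhaustive split by *base* sample: augmented
#' variants of one base sample never straddle splits.
#'
#' @param corpus A `tfm_corpus` (or its manifest tibble).
#' @param fractions Numeric vector summing to 1 (e.g. `c(0.8, 0.1, 0.1)`),
#'   each entry in (0, 1).
#' @param seed Integer seed.
#' @return Named list of integer index vectors (`train`, `validation`,
#'   `test`; names taken from `names(fractions)` if set).
#' @export
split_corpus <- function(corpus, fractions = c(train = 0.8, validation = 0.1,
                                               test = 0.1), seed = 1L) {
  manifest <- if (inherits(corpus, "tfm_corpus")) corpus$manifest else corpus
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split_corpus: fractions must sum to 1")
  }
  if (any(fractions <= 0) || any(fractions >= 1)) {
    stop("split_corpus: each fraction must lie in (0, 1)")
  }
  nms <- names(fractions) %||% c("train", "validation", "test")[seq_along(fractions)]
  groups <- unique(manifest$base_id)
  set.seed(as.integer(seed))
  groups <- sample(groups)
  cuts <- round(cumsum(fractions) * length(groups))
  cuts[length(cuts)] <- length(groups)
  starts <- c(1, head(cuts, -1) + 1)
  out <- purrr::map2(starts, cuts, function(a, b) {
    ids <- groups[seq(a, b)]
    sort(manifest$id[manifest$base_id %in% ids])
  })
  stats::setNames(out, nms)
}

#' Encode a sample into the network conditioning stack
#'
#' Fixed channel order: channel 1 is the binary indicator (no normalization
#' applied to the mask), channel 2 the min-max normalized stiffness map
#' `E_s(x)`, channel 3 a constant map of the normalized mean radius (the
#' contractility is implicit through the stiffness via the contractility
#' law, while the radius carries the physical scale lost to fixed-fraction
#' framing). Conditioning scalars are broadcast as constant channels so the
#' generator stays fully convolutional and spatial and uniform stiffness are
#' handled identically.
#'
#' @param s A [tfm_sample()].
#' @param ranges Normalization ranges ([default_ranges()]).
#' @return `n x n x 3` numeric array.
#' @export
encode_inputs <- function(s, ranges = default_ranges()) {
  stopifnot(inherits(s, "tfm_sample"))
  n <- s$geometry$n
  es <- s$properties$stiffness_field$values
  if (!all(dim(es) == c(n, n))) stop("encode_inputs: shape mismatch")
  out <- array(0, c(n, n, 3))
  out[, , 1] <- s$geometry$indicator
  out[, , 2] <- norm_scalar(es, ranges$e_s)
  out[, , 3] <- norm_scalar(s$properties$mean_radius, ranges$rbar)
  out
}
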