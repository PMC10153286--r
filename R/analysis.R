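#' Average pixelwise relative traction error
#'
#' The headline error statistic: for each sample the vector-magnitude
#' relative error `|T_pred - T_true| / |T_true|` is averaged over the pixels
#' where the true magnitude exceeds `tau` times its per-sample maximum, then
#' averaged over samples. The relative mask is required because the pointwise
#' ratio is undefined where the true traction vanishes (everywhere outside
#' the colony); the mask policy is recorded in the report. The statistic is
#' scale-consistent: multiplying both fields by any positive constant leaves
#' it unchanged.
#'
#' @param preds List of predicted [traction_field()]s (or a single field).
#' @param truths Matched list of ground-truth fields.
#' @param tau Relative mask threshold in (0, 1), default 0.05.
#' @return Object of class `tfm_error_report`: `epsilon_t` (grand mean),
#'   `n_samples`, `mask_policy`, and a `per_sample` tibble.
#' @examples
#' comp <- array(0, c(8, 8, 2)); comp[4:5, 4:5, 1] <- 100
#' t0 <- traction_field(comp, 1)
#' epsilon_t(t0, t0)$epsilon_t  # 0
#' @export
epsilon_t <- function(preds, truths, tau = 0.05) {
  if (inherits(preds, "traction_field")) preds <- list(preds)
  if (inherits(truths, "traction_field")) truths <- list(truths)
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  if (tau <= 0 || tau >= 1) stop("epsilon_t: tau must lie in (0, 1)")
  per <- purrr::map_dbl(seq_along(preds), function(i) {
    p <- preds[[i]]; t0 <- truths[[i]]
    if (!all(dim(p$components) == dim(t0$components))) {
      stop("epsilon_t: shape mismatch in sample ", i)
    }
    mt <- traction_magnitude(t0)
    mask <- mt > tau * max(mt)
    if (!any(mask)) stop("epsilon_t: empty mask in sample ", i)
    dd <- sqrt((p$components[, , 1] - t0$components[, , 1])^2 +
               (p$components[, , 2] - t0$components[, , 2])^2)
    mean(dd[mask] / mt[mask])
  })
  structure(
    list(epsilon_t = mean(per), n_samples = length(per),
         mask_policy = list(type = "relative-magnitude", tau = tau),
         per_sample = tibble::tibble(sample = seq_along(per), epsilon_t = per)),
    class = "tfm_error_report"
  )
}

#' @exportS3Method base::print
print.tfm_error_report <- function(x, ...) {
  cat(sprintf(
    "<tfm_error_report> epsilon_T = %.4f (%.1f%%) over %d samples (mask: |T| > %.2g max)\n",
    x$epsilon_t, 100 * x$epsilon_t, x$n_samples, x$mask_policy$tau
  ))
  invisible(x)
}

#' @export
tidy.tfm_error_report <- function(x, ...) x$per_sample

#' @export
glance.tfm_error_report <- function(x, ...) {
  tibble::tibble(
    epsilon_t = x$epsilon_t,
    epsilon_t_pct = 100 * x$epsilon_t,
    n_samples = x$n_samples,
    tau = x$mask_policy$tau,
    sd = sd(x$per_sample$epsilon_t)
  )
}

#' Net force imbalance of a traction field
#'
#' `|sum of T| / sum of |T|`: zero for a self-equilibrated field (every
#' simulator output, by the free-edge divergence theorem), one for a uniform
#' nonzero field. Defined as 0 for an all-zero field.
#'
#' @param tf A [traction_field()].
#' @return Dimensionless residual in `[0, 1]`.
#' @export
force_balance_residual <- function(tf) {
  stopifnot(inherits(tf, "traction_field"))
  sx <- sum(tf$components[, , 1])
  sy <- sum(tf$components[, , 2])
  denom <- sum(sqrt(tf$components[, , 1]^2 + tf$components[, , 2]^2))
  if (denom == 0) return(0)
  sqrt(sx^2 + sy^2) / denom
}

#' Durotaxis traction difference and asymmetry
#'
#' Compares the traction map on a stiffness-gradient substrate (`t_g`)
#' against the map of the same colony on a uniform substrate with the same
#' average stiffness (`t_0`): the componentwise difference field, its
#' x-channel (the gradient direction), and the stiff/soft asymmetry
#' `A = (S+ - S-) / (S+ + S-)` where `S+`/`S-` sum `|T_G|` over the
#' footprint halves on the stiff/soft side of the footprint centroid
#' (split perpendicular to the gradient; the centroid, not the image
#' centre, because colonies are not centred in general).
#'
#' @param t_g Traction field on the gradient substrate.
#' @param t_0 Traction field on the matched uniform substrate.
#' @param g The shared [cell_geometry()].
#' @return Object of class `durotaxis_report`: `delta_t` (n x n x 2, Pa),
#'   `delta_t_x`, `asymmetry`.
#' @export
traction_difference <- function(t_g, t_0, g) {
  stopifnot(inherits(t_g, "traction_field"), inherits(t_0, "traction_field"),
            inherits(g, "cell_geometry"))
  if (t_g$n != t_0$n || t_g$n != g$n) {
    stop("traction_difference: geometry/resolution mismatch")
  }
  delta <- t_g$components - t_0$components
  structure(
    list(delta_t = delta, delta_t_x = delta[, , 1],
         asymmetry = traction_asymmetry(t_g, g), n = g$n,
         pixel_size = g$pixel_size),
    class = "durotaxis_report"
  )
}

#' @exportS3Method base::print
print.durotaxis_report <- function(x, ...) {
  cat(sprintf(
    "<durotaxis_report> max |dT_x| = %.3g Pa, asymmetry A = %+.4f\n",
    max(abs(x$delta_t_x)), x$asymmetry
  ))
  invisible(x)
}

# stiff/soft traction share asymmetry of a single map, split at the
# footprint centroid perpendicular to the (+x) gradient direction
traction_asymmetry <- function(tf, g) {
  mag <- traction_magnitude(tf)
  fg <- g$indicator == 1
  xs <- matrix(pixel_centers(g$n, g$pixel_size), g$n, g$n)
  cx <- mean(xs[fg])
  s_plus <- sum(mag[fg & xs > cx])
  s_minus <- sum(mag[fg & xs <= cx])
  if (s_plus + s_minus == 0) return(0)
  (s_plus - s_minus) / (s_plus + s_minus)
}

#' Sweep durotaxis asymmetry over gradients and colony sizes
#'
#' Simulator-based study of collective durotaxis: for each stiffness
#' gradient (at fixed colony radius) and each radius (at fixed gradient),
#' simulates `n_reps` random colonies on linear-gradient substrates centred
#' at `e0` and records the stiff-side traction asymmetry. Invalid gradients
#' (driving the stiffness non-positive anywhere) are skipped with a log
#' entry.
#'
#' @param gradients Stiffness gradients in Pa/um (along +x).
#' @param radii Colony mean radii in um.
#' @param n_reps Replicates per condition.
#' @param e0 Centre stiffness, Pa.
#' @param params [mechanics_params()].
#' @param n Grid side length.
#' @param seed Integer seed.
#' @return A tibble of class `durotaxis_sweep`: one row per condition with
#'   `vary` (gradient/radius), `gradient`, `rbar`, mean/sd/se of A and
#'   `n_reps`.
#' @export
durotaxis_sweep <- function(gradients = c(25, 50, 100), radii = c(50, 80, 120),
                            n_reps = 8L, e0 = 20000,
                            params = mechanics_params(), n = 64L,
                            seed = 1L) {
  mid_grad <- gradients[ceiling(length(gradients) / 2)]
  mid_rad <- radii[ceiling(length(radii) / 2)]
  conds <- dplyr::bind_rows(
    tibble::tibble(vary = "gradient", gradient = gradients, rbar = mid_rad),
    tibble::tibble(vary = "radius", gradient = mid_grad, rbar = radii)
  )
  rows <- purrr::pmap(conds, function(vary, gradient, rbar) {
    a_vals <- purrr::map_dbl(seq_len(n_reps), function(rep) {
      sub <- (as.integer(seed) + 104723L * rep +
                997L * round(gradient) + 13L * round(rbar)) %%
        .Machine$integer.max
      d_ranges <- default_d_ranges()
      d_ranges$rbar <- c(rbar, rbar)
      geo <- random_cell_geometry(sub, n = n, d_ranges = d_ranges)
      g <- geo$geometry
      s <- tryCatch(
        make_stiffness_field("linear", n, g$pixel_size, e0 = e0,
                             gradient = gradient),
        error = function(e) e
      )
      if (inherits(s, "error")) {
        message("durotaxis_sweep: skipping gradient ", gradient, " Pa/um (",
                conditionMessage(s), ")")
        return(NA_real_)
      }
      tf <- solve_traction(g, s, params)
      traction_asymmetry(tf, g)
    })
    a_vals <- a_vals[is.finite(a_vals)]
    tibble::tibble(
      vary = vary, gradient = gradient, rbar = rbar,
      a_mean = mean(a_vals), a_sd = sd(a_vals),
      a_se = sd(a_vals) / sqrt(length(a_vals)), n_reps = length(a_vals)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("durotaxis_sweep", class(out))
  out
}
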