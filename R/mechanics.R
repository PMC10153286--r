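#' Continuum model constants for the contractile monolayer
#'
#' Parameters of the traction-force simulator: a linear-elastic contractile
#' monolayer of thickness `h` (plane stress, modulus `e_c`, Poisson ratio
#' `nu_c`) coupled to the substrate through an elastic foundation of
#' stiffness density `Y(x) = E_s(x) / l_s` (Pa per micrometre). The active
#' contractile stress follows a saturating (Hill-type) law of the local
#' substrate stiffness with ceiling `sigma_max` and half-saturation stiffness
#' `e_half`.
#'
#' The traction localization length is `ell = sqrt(h * e_c / (Y * (1 -
#' nu_c^2)))`; with the defaults it spans roughly 9-25 um over substrate
#' stiffnesses of 5-40 kPa, so traction concentrates in a boundary layer at
#' the colony edge and decays exponentially toward the centre.
#'
#' @param h Monolayer thickness, um (default 5).
#' @param e_c Monolayer Young modulus, Pa (default 10000).
#' @param nu_c Monolayer Poisson ratio in `[0, 0.5)` (default 0.45).
#' @param l_s Effective substrate coupling depth, um (default 50).
#' @param sigma_max Saturating contractility, Pa (default 2000).
#' @param e_half Half-saturation substrate stiffness, Pa (default 15000).
#' @return An object of class `mechanics_params`.
#' @export
mechanics_params <- function(h = 5, e_c = 10000, nu_c = 0.45, l_s = 50,
                             sigma_max = 2000, e_half = 15000) {
  stopifnot(h > 0, e_c > 0, nu_c >= 0, nu_c < 0.5, l_s > 0,
            sigma_max >= 0, e_half > 0)
  structure(
    list(h = h, e_c = e_c, nu_c = nu_c, l_s = l_s,
         sigma_max = sigma_max, e_half = e_half),
    class = "mechanics_params"
  )
}

#' @exportS3Method base::print
print.mechanics_params <- function(x, ...) {
  cat(sprintf(
    "<mechanics_params> h=%g um, E_c=%g Pa, nu=%g, L_s=%g um, sigma_max=%g Pa, E_half=%g Pa\n",
    x$h, x$e_c, x$nu_c, x$l_s, x$sigma_max, x$e_half
  ))
  invisible(x)
}

#' Contractility as a function of substrate stiffness
#'
#' Hill-type saturating law `sigma_A = sigma_max * E_s / (e_half + E_s)`:
#' strictly increasing in the substrate stiffness, vanishing on vanishingly
#' soft substrates and saturating at `sigma_max` on rigid ones. This is the
#' mechanotransduction relation the inverse network is later asked to
#' recover from traction maps alone.
#'
#' @param e_s Substrate stiffness in Pa (scalar, vector or matrix; all > 0).
#' @param params A [mechanics_params()].
#' @return Active stress `sigma_A` in Pa, same shape as `e_s`.
#' @examples
#' p <- mechanics_params()
#' contractility_law(p$e_half, p)  # sigma_max / 2
#' @export
contractility_law <- function(e_s, params = mechanics_params()) {
  stopifnot(inherits(params, "mechanics_params"))
  if (any(e_s <= 0)) stop("contractility_law: substrate stiffness must be > 0")
  params$sigma_max * e_s / (params$e_half + e_s)
}

#' Traction localization length
#'
#' `ell = sqrt(h * e_c / (Y * (1 - nu_c^2)))` with foundation density
#' `Y = e_s / l_s`: the decay length of traction from the colony edge.
#'
#' @param e_s Substrate stiffness, Pa.
#' @param params A [mechanics_params()].
#' @return Localization length in micrometres.
#' @export
localization_length <- function(e_s, params = mechanics_params()) {
  y <- e_s / params$l_s
  sqrt(params$h * params$e_c / (y * (1 - params$nu_c^2)))
}

#' Spatial substrate stiffness field
#'
#' Builds an `n x n` map of substrate Young modulus `E_s(x)` in Pa in one of
#' three patterning modes: `uniform`, `linear` (constant gradient along x,
#' `E(x) = e0 + gradient * (x - x_center)`) or `circular` (a disk of
#' `e_inner` inside radius `radius`, `e_outer` outside, logistic-smoothed
#' edge of width `edge_width`).
#'
#' @param mode One of `"uniform"`, `"linear"`, `"circular"`.
#' @param n Grid side length.
#' @param pixel_size Micrometres per pixel.
#' @param e0 Base stiffness, Pa (uniform value / linear-mode centre value).
#' @param gradient Stiffness gradient along x, Pa per um (linear mode).
#' @param e_inner,e_outer Inside/outside stiffness, Pa (circular mode).
#' @param radius Pattern disk radius, um (circular mode).
#' @param edge_width Logistic edge smoothing width, um (circular mode).
#' @return Object of class `stiffness_field`: `values` (n x n, Pa), `mode`,
#'   `gradient`, `pixel_size`.
#' @examples
#' s <- make_stiffness_field("uniform", n = 64, pixel_size = 2, e0 = 20700)
#' unique(as.vector(s$values))
#' @export
make_stiffness_field <- function(mode = c("uniform", "linear", "circular"),
                                 n, pixel_size, e0 = 20000, gradient = 0,
                                 e_inner = 30000, e_outer = 10000,
                                 radius = 60, edge_width = 10) {
  mode <- match.arg(mode)
  xs <- pixel_centers(n, pixel_size)
  values <- switch(mode,
    uniform = matrix(e0, n, n),
    linear = matrix(e0 + gradient * xs, n, n),
    circular = {
      px <- matrix(xs, n, n)
      py <- matrix(xs, n, n, byrow = TRUE)
      rho <- sqrt(px^2 + py^2)
      w <- 1 / (1 + exp((rho - radius) / max(edge_width, 1e-6)))
      e_outer + (e_inner - e_outer) * w
    }
  )
  if (any(values <= 0)) {
    stop("make_stiffness_field: parameters produce non-positive stiffness ",
         "(min ", format(min(values)), " Pa)")
  }
  structure(
    list(values = values, mode = mode,
         gradient = if (mode == "linear") gradient else 0,
         pixel_size = pixel_size, n = n),
    class = "stiffness_field"
  )
}

#' @exportS3Method base::print
print.stiffness_field <- function(x, ...) {
  cat(sprintf(
    "<stiffness_field> %dx%d, mode=%s, E_s in [%.3g, %.3g] kPa\n",
    x$n, x$n, x$mode, min(x$values) / 1000, max(x$values) / 1000
  ))
  invisible(x)
}

#' Mean substrate stiffness under the colony footprint
#'
#' @param field A [make_stiffness_field()] result.
#' @param g A [cell_geometry()] sharing the grid.
#' @return Arithmetic mean of `E_s` over foreground pixels, Pa.
#' @export
mean_stiffness <- function(field, g) {
  stopifnot(inherits(field, "stiffness_field"), inherits(g, "cell_geometry"))
  stopifnot(field$n == g$n)
  m <- g$indicator == 1
  if (!any(m)) stop("mean_stiffness: empty footprint")
  mean(field$values[m])
}

#' Traction field container
#'
#' An `n x n x 2` array of traction stress in Pa (x and y channels),
#' identically zero outside the colony footprint. The stored sign convention
#' is the traction the cell exerts on the substrate: contraction produces
#' inward-pointing vectors.
#'
#' @param components `n x n x 2` numeric array, Pa.
#' @param pixel_size Micrometres per pixel.
#' @return Object of class `traction_field`.
#' @export
traction_field <- function(components, pixel_size) {
  stopifnot(is.array(components), length(dim(components)) == 3,
            dim(components)[3] == 2, dim(components)[1] == dim(components)[2])
  stopifnot(pixel_size > 0)
  structure(
    list(components = components, pixel_size = pixel_size,
         n = dim(components)[1]),
    class = "traction_field"
  )
}

#' @exportS3Method base::print
print.traction_field <- function(x, ...) {
  mag <- traction_magnitude(x)
  cat(sprintf(
    "<traction_field> %dx%dx2, pixel %.3g um, max |T| = %.3g Pa\n",
    x$n, x$n, x$pixel_size, max(mag)
  ))
  invisible(x)
}

#' Pixelwise traction magnitude
#'
#' @param tf A [traction_field()].
#' @return `n x n` matrix of vector magnitudes, Pa.
#' @export
traction_magnitude <- function(tf) {
  sqrt(tf$components[, , 1]^2 + tf$components[, , 2]^2)
}

# 8x8 plane-stress Q4 element stiffness (unit thickness, unit modulus scale
# handled by caller). In 2-D the element stiffness is independent of the
# element edge length. DOF order: (ux1, uy1, ..., ux4, uy4), nodes counter-
# clockwise from the lower-left corner.
q4_stiffness <- function(e_c, nu_c) {
  c_mat <- e_c / (1 - nu_c^2) *
    matrix(c(1, nu_c, 0, nu_c, 1, 0, 0, 0, (1 - nu_c) / 2), 3, 3)
  gp <- c(-1, 1) / sqrt(3)
  ke <- matrix(0, 8, 8)
  # reference square [-1,1]^2, shape functions N_i, jacobian = edge/2 (cancels)
  for (xi in gp) for (eta in gp) {
    dn_dxi <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    dn_deta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    # physical derivatives carry 2/edge; dA carries (edge/2)^2 -> net (edge)^0
    b <- matrix(0, 3, 8)
    b[1, seq(1, 8, 2)] <- dn_dxi * 2
    b[2, seq(2, 8, 2)] <- dn_deta * 2
    b[3, seq(1, 8, 2)] <- dn_deta * 2
    b[3, seq(2, 8, 2)] <- dn_dxi * 2
    ke <- ke + t(b) %*% c_mat %*% b * 0.25
  }
  ke
}

#' Solve the contractile-monolayer traction problem
#'
#' Ground-truth traction simulator. On the pixels inside the colony the
#' plane-stress equilibrium of a thin contractile sheet on an elastic
#' foundation is solved:
#' `h * div(sigma_el + sigma_A(E_s(x)) I) = Y(x) u`, with foundation density
#' `Y = E_s / l_s`, a traction-free monolayer edge
#' (`(sigma_el + sigma_A I) . n = 0` on the boundary), and
#' `sigma_A` given by [contractility_law()]. The discretization is a
#' bilinear-quadrilateral finite-element form of the underlying energy
#' functional on the pixel grid, which makes the free-edge condition natural
#' and the discrete net force identically zero. The sparse symmetric
#' positive-definite system is solved by a direct factorization with one step
#' of iterative refinement.
#'
#' The returned traction `T = Y u`, sampled per pixel, is the stress the cell
#' exerts on the substrate (inward-pointing under contraction) and is exactly
#' zero outside the footprint.
#'
#' @param g A [cell_geometry()].
#' @param s A [make_stiffness_field()] result on the same grid.
#' @param params A [mechanics_params()].
#' @return A [traction_field()].
#' @examples
#' gg <- random_cell_geometry(seed = 1, n = 64)
#' s <- make_stiffness_field("uniform", 64, gg$geometry$pixel_size, e0 = 20000)
#' tf <- solve_traction(gg$geometry, s)
#' force_balance_residual(tf)
#' @export
solve_traction <- function(g, s, params = mechanics_params()) {
  stopifnot(inherits(g, "cell_geometry"), inherits(s, "stiffness_field"))
  stopifnot(inherits(params, "mechanics_params"))
  if (g$n != s$n || abs(g$pixel_size - s$pixel_size) > 1e-9 * g$pixel_size) {
    stop("solve_traction: geometry and stiffness field must share grid and pixel size")
  }
  n <- g$n
  p <- g$pixel_size
  inside <- which(g$indicator == 1, arr.ind = TRUE)
  if (nrow(inside) == 0) stop("solve_traction: empty geometry")

  # element (pixel) corners are nodes on the (n+1)x(n+1) corner lattice;
  # corner (i, j) with i, j in 0..n has lattice id i + (n+1)*j + 1
  ex <- inside[, 1]
  ey <- inside[, 2]
  corner_id <- function(ix, iy) ix + (n + 1L) * iy + 1L
  # counter-clockwise: (i-1,j-1), (i,j-1), (i,j), (i-1,j)
  nodes4 <- cbind(
    corner_id(ex - 1L, ey - 1L), corner_id(ex, ey - 1L),
    corner_id(ex, ey), corner_id(ex - 1L, ey)
  )
  used <- sort(unique(as.vector(nodes4)))
  node_map <- integer((n + 1L)^2)
  node_map[used] <- seq_along(used)
  nn <- length(used)
  loc4 <- matrix(node_map[nodes4], ncol = 4)
  ne <- nrow(loc4)

  y_e <- s$values[cbind(ex, ey)] / params$l_s        # Pa/um per element
  sig_e <- if (params$sigma_max == 0) rep(0, ne) else
    contractility_law(s$values[cbind(ex, ey)], params)

  # global dof ids: ux = 2*node-1, uy = 2*node
  dof8 <- matrix(0L, ne, 8)
  dof8[, seq(1, 8, 2)] <- 2L * loc4 - 1L
  dof8[, seq(2, 8, 2)] <- 2L * loc4

  ke <- q4_stiffness(params$e_c, params$nu_c) * params$h   # Pa*um
  # triplets: for element e, entry ke[a,b] goes to (dof8[e,a], dof8[e,b]);
  # element-major ordering, duplicate entries are summed by sparseMatrix
  ia <- rep(seq_len(8), times = 8)
  ib <- rep(seq_len(8), each = 8)
  rows <- as.vector(t(dof8[, ia, drop = FALSE]))
  cols <- as.vector(t(dof8[, ib, drop = FALSE]))
  vals <- rep(as.vector(ke[cbind(ia, ib)]), times = ne)
  k_mat <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                dims = c(2 * nn, 2 * nn))

  # lumped foundation: each element adds Y_e * p^2 / 4 to both dofs of its
  # 4 corner nodes
  m_diag <- numeric(2 * nn)
  add <- y_e * p^2 / 4
  for (a in 1:4) {
    # for a fixed corner position the element -> node map is injective
    dof_x <- 2L * loc4[, a] - 1L
    m_diag[dof_x] <- m_diag[dof_x] + add
    m_diag[dof_x + 1L] <- m_diag[dof_x + 1L] + add
  }
  a_mat <- k_mat + Matrix::Diagonal(2 * nn, m_diag)

  # active-stress load: -d/du [ sigma_A h * int(tr eps) ] ; per element the
  # contour form gives +/- sigma_A h p / 2 on edge nodes
  f <- numeric(2 * nn)
  cf <- sig_e * params$h * p / 2
  # ux dofs: nodes 1,4 (left, +cf pushes right? see derivation: f_x = -dPi/du)
  # corners ccw: 1=(l,b) 2=(r,b) 3=(r,t) 4=(l,t)
  contrib <- list(
    list(a = 1, comp = 1, sgn = +1), list(a = 4, comp = 1, sgn = +1),
    list(a = 2, comp = 1, sgn = -1), list(a = 3, comp = 1, sgn = -1),
    list(a = 1, comp = 2, sgn = +1), list(a = 2, comp = 2, sgn = +1),
    list(a = 3, comp = 2, sgn = -1), list(a = 4, comp = 2, sgn = -1)
  )
  for (cb in contrib) {
    d <- 2L * loc4[, cb$a] - 2L + cb$comp
    f_add <- cb$sgn * cf
    f[d] <- f[d] + f_add
  }

  if (all(f == 0)) {
    u <- numeric(2 * nn)
  } else {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(a_mat), LDL = FALSE)
    u <- as.numeric(Matrix::solve(ch, f))
    # one step of iterative refinement for tight equivariance/balance
    r <- f - as.numeric(a_mat %*% u)
    u <- u + as.numeric(Matrix::solve(ch, r))
  }

  ux <- u[seq(1, 2 * nn, 2)]
  uy <- u[seq(2, 2 * nn, 2)]
  # per-pixel traction: T = Y_e * mean of the 4 corner displacements
  tx <- y_e * (ux[loc4[, 1]] + ux[loc4[, 2]] + ux[loc4[, 3]] + ux[loc4[, 4]]) / 4
  ty <- y_e * (uy[loc4[, 1]] + uy[loc4[, 2]] + uy[loc4[, 3]] + uy[loc4[, 4]]) / 4

  comp <- array(0, c(n, n, 2))
  comp[cbind(ex, ey, 1L)] <- tx
  comp[cbind(ex, ey, 2L)] <- ty
  traction_field(comp, p)
}

#' Analytic traction profile of an infinite strip
#'
#' Closed-form transverse traction of an infinitely long contractile strip of
#' half-width `w` on a uniform elastic foundation,
#' `T_x(x) = (sigma_a * h / ell) * sinh(x / ell) / cosh(w / ell)`, written in
#' the outward-positive convention (the stored simulator fields use the
#' opposite, inward-positive sign). Serves as the independent analytic oracle
#' for the finite-element solver.
#'
#' @param x Transverse position from the strip midline, um (`|x| <= w`).
#' @param w Strip half-width, um.
#' @param ell Localization length, um (> 0).
#' @param sigma_a Active stress, Pa.
#' @param h Monolayer thickness, um.
#' @return Traction `T_x` in Pa (outward-positive).
#' @examples
#' strip_closed_form(0, w = 20, ell = 10, sigma_a = 1000, h = 5)  # 0 by symmetry
#' @export
strip_closed_form <- function(x, w, ell, sigma_a, h) {
  stopifnot(ell > 0, all(abs(x) <= w + 1e-9))
  (sigma_a * h / ell) * sinh(x / ell) / cosh(w / ell)
}
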