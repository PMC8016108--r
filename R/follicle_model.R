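#' @title Follicle sinus complex model
#' @description
#' Builds the 13-element, 20-DOF beam-and-spring model of the whisker
#' follicle sinus complex (FSC): the vibrissa as an elastic Euler-Bernoulli
#' beam, the follicle wall as a much stiffer beam, four internal springs at
#' the hair bulb (HB), cavernous sinus (CS), ring sinus (RS) and follicle
#' entrance, and two external springs anchoring the wall to the surrounding
#' tissue (ground).
#' @name follicle_model
NULL

# Global DOF layout (20 DOFs):
#   vibrissa nodes 1..5  -> (u, theta) = (1,2) (3,4) (5,6) (7,8) (9,10)
#   wall     nodes 1..4  -> (u, theta) = (11,12) (13,14) (15,16) (17,18)
#   ground translations  -> 19 (deep, k5), 20 (superficial, k6)
# Vibrissa node axial positions: x1=0 (HB), x2 (CS), x3 (RS), x4=L (entrance),
# plus a free external node beyond the entrance. Wall nodes coincide with the
# first four vibrissa nodes.

#' Physical and geometric parameters of the follicle model
#'
#' Collects every constant defining one model instance. Arguments are in
#' convenient user units (GPa, micrometres, millimetres, N/m, degrees);
#' values are stored internally in SI (Pa, m, N/m, rad).
#'
#' @param vibrissa_modulus_GPa Young's modulus of the whisker shaft (GPa).
#' @param vibrissa_radius_um Whisker base radius (micrometres); the second
#'   moment of area is \eqn{I = \pi R^4/4}.
#' @param follicle_length_mm Follicle length L from base to apex (mm).
#' @param k1,k2,k3,k4 Internal spring stiffnesses (N/m) at the hair bulb,
#'   cavernous sinus, ring sinus and follicle entrance respectively.
#' @param k5,k6 External spring stiffnesses (N/m) anchoring the deep and
#'   superficial ends of the follicle wall to surrounding tissue. Defaults
#'   satisfy k5 + k6 = 1e4 N/m with k6/k5 = 7/3.
#' @param spring_positions Fractions of L at which the four internal springs
#'   sit: must start at 0 (HB), end at 1 (entrance) and be strictly
#'   increasing. Default `c(0, 0.3, 0.6, 1)` puts the CS at 0.3 L and the RS
#'   at 0.6 L.
#' @param wall_rigidity_factor Dimensionless multiplier on the vibrissa EI
#'   used for the follicle-wall beam elements; large values make the wall
#'   effectively rigid.
#' @param external_segment_frac Length, as a fraction of L, of the vibrissa
#'   beam segment protruding beyond the follicle entrance. Its far end is
#'   free, so it does not affect the solution inside the follicle.
#' @param deflection_angle_deg Rotation prescribed at the follicle entrance
#'   (degrees). The default -10 simulates a 10 degree rostral whisker
#'   deflection (positive deflection direction = rostral).
#' @param skin_modulus_MPa Skin elastic modulus (MPa); used only by the
#'   anatomical-constraint checks (k5 + k6 ~ E_skin * L).
#' @param beta_mode How the penalty number is chosen: `"diag"` (1e7 times the
#'   mean diagonal of the assembled stiffness matrix, default) or
#'   `"modulus"` (1e7 times the vibrissa Young's modulus in Pa).
#' @return An object of class `follicle_params` (a validated list in SI
#'   units).
#' @examples
#' p <- follicle_params()            # the default parameter set
#' p
#' p2 <- follicle_params(k3 = 1e6)   # stiffer ring sinus (high blood pressure)
#' @export
follicle_params <- function(vibrissa_modulus_GPa = 3.5,
                            vibrissa_radius_um = 75,
                            follicle_length_mm = 1,
                            k1 = 1e3, k2 = 1e4, k3 = 1e5, k4 = 1e6,
                            k5 = 3e3, k6 = 7e3,
                            spring_positions = c(0, 0.3, 0.6, 1),
                            wall_rigidity_factor = 1e4,
                            external_segment_frac = 0.2,
                            deflection_angle_deg = -10,
                            skin_modulus_MPa = 8,
                            beta_mode = c("diag", "modulus")) {
  beta_mode <- match.arg(beta_mode)
  ks <- c(k1, k2, k3, k4, k5, k6)
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("follicle_params: spring stiffnesses must be finite and >= 0")
  sp <- as.numeric(spring_positions)
  if (length(sp) != 4L || sp[1] != 0 || sp[4] != 1 || any(diff(sp) <= 0))
    stop("follicle_params: spring_positions must be 0 = x1 < x2 < x3 < x4 = 1")
  if (abs(deflection_angle_deg) >= 90)
    stop("follicle_params: deflection angle must lie in (-90, 90) degrees")
  if (vibrissa_modulus_GPa <= 0 || vibrissa_radius_um <= 0 ||
      follicle_length_mm <= 0 || wall_rigidity_factor <= 0 ||
      external_segment_frac <= 0)
    stop("follicle_params: moduli, lengths and factors must be > 0")
  structure(
    list(
      vibrissa_modulus = gpa_to_pa(vibrissa_modulus_GPa),
      vibrissa_radius = um_to_m(vibrissa_radius_um),
      follicle_length = mm_to_m(follicle_length_mm),
      k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
      spring_positions = sp,
      wall_rigidity_factor = wall_rigidity_factor,
      external_segment_frac = external_segment_frac,
      deflection_angle = deg_to_rad(deflection_angle_deg),
      skin_modulus = mpa_to_pa(skin_modulus_MPa),
      beta_mode = beta_mode
    ),
    class = "follicle_params"
  )
}

#' @export
print.follicle_params <- function(x, ...) {
  cat("<follicle_params>\n")
  cat(sprintf("  vibrissa: E = %.3g GPa, R = %.3g um, I = %.3g m^4\n",
              pa_to_gpa(x$vibrissa_modulus), m_to_um(x$vibrissa_radius),
              second_moment(x)))
  cat(sprintf("  follicle length L = %.3g mm; springs at x/L = %s\n",
              m_to_mm(x$follicle_length),
              paste(x$spring_positions, collapse = ", ")))
  cat(sprintf("  k1..k4 (HB, CS, RS, entrance) = %s N/m\n",
              paste(format(c(x$k1, x$k2, x$k3, x$k4), digits = 3),
                    collapse = ", ")))
  cat(sprintf("  k5, k6 (external) = %s N/m (sum %.3g, k6/k5 = %.3g)\n",
              paste(format(c(x$k5, x$k6), digits = 3), collapse = ", "),
              x$k5 + x$k6, x$k6 / x$k5))
  cat(sprintf("  deflection %.3g deg, wall rigidity factor %.1g, beta mode %s\n",
              rad_to_deg(x$deflection_angle), x$wall_rigidity_factor,
              x$beta_mode))
  invisible(x)
}

#' Second moment of area of the whisker cross-section
#'
#' \eqn{I = \pi R^4 / 4} for a solid circular section of radius R.
#'
#' @param params A `follicle_params`.
#' @return I in m^4.
#' @export
second_moment <- function(params) {
  pi * params$vibrissa_radius^4 / 4
}

#' Build the 13-element finite-element model
#'
#' Translates a parameter set into element lists and boundary conditions:
#' four vibrissa beam segments (HB -> CS -> RS -> entrance -> external tip),
#' three follicle-wall segments with EI scaled by the wall rigidity factor,
#' four internal springs joining vibrissa and wall nodes, two external
#' springs joining the wall ends to ground, and the constraint set
#' (prescribed rotation at the entrance, zero ground translations).
#'
#' @param params A `follicle_params`.
#' @return A list with components `beams` (7 `beam_element`s), `springs`
#'   (6 `spring_element`s), `constraints` (data frame dof/value), `n_dofs`
#'   (20) and `node_x` (axial positions in m of the five vibrissa nodes).
#' @export
build_model <- function(params) {
  stopifnot(inherits(params, "follicle_params"))
  E <- params$vibrissa_modulus
  I <- second_moment(params)
  L <- params$follicle_length
  xn <- c(params$spring_positions * L,
          L * (1 + params$external_segment_frac))
  seg <- diff(xn)

  vib_dofs <- list(c(1, 2, 3, 4), c(3, 4, 5, 6), c(5, 6, 7, 8),
                   c(7, 8, 9, 10))
  beams <- vector("list", 7L)
  for (i in 1:4)
    beams[[i]] <- beam_element(E, I, seg[i], vib_dofs[[i]])

  wall_dofs <- list(c(11, 12, 13, 14), c(13, 14, 15, 16), c(15, 16, 17, 18))
  for (i in 1:3)
    beams[[4L + i]] <- beam_element(E, I * params$wall_rigidity_factor,
                                    seg[i], wall_dofs[[i]])

  springs <- list(
    spring_element(params$k1, c(1, 11)),   # hair bulb
    spring_element(params$k2, c(3, 13)),   # cavernous sinus
    spring_element(params$k3, c(5, 15)),   # ring sinus
    spring_element(params$k4, c(7, 17)),   # follicle entrance
    spring_element(params$k5, c(11, 19)),  # deep external support
    spring_element(params$k6, c(17, 20))   # superficial external support
  )

  constraints <- data.frame(
    dof = c(8L, 19L, 20L),
    value = c(params$deflection_angle, 0, 0)
  )
  list(beams = beams, springs = springs, constraints = constraints,
       n_dofs = 20L, node_x = xn)
}

penalty_beta <- function(params, K) {
  if (params$beta_mode == "modulus") 1e7 * params$vibrissa_modulus
  else 1e7 * mean(diag(K))
}

#' Solve the follicle model for nodal displacements
#'
#' Assembles the global system, applies the penalty boundary conditions and
#' solves. Mostly an internal step; [compute_profiles()] is the user-facing
#' entry point.
#'
#' @param params A `follicle_params`.
#' @return Length-20 numeric displacement vector.
#' @export
solve_follicle <- function(params) {
  m <- build_model(params)
  sys <- assemble_global(m$beams, m$springs, m$n_dofs)
  sys <- apply_boundary_conditions(sys, m$constraints,
                                   beta = penalty_beta(params, sys$K))
  solve_displacements(sys)
}

# Cubic Hermite evaluation of u, u'' and u''' on one beam segment.
# xi in [0,1]; ua/ta/ub/tb nodal translation and slope; h segment length.
hermite_u <- function(xi, ua, ta, ub, tb, h) {
  h00 <- 2 * xi^3 - 3 * xi^2 + 1
  h10 <- xi^3 - 2 * xi^2 + xi
  h01 <- -2 * xi^3 + 3 * xi^2
  h11 <- xi^3 - xi^2
  h00 * ua + h10 * h * ta + h01 * ub + h11 * h * tb
}

hermite_u2 <- function(xi, ua, ta, ub, tb, h) {
  ((12 * xi - 6) * ua + (6 * xi - 4) * h * ta +
   (6 - 12 * xi) * ub + (6 * xi - 2) * h * tb) / h^2
}

hermite_u3 <- function(ua, ta, ub, tb, h) {
  (12 * ua + 6 * h * ta - 12 * ub + 6 * h * tb) / h^3
}

#' Deformation profiles of the whisker inside the follicle
#'
#' Solves the model and reconstructs, on an equispaced grid over the follicle
#' axis \eqn{[0, L]}:
#' \itemize{
#'   \item the absolute whisker displacement u(x), by elementwise cubic
#'     Hermite interpolation of the nodal translations and rotations (exact
#'     for a beam loaded only at nodes, where \eqn{EI\,u''' = V} holds with
#'     piecewise-constant shear);
#'   \item the follicle-wall displacement f(x), by linear interpolation of
#'     the wall nodal translations (the wall is effectively rigid);
#'   \item the relative displacement r(x) = u(x) - f(x), the quantity that
#'     loads the mechanoreceptor-bearing tissue;
#'   \item the shear force V(x) = EI u'''(x), piecewise constant between
#'     spring attachment points.
#' }
#'
#' @param params A `follicle_params`.
#' @param n_samples Number of sample points on \eqn{[0, L]} (default 201).
#' @return An object of class `deformation_profiles`: list with `x` (m),
#'   `u`, `f`, `r` (m), `V` (N), `nodal` (the 20-vector) and `params`.
#' @examples
#' pr <- compute_profiles(follicle_params())
#' rs_displacement(pr)           # r at the ring-sinus level, in m
#' @export
compute_profiles <- function(params, n_samples = 201L) {
  stopifnot(inherits(params, "follicle_params"), n_samples >= 2L)
  d <- solve_follicle(params)
  L <- params$follicle_length
  xn <- params$spring_positions * L      # vibrissa/wall node positions in [0,L]
  x <- seq(0, L, length.out = n_samples)

  u_dof <- c(1, 3, 5, 7)   # vibrissa translations at the four in-follicle nodes
  t_dof <- c(2, 4, 6, 8)
  w_dof <- c(11, 13, 15, 17)
  EI <- params$vibrissa_modulus * second_moment(params)

  u <- numeric(n_samples)
  V <- numeric(n_samples)
  seg_idx <- pmin(findInterval(x, xn, rightmost.closed = TRUE), 3L)
  for (s in 1:3) {
    in_s <- seg_idx == s
    if (!any(in_s)) next
    h <- xn[s + 1] - xn[s]
    xi <- (x[in_s] - xn[s]) / h
    ua <- d[u_dof[s]]; ta <- d[t_dof[s]]
    ub <- d[u_dof[s + 1]]; tb <- d[t_dof[s + 1]]
    u[in_s] <- hermite_u(xi, ua, ta, ub, tb, h)
    V[in_s] <- EI * hermite_u3(ua, ta, ub, tb, h)
  }
  f <- approx(xn, d[w_dof], xout = x)$y
  structure(
    list(x = x, u = u, f = f, r = u - f, V = V, nodal = d, params = params),
    class = "deformation_profiles"
  )
}

#' @export
print.deformation_profiles <- function(x, ...) {
  cat("<deformation_profiles> ", length(x$x), " samples on [0, ",
      format(m_to_mm(max(x$x))), " mm]\n", sep = "")
  cat(sprintf("  max |r| = %.3g um; r at RS (x = %.2g mm) = %.3g um\n",
              m_to_um(max(abs(x$r))),
              m_to_mm(rs_position(x$params)),
              m_to_um(rs_displacement(x))))
  invisible(x)
}

#' Plot u(x), f(x) and r(x)
#'
#' @param x A `deformation_profiles`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.deformation_profiles <- function(x, ...) {
  graphics::matplot(m_to_mm(x$x),
                    cbind(m_to_um(x$u), m_to_um(x$f), m_to_um(x$r)),
                    type = "l", lty = 1, col = c("purple", "orange", "black"),
                    xlab = "x (mm)", ylab = "displacement (um)", ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topleft", c("u(x)", "f(x)", "r(x)"), lty = 1,
                   col = c("purple", "orange", "black"), bty = "n")
}

#' Axial position of the ring sinus
#'
#' @param params A `follicle_params`.
#' @return Position in m (spring position x3 times L; 0.6 mm by default).
#' @export
rs_position <- function(params) {
  params$spring_positions[3] * params$follicle_length
}

#' Relative displacement at the ring-sinus level
#'
#' Linear interpolation of r(x) at the RS spring position.
#'
#' @param profiles A `deformation_profiles`.
#' @return r at the RS, in m (signed).
#' @export
rs_displacement <- function(profiles) {
  approx(profiles$x, profiles$r, xout = rs_position(profiles$params))$y
}

#' Check the anatomically motivated stiffness constraints
#'
#' The histology of the follicle implies stiffness orderings (k1 <= k2 < k4,
#' k1 <= k3 < k4, k5 < k6) and the skin stiffness implies magnitude rules
#' (k5 + k6 ~ E_skin * L within a factor of ~3; k4 >= 100 (k5 + k6)). This
#' reports all violations; it never errors, so exploratory parameter sets
#' outside the anatomical range can still be simulated.
#'
#' @param params A `follicle_params`.
#' @return Character vector of violation messages (empty when all rules
#'   hold).
#' @export
validate_anatomical_constraints <- function(params) {
  p <- params
  v <- character(0)
  if (!(p$k1 <= p$k2 && p$k2 < p$k4))
    v <- c(v, "ordering k1 <= k2 < k4 violated")
  if (!(p$k1 <= p$k3 && p$k3 < p$k4))
    v <- c(v, "ordering k1 <= k3 < k4 violated")
  if (!(p$k5 < p$k6))
    v <- c(v, "ordering k5 < k6 violated")
  skin <- p$skin_modulus * p$follicle_length
  if (p$k5 + p$k6 < skin / 3 || p$k5 + p$k6 > skin * 3)
    v <- c(v, sprintf(
      "k5 + k6 = %.3g N/m far from skin stiffness E_skin * L = %.3g N/m",
      p$k5 + p$k6, skin))
  if (p$k4 < 100 * (p$k5 + p$k6))
    v <- c(v, "entrance spring k4 below 100 * (k5 + k6)")
  v
}
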