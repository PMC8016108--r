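#' @title Profile classification and feasibility
#' @description
#' Tools that interpret a solved deformation profile: classification of r(x)
#' into C-, S1- and S2-shapes by its zero crossings, the ex vivo feasibility
#' test (displacement bound and sign constancy at the ring sinus), and the
#' internal force on the RS tissue.
#' @name profile_analysis
NULL

#' Classify a deformation profile by its zero crossings
#'
#' Counts sign changes of the relative displacement r(x) strictly inside
#' the follicle. Two guards keep the count grid-independent: samples with
#' |r| below a relative threshold `eps_rel * max|r|` are ignored, and a
#' margin at the follicle entrance (default the last 5% of L) is excluded -
#' the entrance spring clamps the whisker there, so r hovers within the
#' clamp tolerance of zero and would otherwise contribute spurious
#' crossings. Zero crossings map to the three profile classes: 0 crossings
#' = C-shape, 1 = S1-shape, 2 = S2-shape.
#'
#' @param profiles A `deformation_profiles` (at least 50 samples).
#' @param eps_rel Relative magnitude threshold below which samples are
#'   treated as zero (default 1e-3).
#' @param entrance_margin Fraction of L adjacent to the entrance excluded
#'   from crossing detection (default 0.05, matching the clamp tolerance on
#'   |r| at the entrance).
#' @return An object of class `profile_class`: list with `label` ("C", "S1"
#'   or "S2"), `n_crossings`, and `crossing_positions` (m, linearly
#'   interpolated).
#' @examples
#' cls <- classify_profile(compute_profiles(follicle_params()))
#' cls$label
#' @export
classify_profile <- function(profiles, eps_rel = 1e-3,
                             entrance_margin = 0.05) {
  stopifnot(inherits(profiles, "deformation_profiles"))
  if (length(profiles$x) < 50L)
    stop("classify_profile: need at least 50 samples")
  L <- profiles$params$follicle_length
  inside <- profiles$x > 0 & profiles$x <= (1 - entrance_margin) * L
  x <- profiles$x[inside]
  r <- profiles$r[inside]
  eps <- eps_rel * max(abs(profiles$r))
  if (all(abs(r) < eps) || eps == 0)
    stop("classify_profile: degenerate profile (r is identically ~0)")
  keep <- abs(r) >= eps
  xs <- x[keep]
  rs <- r[keep]
  sgn <- sign(rs)
  flips <- which(diff(sgn) != 0)
  crossings <- vapply(flips, function(i) {
    # linear interpolation between the two retained samples
    xs[i] - rs[i] * (xs[i + 1] - xs[i]) / (rs[i + 1] - rs[i])
  }, numeric(1))
  n <- length(crossings)
  label <- switch(as.character(n), "0" = "C", "1" = "S1", "2" = "S2",
                  stop("classify_profile: ", n,
                       " crossings; profile outside the C/S1/S2 taxonomy"))
  structure(list(label = label, n_crossings = n,
                 crossing_positions = crossings),
            class = "profile_class")
}

#' @export
print.profile_class <- function(x, ...) {
  cat("<profile_class> ", x$label, " (", x$n_crossings, " zero crossings",
      if (x$n_crossings)
        paste0(" at x = ",
               paste(format(m_to_mm(x$crossing_positions), digits = 3),
                     collapse = ", "), " mm"),
      ")\n", sep = "")
  invisible(x)
}

#' Test a profile against the ex vivo displacement constraints
#'
#' A profile is feasible when (i) the magnitude of the relative displacement
#' at the ring-sinus level is strictly below `rs_bound_um` (4.8 um from the
#' ex vivo imaging mean; 12 um is the relaxed variant using the maximal
#' recorded displacement) and (ii) r(x) keeps a constant sign throughout the
#' RS window x in \[0.55 L, 0.65 L\], that sign being opposite to the whisker
#' deflection direction (a rostrally deflected whisker displaces caudally
#' inside the follicle at the RS, pivoting about the entrance).
#'
#' @param profiles A `deformation_profiles`.
#' @param rs_bound_um Displacement bound at the RS in micrometres
#'   (default 4.8).
#' @param eps_rel Relative threshold treating tiny |r| as zero for the sign
#'   test.
#' @return An object of class `feasibility_verdict`: list with `feasible`,
#'   `rs_displacement` (m), and `reasons` (character, empty when feasible).
#' @export
feasibility_test <- function(profiles, rs_bound_um = 4.8, eps_rel = 1e-3) {
  stopifnot(inherits(profiles, "deformation_profiles"))
  p <- profiles$params
  L <- p$follicle_length
  r_rs <- rs_displacement(profiles)
  reasons <- character(0)
  if (!(abs(r_rs) < um_to_m(rs_bound_um)))
    reasons <- c(reasons, sprintf(
      "|r| at RS = %.3g um not below the %.3g um bound",
      m_to_um(abs(r_rs)), rs_bound_um))

  win <- profiles$x >= 0.55 * L & profiles$x <= 0.65 * L
  rw <- profiles$r[win]
  eps <- eps_rel * max(abs(profiles$r))
  sgns <- unique(sign(rw[abs(rw) >= eps]))
  # With slope convention theta = du/dx, the whisker segment outside the
  # follicle displaces toward sign(theta_entrance); "opposite the deflection
  # direction" therefore requires r at the RS to carry the opposite sign.
  required <- -sign(p$deflection_angle)
  if (length(sgns) == 0L)
    reasons <- c(reasons, "r is negligible throughout the RS window")
  else if (length(sgns) > 1L)
    reasons <- c(reasons, "r changes sign within the RS window [0.55L, 0.65L]")
  else if (required != 0 && sgns != required)
    reasons <- c(reasons,
                 "r in the RS window points along the deflection direction")
  structure(list(feasible = length(reasons) == 0L, rs_displacement = r_rs,
                 reasons = reasons),
            class = "feasibility_verdict")
}

#' @export
print.feasibility_verdict <- function(x, ...) {
  cat("<feasibility_verdict> ",
      if (x$feasible) "FEASIBLE" else "infeasible",
      sprintf(" (r at RS = %.3g um)\n", m_to_um(x$rs_displacement)), sep = "")
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Internal force on the ring-sinus tissue
#'
#' The force exchanged between the whisker shaft and the RS tissue, modelled
#' as the RS spring stiffness times the relative whisker displacement at the
#' RS level: \eqn{F = k_3 \, r(0.6\,L)} (signed).
#'
#' @param params A `follicle_params` (supplies k3).
#' @param profiles A `deformation_profiles` solved from the same parameters.
#' @return Force in N (signed).
#' @export
internal_force_rs <- function(params, profiles) {
  stopifnot(inherits(params, "follicle_params"),
            inherits(profiles, "deformation_profiles"))
  params$k3 * rs_displacement(profiles)
}
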