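#' @title Parameter sweeps
#' @description
#' The four stiffness-sweep experiments built on the follicle model: k1
#' sensitivity, the (k2, k3) feasibility map, the external-support (muscle)
#' sweep and the blood-pressure (k3) sweep. Each returns a `sweep_result`:
#' a tidy data frame of one row per grid point plus reproducibility metadata.
#' The whole pipeline is deterministic.
#' @name sweeps
NULL

new_sweep_result <- function(table, kind, grid, base) {
  structure(list(table = table, kind = kind, grid = grid, base = base,
                 version = as.character(utils::packageVersion("follisim"))),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", x$kind, ": ", nrow(x$table), " grid points\n",
      sep = "")
  print(utils::head(x$table, 8))
  if (nrow(x$table) > 8) cat("  ... (", nrow(x$table) - 8, " more rows)\n")
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) x$table

clone_params <- function(base, ...) {
  upd <- list(...)
  for (nm in names(upd)) base[[nm]] <- upd[[nm]]
  base
}

#' Sensitivity of the deformation profile to the hair-bulb spring k1
#'
#' For every (k2, k3) combination, sweeps k1 over a dense logarithmic grid
#' and measures the spread (max minus min over k1) of the relative
#' displacement r(x) at each sampled position. Reports the spread at the
#' ring-sinus level, the largest spread along the profile with its location,
#' and the largest spread within a window around the cavernous-sinus spring.
#'
#' @param base A `follicle_params` supplying all non-swept parameters.
#' @param k1_range Endpoints of the k1 sweep in N/m (default 1e2 to 1e6).
#' @param n_k1 Number of log-spaced k1 values (default 9).
#' @param k2_values,k3_values Grids for the other internal springs (defaults:
#'   4 log-spaced values over \[1e3, 1e6\] and \[1e4, 1e6\] N/m).
#' @param n_samples Profile sampling resolution.
#' @param cs_halfwidth Half-width (fraction of L) of the window around the CS
#'   spring position used for the CS-level spread; the default 0.05 mirrors
#'   the RS-window convention (RS +/- 0.05 L) used by the feasibility test.
#' @return A `sweep_result` whose table has one row per (k2, k3) with
#'   columns `k2`, `k3`, `width_rs_um`, `width_cs_um`, `max_width_um`,
#'   `max_width_x_mm`.
#' @export
k1_sensitivity_sweep <- function(base = follicle_params(),
                                 k1_range = c(1e2, 1e6), n_k1 = 9L,
                                 k2_values = log_space(1e3, 1e6, 4),
                                 k3_values = log_space(1e4, 1e6, 4),
                                 n_samples = 201L,
                                 cs_halfwidth = 0.05) {
  stopifnot(inherits(base, "follicle_params"))
  k1_values <- log_space(k1_range[1], k1_range[2], n_k1)
  L <- base$follicle_length
  x <- seq(0, L, length.out = n_samples)
  x_cs <- base$spring_positions[2] * L
  cs_win <- abs(x - x_cs) <= cs_halfwidth * L

  rows <- expand.grid(k3 = k3_values, k2 = k2_values)[, c("k2", "k3")]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    rmat <- vapply(k1_values, function(k1) {
      compute_profiles(clone_params(base, k1 = k1, k2 = rows$k2[i],
                                    k3 = rows$k3[i]), n_samples)$r
    }, numeric(n_samples))
    width <- apply(rmat, 1L, max) - apply(rmat, 1L, min)
    rs_w <- approx(x, width, xout = rs_position(base))$y
    imax <- which.max(width)
    data.frame(
      k2 = rows$k2[i], k3 = rows$k3[i],
      width_rs_um = m_to_um(rs_w),
      width_cs_um = m_to_um(max(width[cs_win])),
      max_width_um = m_to_um(width[imax]),
      max_width_x_mm = m_to_mm(x[imax])
    )
  })
  new_sweep_result(do.call(rbind, out), "k1_sensitivity",
                   grid = list(k1 = k1_values, k2 = k2_values,
                               k3 = k3_values, n_samples = n_samples,
                               cs_halfwidth = cs_halfwidth),
                   base = base)
}

#' Feasibility map over the internal springs (k2, k3)
#'
#' Samples (k2, k3) on a logarithmic grid (k1 held at its intermediate
#' default), classifies each deformation profile as C/S1/S2 and applies the
#' ex vivo feasibility test.
#'
#' @param base A `follicle_params`; its k1 is used for every grid point.
#' @param grid_bounds Common bounds of the k2 and k3 axes in N/m (default
#'   1e3 to 1e6).
#' @param n_per_axis Points per axis (default 13).
#' @param rs_bound_um Feasibility bound at the RS, micrometres.
#' @param n_samples Profile sampling resolution.
#' @return A `sweep_result` with columns `k2`, `k3`, `class`, `n_crossings`,
#'   `feasible`, `rs_disp_um`.
#' @export
k2k3_feasibility_map <- function(base = follicle_params(),
                                 grid_bounds = c(1e3, 1e6),
                                 n_per_axis = 13L,
                                 rs_bound_um = 4.8,
                                 n_samples = 201L) {
  stopifnot(inherits(base, "follicle_params"))
  kv <- log_space(grid_bounds[1], grid_bounds[2], n_per_axis)
  rows <- expand.grid(k3 = kv, k2 = kv)[, c("k2", "k3")]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    pr <- compute_profiles(clone_params(base, k2 = rows$k2[i],
                                        k3 = rows$k3[i]), n_samples)
    cls <- classify_profile(pr)
    fz <- feasibility_test(pr, rs_bound_um = rs_bound_um)
    data.frame(k2 = rows$k2[i], k3 = rows$k3[i], class = cls$label,
               n_crossings = cls$n_crossings, feasible = fz$feasible,
               rs_disp_um = m_to_um(fz$rs_displacement))
  })
  new_sweep_result(do.call(rbind, out), "k2k3_feasibility",
                   grid = list(k2 = kv, k3 = kv, rs_bound_um = rs_bound_um,
                               n_samples = n_samples),
                   base = base)
}

support_row <- function(base, total, ratio, n_samples, sweep) {
  # ratio = k5 / k6
  k6 <- total / (1 + ratio)
  k5 <- total - k6
  pr <- compute_profiles(clone_params(base, k5 = k5, k6 = k6), n_samples)
  data.frame(sweep = sweep, k5_plus_k6 = total, k5_over_k6 = ratio,
             k5 = k5, k6 = k6, rs_disp_um = m_to_um(rs_displacement(pr)))
}

#' External-support sweep (passive touch vs active whisking)
#'
#' Varies the external springs k5 and k6 that model the intrinsic-muscle and
#' tissue support of the follicle, in two independent one-dimensional
#' sweeps: (i) the total stiffness k5 + k6 over \[1e4, 1e5\] N/m at the
#' default ratio k6/k5 = 7/3, and (ii) the balance k5/k6 over
#' \[1/20, 20\] at total 1e4 N/m. Each row reports r at the ring-sinus
#' level and its percentage of the sweep's baseline (total = 1e4 N/m for
#' the total sweep, ratio = 1 for the ratio sweep).
#'
#' @param base A `follicle_params`.
#' @param total_values Total-stiffness grid, N/m (default 9 log-spaced over
#'   \[1e4, 1e5\]).
#' @param ratio_values k5/k6 grid (default 9 log-spaced over \[1/20, 20\],
#'   symmetric about 1).
#' @param n_samples Profile sampling resolution.
#' @return A `sweep_result` with columns `sweep` ("total" or "ratio"),
#'   `k5_plus_k6`, `k5_over_k6`, `k5`, `k6`, `rs_disp_um`,
#'   `pct_of_baseline`.
#' @export
external_support_sweep <- function(base = follicle_params(),
                                   total_values = log_space(1e4, 1e5, 9),
                                   ratio_values = log_space(1 / 20, 20, 9),
                                   n_samples = 201L) {
  stopifnot(inherits(base, "follicle_params"))
  default_ratio <- 3 / 7          # k5/k6 with k6/k5 = 7/3
  tot <- do.call(rbind, lapply(total_values, support_row, base = base,
                               ratio = default_ratio, n_samples = n_samples,
                               sweep = "total"))
  rat <- do.call(rbind, lapply(ratio_values, function(rho)
    support_row(base, total = 1e4, ratio = rho, n_samples = n_samples,
                sweep = "ratio")))

  tot_base <- support_row(base, total = 1e4, ratio = default_ratio,
                          n_samples, "total")$rs_disp_um
  rat_base <- support_row(base, total = 1e4, ratio = 1,
                          n_samples, "ratio")$rs_disp_um
  tot$pct_of_baseline <- 100 * tot$rs_disp_um / tot_base
  rat$pct_of_baseline <- 100 * rat$rs_disp_um / rat_base
  new_sweep_result(rbind(tot, rat), "external_support",
                   grid = list(total = total_values, ratio = ratio_values,
                               n_samples = n_samples),
                   base = base)
}

#' Blood-pressure sweep (ring-sinus spring k3)
#'
#' Simulates rising hydrostatic blood pressure in the ring sinus by
#' increasing k3. Reports r at the RS, the internal force k3 * r, and the
#' force relative to the base state k3 = 1e5 N/m.
#'
#' @param base A `follicle_params`.
#' @param k3_values k3 grid, N/m (default 9 log-spaced over \[1e5, 1e6\]).
#' @param n_samples Profile sampling resolution.
#' @return A `sweep_result` with columns `k3`, `rs_disp_um`, `force_N`,
#'   `force_rel_base`.
#' @export
blood_pressure_sweep <- function(base = follicle_params(),
                                 k3_values = log_space(1e5, 1e6, 9),
                                 n_samples = 201L) {
  stopifnot(inherits(base, "follicle_params"))
  out <- do.call(rbind, lapply(k3_values, function(k3) {
    p <- clone_params(base, k3 = k3)
    pr <- compute_profiles(p, n_samples)
    data.frame(k3 = k3, rs_disp_um = m_to_um(rs_displacement(pr)),
               force_N = internal_force_rs(p, pr))
  }))
  p0 <- clone_params(base, k3 = 1e5)
  f0 <- internal_force_rs(p0, compute_profiles(p0, n_samples))
  out$force_rel_base <- out$force_N / f0
  new_sweep_result(out, "blood_pressure",
                   grid = list(k3 = k3_values, n_samples = n_samples),
                   base = base)
}
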