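#' @title Finite-element core: beam and spring elements, assembly, penalty BCs
#' @description
#' Generic machinery for small beam-and-spring stiffness systems: local
#' Euler-Bernoulli beam and linear spring stiffness matrices, scatter-assembly
#' into a global matrix, essential boundary conditions by the penalty method,
#' a dense solve, and an exact (elimination-based) constrained solve used as a
#' cross-check of the penalty route.
#' @name fem_core
NULL

#' Create a beam element specification
#'
#' A planar Euler-Bernoulli beam segment with constant flexural rigidity
#' \eqn{EI}, described by its Young's modulus, second moment of area, length,
#' and the four global degrees of freedom (translation, rotation at each end)
#' it connects to.
#'
#' @param youngs_modulus Young's modulus E in Pa (> 0).
#' @param second_moment Second moment of area I in m^4 (> 0).
#' @param length Element length in m (> 0).
#' @param dofs Integer vector of 4 distinct global DOF indices, ordered
#'   (u_a, theta_a, u_b, theta_b).
#' @return An object of class `beam_element`.
#' @export
beam_element <- function(youngs_modulus, second_moment, length, dofs) {
  stopifnot(is.numeric(youngs_modulus), is.numeric(second_moment),
            is.numeric(length), length(dofs) == 4L)
  if (youngs_modulus <= 0) stop("beam element: Young's modulus must be > 0")
  if (second_moment <= 0) stop("beam element: second moment must be > 0")
  if (length <= 0) stop("beam element: length must be > 0")
  dofs <- as.integer(dofs)
  if (anyDuplicated(dofs)) stop("beam element: DOF indices must be distinct")
  structure(
    list(youngs_modulus = youngs_modulus, second_moment = second_moment,
         length = length, dofs = dofs),
    class = "beam_element"
  )
}

#' Create a spring element specification
#'
#' A linear spring of stiffness k (N/m) connecting two translational DOFs.
#'
#' @param stiffness Spring constant in N/m (>= 0).
#' @param dofs Integer vector of 2 distinct global DOF indices.
#' @return An object of class `spring_element`.
#' @export
spring_element <- function(stiffness, dofs) {
  stopifnot(is.numeric(stiffness), length(dofs) == 2L)
  if (stiffness < 0) stop("spring element: stiffness must be >= 0")
  dofs <- as.integer(dofs)
  if (dofs[1] == dofs[2]) stop("spring element: DOF indices must be distinct")
  structure(list(stiffness = stiffness, dofs = dofs), class = "spring_element")
}

#' Local stiffness matrix of an Euler-Bernoulli beam element
#'
#' Returns the standard 4x4 beam bending stiffness matrix for DOF ordering
#' (u_a, theta_a, u_b, theta_b):
#' \deqn{\frac{EI}{L^3}\begin{pmatrix} 12 & 6L & -12 & 6L \\ 6L & 4L^2 & -6L &
#' 2L^2 \\ -12 & -6L & 12 & -6L \\ 6L & 2L^2 & -6L & 4L^2 \end{pmatrix}}
#' The matrix is symmetric with rank 2; rigid translation and rigid rotation
#' span its null space.
#'
#' @param spec A `beam_element`.
#' @return A symmetric 4x4 numeric matrix.
#' @export
beam_element_stiffness <- function(spec) {
  stopifnot(inherits(spec, "beam_element"))
  E <- spec$youngs_modulus; I <- spec$second_moment; L <- spec$length
  c1 <- 12 * E * I / L^3
  c2 <- 6 * E * I / L^2
  c3 <- 4 * E * I / L
  c4 <- 2 * E * I / L
  matrix(c( c1,  c2, -c1,  c2,
            c2,  c3, -c2,  c4,
           -c1, -c2,  c1, -c2,
            c2,  c4, -c2,  c3), 4, 4, byrow = TRUE)
}

#' Local stiffness matrix of a spring element
#'
#' @param spec A `spring_element`.
#' @return The 2x2 matrix `[[k, -k], [-k, k]]`.
#' @export
spring_element_stiffness <- function(spec) {
  stopifnot(inherits(spec, "spring_element"))
  k <- spec$stiffness
  matrix(c(k, -k, -k, k), 2, 2)
}

local_stiffness <- function(el) {
  if (inherits(el, "beam_element")) beam_element_stiffness(el)
  else spring_element_stiffness(el)
}

#' Assemble the global stiffness matrix
#'
#' Scatter-adds every element's local stiffness matrix into an
#' `n_dofs` x `n_dofs` global matrix; entries shared by several elements are
#' summed. The result is returned as a `global_system` with a zero load
#' vector, ready for boundary conditions.
#'
#' @param beams List of `beam_element` objects.
#' @param springs List of `spring_element` objects.
#' @param n_dofs Total number of global degrees of freedom.
#' @return An object of class `global_system` with components `K` (stiffness
#'   matrix), `f` (load vector, zero), `beta` (`NA` until boundary conditions
#'   are applied) and `constraints` (empty data frame).
#' @export
assemble_global <- function(beams, springs, n_dofs) {
  n_dofs <- as.integer(n_dofs)
  elements <- c(beams, springs)
  K <- matrix(0, n_dofs, n_dofs)
  for (el in elements) {
    idx <- el$dofs
    if (any(idx < 1L) || any(idx > n_dofs))
      stop("assembly: DOF index out of range [1, ", n_dofs, "]")
    K[idx, idx] <- K[idx, idx] + local_stiffness(el)
  }
  structure(
    list(K = K, f = numeric(n_dofs), beta = NA_real_,
         constraints = data.frame(dof = integer(0), value = numeric(0))),
    class = "global_system"
  )
}

#' @export
print.global_system <- function(x, ...) {
  n <- nrow(x$K)
  cat("<global_system> ", n, " DOFs, ", sum(x$K != 0), " nonzero entries\n",
      sep = "")
  if (nrow(x$constraints)) {
    cat("  penalty beta = ", format(x$beta), "; constrained DOFs: ",
        paste(x$constraints$dof, collapse = ", "), "\n", sep = "")
  } else cat("  no boundary conditions applied yet\n")
  invisible(x)
}

#' Apply essential boundary conditions by the penalty method
#'
#' Adds a large penalty `beta` to the diagonal entry of every constrained DOF
#' and sets the corresponding load-vector entry to `beta * prescribed value`
#' (no other external loads act in this model). By default `beta` is
#' 1e7 times the mean diagonal of K, which keeps the penalty scale-consistent
#' with the assembled stiffness; `beta` may also be given explicitly (e.g.
#' 1e7 times a Young's modulus).
#'
#' @param system A `global_system` from [assemble_global()].
#' @param constraints Data frame with columns `dof` (integer index) and
#'   `value` (prescribed displacement/rotation), one row per constrained DOF.
#' @param beta Penalty number; `NULL` (default) uses `1e7 * mean(diag(K))`.
#' @return The `global_system` with penalties folded into `K` and `f`.
#' @export
apply_boundary_conditions <- function(system, constraints, beta = NULL) {
  stopifnot(inherits(system, "global_system"))
  constraints <- as.data.frame(constraints)
  if (nrow(constraints) == 0L) return(system)
  stopifnot(all(c("dof", "value") %in% names(constraints)))
  dofs <- as.integer(constraints$dof)
  n <- nrow(system$K)
  if (any(dofs < 1L) || any(dofs > n))
    stop("boundary conditions: constrained DOF out of range")
  if (anyDuplicated(dofs))
    stop("boundary conditions: duplicate constraint on DOF ",
         dofs[duplicated(dofs)][1])
  if (is.null(beta)) beta <- 1e7 * mean(diag(system$K))
  K <- system$K
  f <- system$f
  K[cbind(dofs, dofs)] <- K[cbind(dofs, dofs)] + beta
  f[dofs] <- beta * constraints$value
  system$K <- K
  system$f <- f
  system$beta <- beta
  system$constraints <- data.frame(dof = dofs, value = constraints$value)
  system
}

#' Solve the penalised system for nodal displacements
#'
#' Dense solve of `K d = f`. Because the system mixes translational and
#' rotational DOFs (SI units) and carries large penalty entries, the raw
#' matrix is badly scaled; the solve therefore applies symmetric Jacobi
#' equilibration (`D K D y = D f`, `d = D y`, `D = diag(K)^{-1/2}`), which
#' leaves the solution unchanged while restoring floating-point
#' conditioning. Fails with a condition estimate if the equilibrated matrix
#' is still numerically singular; verifies the residual afterwards.
#'
#' @param system A `global_system` after [apply_boundary_conditions()].
#' @param rcond_min Reciprocal-condition threshold (on the equilibrated
#'   matrix) below which the solve is refused.
#' @return Numeric displacement vector `d` (translations in m, rotations in
#'   rad, in the global DOF ordering).
#' @export
solve_displacements <- function(system, rcond_min = 1e-14) {
  stopifnot(inherits(system, "global_system"))
  K <- system$K
  dg <- diag(K)
  s <- ifelse(dg > 0, 1 / sqrt(dg), 1)
  Ks <- K * tcrossprod(s)          # D K D
  rc <- rcond(Ks)
  if (!is.finite(rc) || rc < rcond_min)
    stop("solve: stiffness matrix numerically singular ",
         "(equilibrated rcond = ", format(rc), ")")
  d <- s * solve(Ks, s * system$f)
  fn <- sqrt(sum((s * system$f)^2))
  if (fn > 0) {
    res <- sqrt(sum((s * (K %*% d - system$f))^2)) / fn
    if (res > 1e-8)
      stop("solve: residual too large (", format(res), ")")
  }
  as.numeric(d)
}

#' Exactly constrained solve (elimination oracle)
#'
#' Solves the same beam-and-spring system with the essential boundary
#' conditions enforced exactly by elimination: constrained DOFs are fixed at
#' their prescribed values and the free block `K_ff d_f = -K_fc d_c` is
#' solved. Intended as an independent cross-check of the penalty-method
#' solution path.
#'
#' @inheritParams assemble_global
#' @param constraints Data frame with columns `dof`, `value`.
#' @return Full displacement vector of length `n_dofs`.
#' @export
oracle_constrained_solve <- function(beams, springs, constraints,
                                     n_dofs = 20L) {
  sys <- assemble_global(beams, springs, n_dofs)
  constraints <- as.data.frame(constraints)
  cdof <- as.integer(constraints$dof)
  if (anyDuplicated(cdof)) stop("oracle: duplicate constraint")
  cval <- constraints$value
  free <- setdiff(seq_len(n_dofs), cdof)
  d <- numeric(n_dofs)
  d[cdof] <- cval
  if (length(free)) {
    rhs <- -sys$K[free, cdof, drop = FALSE] %*% cval
    Kff <- sys$K[free, free, drop = FALSE]
    dg <- diag(Kff)
    s <- ifelse(dg > 0, 1 / sqrt(dg), 1)   # same equilibration as the solver
    d[free] <- s * solve(Kff * tcrossprod(s), s * rhs)
  }
  d
}
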