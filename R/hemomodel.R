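#' Elastic pressure--area constitutive law
#'
#' Transmural pressure of a thin elastic vessel wall:
#' `p = pext + beta * (sqrt(A) - sqrt(A0))`. [area_from_pressure()] is the
#' exact algebraic inverse.
#'
#' @param A Cross-sectional area (m^2), any numeric array; must be positive.
#' @param segment A [vessel_segment()].
#' @return Pressure (Pa), same shape as `A`.
#' @examples
#' seg <- vessel_segment("parent", 0.01763, 3.8191e-4, beta = 2.32586e6)
#' constitutive_pressure(seg$A0, seg)      # = pext
#' area_from_pressure(constitutive_pressure(1.1 * seg$A0, seg), seg)
#' @export
constitutive_pressure <- function(A, segment) {
  if (any(A <= 0)) abort("`A` must be positive everywhere.")
  segment$pext + segment$beta * (sqrt(A) - sqrt(segment$A0))
}

#' @rdname constitutive_pressure
#' @param p Pressure (Pa).
#' @export
area_from_pressure <- function(p, segment) {
  s <- sqrt(segment$A0) + (p - segment$pext) / segment$beta
  if (any(s <= 0)) abort("pressure below the collapse limit of the wall law.")
  s^2
}

#' Linearised pulse wave speed of an elastic segment
#'
#' Characteristic speed `c = sqrt(beta * sqrt(A) / (2 rho))` of
#' small-amplitude waves under the elastic wall law; evaluated at `A = A0`
#' unless another area is given.
#'
#' @param segment A [vessel_segment()].
#' @param rho Blood density (kg/m^3).
#' @param A Area at which to evaluate (defaults to `A0`).
#' @return Wave speed (m/s).
#' @export
segment_wave_speed <- function(segment, rho = 1060, A = segment$A0) {
  sqrt(segment$beta * sqrt(A) / (2 * rho))
}

#' Residual of the 1D mass-conservation equation
#'
#' `dA/dt + A du/dx + u dA/dx`, elementwise. All arguments must be
#' conformable arrays; derivatives are supplied by the caller (analytic,
#' numerical, or network tangents).
#'
#' @param A Area (m^2). @param u Velocity (m/s).
#' @param dA_dt,dA_dx,du_dx Partial derivatives of `A` and `u`.
#' @return Residual (m^2/s), zero on exact solutions.
#' @export
mass_residual <- function(A, u, dA_dt, dA_dx, du_dx) {
  check_conformable(A, u, dA_dt, dA_dx, du_dx)
  dA_dt + A * du_dx + u * dA_dx
}

#' Residual of the 1D momentum-balance equation
#'
#' `du/dt + alpha u du/dx + shape + (1/rho) dp/dx - KR u / A`, where
#' `shape = (u/A) d((alpha-1) u A)/dx` is the profile-shape term. With a
#' flat velocity profile (`alpha = 1`) it vanishes identically; otherwise
#' it expands to `(alpha-1) (u/A) (A du/dx + u dA/dx)`.
#'
#' @param A Area (m^2), positive. @param u Velocity (m/s).
#' @param dp_dx Pressure gradient (Pa/m).
#' @param du_dt,du_dx Velocity derivatives.
#' @param fluid A [fluid_model()].
#' @param dA_dx Area gradient; only needed when `alpha != 1`.
#' @return Residual (m/s^2), zero on exact solutions.
#' @export
momentum_residual <- function(A, u, dp_dx, du_dt, du_dx, fluid,
                              dA_dx = NULL) {
  check_conformable(A, u, dp_dx, du_dt, du_dx)
  if (any(A <= 0)) abort("`A` must be positive everywhere.")
  al <- fluid$alpha
  shape_term <- 0
  if (al != 1) {
    if (is.null(dA_dx)) abort("`dA_dx` is required when `alpha != 1`.")
    shape_term <- (al - 1) * (u / A) * (A * du_dx + u * dA_dx)
  }
  du_dt + al * u * du_dx + shape_term + dp_dx / fluid$rho - fluid$KR * u / A
}

#' Junction flow-continuity residual
#'
#' `A1 u1 - A2 u2 - A3 u3`: conservation of volume flux where the
#' parent outlet meets the two daughter inlets.
#'
#' @param state1,state2,state3 Lists (or one-row data frames) with elements
#'   `A` and `u` evaluated at the junction (parent at `x = L`, daughters at
#'   `x = 0`); vectors over time are allowed.
#' @return Residual (m^3/s).
#' @export
junction_flow_residual <- function(state1, state2, state3) {
  check_conformable(state1$A, state2$A, state3$A, state1$u, state2$u, state3$u)
  state1$A * state1$u - state2$A * state2$u - state3$A * state3$u
}

#' Junction total-pressure (Bernoulli) residuals
#'
#' Continuity of total pressure `p + rho u^2 / 2` across the junction,
#' assuming lossless merging flow. Returns both parent-to-daughter
#' residuals.
#'
#' @param state1,state2,state3 Lists with `p` (Pa) and `u` (m/s) at the
#'   junction coordinates.
#' @param rho Blood density (kg/m^3).
#' @return A list with elements `r12` and `r13` (Pa).
#' @export
junction_bernoulli_residuals <- function(state1, state2, state3, rho = 1060) {
  tp <- function(s) s$p + 0.5 * rho * s$u^2
  list(r12 = tp(state1) - tp(state2), r13 = tp(state1) - tp(state3))
}

check_conformable <- function(...) {
  lens <- vapply(list(...), length, 1L)
  if (length(unique(lens[lens > 1L])) > 1L)
    abort("arrays are not conformable.")
  invisible(TRUE)
}
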