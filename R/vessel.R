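#' Define one 1D arterial segment
#'
#' A vessel segment is a straight, circular 1D vessel with constant
#' equilibrium area `A0` and an elastic wall characterised by the lumped
#' stiffness parameter `beta` of the pressure--area constitutive law
#' `p = pext + beta * (sqrt(A) - sqrt(A0))`. `beta` may be given directly
#' or derived from wall mechanics via
#' `beta = sqrt(pi) * h0 * E / ((1 - nu^2) * A0)`.
#'
#' @param id Character label (e.g. `"parent"`, `"left"`, `"right"`).
#' @param length Segment length along the centerline (m).
#' @param A0 Equilibrium (diastolic minimum) cross-sectional area (m^2).
#' @param beta Wall stiffness parameter (Pa/m). If `NULL`, it is derived
#'   from `E`, `h0`, `nu` and `A0`.
#' @param pext External (tissue) pressure (Pa). Default 16 mmHg.
#' @param E Young's modulus of the wall (Pa); only used when `beta` is `NULL`.
#' @param h0 Wall thickness (m); defaults to `0.1 * R0` when mechanics are
#'   used, where `R0 = sqrt(A0/pi)` is the equilibrium radius.
#' @param nu Poisson ratio of the wall (default 0.5, incompressible).
#' @return An object of class `vessel_segment`.
#' @examples
#' vessel_segment("parent", length = 0.01763, A0 = 3.8191e-4, beta = 2.32586e6)
#' # derive beta from mechanics instead:
#' vessel_segment("parent", length = 0.01763, A0 = 3.8191e-4, E = 340898.12)
#' @export
vessel_segment <- function(id, length, A0, beta = NULL,
                           pext = mmhg_to_pa(16),
                           E = NULL, h0 = NULL, nu = 0.5) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(length) || length <= 0) abort("`length` must be positive (m).")
  if (!is.numeric(A0) || A0 <= 0) abort("`A0` must be positive (m^2).")
  if (nu < 0 || nu >= 1) abort("`nu` must lie in [0, 1).")
  R0 <- sqrt(A0 / pi)
  if (is.null(beta)) {
    if (is.null(E)) abort("give either `beta` or `E` (with optional `h0`, `nu`).")
    if (is.null(h0)) h0 <- 0.1 * R0
    beta <- beta_from_mechanics(E, h0, nu, A0)
  } else if (!is.null(E)) {
    abort("`beta` and wall mechanics (`E`) are both given; supply only one.")
  }
  if (beta <= 0) abort("`beta` must be positive (Pa/m).")
  structure(
    list(id = id, length = length, A0 = A0, beta = beta, pext = pext,
         h0 = h0, E = E, nu = nu, R0 = R0),
    class = "vessel_segment"
  )
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf(
    "<vessel_segment '%s'>  L = %.4g m, A0 = %.4g m^2, beta = %.6g Pa/m, pext = %.4g mmHg\n",
    x$id, x$length, x$A0, x$beta, pa_to_mmhg(x$pext)))
  invisible(x)
}

#' Blood properties and momentum closure
#'
#' @param rho Blood density (kg/m^3), default 1060.
#' @param alpha Momentum-flux correction factor (1 for a flat velocity
#'   profile, appropriate at the high Womersley numbers of the large
#'   pulmonary arteries).
#' @param KR Friction parameter (m^2/s); 0 neglects linear viscous losses.
#' @return An object of class `fluid_model`.
#' @examples
#' fluid_model()
#' @export
fluid_model <- function(rho = 1060, alpha = 1, KR = 0) {
  if (rho <= 0) abort("`rho` must be positive.")
  if (alpha < 1) abort("`alpha` must be >= 1.")
  if (KR < 0) abort("`KR` must be >= 0.")
  structure(list(rho = rho, alpha = alpha, KR = KR), class = "fluid_model")
}

#' @export
print.fluid_model <- function(x, ...) {
  cat(sprintf("<fluid_model>  rho = %g kg/m^3, alpha = %g, KR = %g m^2/s\n",
              x$rho, x$alpha, x$KR))
  invisible(x)
}

#' Assemble a Y-shaped bifurcation problem
#'
#' Three vessel segments joined at a single junction: the parent's outlet
#' (`x = L_parent`) meets both daughters' inlets (`x = 0`). Boundary
#' measurement series (area and velocity at segment extremities) may be
#' attached per vessel end.
#'
#' @param parent,daughter1,daughter2 `vessel_segment` objects.
#' @param fluid A `fluid_model`.
#' @param measurements Optional tibble of boundary series with columns
#'   `vessel_id`, `end` (`"inlet"`/`"outlet"`), `t_s`, and `u_m_s` and/or
#'   `area_m2` (see [read_boundary_csv()]).
#' @param cycle_duration Cardiac cycle duration (s), default 0.89.
#' @return An object of class `bifurcation_problem`.
#' @examples
#' prob <- pa_problem()
#' prob
#' @export
bifurcation_problem <- function(parent, daughter1, daughter2,
                                fluid = fluid_model(),
                                measurements = NULL,
                                cycle_duration = 0.89) {
  for (v in list(parent, daughter1, daughter2))
    if (!inherits(v, "vessel_segment")) abort("vessels must be `vessel_segment`s.")
  if (!inherits(fluid, "fluid_model")) abort("`fluid` must be a `fluid_model`.")
  ids <- c(parent$id, daughter1$id, daughter2$id)
  if (anyDuplicated(ids)) abort("vessel ids must be distinct.")
  if (cycle_duration <= 0) abort("`cycle_duration` must be positive.")
  if (!is.null(measurements)) measurements <- validate_measurements(measurements, ids)
  structure(
    list(vessels = list(parent, daughter1, daughter2),
         fluid = fluid,
         measurements = measurements,
         cycle_duration = cycle_duration),
    class = "bifurcation_problem"
  )
}

validate_measurements <- function(m, ids) {
  m <- as_tibble(m)
  need <- c("vessel_id", "end", "t_s")
  if (!all(need %in% names(m)))
    abort(paste0("measurements need columns: ", paste(need, collapse = ", ")))
  if (!any(c("u_m_s", "area_m2") %in% names(m)))
    abort("measurements need at least one of `u_m_s`, `area_m2`.")
  bad <- setdiff(unique(m$vessel_id), ids)
  if (length(bad)) abort(paste0("unknown vessel_id in measurements: ",
                                paste(bad, collapse = ", ")))
  if (!all(m$end %in% c("inlet", "outlet")))
    abort("`end` must be 'inlet' or 'outlet'.")
  m
}

#' @export
print.bifurcation_problem <- function(x, ...) {
  cat("<bifurcation_problem>\n")
  for (v in x$vessels) print(v)
  print(x$fluid)
  cat(sprintf("  cycle duration: %g s; measurements: %s\n", x$cycle_duration,
              if (is.null(x$measurements)) "none" else
                paste0(nrow(x$measurements), " rows")))
  invisible(x)
}

#' Reference pulmonary bifurcation parameter set
#'
#' Geometry and wall stiffness of a healthy adult main pulmonary artery
#' bifurcation: segment lengths around 1.8--2 cm, parent equilibrium area
#' 3.8191e-4 m^2 with beta = 2.32586e6 Pa/m, daughter areas of
#' 1.7338e-4 / 1.7491e-4 m^2 with betas near 3.45e6 Pa/m, blood density
#' 1060 kg/m^3 and external pressure 16 mmHg.
#'
#' @param pext External pressure (Pa).
#' @param fluid A `fluid_model`.
#' @return A `bifurcation_problem`.
#' @export
pa_problem <- function(pext = mmhg_to_pa(16), fluid = fluid_model()) {
  bifurcation_problem(
    vessel_segment("parent", length = 0.01763, A0 = 3.8191e-4,
                   beta = 2.32586e6, pext = pext),
    vessel_segment("left",   length = 0.01892, A0 = 1.7338e-4,
                   beta = 3.45194e6, pext = pext),
    vessel_segment("right",  length = 0.02024, A0 = 1.7491e-4,
                   beta = 3.43681e6, pext = pext),
    fluid = fluid
  )
}
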