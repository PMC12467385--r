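#' Characteristic scales mapping physical fields to network coordinates
#'
#' The networks operate on dimensionless, z-scored variables. Physical
#' fields are first non-dimensionalised by characteristic scales
#' (`A* = A / A_ref`, `u* = u / U_char`, `p* = p / p_ref` with
#' `p_ref = rho U_char^2`, `x* = x / L_char`, `t* = t / T_char`), then the
#' coordinates are z-scored (`x_hat = (x* - mu_x) / sigma_x`, likewise for
#' `t`). The default `T_char = L_char / U_char` makes the advective time
#' scale the unit of dimensionless time, so the physics residuals carry
#' only the `1/sigma` normalisation factors in front of the derivatives.
#'
#' `mu`/`sigma` default to the exact mean and standard deviation of a
#' uniform distribution over the dimensionless space-time rectangle
#' (`sigma = range / sqrt(12)`), which is how collocation points are drawn.
#'
#' @param U_char Characteristic velocity (m/s), e.g. the peak observed
#'   speed. @param L_char Characteristic length (m), the segment length.
#' @param A_ref Reference area (m^2), the parent equilibrium area.
#' @param rho Blood density (kg/m^3) fixing `p_ref = rho U_char^2`.
#' @param T_char Characteristic time (s); default `L_char / U_char`.
#' @param t_range Physical time window `(t0, t1)` (s) covered by training.
#' @return An object of class `normalization_scales`.
#' @examples
#' sc <- normalization_scales(U_char = 0.45, L_char = 0.01763,
#'                            A_ref = 3.8191e-4, t_range = c(0, 0.89))
#' @export
normalization_scales <- function(U_char, L_char, A_ref, rho = 1060,
                                 T_char = L_char / U_char,
                                 t_range = c(0, 0.89)) {
  if (any(c(U_char, L_char, A_ref, rho, T_char) <= 0))
    abort("all characteristic scales must be positive.")
  ts <- t_range / T_char                # dimensionless time window
  xs <- c(0, 1)                         # dimensionless space window
  structure(list(
    U_char = U_char, L_char = L_char, T_char = T_char,
    A_ref = A_ref, p_ref = rho * U_char^2,
    mu_x = mean(xs), sigma_x = diff(xs) / sqrt(12),
    mu_t = mean(ts), sigma_t = diff(ts) / sqrt(12),
    # residual time coefficient; 1 under the default advective T_char
    lambda_t = L_char / (U_char * T_char)
  ), class = "normalization_scales")
}

#' Map physical fields to dimensionless network variables and back
#'
#' @param fields A data frame (or tibble) with columns among `x_m`, `t_s`,
#'   `area_m2`, `u_m_s`, `pressure_pa`; or the dimensionless counterparts
#'   `x_hat`, `t_hat`, `A_star`, `u_star`, `p_star` for the inverse map.
#' @param scales A [normalization_scales()].
#' @return A tibble with the transformed columns.
#' @examples
#' sc <- normalization_scales(0.45, 0.01763, 3.8191e-4, t_range = c(0, 0.89))
#' d <- tibble::tibble(x_m = 0.01, t_s = 0.3, area_m2 = 4e-4,
#'                     u_m_s = 0.2, pressure_pa = 2500)
#' redimensionalize(nondimensionalize(d, sc), sc)
#' @export
nondimensionalize <- function(fields, scales) {
  s <- scales
  out <- tibble(.rows = nrow(as.data.frame(fields)))
  f <- as_tibble(fields)
  if ("x_m" %in% names(f))
    out$x_hat <- (f$x_m / s$L_char - s$mu_x) / s$sigma_x
  if ("t_s" %in% names(f))
    out$t_hat <- (f$t_s / s$T_char - s$mu_t) / s$sigma_t
  if ("area_m2" %in% names(f)) out$A_star <- f$area_m2 / s$A_ref
  if ("u_m_s" %in% names(f)) out$u_star <- f$u_m_s / s$U_char
  if ("pressure_pa" %in% names(f)) out$p_star <- f$pressure_pa / s$p_ref
  out
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(fields, scales) {
  s <- scales
  f <- as_tibble(fields)
  out <- tibble(.rows = nrow(f))
  if ("x_hat" %in% names(f))
    out$x_m <- (f$x_hat * s$sigma_x + s$mu_x) * s$L_char
  if ("t_hat" %in% names(f))
    out$t_s <- (f$t_hat * s$sigma_t + s$mu_t) * s$T_char
  if ("A_star" %in% names(f)) out$area_m2 <- f$A_star * s$A_ref
  if ("u_star" %in% names(f)) out$u_m_s <- f$u_star * s$U_char
  if ("p_star" %in% names(f)) out$pressure_pa <- f$p_star * s$p_ref
  out
}

#' Scales for each vessel of a bifurcation problem
#'
#' Builds per-vessel [normalization_scales()] sharing one `A_ref` (the
#' parent equilibrium area), one `U_char` (peak observed or expected
#' speed) and one `p_ref`, with per-vessel `L_char` so `x* in [0, 1]`.
#'
#' @param problem A [bifurcation_problem()].
#' @param U_char Shared characteristic velocity; by default the peak
#'   `|u|` over the attached measurements (error if none attached).
#' @return A named list of `normalization_scales`, one per vessel id.
#' @export
problem_scales <- function(problem, U_char = NULL) {
  if (is.null(U_char)) {
    m <- problem$measurements
    if (is.null(m) || !"u_m_s" %in% names(m))
      abort("no velocity measurements attached; give `U_char` explicitly.")
    U_char <- max(abs(m$u_m_s))
    if (U_char <= 0) abort("measured velocities are identically zero.")
  }
  A_ref <- problem$vessels[[1]]$A0
  out <- lapply(problem$vessels, function(v)
    normalization_scales(U_char = U_char, L_char = v$length, A_ref = A_ref,
                         rho = problem$fluid$rho,
                         t_range = c(0, problem$cycle_duration)))
  names(out) <- vapply(problem$vessels, `[[`, "", "id")
  out
}
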