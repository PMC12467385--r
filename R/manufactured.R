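#' Closed-form fields with analytic residuals (method of manufactured
#' solutions)
#'
#' Builds smooth space-time fields on one segment,
#' `A = A0 (1 + a sin(pi x / L) cos(2 pi t / T))`,
#' `u = U sin(pi x / L) sin(2 pi t / T)`,
#' `p = pext + beta (sqrt(A) - sqrt(A0))`,
#' together with their exact partial derivatives and the exact residuals
#' ("forcings") of the mass and momentum equations. The pressure follows
#' the wall law, so the constitutive residual is identically zero. Used
#' as an independent oracle for the residual operators and the
#' physics-loss evaluation.
#'
#' @param segment A [vessel_segment()]. @param fluid A [fluid_model()].
#' @param amplitude Relative area oscillation amplitude `a`.
#' @param U Velocity amplitude (m/s).
#' @param T Period (s).
#' @return An object of class `manufactured_solution`: a list of
#'   vectorised functions `A, u, p, dA_dt, dA_dx, du_dt, du_dx, dp_dx,
#'   forcing_mass, forcing_momentum` of `(x, t)`.
#' @examples
#' ms <- manufactured_solution(
#'   vessel_segment("parent", 0.01763, 3.8191e-4, beta = 2.32586e6),
#'   fluid_model())
#' ms$forcing_mass(0.005, 0.1)
#' @export
manufactured_solution <- function(segment, fluid, amplitude = 0.05,
                                  U = 0.3, T = 0.89) {
  L <- segment$length; A0 <- segment$A0; beta <- segment$beta
  pext <- segment$pext
  kx <- pi / L; wt <- 2 * pi / T
  A <- function(x, t) A0 * (1 + amplitude * sin(kx * x) * cos(wt * t))
  u <- function(x, t) U * sin(kx * x) * sin(wt * t)
  dA_dt <- function(x, t) -A0 * amplitude * wt * sin(kx * x) * sin(wt * t)
  dA_dx <- function(x, t) A0 * amplitude * kx * cos(kx * x) * cos(wt * t)
  du_dt <- function(x, t) U * wt * sin(kx * x) * cos(wt * t)
  du_dx <- function(x, t) U * kx * cos(kx * x) * sin(wt * t)
  p <- function(x, t) pext + beta * (sqrt(A(x, t)) - sqrt(A0))
  dp_dx <- function(x, t) beta / (2 * sqrt(A(x, t))) * dA_dx(x, t)
  forcing_mass <- function(x, t)
    mass_residual(A(x, t), u(x, t), dA_dt(x, t), dA_dx(x, t), du_dx(x, t))
  forcing_momentum <- function(x, t)
    momentum_residual(A(x, t), u(x, t), dp_dx(x, t), du_dt(x, t),
                      du_dx(x, t), fluid, dA_dx = dA_dx(x, t))
  structure(list(
    segment = segment, fluid = fluid, amplitude = amplitude, U = U, T = T,
    A = A, u = u, p = p, dA_dt = dA_dt, dA_dx = dA_dx,
    du_dt = du_dt, du_dx = du_dx, dp_dx = dp_dx,
    forcing_mass = forcing_mass, forcing_momentum = forcing_momentum
  ), class = "manufactured_solution")
}

#' Emit clinical-like boundary measurements from a reference solution
#'
#' Samples the solved fields at each vessel extremity at `n_frames`
#' uniform times over the cycle (emulating a 4D Flow acquisition of 34
#' frames over 0.89 s), optionally adds multiplicative measurement noise,
#' and optionally rescales each area series affinely so its peak-to-trough
#' variation is exactly the assumed physiological fraction. The hidden
#' ground-truth solution is kept alongside for evaluation only.
#'
#' @param solution A [solve_bifurcation()] result.
#' @param n_frames Frames per cycle (default from the solution waveform).
#' @param noise Multiplicative Gaussian noise fraction (0 = exact).
#' @param area_variation If non-`NULL`, rescale each area series so
#'   `min = (1 - area_variation) * max` (default 0.10).
#' @param seed Integer seed controlling the noise.
#' @return An object of class `clinical_dataset`: list with
#'   `measurements` (tibble `vessel_id`, `end`, `x_m`, `t_s`, `u_m_s`,
#'   `area_m2`), `truth` (the solution), `noise`, `seed`.
#' @export
make_clinical_like_dataset <- function(solution,
                                       n_frames = solution$waveform$n_frames,
                                       noise = solution$waveform$noise,
                                       area_variation = 0.10,
                                       seed = 1L) {
  T <- solution$problem$cycle_duration
  tq <- seq(0, T, length.out = n_frames)
  segs <- solution$problem$vessels
  set.seed(seed)
  rows <- purrr::map_dfr(seq_along(segs), function(j) {
    s <- segs[[j]]
    purrr::map_dfr(c(0, s$length), function(xv) {
      tr <- solution_at(solution, s$id, xv)
      u <- approx(tr$t_s, tr$velocity_m_s, tq, rule = 2)$y
      a <- approx(tr$t_s, tr$area_m2, tq, rule = 2)$y
      if (noise > 0) {
        u <- u * (1 + noise * rnorm(length(u)))
        a <- a * (1 + noise * rnorm(length(a)))
      }
      if (!is.null(area_variation)) {
        amax <- max(a); amin <- min(a)
        target_min <- (1 - area_variation) * amax
        if (amax > amin)
          a <- target_min + (a - amin) * (amax - target_min) / (amax - amin)
      }
      tibble(vessel_id = s$id,
             end = if (xv == 0) "inlet" else "outlet",
             x_m = xv, t_s = tq, u_m_s = u, area_m2 = a)
    })
  })
  structure(list(measurements = rows, truth = solution,
                 noise = noise, area_variation = area_variation,
                 seed = seed),
            class = "clinical_dataset")
}

#' @export
print.clinical_dataset <- function(x, ...) {
  cat(sprintf(
    "<clinical_dataset>  %d measurement rows (%d frames), noise = %g, seed = %d\n",
    nrow(x$measurements), length(unique(x$measurements$t_s)), x$noise, x$seed))
  invisible(x)
}
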