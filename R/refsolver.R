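#' Pulsatile inlet waveform specification
#'
#' Describes the inlet velocity waveform of one cardiac cycle as sampled
#' by clinical 4D Flow acquisitions: a systolic pulse (Gaussian bump or
#' half sine) over a diastolic baseline, with the clinical cycle duration
#' (0.89 s) and frame count (34) as defaults.
#'
#' @param cycle_duration Cardiac cycle length (s).
#' @param n_frames Frames per cycle emitted by
#'   [make_clinical_like_dataset()].
#' @param peak_velocity Peak systolic inlet velocity (m/s). The default
#'   0.45 m/s is a physiological main-pulmonary-artery mean velocity and,
#'   for the reference vessel parameters, drives a natural area pulsation
#'   close to 10 percent peak-to-trough.
#' @param shape `"gaussian"` or `"halfsine"` systolic pulse.
#' @param peak_time_frac Pulse centre as a fraction of the cycle.
#' @param width_frac Gaussian pulse standard deviation as a fraction of
#'   the cycle (`shape = "gaussian"`).
#' @param systole_frac Systole duration fraction (`shape = "halfsine"`).
#' @param baseline Diastolic baseline velocity (m/s).
#' @param noise Multiplicative measurement-noise fraction applied by
#'   [make_clinical_like_dataset()].
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(cycle_duration = 0.89, n_frames = 34,
                          peak_velocity = 0.45,
                          shape = c("gaussian", "halfsine"),
                          peak_time_frac = 0.25, width_frac = 0.07,
                          systole_frac = 0.35, baseline = 0, noise = 0) {
  shape <- match.arg(shape)
  if (cycle_duration <= 0) abort("`cycle_duration` must be positive.")
  if (n_frames < 8) abort("`n_frames` must be at least 8.")
  if (noise < 0) abort("`noise` must be non-negative.")
  structure(list(cycle_duration = cycle_duration, n_frames = n_frames,
                 peak_velocity = peak_velocity, shape = shape,
                 peak_time_frac = peak_time_frac, width_frac = width_frac,
                 systole_frac = systole_frac, baseline = baseline,
                 noise = noise),
            class = "waveform_spec")
}

#' Evaluate an inlet waveform
#' @param spec A [waveform_spec()].
#' @param t Times (s); periodic in the cycle duration.
#' @return Inlet velocity (m/s).
#' @export
inlet_velocity <- function(spec, t) {
  T <- spec$cycle_duration
  tau <- t %% T
  if (spec$shape == "gaussian") {
    t0 <- spec$peak_time_frac * T
    w <- spec$width_frac * T
    spec$baseline + (spec$peak_velocity - spec$baseline) *
      exp(-(tau - t0)^2 / (2 * w^2))
  } else {
    Ts <- spec$systole_frac * T
    ifelse(tau < Ts,
           spec$baseline + (spec$peak_velocity - spec$baseline) *
             sin(pi * tau / Ts),
           spec$baseline)
  }
}

#' Space-time discretisation of the reference solver
#'
#' @param n_cells Cells per vessel (at least 20).
#' @param cfl Courant number (at most 0.9).
#' @param n_store Solution snapshots kept per cycle.
#' @return An object of class `solver_grid`.
#' @export
solver_grid <- function(n_cells = 28, cfl = 0.8, n_store = 200) {
  if (n_cells < 20) abort("`n_cells` must be at least 20.")
  if (cfl <= 0 || cfl > 0.9) abort("`cfl` must lie in (0, 0.9].")
  structure(list(n_cells = n_cells, cfl = cfl, n_store = n_store),
            class = "solver_grid")
}

wave_speed_A <- function(A, beta, rho) sqrt(beta * sqrt(A) / (2 * rho))

# One Richtmyer (two-step Lax-Wendroff) update of the interior nodes of a
# single vessel carrying (A, Q = A u). Returns interior values 2..(M-1).
lw_interior_step <- function(A, Q, dx, dt, beta, rho, alpha, KR) {
  flux_Q <- function(A, Q) alpha * Q^2 / A + beta * A^1.5 / (3 * rho)
  M <- length(A)
  F1 <- Q
  F2 <- flux_Q(A, Q)
  Ah <- 0.5 * (A[-M] + A[-1]) - dt / (2 * dx) * diff(F1)
  Qh <- 0.5 * (Q[-M] + Q[-1]) - dt / (2 * dx) * diff(F2)
  if (KR != 0) Qh <- Qh + (dt / 2) * KR * 0.5 * (Q[-M] / A[-M] + Q[-1] / A[-1])
  if (any(Ah <= 0)) abort("negative area in half step: reduce CFL or amplitude.")
  F1h <- Qh
  F2h <- flux_Q(Ah, Qh)
  Ai <- A[2:(M - 1)] - dt / dx * diff(F1h)
  Qi <- Q[2:(M - 1)] - dt / dx * diff(F2h)
  if (KR != 0) Qi <- Qi + dt * KR * 0.5 * (Qh[-(M - 1)] / Ah[-(M - 1)] +
                                           Qh[-1] / Ah[-1])
  list(A = Ai, Q = Qi)
}

# Riemann invariant value advected to a boundary: linear interpolation at
# the foot of the outgoing characteristic.
char_foot <- function(W, lambda, dt, dx, side) {
  M <- length(W)
  if (side == "left") {        # outgoing u - c runs leftward; foot at x > 0
    frac <- min(max(-lambda * dt / dx, 0), 1)
    (1 - frac) * W[1] + frac * W[2]
  } else {                     # outgoing u + c runs rightward; foot at x < L
    frac <- min(max(lambda * dt / dx, 0), 1)
    (1 - frac) * W[M] + frac * W[M - 1]
  }
}

# Newton solve of the junction system: outgoing invariants of the three
# vessels + flow continuity + two total-pressure continuities.
solve_junction <- function(W1p, W2m, W3m, segs, rho, guess, tol = 1e-12,
                           maxit = 30) {
  b <- vapply(segs, `[[`, 1.0, "beta")
  A0 <- vapply(segs, `[[`, 1.0, "A0")
  pe <- vapply(segs, `[[`, 1.0, "pext")
  v <- guess  # (A1, u1, A2, u2, A3, u3)
  scale_p <- rho * max(wave_speed_A(A0, b, rho))^2
  scale_q <- max(A0)
  for (it in seq_len(maxit)) {
    A <- v[c(1, 3, 5)]; u <- v[c(2, 4, 6)]
    if (any(A <= 0)) abort("junction Newton produced non-positive area.")
    c_ <- wave_speed_A(A, b, rho)
    p <- pe + b * (sqrt(A) - sqrt(A0))
    dc_dA <- b / (8 * rho * sqrt(A) * c_)
    dp_dA <- b / (2 * sqrt(A))
    g <- c(u[1] + 4 * c_[1] - W1p,
           u[2] - 4 * c_[2] - W2m,
           u[3] - 4 * c_[3] - W3m,
           A[1] * u[1] - A[2] * u[2] - A[3] * u[3],
           p[1] + 0.5 * rho * u[1]^2 - p[2] - 0.5 * rho * u[2]^2,
           p[1] + 0.5 * rho * u[1]^2 - p[3] - 0.5 * rho * u[3]^2)
    J <- matrix(0, 6, 6)
    J[1, 1] <- 4 * dc_dA[1]; J[1, 2] <- 1
    J[2, 3] <- -4 * dc_dA[2]; J[2, 4] <- 1
    J[3, 5] <- -4 * dc_dA[3]; J[3, 6] <- 1
    J[4, ] <- c(u[1], A[1], -u[2], -A[2], -u[3], -A[3])
    J[5, ] <- c(dp_dA[1], rho * u[1], -dp_dA[2], -rho * u[2], 0, 0)
    J[6, ] <- c(dp_dA[1], rho * u[1], 0, 0, -dp_dA[3], -rho * u[3])
    step <- solve(J, -g)
    v <- v + step
    err <- max(abs(g[1:3]) / max(c_), abs(g[4]) / scale_q,
               abs(g[5:6]) / scale_p)
    if (err < tol && max(abs(step) / pmax(abs(v), 1e-12)) < tol) break
  }
  v
}

#' Solve the bifurcation hemodynamics with a Lax-Wendroff reference solver
#'
#' Integrates the 1D mass/momentum system with the elastic wall law on
#' each vessel (two-step Lax-Wendroff on the conservative variables
#' `(A, A u)`), coupling the parent outlet to both daughter inlets at
#' every time step through a Newton solve of flow continuity, the two
#' total-pressure continuities, and the three outgoing characteristic
#' invariants `u +/- 4c`. The parent inlet imposes the velocity waveform
#' (area follows the outgoing invariant); daughter outlets use
#' non-reflecting characteristic conditions. The run covers `n_cycles`
#' cardiac cycles so initial transients wash out; only the last cycle is
#' returned.
#'
#' @param problem A [bifurcation_problem()].
#' @param waveform A [waveform_spec()] for the parent inlet.
#' @param grid A [solver_grid()].
#' @param n_cycles Number of cycles to integrate (default 3).
#' @return An object of class `bifurcation_solution`: snapshots of
#'   `(A, u, p)` per vessel over the last cycle, the per-step junction
#'   states, and diagnostics. Use [solution_fields()] for a tidy view.
#' @examples
#' \donttest{
#' sol <- solve_bifurcation(pa_problem(), waveform_spec(), solver_grid())
#' dplyr::glimpse(solution_fields(sol))
#' }
#' @export
solve_bifurcation <- function(problem, waveform = waveform_spec(),
                              grid = solver_grid(), n_cycles = 3) {
  segs <- problem$vessels
  fl <- problem$fluid
  rho <- fl$rho
  T <- problem$cycle_duration
  M <- grid$n_cells + 1L
  dx <- vapply(segs, function(s) s$length / grid$n_cells, 1.0)
  x <- lapply(seq_along(segs), function(j) seq(0, segs[[j]]$length,
                                               length.out = M))
  A <- lapply(segs, function(s) rep(s$A0, M))
  Q <- lapply(segs, function(s) rep(0, M))
  b <- vapply(segs, `[[`, 1.0, "beta")
  A0 <- vapply(segs, `[[`, 1.0, "A0")

  t_end <- n_cycles * T
  t_store0 <- (n_cycles - 1) * T
  store_times <- seq(t_store0, t_end, length.out = grid$n_store)
  next_store <- 1L
  snapA <- lapply(1:3, function(j) matrix(NA_real_, M, grid$n_store))
  snapU <- lapply(1:3, function(j) matrix(NA_real_, M, grid$n_store))
  snap_t <- rep(NA_real_, grid$n_store)

  jn_t <- list(); jn_state <- list()
  jn_guess <- c(A0[1], 0, A0[2], 0, A0[3], 0)
  t <- 0
  step <- 0L
  while (t < t_end - 1e-14) {
    cs <- lapply(1:3, function(j) wave_speed_A(A[[j]], b[j], rho))
    smax <- max(vapply(1:3, function(j)
      max(abs(Q[[j]] / A[[j]]) + cs[[j]]), 1.0))
    dt <- min(grid$cfl * min(dx) / smax, t_end - t)
    tn <- t + dt

    u <- lapply(1:3, function(j) Q[[j]] / A[[j]])
    # invariants at time n for boundary feet
    Wp <- lapply(1:3, function(j) u[[j]] + 4 * cs[[j]])
    Wm <- lapply(1:3, function(j) u[[j]] - 4 * cs[[j]])

    interior <- lapply(1:3, function(j)
      lw_interior_step(A[[j]], Q[[j]], dx[j], dt, b[j], rho, fl$alpha, fl$KR))

    # parent inlet: prescribed velocity, area from the outgoing invariant
    uin <- inlet_velocity(waveform, tn)
    Wm_foot <- char_foot(Wm[[1]], u[[1]][1] - cs[[1]][1], dt, dx[1], "left")
    c_in <- (uin - Wm_foot) / 4
    if (c_in <= 0) abort("inlet characteristic collapsed; check waveform.")
    A_in <- (2 * rho * c_in^2 / b[1])^2

    # daughter outlets: non-reflecting (incoming invariant at equilibrium)
    out_bc <- lapply(2:3, function(j) {
      Wp_foot <- char_foot(Wp[[j]], u[[j]][M] + cs[[j]][M], dt, dx[j], "right")
      Wm_eq <- -4 * wave_speed_A(A0[j], b[j], rho)
      u_o <- (Wp_foot + Wm_eq) / 2
      c_o <- (Wp_foot - Wm_eq) / 8
      list(A = (2 * rho * c_o^2 / b[j])^2, u = u_o)
    })

    # junction: parent outlet <-> daughter inlets
    W1p <- char_foot(Wp[[1]], u[[1]][M] + cs[[1]][M], dt, dx[1], "right")
    W2m <- char_foot(Wm[[2]], u[[2]][1] - cs[[2]][1], dt, dx[2], "left")
    W3m <- char_foot(Wm[[3]], u[[3]][1] - cs[[3]][1], dt, dx[3], "left")
    jv <- solve_junction(W1p, W2m, W3m, segs, rho, jn_guess)
    jn_guess <- jv

    A[[1]] <- c(A_in, interior[[1]]$A, jv[1])
    Q[[1]] <- c(A_in * uin, interior[[1]]$Q, jv[1] * jv[2])
    A[[2]] <- c(jv[3], interior[[2]]$A, out_bc[[1]]$A)
    Q[[2]] <- c(jv[3] * jv[4], interior[[2]]$Q, out_bc[[1]]$A * out_bc[[1]]$u)
    A[[3]] <- c(jv[5], interior[[3]]$A, out_bc[[2]]$A)
    Q[[3]] <- c(jv[5] * jv[6], interior[[3]]$Q, out_bc[[2]]$A * out_bc[[2]]$u)
    for (j in 1:3) if (any(A[[j]] <= 0))
      abort(sprintf("negative area in vessel %d at t = %.5f s.", j, tn))

    t <- tn
    step <- step + 1L
    if (t >= t_store0 - 1e-14) {
      jn_t[[length(jn_t) + 1L]] <- t
      jn_state[[length(jn_state) + 1L]] <- jv
      while (next_store <= grid$n_store &&
             t >= store_times[next_store] - 1e-12) {
        snap_t[next_store] <- t
        for (j in 1:3) {
          snapA[[j]][, next_store] <- A[[j]]
          snapU[[j]][, next_store] <- Q[[j]] / A[[j]]
        }
        next_store <- next_store + 1L
      }
    }
  }

  jn <- as_tibble(as.data.frame(do.call(rbind, jn_state)))
  names(jn) <- c("A1", "u1", "A2", "u2", "A3", "u3")
  jn$t_s <- unlist(jn_t)
  jn$p1 <- constitutive_pressure(jn$A1, segs[[1]])
  jn$p2 <- constitutive_pressure(jn$A2, segs[[2]])
  jn$p3 <- constitutive_pressure(jn$A3, segs[[3]])
  jn$flow_residual <- jn$A1 * jn$u1 - jn$A2 * jn$u2 - jn$A3 * jn$u3
  jn$bernoulli_residual_12 <- jn$p1 + 0.5 * rho * jn$u1^2 -
    jn$p2 - 0.5 * rho * jn$u2^2
  jn$bernoulli_residual_13 <- jn$p1 + 0.5 * rho * jn$u1^2 -
    jn$p3 - 0.5 * rho * jn$u3^2

  keep <- !is.na(snap_t)
  structure(list(
    problem = problem, waveform = waveform, grid = grid,
    n_cycles = n_cycles,
    t = snap_t[keep] - t_store0,
    x = x,
    A = lapply(snapA, function(m) m[, keep, drop = FALSE]),
    u = lapply(snapU, function(m) m[, keep, drop = FALSE]),
    junction = jn,
    n_steps = step
  ), class = "bifurcation_solution")
}

#' @export
print.bifurcation_solution <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_solution>  %d vessels, %d snapshots over one cycle (%.3g s), %d steps total\n",
    length(x$A), length(x$t), x$problem$cycle_duration, x$n_steps))
  cat(sprintf("  max |junction flow residual|: %.3g m^3/s; peak flow: %.3g m^3/s\n",
              max(abs(x$junction$flow_residual)), peak_flow(x)))
  invisible(x)
}

#' Peak junction volume flux of a solution (m^3/s)
#' @param solution A `bifurcation_solution`.
#' @export
peak_flow <- function(solution) max(abs(solution$junction$A1 * solution$junction$u1))

#' Tidy view of a reference solution
#'
#' @param solution A `bifurcation_solution`.
#' @return A tibble with columns `vessel_id`, `x_m`, `t_s`, `area_m2`,
#'   `velocity_m_s`, `pressure_pa` over the stored space-time grid of the
#'   final cycle.
#' @export
solution_fields <- function(solution) {
  segs <- solution$problem$vessels
  purrr::map_dfr(seq_along(segs), function(j) {
    A <- solution$A[[j]]; u <- solution$u[[j]]
    tibble(
      vessel_id = segs[[j]]$id,
      x_m = rep(solution$x[[j]], times = length(solution$t)),
      t_s = rep(solution$t, each = length(solution$x[[j]])),
      area_m2 = as.vector(A),
      velocity_m_s = as.vector(u),
      pressure_pa = as.vector(constitutive_pressure(A, segs[[j]]))
    )
  })
}

#' Interpolate a solution field at one location over time
#'
#' @param solution A `bifurcation_solution`.
#' @param vessel_id Vessel label.
#' @param x Position along the vessel (m).
#' @return Tibble `t_s`, `area_m2`, `velocity_m_s`, `pressure_pa`.
#' @export
solution_at <- function(solution, vessel_id, x) {
  ids <- vapply(solution$problem$vessels, `[[`, "", "id")
  j <- match(vessel_id, ids)
  if (is.na(j)) abort(paste0("unknown vessel id: ", vessel_id))
  xg <- solution$x[[j]]
  if (x < min(xg) || x > max(xg)) abort("`x` outside the vessel.")
  i <- findInterval(x, xg, all.inside = TRUE)
  w <- (x - xg[i]) / (xg[i + 1] - xg[i])
  interp <- function(m) (1 - w) * m[i, ] + w * m[i + 1, ]
  A <- interp(solution$A[[j]])
  tibble(t_s = solution$t,
         area_m2 = A,
         velocity_m_s = interp(solution$u[[j]]),
         pressure_pa = constitutive_pressure(A, solution$problem$vessels[[j]]))
}

#' Single-vessel reference solve (used for wave-speed verification)
#'
#' Same interior scheme and characteristic boundaries as
#' [solve_bifurcation()], for one segment with a prescribed inlet velocity
#' and a non-reflecting outlet.
#'
#' @param segment A [vessel_segment()]. @param fluid A [fluid_model()].
#' @param inlet Function of time returning the inlet velocity (m/s).
#' @param t_end Final time (s).
#' @param grid A [solver_grid()].
#' @param store_every Store every k-th step (default 1).
#' @return List with `t` (times), `x` (nodes), `A`, `u` matrices
#'   (nodes x times).
#' @export
solve_vessel <- function(segment, fluid, inlet, t_end,
                         grid = solver_grid(), store_every = 1L) {
  rho <- fluid$rho
  M <- grid$n_cells + 1L
  dx <- segment$length / grid$n_cells
  x <- seq(0, segment$length, length.out = M)
  A <- rep(segment$A0, M); Q <- rep(0, M)
  b <- segment$beta
  ts <- c(0); As <- list(A); Us <- list(Q / A)
  t <- 0; k <- 0L
  while (t < t_end - 1e-14) {
    cs <- wave_speed_A(A, b, rho)
    u <- Q / A
    dt <- min(grid$cfl * dx / max(abs(u) + cs), t_end - t)
    tn <- t + dt
    Wp <- u + 4 * cs; Wm <- u - 4 * cs
    interior <- lw_interior_step(A, Q, dx, dt, b, rho, fluid$alpha, fluid$KR)
    uin <- inlet(tn)
    Wm_foot <- char_foot(Wm, u[1] - cs[1], dt, dx, "left")
    c_in <- (uin - Wm_foot) / 4
    if (c_in <= 0) abort("inlet characteristic collapsed.")
    A_in <- (2 * rho * c_in^2 / b)^2
    Wp_foot <- char_foot(Wp, u[M] + cs[M], dt, dx, "right")
    Wm_eq <- -4 * wave_speed_A(segment$A0, b, rho)
    u_o <- (Wp_foot + Wm_eq) / 2
    c_o <- (Wp_foot - Wm_eq) / 8
    A_o <- (2 * rho * c_o^2 / b)^2
    A <- c(A_in, interior$A, A_o)
    Q <- c(A_in * uin, interior$Q, A_o * u_o)
    if (any(A <= 0)) abort(sprintf("negative area at t = %.5f s.", tn))
    t <- tn; k <- k + 1L
    if (k %% store_every == 0L) {
      ts <- c(ts, t); As <- c(As, list(A)); Us <- c(Us, list(Q / A))
    }
  }
  list(t = ts, x = x, A = do.call(cbind, As), u = do.call(cbind, Us))
}
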