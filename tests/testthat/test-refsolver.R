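test_that("equilibrium is a fixed point of the solver", {
  p <- bifurcation_problem(
    vessel_segment("parent", 0.01763, 3.8191e-4, beta = 2.32586e6),
    vessel_segment("left", 0.01892, 1.7338e-4, beta = 3.45194e6),
    vessel_segment("right", 0.02024, 1.7491e-4, beta = 3.43681e6),
    cycle_duration = 0.1)
  wf <- waveform_spec(cycle_duration = 0.1, peak_velocity = 0, baseline = 0)
  sol <- solve_bifurcation(p, wf, solver_grid(n_cells = 20, n_store = 20),
                           n_cycles = 1)
  for (j in 1:3) {
    expect_lt(max(abs(sol$A[[j]] / p$vessels[[j]]$A0 - 1)), 1e-10)
    expect_lt(max(abs(sol$u[[j]])), 1e-10)
  }
  f <- solution_fields(sol)
  expect_lt(max(abs(f$pressure_pa - mmhg_to_pa(16))), 1e-6)
})

test_that("junction states satisfy flow and total-pressure continuity", {
  sol <- fx_solution()
  jn <- sol$junction
  qpk <- peak_flow(sol)
  ppk <- max(abs(jn$p1))
  expect_lt(max(abs(jn$flow_residual)), 1e-8 * qpk)
  expect_lt(max(abs(c(jn$bernoulli_residual_12, jn$bernoulli_residual_13))),
            1e-6 * ppk)
  # the same states, pushed through the public residual operators
  r <- junction_flow_residual(list(A = jn$A1, u = jn$u1),
                              list(A = jn$A2, u = jn$u2),
                              list(A = jn$A3, u = jn$u3))
  expect_lt(max(abs(r)), 1e-8 * qpk)
  rb <- junction_bernoulli_residuals(list(p = jn$p1, u = jn$u1),
                                     list(p = jn$p2, u = jn$u2),
                                     list(p = jn$p3, u = jn$u3),
                                     rho = sol$problem$fluid$rho)
  expect_lt(max(abs(c(rb$r12, rb$r13))), 1e-6 * ppk)
})

test_that("net volume flux into the junction is conserved over the cycle", {
  sol <- fx_solution()
  jn <- sol$junction
  dt <- diff(jn$t_s)
  mid <- (jn$flow_residual[-1] + jn$flow_residual[-nrow(jn)]) / 2
  net_volume <- sum(mid * dt)
  stroke <- sum((jn$A1 * jn$u1)[-1] * dt)   # parent stroke volume
  expect_lt(abs(net_volume), 1e-3 * abs(stroke))
})

test_that("solver pressure is the constitutive pressure of its area", {
  sol <- fx_solution()
  f <- solution_fields(sol)
  for (j in 1:3) {
    seg <- sol$problem$vessels[[j]]
    fj <- f[f$vessel_id == seg$id, ]
    expect_equal(fj$pressure_pa, constitutive_pressure(fj$area_m2, seg),
                 tolerance = 1e-14)
  }
})

test_that("small-amplitude pulses propagate at the analytic wave speed", {
  seg <- vessel_segment("tube", length = 0.5, A0 = 3.8191e-4,
                        beta = 2.32586e6)
  fl <- fluid_model()
  c0 <- segment_wave_speed(seg, fl$rho)
  expect_equal(c0, sqrt(seg$beta * sqrt(seg$A0) / (2 * fl$rho)))
  inlet <- function(t) 0.01 * exp(-(t - 0.012)^2 / (2 * 0.004^2))
  out <- solve_vessel(seg, fl, inlet, t_end = 0.12,
                      grid = solver_grid(n_cells = 100, cfl = 0.8))
  x1 <- 0.1; x2 <- 0.4
  peak_time <- function(xq) {
    i <- which.min(abs(out$x - xq))
    u <- out$u[i, ]
    k <- which.max(u)
    # parabolic refinement of the peak time
    tt <- out$t[(k - 1):(k + 1)]; uu <- u[(k - 1):(k + 1)]
    a <- (uu[1] - 2 * uu[2] + uu[3])
    if (abs(a) < 1e-30) return(tt[2])
    tt[2] + 0.5 * (uu[1] - uu[3]) / a * (tt[3] - tt[1]) / 2
  }
  c_measured <- (x2 - x1) / (peak_time(x2) - peak_time(x1))
  expect_lt(abs(c_measured - c0) / c0, 0.05)
})

test_that("grid refinement shows self-convergence of the pressure field", {
  p <- fx_problem()
  p$cycle_duration <- 0.4
  wf <- waveform_spec(cycle_duration = 0.4, peak_velocity = 0.3)
  mid_p <- function(n_cells) {
    sol <- solve_bifurcation(p, wf,
                             solver_grid(n_cells = n_cells, n_store = 60),
                             n_cycles = 2)
    stats::approx(sol$t, solution_at(sol, "parent",
                                     p$vessels[[1]]$length / 2)$pressure_pa,
                  seq(0.02, 0.38, length.out = 40))$y
  }
  p20 <- mid_p(20); p40 <- mid_p(40); p80 <- mid_p(80)
  err_coarse <- sqrt(mean((p20 - p40)^2))
  err_fine <- sqrt(mean((p40 - p80)^2))
  expect_lt(err_fine, err_coarse)
})

test_that("manufactured solution: zero forcing at equilibrium, oracle match,
           near-linear amplitude scaling", {
  seg <- vessel_segment("parent", 0.01763, 3.8191e-4, beta = 2.32586e6,
                        pext = 2133.16)
  fl <- fluid_model()
  ms0 <- manufactured_solution(seg, fl, amplitude = 0, U = 0)
  xs <- c(0.002, 0.009, 0.015); ts <- c(0.1, 0.4, 0.8)
  expect_lt(max(abs(ms0$forcing_mass(xs, ts))), 1e-14)
  expect_lt(max(abs(ms0$forcing_momentum(xs, ts))), 1e-14)

  # residual operators fed with the analytic derivatives reproduce the
  # forcings (same algebra path as the physics loss)
  ms <- manufactured_solution(seg, fl, amplitude = 0.05, U = 0.3)
  got_mass <- mass_residual(ms$A(xs, ts), ms$u(xs, ts), ms$dA_dt(xs, ts),
                            ms$dA_dx(xs, ts), ms$du_dx(xs, ts))
  expect_rel_equal(got_mass, ms$forcing_mass(xs, ts), 1e-12)

  # amplitude sweep: mass forcing is linear in the area amplitude when
  # the velocity field is held fixed
  f1 <- manufactured_solution(seg, fl, amplitude = 1e-3,
                              U = 0.3)$forcing_mass(xs, ts)
  f2 <- manufactured_solution(seg, fl, amplitude = 2e-3,
                              U = 0.3)$forcing_mass(xs, ts)
  f0 <- manufactured_solution(seg, fl, amplitude = 0,
                              U = 0.3)$forcing_mass(xs, ts)
  expect_rel_equal(f2 - f0, 2 * (f1 - f0), 1e-6)
})

test_that("clinical-like dataset: exact sampling, variation, determinism", {
  sol <- fx_solution()
  ds_raw <- make_clinical_like_dataset(sol, noise = 0,
                                       area_variation = NULL, seed = 1)
  m <- ds_raw$measurements
  expect_equal(nrow(m), 3 * 2 * 34)
  # noise-free series equal the solver fields at the sample times
  tr <- solution_at(sol, "parent", 0)
  sub <- m[m$vessel_id == "parent" & m$end == "inlet", ]
  want_u <- approx(tr$t_s, tr$velocity_m_s, sub$t_s, rule = 2)$y
  expect_equal(sub$u_m_s, want_u, tolerance = 1e-12)

  # default emission rescales the areas to the assumed 10% variation
  ds <- make_clinical_like_dataset(sol, noise = 0, seed = 1)
  for (g in split(ds$measurements, paste(ds$measurements$vessel_id,
                                         ds$measurements$end))) {
    expect_equal(min(g$area_m2) / max(g$area_m2), 0.9, tolerance = 1e-10)
  }
  # the raw hemodynamics already pulsate close to that fraction
  raw_var <- 1 - min(sub$area_m2) / max(sub$area_m2)
  expect_gt(raw_var, 0.07); expect_lt(raw_var, 0.13)

  ds_a <- make_clinical_like_dataset(sol, noise = 0.02, seed = 7)
  ds_b <- make_clinical_like_dataset(sol, noise = 0.02, seed = 7)
  expect_equal(ds_a$measurements, ds_b$measurements)
  ds_c <- make_clinical_like_dataset(sol, noise = 0.02, seed = 8)
  expect_false(isTRUE(all.equal(ds_a$measurements$u_m_s,
                                ds_c$measurements$u_m_s)))
})

test_that("waveform specification validates and evaluates", {
  wf <- waveform_spec()
  expect_equal(wf$cycle_duration, 0.89)
  expect_equal(wf$n_frames, 34)
  expect_equal(max(inlet_velocity(wf, seq(0, 0.89, by = 1e-3))),
               wf$peak_velocity, tolerance = 1e-3)
  # periodic
  expect_equal(inlet_velocity(wf, 0.3), inlet_velocity(wf, 0.3 + 0.89))
  hs <- waveform_spec(shape = "halfsine")
  expect_equal(inlet_velocity(hs, hs$systole_frac * 0.89 / 2),
               hs$peak_velocity)
  expect_equal(inlet_velocity(hs, 0.8), 0)
  expect_error(waveform_spec(n_frames = 4), "n_frames")
  expect_error(solver_grid(n_cells = 10), "n_cells")
  expect_error(solver_grid(cfl = 1.2), "cfl")
})
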