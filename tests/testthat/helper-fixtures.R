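# Shared fixtures. The reference solver run is cached for the session so
# several test files can reuse one solution.

.fx_cache <- new.env(parent = emptyenv())

fx_problem <- function() pa_problem()

# Reference solution of the default scenario (last of 3 cycles).
fx_solution <- function() {
  if (is.null(.fx_cache$sol)) {
    .fx_cache$sol <- solve_bifurcation(fx_problem(), waveform_spec(),
                                       solver_grid(), n_cycles = 3)
  }
  .fx_cache$sol
}

# Clinical-like dataset (34 frames, no noise) from the cached solution.
fx_dataset <- function(seed = 1L) {
  make_clinical_like_dataset(fx_solution(), noise = 0, seed = seed)
}

fx_problem_with_measurements <- function(seed = 1L) {
  p <- fx_problem()
  bifurcation_problem(p$vessels[[1]], p$vessels[[2]], p$vessels[[3]],
                      p$fluid, measurements = fx_dataset(seed)$measurements)
}

# Analytic (non-solver) measurements for cheap training-plumbing tests.
fx_analytic_measurements <- function(problem = fx_problem(),
                                     n_frames = 34) {
  T <- problem$cycle_duration
  tq <- seq(0, T, length.out = n_frames)
  purrr::map_dfr(seq_along(problem$vessels), function(j) {
    s <- problem$vessels[[j]]
    purrr::map_dfr(c(0, s$length), function(xv) {
      tibble::tibble(
        vessel_id = s$id, end = if (xv == 0) "inlet" else "outlet",
        x_m = xv, t_s = tq,
        u_m_s = 0.3 * sin(pi * tq / T)^2 + 0.01 * j,
        area_m2 = s$A0 * (1 + 0.05 * sin(2 * pi * tq / T)))
    })
  })
}

fx_small_assembly <- function(seed = 5L, width = 12L, epochs = 10L) {
  p <- fx_problem()
  prob <- bifurcation_problem(p$vessels[[1]], p$vessels[[2]], p$vessels[[3]],
                              p$fluid, fx_analytic_measurements(p))
  assemble_pinn(prob, network_spec(2, width),
                training_control(epochs = epochs, n_collocation = 60,
                                 n_boundary = 11, log_every = 1,
                                 seed = seed))
}

# A model whose networks are frozen at the per-vessel equilibrium state:
# zero weights, output biases set to (A0_j / A_ref, 0, pext / p_ref).
fx_frozen_model <- function(p_star = NULL) {
  asm <- fx_small_assembly()
  A_ref <- asm$problem$vessels[[1]]$A0
  nets <- lapply(1:3, function(j) {
    net <- asm$nets[[j]]
    sc <- asm$scales[[j]]
    seg <- asm$problem$vessels[[j]]
    for (l in seq_along(net$W)) net$W[[l]][] <- 0
    for (l in seq_along(net$b)) net$b[[l]][] <- 0
    net$out_scale <- c(1, 1, 1)
    net$out_shift <- c(seg$A0 / A_ref, 0,
                       if (is.null(p_star)) seg$pext / sc$p_ref else p_star)
    net
  })
  structure(list(nets = nets, scales = asm$scales, problem = asm$problem,
                 network = asm$network, control = asm$control,
                 history = tibble::tibble(), final = NULL, elapsed_s = 0),
            class = "pinn_model")
}

expect_rel_equal <- function(got, want, tol) {
  expect_lt(max(abs(got - want) / pmax(abs(want), .Machine$double.eps)), tol)
}
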