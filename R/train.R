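#' Training configuration for the bifurcation PINN
#'
#' Defaults follow the reference training setup: Adam with a fixed
#' learning rate of 0.001 for 50,000 epochs, 2000 collocation points per
#' vessel, 101 uniformly spaced time samples for the boundary data and
#' interface conditions, unit loss weights, and a zero initial-velocity
#' condition. All randomness (weight initialisation, collocation
#' sampling) derives deterministically from `seed`.
#'
#' @param epochs Number of Adam steps.
#' @param learning_rate Fixed Adam learning rate.
#' @param n_collocation Interior collocation points per vessel, sampled
#'   once (uniformly over the normalized space-time rectangle) before
#'   training.
#' @param n_boundary Number of uniform time samples at each measurement
#'   location, of interface times, and of initial-condition points.
#' @param weights Named weights of the loss components
#'   (`physics`, `data`, `interface`); the reference composite loss is
#'   their unweighted sum.
#' @param ic_zero_velocity Enforce `u(x, 0) = 0` as an extra data term.
#' @param log_every Record component losses every this many epochs.
#' @param seed Master integer seed.
#' @return An object of class `training_control`.
#' @export
training_control <- function(epochs = 50000, learning_rate = 0.001,
                             n_collocation = 2000, n_boundary = 101,
                             weights = c(physics = 1, data = 1,
                                         interface = 1),
                             ic_zero_velocity = TRUE,
                             log_every = 100, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate >= 0, n_collocation >= 1,
            n_boundary >= 2)
  w <- c(physics = 1, data = 1, interface = 1)
  w[names(weights)] <- weights
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 n_collocation = as.integer(n_collocation),
                 n_boundary = as.integer(n_boundary),
                 weights = w, ic_zero_velocity = isTRUE(ic_zero_velocity),
                 log_every = as.integer(log_every),
                 seed = as.integer(seed)),
            class = "training_control")
}

norm_coords <- function(x_star, t_star, scales) {
  rbind((x_star - scales$mu_x) / scales$sigma_x,
        (t_star - scales$mu_t) / scales$sigma_t)
}

#' Assemble networks, collocation sets and normalized training data
#'
#' Builds everything [train_pinn()] needs: one network per vessel
#' (Glorot-initialised from per-vessel seeds), a fixed uniform collocation
#' set per vessel, boundary measurement targets interpolated to
#' `n_boundary` uniform times (quadratic Lagrange smoothing), the
#' zero-initial-velocity points, and the shared interface times. The
#' measurement locations are the segment endpoints; pressure is never a
#' target.
#'
#' @param problem A [bifurcation_problem()] with measurements attached.
#' @param network A [network_spec()] (its `init_seed` is combined with
#'   the control seed per vessel).
#' @param control A [training_control()].
#' @return An object of class `pinn_assembly`.
#' @export
assemble_pinn <- function(problem, network = network_spec(),
                          control = training_control()) {
  if (is.null(problem$measurements))
    abort("`problem` has no boundary measurements attached.")
  scales <- problem_scales(problem)
  segs <- problem$vessels
  T <- problem$cycle_duration
  nb <- control$n_boundary
  tb <- seq(0, T, length.out = nb)

  parts <- lapply(seq_along(segs), function(j) {
    s <- segs[[j]]; sc <- scales[[j]]
    set.seed(control$seed + 7919L * j)
    xs <- runif(control$n_collocation)                 # x* in [0, 1]
    ts <- runif(control$n_collocation, 0, T / sc$T_char)
    Xc <- norm_coords(xs, ts, sc)

    m <- problem$measurements[problem$measurements$vessel_id == s$id, ]
    if (!nrow(m)) abort(paste0("no measurements for vessel ", s$id))
    bd <- purrr::map_dfr(unique(m$end), function(e) {
      me <- m[m$end == e, ]
      u <- smooth_series(me[, c("t_s", "u_m_s")], n_out = nb)$u_m_s
      a <- smooth_series(me[, c("t_s", "area_m2")], n_out = nb,
                         value = "area_m2")$area_m2
      tibble(x_star = if (e == "inlet") 0 else 1, t_s = tb,
             u_star = u / sc$U_char, A_star = a / sc$A_ref)
    })
    Xd <- norm_coords(bd$x_star, bd$t_s / sc$T_char, sc)

    Xic <- if (control$ic_zero_velocity)
      norm_coords(seq(0, 1, length.out = nb), rep(0, nb), sc)
    else matrix(0, 2, 0)

    # junction coordinate: parent outlet (x* = 1), daughter inlets (x* = 0)
    xj <- if (j == 1L) 1 else 0
    Xi <- norm_coords(rep(xj, nb), tb / sc$T_char, sc)

    X <- cbind(Xc, Xd, Xic, Xi)
    nC <- ncol(Xc); nD <- ncol(Xd); nI <- ncol(Xic)

    # output statistics: z-scores of the measured series, with the
    # pressure statistics propagated from the area spread through the
    # wall law; they set both the networks' affine output maps and the
    # normalization of the wall-law residual
    muA <- mean(bd$A_star); sA <- max(sd(bd$A_star), 1e-3)
    muU <- mean(bd$u_star); sU <- max(sd(bd$u_star), 1e-3)
    b0_raw <- (s$pext - s$beta * sqrt(s$A0)) / sc$p_ref
    b1_raw <- s$beta * sqrt(sc$A_ref) / sc$p_ref
    muP <- b0_raw + b1_raw * sqrt(muA)
    sP <- max(b1_raw * sA / (2 * sqrt(muA)), 1e-3)

    list(
      X = X,
      colloc_cols = seq_len(nC),
      u_cols = nC + seq_len(nD), u_target = bd$u_star,
      A_cols = nC + seq_len(nD), A_target = bd$A_star,
      ic_cols = if (nI) nC + nD + seq_len(nI) else integer(0),
      iface_cols = nC + nD + nI + seq_len(nb),
      out_shift = c(muA, muU, muP),
      out_scale = c(sA, sU, sP),
      consts = residual_constants(s, problem$fluid, sc,
                                  p_resid_scale = sP)
    )
  })

  # Glorot weights from per-vessel seeds. The affine output map of each
  # network is set from the boundary-data statistics (the normalization
  # and recovery of the unknowns): outputs are z-scored residuals around
  # the measured means, with the pressure statistics propagated from the
  # area statistics through the wall law. Training therefore starts at
  # the mean state with a correctly pinned pressure gauge, and every
  # output works at unit scale regardless of its physical amplitude.
  nets <- lapply(seq_along(segs), function(j) {
    sp <- network
    sp$init_seed <- network$init_seed + control$seed + 131L * j
    net <- build_network(sp)
    net$out_shift <- parts[[j]]$out_shift
    net$out_scale <- parts[[j]]$out_scale
    net
  })

  structure(list(nets = nets, parts = parts, scales = scales,
                 problem = problem, network = network, control = control),
            class = "pinn_assembly")
}

adam_init <- function(net) {
  zero <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b))
}

adam_step <- function(net, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- b1 * st$mW[[l]] + (1 - b1) * g$W[[l]]
    st$vW[[l]] <- b2 * st$vW[[l]] + (1 - b2) * g$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- b1 * st$mb[[l]] + (1 - b1) * g$b[[l]]
    st$vb[[l]] <- b2 * st$vb[[l]] + (1 - b2) * g$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

#' Train the three-network PINN
#'
#' Minimises the composite loss (per-vessel physics residuals + boundary
#' data mismatch + junction interface continuity) with Adam at a fixed
#' learning rate, recording the per-component loss history. Training is
#' deterministic given the seeds in the assembly (single-threaded
#' pseudo-randomness; bit-reproducibility is promised per platform, not
#' across BLAS implementations).
#'
#' @param x A [bifurcation_problem()] with measurements, or a
#'   [assemble_pinn()] result.
#' @param network A [network_spec()] (ignored if `x` is an assembly).
#' @param control A [training_control()] (ignored if `x` is an assembly).
#' @param quiet Suppress progress messages.
#' @return An object of class `pinn_model`: trained networks, scales,
#'   loss history (a tibble), and the assembly.
#' @export
train_pinn <- function(x, network = network_spec(),
                       control = training_control(), quiet = TRUE) {
  asm <- if (inherits(x, "pinn_assembly")) x
         else assemble_pinn(x, network, control)
  control <- asm$control
  nets <- asm$nets
  t0 <- Sys.time()
  res <- train_loop_cpp(
    lapply(nets, `[[`, "W"), lapply(nets, `[[`, "b"),
    lapply(nets, `[[`, "out_shift"), lapply(nets, `[[`, "out_scale"),
    lapply(asm$parts, `[[`, "X"),
    vapply(asm$parts, function(p) length(p$colloc_cols), 1L),
    vapply(asm$parts, function(p) length(p$u_cols), 1L),
    vapply(asm$parts, function(p) length(p$ic_cols), 1L),
    vapply(asm$parts, function(p) length(p$iface_cols), 1L),
    lapply(asm$parts, `[[`, "u_target"),
    lapply(asm$parts, `[[`, "A_target"),
    lapply(asm$parts, function(p)
      with(p$consts, c(cx, ct, alpha, Ktilde, b0, b1, cp))),
    unname(control$weights[c("physics", "data", "interface")]),
    control$epochs, control$learning_rate, control$log_every)
  for (j in 1:3) {
    nets[[j]]$W <- res$W[[j]]
    nets[[j]]$b <- lapply(res$b[[j]], as.numeric)
  }
  history <- as_tibble(as.data.frame(res$history))
  names(history) <- c("epoch", "physics_1", "physics_2", "physics_3",
                      "data_1", "data_2", "data_3", "interface", "total")
  if (!quiet)
    message(sprintf("trained %d epochs; final total loss %.4e",
                    control$epochs, history$total[nrow(history)]))
  final <- pinn_objective(nets, asm$parts, control$weights, grad = FALSE)
  structure(list(nets = nets, scales = asm$scales, problem = asm$problem,
                 network = asm$network, control = control,
                 history = history, final = final,
                 elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
            class = "pinn_model")
}

#' @export
print.pinn_model <- function(x, ...) {
  cat(sprintf(
    "<pinn_model>  3 networks (%d x %d tanh), %d epochs in %.1f s\n",
    x$network$hidden_layers, x$network$hidden_width, x$control$epochs,
    x$elapsed_s))
  cat(sprintf("  final losses: physics %s | data %s | interface %.3e | total %.3e\n",
              paste(signif(x$final$physics, 3), collapse = "/"),
              paste(signif(x$final$data, 3), collapse = "/"),
              x$final$interface, x$final$total))
  invisible(x)
}

#' Predict physical fields from a trained model
#'
#' Evaluates a vessel's network on an `(x, t)` grid and converts the
#' dimensionless outputs back to physical units.
#'
#' @param model A [train_pinn()] result.
#' @param vessel_id Vessel label.
#' @param x Positions along the vessel (m).
#' @param t Times (s).
#' @return A tibble `vessel_id, x_m, t_s, area_m2, velocity_m_s,
#'   pressure_pa` over the full `x` x `t` grid. Points outside the
#'   trained domain are flagged in the logical column `extrapolated`
#'   (with a warning).
#' @export
predict_fields <- function(model, vessel_id, x, t) {
  ids <- vapply(model$problem$vessels, `[[`, "", "id")
  j <- match(vessel_id, ids)
  if (is.na(j)) abort(paste0("unknown vessel id: ", vessel_id))
  sc <- model$scales[[j]]
  seg <- model$problem$vessels[[j]]
  grid <- tidyr::expand_grid(x_m = x, t_s = t)
  extra <- grid$x_m < 0 | grid$x_m > seg$length |
    grid$t_s < 0 | grid$t_s > model$problem$cycle_duration
  if (any(extra))
    warn(sprintf("%d prediction points lie outside the trained domain.",
                 sum(extra)))
  X <- norm_coords(grid$x_m / sc$L_char, grid$t_s / sc$T_char, sc)
  Y <- mlp_forward(model$nets[[j]], X, tangents = FALSE)$Y
  phys <- redimensionalize(
    tibble(A_star = Y[1, ], u_star = Y[2, ], p_star = Y[3, ]), sc)
  tibble(vessel_id = vessel_id, x_m = grid$x_m, t_s = grid$t_s,
         area_m2 = phys$area_m2, velocity_m_s = phys$u_m_s,
         pressure_pa = phys$pressure_pa, extrapolated = extra)
}

#' Diastolic, systolic and mean pressure of a trained model
#'
#' Scans the predicted pressure over the space-time domain of all three
#' vessels and reports the minimum (diastolic), maximum (systolic), and
#' the clinical mean `(2 Pd + Ps) / 3`.
#'
#' @param model A [train_pinn()] result.
#' @param n_x,n_t Grid resolution of the scan.
#' @return A one-row tibble with `Pd`, `Ps`, `mPA` in both Pa and mmHg.
#' @export
pressure_summary <- function(model, n_x = 11, n_t = 101) {
  T <- model$problem$cycle_duration
  p <- purrr::map_dfr(model$problem$vessels, function(s)
    predict_fields(model, s$id, seq(0, s$length, length.out = n_x),
                   seq(0, T, length.out = n_t)))
  Pd <- min(p$pressure_pa); Ps <- max(p$pressure_pa)
  tibble(Pd_pa = Pd, Ps_pa = Ps,
         mPA_pa = mean_pulmonary_pressure(Pd, Ps),
         Pd_mmhg = pa_to_mmhg(Pd), Ps_mmhg = pa_to_mmhg(Ps),
         mPA_mmhg = mean_pulmonary_pressure(pa_to_mmhg(Pd), pa_to_mmhg(Ps)))
}

#' @exportS3Method generics::tidy
tidy.pinn_model <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "component",
                      values_to = "loss")
}

#' @exportS3Method generics::glance
glance.pinn_model <- function(x, ...) {
  tibble(epochs = x$control$epochs,
         learning_rate = x$control$learning_rate,
         n_collocation = x$control$n_collocation,
         n_boundary = x$control$n_boundary,
         physics_loss = sum(x$final$physics),
         data_loss = sum(x$final$data),
         interface_loss = x$final$interface,
         total_loss = x$final$total,
         elapsed_s = x$elapsed_s)
}

#' Loss components of an assembly or trained model
#'
#' Recomputes the composite loss (three physics, three data, one
#' interface component and their weighted total) at the current network
#' parameters.
#'
#' @param x A `pinn_assembly` or `pinn_model`.
#' @return A one-row tibble of loss components.
#' @export
total_loss <- function(x) {
  stopifnot(inherits(x, c("pinn_assembly", "pinn_model")))
  parts <- if (inherits(x, "pinn_model"))
    assemble_pinn(x$problem, x$network, x$control)$parts else x$parts
  # a trained model evaluates its own nets on the assembly's points
  obj <- pinn_objective(x$nets, parts, x$control$weights, grad = FALSE)
  tibble(physics_1 = obj$physics[1], physics_2 = obj$physics[2],
         physics_3 = obj$physics[3], data_1 = obj$data[1],
         data_2 = obj$data[2], data_3 = obj$data[3],
         interface = obj$interface, total = obj$total)
}

#' Physics residual loss of one network over a collocation set
#'
#' Mean squared dimensionless residuals of mass conservation, momentum
#' balance and the wall law, with the network's exact output derivatives.
#'
#' @param net A [build_network()] result.
#' @param collocation Tibble with normalized columns `x_hat`, `t_hat`.
#' @param scales The vessel's [normalization_scales()].
#' @param segment The [vessel_segment()]. @param fluid A [fluid_model()].
#' @return Scalar loss (non-negative).
#' @export
physics_loss <- function(net, collocation, scales, segment, fluid) {
  X <- rbind(collocation$x_hat, collocation$t_hat)
  fwd <- mlp_forward(net, X, tangents = TRUE)
  k <- residual_constants(segment, fluid, scales)
  physics_term(fwd$Y, fwd$Yx, fwd$Yt, seq_len(ncol(X)), k)$loss
}

#' Boundary-data loss of one network
#'
#' Mean squared mismatch between network predictions and the starred
#' measurement targets (velocity and area; pressure never enters).
#'
#' @param net A [build_network()] result.
#' @param points Tibble with `x_hat`, `t_hat` and targets `u_star`
#'   and/or `A_star` (NA where a field is not measured at that point).
#' @return Scalar loss.
#' @export
data_loss <- function(net, points) {
  X <- rbind(points$x_hat, points$t_hat)
  Y <- mlp_forward(net, X, tangents = FALSE)$Y
  u_ok <- if ("u_star" %in% names(points)) which(!is.na(points$u_star))
          else integer(0)
  a_ok <- if ("A_star" %in% names(points)) which(!is.na(points$A_star))
          else integer(0)
  part <- list(u_cols = u_ok, u_target = points$u_star[u_ok],
               A_cols = a_ok, A_target = points$A_star[a_ok],
               ic_cols = integer(0))
  data_term(Y, part)$loss
}

#' Junction interface loss of the three networks
#'
#' Mean squared flow-continuity and dimensionless total-pressure
#' (`p* + u*^2 / 2`) residuals at shared interface times. The density
#' does not appear explicitly: with `p_ref = rho U^2` the kinetic term is
#' exactly `u*^2 / 2`.
#'
#' @param nets List of three [build_network()] results (parent first).
#' @param interface List of three tibbles (`x_hat`, `t_hat`), one per
#'   network, with identical row counts (same physical interface times).
#' @return Scalar loss.
#' @export
interface_loss <- function(nets, interface) {
  ns <- vapply(interface, nrow, 1L)
  if (length(unique(ns)) != 1L)
    abort("interface grids must have the same number of times for all vessels.")
  Ys <- lapply(1:3, function(j)
    mlp_forward(nets[[j]], rbind(interface[[j]]$x_hat,
                                 interface[[j]]$t_hat),
                tangents = FALSE)$Y)
  interface_term(Ys, lapply(ns, seq_len))$loss
}
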