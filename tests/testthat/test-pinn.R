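test_that("network construction is deterministic and correctly shaped", {
  sp <- network_spec(3, 16, init_seed = 11)
  n1 <- build_network(sp); n2 <- build_network(sp)
  expect_identical(pulsepinn:::net_get_params(n1),
                   pulsepinn:::net_get_params(n2))
  n3 <- build_network(network_spec(3, 16, init_seed = 12))
  expect_false(identical(pulsepinn:::net_get_params(n1),
                         pulsepinn:::net_get_params(n3)))
  X <- matrix(rnorm(2 * 23), 2, 23)
  out <- mlp_forward(n1, X, tangents = FALSE)
  expect_equal(dim(out$Y), c(3L, 23L))
  # Glorot bounds on the first layer
  lim <- (5 / 3) * sqrt(6 / (2 + 16))
  expect_lt(max(abs(n1$W[[1]])), lim)
})

test_that("network input derivatives match central finite differences", {
  net <- build_network(network_spec(3, 24, init_seed = 2))
  set.seed(9)
  X <- matrix(runif(2 * 100, -1.5, 1.5), 2, 100)
  fwd <- mlp_forward(net, X, tangents = TRUE)
  h <- 1e-4
  fdx <- (mlp_forward(net, X + c(h, 0), tangents = FALSE)$Y -
          mlp_forward(net, X - c(h, 0), tangents = FALSE)$Y) / (2 * h)
  fdt <- (mlp_forward(net, X + c(0, h), tangents = FALSE)$Y -
          mlp_forward(net, X - c(0, h), tangents = FALSE)$Y) / (2 * h)
  expect_lt(max(abs(fwd$Yx - fdx) / (abs(fdx) + 1e-8)), 1e-5)
  expect_lt(max(abs(fwd$Yt - fdt) / (abs(fdt) + 1e-8)), 1e-5)
})

test_that("parameter gradients of the composite objective match finite
           differences", {
  asm <- fx_small_assembly()
  obj <- pulsepinn:::pinn_objective(asm$nets, asm$parts,
                                    asm$control$weights, grad = TRUE)
  for (jn in 1:3) {
    g <- unlist(c(obj$grads[[jn]]$W, obj$grads[[jn]]$b))
    th <- pulsepinn:::net_get_params(asm$nets[[jn]])
    lf <- function(theta) {
      ns <- asm$nets
      ns[[jn]] <- pulsepinn:::net_set_params(ns[[jn]], theta)
      pulsepinn:::pinn_objective(ns, asm$parts, asm$control$weights,
                                 grad = FALSE)$total
    }
    set.seed(jn)
    idx <- sort(sample(length(th), 12))
    fd <- vapply(idx, function(i) {
      e <- th
      e[i] <- e[i] + 1e-6; a <- lf(e)
      e[i] <- e[i] - 2e-6; b <- lf(e)
      (a - b) / 2e-6
    }, 1.0)
    # absolute agreement relative to the gradient scale (tiny components
    # are dominated by cancellation noise in the finite differences)
    expect_lt(max(abs(g[idx] - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("physics loss vanishes on the equilibrium-frozen networks", {
  m <- fx_frozen_model()
  for (j in 1:3) {
    pj <- NULL # per-vessel collocation points in normalized coordinates
    sc <- m$scales[[j]]
    set.seed(j)
    colloc <- tibble::tibble(
      x_hat = (runif(100) - sc$mu_x) / sc$sigma_x,
      t_hat = (runif(100, 0, 0.89 / sc$T_char) - sc$mu_t) / sc$sigma_t)
    L <- physics_loss(m$nets[[j]], colloc, sc, m$problem$vessels[[j]],
                      m$problem$fluid)
    expect_lt(L, 1e-12)
    expect_gte(L, 0)
  }
})

test_that("physics loss equals the manufactured-solution oracle", {
  # feed exact starred fields and derivatives of the manufactured
  # solution through the loss algebra; the mean squared dimensionless
  # residuals must equal the independently scaled physical forcings
  seg <- vessel_segment("parent", 0.01763, 3.8191e-4, beta = 2.32586e6,
                        pext = 2133.16)
  fl <- fluid_model()
  ms <- manufactured_solution(seg, fl, amplitude = 0.05, U = 0.3)
  sc <- normalization_scales(U_char = 0.45, L_char = seg$length,
                             A_ref = seg$A0, t_range = c(0, 0.89))
  set.seed(5)
  x <- runif(200, 0, seg$length); t <- runif(200, 0, 0.89)
  # starred outputs and their derivatives w.r.t. normalized coordinates
  Y <- rbind(ms$A(x, t) / sc$A_ref, ms$u(x, t) / sc$U_char,
             ms$p(x, t) / sc$p_ref)
  dxhat <- sc$L_char * sc$sigma_x        # d x / d x_hat
  dthat <- sc$T_char * sc$sigma_t
  Yx <- rbind(ms$dA_dx(x, t) / sc$A_ref, ms$du_dx(x, t) / sc$U_char,
              ms$dp_dx(x, t) / sc$p_ref) * dxhat
  Yt <- rbind(ms$dA_dt(x, t) / sc$A_ref, ms$du_dt(x, t) / sc$U_char,
              0 * x) * dthat
  # p follows the wall law exactly, so only dp_dx matters; dp_dt drops
  # out of the residuals entirely
  k <- pulsepinn:::residual_constants(seg, fl, sc)
  r <- pulsepinn:::physics_residuals(Y, Yx, Yt, k)
  s_mass <- sc$L_char / (sc$U_char * sc$A_ref)
  s_mom <- sc$L_char / sc$U_char^2
  expect_rel_equal(r$rA, s_mass * ms$forcing_mass(x, t), 1e-10)
  expect_rel_equal(r$ru, s_mom * ms$forcing_momentum(x, t), 1e-10)
  expect_lt(max(abs(r$rp)), 1e-12)
  # and the loss is exactly the mean square of the scaled forcings
  got <- pulsepinn:::physics_term(Y, Yx, Yt, seq_along(x), k)$loss
  want <- mean((s_mass * ms$forcing_mass(x, t))^2) +
    mean((s_mom * ms$forcing_momentum(x, t))^2)
  expect_rel_equal(got, want, 1e-10)
})

test_that("data loss: exact fit, quadratic offset, arithmetic oracle", {
  net <- build_network(network_spec(2, 8, init_seed = 4))
  set.seed(2)
  pts <- tibble::tibble(x_hat = runif(30, -1, 1), t_hat = runif(30, -1, 1))
  Y <- mlp_forward(net, rbind(pts$x_hat, pts$t_hat), tangents = FALSE)$Y
  pts$u_star <- Y[2, ]; pts$A_star <- Y[1, ]
  expect_equal(data_loss(net, pts), 0, tolerance = 1e-28)
  delta <- 0.37
  pts2 <- pts; pts2$u_star <- pts2$u_star - delta
  expect_equal(data_loss(net, pts2), delta^2, tolerance = 1e-12)
  # random targets: equals the independently computed mean square error
  pts3 <- pts
  pts3$u_star <- rnorm(30); pts3$A_star <- rnorm(30)
  pts3$A_star[c(3, 14)] <- NA           # unmeasured area at two points
  want <- mean((Y[2, ] - pts3$u_star)^2) +
    mean((Y[1, -c(3, 14)] - pts3$A_star[-c(3, 14)])^2)
  expect_equal(data_loss(net, pts3), want, tolerance = 1e-12)
})

test_that("interface loss: zero at consistent states, arithmetic oracle,
           non-negative", {
  m <- fx_frozen_model()
  tb <- seq(-1, 1, length.out = 21)
  iface <- lapply(1:3, function(j)
    tibble::tibble(x_hat = rep(if (j == 1) 1.7 else -1.7, 21), t_hat = tb))
  # equilibrium: all u = 0 and all pext equal -> both terms vanish
  expect_lt(interface_loss(m$nets, iface), 1e-12)
  # halved daughter flows: loss = mean((q/2)^2) + Bernoulli terms
  nets <- m$nets
  q <- 0.8; u1 <- 0.5; A1 <- q / u1
  mk_const <- function(A, u, p) {
    net <- nets[[1]]
    for (l in seq_along(net$W)) net$W[[l]][] <- 0
    for (l in seq_along(net$b)) net$b[[l]][] <- 0
    net$out_scale <- c(1, 1, 1)
    net$out_shift <- c(A, u, p)
    net
  }
  n1 <- mk_const(A1, u1, 2.0)
  n2 <- mk_const(A1 / 2, u1 / 2, 2.0)  # flow q/4 each
  n3 <- mk_const(A1 / 2, u1 / 2, 2.0)
  got <- interface_loss(list(n1, n2, n3), iface)
  bern <- (0.5 * u1^2 - 0.5 * (u1 / 2)^2)^2
  expect_equal(got, (q / 2)^2 + 2 * bern, tolerance = 1e-12)
  expect_gte(got, 0)
  iface_bad <- iface; iface_bad[[2]] <- iface_bad[[2]][1:10, ]
  expect_error(interface_loss(m$nets, iface_bad), "same number")
})

test_that("total loss equals the sum of its components and is invariant
           to collocation order", {
  asm <- fx_small_assembly()
  obj <- pulsepinn:::pinn_objective(asm$nets, asm$parts,
                                    asm$control$weights, grad = FALSE)
  expect_equal(obj$total, sum(obj$physics) + sum(obj$data) + obj$interface,
               tolerance = 1e-12)
  tl <- total_loss(asm)
  expect_equal(tl$total, obj$total, tolerance = 1e-12)
  # permute collocation points of vessel 1
  asm2 <- asm
  set.seed(1)
  perm <- sample(asm2$parts[[1]]$colloc_cols)
  asm2$parts[[1]]$X[, asm2$parts[[1]]$colloc_cols] <-
    asm2$parts[[1]]$X[, perm]
  obj2 <- pulsepinn:::pinn_objective(asm2$nets, asm2$parts,
                                     asm$control$weights, grad = FALSE)
  expect_equal(obj2$total, obj$total, tolerance = 1e-12)
})

test_that("compiled training loop agrees with the reference R optimiser", {
  asm <- fx_small_assembly(epochs = 10L)
  m <- train_pinn(asm)
  nets <- asm$nets
  states <- lapply(nets, pulsepinn:::adam_init)
  for (ep in 1:10) {
    obj <- pulsepinn:::pinn_objective(nets, asm$parts,
                                      asm$control$weights, grad = TRUE)
    for (j in 1:3) {
      upd <- pulsepinn:::adam_step(nets[[j]], obj$grads[[j]], states[[j]],
                                   asm$control$learning_rate, ep)
      nets[[j]] <- upd$net; states[[j]] <- upd$st
    }
  }
  for (j in 1:3)
    expect_lt(max(abs(pulsepinn:::net_get_params(m$nets[[j]]) -
                      pulsepinn:::net_get_params(nets[[j]]))), 1e-12)
})

test_that("training: history, descent across seeds, zero-lr identity,
           determinism", {
  asm <- fx_small_assembly(epochs = 10L)
  m <- train_pinn(asm)
  expect_equal(nrow(m$history), 10L)
  expect_true(all(is.finite(m$history$total)))

  drops <- vapply(1:10, function(s) {
    mi <- train_pinn(fx_small_assembly(seed = s, epochs = 10L))
    mi$history$total[10] <= mi$history$total[1]
  }, TRUE)
  expect_gte(sum(drops), 8L)

  p <- fx_problem()
  prob <- bifurcation_problem(p$vessels[[1]], p$vessels[[2]], p$vessels[[3]],
                              p$fluid, fx_analytic_measurements(p))
  ctrl0 <- training_control(epochs = 5, learning_rate = 0,
                            n_collocation = 40, n_boundary = 9,
                            log_every = 1, seed = 2)
  asm0 <- assemble_pinn(prob, network_spec(2, 10), ctrl0)
  m0 <- train_pinn(asm0)
  for (j in 1:3)
    expect_identical(pulsepinn:::net_get_params(m0$nets[[j]]),
                     pulsepinn:::net_get_params(asm0$nets[[j]]))

  ma <- train_pinn(fx_small_assembly(seed = 3, epochs = 8L))
  mb <- train_pinn(fx_small_assembly(seed = 3, epochs = 8L))
  expect_identical(ma$history, mb$history)
  expect_identical(pulsepinn:::net_get_params(ma$nets[[2]]),
                   pulsepinn:::net_get_params(mb$nets[[2]]))
})

test_that("prediction: equilibrium stub fields, unit round trip,
           extrapolation flag", {
  m <- fx_frozen_model()
  segs <- m$problem$vessels
  f <- predict_fields(m, "parent", c(0, segs[[1]]$length / 2),
                      c(0, 0.4, 0.89))
  expect_equal(f$area_m2, rep(segs[[1]]$A0, 6), tolerance = 1e-12)
  expect_equal(f$velocity_m_s, rep(0, 6))
  expect_equal(f$pressure_pa, rep(segs[[1]]$pext, 6), tolerance = 1e-12)
  expect_false(any(f$extrapolated))
  # daughters carry their own equilibrium area, not the parent reference
  f2 <- predict_fields(m, "left", 0, 0.2)
  expect_equal(f2$area_m2, segs[[2]]$A0, tolerance = 1e-12)
  # pressure in Pa converts back to the network p* through the scales
  sc <- m$scales[[1]]
  expect_equal(f$pressure_pa[1] / sc$p_ref, segs[[1]]$pext / sc$p_ref,
               tolerance = 1e-12)
  expect_warning(predict_fields(m, "parent", -0.001, 0.1), "outside")
  expect_error(predict_fields(m, "nope", 0, 0), "unknown vessel")
})

test_that("pressure summary reduces to the clinical mPAP formula", {
  m <- fx_frozen_model()
  ps <- pressure_summary(m, n_x = 5, n_t = 11)
  # constant pressure field: Pd = Ps = mPA = pext
  expect_equal(ps$Pd_pa, m$problem$vessels[[1]]$pext, tolerance = 1e-9)
  expect_equal(ps$Ps_pa, ps$Pd_pa, tolerance = 1e-9)
  expect_equal(ps$mPA_pa, ps$Pd_pa, tolerance = 1e-9)
  expect_equal(ps$mPA_mmhg,
               mean_pulmonary_pressure(ps$Pd_mmhg, ps$Ps_mmhg))
})

test_that("tidy, glance and autoplot interfaces work on fitted objects", {
  m <- train_pinn(fx_small_assembly(epochs = 6L))
  td <- tidy(m)
  expect_true(all(c("epoch", "component", "loss") %in% names(td)))
  g <- glance(m)
  expect_equal(g$epochs, 6L)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
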