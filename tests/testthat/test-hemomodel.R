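seg1 <- vessel_segment("parent", length = 0.01763, A0 = 3.8191e-4,
                       beta = 2.32586e6, pext = 2133.16)
fl <- fluid_model()

test_that("constitutive law matches hand arithmetic and round-trips", {
  expect_equal(constitutive_pressure(seg1$A0, seg1), seg1$pext)
  # A = 1.1 A0 => p = pext + beta sqrt(A0) (sqrt(1.1) - 1)
  want <- seg1$pext + seg1$beta * sqrt(seg1$A0) * (sqrt(1.1) - 1)
  expect_equal(constitutive_pressure(1.1 * seg1$A0, seg1), want,
               tolerance = 1e-12)
  set.seed(1)
  A <- runif(50, 0.5, 2) * seg1$A0
  back <- area_from_pressure(constitutive_pressure(A, seg1), seg1)
  expect_rel_equal(back, A, 1e-10)
  expect_error(constitutive_pressure(-1e-5, seg1), "positive")
})

test_that("mass residual vanishes on constant and travelling-wave states", {
  n <- 20
  z <- rep(0, n)
  expect_equal(mass_residual(rep(3e-4, n), rep(0.5, n), z, z, z), z)
  # A = f(x - s t), u = s: dA_dt = -s f', dA_dx = f', du_dx = 0
  s <- 1.3; fp <- rnorm(n)
  r <- mass_residual(A = abs(rnorm(n)) + 1, u = rep(s, n),
                     dA_dt = -s * fp, dA_dx = fp, du_dx = z)
  expect_equal(r, z)
  expect_error(mass_residual(1:3, 1:4, 1:3, 1:3, 1:3), "conformable")
})

test_that("mass residual matches the symbolic oracle", {
  # A = A0 (1 + 0.1 sin x), u = cos t; expected values frozen from
  # symbolic differentiation of the closed-form fields
  A0 <- 3.8191e-4
  pts <- list(c(0.3, 0.2), c(1.1, 0.7), c(2.0, 1.5))
  want <- c(3.5757979848644152e-5, 1.3249582611770247e-5,
            -1.1242308615837893e-6)
  got <- vapply(pts, function(pt) {
    x <- pt[1]; t <- pt[2]
    mass_residual(A = A0 * (1 + 0.1 * sin(x)), u = cos(t),
                  dA_dt = 0, dA_dx = A0 * 0.1 * cos(x), du_dx = 0)
  }, 1.0)
  expect_rel_equal(got, want, 1e-12)
})

test_that("momentum residual: trivial balances and symbolic oracle", {
  n <- 10; z <- rep(0, n)
  expect_equal(momentum_residual(rep(3e-4, n), z, z, z, z, fl), z)
  # steady inviscid Bernoulli: p = C - rho u^2 / 2 => dp_dx = -rho u u_x
  u <- runif(n, 0.1, 1); ux <- rnorm(n)
  r <- momentum_residual(A = rep(3e-4, n), u = u,
                         dp_dx = -fl$rho * u * ux,
                         du_dt = z, du_dx = ux, fl)
  expect_lt(max(abs(r)), 1e-12)
  # general alpha / KR fields vs frozen symbolic values
  fl2 <- fluid_model(alpha = 1.1, KR = 0.003)
  A0 <- 3.8191e-4; L <- 0.02; T <- 0.89
  beta <- 2.32586e6; pext <- 2133.16; rho <- 1060
  kx <- pi / L; wt <- 2 * pi / T
  eval_r <- function(x, t) {
    A <- A0 * (1 + 0.05 * sin(kx * x) * cos(wt * t))
    u <- 0.3 * sin(kx * x) * sin(wt * t) + 0.05
    dA_dx <- A0 * 0.05 * kx * cos(kx * x) * cos(wt * t)
    du_dt <- 0.3 * wt * sin(kx * x) * cos(wt * t)
    du_dx <- 0.3 * kx * cos(kx * x) * sin(wt * t)
    dp_dx <- beta / (2 * sqrt(A)) * dA_dx
    momentum_residual(A, u, dp_dx, du_dt, du_dx, fl2, dA_dx = dA_dx)
  }
  got <- c(eval_r(0.004, 0.1), eval_r(0.011, 0.37), eval_r(0.017, 0.62))
  want <- c(107.10522251143432, 18.904321312189548, 46.128000584920712)
  expect_rel_equal(got, want, 1e-10)
  expect_error(momentum_residual(rep(3e-4, n), u, z, z, z, fl2),
               "dA_dx")
})

test_that("momentum residual with alpha = 1 drops the shape term", {
  set.seed(3)
  n <- 30
  A <- runif(n, 1e-4, 5e-4); u <- rnorm(n); dp <- rnorm(n)
  ut <- rnorm(n); ux <- rnorm(n); Ax <- rnorm(n)
  got <- momentum_residual(A, u, dp, ut, ux, fluid_model(alpha = 1),
                           dA_dx = Ax)
  want <- ut + u * ux + dp / 1060
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("junction residuals: flow continuity and Bernoulli", {
  s1 <- list(A = 2, u = 1, p = 2000)
  s2 <- list(A = 1, u = 1, p = 2000)
  s3 <- list(A = 0.5, u = 2, p = 2000)
  expect_equal(junction_flow_residual(s1, s2, s3), 0)
  z <- list(A = 1, u = 0, p = 500)
  expect_equal(junction_flow_residual(z, z, z), 0)
  rb <- junction_bernoulli_residuals(s1, s1, s1, rho = 1060)
  expect_equal(rb$r12, 0); expect_equal(rb$r13, 0)
  # constructed: p2 = p1 + rho/2 (u1^2 - u2^2) => r12 = 0
  rho <- 1060; u2 <- 1.7
  s2b <- list(p = s1$p + rho / 2 * (s1$u^2 - u2^2), u = u2)
  rb2 <- junction_bernoulli_residuals(list(p = s1$p, u = s1$u), s2b,
                                      list(p = 0, u = 0), rho)
  expect_equal(rb2$r12, 0, tolerance = 1e-12)
})

test_that("all residual operators vanish on the equilibrium state", {
  n <- 15; z <- rep(0, n)
  A <- rep(seg1$A0, n); u <- z; p <- rep(seg1$pext, n)
  expect_lt(max(abs(mass_residual(A, u, z, z, z))), 1e-12)
  expect_lt(max(abs(momentum_residual(A, u, z, z, z, fl))), 1e-12)
  st <- list(A = A, u = u, p = p)
  expect_lt(max(abs(junction_flow_residual(st, st, st))), 1e-12)
  rb <- junction_bernoulli_residuals(st, st, st)
  expect_lt(max(abs(c(rb$r12, rb$r13))), 1e-12)
  expect_lt(max(abs(constitutive_pressure(A, seg1) - p)), 1e-12)
})

test_that("nondimensionalize and redimensionalize are exact inverses", {
  sc <- normalization_scales(U_char = 0.45, L_char = 0.01763,
                             A_ref = 3.8191e-4, t_range = c(0, 0.89))
  expect_equal(sc$p_ref, 1060 * 0.45^2)
  expect_equal(nondimensionalize(tibble::tibble(u_m_s = 0.45), sc)$u_star, 1)
  p <- nondimensionalize(tibble::tibble(pressure_pa = 1060),
                         normalization_scales(1, 0.02, 3e-4))$p_star
  expect_equal(p, 1)
  set.seed(7)
  d <- tibble::tibble(x_m = runif(40, 0, 0.0176), t_s = runif(40, 0, 0.89),
                      area_m2 = runif(40, 1e-4, 5e-4),
                      u_m_s = rnorm(40), pressure_pa = runif(40, 1e3, 5e3))
  back <- redimensionalize(nondimensionalize(d, sc), sc)
  expect_lt(max(abs(as.matrix(back) - as.matrix(d))), 1e-12)
  expect_error(normalization_scales(0, 1, 1), "positive")
})

test_that("pressure unit conversion is the exact 133.322 Pa/mmHg pair", {
  expect_equal(mmhg_to_pa(16), 2133.152)
  expect_equal(mmhg_to_pa(0), 0)
  x <- c(0.1, 16, 32.5, 120)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-14)
})

test_that("vessel constructors enforce their invariants", {
  expect_equal(seg1$R0, sqrt(seg1$A0 / pi))
  expect_error(vessel_segment("v", -1, 1e-4, beta = 1e6), "positive")
  expect_error(vessel_segment("v", 0.01, 1e-4, beta = 1e6, nu = 1), "nu")
  expect_error(vessel_segment("v", 0.01, 1e-4), "beta")
  expect_error(vessel_segment("v", 0.01, 1e-4, beta = 1e6, E = 3e5),
               "both")
  # beta derived from mechanics inside the constructor
  v <- vessel_segment("v", 0.01763, 3.8191e-4, E = 340898.12)
  expect_equal(v$beta, 2.32586e6, tolerance = 1e-5)
  expect_error(fluid_model(alpha = 0.5), "alpha")
  expect_error(
    bifurcation_problem(seg1, seg1, seg1),
    "distinct")
})
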