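# Simulator unit tests: pharmacokinetics, the three elliptic solvers
# against dense loop-assembled oracles, explicit stepping against ODE
# oracles and fixed points, patient initialisation, case integration.

test_that("plasma concentration follows single-exponential bolus decay", {
  expect_equal(plasma_concentration(0, 0.6, 1), 0.6)
  expect_equal(plasma_concentration(1, 1, 1), exp(-1))
  expect_equal(plasma_concentration(5, 0, 2), 0)
  # strictly decreasing in t
  ts <- seq(0, 3, by = 0.25)
  expect_true(all(diff(plasma_concentration(ts, 1, 0.7)) < 0))
  expect_error(plasma_concentration(1, 1, 0), "t_half")
  expect_error(plasma_concentration(-1, 1, 1), ">= 0")
})

test_that("pressure solve: trivial cases, uniform closed form, singularity", {
  g <- tme_grid(9); p <- default_params()
  expect_equal(solve_pressure(matrix(0, 9, 9), p, g), matrix(0, 9, 9))
  Pe <- p$P_v - p$sigma_v * (p$pi_c - p$pi_i)
  Pu <- p$lambda_b * Pe / (p$lambda_b + p$lambda_l)
  expect_equal(solve_pressure(matrix(1, 9, 9), p, g),
               matrix(Pu, 9, 9), tolerance = 1e-10)
  p0 <- default_params(K = 0, lambda_b = 0, lambda_l = 0)
  expect_error(solve_pressure(matrix(0, 9, 9), p0, g), "singular")
})

test_that("drug-A solve: trivial cases, uniform closed form, singularity", {
  g <- tme_grid(9); p <- default_params()
  expect_equal(solve_drug_A(matrix(0, 9, 9), 1, p, g), matrix(0, 9, 9))
  Au <- p$lambda_A * 0.7 / (p$lambda_A + p$Gamma_l + p$k_A)
  expect_equal(solve_drug_A(matrix(1, 9, 9), 0.7, p, g),
               matrix(Au, 9, 9), tolerance = 1e-10)
  p0 <- default_params(lambda_A = 0, Gamma_l = 0, k_A = 0)
  expect_error(solve_drug_A(matrix(1, 9, 9), 1, p0, g), "singular")
})

test_that("drug-d solve: zero source, uniform closed form, error contract", {
  g <- tme_grid(9); p <- default_params()
  z <- matrix(0, 9, 9)
  expect_equal(solve_drug_d(matrix(1, 9, 9), z + 0.3, 0, z, p, g), z)
  # uniform vasculature, uniform P (no convection), no tumor sink
  Pu <- matrix(0.4, 9, 9)
  gb <- p$lambda_b * 1 * (p$P_v - 0.4 - p$sigma_v * (p$pi_c - p$pi_i))
  du <- gb * (1 - p$sigma_d) * 1 / (p$Gamma_l + p$k_d)
  expect_equal(solve_drug_d(matrix(1, 9, 9), Pu, 1, z, p, g),
               matrix(du, 9, 9), tolerance = 1e-10)
  Pbad <- Pu; Pbad[3, 3] <- NaN
  expect_error(solve_drug_d(matrix(1, 9, 9), Pbad, 1, z, p, g), "non-finite")
})

test_that("sparse solvers agree with dense loop-assembled oracles", {
  p <- default_params()
  for (side in c(9, 15)) {
    g <- tme_grid(side)
    set.seed(side)
    m <- matrix(runif(side^2, 0, 1.5), side, side)
    n <- matrix(runif(side^2, 0, 1), side, side)

    P <- solve_pressure(m, p, g)
    expect_lt(max(abs(P - dense_pressure(m, p, g))) / max(abs(P)), 1e-8)

    A <- solve_drug_A(m, 0.8, p, g)
    expect_lt(max(abs(A - dense_drug_A(m, 0.8, p, g))) / max(abs(A)), 1e-8)

    d <- solve_drug_d(m, P, 0.9, n, p, g)
    expect_lt(max(abs(d - dense_drug_d(m, P, 0.9, n, p, g))) / max(abs(d)),
              1e-8)
  }
})

test_that("no-flux discretisation: operators annihilate constants", {
  g <- tme_grid(11)
  const <- matrix(3.7, 11, 11)
  expect_equal(dent:::.cpp_laplacian(const, g$h), matrix(0, 11, 11))
  set.seed(1)
  m <- matrix(runif(121), 11, 11)
  # div(m grad const) = 0 for any m
  expect_equal(dent:::.cpp_div_m_grad_n(m, const, g$h), matrix(0, 11, 11))
  # assembled Laplacian rows sum to zero (no flux through any boundary face)
  L2 <- dent:::neumann_laplacian(g)
  expect_lt(max(abs(as.numeric(L2 %*% rep(1, 121)))), 1e-12)
})

test_that("tumor density step: fixed points and logistic ODE oracle", {
  g <- tme_grid(9); p <- default_params()
  z <- matrix(0, 9, 9)
  st0 <- list(n = z, m = z, d = z)
  expect_equal(step_tumor_density(st0, p, g), z)
  stL <- list(n = z + p$n_lim, m = z, d = z)
  expect_equal(step_tumor_density(stL, p, g), z + p$n_lim)
  # uniform field, no vessels/drug: exact logistic solution over one day
  n0 <- 0.2
  st <- list(n = matrix(n0, 9, 9), m = z, d = z)
  dt <- 1 / 4800
  for (s in 1:4800) st$n <- step_tumor_density(st, p, g, dt)
  exact <- p$n_lim / (1 + (p$n_lim - n0) / n0 * exp(-p$r_n * 1))
  expect_equal(st$n[5, 5], exact, tolerance = 1e-4)
  # stability refusal names sub-stepping
  expect_error(step_tumor_density(st, p, g, dt = 10), "sub-step")
})

test_that("vasculature step: fixed points and cubic ODE oracle", {
  g <- tme_grid(9); p <- default_params()
  z <- matrix(0, 9, 9)
  expect_equal(step_vasculature(list(n = z, m = z, A = z), p, g), z)
  # alpha + beta + gamma = 0 makes m = 1 a fixed point
  expect_equal(p$alpha + p$beta + p$gamma, 0)
  one <- z + 1
  expect_equal(step_vasculature(list(n = z, m = one, A = z), p, g), one)
  # uniform field vs RK4 oracle of the cubic reaction over one day
  m0 <- 0.8
  st <- list(n = z, m = matrix(m0, 9, 9), A = z)
  dt <- 1 / 4800
  for (s in 1:4800) st$m <- step_vasculature(st, p, g, dt)
  oracle <- rk4(function(m) m * (p$alpha + p$beta * m + p$gamma * m^2),
                m0, 1, 10000)
  expect_equal(st$m[5, 5], oracle, tolerance = 1e-4)
})

test_that("patient initialisation is seeded, centered and non-negative", {
  g <- tme_grid(21); p <- default_params()
  s1 <- init_patient(4, p, g)
  s2 <- init_patient(4, p, g)
  expect_identical(s1, s2)
  s3 <- init_patient(5, p, g)
  expect_true(any(s3$m != s1$m))
  # Gaussian peak at the grid center pixel (0-based (10, 10) for 21)
  expect_equal(as.integer(which(s1$n == max(s1$n), arr.ind = TRUE)),
               c(11L, 11L))
  expect_true(all(s1$n >= 0) && all(s1$m >= 0) && all(s1$A == 0) &&
                all(s1$d == 0))
})

test_that("case integration: shape, zero-dose purity, determinism", {
  g <- fixture_grid(); p <- fixture_params()
  cs <- fixture_cases()[[1]]
  expect_equal(dim(cs$daily_frames), c(8, 5, 21, 21))
  expect_equal(dim(cs$post_drug), c(8, 2, 21, 21))
  expect_equal(dim(cs$scalars), c(8, 2))
  # doses recorded at the scheduled steps only
  expect_equal(which(cs$scalars[, 1] > 0), c(1, 3, 5, 7))
  expect_equal(which(cs$scalars[, 2] > 0), c(3, 5, 7))
  # non-negativity of all recorded fields
  expect_true(all(cs$daily_frames[, c(1, 2, 4, 5), , ] >= 0))

  sch0 <- therapy_schedule(6, 0, 0)
  cs0a <- run_case(1, sch0, p, g)
  cs0b <- run_case(1, sch0, p, g)
  expect_identical(cs0a$daily_frames, cs0b$daily_frames)
  expect_true(all(cs0a$daily_frames[, 4, , ] == 0))
  expect_true(all(cs0a$daily_frames[, 5, , ] == 0))
  # untreated growth: same patient, same growth phase as the treated case
  expect_identical(cs0a$daily_frames[1, 1, , ], cs$daily_frames[1, 1, , ])
})

test_that("case design enumeration matches the factorial arithmetic", {
  expect_equal(nrow(case_design(1:5)), 225)
  expect_equal(nrow(case_design(1, init_days = 14, A_doses = 0.5,
                                d_doses = 0.5)), 1)
  d <- case_design(1:2, init_days = c(10, 12), A_doses = c(0.4, 0.8),
                   d_doses = 0.6)
  expect_equal(nrow(d), 8)
})
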