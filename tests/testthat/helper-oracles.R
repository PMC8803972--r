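# Independent oracles used across the suite.  Everything here is written
# from the continuous equations directly (dense matrices, explicit pixel
# loops, classic RK4), deliberately sharing no code with the package's
# sparse/vectorised implementations.

pe_of <- function(p) p$P_v - p$sigma_v * (p$pi_c - p$pi_i)

# dense direct solve of the pressure balance, loop-assembled
dense_pressure <- function(m, p, g) {
  ny <- g$ny; nx <- g$nx; N <- ny * nx
  A <- matrix(0, N, N); b <- numeric(N)
  idx <- function(r, c) r + (c - 1) * ny
  for (r in 1:ny) for (c in 1:nx) {
    i <- idx(r, c)
    for (q in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx) {
        j <- idx(q[1], q[2])
        A[i, i] <- A[i, i] + p$K / g$h^2
        A[i, j] <- A[i, j] - p$K / g$h^2
      }
    }
    A[i, i] <- A[i, i] + p$lambda_b * m[r, c] + p$lambda_l
    b[i] <- p$lambda_b * m[r, c] * pe_of(p)
  }
  matrix(solve(A, b), ny, nx)
}

# dense direct solve of the quasi-steady antiangiogenic field
dense_drug_A <- function(m, plasma_A, p, g) {
  ny <- g$ny; nx <- g$nx; N <- ny * nx
  A <- matrix(0, N, N); b <- numeric(N)
  idx <- function(r, c) r + (c - 1) * ny
  for (r in 1:ny) for (c in 1:nx) {
    i <- idx(r, c)
    for (q in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx) {
        j <- idx(q[1], q[2])
        A[i, i] <- A[i, i] + p$D_A / g$h^2
        A[i, j] <- A[i, j] - p$D_A / g$h^2
      }
    }
    A[i, i] <- A[i, i] + p$lambda_A * m[r, c] + p$Gamma_l + p$k_A
    b[i] <- p$lambda_A * m[r, c] * plasma_A
  }
  matrix(solve(A, b), ny, nx)
}

# dense direct solve of the quasi-steady chemotherapy field (with the
# Starling filtration source and central flux-form convection), no clipping
dense_drug_d <- function(m, P, plasma_d, n, p, g) {
  ny <- g$ny; nx <- g$nx; N <- ny * nx
  A <- matrix(0, N, N); b <- numeric(N)
  idx <- function(r, c) r + (c - 1) * ny
  for (r in 1:ny) for (c in 1:nx) {
    i <- idx(r, c)
    for (q in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx) {
        j <- idx(q[1], q[2])
        A[i, i] <- A[i, i] + p$D_d / g$h^2
        A[i, j] <- A[i, j] - p$D_d / g$h^2
        gij <- p$k_E * p$K * (P[q[1], q[2]] - P[r, c]) / g$h^2
        A[i, i] <- A[i, i] - gij / 2
        A[i, j] <- A[i, j] - gij / 2
      }
    }
    A[i, i] <- A[i, i] + p$Gamma_l + p$k_d + p$d_r * n[r, c]
    gb <- if (p$gamma_b_form == "starling") {
      max(p$lambda_b * m[r, c] * (p$P_v - P[r, c] -
                                    p$sigma_v * (p$pi_c - p$pi_i)), 0)
    } else p$Gamma_b0 * m[r, c]
    b[i] <- gb * (1 - p$sigma_d) * plasma_d
  }
  matrix(solve(A, b), ny, nx)
}

# classic RK4 for a scalar autonomous ODE
rk4 <- function(f, y0, t_end, nsteps) {
  y <- y0; dt <- t_end / nsteps
  for (s in seq_len(nsteps)) {
    k1 <- f(y); k2 <- f(y + dt * k1 / 2)
    k3 <- f(y + dt * k2 / 2); k4 <- f(y + dt * k3)
    y <- y + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  y
}

# direct-formula SSIM: explicit per-window loops, sample (n-1) statistics
naive_ssim <- function(gt, pred, win = 7, k1 = 0.01, k2 = 0.03, L = NULL) {
  if (is.null(L)) L <- max(gt) - min(gt)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  H <- nrow(gt); W <- ncol(gt)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    x <- gt[i:(i + win - 1), j:(j + win - 1)]
    y <- pred[i:(i + win - 1), j:(j + win - 1)]
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / (win^2 - 1); vy <- sum((y - my)^2) / (win^2 - 1)
    cxy <- sum((x - mx) * (y - my)) / (win^2 - 1)
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# pure-R double-precision reference CNN (direct shifted-copy convolution)
ref_conv <- function(x, Wm, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(Wm)
  out <- array(0, c(H, W, Cout))
  for (co in 1:Cout) {
    acc <- matrix(b[co], H, W)
    for (ci in 1:Cin) for (kc in 0:4) for (kr in 0:4) {
      w <- Wm[(ci - 1) * 25 + kc * 5 + kr + 1, co]
      xs <- matrix(0, H, W)
      rs <- (1:H) + kr - 2; cs <- (1:W) + kc - 2
      vr <- rs >= 1 & rs <= H; vc <- cs >= 1 & cs <= W
      xs[vr, vc] <- x[rs[vr], cs[vc], ci]
      acc <- acc + w * xs
    }
    out[, , co] <- acc
  }
  out
}

ref_cnn_forward <- function(layers, xs, eps = 1e-5) {
  N <- length(xs)
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    zs <- lapply(xs, ref_conv, Wm = ly$W, b = ly$b)
    if (ly$bn) {
      Cout <- dim(zs[[1]])[3]
      for (co in 1:Cout) {
        v <- unlist(lapply(zs, function(z) z[, , co]))
        mu <- mean(v); va <- mean((v - mu)^2)
        for (i in 1:N) {
          xh <- (zs[[i]][, , co] - mu) / sqrt(va + eps)
          zs[[i]][, , co] <- pmax(ly$gamma[co] * xh + ly$beta[co], 0)
        }
      }
    }
    xs <- zs
  }
  xs
}

ref_cnn_loss <- function(layers, xs, ys) {
  os <- ref_cnn_forward(layers, xs)
  mean(vapply(seq_along(os), function(i) mean((os[[i]] - ys[[i]])^2), 0))
}

# a fabricated (non-simulated) case with the container layout of run_case,
# for count/ordering tests that need many cases cheaply
stub_case <- function(patient_seed, init_day, A_dose, d_dose, side = 7,
                      n_days = 8) {
  set.seed(patient_seed * 1000 + init_day)
  daily <- array(runif(n_days * 5 * side * side), c(n_days, 5, side, side))
  post <- array(runif(n_days * 2 * side * side), c(n_days, 2, side, side))
  scal <- matrix(0, n_days, 2)
  for (t_step in 0:(n_days - 1)) {
    if (t_step %in% c(0, 2, 4, 6)) scal[t_step + 1, 1] <- A_dose
    if (t_step %in% c(2, 4, 6)) scal[t_step + 1, 2] <- d_dose
  }
  # step 0 is an A-only event: its post-insertion d map equals the daily map
  post[1, 2, , ] <- daily[1, 5, , ]
  structure(list(daily_frames = daily, post_drug = post, scalars = scal,
                 meta = list(patient_seed = patient_seed, init_day = init_day,
                             A_dose = A_dose, d_dose = d_dose,
                             case_id = sprintf("p%04d_i%02d_A%03.0f_d%03.0f",
                                               patient_seed, init_day,
                                               100 * A_dose, 100 * d_dose)),
                 trajectory = NULL), class = "tme_case")
}

stub_cohort <- function(patients, init_days = c(6, 8),
                        A_doses = 0.6, d_doses = c(0.4, 0.8), side = 7) {
  out <- list()
  for (ps in patients) for (day in init_days)
    for (Ad in A_doses) for (dd in d_doses)
      out[[length(out) + 1]] <- stub_case(ps, day, Ad, dd, side)
  out
}

# one small genuinely simulated cohort, shared (memoised) across tests
.fixture_env <- new.env()
fixture_cases <- function() {
  if (is.null(.fixture_env$cases)) {
    g <- tme_grid(21)
    p <- default_params()
    .fixture_env$grid <- g
    .fixture_env$params <- p
    .fixture_env$cases <- simulate_cohort(c(1, 2), p, g, init_days = 6,
                                          A_doses = 0.6, d_doses = 0.8)
  }
  .fixture_env$cases
}
fixture_grid <- function() { fixture_cases(); .fixture_env$grid }
fixture_params <- function() { fixture_cases(); .fixture_env$params }
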