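# Sparse elliptic solvers for the quasi-steady fields: interstitial fluid
# pressure (IFP) and the two drug concentrations.  All three share the
# 5-point no-flux (Neumann) Laplacian; pixel (r, c) maps to linear index
# r + (c-1)*ny, i.e. R's native column-major order.

# graph Laplacian (positive semidefinite) of the grid with no-flux
# boundaries; -K * del^2 u  is approximated by  (K/h^2) * L2 %*% u
neumann_laplacian <- function(grid) {
  key <- paste0("L2_", grid$ny, "x", grid$nx)
  L2 <- .dent_cache[[key]]
  if (is.null(L2)) {
    lap1 <- function(n) {
      Matrix::bandSparse(n, n,
                         k = c(-1, 0, 1),
                         diagonals = list(rep(-1, n - 1),
                                          c(1, rep(2, max(n - 2, 0)), 1)[seq_len(n)],
                                          rep(-1, n - 1)))
    }
    Ly <- lap1(grid$ny)
    Lx <- lap1(grid$nx)
    L2 <- Matrix::kronecker(Matrix::Diagonal(grid$nx), Ly) +
      Matrix::kronecker(Lx, Matrix::Diagonal(grid$ny))
    L2 <- methods::as(L2, "CsparseMatrix")
    .dent_cache[[key]] <- L2
  }
  L2
}

# solve the SPD system (coef/h^2 * L2 + diag(diagv)) x = b, reusing the
# symbolic Cholesky factorization across calls on the same grid
solve_spd <- function(coef, diagv, b, grid, key) {
  L2 <- neumann_laplacian(grid)
  M <- Matrix::forceSymmetric((coef / grid$h^2) * L2 + Matrix::Diagonal(x = diagv))
  ckey <- paste0("chol_", key, "_", grid$ny, "x", grid$nx)
  ch <- .dent_cache[[ckey]]
  ch <- if (is.null(ch)) {
    Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
  } else {
    Matrix::update(ch, M)
  }
  .dent_cache[[ckey]] <- ch
  as.numeric(Matrix::solve(ch, b, system = "A"))
}

#' Solve the interstitial fluid pressure field
#'
#' Elliptic pressure balance: `-K del^2 P = lambda_b m (P_v - P -
#' sigma_v (pi_c - pi_i)) - lambda_l P` with no-flux boundaries.  The
#' vasculature acts as a distributed fluid source (Starling filtration),
#' lymphatics as a distributed sink.
#'
#' @param m vasculature map (matrix, >= 0).
#' @param params a `tme_params` list.
#' @param grid a `tme_grid`.
#' @return The IFP map `P`, a matrix of the same shape as `m`.
#' @examples
#' g <- tme_grid(9)
#' p <- default_params()
#' P <- solve_pressure(matrix(1, 9, 9), p, g)
#' # uniform vasculature: P is the uniform Starling balance everywhere
#' range(P)
#' @export
solve_pressure <- function(m, params, grid) {
  stopifnot(nrow(m) == grid$ny, ncol(m) == grid$nx)
  if (any(m < 0)) stop("vasculature map must be non-negative")
  lam <- params$lambda_b * as.vector(m) + params$lambda_l
  if (all(lam == 0))
    stop("singular pressure system: K = 0 or lambda_b = lambda_l = 0 ",
         "leaves the Neumann operator with no absorption")
  Pe <- params$P_v - params$sigma_v * (params$pi_c - params$pi_i)
  b <- params$lambda_b * as.vector(m) * Pe
  P <- solve_spd(params$K, lam, b, grid, "P")
  matrix(P, grid$ny, grid$nx)
}

#' Solve the quasi-steady antiangiogenic drug field
#'
#' Steady state of the agent transport equation: `0 = D_A del^2 A +
#' lambda_A m (A_v - A) - Gamma_l A - k_A A`, no-flux boundaries.  Solved
#' at quasi-steady state because drug transport is fast compared with
#' tumor growth.
#'
#' @param m vasculature map.
#' @param plasma_A current plasma concentration `A_v` (scalar >= 0).
#' @param params,grid model parameters and grid.
#' @return The agent concentration map (matrix, >= 0).
#' @export
solve_drug_A <- function(m, plasma_A, params, grid) {
  stopifnot(nrow(m) == grid$ny, ncol(m) == grid$nx, plasma_A >= 0)
  if (any(m < 0)) stop("vasculature map must be non-negative")
  diagv <- params$lambda_A * as.vector(m) + params$Gamma_l + params$k_A
  if (all(diagv == 0))
    stop("singular drug-A system: all sink/source coefficients are zero")
  b <- params$lambda_A * as.vector(m) * plasma_A
  A <- solve_spd(params$D_A, diagv, b, grid, "A")
  A <- matrix(A, grid$ny, grid$nx)
  clip_field(A, "A", params)
}

# transvascular convection coefficient Gamma_b for the chemotherapy source.
# Starling form: lambda_b * m * (P_v - P - sigma_v (pi_c - pi_i)), clamped
# at zero (no reverse convective source); alternative plain constant * m.
gamma_b_field <- function(m, P, params) {
  if (params$gamma_b_form == "starling") {
    pmax(params$lambda_b * m *
           (params$P_v - P - params$sigma_v * (params$pi_c - params$pi_i)), 0)
  } else {
    params$Gamma_b0 * m
  }
}

# sparse convection operator C with (C d)_i = div(k_E d K grad P)_i using
# central face averages for d and zero flux through boundary faces
convection_matrix <- function(P, params, grid) {
  ny <- grid$ny; nx <- grid$nx; h <- grid$h
  kK <- params$k_E * params$K
  idx <- matrix(seq_len(ny * nx), ny, nx)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(i_from, i_to) {
    g <- kK * (as.vector(P)[i_to] - as.vector(P)[i_from]) / h^2
    # row i_from: + g/2 * (d_from + d_to)
    ii <<- c(ii, i_from, i_from, i_to, i_to)
    jj <<- c(jj, i_from, i_to, i_to, i_from)
    xx <<- c(xx, g / 2, g / 2, -g / 2, -g / 2)
  }
  # vertical faces: (r, c) - (r+1, c)
  add_faces(as.vector(idx[-ny, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  # horizontal faces: (r, c) - (r, c+1)
  add_faces(as.vector(idx[, -nx, drop = FALSE]), as.vector(idx[, -1, drop = FALSE]))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ny * nx, ny * nx))
}

#' Solve the quasi-steady chemotherapy drug field
#'
#' Steady state of the convection-diffusion transport equation:
#' `0 = D_d del^2 d + div(k_E d K grad P) + Gamma_b (1 - sigma_d) d_v -
#' Gamma_l d - d_r d n - k_d d`, no-flux boundaries.  `Gamma_b` is the
#' transvascular convection coefficient; by default the Starling filtration
#' form `lambda_b m (P_v - P - sigma_v (pi_c - pi_i))` clamped at zero
#' (set `params$gamma_b_form = "constant"` for a plain `Gamma_b0 * m`).
#'
#' @param m vasculature map.
#' @param P IFP map (as from [solve_pressure()]).
#' @param plasma_d current plasma concentration `d_v` (scalar >= 0).
#' @param n tumor cell density map (reaction sink `d_r d n`).
#' @param params,grid model parameters and grid.
#' @return The chemotherapy concentration map (matrix, >= 0).
#' @export
solve_drug_d <- function(m, P, plasma_d, n, params, grid) {
  stopifnot(nrow(m) == grid$ny, ncol(m) == grid$nx,
            all(dim(P) == dim(m)), all(dim(n) == dim(m)), plasma_d >= 0)
  if (!all(is.finite(P))) stop("non-finite pressure field passed to solve_drug_d")
  sink <- params$Gamma_l + params$k_d + params$d_r * as.vector(n)
  if (all(sink == 0) && params$D_d == 0)
    stop("singular drug-d system: all sink/source coefficients are zero")
  L2 <- neumann_laplacian(grid)
  M <- (params$D_d / grid$h^2) * L2 - convection_matrix(P, params, grid) +
    Matrix::Diagonal(x = sink)
  b <- as.vector(gamma_b_field(m, P, params)) * (1 - params$sigma_d) * plasma_d
  d <- as.numeric(Matrix::solve(M, b))
  d <- matrix(d, grid$ny, grid$nx)
  clip_field(d, "d", params)
}

# clip small negative values produced by discretisation; warn when the
# clipped mass is non-negligible relative to the field total
clip_field <- function(x, name, params) {
  neg <- x < 0
  if (any(neg)) {
    lost <- -sum(x[neg])
    tot <- sum(x[!neg])
    if (tot > 0 && lost > params$clip_warn_frac * tot)
      warning(sprintf("clipped %.3g negative mass (%.2g%% of total) in field %s",
                      lost, 100 * lost / tot, name))
    x[neg] <- 0
  }
  x
}
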