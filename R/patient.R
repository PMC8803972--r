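#' Initialize a virtual patient
#'
#' Builds the day-0 state of one patient: a centered isotropic Gaussian
#' tumor seed, a randomly initialized vasculature relaxed into islands by
#' the bistable vessel dynamics, the matching IFP field, and zero drug
#' fields.  The vasculature is the only random ingredient, so a patient is
#' fully identified by the seed: identical seeds give bit-identical states.
#'
#' The raw vasculature is i.i.d. `Uniform(m0_lo, m0_hi)` per pixel and is
#' relaxed for `params$burnin_steps` recorded steps of the vessel equation
#' (with no tumor coupling and no drug), which pushes pixels below the
#' unstable knee `m = a` towards the avascular state and the rest towards
#' the vascularised state `m = 1`, yielding a speckled island pattern.
#'
#' @param seed integer patient seed.
#' @param params,grid model parameters and grid.
#' @return A `tme_state` list with matrices `n`, `m`, `P`, `A`, `d` and the
#'   scalar time `t = 0`.
#' @examples
#' st <- init_patient(1, default_params(), tme_grid(41))
#' which(st$n == max(st$n), arr.ind = TRUE)  # grid center
#' @export
init_patient <- function(seed, params, grid) {
  set.seed(as.integer(seed))
  ny <- grid$ny; nx <- grid$nx
  m <- matrix(runif(ny * nx, params$m0_lo, params$m0_hi), ny, nx)

  zero <- matrix(0, ny, nx)
  # burn-in relaxation of the bistable vessel field, tumor and drug absent:
  # burnin_steps recorded steps (sub-stepped only if stability demands it)
  sub <- max(1L, as.integer(ceiling(grid$dt_record / stability_dt(params, grid))))
  res <- .cpp_step_nm(zero, m, zero, zero, grid$h, grid$dt_record / sub,
                      as.integer(params$burnin_steps) * sub,
                      params$D_n, params$r_n, params$n_lim, params$alpha_mn,
                      params$d_r, params$D_m, params$alpha, params$beta,
                      params$gamma, params$beta_nm, params$alpha_nm, params$A_r)
  st <- list(n = zero, m = res$m, P = zero, A = zero, d = zero, t = 0)

  sigma <- params$n0_sigma
  if (is.na(sigma)) sigma <- nx / 25
  cy <- floor((ny - 1) / 2) + 1  # 0-based center (e.g. pixel 75 for 151)
  cx <- floor((nx - 1) / 2) + 1
  rr <- matrix(seq_len(ny), ny, nx) - cy
  cc <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  st$n <- params$n0_amp * exp(-(rr^2 + cc^2) / (2 * sigma^2))

  st$P <- solve_pressure(st$m, params, grid)
  structure(st, class = "tme_state")
}

#' @export
print.tme_state <- function(x, ...) {
  cat(sprintf("<tme_state> %d x %d, t = %.3f days; total n = %.3f, mean m = %.3f\n",
              nrow(x$n), ncol(x$n), x$t, sum(x$n), mean(x$m)))
  invisible(x)
}
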