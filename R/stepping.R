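# Explicit forward-Euler updates for the two reaction-diffusion fields.
# 5-point flux-form stencils with no-flux boundaries; clipping at zero
# keeps the fields physical.

#' Largest stable explicit time step
#'
#' Diffusive stability bound `safety * h^2 / (4 * max(D_n, D_m))` for the
#' explicit Euler update of the tumor and vasculature fields.
#'
#' @param params,grid model parameters and grid.
#' @return The bound in days.
#' @export
stability_dt <- function(params, grid) {
  Dmax <- max(params$D_n, params$D_m)
  if (Dmax == 0) return(Inf)
  params$safety * grid$h^2 / (4 * Dmax)
}

check_dt <- function(dt, params, grid) {
  bound <- stability_dt(params, grid)
  if (dt > bound)
    stop(sprintf(paste0("dt = %g violates the explicit stability bound %g; ",
                        "integrate with %d sub-steps of dt = %g instead"),
                 dt, bound, ceiling(dt / bound), dt / ceiling(dt / bound)))
  invisible(bound)
}

#' One explicit step of the tumor cell density equation
#'
#' `n' = n + dt * (D_n del^2 n + r_n n (1 - n/n_lim) + alpha_mn n m -
#' d_r n d)`, clipped at zero, no-flux boundaries.  Refuses time steps
#' above the diffusive stability bound (see [stability_dt()]).
#'
#' @param state list with matrices `n`, `m`, `d` (see [init_patient()]).
#' @param params,grid model parameters and grid.
#' @param dt time step in days.
#' @return The updated tumor density matrix.
#' @export
step_tumor_density <- function(state, params, grid, dt = grid$dt_record) {
  check_dt(dt, params, grid)
  n <- state$n
  upd <- n + dt * (params$D_n * .cpp_laplacian(n, grid$h) +
                     params$r_n * n * (1 - n / params$n_lim) +
                     params$alpha_mn * n * state$m -
                     params$d_r * n * state$d)
  clip_field(upd, "n", params)
}

#' One explicit step of the vasculature equation
#'
#' `m' = m + dt * (D_m del^2 m + m (alpha + beta m + gamma m^2) +
#' beta_nm div(m grad n) + alpha_nm n (1 - n/n_lim) m - A_r m A)`, clipped
#' at zero, no-flux boundaries.
#'
#' @inheritParams step_tumor_density
#' @return The updated vasculature matrix.
#' @export
step_vasculature <- function(state, params, grid, dt = grid$dt_record) {
  check_dt(dt, params, grid)
  m <- state$m; n <- state$n
  upd <- m + dt * (params$D_m * .cpp_laplacian(m, grid$h) +
                     m * (params$alpha + params$beta * m + params$gamma * m^2) +
                     params$beta_nm * .cpp_div_m_grad_n(m, n, grid$h) +
                     params$alpha_nm * n * (1 - n / params$n_lim) * m -
                     params$A_r * m * state$A)
  clip_field(upd, "m", params)
}

# fast coupled update used by the case integrator: advances n and m together
# over one recorded step, sub-stepping automatically when needed
advance_nm <- function(state, params, grid, dt = grid$dt_record) {
  bound <- stability_dt(params, grid)
  nsub <- max(1L, as.integer(ceiling(dt / bound)))
  res <- .cpp_step_nm(state$n, state$m, state$A, state$d,
                      grid$h, dt / nsub, nsub,
                      params$D_n, params$r_n, params$n_lim, params$alpha_mn,
                      params$d_r, params$D_m, params$alpha, params$beta,
                      params$gamma, params$beta_nm, params$alpha_nm, params$A_r)
  state$n <- res$n
  state$m <- res$m
  state$t <- state$t + dt
  state
}
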