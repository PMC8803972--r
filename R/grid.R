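#' Simulation grid
#'
#' Regular square pixel grid on which all five microenvironment fields live.
#' Time is measured in days (dimensionless model time); one day is divided
#' into `steps_per_day` recorded steps, the default 48 giving the 30-minute
#' recording resolution of the simulated cases.
#'
#' @param nx,ny grid size in pixels (default 151 x 151).
#' @param h grid spacing in dimensionless length units (1 per pixel).
#' @param steps_per_day recorded integration steps per day of model time.
#' @return A `tme_grid` object (list with `nx`, `ny`, `h`, `steps_per_day`,
#'   `dt_record`).
#' @examples
#' g <- tme_grid(31)
#' g$dt_record * g$steps_per_day  # exactly one day
#' @export
tme_grid <- function(nx = 151L, ny = nx, h = 1, steps_per_day = 48L) {
  stopifnot(nx >= 3, ny >= 3, h > 0, steps_per_day >= 1)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), h = as.numeric(h),
         steps_per_day = as.integer(steps_per_day),
         dt_record = 1 / as.integer(steps_per_day)),
    class = "tme_grid")
}

#' @export
print.tme_grid <- function(x, ...) {
  cat(sprintf("<tme_grid> %d x %d pixels, h = %g, %d steps/day (dt = %.5f)\n",
              x$ny, x$nx, x$h, x$steps_per_day, x$dt_record))
  invisible(x)
}

#' Default dimensionless model parameters
#'
#' Named default coefficient set for the coupled tumor / vasculature /
#' pressure / drug model.  The governing equations come from the published
#' model; their coefficient values are not printed there, so this set was
#' chosen once to reproduce the qualitative tumor-microenvironment features
#' the model is known for (IFP plateau in the core dropping at the rim,
#' vessel density decreasing towards the tumor center, peripheral
#' accumulation of large chemotherapy particles, tumor shrinkage under
#' treatment).  Every value can be overridden.
#'
#' Units: lengths in pixels (h = 1), time in days, field amplitudes O(1)
#' with the tumor carrying capacity `n_lim = 1`.
#'
#' The bistable vessel reaction m(alpha + beta m + gamma m^2) is
#' parameterised as alpha = -a, beta = 1 + a, gamma = -1, giving fixed
#' points at m = 0, m = a (unstable knee) and m = 1, so `a` is the
#' fraction-style knob that decides which initial pixels collapse to the
#' avascular state and which saturate to the vascularised one.
#'
#' @param ... named overrides of any default value.
#' @return A `tme_params` list.
#' @examples
#' p <- default_params(r_n = 0.4)
#' p$r_n
#' @export
default_params <- function(...) {
  a <- 0.5
  p <- list(
    # Tumor cell density (reaction-diffusion, logistic growth)
    D_n = 0.5, r_n = 0.3, n_lim = 1, alpha_mn = 0.01, d_r = 1.0,
    # Vasculature (bistable islands + taxis + angiogenesis + pruning)
    D_m = 0.08, a = a, alpha = -a, beta = 1 + a, gamma = -1,
    beta_nm = 2, alpha_nm = 3, A_r = 2.0,
    # Interstitial fluid pressure (elliptic balance)
    K = 50, lambda_b = 10, lambda_l = 2,
    P_v = 1, sigma_v = 0.25, pi_c = 0.5, pi_i = 0.1,
    # Antiangiogenic agent (small molecule, diffusion-dominated)
    D_A = 2, lambda_A = 1, Gamma_l = 0.3, k_A = 0.5,
    # Chemotherapy drug (~100 nm particles, convection matters)
    D_d = 0.5, k_E = 0.5, sigma_d = 0.5, k_d = 0.3,
    gamma_b_form = "starling", Gamma_b0 = 1,
    # Bolus pharmacokinetics (single-exponential plasma decay)
    A0 = 1, d0 = 1, tA_half = 1, td_half = 1,
    # Initial conditions
    n0_amp = 0.5, n0_sigma = NA_real_,   # NA: sigma = nx / 25 pixels
    m0_lo = 0.2, m0_hi = 0.8, burnin_steps = 200,
    # Numerics
    clip_warn_frac = 1e-6, safety = 0.9,
    # Tumor cell density summary threshold (fraction of n_lim)
    density_threshold_frac = 0.05
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    # keep alpha/beta/gamma consistent when only `a` is overridden
    if ("a" %in% names(over) &&
        !any(c("alpha", "beta", "gamma") %in% names(over))) {
      over$alpha <- -over$a
      over$beta <- 1 + over$a
      over$gamma <- -1
    }
    p <- modifyList(p, over)
  }
  validate_params(structure(p, class = "tme_params"))
}

#' Validate a parameter set
#'
#' Checks the sign constraints every rate and diffusion coefficient must
#' satisfy.  Called by [default_params()]; call directly after manual edits.
#'
#' @param p a `tme_params` list.
#' @return `p`, invisibly classed, or an error.
#' @export
validate_params <- function(p) {
  nonneg <- c("D_n", "r_n", "alpha_mn", "d_r", "D_m", "beta_nm", "alpha_nm",
              "A_r", "K", "lambda_b", "lambda_l", "D_A", "lambda_A",
              "Gamma_l", "k_A", "D_d", "k_E", "k_d", "A0", "d0")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("parameter '", nm, "' must be a finite non-negative scalar")
  }
  if (!is.finite(p$n_lim) || p$n_lim <= 0) stop("n_lim must be > 0")
  if (p$tA_half <= 0 || p$td_half <= 0)
    stop("plasma decay times must be > 0")
  if (!p$gamma_b_form %in% c("starling", "constant"))
    stop("gamma_b_form must be 'starling' or 'constant'")
  if (!inherits(p, "tme_params")) class(p) <- c("tme_params", class(p))
  p
}

#' @export
print.tme_params <- function(x, ...) {
  cat("<tme_params> dimensionless model coefficients\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), "")
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}

# channel order shared by every array in the package
tme_channels <- function() c("n", "m", "P", "A", "d")
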