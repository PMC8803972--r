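#' Plasma concentration after a bolus injection
#'
#' Single-exponential decay of the plasma drug level following a bolus:
#' `c0 * exp(-t / t_half)`.  Note the decay constant enters as an e-folding
#' time exactly as the model writes it (the curve reaches `c0/e`, not
#' `c0/2`, at `t = t_half`).
#'
#' @param t_since_injection time since the bolus, in days (>= 0).
#' @param c0 plasma concentration immediately after the bolus.
#' @param t_half e-folding time of the plasma decay (> 0).
#' @return The plasma concentration, a scalar (vectorised over `t`).
#' @examples
#' plasma_concentration(0, 0.6, 1)    # 0.6
#' plasma_concentration(1, 1, 1)      # exp(-1)
#' @export
plasma_concentration <- function(t_since_injection, c0, t_half) {
  if (!is.numeric(t_half) || length(t_half) != 1 || !is.finite(t_half) ||
      t_half <= 0)
    stop("t_half must be a positive finite scalar")
  if (any(t_since_injection < 0)) stop("t_since_injection must be >= 0")
  c0 * exp(-t_since_injection / t_half)
}
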