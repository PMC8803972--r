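# Image-quality metrics (PSNR, single-scale SSIM) and the thresholded
# tumor-cell-density summary used to track growth/shrinkage.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` where `R` is the dynamic range of the ground
#' truth, `max(gt) - min(gt)`.  Returns `Inf` for a perfect prediction and
#' refuses constant ground truths (undefined range).
#'
#' @param gt,pred numeric matrices of identical shape; `gt` is the
#'   reference image.
#' @return PSNR in dB (a scalar; `Inf` when `pred` equals `gt`).
#' @examples
#' gt <- matrix(c(0, 1), 4, 4)
#' psnr(gt, gt + 0.1)  # R = 1, MSE = 0.01 -> exactly 20
#' @export
psnr <- function(gt, pred) {
  stopifnot(all(dim(gt) == dim(pred)))
  R <- max(gt) - min(gt)
  if (R == 0) stop("undefined PSNR: constant ground-truth image (range 0)")
  mse <- mean((gt - pred)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

# sums over all w x w windows fully inside the matrix, via 2D cumsum
window_sums <- function(x, w) {
  S <- apply(apply(x, 2, cumsum), 1, cumsum)   # S[j, i] = sum x[1:i, 1:j]
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  H <- nrow(x); W <- ncol(x)
  i1 <- 1:(H - w + 1); j1 <- 1:(W - w + 1)
  S[i1 + w, j1 + w, drop = FALSE] - S[i1, j1 + w, drop = FALSE] -
    S[i1 + w, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

#' Structural similarity index (single scale)
#'
#' Windowed SSIM with a uniform `win x win` window over all fully-interior
#' window positions, sample (n-1) normalisation for variances/covariance,
#' and stabilizers `C1 = (k1 L)^2`, `C2 = (k2 L)^2` where the dynamic range
#' `L` defaults to the ground-truth range of the frame.  The score is the
#' mean of the per-window SSIM map and lies in `[-1, 1]`.
#'
#' @param gt,pred numeric matrices of identical shape; `gt` is the
#'   reference.
#' @param win window side in pixels.
#' @param k1,k2 stabilizer constants.
#' @param L dynamic range; default `max(gt) - min(gt)`.
#' @return The mean SSIM, a scalar in `[-1, 1]`.
#' @export
ssim <- function(gt, pred, win = 7, k1 = 0.01, k2 = 0.03, L = NULL) {
  stopifnot(all(dim(gt) == dim(pred)))
  if (win > min(dim(gt)))
    stop("SSIM window (", win, ") larger than the image")
  if (identical(dim(gt), dim(pred)) && all(gt == pred)) return(1)
  if (is.null(L)) L <- max(gt) - min(gt)
  if (L == 0) stop("undefined SSIM: constant ground truth and no range L given")
  nw <- win * win
  mu_x <- window_sums(gt, win) / nw
  mu_y <- window_sums(pred, win) / nw
  # sample variance/covariance (n-1 normalisation)
  vx <- (window_sums(gt^2, win) - nw * mu_x^2) / (nw - 1)
  vy <- (window_sums(pred^2, win) - nw * mu_y^2) / (nw - 1)
  cxy <- (window_sums(gt * pred, win) - nw * mu_x * mu_y) / (nw - 1)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  smap <- ((2 * mu_x * mu_y + C1) * (2 * cxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (vx + vy + C2))
  mean(smap)
}

#' Thresholded tumor cell density
#'
#' Dimensionless summary `C`: the mean of the tumor-density pixels whose
#' value exceeds the threshold; 0 when no pixel qualifies.  Computed on
#' unscaled (physical) density maps.
#'
#' @param n_map tumor density matrix (unscaled).
#' @param threshold density threshold (default 0.05, i.e. 5% of a unit
#'   carrying capacity).
#' @return The scalar density summary `C`.
#' @export
tumor_cell_density <- function(n_map, threshold = 0.05) {
  v <- n_map[n_map > threshold]
  if (length(v) == 0) return(0)
  mean(v)
}

#' Absolute percentage error series of tumor cell density
#'
#' `100 * |C_gt - C_pred| / C_gt` per day.
#'
#' @param C_gt,C_pred per-day density summaries (equal-length vectors,
#'   `C_gt > 0`).
#' @return Vector of absolute percentage errors.
#' @export
mape_series <- function(C_gt, C_pred) {
  stopifnot(length(C_gt) == length(C_pred))
  if (any(C_gt == 0))
    stop("undefined MAPE: ground-truth tumor cell density is zero")
  100 * abs(C_gt - C_pred) / C_gt
}
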