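# Test-set evaluation: roll the trained forecaster out over the seven
# therapy days of each held-out case and score the predicted maps with
# framewise SSIM/PSNR plus the thresholded tumor-cell-density error.

#' Evaluate a trained model on held-out cases
#'
#' For every case: scale the step-0 maps with the model's (training-fitted)
#' scaler, roll out 7 composed steps under the case's dose schedule, then
#' score each predicted day.  SSIM and PSNR are computed per day and per
#' channel on the scaled maps (a common scale makes the cross-channel
#' average meaningful) and averaged over the five channels, then over
#' cases; the tumor-cell-density summary `C` is computed on the
#' inverse-scaled (physical) density maps.  Per-day spread is the sample
#' standard deviation across cases.  Infinite PSNR values (exact
#' reproductions) are excluded from averages and counted, as are
#' channel-days whose ground truth is constant (e.g. the chemotherapy map
#' before the first chemo bolus), where the PSNR dynamic range is
#' undefined; SSIM falls back to the scaled-space range L = 1 there.
#'
#' @param model a trained `dent_model` with its scaler.
#' @param test_cases list of `tme_case` from patients unseen in training.
#' @param threshold density threshold for `C` (default `0.05 * n_lim`
#'   with a unit carrying capacity).
#' @param x_steps number of rollout days (default 7).
#' @param rollout_fn the forecasting function; defaults to [rollout()].
#'   Injectable so oracle forecasters can exercise the harness in tests.
#' @return A `metric_series`: list with `per_day` (data.frame: day,
#'   ssim_mean/sd, psnr_mean/sd, mape_mean/sd), `n_cases`, `C_gt`,
#'   `C_pred` (cases x days matrices including day 0), `psnr_inf_count`.
#' @export
evaluate_testset <- function(model, test_cases, threshold = 0.05,
                             x_steps = 7, rollout_fn = rollout) {
  stopifnot(inherits(model, "dent_model"), length(test_cases) > 0)
  stats <- model$scaler
  n_cases <- length(test_cases)
  ssim_cd <- matrix(NA_real_, n_cases, x_steps)
  psnr_cd <- matrix(NA_real_, n_cases, x_steps)
  C_gt <- matrix(NA_real_, n_cases, x_steps + 1)
  C_pred <- matrix(NA_real_, n_cases, x_steps + 1)
  inf_count <- 0L
  skip_count <- 0L

  for (ci in seq_len(n_cases)) {
    cs <- test_cases[[ci]]
    x0 <- scale_maps(frame_to_maps(cs$daily_frames, 1), stats)
    doses <- cs$scalars[seq_len(x_steps), , drop = FALSE]
    preds <- rollout_fn(model, x0, doses, x_steps)
    C_gt[ci, 1] <- tumor_cell_density(cs$daily_frames[1, 1, , ], threshold)
    C_pred[ci, 1] <- C_gt[ci, 1]
    for (day in seq_len(x_steps)) {
      gt_s <- scale_maps(frame_to_maps(cs$daily_frames, day + 1), stats)
      pr_s <- preds[[day]]
      svals <- pvals <- numeric(0)
      for (ch in 1:5) {
        gt_ch <- gt_s[, , ch]; pr_ch <- pr_s[, , ch]
        if (max(gt_ch) == min(gt_ch)) {
          skip_count <- skip_count + 1L
          svals <- c(svals, ssim(gt_ch, pr_ch, L = 1))
          next
        }
        svals <- c(svals, ssim(gt_ch, pr_ch))
        p <- psnr(gt_ch, pr_ch)
        if (is.infinite(p)) inf_count <- inf_count + 1L else pvals <- c(pvals, p)
      }
      ssim_cd[ci, day] <- mean(svals)
      psnr_cd[ci, day] <- if (length(pvals)) mean(pvals) else NA_real_
      C_gt[ci, day + 1] <- tumor_cell_density(cs$daily_frames[day + 1, 1, , ],
                                              threshold)
      C_pred[ci, day + 1] <- tumor_cell_density(
        invert_minmax(pr_s[, , 1], stats, "n"), threshold)
    }
  }
  if (inf_count > 0)
    message(inf_count, " infinite PSNR value(s) excluded from averages")

  mape_cd <- matrix(NA_real_, n_cases, x_steps)
  for (ci in seq_len(n_cases))
    mape_cd[ci, ] <- mape_series(C_gt[ci, -1], C_pred[ci, -1])

  per_day <- data.frame(
    day = seq_len(x_steps),
    ssim_mean = colMeans(ssim_cd), ssim_sd = apply(ssim_cd, 2, sd),
    psnr_mean = colMeans(psnr_cd, na.rm = TRUE),
    psnr_sd = apply(psnr_cd, 2, sd, na.rm = TRUE),
    mape_mean = colMeans(mape_cd), mape_sd = apply(mape_cd, 2, sd))
  structure(list(per_day = per_day, n_cases = n_cases, C_gt = C_gt,
                 C_pred = C_pred, psnr_inf_count = inf_count,
                 psnr_skip_count = skip_count),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %d cases, %d prediction days\n", x$n_cases,
              nrow(x$per_day)))
  print(format(x$per_day, digits = 4), row.names = FALSE)
  invisible(x)
}
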