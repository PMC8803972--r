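# Supervised dataset construction: min-max scaling fitted on training data
# only, Diffuser pairs (drug insertion events) and Elapser pairs (one-day
# transitions), and patient-wise cross-validation folds.

#' Fit min-max scaling statistics on training cases
#'
#' Per-channel global minimum and maximum pooled over every training pixel,
#' and per-drug minimum and maximum over the training insertion doses.
#' Drug channels additionally pool the one-hour post-insertion maps, which
#' are the Diffuser targets and exceed every pre-insertion daily frame.
#' Fitting must only ever see training cases; the returned statistics are
#' all that later stages may carry forward (no leakage).
#'
#' @param cases list of `tme_case` training cases.
#' @return A `scaler_stats` list with `ch_min`, `ch_max` (length 5, channel
#'   order n, m, P, A, d) and `dose_min`, `dose_max` (length 2, A then d).
#' @export
fit_minmax <- function(cases) {
  if (length(cases) == 0) stop("cannot fit scaling on an empty training set")
  ch_min <- rep(Inf, 5); ch_max <- rep(-Inf, 5)
  doses <- list(numeric(0), numeric(0))
  for (cs in cases) {
    for (ch in 1:5) {
      v <- cs$daily_frames[, ch, , ]
      ch_min[ch] <- min(ch_min[ch], min(v))
      ch_max[ch] <- max(ch_max[ch], max(v))
    }
    for (k in 1:2) {
      v <- cs$post_drug[, k, , ]
      ch_min[3 + k] <- min(ch_min[3 + k], min(v))
      ch_max[3 + k] <- max(ch_max[3 + k], max(v))
      dk <- cs$scalars[, k]
      doses[[k]] <- c(doses[[k]], dk[dk > 0])
    }
  }
  dose_min <- vapply(doses, function(v) if (length(v)) min(v) else NA_real_, 0)
  dose_max <- vapply(doses, function(v) if (length(v)) max(v) else NA_real_, 0)
  for (ch in 1:5) {
    if (!(ch_max[ch] > ch_min[ch]))
      stop(sprintf("degenerate scale: channel %s is constant (min = max = %g)",
                   tme_channels()[ch], ch_min[ch]))
  }
  for (k in 1:2) {
    if (!is.na(dose_min[k]) && !(dose_max[k] > dose_min[k])) {
      # a single dose level in training is legal; pin it to 1
      dose_min[k] <- 0
      if (dose_max[k] == 0) stop("degenerate scale: all doses are zero")
    }
  }
  structure(list(ch_min = ch_min, ch_max = ch_max,
                 dose_min = dose_min, dose_max = dose_max,
                 channels = tme_channels()),
            class = "scaler_stats")
}

#' Min-max scale values
#'
#' `z = (x - min) / (max - min)` with the fitted training statistics.
#' Training values map into `[0, 1]`; values outside the training range map
#' outside `[0, 1]` and are deliberately not clipped.
#'
#' @param x numeric vector/matrix/array to scale.
#' @param stats a `scaler_stats` from [fit_minmax()].
#' @param what which statistic to use: one of `"n"`, `"m"`, `"P"`, `"A"`,
#'   `"d"`, `"A_dose"`, `"d_dose"`.
#' @return `x` scaled (same shape).
#' @export
apply_minmax <- function(x, stats, what) {
  rng <- scaler_range(stats, what)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(x, stats, what) {
  rng <- scaler_range(stats, what)
  x * (rng[2] - rng[1]) + rng[1]
}

scaler_range <- function(stats, what) {
  chs <- stats$channels
  if (what %in% chs) {
    i <- match(what, chs)
    c(stats$ch_min[i], stats$ch_max[i])
  } else if (what == "A_dose") {
    c(stats$dose_min[1], stats$dose_max[1])
  } else if (what == "d_dose") {
    c(stats$dose_min[2], stats$dose_max[2])
  } else stop("unknown scaling target: ", what)
}

# scale a 5-channel (ny, nx, 5) map stack channel-wise
scale_maps <- function(maps, stats, invert = FALSE) {
  f <- if (invert) invert_minmax else apply_minmax
  for (ch in 1:5) maps[, , ch] <- f(maps[, , ch], stats, stats$channels[ch])
  maps
}

# (day, channel, ny, nx) frame -> (ny, nx, channels) array
frame_to_maps <- function(frames, day, channels = 1:5) {
  out <- array(0, c(dim(frames)[3], dim(frames)[4], length(channels)))
  for (k in seq_along(channels)) out[, , k] <- frames[day, channels[k], , ]
  out
}

#' Build the drug-insertion (Diffuser) training pairs
#'
#' One pair per insertion event per case: the input is the scaled
#' five-channel state at the insertion step plus the raw and scaled dose
#' scalars; the target is the scaled two-channel (A, d) drug maps one hour
#' after the insertion.  Ordering is canonical (case id, then step) so the
#' dataset is byte-stable across runs.
#'
#' @param cases list of `tme_case`.
#' @param stats `scaler_stats` fitted on the training cases.
#' @return List of pairs, each a list with `x` (ny x nx x 5, scaled),
#'   `A_dose`, `d_dose` (raw), `A_dose_s`, `d_dose_s` (scaled), `y`
#'   (ny x nx x 2, scaled), `case_id`, `step`.
#' @export
build_diffuser_pairs <- function(cases, stats) {
  cases <- sort_cases(cases)
  pairs <- list()
  for (cs in cases) {
    ins <- which(rowSums(cs$scalars) > 0) - 1L    # 0-based steps
    for (t_step in sort(ins)) {
      if (t_step + 1L > dim(cs$post_drug)[1])
        stop("malformed case ", cs$meta$case_id,
             ": missing post-insertion frame at step ", t_step)
      x <- scale_maps(frame_to_maps(cs$daily_frames, t_step + 1L), stats)
      y <- array(0, c(dim(x)[1], dim(x)[2], 2))
      y[, , 1] <- apply_minmax(cs$post_drug[t_step + 1L, 1, , ], stats, "A")
      y[, , 2] <- apply_minmax(cs$post_drug[t_step + 1L, 2, , ], stats, "d")
      Ad <- cs$scalars[t_step + 1L, 1]; dd <- cs$scalars[t_step + 1L, 2]
      pairs[[length(pairs) + 1L]] <- list(
        x = x, A_dose = Ad, d_dose = dd,
        A_dose_s = if (Ad > 0) apply_minmax(Ad, stats, "A_dose") else 0,
        d_dose_s = if (dd > 0) apply_minmax(dd, stats, "d_dose") else 0,
        y = y, case_id = cs$meta$case_id, step = t_step)
    }
  }
  pairs
}

#' Build the one-day transition (Elapser) training pairs
#'
#' One pair per consecutive-day transition per case (7 per 8-day case).
#' The input is the post-insertion state of day t (daily n, m, P with the
#' one-hour-post drug maps, matching what the composed forecaster sees);
#' the target is the pre-insertion state of day t + 1, so no injection ever
#' falls inside a pair's interval.
#'
#' @inheritParams build_diffuser_pairs
#' @return List of pairs with `x`, `y` (both ny x nx x 5, scaled),
#'   `case_id`, `step`.
#' @export
build_elapser_pairs <- function(cases, stats) {
  cases <- sort_cases(cases)
  pairs <- list()
  for (cs in cases) {
    n_days <- dim(cs$daily_frames)[1]
    for (t_step in 0:(n_days - 2L)) {
      x <- frame_to_maps(cs$daily_frames, t_step + 1L)
      x[, , 4] <- cs$post_drug[t_step + 1L, 1, , ]
      x[, , 5] <- cs$post_drug[t_step + 1L, 2, , ]
      pairs[[length(pairs) + 1L]] <- list(
        x = scale_maps(x, stats),
        y = scale_maps(frame_to_maps(cs$daily_frames, t_step + 2L), stats),
        case_id = cs$meta$case_id, step = t_step)
    }
  }
  pairs
}

sort_cases <- function(cases) {
  ids <- vapply(cases, function(cs) cs$meta$case_id, "")
  cases[order(ids)]
}

#' Tile dose scalars onto a map stack
#'
#' Appends two constant planes holding the scaled dose scalars to a
#' five-channel input, producing the 7-channel tensor the drug-insertion
#' networks consume.
#'
#' @param maps ny x nx x 5 scaled maps.
#' @param A_dose_s,d_dose_s scaled dose scalars.
#' @return ny x nx x 7 array; channels 6 and 7 are the constant planes.
#' @export
tile_scalars <- function(maps, A_dose_s, d_dose_s) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[3] == 5)
  out <- array(0, dim(maps) + c(0, 0, 2))
  out[, , 1:5] <- maps
  out[, , 6] <- A_dose_s
  out[, , 7] <- d_dose_s
  out
}

#' Patient-wise cross-validation folds
#'
#' Assigns whole patients to validation folds so that no patient - and
#' hence no spatially or temporally correlated case - appears on both sides
#' of any split.  With `k` equal to the number of patients this is
#' leave-one-patient-out.
#'
#' @param patient_ids vector of patient identifiers (seeds).
#' @param k number of folds.
#' @return A `fold_split`: list of `k` elements, each with `train` and
#'   `val` patient id vectors.
#' @export
patient_folds <- function(patient_ids, k = 5) {
  ids <- sort(unique(patient_ids))
  if (k > length(ids))
    stop("k = ", k, " exceeds the number of patients (", length(ids), ")")
  assign <- ((seq_along(ids) - 1L) %% k) + 1L
  folds <- lapply(seq_len(k), function(f)
    list(train = ids[assign != f], val = ids[assign == f]))
  structure(folds, class = "fold_split")
}

# subset a case list by patient seed
cases_of <- function(cases, patient_ids) {
  keep <- vapply(cases, function(cs) cs$meta$patient_seed %in% patient_ids, TRUE)
  cases[keep]
}
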