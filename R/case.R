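# Case simulation: untreated growth up to the therapy initiation day, then
# eight therapy days at 30-minute resolution with scheduled bolus
# injections and quasi-steady drug transport.

#' Therapy schedule
#'
#' Insertion schedule for one case.  The defaults encode the fixed design
#' used throughout: antiangiogenic boluses at the end of therapy steps
#' 0, 2, 4, 6 and chemotherapy boluses at the end of steps 2, 4, 6, where
#' step 0 is the therapy initiation day.  "End of step t" means the bolus
#' is given right after the daily frame of step t is recorded.
#'
#' @param init_day day of model time at which therapy starts.
#' @param A_dose,d_dose dose scalars in `[0, 1]` multiplying the reference
#'   plasma peaks `A0` and `d0`.
#' @param A_steps,d_steps therapy step indices (0-based) of the boluses.
#' @return A `therapy_schedule` list.
#' @export
therapy_schedule <- function(init_day, A_dose, d_dose,
                             A_steps = c(0, 2, 4, 6), d_steps = c(2, 4, 6)) {
  stopifnot(init_day >= 0, A_dose >= 0, A_dose <= 1, d_dose >= 0, d_dose <= 1,
            all(A_steps %in% 0:6), all(d_steps %in% 0:6))
  structure(list(init_day = init_day, A_dose = A_dose, d_dose = d_dose,
                 A_steps = as.integer(A_steps), d_steps = as.integer(d_steps)),
            class = "therapy_schedule")
}

n_therapy_days <- 8L   # daily frames at therapy steps 0..7
post_lag_steps <- 2L   # "one hour after insertion" = 2 recorded steps

assert_finite <- function(x, field, t) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in field '%s' at t = %.4f days", field, t))
}

# refresh the quasi-steady fields for the current vasculature/plasma state
refresh_drugs <- function(st, pA, pd, params, grid, need_P = TRUE) {
  tol <- 1e-12
  if (need_P || pd > tol) st$P <- solve_pressure(st$m, params, grid)
  st$A <- if (pA > tol) solve_drug_A(st$m, pA, params, grid) else st$A * 0
  st$d <- if (pd > tol) solve_drug_d(st$m, st$P, pd, st$n, params, grid) else st$d * 0
  st
}

#' Simulate one treatment case
#'
#' Runs untreated growth from `t = 0` to the schedule's initiation day,
#' then eight therapy days at the recording resolution.  At each scheduled
#' bolus the corresponding plasma level jumps by `dose * c0` (additive if a
#' previous bolus has not fully decayed) and decays exponentially between
#' steps; the quasi-steady pressure and drug fields are re-solved at every
#' recorded step while plasma drug is present.  Drug maps recorded one hour
#' (two recorded steps) after each insertion are kept as the targets of the
#' drug-insertion ("Diffuser") learning task.
#'
#' @param seed patient seed (identical seeds share the initial vasculature).
#' @param schedule a [therapy_schedule()].
#' @param params,grid model parameters and grid.
#' @param init_state optional pre-grown `tme_state` at the initiation day
#'   (used by [simulate_patient()] to share the growth phase across cases).
#' @param full_trajectory keep every 30-minute frame (memory-heavy).
#' @return A `tme_case`: list with `daily_frames` (8 x 5 x ny x nx),
#'   `post_drug` (8 x 2 x ny x nx), `scalars` (8 x 2), `meta`, and
#'   optionally `trajectory`.
#' @export
run_case <- function(seed, schedule, params, grid,
                     init_state = NULL, full_trajectory = FALSE) {
  stopifnot(inherits(schedule, "therapy_schedule"))
  st <- if (is.null(init_state)) {
    grow_patient(init_patient(seed, params, grid), schedule$init_day,
                 params, grid)
  } else init_state

  ny <- grid$ny; nx <- grid$nx
  daily <- array(0, c(n_therapy_days, 5, ny, nx))
  post <- array(0, c(n_therapy_days, 2, ny, nx))
  scal <- matrix(0, n_therapy_days, 2,
                 dimnames = list(NULL, c("A_dose", "d_dose")))
  traj <- if (full_trajectory) list() else NULL
  pA <- 0; pd <- 0
  dtr <- grid$dt_record

  for (t_step in 0:(n_therapy_days - 1L)) {
    st <- refresh_drugs(st, pA, pd, params, grid, need_P = TRUE)
    for (ch in 1:5) daily[t_step + 1L, ch, , ] <- st[[tme_channels()[ch]]]
    scal[t_step + 1L, ] <- c(
      if (t_step %in% schedule$A_steps) schedule$A_dose else 0,
      if (t_step %in% schedule$d_steps) schedule$d_dose else 0)
    if (t_step == n_therapy_days - 1L) break

    # bolus right after the daily frame is recorded
    if (t_step %in% schedule$A_steps) pA <- pA + schedule$A_dose * params$A0
    if (t_step %in% schedule$d_steps) pd <- pd + schedule$d_dose * params$d0

    for (s in seq_len(grid$steps_per_day)) {
      st <- advance_nm(st, params, grid, dtr)
      pA <- pA * exp(-dtr / params$tA_half)
      pd <- pd * exp(-dtr / params$td_half)
      st <- refresh_drugs(st, pA, pd, params, grid, need_P = FALSE)
      assert_finite(st$n, "n", st$t); assert_finite(st$m, "m", st$t)
      assert_finite(st$A, "A", st$t); assert_finite(st$d, "d", st$t)
      if (s == post_lag_steps) {
        post[t_step + 1L, 1, , ] <- st$A
        post[t_step + 1L, 2, , ] <- st$d
      }
      if (full_trajectory) traj[[length(traj) + 1L]] <- st
    }
  }
  # final day: post-insertion maps equal the evolving maps (no bolus at 7)
  post[n_therapy_days, 1, , ] <- daily[n_therapy_days, 4, , ]
  post[n_therapy_days, 2, , ] <- daily[n_therapy_days, 5, , ]

  structure(list(
    daily_frames = daily, post_drug = post, scalars = scal,
    meta = list(patient_seed = seed, init_day = schedule$init_day,
                A_dose = schedule$A_dose, d_dose = schedule$d_dose,
                case_id = sprintf("p%04d_i%02d_A%03.0f_d%03.0f",
                                  as.integer(seed), schedule$init_day,
                                  100 * schedule$A_dose, 100 * schedule$d_dose)),
    trajectory = traj), class = "tme_case")
}

# integrate untreated growth (no drugs) from the state's time to `day`
grow_patient <- function(st, day, params, grid) {
  while (st$t < day - 1e-9) {
    st <- advance_nm(st, params, grid, grid$dt_record)
    assert_finite(st$n, "n", st$t); assert_finite(st$m, "m", st$t)
  }
  st
}

#' Simulate the full case set of one patient
#'
#' Every case of a patient shares the seed-determined vasculature and the
#' untreated growth phase; cases then branch by initiation day and dose
#' combination.  The growth phase is integrated once up to the latest
#' initiation day with snapshots at each requested day.
#'
#' @param seed patient seed.
#' @param params,grid model parameters and grid.
#' @param init_days therapy initiation days.
#' @param A_doses,d_doses dose grids; cases are the full factorial
#'   `init_days x A_doses x d_doses`.
#' @return List of `tme_case` objects (length
#'   `length(init_days) * length(A_doses) * length(d_doses)`).
#' @export
simulate_patient <- function(seed, params, grid,
                             init_days = c(14, 16, 18, 20, 21),
                             A_doses = c(0.4, 0.6, 0.8),
                             d_doses = c(0.4, 0.6, 0.8)) {
  init_days <- sort(unique(init_days))
  st <- init_patient(seed, params, grid)
  snaps <- list()
  for (day in init_days) {
    st <- grow_patient(st, day, params, grid)
    snaps[[as.character(day)]] <- st
  }
  cases <- list()
  for (day in init_days) {
    for (Ad in A_doses) {
      for (dd in d_doses) {
        sch <- therapy_schedule(day, Ad, dd)
        cases[[length(cases) + 1L]] <-
          run_case(seed, sch, params, grid,
                   init_state = snaps[[as.character(day)]])
      }
    }
  }
  cases
}

#' Enumerate a cohort case design
#'
#' The factorial design table (patient x initiation day x dose combo)
#' without running any simulation; used for bookkeeping and design checks.
#'
#' @param patient_seeds integer seeds, one per patient.
#' @param init_days,A_doses,d_doses design axes as in [simulate_patient()].
#' @return A data.frame with one row per case.
#' @examples
#' nrow(case_design(1:5))  # 225 cases: 5 patients x 5 days x 9 dose combos
#' @export
case_design <- function(patient_seeds, init_days = c(14, 16, 18, 20, 21),
                        A_doses = c(0.4, 0.6, 0.8),
                        d_doses = c(0.4, 0.6, 0.8)) {
  expand.grid(patient_seed = patient_seeds, init_day = init_days,
              A_dose = A_doses, d_dose = d_doses,
              KEEP.OUT.ATTRS = FALSE)
}

#' Simulate a cohort of patients
#'
#' @param patient_seeds integer seeds, one per patient.
#' @inheritParams simulate_patient
#' @param progress print one line per patient.
#' @return Flat list of `tme_case` objects, 45 per patient under the
#'   default design.
#' @export
simulate_cohort <- function(patient_seeds, params, grid,
                            init_days = c(14, 16, 18, 20, 21),
                            A_doses = c(0.4, 0.6, 0.8),
                            d_doses = c(0.4, 0.6, 0.8),
                            progress = FALSE) {
  out <- list()
  for (s in patient_seeds) {
    if (progress) message(sprintf("simulating patient seed %d ...", s))
    out <- c(out, simulate_patient(s, params, grid, init_days,
                                   A_doses, d_doses))
  }
  out
}

#' Write / read a case container
#'
#' Cases are persisted as a single RDS container holding the list of
#' `tme_case` objects plus the grid and parameter set that produced them.
#'
#' @param cases list of `tme_case` objects.
#' @param path file path.
#' @param params,grid provenance to embed.
#' @return `write_cases` returns `path` invisibly; `read_cases` returns the
#'   stored list with `grid` and `params` attached as attributes.
#' @export
write_cases <- function(cases, path, params = NULL, grid = NULL) {
  saveRDS(list(cases = cases, params = params, grid = grid,
               channel_names = tme_channels()), path)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  obj <- readRDS(path)
  cases <- obj$cases
  attr(cases, "params") <- obj$params
  attr(cases, "grid") <- obj$grid
  cases
}

#' @export
print.tme_case <- function(x, ...) {
  cat(sprintf("<tme_case> %s: %d daily frames, init day %d, doses A=%.2f d=%.2f\n",
              x$meta$case_id, dim(x$daily_frames)[1], x$meta$init_day,
              x$meta$A_dose, x$meta$d_dose))
  invisible(x)
}
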