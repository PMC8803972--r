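# Dataset construction: scaling statistics and their leakage contract,
# pair builders and their count identities, scalar tiling, patient folds.

test_that("min-max statistics pool training pixels and doses globally", {
  cases <- stub_cohort(1:2)
  stats <- fit_minmax(cases)
  for (ch in 1:5) {
    lo <- min(sapply(cases, function(cs) min(cs$daily_frames[, ch, , ])))
    expect_lte(stats$ch_min[ch], lo)
    expect_gt(stats$ch_max[ch], stats$ch_min[ch])
  }
  # global max across cases: inflate one case's channel and refit
  cases2 <- cases
  cases2[[3]]$daily_frames[2, 1, 1, 1] <- 99
  expect_equal(fit_minmax(cases2)$ch_max[1], 99)
  # dose stats come from insertion events only
  expect_equal(stats$dose_min[2], 0.4)
  expect_equal(stats$dose_max[2], 0.8)
  # degenerate constant channel refuses
  bad <- cases
  for (i in seq_along(bad)) bad[[i]]$daily_frames[, 3, , ] <- 0.5
  expect_error(fit_minmax(bad), "degenerate")
})

test_that("scaling statistics are reproducible from the fold alone (no leakage)", {
  cases <- stub_cohort(1:3)
  ids <- vapply(cases, function(cs) cs$meta$patient_seed, 0)
  fold_cases <- cases[ids %in% 1:2]
  s_fold <- fit_minmax(fold_cases)
  s_all <- fit_minmax(cases)
  expect_identical(s_fold, fit_minmax(fold_cases))  # pure function of the fold
  # test patient pixels shift the pooled stats, so the fold stats cannot
  # have seen them
  expect_false(identical(s_fold$ch_min, s_all$ch_min) &&
                 identical(s_fold$ch_max, s_all$ch_max))
})

test_that("min-max transform endpoints, midpoint and round trip", {
  cases <- stub_cohort(1)
  stats <- fit_minmax(cases)
  lo <- stats$ch_min[1]; hi <- stats$ch_max[1]
  expect_equal(apply_minmax(lo, stats, "n"), 0)
  expect_equal(apply_minmax(hi, stats, "n"), 1)
  expect_equal(apply_minmax((lo + hi) / 2, stats, "n"), 0.5)
  # out-of-range values are not clipped
  expect_gt(apply_minmax(hi + 1, stats, "n"), 1)
  set.seed(9)
  x <- matrix(runif(25, -2, 4), 5, 5)
  expect_equal(invert_minmax(apply_minmax(x, stats, "P"), stats, "P"), x,
               tolerance = 1e-12)
})

test_that("pair builders honour the count identities and ordering", {
  cases <- stub_cohort(1:3)              # 3 patients x 2 days x 2 doses = 12
  stats <- fit_minmax(cases)
  dp <- build_diffuser_pairs(cases, stats)
  ep <- build_elapser_pairs(cases, stats)
  expect_equal(length(dp), 4 * length(cases))
  expect_equal(length(ep), 7 * length(cases))
  expect_equal(length(build_diffuser_pairs(list(cases[[1]]), stats)), 4)
  expect_equal(length(build_elapser_pairs(list(cases[[1]]), stats)), 7)
  expect_equal(length(build_diffuser_pairs(list(), stats)), 0)
  expect_equal(length(build_elapser_pairs(list(), stats)), 0)
  # canonical ordering: case id then step, stable across input shuffling
  dp2 <- build_diffuser_pairs(rev(cases), stats)
  expect_identical(dp, dp2)
  ids <- vapply(dp, function(p) p$case_id, "")
  expect_identical(ids, sort(ids))
  # every pair sits at an insertion event
  expect_true(all(vapply(dp, function(p) p$A_dose > 0 || p$d_dose > 0, TRUE)))
})

test_that("step-0 insertion is A-only: its target d channel equals the input", {
  cases <- stub_cohort(1:2)
  stats <- fit_minmax(cases)
  dp <- build_diffuser_pairs(cases, stats)
  p0 <- Filter(function(p) p$step == 0, dp)
  expect_gt(length(p0), 0)
  for (p in p0) {
    expect_equal(p$d_dose, 0)
    expect_equal(p$y[, , 2], p$x[, , 5], tolerance = 1e-12)
  }
})

test_that("elapser pairs use the post-insertion drug state as input", {
  cases <- fixture_cases()
  stats <- fit_minmax(cases)
  ep <- build_elapser_pairs(cases, stats)
  cs <- sort(vapply(cases, function(x) x$meta$case_id, ""))[1]
  case1 <- Filter(function(p) p$case_id == cs, ep)
  case_obj <- Filter(function(x) x$meta$case_id == cs, cases)[[1]]
  p2 <- Filter(function(p) p$step == 2, case1)[[1]]    # chemo insertion day
  expect_equal(p2$x[, , 5],
               apply_minmax(case_obj$post_drug[3, 2, , ], stats, "d"))
  expect_equal(p2$y[, , 1],
               apply_minmax(case_obj$daily_frames[4, 1, , ], stats, "n"))
})

test_that("dose scalars tile to constant planes", {
  maps <- array(runif(5 * 5 * 5), c(5, 5, 5))
  out <- tile_scalars(maps, 0.6, 0.25)
  expect_equal(dim(out), c(5, 5, 7))
  expect_equal(out[, , 1:5], maps)
  expect_true(all(out[, , 6] == 0.6))
  expect_true(all(out[, , 7] == 0.25))
  zz <- tile_scalars(maps, 0, 0)
  expect_true(all(zz[, , 6:7] == 0))
})

test_that("patient folds partition patients with no overlap", {
  f <- patient_folds(1:5, k = 5)
  expect_length(f, 5)
  for (fold in f) {
    expect_length(fold$val, 1)
    expect_length(fold$train, 4)
    expect_length(intersect(fold$train, fold$val), 0)
  }
  expect_setequal(unlist(lapply(f, `[[`, "val")), 1:5)
  expect_error(patient_folds(1:3, k = 5), "exceeds")
  # leave-one-patient-out case counts under the full stated design
  des <- case_design(1:5)
  per_patient <- table(des$patient_seed)
  expect_true(all(per_patient == 45))
  expect_equal(sum(per_patient[as.character(f[[1]]$train)]), 180)
  expect_equal(sum(per_patient[as.character(f[[1]]$val)]), 45)
})
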