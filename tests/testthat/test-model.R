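# Model architecture and composition: stack construction, forward-pass
# equivalence with an independent reference network, conditional drug
# insertion, the composed step and the rollout contract.

test_that("stack construction matches the published layer table", {
  arch <- dent_architecture()
  expect_equal(arch$diffuser, c(128L, 64L, 32L, 16L, 8L, 1L))
  expect_equal(arch$elapser_small, c(128L, 64L, 32L, 16L, 8L, 4L, 1L))
  expect_equal(arch$elapser_large, c(256L, 128L, 64L, 32L, 16L, 8L, 4L, 1L))
  dif <- conv_stack(7, arch$diffuser)
  expect_length(dif$layers, 6)
  el5 <- conv_stack(5, arch$elapser_large)
  expect_length(el5$layers, 8)
  expect_error(conv_stack(5, integer(0)), "non-empty")

  # parameter counts recomputed independently: 25*in*out + out (+2*out BN)
  count <- function(in_ch, hidden) {
    tot <- 0; prev <- in_ch
    for (l in seq_along(hidden)) {
      tot <- tot + 25 * prev * hidden[l] + hidden[l] +
        if (l < length(hidden)) 2 * hidden[l] else 0
      prev <- hidden[l]
    }
    tot
  }
  m <- dent_model(seed = 3)
  expect_equal(n_params(m$diffuser_A), count(7, arch$diffuser))
  expect_equal(n_params(m$diffuser_d), count(7, arch$diffuser))
  for (i in 1:3) expect_equal(n_params(m$elapser[[i]]),
                              count(5, arch$elapser_small))
  for (i in 4:5) expect_equal(n_params(m$elapser[[i]]),
                              count(5, arch$elapser_large))
})

test_that("forward pass preserves shape and matches the reference network", {
  set.seed(1)
  st <- conv_stack(3, c(6, 4, 1), seed = 2)
  x <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  out <- stack_forward(st, x)
  expect_equal(dim(out), c(12, 12, 1))
  # inference mode with freshly initialised running stats (mean 0, var 1)
  # equals the reference network with those statistics
  ref_infer <- function(layers, x) {
    for (l in seq_along(layers)) {
      ly <- layers[[l]]
      z <- ref_conv(x, ly$W, ly$b)
      if (ly$bn) {
        for (co in seq_along(ly$b)) {
          xh <- (z[, , co] - ly$rmean[co]) / sqrt(ly$rvar[co] + 1e-5)
          z[, , co] <- pmax(ly$gamma[co] * xh + ly$beta[co], 0)
        }
      }
      x <- z
    }
    x
  }
  expect_equal(out, ref_infer(st$layers, x), tolerance = 1e-5)
  # wrong channel count refuses
  expect_error(stack_forward(st, array(0, c(12, 12, 4))), "channels")
})

test_that("zero-dose drug channels pass through the insertion stage bit-identically", {
  stats <- fit_minmax(stub_cohort(1))
  m <- dent_model(scaler = stats, seed = 5,
                  arch = list(diffuser = c(6, 1), elapser_small = c(6, 1),
                              elapser_large = c(8, 1)))
  maps <- array(runif(9 * 9 * 5), c(9, 9, 5))
  out0 <- diffuser_forward(m, maps, 0, 0)
  expect_identical(out0$A, maps[, , 4])
  expect_identical(out0$d, maps[, , 5])
  outA <- diffuser_forward(m, maps, 0.6, 0)
  expect_identical(outA$d, maps[, , 5])
  expect_false(identical(outA$A, maps[, , 4]))
  expect_equal(dim(outA$A), c(9, 9))
})

test_that("per-channel forecaster assembles channels in canonical order", {
  stats <- fit_minmax(stub_cohort(1))
  arch <- list(diffuser = c(4, 1), elapser_small = c(4, 1),
               elapser_large = c(6, 1))
  m <- dent_model(scaler = stats, seed = 7, arch = arch)
  maps <- array(runif(9 * 9 * 5), c(9, 9, 5))
  out <- elapser_forward(m, maps)
  expect_equal(dim(out), c(9, 9, 5))
  for (i in 1:5)
    expect_equal(out[, , i], stack_forward(m$elapser[[i]], maps)[, , 1])
  # zero-weight stacks output exactly zero
  z <- m
  for (i in 1:5) {
    for (l in seq_along(z$elapser[[i]]$layers)) {
      z$elapser[[i]]$layers[[l]]$W[] <- 0
      z$elapser[[i]]$layers[[l]]$b[] <- 0
      if (z$elapser[[i]]$layers[[l]]$bn) z$elapser[[i]]$layers[[l]]$beta[] <- 0
    }
  }
  expect_true(all(elapser_forward(z, maps) == 0))
})

test_that("every output channel depends on every input channel", {
  stats <- fit_minmax(stub_cohort(1))
  arch <- list(diffuser = c(4, 1), elapser_small = c(4, 1),
               elapser_large = c(4, 1))
  m <- dent_model(scaler = stats, seed = 9, arch = arch)
  set.seed(3)
  maps <- array(runif(9 * 9 * 5), c(9, 9, 5))
  base <- elapser_forward(m, maps)
  for (in_ch in 1:5) {
    pert <- maps
    pert[, , in_ch] <- pert[, , in_ch] + 0.37
    out <- elapser_forward(m, pert)
    for (out_ch in 1:5)
      expect_gt(max(abs(out[, , out_ch] - base[, , out_ch])), 0)
  }
})

test_that("composed step and rollout: pass-through, identity, determinism", {
  stats <- fit_minmax(stub_cohort(1))
  arch <- list(diffuser = c(4, 1), elapser_small = c(4, 1),
               elapser_large = c(4, 1))
  m <- dent_model(scaler = stats, seed = 11, arch = arch)
  maps <- array(runif(9 * 9 * 5), c(9, 9, 5))
  # zero doses: dent_step is elapser_forward on the untouched maps
  expect_equal(dent_step(m, maps, 0, 0), elapser_forward(m, maps))
  expect_equal(dim(dent_step(m, maps, 0.5, 0.5)), c(9, 9, 5))
  # x_steps = 1 equals a single composed step
  doses <- matrix(c(0.6, 0.8), 1, 2)
  r1 <- rollout(m, maps, doses, 1)
  expect_equal(r1[[1]], dent_step(m, maps, 0.6, 0.8))
  # full 7-step rollout under the standard schedule, twice, identically
  sched <- matrix(0, 7, 2)
  sched[c(1, 3, 5, 7), 1] <- 0.6
  sched[c(3, 5, 7), 2] <- 0.8
  ra <- rollout(m, maps, sched)
  rb <- rollout(m, maps, sched)
  expect_length(ra, 7)
  expect_identical(ra, rb)
  # no-injection rollout equals iterating the forecaster alone
  rz <- rollout(m, maps, matrix(0, 3, 2))
  x <- maps
  for (k in 1:3) {
    x <- elapser_forward(m, x)
    expect_equal(rz[[k]], x)
  }
  expect_error(rollout(m, maps, doses, 0), "x_steps")
})
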