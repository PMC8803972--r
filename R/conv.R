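# The surrogate model: plain convolutional stacks (5x5, stride 1, "same"
# padding, batch norm + ReLU after every layer but the last) composed into
# the two-headed conditional drug-insertion network ("Diffuser") and the
# five per-channel one-day forecasters ("Elapser"), plus the composed
# one-day step and the autoregressive rollout.

#' Build a convolutional stack
#'
#' A sequence of `length(hidden)` 5x5 convolutions (stride 1, padding 2, so
#' 151 x 151 in gives 151 x 151 out); every layer except the last is
#' followed by 2D batch normalisation and ReLU.  Weights use fan-in uniform
#' initialisation `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` drawn from the given
#' seed, so stacks are reproducible.
#'
#' @param in_channels number of input channels.
#' @param hidden ordered vector of layer output channels, ending in the
#'   stack's output channel count (1 for every submodel here).
#' @param seed RNG seed for the weight draw.
#' @return A `conv_stack` object.
#' @examples
#' st <- conv_stack(7, c(8, 4, 1), seed = 1)
#' n_params(st)
#' @export
conv_stack <- function(in_channels, hidden, seed = 1) {
  if (length(hidden) == 0) stop("hidden channel list must be non-empty")
  stopifnot(in_channels >= 1, all(hidden >= 1))
  set.seed(as.integer(seed))
  layers <- vector("list", length(hidden))
  prev <- in_channels
  for (l in seq_along(hidden)) {
    out <- hidden[l]
    fan_in <- prev * 25
    k <- 1 / sqrt(fan_in)
    ly <- list(
      W = matrix(runif(out * fan_in, -k, k), fan_in, out),
      b = runif(out, -k, k),
      bn = l < length(hidden))
    if (ly$bn) {
      ly$gamma <- rep(1, out); ly$beta <- rep(0, out)
      ly$rmean <- rep(0, out); ly$rvar <- rep(1, out)
    }
    layers[[l]] <- ly
    prev <- out
  }
  structure(list(in_channels = as.integer(in_channels),
                 hidden = as.integer(hidden), kernel = 5L, stride = 1L,
                 padding = 2L, seed = as.integer(seed), layers = layers),
            class = "conv_stack")
}

#' @export
print.conv_stack <- function(x, ...) {
  cat(sprintf("<conv_stack> in=%d -> [%s], 5x5 same, %d parameters\n",
              x$in_channels, paste(x$hidden, collapse = ", "), n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a stack
#' @param stack a `conv_stack`.
#' @return Integer parameter count (weights, biases, batch-norm affines).
#' @export
n_params <- function(stack) {
  sum(vapply(stack$layers, function(ly) {
    length(ly$W) + length(ly$b) +
      if (ly$bn) length(ly$gamma) + length(ly$beta) else 0L
  }, 0))
}

#' Forward pass of a stack (inference mode)
#'
#' Batch norm uses its running statistics (inference statistics are also
#' what the rollout uses).
#'
#' @param stack a `conv_stack`.
#' @param x input array `ny x nx x in_channels`, or a list of such arrays.
#' @param bn_eps batch-norm stabilizer.
#' @return Output array `ny x nx x out_channels` (list in, list out).
#' @export
stack_forward <- function(stack, x, bn_eps = 1e-5) {
  single <- !is.list(x)
  xs <- if (single) list(x) else x
  for (xx in xs) {
    stopifnot(length(dim(xx)) == 3)
    if (dim(xx)[3] != stack$in_channels)
      stop("input has ", dim(xx)[3], " channels; stack expects ",
           stack$in_channels)
  }
  out <- .cpp_cnn_predict(stack$layers, xs, bn_eps)
  if (single) out[[1]] else out
}

#' Table of default submodel architectures
#'
#' The seven hidden-channel lists: the two drug-insertion heads share one
#' stack shape; the three slow channels (n, m, P) share a deeper narrow
#' stack; the two fast drug channels get the widest stacks.
#'
#' @return Named list of integer vectors.
#' @export
dent_architecture <- function() {
  list(diffuser = c(128L, 64L, 32L, 16L, 8L, 1L),
       elapser_small = c(128L, 64L, 32L, 16L, 8L, 4L, 1L),
       elapser_large = c(256L, 128L, 64L, 32L, 16L, 8L, 4L, 1L))
}

#' Assemble the composed forecaster
#'
#' Seven independent submodels: two conditional drug-insertion CNNs
#' (7-channel input: five maps plus two tiled dose planes) and five
#' per-channel one-day forecasters (5-channel input).  By default the n, m
#' and P forecasters use the smaller stack and the two drug-channel
#' forecasters the larger one; pass `arch` to override (e.g. for reduced
#' desk-scale experiments).
#'
#' @param scaler `scaler_stats` the model operates under (rollout runs in
#'   scaled space).
#' @param seed base RNG seed; submodel `i` uses `seed + i`.
#' @param arch list like [dent_architecture()].
#' @return A `dent_model`.
#' @export
dent_model <- function(scaler = NULL, seed = 1, arch = dent_architecture()) {
  elap_hidden <- list(arch$elapser_small, arch$elapser_small,
                      arch$elapser_small, arch$elapser_large,
                      arch$elapser_large)
  elapser <- lapply(1:5, function(i)
    conv_stack(5L, elap_hidden[[i]], seed = seed + 2 + i))
  structure(list(
    diffuser_A = conv_stack(7L, arch$diffuser, seed = seed + 1),
    diffuser_d = conv_stack(7L, arch$diffuser, seed = seed + 2),
    elapser = elapser, scaler = scaler, seed = as.integer(seed)),
    class = "dent_model")
}

#' @export
print.dent_model <- function(x, ...) {
  cat("<dent_model> 7 submodels\n")
  cat("  diffuser A/d : in=7 -> [",
      paste(x$diffuser_A$hidden, collapse = ", "), "]\n", sep = "")
  for (i in 1:5)
    cat(sprintf("  elapser %s    : in=5 -> [%s]\n", tme_channels()[i],
                paste(x$elapser[[i]]$hidden, collapse = ", ")))
  invisible(x)
}

#' Conditional drug-insertion forward pass
#'
#' Tiles the scaled dose scalars onto the scaled input maps and runs each
#' drug head -- but only for drugs with a nonzero dose: a zero-dose drug
#' channel passes through bit-identically (the insertion networks are
#' conditional and untouched drug maps must not be altered).
#'
#' @param model a `dent_model` with a fitted scaler.
#' @param maps `ny x nx x 5` scaled maps.
#' @param A_dose,d_dose raw dose scalars in `[0, 1]`.
#' @return List with matrices `A` and `d` (scaled post-insertion drug maps).
#' @export
diffuser_forward <- function(model, maps, A_dose, d_dose) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[3] == 5)
  As <- if (A_dose > 0) apply_minmax(A_dose, model$scaler, "A_dose") else 0
  ds <- if (d_dose > 0) apply_minmax(d_dose, model$scaler, "d_dose") else 0
  x7 <- tile_scalars(maps, As, ds)
  list(
    A = if (A_dose > 0) stack_forward(model$diffuser_A, x7)[, , 1] else maps[, , 4],
    d = if (d_dose > 0) stack_forward(model$diffuser_d, x7)[, , 1] else maps[, , 5])
}

#' One-day forecaster forward pass
#'
#' Runs the five per-channel stacks on the same 5-channel input and
#' assembles the next-day maps in canonical channel order (n, m, P, A, d).
#'
#' @param model a `dent_model`.
#' @param maps `ny x nx x 5` scaled maps.
#' @return `ny x nx x 5` scaled next-day maps.
#' @export
elapser_forward <- function(model, maps) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[3] == 5)
  out <- array(0, dim(maps))
  for (i in 1:5) out[, , i] <- stack_forward(model$elapser[[i]], maps)[, , 1]
  out
}

#' Composed one-day step
#'
#' Drug insertion first (conditional), then the one-day forecast on
#' `[n, m, P, inserted A, inserted d]`.
#'
#' @inheritParams diffuser_forward
#' @return `ny x nx x 5` scaled next-day maps.
#' @export
dent_step <- function(model, maps, A_dose = 0, d_dose = 0) {
  dr <- diffuser_forward(model, maps, A_dose, d_dose)
  maps[, , 4] <- dr$A
  maps[, , 5] <- dr$d
  elapser_forward(model, maps)
}

#' Autoregressive rollout
#'
#' Iterates the composed one-day step, feeding each prediction back as the
#' next input, with the per-day doses of the treatment schedule applied at
#' their steps.  Runs entirely in scaled space.
#'
#' @param model a `dent_model`.
#' @param initial_maps `ny x nx x 5` scaled maps at therapy step 0.
#' @param doses `x_steps x 2` matrix of raw doses (A, d) applied at the end
#'   of steps `0 .. x_steps - 1`; zero rows mean no injection.
#' @param x_steps number of predicted days (>= 1).
#' @return List of `x_steps` predicted scaled map arrays (days 1..x_steps).
#' @export
rollout <- function(model, initial_maps, doses, x_steps = nrow(doses)) {
  if (is.null(x_steps) || x_steps < 1) stop("x_steps must be >= 1")
  doses <- matrix(doses, ncol = 2)
  if (nrow(doses) < x_steps) stop("doses must have one row per rollout step")
  maps <- initial_maps
  out <- vector("list", x_steps)
  for (t_step in seq_len(x_steps)) {
    maps <- dent_step(model, maps, doses[t_step, 1], doses[t_step, 2])
    out[[t_step]] <- maps
  }
  out
}
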