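# Training: per-submodel Adam + MSE with patient-held-out validation and
# early stopping, and the full cross-validated protocol that assembles a
# trained forecaster.

#' Training configuration
#'
#' Defaults follow the training protocol: MSE loss, Adam with learning
#' rate 1e-4, batch size 10, up to 200 epochs with early stopping.  The
#' patience (10 epochs without validation improvement) is this package's
#' choice; the protocol specifies early stopping without a patience value.
#'
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param bn_momentum,bn_eps batch-norm running-stat momentum and epsilon.
#' @param seed RNG seed for mini-batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, batch_size = 10, max_epochs = 200,
                         patience = 10, bn_momentum = 0.1, bn_eps = 1e-5,
                         seed = 1) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_update <- function(theta, g, st, cfg) {
  st$t <- st$t + 1
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
  mhat <- st$m / (1 - cfg$beta1^st$t)
  vhat <- st$v / (1 - cfg$beta2^st$t)
  list(theta = theta - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps), st = st)
}

# mean MSE of a stack over a pair list, inference mode
stack_mse <- function(layers, pairs, xs, ys, bn_eps) {
  preds <- .cpp_cnn_predict(layers, xs, bn_eps)
  mean(vapply(seq_along(preds),
              function(i) mean((preds[[i]] - ys[[i]])^2), 0))
}

#' Train one submodel
#'
#' Minimises MSE with Adam over shuffled mini-batches; after every epoch
#' the validation loss (inference-mode batch norm) is evaluated on pairs
#' from held-out patients.  Stops at the epoch cap or when validation has
#' not improved for `patience` epochs, and restores the best-validation
#' weights.  Fully reproducible given `cfg$seed`.
#'
#' @param stack a `conv_stack`.
#' @param train_pairs,val_pairs pair lists; each pair needs the fields
#'   named by `input_fn` / `target_fn`.
#' @param cfg a [train_config()].
#' @param input_fn,target_fn functions extracting the input array and the
#'   target array from one pair (defaults take `p$x` and `p$y`).
#' @param verbose print one line per epoch.
#' @return List with `stack` (best weights), `report` (per-epoch
#'   data.frame), `best_epoch`, `stopped` reason.
#' @export
train_submodel <- function(stack, train_pairs, val_pairs, cfg = train_config(),
                           input_fn = function(p) p$x,
                           target_fn = function(p) p$y,
                           verbose = FALSE) {
  if (length(train_pairs) == 0) stop("empty training set")
  set.seed(cfg$seed)
  layers <- stack$layers
  tx <- lapply(train_pairs, input_fn); ty <- lapply(train_pairs, target_fn)
  vx <- lapply(val_pairs, input_fn); vy <- lapply(val_pairs, target_fn)

  adam <- lapply(layers, function(ly) {
    s <- list(W = list(m = ly$W * 0, v = ly$W * 0, t = 0),
              b = list(m = ly$b * 0, v = ly$b * 0, t = 0))
    if (ly$bn) {
      s$gamma <- list(m = ly$gamma * 0, v = ly$gamma * 0, t = 0)
      s$beta <- list(m = ly$beta * 0, v = ly$beta * 0, t = 0)
    }
    s
  })

  nt <- length(tx)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_mse = numeric(),
                     val_mse = numeric())
  stopped <- "max_epochs"
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(nt)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, nt, by = cfg$batch_size)) {
      bidx <- idx[start:min(start + cfg$batch_size - 1, nt)]
      res <- .cpp_cnn_train_batch(layers, tx[bidx], ty[bidx],
                                  cfg$bn_momentum, cfg$bn_eps)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite training loss at epoch %d (batch of %d)",
                     epoch, length(bidx)))
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
      for (l in seq_along(layers)) {
        g <- res$grads[[l]]
        for (par in c("W", "b", if (layers[[l]]$bn) c("gamma", "beta"))) {
          u <- adam_update(layers[[l]][[par]], g[[paste0("d", par)]],
                           adam[[l]][[par]], cfg)
          layers[[l]][[par]] <- u$theta
          adam[[l]][[par]] <- u$st
        }
        if (layers[[l]]$bn) {
          layers[[l]]$rmean <- as.numeric(g$rmean)
          layers[[l]]$rvar <- as.numeric(g$rvar)
        }
      }
    }
    val <- if (length(vx)) stack_mse(layers, NULL, vx, vy, cfg$bn_eps) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_mse = ep_loss / nb,
                                   val_mse = val))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                      ep_loss / nb, val))
    crit <- if (is.na(val)) ep_loss / nb else val
    if (crit < best$loss) {
      best <- list(loss = crit, layers = layers, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      stopped <- "early_stopping"
      break
    }
  }
  stack$layers <- best$layers
  list(stack = stack, report = hist, best_epoch = best$epoch,
       best_val = best$loss, stopped = stopped)
}

#' Train the full forecaster with patient-wise cross-validation
#'
#' For each fold: fit the scaler on the training patients only, build both
#' pair datasets, and train the seven submodels independently (two
#' drug-insertion heads on insertion pairs, five per-channel forecasters on
#' one-day pairs).  The delivered model is the fold with the lowest mean
#' validation loss across its seven submodels.
#'
#' At the published protocol's scale (225 cases of 151 x 151 maps, up to
#' 200 epochs, 5 folds) this is an hours-to-days CPU computation; pass a
#' reduced `arch` and fewer cases for desk-scale runs.
#'
#' @param cases list of training `tme_case` objects (all patients).
#' @param cfg a [train_config()].
#' @param k number of folds (default 5, leave-one-patient-out for 5
#'   patients).
#' @param arch architecture list as in [dent_model()].
#' @param verbose print progress.
#' @return List with `model` (the delivered `dent_model`), `fold_reports`,
#'   `best_fold`.
#' @export
train_all <- function(cases, cfg = train_config(), k = 5,
                      arch = dent_architecture(), verbose = FALSE) {
  patients <- sort(unique(vapply(cases, function(cs) cs$meta$patient_seed, 0)))
  folds <- patient_folds(patients, k)
  fold_models <- list(); fold_reports <- list()
  for (f in seq_along(folds)) {
    tr_cases <- cases_of(cases, folds[[f]]$train)
    va_cases <- cases_of(cases, folds[[f]]$val)
    stats <- fit_minmax(tr_cases)
    dtr <- build_diffuser_pairs(tr_cases, stats)
    dva <- build_diffuser_pairs(va_cases, stats)
    etr <- build_elapser_pairs(tr_cases, stats)
    eva <- build_elapser_pairs(va_cases, stats)
    model <- dent_model(scaler = stats, seed = cfg$seed + 100 * f, arch = arch)
    reports <- list(); vals <- numeric(0)

    diff_in <- function(p) tile_scalars(p$x, p$A_dose_s, p$d_dose_s)
    for (head in c("A", "d")) {
      ch <- if (head == "A") 1 else 2
      tgt <- function(p) p$y[, , ch, drop = FALSE]
      nm <- paste0("diffuser_", head)
      if (verbose) message(sprintf("fold %d: training %s", f, nm))
      res <- train_submodel(model[[nm]], dtr, dva,
                            sub_cfg(cfg, f * 10 + ch), diff_in, tgt,
                            verbose = verbose)
      model[[nm]] <- res$stack
      reports[[nm]] <- res$report
      vals <- c(vals, res$best_val)
    }
    for (i in 1:5) {
      tgt <- function(p) p$y[, , i, drop = FALSE]
      nm <- paste0("elapser_", tme_channels()[i])
      if (verbose) message(sprintf("fold %d: training %s", f, nm))
      res <- train_submodel(model$elapser[[i]], etr, eva,
                            sub_cfg(cfg, f * 10 + 2 + i),
                            function(p) p$x, tgt, verbose = verbose)
      model$elapser[[i]] <- res$stack
      reports[[nm]] <- res$report
      vals <- c(vals, res$best_val)
    }
    fold_models[[f]] <- model
    fold_reports[[f]] <- list(reports = reports, mean_val = mean(vals))
  }
  best_fold <- which.min(vapply(fold_reports, function(r) r$mean_val, 0))
  list(model = fold_models[[best_fold]], fold_reports = fold_reports,
       best_fold = best_fold)
}

# derive an independent, reproducible per-submodel seed
sub_cfg <- function(cfg, offset) {
  cfg$seed <- (cfg$seed * 1000L + as.integer(offset)) %% .Machine$integer.max
  cfg
}
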