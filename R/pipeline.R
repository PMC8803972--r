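# End-to-end pipeline plumbing: configuration, staged execution with
# resumable RDS artifacts, and PNG panel export of cases/predictions.

#' Default pipeline configuration
#'
#' The full stated design: 5 training/validation patients and 3 test
#' patients, 5 therapy initiation days, a 3 x 3 dose grid, 151 x 151 maps
#' at 30-minute resolution, and the published training protocol.  Every
#' block can be overridden (the desk-scale runs in the tests and the
#' acceptance script shrink the grid, case design and epochs).
#'
#' @param ... named overrides of top-level blocks (`grid`, `params`,
#'   `design`, `train`, `eval`, `arch`, `seed`).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(nx = 151L, steps_per_day = 48L),
    params = list(),                       # overrides of default_params()
    design = list(train_patients = 1:5, test_patients = 6:8,
                  init_days = c(14, 16, 18, 20, 21),
                  A_doses = c(0.4, 0.6, 0.8), d_doses = c(0.4, 0.6, 0.8)),
    train = list(max_epochs = 200L, batch_size = 10L, lr = 1e-4,
                 patience = 10L, folds = 5L),
    eval = list(threshold = 0.05, x_steps = 7L),
    arch = dent_architecture(),
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
    for (nm in names(over)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
        modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
    }
  }
  cfg
}

# deterministic hash of a config for artifact provenance
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(cfg, NULL, version = 2), f)
  substr(unname(tools::md5sum(f)), 1, 12)
}

log_line <- function(stage, ...) {
  kv <- paste(names(list(...)), unlist(list(...)), sep = "=", collapse = " ")
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, kv))
}

#' Run the full pipeline
#'
#' Executes simulate -> build-datasets -> train -> evaluate, writing one
#' RDS artifact per stage into `out_dir` (plus `metrics.json`).  Stages
#' whose artifact already exists are reloaded, making the pipeline
#' resumable; the embedded config hash guards against mixing artifacts
#' from different configurations.  Deterministic given `config$seed`.
#'
#' @param config a [default_config()].
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of stages to run.
#' @param dry_run print the stage plan and write nothing.
#' @return List of artifacts (`cases`, `test_cases`, `train_result`,
#'   `metrics`), invisibly for `dry_run`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "artifacts",
                         stages = c("simulate", "datasets", "train",
                                    "evaluate"),
                         dry_run = FALSE) {
  hash <- config_hash(config)
  if (dry_run) {
    message("pipeline plan (config ", hash, "): ",
            paste(stages, collapse = " -> "), "; out_dir = ", out_dir)
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- tme_grid(config$grid$nx, steps_per_day = config$grid$steps_per_day)
  params <- do.call(default_params, config$params)
  des <- config$design
  art <- list(config_hash = hash)

  stage_file <- function(nm) file.path(out_dir, paste0(nm, "_", hash, ".rds"))

  if ("simulate" %in% stages) {
    f <- stage_file("cases")
    if (file.exists(f)) {
      art$cases <- read_cases(f)
      log_line("simulate", status = "reused", file = f)
    } else {
      log_line("simulate", patients = length(des$train_patients))
      art$cases <- simulate_cohort(des$train_patients, params, grid,
                                   des$init_days, des$A_doses, des$d_doses)
      write_cases(art$cases, f, params, grid)
    }
    ft <- stage_file("test_cases")
    if (file.exists(ft)) {
      art$test_cases <- read_cases(ft)
    } else {
      log_line("simulate", test_patients = length(des$test_patients))
      art$test_cases <- simulate_cohort(des$test_patients, params, grid,
                                        des$init_days, des$A_doses, des$d_doses)
      write_cases(art$test_cases, ft, params, grid)
    }
  }
  if ("datasets" %in% stages) {
    f <- stage_file("datasets")
    if (file.exists(f)) {
      art$datasets <- readRDS(f)$datasets
      log_line("datasets", status = "reused", file = f)
    } else {
      stats <- fit_minmax(art$cases)
      art$datasets <- list(
        stats = stats,
        folds = patient_folds(vapply(art$cases,
                                     function(cs) cs$meta$patient_seed, 0),
                              k = config$train$folds),
        n_diffuser = length(build_diffuser_pairs(art$cases, stats)),
        n_elapser = length(build_elapser_pairs(art$cases, stats)))
      log_line("datasets", diffuser = art$datasets$n_diffuser,
               elapser = art$datasets$n_elapser)
      saveRDS(list(datasets = art$datasets, config_hash = hash), f)
    }
  }
  if ("train" %in% stages) {
    f <- stage_file("model")
    if (file.exists(f)) {
      art$train_result <- readRDS(f)$train_result
      log_line("train", status = "reused", file = f)
    } else {
      tcfg <- train_config(lr = config$train$lr,
                           batch_size = config$train$batch_size,
                           max_epochs = config$train$max_epochs,
                           patience = config$train$patience,
                           seed = config$seed)
      log_line("train", folds = config$train$folds,
               max_epochs = tcfg$max_epochs)
      art$train_result <- train_all(art$cases, tcfg, k = config$train$folds,
                                    arch = config$arch)
      saveRDS(list(train_result = art$train_result, config_hash = hash), f)
    }
  }
  if ("evaluate" %in% stages) {
    if (is.null(art$train_result)) {
      f <- stage_file("model")
      if (!file.exists(f))
        stop("stage 'evaluate' failed: no trained model artifact at ", f)
      art$train_result <- readRDS(f)$train_result
    }
    log_line("evaluate", cases = length(art$test_cases))
    art$metrics <- evaluate_testset(art$train_result$model, art$test_cases,
                                    threshold = config$eval$threshold,
                                    x_steps = config$eval$x_steps)
    pd <- art$metrics$per_day
    jsonlite::write_json(
      list(config_hash = hash, n_cases = art$metrics$n_cases,
           per_day = pd),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  art
}

#' Export per-day, per-channel PNG panels
#'
#' One PNG per day and channel with a shared per-channel color scale and a
#' scale bar; the vasculature channel optionally gets a zoomed center
#' inset.  When `pred_frames` is supplied, ground truth and prediction are
#' placed side by side.
#'
#' @param case a `tme_case` (or any `days x 5 x ny x nx` array in
#'   `gt_frames`).
#' @param out_dir output directory.
#' @param pred_frames optional `days x 5 x ny x nx` array of predictions.
#' @param zoom_inset draw the vasculature center zoom.
#' @return Character vector of written file paths, invisibly.
#' @export
export_panels <- function(case, out_dir, pred_frames = NULL,
                          zoom_inset = TRUE) {
  frames <- if (inherits(case, "tme_case")) case$daily_frames else case
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  chs <- tme_channels()
  n_days <- dim(frames)[1]
  files <- character(0)
  for (ch in 1:5) {
    zl <- range(frames[, ch, , ], if (!is.null(pred_frames))
      pred_frames[, ch, , ] else NULL)
    if (zl[1] == zl[2]) zl <- zl + c(0, 1e-12)
    for (day in seq_len(n_days)) {
      f <- file.path(out_dir, sprintf("day%02d_%s.png", day - 1, chs[ch]))
      grDevices::png(f, width = if (is.null(pred_frames)) 480 else 900,
                     height = 480)
      op <- graphics::par(mfrow = c(1, if (is.null(pred_frames)) 1 else 2),
                          mar = c(2, 2, 2, 4))
      draw_map(frames[day, ch, , ], zl,
               sprintf("%s day %d%s", chs[ch], day - 1,
                       if (is.null(pred_frames)) "" else " (truth)"),
               zoom = zoom_inset && ch == 2)
      if (!is.null(pred_frames))
        draw_map(pred_frames[day, ch, , ], zl,
                 sprintf("%s day %d (predicted)", chs[ch], day - 1),
                 zoom = zoom_inset && ch == 2)
      graphics::par(op)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

draw_map <- function(mp, zl, title, zoom = FALSE) {
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(t(mp[rev(seq_len(nrow(mp))), ]), zlim = zl, col = pal,
                  axes = FALSE, main = title, useRaster = TRUE)
  # scale bar
  graphics::mtext(sprintf("[%.3g, %.3g]", zl[1], zl[2]), side = 4, line = 0.5,
                  cex = 0.8)
  if (zoom) {
    ny <- nrow(mp); cz <- max(3, round(ny / 6))
    ctr <- (ny %/% 2 - cz):(ny %/% 2 + cz)
    graphics::rasterImage(
      grDevices::as.raster((mp[ctr, ctr] - zl[1]) / diff(zl)),
      0.72, 0.0, 1.0, 0.28, interpolate = FALSE)
  }
}
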