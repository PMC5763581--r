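#' Save / load a dynamic dataset directory
#'
#' Layout written by [save_dataset()] (and by the `simulate` CLI subcommand):
#' `frames.nii.gz` (uniform-shaped frames stacked along the third dimension),
#' `specs.csv` (per-frame acquisition description: `frame, mode, row_start,
#' n_rows, profile_sigma`), `surrogate.csv`, and optionally the simulation
#' truth (`I_true.nii.gz`, `maps.nii.gz`, `body_mask.nii.gz`).  Frame order
#' comes from the `frame` column of `specs.csv`, not from file names.
#'
#' @param dataset a `phantom_dataset` or a list with `frames`, `specs`,
#'   `surrogate` (and optional truth elements).
#' @param dir directory to write into (created if missing).
#' @name dataset-io
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- dataset$frames
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("frames must share a shape to be stacked")
  arr <- array(unlist(frames), dim = c(shp, length(frames)))
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, "frames.nii.gz"))
  sp <- do.call(rbind, lapply(seq_along(dataset$specs), function(i) {
    s <- dataset$specs[[i]]
    data.frame(frame = i, mode = s$mode, row_start = s$row_start,
               n_rows = s$n_rows, profile_sigma = s$profile_sigma)
  }))
  write.csv(sp, file.path(dir, "specs.csv"), row.names = FALSE)
  write_surrogate_csv(dataset$surrogate, file.path(dir, "surrogate.csv"))
  if (!is.null(dataset$I_true))
    write_image_nifti(dataset$I_true, file.path(dir, "I_true.nii.gz"))
  if (!is.null(dataset$maps)) {
    m <- array(unlist(dataset$maps), dim = c(dim(dataset$maps$my1), 4))
    RNifti::writeNifti(RNifti::asNifti(m), file.path(dir, "maps.nii.gz"))
  }
  if (!is.null(dataset$body_mask))
    write_image_nifti(raster_image(dataset$body_mask * 1),
                      file.path(dir, "body_mask.nii.gz"))
  invisible(dir)
}

#' @rdname dataset-io
#' @param normalize mean-centre the surrogate signals on load?
#' @export
load_dataset <- function(dir, normalize = TRUE) {
  need <- c("frames.nii.gz", "specs.csv", "surrogate.csv")
  for (f in need) if (!file.exists(file.path(dir, f)))
    stop("dataset directory is missing ", f)
  arr <- as.array(RNifti::readNifti(file.path(dir, "frames.nii.gz")))
  sp <- read.csv(file.path(dir, "specs.csv"), stringsAsFactors = FALSE)
  sp <- sp[order(sp$frame), ]
  if (!identical(sp$frame, seq_len(dim(arr)[3])) || nrow(sp) != dim(arr)[3])
    stop("specs.csv frame indices do not match the ", dim(arr)[3], " stored frames")
  specs <- lapply(seq_len(nrow(sp)), function(i)
    acq_spec(sp$mode[i], sp$row_start[i], sp$n_rows[i], sp$profile_sigma[i]))
  frames <- lapply(seq_len(dim(arr)[3]), function(i) {
    m <- matrix(arr[, , i], dim(arr)[1], dim(arr)[2]); storage.mode(m) <- "double"; m
  })
  sur <- read_surrogate_csv(file.path(dir, "surrogate.csv"))
  if (nrow(sur) != length(frames))
    stop("surrogate CSV has ", nrow(sur), " rows but there are ",
         length(frames), " frames; missing frame ",
         min(setdiff(seq_along(frames), seq_len(nrow(sur)))))
  if (normalize) sur <- normalize_surrogate(sur)
  out <- list(frames = frames, specs = specs, surrogate = sur)
  if (file.exists(file.path(dir, "I_true.nii.gz")))
    out$I_true <- read_image_nifti(file.path(dir, "I_true.nii.gz"))
  if (file.exists(file.path(dir, "maps.nii.gz"))) {
    m <- as.array(RNifti::readNifti(file.path(dir, "maps.nii.gz")))
    pick <- function(i) matrix(as.numeric(m[, , i]), dim(m)[1], dim(m)[2])
    out$maps <- list(my1 = pick(1), my2 = pick(2), mx1 = pick(3), mx2 = pick(4))
  }
  if (file.exists(file.path(dir, "body_mask.nii.gz")))
    out$body_mask <- read_image_nifti(file.path(dir, "body_mask.nii.gz"))$data >= 0.5
  out
}

#' Run a configured experiment end-to-end
#'
#' Orchestrates simulate (or load) -> fit (or alternating fit/MCIR) ->
#' evaluate for one experiment configuration, writing the fitted model, any
#' reconstruction, a metrics CSV (no-motion and model DFE rows, plus
#' reconstruction agreement when an MCIR is performed) and a YAML log of the
#' resolved configuration.  Fully reproducible from the configuration and its
#' seed.
#'
#' @param config a named list (or path to a YAML file) with fields `regime`,
#'   `model` (kind), `cpg_spacing`, `reference` (`"true"`, `"mcir-average"`,
#'   `"mcir-superres"`), `seed`, and optional `size`, `target_dfe`, `levels`,
#'   `max_iter`, `n_outer`, `n_terms`, `data_dir` (load instead of simulate).
#' @param out_dir directory for results.
#' @return Invisibly, a list with `model`, `metrics`, and (if reconstructed)
#'   `I0`.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(model = "linear_sdot", cpg_spacing = 5, reference = "true",
                   seed = 1L, levels = 3L, max_iter = 60L, n_outer = 3L,
                   n_terms = 4L)
  config <- utils::modifyList(defaults, config)
  res <- tryCatch({
    ds <- if (!is.null(config$data_dir)) load_dataset(config$data_dir)
          else simulate_dataset(phantom_spec(config$regime, seed = config$seed,
                                             size = config$size,
                                             target_dfe = config$target_dfe))
    cfg <- fit_config(cpg_spacing = config$cpg_spacing, levels = config$levels,
                      max_iter = config$max_iter)
    if (config$reference == "true") {
      if (is.null(ds$I_true)) stop("reference 'true' needs a dataset with I_true")
      model <- fit_model(ds$frames, ds$specs, ds$surrogate, ds$I_true,
                         config$model, cfg, n_terms = config$n_terms)
      I0 <- NULL
    } else {
      fm <- fit_with_mcir(ds$frames, ds$specs, ds$surrogate, config$model, cfg,
                          n_terms = config$n_terms, n_outer = config$n_outer,
                          mcir = if (config$reference == "mcir-superres")
                            "superres" else "average")
      model <- fm$model; I0 <- fm$I0
      utils::write.csv(data.frame(round = seq_along(fm$cost_trace),
                                  cost = fm$cost_trace),
                       file.path(out_dir, "cost_trace.csv"), row.names = FALSE)
    }
    write_model(model, file.path(out_dir, "model"))
    metrics <- NULL
    if (inherits(ds, "phantom_dataset")) {
      metrics <- rbind(cbind(experiment = "no motion", model_dfe_stats(ds, NULL)),
                       cbind(experiment = "model", model_dfe_stats(ds, model)))
      if (!is.null(I0)) {
        agr <- image_agreement(I0, ds$I_true, ds$body_mask)
        metrics <- rbind(metrics,
                         cbind(experiment = "reconstruction",
                               data.frame(mean = agr$mean, sd = agr$sd,
                                          p95 = agr$p95, n = agr$n)))
        attr(metrics, "correlation") <- agr$r
        write_image_nifti(I0, file.path(out_dir, "I0.nii.gz"))
      }
      write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    }
    yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
    list(model = model, metrics = metrics, I0 = I0)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    stop(e)
  })
  invisible(res)
}
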