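#' Write a sample_set as wide CSV plus JSON sidecar
#'
#' The native exchange dialect: `spectra.csv` holds the wavenumber axis in
#' column 1 and one column per spectrum (headers are spectrum ids);
#' `spectra.json` maps each spectrum id to its `sample_id`, `class_label`
#' and `stage`.
#'
#' @param ss A `sample_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spectra <- function(ss, dir) {
  validate_sample_set(ss)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- data.frame(wavenumber = ss$wavenumber, t(ss$intensities),
                     check.names = FALSE)
  names(wide)[-1] <- ss$meta$spectrum_id
  utils::write.csv(wide, file.path(dir, "spectra.csv"), row.names = FALSE)
  side <- lapply(seq_len(nrow(ss$meta)), function(i)
    list(sample_id = ss$meta$sample_id[i],
         class_label = ss$meta$class_label[i],
         stage = ss$meta$stage[i]))
  names(side) <- ss$meta$spectrum_id
  jsonlite::write_json(side, file.path(dir, "spectra.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a sample_set written by [write_spectra()]
#'
#' Enforces axis monotonicity, one sidecar entry per spectrum column, and
#' label consistency within each sample on load.
#'
#' @param dir Directory containing `spectra.csv` and `spectra.json`.
#' @return A validated `sample_set`.
#' @export
read_spectra <- function(dir) {
  csv <- file.path(dir, "spectra.csv")
  side_path <- file.path(dir, "spectra.json")
  if (!file.exists(csv)) stop("missing ", csv)
  if (!file.exists(side_path)) stop("missing sidecar ", side_path)
  wide <- utils::read.csv(csv, check.names = FALSE)
  if (names(wide)[1] != "wavenumber")
    stop("first CSV column must be 'wavenumber'")
  side <- jsonlite::read_json(side_path)
  ids <- names(wide)[-1]
  missing <- setdiff(ids, names(side))
  if (length(missing))
    stop("sidecar lacks entries for spectrum id(s): ",
         paste(missing, collapse = ", "))
  meta <- data.frame(
    spectrum_id = ids,
    sample_id = unname(vapply(side[ids], function(e) e$sample_id, character(1))),
    class_label = unname(vapply(side[ids], function(e) e$class_label, character(1))),
    stage = unname(vapply(side[ids], function(e) e$stage, character(1))),
    stringsAsFactors = FALSE)
  sample_set(wide$wavenumber, t(as.matrix(wide[, -1, drop = FALSE])), meta)
}

#' Export one spectrum as JCAMP-DX
#'
#' Writes a minimal JCAMP-DX file with an `(X++(Y..Y))` XYDATA table, one
#' X/Y pair per line.
#'
#' @param wavenumber,intensity Numeric vectors of equal length.
#' @param path Output file path.
#' @param title `##TITLE` record.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(wavenumber, intensity, path, title = "spectrum") {
  stopifnot(length(wavenumber) == length(intensity))
  lines <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    paste0("##NPOINTS=", length(wavenumber)),
    paste0("##FIRSTX=", format(wavenumber[1], digits = 15)),
    paste0("##LASTX=", format(wavenumber[length(wavenumber)], digits = 15)),
    paste0("##DELTAX=", format(wavenumber[2] - wavenumber[1], digits = 15)),
    "##XFACTOR=1",
    "##YFACTOR=1",
    "##XYDATA=(X++(Y..Y))",
    paste(format(wavenumber, digits = 15, trim = TRUE),
          format(intensity, digits = 15, trim = TRUE)),
    "##END=")
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Parses the `XYDATA=(X++(Y..Y))` table (one or more Y values per line,
#' X spacing taken from `##DELTAX` when a line carries several), applying
#' `##XFACTOR`/`##YFACTOR`.
#'
#' @param path File path.
#' @return List with `wavenumber`, `intensity` and `title`.
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path)
  grab <- function(key, default = NA) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  title <- grab("TITLE", "")
  xf <- as.numeric(grab("XFACTOR", "1"))
  yf <- as.numeric(grab("YFACTOR", "1"))
  dx <- as.numeric(grab("DELTAX", NA))
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("no ##XYDATA record in ", path)
  stop_at <- grep("^##END", lines)
  stop_at <- min(stop_at[stop_at > start[1]])
  w <- numeric(0); y <- numeric(0)
  for (ln in lines[(start[1] + 1):(stop_at - 1)]) {
    tok <- as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1]])
    if (!length(tok) || anyNA(tok)) next
    if (length(tok) == 1) stop("XYDATA line with no Y value in ", path)
    ys <- tok[-1]
    xs <- tok[1] + (seq_along(ys) - 1) * (if (is.na(dx)) 0 else dx)
    w <- c(w, xs); y <- c(y, ys)
  }
  list(wavenumber = w * xf, intensity = y * yf, title = title)
}

build_grid <- function(family, grid_entry) {
  if (is.null(grid_entry) || !length(grid_entry))
    return(list(model_spec(family)))
  lapply(grid_entry, function(hp) do.call(model_spec, c(list(family), hp)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate (or load) -> two-class/three-class task filtering ->
#' repeated nested cross-validation per model family -> metrics (plus ROC
#' curves for the two-class task) -> optional occlusion study on a model
#' refitted to the full dataset. Every stage draws its randomness from a
#' named substream of the global seed.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure: fields `task` (`"two_class"` drops NORMAL samples, per the
#'   clinical use of MSI testing on confirmed CRC; `"three_class"` keeps
#'   all), `seed`, and optional blocks `design`, `profiles`, `data` (a
#'   directory for [read_spectra()], overriding simulation), `preprocess`,
#'   `augment`, `cv`, `models` (named list family -> list(grid = list of
#'   hyperparameter lists)) and `occlusion`.
#' @param out_dir Optional output directory; when given, writes
#'   `results.json`, per-family confusion-matrix CSVs, a metrics CSV, ROC
#'   points (two-class) and the occlusion map CSV.
#' @return Invisibly, a list with the generated `sample_set`, per-family
#'   fold results and `metrics_summary`s, ROC curves (two-class) and the
#'   occlusion map (when enabled).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  task <- match.arg(config$task %||% "three_class",
                    c("two_class", "three_class"))
  seed <- as.integer(config$seed %||% 1)

  if (!is.null(config$data)) {
    ss <- read_spectra(config$data)
  } else {
    prof_args <- config$profiles %||% list()
    profiles <- do.call(default_profiles, prof_args)
    des_args <- config$design %||% list()
    des_args$seed <- derive_seed(seed, "simulate")
    design <- do.call(study_design, des_args)
    ss <- generate_study(design, profiles)
  }
  if (task == "two_class") {
    keep <- names(sample_labels(ss))[sample_labels(ss) != "NORMAL"]
    ss <- subset_samples(ss, keep)
  }

  prep_cfg <- do.call(preprocess_config, config$preprocess %||% list())
  aug_cfg <- do.call(augmentation_config, config$augment %||% list())
  cv_args <- config$cv %||% list()
  cv_args$seed <- derive_seed(seed, "cv")
  cfg <- do.call(cv_config, cv_args)

  model_blocks <- config$models %||%
    list(pca_lda = list(), svm_rbf = list(), cnn_1d = list())
  families <- names(model_blocks)
  results <- list()
  for (fam in families) {
    grid <- build_grid(fam, model_blocks[[fam]]$grid)
    folds <- nested_cv(ss, grid, aug_cfg, prep_cfg, cfg)
    metrics <- compute_metrics(folds, cfg)
    roc <- if (task == "two_class") roc_curve(folds, cfg) else NULL
    results[[fam]] <- list(folds = folds, metrics = metrics, roc = roc)
  }

  occ_cfg <- config$occlusion %||% list(enabled = FALSE)
  occlusion <- NULL
  if (isTRUE(occ_cfg$enabled)) {
    fam <- occ_cfg$model %||% families[1]
    acfg <- aug_cfg
    acfg$seed <- derive_seed(seed, "occlusion-aug")
    full_pp <- preprocess_set(augment_training_set(ss, acfg), prep_cfg)
    model <- fit_model(build_grid(fam, model_blocks[[fam]]$grid)[[1]],
                       full_pp, seed = derive_seed(seed, "occlusion-fit"))
    probe <- preprocess_set(ss, prep_cfg)
    occlusion <- occlusion_study(model, probe,
                                 window_width = occ_cfg$window_width %||% 30,
                                 stride = occ_cfg$stride %||% 10)
  }

  out <- list(task = task, seed = seed, data = ss,
              results = results, occlusion = occlusion)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fold_record <- function(fr) {
  list(repeat_index = fr$repeat_index, fold_index = fr$fold_index,
       family = fr$spec$family,
       hyperparameters = fr$spec$hyperparameters[
         !vapply(fr$spec$hyperparameters, is.null, logical(1))],
       test_samples = as.list(stats::setNames(fr$truth, fr$test_samples)),
       voted = as.list(stats::setNames(fr$voted, fr$test_samples)))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(schema = "ramanmsi/results/1", task = out$task, seed = out$seed,
             models = lapply(out$results, function(res) list(
               folds = lapply(res$folds, fold_record),
               summary = res$metrics$summary,
               confusion_percent = as.data.frame.matrix(res$metrics$confusion))))
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  metr <- do.call(rbind, lapply(names(out$results), function(fam) {
    s <- out$results[[fam]]$metrics$summary
    cbind(model = fam, s)
  }))
  utils::write.csv(metr, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  for (fam in names(out$results)) {
    utils::write.csv(
      as.data.frame.matrix(out$results[[fam]]$metrics$confusion),
      file.path(out_dir, paste0("confusion_", fam, ".csv")))
    roc <- out$results[[fam]]$roc
    if (!is.null(roc))
      utils::write.csv(roc$mean,
                       file.path(out_dir, paste0("roc_", fam, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(out$occlusion))
    utils::write.csv(as.data.frame(out$occlusion),
                     file.path(out_dir, "occlusion.csv"), row.names = FALSE)
  invisible(out_dir)
}
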