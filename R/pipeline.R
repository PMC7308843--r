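# End-to-end experiment driver and pixel-wise quality distribution maps.

#' Experiment configuration
#'
#' @param target `"ssc"`, `"ph"` or `"vc"`.
#' @param blocks feature blocks to fuse, subset of
#'   `c("spectral", "color", "texture")`.
#' @param pretreatment `"none"`, `"wt"` or `"msc"` (spectral block only).
#' @param model `"plsr"`, `"svr"` or `"lwr"`.
#' @param selector `"none"`, `"cars"` or `"uve"`.
#' @param n_components PLSR components; `NULL` chooses by RMSECV.
#' @param seed experiment seed (selection, folds, SVR tuning).
#' @param window wavelength crop window in nm.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(target = c("ssc", "ph", "vc"),
                              blocks = "spectral",
                              pretreatment = c("none", "wt", "msc"),
                              model = c("plsr", "svr", "lwr"),
                              selector = c("none", "cars", "uve"),
                              n_components = NULL, seed = 1L,
                              window = c(400, 1000)) {
  structure(list(target = match.arg(target),
                 blocks = match.arg(blocks, c("spectral", "color", "texture"),
                                    several.ok = TRUE),
                 pretreatment = match.arg(pretreatment),
                 model = match.arg(model), selector = match.arg(selector),
                 n_components = n_components, seed = as.integer(seed),
                 window = window),
            class = "experiment_config")
}

#' Run one end-to-end experiment
#'
#' Takes a dataset as produced by [generate_dataset()] (truth table plus
#' extracted spectra and optional color/texture blocks), crops the spectra
#' to the configured window, applies the pretreatment (MSC reference frozen
#' on the calibration rows), assembles the fused feature table, optionally
#' runs variable selection on the calibration rows, splits by grouped
#' Kennard-Stone 3:1, fits the configured model and reports calibration and
#' prediction metrics.
#'
#' @param cfg `experiment_config`.
#' @param dataset list with `truth`, `spectra`, optionally `color`,
#'   `texture`.
#' @param out_dir optional directory; when given, the report, selection and
#'   provenance JSON files are written there.
#' @return list of class `experiment_result`: `report`
#'   (`evaluation_report`), `split`, `selection` (or NULL), `model`,
#'   `feature_names`, `blocks`, `config`.
#' @export
run_experiment <- function(cfg, dataset, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  truth <- dataset$truth
  y_all <- truth[[cfg$target]]
  spectra <- stage("crop", crop_bands(dataset$spectra, cfg$window[1],
                                      cfg$window[2]))

  # the split must precede MSC so its reference uses calibration rows only;
  # KS operates on the raw cropped spectra
  split <- stage("split", kennard_stone_split(spectra$X, truth$id,
                                              truth$group))
  spectra <- stage("pretreat",
                   pretreat(spectra, cfg$pretreatment, split$calibration_ids))

  texture <- if ("texture" %in% cfg$blocks) dataset$texture[[cfg$target]] else NULL
  feats <- stage("features",
                 assemble_features(spectra, color = dataset$color,
                                   texture = texture, include = cfg$blocks))
  cal <- feats$ids %in% split$calibration_ids
  # color/texture blocks live on arbitrary scales; z-score them with
  # calibration statistics so distance- and coefficient-based methods treat
  # the blocks comparably (spectral columns stay in reflectance units)
  nonspec <- which(feats$blocks != "spectral")
  if (length(nonspec)) {
    mu <- colMeans(feats$F[cal, nonspec, drop = FALSE])
    sdv <- apply(feats$F[cal, nonspec, drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    feats$F[, nonspec] <- sweep(sweep(feats$F[, nonspec, drop = FALSE],
                                      2, mu, "-"), 2, sdv, "/")
  }
  X_cal <- feats$F[cal, , drop = FALSE]
  X_pred <- feats$F[!cal, , drop = FALSE]
  y_cal <- y_all[cal]; y_pred <- y_all[!cal]

  selection <- NULL
  keep <- seq_len(ncol(feats$F))
  if (cfg$selector != "none") {
    selection <- stage("selection", switch(cfg$selector,
      cars = cars(X_cal, y_cal, n_components = cfg$n_components,
                  seed = cfg$seed),
      uve = uve(X_cal, y_cal,
                n_components = if (is.null(cfg$n_components)) 10L else
                  cfg$n_components, seed = cfg$seed)))
    keep <- selection$selected
    X_cal <- X_cal[, keep, drop = FALSE]
    X_pred <- X_pred[, keep, drop = FALSE]
  }

  model <- stage("fit", switch(cfg$model,
    plsr = {
      A <- if (is.null(cfg$n_components))
        choose_components(X_cal, y_cal, seed = cfg$seed) else
        min(cfg$n_components, nrow(X_cal) - 1, ncol(X_cal))
      fit_plsr(X_cal, y_cal, A)
    },
    svr = fit_svr(X_cal, y_cal, seed = cfg$seed),
    lwr = structure(list(method = "lwr", X_cal = X_cal, y_cal = y_cal,
                         n_features = ncol(X_cal)),
                    class = c("lwr_model", "regression_model"))))
  yhat_cal <- stage("predict", .predict_any(model, X_cal))
  yhat_pred <- stage("predict", .predict_any(model, X_pred))
  report <- stage("evaluate", evaluate(y_cal, yhat_cal, y_pred, yhat_pred))

  res <- structure(list(report = report, split = split,
                        selection = selection, model = model,
                        feature_names = feats$names[keep],
                        blocks = feats$blocks[keep],
                        wavelengths = feats$wavelengths[keep],
                        config = cfg),
                   class = "experiment_result")
  if (!is.null(out_dir)) .persist_experiment(res, out_dir)
  res
}

.predict_any <- function(model, X) {
  if (inherits(model, "lwr_model")) {
    if (ncol(X) != model$n_features)
      stop(sprintf("model expects %d features, got %d",
                   model$n_features, ncol(X)))
    lwr_predict(model$X_cal, model$y_cal, X)
  } else predict(model, X)
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("experiment: %s ~ %s | pretreat %s | model %s | selector %s\n",
              cfg$target, paste(cfg$blocks, collapse = "+"),
              cfg$pretreatment, cfg$model, cfg$selector))
  if (!is.null(x$selection)) {
    tab <- table(x$blocks)
    cat(sprintf("  selected %d variables (%s)\n", length(x$selection$selected),
                paste(sprintf("%s %d", names(tab), tab), collapse = " + ")))
  }
  cat("  "); print(x$report)
  invisible(x)
}

#' Flatten an experiment report to a one-row data frame
#' @param res `experiment_result`.
#' @return data.frame keyed by (target, features, pretreatment, model,
#'   selector) with the four metrics; rows mirror the layout of standard
#'   chemometric results tables.
#' @export
report_row <- function(res) {
  cfg <- res$config; r <- res$report
  data.frame(target = cfg$target,
             features = paste(cfg$blocks, collapse = "+"),
             pretreatment = cfg$pretreatment, model = cfg$model,
             selector = cfg$selector,
             n_variables = length(res$feature_names),
             rc2 = r$rc2, rmsec = r$rmsec, rp2 = r$rp2, rmsep = r$rmsep)
}

# Deterministic JSON artifacts: report + provenance (+ selection).
.persist_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  stub <- paste(cfg$target, paste(cfg$blocks, collapse = "-"),
                cfg$pretreatment, cfg$model, cfg$selector, sep = "_")
  r <- res$report
  jsonlite::write_json(
    list(rc2 = r$rc2, rmsec = r$rmsec, rp2 = r$rp2, rmsep = r$rmsep,
         n_cal = r$n_cal, n_pred = r$n_pred),
    file.path(out_dir, paste0(stub, "_report.json")),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = unclass(cfg), seed = cfg$seed,
         package_version = as.character(utils::packageVersion("berryhsi")),
         calibration_ids = res$split$calibration_ids,
         prediction_ids = res$split$prediction_ids,
         n_features = length(res$feature_names)),
    file.path(out_dir, paste0(stub, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(res$selection))
    write_selection_json(res$selection,
                         file.path(out_dir, paste0(stub, "_selection.json")))
  invisible(res)
}

#' Pixel-wise quality distribution map
#'
#' Extracts each masked pixel's reflectance at the model's wavelengths and
#' predicts the quality parameter per pixel; pixels outside the mask are NA.
#' The model must have been trained on exactly those band values (maps use
#' raw reflectance; when the model was trained on MSC spectra, pass the
#' frozen calibration reference through `msc_reference` so each pixel
#' spectrum is corrected the same way).
#'
#' @param cube reflectance `hypercube`.
#' @param mask `roi_mask` or logical matrix.
#' @param model a `regression_model` (or `lwr_model`).
#' @param wavelengths the wavelengths (nm) the model consumes, in training
#'   column order.
#' @param msc_reference optional full-spectrum MSC reference; when supplied,
#'   per-pixel spectra are scatter-corrected against it before band
#'   extraction (the reference must cover `ref_wavelengths`).
#' @param ref_wavelengths wavelengths of `msc_reference`.
#' @return object of class `distribution_map`: `values` matrix (NA outside
#'   the mask), `mask`, `wavelengths`.
#' @export
distribution_map <- function(cube, mask, model, wavelengths,
                             msc_reference = NULL, ref_wavelengths = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  d <- dim(cube$data)
  px <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  if (!is.null(msc_reference)) {
    if (is.null(ref_wavelengths)) ref_wavelengths <- cube$wavelengths
    keep <- resolve_bands(cube$wavelengths, ref_wavelengths)
    tab <- msc(spectra_table(px[, keep, drop = FALSE], ref_wavelengths),
               msc_reference)
    px <- tab$X
    bands <- resolve_bands(ref_wavelengths, wavelengths)
  } else {
    bands <- resolve_bands(cube$wavelengths, wavelengths)
  }
  Xpix <- px[, bands, drop = FALSE]
  pred <- .predict_any(model, Xpix)
  values <- matrix(NA_real_, d[1], d[2])
  values[idx] <- pred
  structure(list(values = values, mask = m, wavelengths = wavelengths),
            class = "distribution_map")
}

#' Render a distribution map as a PNG
#'
#' Blue (low) to red (high) colormap scaled to the map's finite range;
#' pixels outside the mask are fully transparent. A JSON sidecar records the
#' value bounds used for the color scaling, and a colorbar strip PNG is
#' written next to the map.
#'
#' @param map `distribution_map`.
#' @param path output PNG path.
#' @return the value bounds used, invisibly.
#' @export
render_map <- function(map, path) {
  stopifnot(inherits(map, "distribution_map"))
  v <- map$values
  rng <- range(v, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) ifelse(is.na(v), NA, 0.5) else
    (v - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  rgba <- array(0, dim = c(nrow(v), ncol(v), 4))
  ok <- which(!is.na(scaled))
  cols <- ramp(scaled[ok]) / 255
  for (ch in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- cols[, ch]
    rgba[, , ch] <- plane
  }
  alpha <- matrix(0, nrow(v), ncol(v))
  alpha[ok] <- 1
  rgba[, , 4] <- alpha
  png::writePNG(rgba, path)
  bar <- ramp(seq(1, 0, length.out = 128)) / 255   # red at top
  strip <- aperm(array(t(bar), dim = c(3, 128, 12)), c(2, 3, 1))
  png::writePNG(strip, sub("\\.png$", "_colorbar.png", path))
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       sub("\\.png$", "_bounds.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(rng)
}
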