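#' Pipeline configuration
#'
#' Collects the thresholds, board layout, model choice and seed for an
#' end-to-end run. All thresholds are validated against their documented
#' ranges; the seed and a configuration hash are embedded in every output.
#'
#' @param layout a [board_layout()] (or a YAML path).
#' @param thresholds a [default_thresholds()] list.
#' @param gamma_target gray-card target value (fixed at 119 for the 18%
#'   card; exposed for completeness).
#' @param model regressor kind for [gmc_train()].
#' @param seed integer seed.
#' @param use_luminance use scalar luminance instead of per-channel
#'   white/black values in the contrast stretch.
#' @return A `pipeline_config` list with a `hash`.
#' @export
pipeline_config <- function(layout = board_layout(),
                            thresholds = default_thresholds(),
                            gamma_target = 119,
                            model = c("SVR", "RF", "MLP", "MLR"),
                            seed = 1, use_luminance = FALSE) {
  if (is.character(layout)) layout <- read_layout(layout)
  model <- match.arg(model)
  stopifnot(thresholds$halation_cut >= 0,
            thresholds$stem_hue_cut >= 25, thresholds$stem_hue_cut <= 35)
  cfg <- list(layout = layout, thresholds = thresholds,
              gamma_target = gamma_target, model = model, seed = seed,
              use_luminance = use_luminance)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

# small FNV-style rolling hash over the deparsed configuration
config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(txt)) h <- ((h * 16777619) + v) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a sample-weights CSV
#'
#' Schema: `sample_id`, `w_wet`, `w_dry` (grams), optional `survey_date`
#' (ISO 8601). Extra columns are preserved; the wet-basis GMC is computed
#' and attached as `gmc_wb`.
#'
#' @param path CSV path.
#' @return data.frame with `gmc_wb`.
#' @export
read_samples_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "w_wet", "w_dry")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("samples CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  df$gmc_wb <- wet_basis_gmc(df$w_wet, df$w_dry)
  if ("survey_date" %in% names(df)) df$survey_date <- as.Date(df$survey_date)
  df
}

#' Write / read a feature table CSV
#'
#' Schema: `sample_id`, `n_pixels`, the 18 [CI_NAMES] columns, then any
#' extra columns (e.g. `gmc_wb`), which round-trip untouched.
#'
#' @param features data.frame of per-sample features.
#' @param path CSV path.
#' @param seed,hash optional provenance, embedded as comment-free extra
#'   columns on write when supplied.
#' @return `write_features_csv`: `path` invisibly; `read_features_csv`:
#'   the data.frame.
#' @export
write_features_csv <- function(features, path, seed = NULL, hash = NULL) {
  if (!is.null(seed)) features$seed <- seed
  if (!is.null(hash)) features$config_hash <- hash
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", CI_NAMES), names(df))
  if (length(miss))
    stop("features CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read / write a multiday series CSV
#'
#' Schema: `date` (ISO 8601), `growth_day`, `mean_gmc_pct`,
#' `n_subsamples`. GMC is stored in the file as percent and held in memory
#' as a fraction.
#'
#' @param path CSV path.
#' @return `read_multiday_csv`: a [multiday_series()];
#'   `write_multiday_csv`: `path` invisibly.
#' @export
read_multiday_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "growth_day", "mean_gmc_pct", "n_subsamples")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("multiday CSV schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  multiday_series(date = as.Date(df$date), growth_day = df$growth_day,
                  mean_gmc = df$mean_gmc_pct / 100,
                  n_subsamples = df$n_subsamples)
}

#' @rdname read_multiday_csv
#' @param series a [multiday_series()].
#' @export
write_multiday_csv <- function(series, path) {
  write.csv(data.frame(date = format(series$date, "%Y-%m-%d"),
                       growth_day = series$growth_day,
                       mean_gmc_pct = series$mean_gmc * 100,
                       n_subsamples = series$n_subsamples),
            path, row.names = FALSE)
  invisible(path)
}

#' Run the image pipeline end to end
#'
#' For each input image: calibrate (anchors, contrast, gamma, halation),
#' crop the ROI, run the background-removal cascade, and average the 18
#' color indices. Per-sample failures are isolated and collected; the run
#' continues. When a weights table is supplied, GMC is attached (after the
#' validity filter) and a regressor is trained on PCA-selected indices.
#'
#' @param images list of [raw_image()] objects, PNG paths, or rendered
#'   scenes (lists with an `image` element).
#' @param weights optional data.frame from [read_samples_csv()] (or a CSV
#'   path), keyed by `sample_id`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   `eval.json` and a `run.log`.
#' @return list: `features` (data.frame), `failures` (named list of error
#'   messages), and when trained, `model`, `selection`, `report`.
#' @export
run_pipeline <- function(images, weights = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(weights)) weights <- read_samples_csv(weights)
  rows <- list(); failures <- list()
  for (k in seq_along(images)) {
    res <- tryCatch({
      im <- images[[k]]
      if (is.character(im)) im <- read_image(im)
      if (is.list(im) && !inherits(im, "raw_image") && !is.null(im$image))
        im <- im$image
      cal <- calibrate_image(im, layout = config$layout,
                             sigma_threshold = config$thresholds$halation_cut)
      roi <- crop_roi(cal$corrected, cal$anchors, config$layout)
      hal <- crop_apply(roi, cal$halation$retained)
      gm <- remove_background(roi, config$thresholds, halation = hal)
      ci <- sample_ci_vector(roi, gm)
      id <- if (!is.na(cal$anchors$sample_code)) cal$anchors$sample_code
            else im$sample_id
      data.frame(sample_id = as.character(id),
                 n_pixels = attr(ci, "n_pixels"),
                 as.list(ci), check.names = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nm <- if (is.character(images[[k]])) images[[k]] else paste0("image_", k)
      failures[[nm]] <- conditionMessage(res)
    } else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("pipeline produced no features")
  features <- do.call(rbind, rows)
  out <- list(features = features, failures = failures,
              seed = config$seed, config_hash = config$hash)
  if (!is.null(weights)) {
    merged <- merge(features, weights[, c("sample_id", "gmc_wb")],
                    by = "sample_id")
    merged <- filter_valid(merged)
    if (nrow(merged) >= 10) {
      std <- ci_standardize(merged[, CI_NAMES])
      pca <- ci_pca(std$z)
      keep <- retain_components(pca$eigenvalues)
      sel <- select_cis(pca$loadings, keep)
      sp <- split_and_fold(merged$gmc_wb, seed = config$seed)
      x <- as.matrix(merged[, sel, drop = FALSE])
      mdl <- gmc_train(x[sp$train, , drop = FALSE],
                       merged$gmc_wb[sp$train],
                       regressor_spec(config$model, seed = config$seed))
      pred <- predict(mdl, x[sp$test, , drop = FALSE])
      out$model <- mdl
      out$selection <- sel
      out$report <- interval_report(merged$gmc_wb[sp$test], pred)
      out$labeled <- merged
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features_csv(features, file.path(out_dir, "features.csv"),
                       seed = config$seed, hash = config$hash)
    if (!is.null(out$report))
      jsonlite::write_json(
        list(seed = config$seed, config_hash = config$hash,
             selection = out$selection, report = out$report,
             r_squared = attr(out$report, "r_squared")),
        file.path(out_dir, "eval.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("seed: %d  config: %s", config$seed, config$hash),
                 sprintf("samples ok: %d  failed: %d", nrow(features),
                         length(failures)),
                 if (length(failures))
                   paste0("FAIL ", names(failures), ": ",
                          unlist(failures))),
               file.path(out_dir, "run.log"))
  }
  out
}
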