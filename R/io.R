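#' Read a print-parameter dataset CSV
#'
#' Strict reader for the canonical dataset schema: header
#' `viscosity_mPa_s, nozzle_id_mm, printing_time_s, pressure_psi,
#' cell_conc_per_mL, volume_uL`, UTF-8, comma separator, `.` decimal point.
#' Missing columns raise a schema error naming the column; any cell that
#' does not parse as a number (including decimal commas and blanks) raises
#' a row-indexed parse error.
#'
#' @param path CSV file path.
#' @return A tibble of typed records, row order preserved.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop_dropsizer(paste0("Dataset not found: ", path),
                   class = "dropsizer_error_input")
  }
  schema <- c(feature_names(), "volume_uL")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(schema, names(raw))
  if (length(missing_cols)) {
    stop_dropsizer(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
                   class = "dropsizer_error_schema")
  }
  out <- raw[schema]
  for (col in schema) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_dropsizer(
        sprintf("Column `%s`: non-numeric value \"%s\" at data row %d.",
                col, out[[col]][bad[1]], bad[1]),
        class = "dropsizer_error_parse"
      )
    }
    out[[col]] <- v
  }
  tibble::as_tibble(out)
}

#' Write a print-parameter dataset CSV
#'
#' Inverse of [read_dataset()]: canonical column order, comma separator,
#' `.` decimals. Writing then re-reading is the identity, and re-writing a
#' file produced by this function is byte-identical.
#'
#' @param records Data frame with the schema columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  check_records(records)
  readr::write_csv(records[c(feature_names(), "volume_uL")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write a JSON model card
#'
#' Records the provenance of a trained model: algorithm, hyperparameters,
#' seed, held-out metrics (the card's `accuracy` is the held-out test R2),
#' training size and package version.
#'
#' @param model A [fit_droplet_model()] result.
#' @param metrics One-row tibble from [evaluate_model()] (optional).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model_card <- function(model, path, metrics = NULL) {
  stopifnot(inherits(model, "droplet_model"))
  card <- list(
    algorithm = model$spec$algorithm,
    hyperparameters = model$spec$hyperparameters,
    seed = model$spec$seed,
    n_train = model$n_train,
    train_time_ms = model$train_time_ms,
    package_version = as.character(utils::packageVersion("dropsizer"))
  )
  if (!is.null(metrics)) {
    card$metrics <- as.list(metrics[c("mae", "mse", "rmse", "r2",
                                      "test_time_ms")])
    card$accuracy <- metrics$r2
  }
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON model card
#' @param path Path written by [write_model_card()].
#' @return A named list.
#' @export
read_model_card <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# sidecar provenance file: every CLI artifact <out> gets <out>.meta.json with
# the seed and a hash of the generating configuration
write_meta <- function(path, seed, config) {
  meta <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("dropsizer")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(NULL)
}
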