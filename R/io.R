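# Plain-text on-disk dialects: one directory per patient holding
# eeg.csv (single column, 125 Hz), vitals.csv, raters.csv and meta.json,
# plus feature tables with their normalization bounds.

#' Write a synthetic patient to a directory
#'
#' @param patient a `synthetic_patient`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(eeg = patient$eeg),
            file.path(dir, "eeg.csv"), row.names = FALSE)
  write.csv(patient$vitals, file.path(dir, "vitals.csv"), row.names = FALSE)
  write.csv(patient$raters, file.path(dir, "raters.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = patient$seed, fs = 125, window_s = 5,
         profile = cbind(channel = rownames(patient$profile),
                         patient$profile),
         latent = patient$latent),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "columns"
  )
  invisible(dir)
}

#' Read a patient directory written by [write_patient()]
#'
#' Also accepts externally produced directories with the same layout;
#' `meta.json` and the latent trajectory are optional.
#'
#' @param dir patient directory.
#' @return list with `eeg`, `vitals`, `raters` (and `latent`, `seed` when
#'   recorded).
#' @export
read_patient <- function(dir) {
  out <- list(
    eeg = read.csv(file.path(dir, "eeg.csv"))[[1]],
    vitals = read.csv(file.path(dir, "vitals.csv")),
    raters = read.csv(file.path(dir, "raters.csv"))
  )
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    out$seed <- meta$seed
    if (!is.null(meta$latent)) {
      out$latent <- structure(as.data.frame(meta$latent),
                              class = c("latent_trajectory", "data.frame"))
    }
  }
  out
}

#' Write / read a feature table with its normalization bounds
#'
#' The table goes to `<stem>.csv` and the bounds to `<stem>_bounds.json`.
#'
#' @param table unnormalized feature table.
#' @param bounds a `norm_bounds` object (optional).
#' @param stem file stem (no extension).
#' @export
write_features <- function(table, stem, bounds = NULL) {
  write.csv(table, paste0(stem, ".csv"), row.names = FALSE)
  if (!is.null(bounds)) {
    jsonlite::write_json(lapply(bounds, identity),
                         paste0(stem, "_bounds.json"), digits = NA)
  }
  invisible(stem)
}

#' @rdname write_features
#' @export
read_features <- function(stem) {
  tab <- read.csv(paste0(stem, ".csv"))
  bpath <- paste0(stem, "_bounds.json")
  if (file.exists(bpath)) {
    attr(tab, "bounds") <- structure(
      lapply(jsonlite::read_json(bpath, simplifyVector = TRUE), as.numeric),
      class = "norm_bounds"
    )
  }
  tab
}
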