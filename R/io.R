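#' Write / read a recording as CSV matrix + JSON sidecar
#'
#' The on-disk form of a recording is a pair `<stem>.csv` (samples x
#' channels, header = channel labels, '.' decimal) and `<stem>.json`
#' holding `fs`, `labels`, `subject`, `group`, `age`, `sex` and the epoch
#' boundaries (sample indices). Round-trips preserve samples to numeric
#' precision.
#'
#' @param recording A `recording`.
#' @param stem Output path without extension.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns a `recording`.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "recording"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  m <- t(recording$samples)
  colnames(m) <- recording$labels
  utils::write.csv(m, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(fs = recording$fs, labels = recording$labels,
               subject = recording$subject, group = recording$group,
               age = recording$age, sex = recording$sex,
               epochs = apply(recording$epochs, 1, as.list))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @param path Path to the `.csv` (or its stem); the `.json` sidecar must
#'   sit beside it.
#' @export
read_recording <- function(path) {
  stem <- sub("\\.csv$", "", path)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("missing data file: ", csv)
  if (!file.exists(js)) stop("missing JSON sidecar: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0) stop("sidecar fs missing or invalid")
  m <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  if (!is.numeric(m)) stop("non-numeric values in ", csv)
  if (anyNA(m)) stop("NaN/NA samples in ", csv)
  labels <- colnames(m)
  if (!identical(labels, as.character(meta$labels)))
    stop("channel labels in CSV header and sidecar disagree")
  epochs <- as.matrix(meta$epochs)
  storage.mode(epochs) <- "integer"
  if (nrow(epochs) && max(epochs) > nrow(m))
    stop("file truncated: epochs extend to sample ", max(epochs),
         " but only ", nrow(m), " samples present")
  structure(list(samples = t(m), fs = as.numeric(meta$fs), labels = labels,
                 subject = meta$subject %||% stem, group = meta$group,
                 age = as.numeric(meta$age %||% NA_real_),
                 sex = meta$sex %||% NA_character_,
                 epochs = epochs), class = "recording")
}

#' Write / read a cohort directory
#'
#' One CSV+JSON recording pair per subject plus `manifest.csv` with the
#' subject covariates, seeds and ground-truth generator parameters.
#'
#' @param cohort List from [gen_cohort()].
#' @param dir Cohort directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, rec$subject))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_file <- file.path(dir, "manifest.csv")
  if (!file.exists(man_file)) stop("no manifest.csv in ", dir)
  manifest <- tibble::as_tibble(utils::read.csv(man_file, check.names = FALSE))
  recs <- lapply(manifest$subject, function(id)
    read_recording(file.path(dir, id)))
  list(recordings = recs, manifest = manifest)
}
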