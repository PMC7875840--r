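trial_columns <- c("subject_id", "session", "trial_index", "condition",
                   "numerosity", "response", "rt", "area_control",
                   "is_training")

#' Read a trial table from CSV
#'
#' Expects the canonical schema
#' `subject_id,session,trial_index,condition,numerosity,response,rt,area_control,is_training`
#' with conditions spelled `VSL`/`IS`/`ID` and reaction times in seconds.
#'
#' @param path CSV file path.
#' @return Validated trial data frame.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("Trial CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(trials$condition), conditions())
  if (length(bad)) {
    stop("Unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  trials$area_control <- as.logical(trials$area_control)
  trials$is_training <- as.logical(trials$is_training)
  if (any(trials$rt <= 0)) stop("Reaction times must be positive.")
  trials
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds (any subset of) the fields of [default_config()]:
#' session design, per-condition observer and reaction-time parameters,
#' cleaning rules, fitting options and the master seed. Unspecified fields
#' fall back to the defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("Config must be a .yaml/.yml or .json file.")
  }
}
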