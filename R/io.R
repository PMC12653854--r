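DATASET_COLUMNS <- c("subject_id", "trial", "age_y", "weight_kg",
                     "phenotype", "compound", "time_h", "conc_mg_per_L",
                     "dose_mg", "regimen_id")

#' Read a tidy concentration-time dataset
#'
#' Strict-schema CSV reader for the package's interchange format
#' (columns: subject_id, trial, age_y, weight_kg, phenotype, compound,
#' time_h, conc_mg_per_L, dose_mg, regimen_id).
#'
#' @param path CSV path.
#' @return Data frame with the validated schema.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("empty dataset file: ", path, call. = FALSE)
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("dataset has a header but no rows: ", path,
                         call. = FALSE)
  missing <- setdiff(DATASET_COLUMNS, names(d))
  if (length(missing)) {
    stop("dataset is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age_y", "weight_kg", "time_h", "conc_mg_per_L",
                "dose_mg")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad)) {
      stop("malformed numeric value in column '", col, "' at data line ",
           bad[1] + 1, call. = FALSE)
    }
    d[[col]] <- v
  }
  if (any(d$conc_mg_per_L < 0, na.rm = TRUE)) {
    stop("negative concentrations in dataset", call. = FALSE)
  }
  d
}

#' Write a tidy concentration-time dataset
#' @param data Data frame with the dataset schema columns.
#' @param path Output CSV path.
#' @export
write_dataset <- function(data, path) {
  missing <- setdiff(DATASET_COLUMNS, names(data))
  if (length(missing)) {
    stop("dataset is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  write.csv(data[, DATASET_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Convert a trial-set result to the tidy dataset format
#' @param trial_result Output of [run_trial_set()].
#' @param regimen_id Label for the regimen.
#' @export
subjects_to_dataset <- function(trial_result, regimen_id = "trial") {
  d <- trial_result$subjects
  data.frame(subject_id = d$subject_id, trial = d$trial, age_y = d$age_y,
             weight_kg = d$weight_kg, phenotype = d$phenotype,
             compound = d$compound, time_h = d$t_end,
             conc_mg_per_L = d$cavg, dose_mg = NA_real_,
             regimen_id = regimen_id)
}

#' Read and validate a run configuration
#'
#' YAML configuration with a closed schema; unknown keys are rejected.
#' Recognised keys: `scenario`, `seed`, `out_dir`, `physiology_path`,
#' `compound_paths`, `solver` (`rtol`, `atol`, `output_step`),
#' `population` (passed to [population_spec()]).
#'
#' @param path YAML path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("scenario", "seed", "out_dir", "physiology_path",
               "compound_paths", "solver", "population")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("config needs a seed", call. = FALSE)
  if (!is.null(cfg$solver)) {
    bad <- setdiff(names(cfg$solver), c("rtol", "atol", "output_step"))
    if (length(bad)) {
      stop("unknown solver keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}
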