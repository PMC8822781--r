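# Delimited-text formats: person-year tables, model-parameter documents,
# run configuration. All formats are plain text and round-trip losslessly.

py_columns <- c("person_id", "region", "year_index", "age", "cci", "dci",
                "died", "censored", "cci_next", "dci_next")

#' Write a person-year table
#'
#' Comma-delimited with a header row and the fixed column set
#' `person_id, region, year_index, age, cci, dci, died, censored,
#' cci_next, dci_next`; absent next-year values are empty cells.
#'
#' @param cohort person-year data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_person_year_table <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(py_columns %in% names(cohort)))
  utils::write.csv(cohort[, py_columns, drop = FALSE], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read and validate a person-year table
#'
#' Parses the delimited person-year schema and validates every record:
#' legal ranges, the DCI grid, the cumulative-CCI invariant
#' (`cci_next >= cci`), mutual exclusion of `died` and `censored`,
#' next-year values absent exactly on death/censoring years, and
#' uniqueness of `(person_id, year_index)`. Validation failures name the
#' offending data rows.
#'
#' @param path file path.
#' @return validated person-year data.frame (possibly with zero rows).
#' @export
read_person_year_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_person_year_table: no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!identical(names(raw), py_columns)) {
    stop("read_person_year_table: header must be exactly: ",
         paste(py_columns, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.frame(person_id = character(), region = integer(),
                      year_index = integer(), age = integer(),
                      cci = integer(), dci = numeric(), died = integer(),
                      censored = integer(), cci_next = integer(),
                      dci_next = numeric())
    return(out)
  }
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems,
                     paste0("row ", paste(utils::head(rows, 5),
                                          collapse = ", "),
                            if (length(rows) > 5) ", ..." else "",
                            ": ", msg))
    }
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  blank <- function(x) is.na(x) | trimws(x) == ""

  out <- data.frame(
    person_id = raw$person_id,
    region = num(raw$region), year_index = num(raw$year_index),
    age = num(raw$age), cci = num(raw$cci), dci = num(raw$dci),
    died = num(raw$died), censored = num(raw$censored),
    cci_next = ifelse(blank(raw$cci_next), NA, num(raw$cci_next)),
    dci_next = ifelse(blank(raw$dci_next), NA, num(raw$dci_next))
  )
  rows <- seq_len(n)
  is_int <- function(x) !is.na(x) & abs(x - round(x)) < 1e-9
  on_grid <- function(x) !is.na(x) & abs(x / 0.25 - round(x / 0.25)) < 1e-9

  note(rows[blank(raw$person_id)], "empty person_id")
  note(rows[!is_int(out$region) | out$region < 1],
       "malformed region (positive integer required)")
  note(rows[!is_int(out$year_index) | out$year_index < 0],
       "malformed year_index")
  note(rows[!is_int(out$age) | out$age < 65 | out$age > 105],
       "age outside [65, 105]")
  note(rows[!is_int(out$cci) | out$cci < 0], "malformed cci (integer >= 0)")
  note(rows[!on_grid(out$dci) | out$dci < -0.75],
       "dci off the 0.25 grid or below -0.75")
  note(rows[!out$died %in% c(0, 1) | !out$censored %in% c(0, 1)],
       "died/censored must be 0 or 1")
  both <- !is.na(out$died) & !is.na(out$censored) &
    out$died == 1 & out$censored == 1
  note(rows[both], "died and censored cannot both be 1")
  terminal <- !is.na(out$died) & !is.na(out$censored) &
    (out$died == 1 | out$censored == 1)
  note(rows[terminal & (!is.na(out$cci_next) | !is.na(out$dci_next))],
       "next-year values must be absent on death/censoring rows")
  note(rows[!terminal & (is.na(out$cci_next) | is.na(out$dci_next))],
       "completed rows must carry cci_next and dci_next")
  has_cn <- !is.na(out$cci_next)
  note(rows[has_cn & (!is_int(out$cci_next) | out$cci_next < out$cci)],
       "cci_next < cci violates the cumulative-CCI invariant")
  has_dn <- !is.na(out$dci_next)
  note(rows[has_dn & (!on_grid(out$dci_next) | out$dci_next < -0.75)],
       "dci_next off the 0.25 grid or below -0.75")
  dup <- duplicated(paste(raw$person_id, out$year_index, sep = "\r"))
  note(rows[dup], "duplicate (person_id, year_index)")

  if (length(problems)) {
    stop("read_person_year_table: invalid table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  for (cl in c("region", "year_index", "age", "cci", "died", "censored",
               "cci_next")) {
    out[[cl]] <- as.integer(out[[cl]])
  }
  if (all(grepl("^[0-9]+$", out$person_id))) {
    out$person_id <- as.integer(out$person_id)
  }
  out
}

# ---- model-parameter document ---------------------------------------------

sub_to_list <- function(sub) {
  list(coefs = as.list(sub$coefs), terms = as.list(sub$terms),
       xlev = lapply(sub$xlev, as.list))
}

sub_from_list <- function(x) {
  cat_submodel(unlist(x$coefs), unlist(x$terms),
               lapply(x$xlev, function(l) unlist(l)))
}

#' Serialize a transition model set to a YAML document
#'
#' A fitted model set is written as a human-readable structured text
#' document with nested sections per sub-model, including the QCS cut
#' points and the categorizer bins, so the file is fully self-describing.
#'
#' @param models a [transition_model_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(models, path) {
  stopifnot(inherits(models, "transition_model_set"))
  d <- models$death
  doc <- list(
    format = "morbsim-model-set", version = 1L,
    death = d[c("intercept", "beta_age", "beta_cci", "beta_dci",
                "gamma_cci", "gamma_dci", "cut_cci", "cut_dci", "cut_age")],
    categorizer = list(
      cci_breaks = as.list(models$categorizer$cci_breaks),
      dci_breaks = as.list(models$categorizer$dci_breaks),
      age_breaks = as.list(models$categorizer$age_breaks)),
    cci = list(occurrence = sub_to_list(models$cci$occurrence),
               size0 = sub_to_list(models$cci$size0),
               size1 = sub_to_list(models$cci$size1),
               size_fixed = models$cci$size_fixed),
    dci = list(occurrence = sub_to_list(models$dci$occurrence),
               direction = sub_to_list(models$dci$direction),
               increase = list(shape = models$dci$increase$shape,
                               mean = sub_to_list(models$dci$increase$mean)),
               decrease = list(shape = models$dci$decrease$shape,
                               mean = sub_to_list(models$dci$decrease$mean)),
               step_fixed = models$dci$step_fixed)
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a transition model set from a YAML document
#'
#' @param path file written by [write_model_params()].
#' @return a [transition_model_set()].
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) {
    stop("read_model_params: no such file: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "morbsim-model-set")) {
    stop("read_model_params: not a morbsim model-set document", call. = FALSE)
  }
  d <- doc$death
  death <- death_model_params(d$intercept, d$beta_age, d$beta_cci,
                              d$beta_dci, d$gamma_cci, d$gamma_dci,
                              d$cut_cci, d$cut_dci, d$cut_age)
  categorizer <- covariate_categorizer(unlist(doc$categorizer$cci_breaks),
                                       unlist(doc$categorizer$dci_breaks),
                                       unlist(doc$categorizer$age_breaks))
  cci <- cci_change_params(sub_from_list(doc$cci$occurrence),
                           sub_from_list(doc$cci$size0),
                           sub_from_list(doc$cci$size1),
                           size_fixed = doc$cci$size_fixed)
  dci <- dci_change_params(
    sub_from_list(doc$dci$occurrence),
    sub_from_list(doc$dci$direction),
    increase = list(shape = doc$dci$increase$shape,
                    mean = sub_from_list(doc$dci$increase$mean)),
    decrease = list(shape = doc$dci$decrease$shape,
                    mean = sub_from_list(doc$dci$decrease$mean)),
    step_fixed = doc$dci$step_fixed)
  transition_model_set(death, cci, dci, categorizer)
}

# ---- run configuration -----------------------------------------------------

config_defaults <- function() {
  list(
    seed = NULL,
    cohort = list(n_individuals = 25000L, n_regions = 6L,
                  max_followup = 11L, annual_censor_prob = 0.02),
    models = list(cut_cci = 7, cut_dci = 14, cut_age = 100,
                  cci_breaks = c(1, 2, 3), dci_breaks = c(0, 1, 3),
                  age_breaks = c(75, 85)),
    simulation = list(n_individuals = 10000L, max_age = 105L,
                      start_ages = 65:90, start_cci = 0:10,
                      start_dci = seq(-0.75, 13.5, by = 0.25),
                      quadrature = "trapezoid"),
    validation = list(n_bins = 10L, horizon = 10L),
    output = list(dir = ".")
  )
}

#' Read a run-configuration document
#'
#' YAML with sections `cohort`, `models`, `simulation`, `validation`,
#' `output` and a top-level `seed`; every key is optional and defaults are
#' documented in [config_defaults]. Unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop("read_run_config: no such file: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) {
    stop("read_run_config: malformed config document", call. = FALSE)
  }
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("read_run_config: unknown top-level keys: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (sec in intersect(names(user), setdiff(names(cfg), "seed"))) {
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad)) {
      stop("read_run_config: unknown keys in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- unlist(user[[sec]][[k]])
  }
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  cfg
}
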