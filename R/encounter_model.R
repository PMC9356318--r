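#' Encounter data model
#'
#' An encounter bundle holds the three tables the analysis consumes:
#' admissions (one row per hospitalization, the future network node),
#' unit stays (intervals of days an admission spends in one unit, the
#' source of colocation), and antibiotic exposures (days on which an
#' admission is receiving an agent of a given spectrum rank).
#'
#' All dates are day-granular; stay intervals are inclusive on both ends,
#' so a stay with `entry_date == exit_date` contributes that single day.
#'
#' @param admissions Data frame with columns `admission_id`, `patient_id`,
#'   `hospital_id`, `age` (integer years, 0-90 top-coded), `sex`
#'   (`"F"`, `"M"` or `NA`), `elixhauser` (integer 0-16), `admit_date`,
#'   `discharge_date` (`Date`).
#' @param stays Data frame with columns `admission_id`, `unit_id`,
#'   `unit_type` (free-text NHSN-style label), `entry_date`, `exit_date`.
#' @param exposures Data frame with columns `admission_id`, `date`, `rank`
#'   (one of `"narrow"`, `"broad"`, `"extended"`, `"protected"`).
#'
#' @return An object of class `encounter_bundle`: a list of the three
#'   tibbles, structurally checked (schema, enum levels, foreign keys).
#'   Range and ordering invariants are reported, not thrown, by
#'   [validate_bundle()].
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
#' @examples
#' b <- encounter_bundle(
#'   admissions = data.frame(
#'     admission_id = "A1", patient_id = "P1", hospital_id = "H1",
#'     age = 40L, sex = "F", elixhauser = 2L,
#'     admit_date = as.Date("2017-01-01"), discharge_date = as.Date("2017-01-05")
#'   ),
#'   stays = data.frame(
#'     admission_id = "A1", unit_id = "H1-U1", unit_type = "adult medical ward",
#'     entry_date = as.Date("2017-01-01"), exit_date = as.Date("2017-01-05")
#'   ),
#'   exposures = data.frame(
#'     admission_id = "A1", date = as.Date("2017-01-02"), rank = "narrow"
#'   )
#' )
#' validate_bundle(b)
encounter_bundle <- function(admissions = NULL, stays = NULL, exposures = NULL) {
  admissions <- coerce_table(admissions, ADMISSIONS_SCHEMA, "admissions")
  stays <- coerce_table(stays, STAYS_SCHEMA, "unit_stays")
  exposures <- coerce_table(exposures, EXPOSURES_SCHEMA, "abx_exposures")

  bad_rank <- setdiff(unique(exposures$rank[!is.na(exposures$rank)]), ABX_RANKS)
  if (length(bad_rank) > 0) {
    stop(
      "abx_exposures: unknown rank(s) ", paste(sQuote(bad_rank), collapse = ", "),
      "; allowed levels are ", paste(ABX_RANKS, collapse = ", "),
      call. = FALSE
    )
  }
  bad_sex <- setdiff(unique(admissions$sex[!is.na(admissions$sex)]), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    stop(
      "admissions: unknown sex value(s) ", paste(sQuote(bad_sex), collapse = ", "),
      "; allowed are F, M or missing (NA)",
      call. = FALSE
    )
  }

  dangling_stays <- setdiff(stays$admission_id, admissions$admission_id)
  if (length(dangling_stays) > 0) {
    stop(
      "unit_stays reference admission_id(s) absent from admissions: ",
      paste(head(sort(dangling_stays), 5), collapse = ", "),
      call. = FALSE
    )
  }
  dangling_exp <- setdiff(exposures$admission_id, admissions$admission_id)
  if (length(dangling_exp) > 0) {
    stop(
      "abx_exposures reference admission_id(s) absent from admissions: ",
      paste(head(sort(dangling_exp), 5), collapse = ", "),
      call. = FALSE
    )
  }

  structure(
    list(admissions = admissions, stays = stays, exposures = exposures),
    class = "encounter_bundle"
  )
}

ADMISSIONS_SCHEMA <- list(
  admission_id = "character", patient_id = "character", hospital_id = "character",
  age = "integer", sex = "character", elixhauser = "integer",
  admit_date = "Date", discharge_date = "Date"
)
STAYS_SCHEMA <- list(
  admission_id = "character", unit_id = "character", unit_type = "character",
  entry_date = "Date", exit_date = "Date"
)
EXPOSURES_SCHEMA <- list(
  admission_id = "character", date = "Date", rank = "character"
)

coerce_table <- function(x, schema, name) {
  if (is.null(x)) {
    x <- tibble::as_tibble(lapply(schema, function(type) {
      switch(type,
        character = character(),
        integer = integer(),
        Date = as.Date(character())
      )
    }))
    return(x)
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(names(schema), names(x))
  if (length(missing_cols) > 0) {
    stop(
      name, ": missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- x[names(schema)]
  for (col in names(schema)) {
    x[[col]] <- switch(schema[[col]],
      character = as.character(x[[col]]),
      integer = as.integer(x[[col]]),
      Date = as.Date(x[[col]])
    )
  }
  x
}

#' @export
print.encounter_bundle <- function(x, ...) {
  cat(
    "<encounter_bundle> ",
    nrow(x$admissions), " admissions, ",
    nrow(x$stays), " unit stays, ",
    nrow(x$exposures), " abx exposures; ",
    dplyr::n_distinct(x$admissions$hospital_id), " hospital(s)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.encounter_bundle <- function(x, ...) {
  sprintf(
    "<encounter_bundle: %d admissions, %d stays, %d exposures>",
    nrow(x$admissions), nrow(x$stays), nrow(x$exposures)
  )
}

#' Read an encounter bundle from CSV files
#'
#' Reads the three fixed-schema CSV files (`admissions`, `unit_stays`,
#' `abx_exposures`) and returns a structurally checked [encounter_bundle()].
#' Dates must be ISO-8601 (`YYYY-MM-DD`). Missing sex is the literal token
#' `NA`. Schema errors (missing columns), unparseable dates (reported with
#' line numbers) and dangling foreign keys are errors; soft invariant
#' violations (e.g. an out-of-range age) are reported by
#' [validate_bundle()] instead.
#'
#' @param admissions_path,stays_path,exposures_path Paths to the CSV files.
#' @return An `encounter_bundle`.
#' @export
read_bundle <- function(admissions_path, stays_path, exposures_path) {
  admissions <- read_encounter_csv(admissions_path, ADMISSIONS_SCHEMA, "admissions")
  stays <- read_encounter_csv(stays_path, STAYS_SCHEMA, "unit_stays")
  exposures <- read_encounter_csv(exposures_path, EXPOSURES_SCHEMA, "abx_exposures")
  encounter_bundle(admissions, stays, exposures)
}

read_encounter_csv <- function(path, schema, name) {
  if (!file.exists(path)) {
    stop(name, ": file not found: ", path, call. = FALSE)
  }
  header <- names(readr::read_csv(
    path,
    n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols) > 0) {
    stop(
      name, ": missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  spec <- do.call(readr::cols, lapply(schema, function(type) {
    switch(type,
      character = readr::col_character(),
      integer = readr::col_integer(),
      Date = readr::col_date(format = "%Y-%m-%d")
    )
  }))
  x <- readr::read_csv(
    path,
    col_types = spec, na = "NA", progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    stop(
      name, ": ", nrow(probs), " unparseable value(s); first at line ",
      first$row, " column ", first$col, " (expected ", first$expected, ")",
      call. = FALSE
    )
  }
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Write an encounter bundle to CSV files
#'
#' Writes `admissions.csv`, `unit_stays.csv` and `abx_exposures.csv` into
#' `directory` (created if absent). Dates are ISO-8601; missing values
#' (including missing sex) are written as the literal token `NA`, so
#' `read_bundle()` on the output restores the bundle field-for-field.
#'
#' @param bundle An [encounter_bundle()].
#' @param directory Output directory.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  assert_bundle(bundle)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(
    admissions = file.path(directory, "admissions.csv"),
    unit_stays = file.path(directory, "unit_stays.csv"),
    abx_exposures = file.path(directory, "abx_exposures.csv")
  )
  readr::write_csv(bundle$admissions, paths[["admissions"]], na = "NA")
  readr::write_csv(bundle$stays, paths[["unit_stays"]], na = "NA")
  readr::write_csv(bundle$exposures, paths[["abx_exposures"]], na = "NA")
  invisible(paths)
}

#' Validate an encounter bundle
#'
#' Checks every type invariant and reports violations instead of throwing:
#' date ordering, age within 0-90, Elixhauser within 0-16, admission id
#' uniqueness, stay containment within the parent admission, duplicate stay
#' rows, and exposure dates within the parent stay. The report is
#' deterministic and ordered by table, record key, then rule.
#'
#' @param bundle An [encounter_bundle()].
#' @return A tibble with columns `table`, `record_key`, `rule`, `detail`;
#'   zero rows iff all invariants hold.
#' @export
validate_bundle <- function(bundle) {
  assert_bundle(bundle)
  adm <- bundle$admissions
  stays <- bundle$stays
  exp <- bundle$exposures

  v <- list()
  viol <- function(table, key, rule, detail) {
    tibble::tibble(table = table, record_key = key, rule = rule, detail = detail)
  }

  bad <- adm[!is.na(adm$admit_date) & !is.na(adm$discharge_date) &
    adm$admit_date > adm$discharge_date, ]
  v[[length(v) + 1]] <- viol(
    "admissions", bad$admission_id, "admit_before_discharge",
    sprintf("admit %s after discharge %s", bad$admit_date, bad$discharge_date)
  )

  bad <- adm[is.na(adm$age) | adm$age < 0L | adm$age > AGE_MAX, ]
  v[[length(v) + 1]] <- viol(
    "admissions", bad$admission_id, "age_in_range",
    sprintf("age %s out of [0,%d]", bad$age, AGE_MAX)
  )

  bad <- adm[is.na(adm$elixhauser) | adm$elixhauser < 0L | adm$elixhauser > ELIX_MAX, ]
  v[[length(v) + 1]] <- viol(
    "admissions", bad$admission_id, "elixhauser_in_range",
    sprintf("elixhauser %s out of [0,%d]", bad$elixhauser, ELIX_MAX)
  )

  dup <- adm$admission_id[duplicated(adm$admission_id)]
  v[[length(v) + 1]] <- viol(
    "admissions", unique(dup), "admission_id_unique", "duplicated admission_id"
  )

  bad <- stays[!is.na(stays$entry_date) & !is.na(stays$exit_date) &
    stays$entry_date > stays$exit_date, ]
  v[[length(v) + 1]] <- viol(
    "unit_stays", stay_key(bad), "entry_before_exit",
    sprintf("entry %s after exit %s", bad$entry_date, bad$exit_date)
  )

  joined <- dplyr::inner_join(
    stays, adm[, c("admission_id", "admit_date", "discharge_date")],
    by = "admission_id"
  )
  bad <- joined[joined$entry_date < joined$admit_date |
    joined$exit_date > joined$discharge_date, ]
  v[[length(v) + 1]] <- viol(
    "unit_stays", stay_key(bad), "stay_within_admission",
    sprintf(
      "stay [%s,%s] outside admission [%s,%s]",
      bad$entry_date, bad$exit_date, bad$admit_date, bad$discharge_date
    )
  )

  dup_stay <- stays[duplicated(stays[, c("admission_id", "unit_id", "entry_date")]), ]
  v[[length(v) + 1]] <- viol(
    "unit_stays", stay_key(dup_stay), "stay_not_duplicated",
    "duplicate (admission_id, unit_id, entry_date)"
  )

  jexp <- dplyr::inner_join(
    exp, adm[, c("admission_id", "admit_date", "discharge_date")],
    by = "admission_id"
  )
  bad <- jexp[jexp$date < jexp$admit_date | jexp$date > jexp$discharge_date, ]
  v[[length(v) + 1]] <- viol(
    "abx_exposures", paste(bad$admission_id, bad$date, sep = "/"),
    "exposure_within_admission",
    sprintf("exposure on %s outside [%s,%s]", bad$date, bad$admit_date, bad$discharge_date)
  )

  dplyr::arrange(dplyr::bind_rows(v), .data$table, .data$record_key, .data$rule)
}

stay_key <- function(stays) {
  if (nrow(stays) == 0) return(character())
  paste(stays$admission_id, stays$unit_id, stays$entry_date, sep = "/")
}
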