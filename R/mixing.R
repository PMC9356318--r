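#' Analysis scope for mixing matrices
#'
#' Restricts a mixing computation to a hospital, to particular units or
#' NHSN-style unit types, and/or to a time window. `NULL` fields are
#' unrestricted.
#'
#' @param hospital_id,unit_id,unit_type Character filters (any length).
#' @param window Length-2 date vector; defaults to the full span of the
#'   bundle's stays.
#' @return An object of class `mixing_scope`.
#' @export
mixing_scope <- function(hospital_id = NULL, unit_id = NULL, unit_type = NULL,
                         window = NULL) {
  structure(
    list(
      hospital_id = hospital_id, unit_id = unit_id, unit_type = unit_type,
      window = as_window(window)
    ),
    class = "mixing_scope"
  )
}

# Contact events within a scope, with a row id, plus the scoped admissions.
scoped_events <- function(bundle, scope = NULL) {
  assert_bundle(bundle)
  scope <- scope %||% mixing_scope()
  stopifnot(inherits(scope, "mixing_scope"))
  adm <- bundle$admissions
  stays <- bundle$stays
  if (!is.null(scope$hospital_id)) {
    adm <- dplyr::filter(adm, .data$hospital_id %in% scope$hospital_id)
    stays <- dplyr::semi_join(stays, adm, by = "admission_id")
  }
  if (!is.null(scope$unit_id)) {
    stays <- dplyr::filter(stays, .data$unit_id %in% scope$unit_id)
  }
  if (!is.null(scope$unit_type)) {
    stays <- dplyr::filter(stays, .data$unit_type %in% scope$unit_type)
  }
  window <- scope$window
  if (is.null(window)) {
    window <- if (nrow(stays) == 0) {
      as.Date(c("1970-01-01", "1970-01-01"))
    } else {
      c(min(stays$entry_date), max(stays$exit_date))
    }
  }
  events <- enumerate_contacts(daily_rosters(stays, window))
  events$event_id <- seq_len(nrow(events))
  list(
    events = events,
    admissions = dplyr::semi_join(adm, stays, by = "admission_id"),
    window = window
  )
}

new_mixing_matrix <- function(counts, axis_name, scope, excluded = 0L) {
  structure(
    list(
      axis = rownames(counts), axis_name = axis_name,
      counts = counts, normalized = NULL, normalization_flag = NULL,
      scope = scope, excluded_events = as.integer(excluded)
    ),
    class = "mixing_matrix"
  )
}

tabulate_ordered <- function(class_a, class_b, axis) {
  fa <- factor(class_a, levels = axis)
  fb <- factor(class_b, levels = axis)
  # symmetric double count: each contribution fills (i,j) and (j,i), so a
  # same-class contribution adds 2 to the diagonal and row sums read as
  # per-class contact exposure
  m <- unclass(table(c(fa, fb), c(fb, fa)))
  storage.mode(m) <- "double"
  dimnames(m) <- list(axis, axis)
  m
}

#' Mixing matrix from contact events and a classification
#'
#' Tallies contact events into a square class-by-class matrix under the
#' ordered-pair convention: an event between classes i and j increments
#' both cell (i, j) and cell (j, i), so a same-class event adds 2 to the
#' diagonal and row sums equal per-class contact exposure. Repeated
#' contacts across days add linearly.
#'
#' @param events Contact events ([enumerate_contacts()] output or the
#'   `events` element of a [build_network()] result).
#' @param classes Classification table. Single-valued: columns
#'   `admission_id`, `class`. Set-valued per day (antibiotic ranks):
#'   columns `admission_id`, `date`, `class`, several rows forming the
#'   day's class set; an event then contributes one ordered pair for every
#'   element of `classSet_a x classSet_b`, and events where either side
#'   has an empty set are excluded and tallied.
#' @param axis Ordered vector of all class labels.
#' @param axis_name Label for the axis (e.g. `"age"`).
#' @param policy `"lenient"` (default) excludes unclassifiable events and
#'   tallies them; `"strict"` raises an error naming the admission.
#' @param scope Optional [mixing_scope()] carried in the result.
#' @return An object of class `mixing_matrix` with elements `axis`,
#'   `counts`, `normalized` (filled by [normalize_mixing()]),
#'   `excluded_events`.
#' @export
mixing_matrix <- function(events, classes, axis, axis_name = "class",
                          policy = c("lenient", "strict"), scope = NULL) {
  policy <- match.arg(policy)
  axis <- as.character(axis)
  events <- tibble::as_tibble(events)
  if (!"event_id" %in% names(events)) events$event_id <- seq_len(nrow(events))
  classes <- tibble::as_tibble(classes)
  set_valued <- "date" %in% names(classes)

  if (nrow(events) == 0) {
    counts <- matrix(0, length(axis), length(axis), dimnames = list(axis, axis))
    return(new_mixing_matrix(counts, axis_name, scope))
  }

  if (!set_valued) {
    cls <- dplyr::select(classes, "admission_id", "class")
    ev <- events |>
      dplyr::left_join(cls, by = c(admission_a = "admission_id")) |>
      dplyr::rename(class_a = "class") |>
      dplyr::left_join(cls, by = c(admission_b = "admission_id")) |>
      dplyr::rename(class_b = "class")
    bad <- is.na(ev$class_a) | is.na(ev$class_b)
    if (policy == "strict" && any(bad)) {
      culprit <- ifelse(is.na(ev$class_a[bad]), ev$admission_a[bad], ev$admission_b[bad])
      stop("unclassifiable admission(s): ", paste(unique(culprit)[1:min(5, length(unique(culprit)))], collapse = ", "),
        call. = FALSE
      )
    }
    ev <- ev[!bad, ]
    counts <- tabulate_ordered(as.character(ev$class_a), as.character(ev$class_b), axis)
    return(new_mixing_matrix(counts, axis_name, scope, excluded = sum(bad)))
  }

  cls <- dplyr::select(classes, "admission_id", "date", "class")
  a_cls <- events |>
    dplyr::inner_join(cls,
      by = c(admission_a = "admission_id", date = "date"),
      relationship = "many-to-many"
    ) |>
    dplyr::select("event_id", class_a = "class")
  b_cls <- events |>
    dplyr::inner_join(cls,
      by = c(admission_b = "admission_id", date = "date"),
      relationship = "many-to-many"
    ) |>
    dplyr::select("event_id", class_b = "class")
  pairs <- dplyr::inner_join(a_cls, b_cls, by = "event_id", relationship = "many-to-many")
  classified <- unique(pairs$event_id)
  excluded <- nrow(events) - length(classified)
  if (policy == "strict" && excluded > 0) {
    miss <- events[!events$event_id %in% classified, ]
    stop(
      "events with unclassifiable side(s), e.g. admissions ",
      paste(unique(c(miss$admission_a, miss$admission_b))[1:3], collapse = ", "),
      call. = FALSE
    )
  }
  counts <- tabulate_ordered(as.character(pairs$class_a), as.character(pairs$class_b), axis)
  new_mixing_matrix(counts, axis_name, scope, excluded = excluded)
}

#' Age mixing matrix
#'
#' 91 x 91 matrix over ages 0..90 (top-coded): cell (i, j) counts contact
#' events between a patient of age i and a patient of age j within the
#' scope, under the ordered-pair convention of [mixing_matrix()]. Because
#' every co-located day contributes, a small group with long lengths of
#' stay can dominate the matrix out of proportion to its headcount.
#'
#' @param bundle An [encounter_bundle()].
#' @param scope Optional [mixing_scope()].
#' @return A `mixing_matrix`.
#' @export
#' @examples
#' b <- generate_bundle(archetype_config("elderly_small", 150, seed = 11))
#' m <- normalize_mixing(age_mixing(b))
#' m$normalized["90", "90"]
age_mixing <- function(bundle, scope = NULL) {
  sc <- scoped_events(bundle, scope)
  classes <- tibble::tibble(
    admission_id = sc$admissions$admission_id,
    class = as.character(sc$admissions$age)
  )
  mixing_matrix(sc$events, classes, axis = 0:AGE_MAX, axis_name = "age", scope = scope)
}

#' Elixhauser-score mixing matrix
#'
#' 17 x 17 matrix over comorbidity scores 0..16: cell (i, j) counts
#' contact events between a patient with score i and one with score j.
#'
#' @inheritParams age_mixing
#' @return A `mixing_matrix`.
#' @export
elixhauser_mixing <- function(bundle, scope = NULL) {
  sc <- scoped_events(bundle, scope)
  classes <- tibble::tibble(
    admission_id = sc$admissions$admission_id,
    class = as.character(sc$admissions$elixhauser)
  )
  mixing_matrix(sc$events, classes, axis = 0:ELIX_MAX, axis_name = "elixhauser", scope = scope)
}

#' Antibiotic-spectrum mixing matrix
#'
#' 4 x 4 matrix over spectrum ranks (narrow, broad, extended, protected).
#' Under `timing_policy = "per_day"` (default) an admission's class set on
#' the event's day is the set of ranks with an exposure record that day;
#' under `"whole_stay"` it is the ranks recorded at any point of the
#' admission. An event contributes one ordered pair for every element of
#' `classSet_a x classSet_b`, so a patient on two ranks the same day
#' spreads mass across cells — including the off-diagonal cells that
#' reveal combination empirical therapy. Events where either patient is
#' unexposed are excluded from the matrix and counted in
#' `excluded_events` (see [abx_none_ratio()] for their analysis).
#'
#' @inheritParams age_mixing
#' @param timing_policy `"per_day"` or `"whole_stay"`.
#' @param collapse `"cross"` (default: full cross-product of active ranks)
#'   or `"highest"` (each class set collapsed to its single broadest rank
#'   before tabulation).
#' @return A `mixing_matrix` with `excluded_events` filled.
#' @export
abx_mixing <- function(bundle, scope = NULL,
                       timing_policy = c("per_day", "whole_stay"),
                       collapse = c("cross", "highest")) {
  timing_policy <- match.arg(timing_policy)
  collapse <- match.arg(collapse)
  sc <- scoped_events(bundle, scope)
  exp <- dplyr::semi_join(bundle$exposures, sc$admissions, by = "admission_id")

  if (timing_policy == "per_day") {
    cls <- dplyr::distinct(exp, .data$admission_id, .data$date, class = .data$rank)
    if (collapse == "highest") {
      cls <- cls |>
        dplyr::group_by(.data$admission_id, .data$date) |>
        dplyr::summarise(class = highest_rank(.data$class), .groups = "drop")
    }
  } else {
    # whole-stay class sets apply to every event day of the admission
    sets <- dplyr::distinct(exp, .data$admission_id, class = .data$rank)
    if (collapse == "highest") {
      sets <- sets |>
        dplyr::group_by(.data$admission_id) |>
        dplyr::summarise(class = highest_rank(.data$class), .groups = "drop")
    }
    event_days <- dplyr::distinct(dplyr::bind_rows(
      dplyr::select(sc$events, admission_id = "admission_a", "date"),
      dplyr::select(sc$events, admission_id = "admission_b", "date")
    ))
    cls <- dplyr::inner_join(sets, event_days,
      by = "admission_id", relationship = "many-to-many"
    )
  }
  mixing_matrix(sc$events, cls, axis = ABX_RANKS, axis_name = "abx_rank", scope = scope)
}

highest_rank <- function(ranks) {
  ABX_RANKS[max(match(ranks, ABX_RANKS))]
}

#' Ratio of antibiotic-free to antibiotic-exposed contact pairs
#'
#' Classifies every contact event (per-day exposure) by whether neither
#' patient in the pair was receiving any antibiotic that day, versus one
#' or both receiving. The ratio `events_neither / events_any` summarizes
#' how much of a unit's mixing happens entirely outside antibiotic
#' pressure.
#'
#' @inheritParams age_mixing
#' @return One-row tibble: `events_neither`, `events_any`, `events_total`,
#'   `ratio` (`NA` with `no_exposed_flag = TRUE` when no pair involves an
#'   exposed patient).
#' @export
abx_none_ratio <- function(bundle, scope = NULL) {
  sc <- scoped_events(bundle, scope)
  events <- sc$events
  exp_days <- dplyr::distinct(
    dplyr::semi_join(bundle$exposures, sc$admissions, by = "admission_id"),
    .data$admission_id, .data$date
  )
  exp_days$exposed <- TRUE
  ev <- events |>
    dplyr::left_join(exp_days, by = c(admission_a = "admission_id", date = "date")) |>
    dplyr::rename(exp_a = "exposed") |>
    dplyr::left_join(exp_days, by = c(admission_b = "admission_id", date = "date")) |>
    dplyr::rename(exp_b = "exposed")
  neither <- sum(is.na(ev$exp_a) & is.na(ev$exp_b))
  total <- nrow(events)
  any_n <- total - neither
  tibble::tibble(
    events_neither = neither,
    events_any = any_n,
    events_total = total,
    ratio = if (any_n == 0) NA_real_ else neither / any_n,
    no_exposed_flag = any_n == 0
  )
}

#' Min-max normalize a mixing matrix
#'
#' Rescales the whole matrix cellwise as
#' `(counts - min(counts)) / (max(counts) - min(counts))`, so the least
#' populated cell maps to 0 and the most populated to 1 — comparable
#' across hospitals of different sizes. A constant matrix (the formula's
#' 0/0 case) is returned as all zeros with
#' `normalization_flag = "constant"`.
#'
#' @param matrix A `mixing_matrix`.
#' @return The same object with `normalized` (and possibly
#'   `normalization_flag`) filled.
#' @export
normalize_mixing <- function(matrix) {
  stopifnot(inherits(matrix, "mixing_matrix"))
  counts <- matrix$counts
  rng <- range(counts)
  if (rng[1] == rng[2]) {
    matrix$normalized <- counts * 0
    matrix$normalization_flag <- "constant"
  } else {
    matrix$normalized <- (counts - rng[1]) / (rng[2] - rng[1])
    matrix$normalization_flag <- NULL
  }
  matrix
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat(
    "<mixing_matrix> axis: ", x$axis_name, " (", length(x$axis), " levels), ",
    "total ordered count: ", sum(x$counts),
    if (x$excluded_events > 0) paste0(", excluded events: ", x$excluded_events) else "",
    if (!is.null(x$normalized)) ", normalized" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn mixing_matrix `tidy()` returns the matrix in long form:
#'   `class_a`, `class_b`, `count` and, when present, `normalized`.
#' @param x A `mixing_matrix`.
#' @export
tidy.mixing_matrix <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(long) <- c("class_a", "class_b", "count")
  long$class_a <- factor(long$class_a, levels = x$axis)
  long$class_b <- factor(long$class_b, levels = x$axis)
  if (!is.null(x$normalized)) {
    long$normalized <- as.vector(x$normalized)
  }
  dplyr::arrange(long, .data$class_a, .data$class_b)
}

#' Whole-stay antibiotic exposure patterns of admissions
#'
#' Admission-level (not event-level) tabulation of antibiotic exposure:
#' each admission in scope is counted once, either by the combination of
#' ranks recorded at any time during the stay (`by_rank_combination`,
#' labels like `"narrow+extended"`, unexposed admissions as `"none"`) or
#' by its single broadest rank (`by_highest_rank`). Percentages sum to
#' 100 over categories. This is the table that separates "two distinct
#' patient groups on different agents" from "the same patients on both
#' agents" behind a bimodal mixing matrix.
#'
#' @inheritParams age_mixing
#' @param grouping `"by_rank_combination"` or `"by_highest_rank"`.
#' @return Tibble `category`, `n`, `pct`, sorted by descending `n`.
#' @export
pattern_contingency <- function(bundle, scope = NULL,
                                grouping = c("by_rank_combination", "by_highest_rank")) {
  grouping <- match.arg(grouping)
  assert_bundle(bundle)
  scope <- scope %||% mixing_scope()
  sc_adm <- scoped_admissions(bundle, scope)
  if (nrow(sc_adm) == 0) {
    return(tibble::tibble(category = character(), n = integer(), pct = numeric()))
  }
  sets <- bundle$exposures |>
    dplyr::semi_join(sc_adm, by = "admission_id") |>
    dplyr::distinct(.data$admission_id, .data$rank)
  labels <- sets |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(
      category = if (grouping == "by_highest_rank") {
        highest_rank(.data$rank)
      } else {
        paste(ABX_RANKS[sort(match(unique(.data$rank), ABX_RANKS))], collapse = "+")
      },
      .groups = "drop"
    )
  sc_adm |>
    dplyr::left_join(labels, by = "admission_id") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "none")) |>
    dplyr::count(.data$category, sort = TRUE) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}

# Admissions with at least one stay matching the scope's filters.
scoped_admissions <- function(bundle, scope) {
  adm <- bundle$admissions
  stays <- bundle$stays
  if (!is.null(scope$hospital_id)) {
    adm <- dplyr::filter(adm, .data$hospital_id %in% scope$hospital_id)
  }
  stays <- dplyr::semi_join(stays, adm, by = "admission_id")
  if (!is.null(scope$unit_id)) {
    stays <- dplyr::filter(stays, .data$unit_id %in% scope$unit_id)
  }
  if (!is.null(scope$unit_type)) {
    stays <- dplyr::filter(stays, .data$unit_type %in% scope$unit_type)
  }
  if (!is.null(scope$window)) {
    stays <- dplyr::filter(
      stays,
      .data$entry_date <= scope$window[2], .data$exit_date >= scope$window[1]
    )
  }
  dplyr::semi_join(adm, stays, by = "admission_id")
}

#' Export a mixing matrix to CSV
#'
#' Writes the long form (`class_a,class_b,count[,normalized]`) and the
#' square form (classes as rows and columns) next to each other.
#'
#' @param matrix A `mixing_matrix`.
#' @param path Path of the long-form CSV; the square form goes to the same
#'   name with suffix `_square.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_mixing <- function(matrix, path) {
  stopifnot(inherits(matrix, "mixing_matrix"))
  long <- tidy(matrix)
  readr::write_csv(long, path, na = "NA")
  square_path <- sub("\\.csv$", "_square.csv", path)
  square <- tibble::as_tibble(matrix$counts, rownames = "class")
  readr::write_csv(square, square_path, na = "NA")
  invisible(c(long = path, square = square_path))
}
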