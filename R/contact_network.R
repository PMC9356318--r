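#' Daily unit rosters
#'
#' Expands unit stays into one row per (unit, day, admission): the roster
#' of who was present where on each calendar day. Stay intervals are
#' inclusive on both ends, so a transfer whose outgoing and incoming stays
#' share a boundary day puts the patient on both units' rosters that day.
#'
#' @param stays Tibble of unit stays (`admission_id`, `unit_id`,
#'   `unit_type`, `entry_date`, `exit_date`), e.g. `bundle$stays`.
#' @param window Length-2 date vector; stay days are clipped to it.
#' @return A tibble `unit_id`, `date`, `admission_id`, one row per
#'   presence, sorted.
#' @export
daily_rosters <- function(stays, window) {
  window <- as_window(window)
  stays <- tibble::as_tibble(stays)
  if (nrow(stays) == 0) {
    return(tibble::tibble(
      unit_id = character(), date = as.Date(character()), admission_id = character()
    ))
  }
  clipped <- stays |>
    dplyr::mutate(
      from = pmax(.data$entry_date, window[1]),
      to = pmin(.data$exit_date, window[2])
    ) |>
    dplyr::filter(.data$from <= .data$to)
  if (nrow(clipped) == 0) {
    return(tibble::tibble(
      unit_id = character(), date = as.Date(character()), admission_id = character()
    ))
  }
  clipped |>
    dplyr::mutate(date = purrr::map2(.data$from, .data$to, seq, by = "day")) |>
    tidyr::unnest("date") |>
    dplyr::distinct(.data$unit_id, .data$date, .data$admission_id) |>
    dplyr::arrange(.data$unit_id, .data$date, .data$admission_id)
}

#' Enumerate pairwise colocation contacts
#'
#' Two admissions recorded in the same unit on the same day are in contact
#' for that day; a roster cell with k members yields all k-choose-2
#' unordered pairs (4 co-located patients imply 6 pairwise contacts). A
#' pair co-located in two different units on the same day yields two
#' contact events, one per unit; repeated contacts on later days
#' accumulate linearly.
#'
#' @param rosters Output of [daily_rosters()].
#' @return A tibble of contact events: `admission_a`, `admission_b`
#'   (canonically ordered so `admission_a < admission_b`), `unit_id`,
#'   `date`.
#' @export
enumerate_contacts <- function(rosters) {
  rosters <- tibble::as_tibble(rosters)
  events <- dplyr::inner_join(
    rosters, rosters,
    by = c("unit_id", "date"), suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$admission_id_a < .data$admission_id_b)
  tibble::tibble(
    admission_a = events$admission_id_a,
    admission_b = events$admission_id_b,
    unit_id = events$unit_id,
    date = events$date
  )
}

#' Build a per-hospital contact network
#'
#' Assembles the undirected weighted colocation network of one hospital in
#' a time window: nodes are admissions with at least one roster day in the
#' window (isolates retained), and the weight of edge (a, b) is the number
#' of (unit, day) roster cells containing both — contact-days, with
#' repeated contacts adding linearly. Edges never cross hospitals.
#'
#' @param bundle An [encounter_bundle()].
#' @param hospital_id Hospital to build the network for.
#' @param window Length-2 date vector.
#' @param dedupe_same_day If `TRUE`, a pair co-located in two different
#'   units on the same day counts once instead of twice (default `FALSE`:
#'   one event per unit per day).
#' @return An object of class `contact_network`: a list with `nodes`
#'   (admission attributes), `edges` (`admission_a`, `admission_b`,
#'   `weight`), `events` (the contact events), `window`, `hospital_id`.
#' @export
#' @examples
#' b <- generate_bundle(archetype_config("elderly_small", 100, seed = 1))
#' net <- build_network(b, "H-elderly_small", as.Date(c("2017-01-01", "2017-01-30")))
#' glance(net)
build_network <- function(bundle, hospital_id, window, dedupe_same_day = FALSE) {
  assert_bundle(bundle)
  window <- as_window(window)
  if (!hospital_id %in% bundle$admissions$hospital_id) {
    stop("unknown hospital_id: ", hospital_id, call. = FALSE)
  }
  adm <- dplyr::filter(bundle$admissions, .data$hospital_id == !!hospital_id)
  stays <- dplyr::semi_join(bundle$stays, adm, by = "admission_id")
  rosters <- daily_rosters(stays, window)
  events <- enumerate_contacts(rosters)
  if (dedupe_same_day) {
    events <- dplyr::distinct(events, .data$admission_a, .data$admission_b, .data$date,
      .keep_all = TRUE
    )
  }
  edges <- events |>
    dplyr::count(.data$admission_a, .data$admission_b, name = "weight") |>
    dplyr::arrange(.data$admission_a, .data$admission_b)
  nodes <- adm |>
    dplyr::semi_join(dplyr::distinct(rosters, .data$admission_id), by = "admission_id") |>
    dplyr::arrange(.data$admission_id)
  structure(
    list(
      nodes = nodes, edges = edges, events = events,
      window = window, hospital_id = hospital_id
    ),
    class = "contact_network"
  )
}

#' @export
print.contact_network <- function(x, ...) {
  cat(
    "<contact_network> ", x$hospital_id, ": ",
    nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
    sum(x$edges$weight), " contact-days), ",
    format(x$window[1]), " to ", format(x$window[2]), "\n",
    sep = ""
  )
  invisible(x)
}

#' Convert a contact network to an igraph graph
#'
#' @param network A [build_network()] result.
#' @param weighted Keep contact-day weights as the `weight` edge attribute.
#' @return An undirected `igraph` graph with one vertex per admission.
#' @export
as_igraph <- function(network, weighted = TRUE) {
  stopifnot(inherits(network, "contact_network"))
  edges <- network$edges
  if (!weighted) edges$weight <- NULL
  igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = network$nodes$admission_id)
  )
}

#' @describeIn build_network `tidy()` returns the weighted edge list.
#' @param x,object A `contact_network`.
#' @param ... Unused.
#' @export
tidy.contact_network <- function(x, ...) {
  x$edges
}

#' @describeIn build_network `glance()` returns a one-row tibble of node,
#'   edge and contact-day counts.
#' @export
glance.contact_network <- function(x, ...) {
  tibble::tibble(
    hospital_id = x$hospital_id,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    total_contact_days = sum(x$edges$weight),
    window_start = x$window[1],
    window_end = x$window[2]
  )
}

#' Single- vs multi-ward admissions and their edges
#'
#' Quantifies how much of the contact network is carried by admissions that
#' moved between units: the percentage of admissions with stays in two or
#' more distinct units, and the percentage of edges with at least one
#' multi-unit endpoint.
#'
#' @param network A [build_network()] result.
#' @param stays The unit-stay tibble the network was built from.
#' @return One-row tibble: `pct_multiunit_admissions`,
#'   `pct_edges_touching_multiunit`, `n_admissions`, `n_edges`,
#'   `no_edges_flag` (`TRUE` when the edge percentage is reported as 0
#'   because the network has no edges at all).
#' @export
multiward_summary <- function(network, stays) {
  stopifnot(inherits(network, "contact_network"))
  stays <- dplyr::semi_join(tibble::as_tibble(stays), network$nodes, by = "admission_id")
  multi_ids <- stays |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(multi = dplyr::n_distinct(.data$unit_id) >= 2L) |>
    dplyr::filter(.data$multi) |>
    dplyr::pull("admission_id")
  n_adm <- nrow(network$nodes)
  n_edges <- nrow(network$edges)
  pct_adm <- if (n_adm == 0) 0 else 100 * length(multi_ids) / n_adm
  no_edges <- n_edges == 0
  pct_edges <- if (no_edges) {
    0
  } else {
    touching <- network$edges$admission_a %in% multi_ids |
      network$edges$admission_b %in% multi_ids
    100 * mean(touching)
  }
  tibble::tibble(
    pct_multiunit_admissions = pct_adm,
    pct_edges_touching_multiunit = pct_edges,
    n_admissions = n_adm,
    n_edges = n_edges,
    no_edges_flag = no_edges
  )
}

#' Export a contact network to CSV files
#'
#' Writes the weighted edge list (`edges.csv`) and the node attribute table
#' (`nodes.csv`) into `directory`.
#'
#' @param network A [build_network()] result.
#' @param directory Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_network <- function(network, directory) {
  stopifnot(inherits(network, "contact_network"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(
    edges = file.path(directory, "edges.csv"),
    nodes = file.path(directory, "nodes.csv")
  )
  readr::write_csv(network$edges, paths[["edges"]], na = "NA")
  readr::write_csv(network$nodes, paths[["nodes"]], na = "NA")
  invisible(paths)
}
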