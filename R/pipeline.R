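#' Pipeline run configuration
#'
#' Describes one end-to-end run: where the encounter data come from
#' (exactly one of a synthetic archetype or a directory of CSVs), which
#' hospitals and window to analyze, which mixing axes to compute, and
#' where outputs go. A single seed fans out deterministically to every
#' stochastic stage, so one number reproduces a whole run.
#'
#' @param synthetic `list(archetype =, n_admissions =)` to simulate input,
#'   or `NULL`.
#' @param csv_dir Directory containing `admissions.csv`, `unit_stays.csv`,
#'   `abx_exposures.csv`, or `NULL`. Exactly one of `synthetic`/`csv_dir`
#'   must be given.
#' @param window Length-2 date vector; default: the full span of the
#'   bundle's stays.
#' @param hospitals Hospital ids to analyze; default: all in the bundle.
#' @param axes Subset of `c("age", "elixhauser", "abx")`.
#' @param timing_policy Antibiotic classification policy, `"per_day"` or
#'   `"whole_stay"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param log_level `"info"` (stage messages) or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, csv_dir = NULL, window = NULL,
                       hospitals = NULL, axes = c("age", "elixhauser", "abx"),
                       timing_policy = c("per_day", "whole_stay"),
                       out_dir, seed = 1L, log_level = c("info", "quiet")) {
  if (is.null(synthetic) == is.null(csv_dir)) {
    stop("exactly one input mode: give `synthetic` or `csv_dir`", call. = FALSE)
  }
  if (!is.null(synthetic)) {
    stopifnot(is.list(synthetic), !is.null(synthetic$archetype), !is.null(synthetic$n_admissions))
  }
  axes <- match.arg(axes, c("age", "elixhauser", "abx"), several.ok = TRUE)
  structure(
    list(
      synthetic = synthetic, csv_dir = csv_dir, window = as_window(window),
      hospitals = hospitals, axes = axes,
      timing_policy = match.arg(timing_policy),
      out_dir = out_dir, seed = as.integer(seed),
      log_level = match.arg(log_level)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments, e.g.:
#' ```yaml
#' synthetic: {archetype: elderly_small, n_admissions: 200}
#' axes: [age, abx]
#' out_dir: results
#' seed: 7
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    synthetic = y$synthetic,
    csv_dir = y$csv_dir,
    window = if (!is.null(y$window)) as.Date(unlist(y$window)),
    hospitals = y$hospitals,
    axes = y$axes %||% c("age", "elixhauser", "abx"),
    timing_policy = y$timing_policy %||% "per_day",
    out_dir = y$out_dir %||% stop("config must set out_dir", call. = FALSE),
    seed = y$seed %||% 1L,
    log_level = y$log_level %||% "info"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> contact networks -> network metrics
#' -> mixing matrices -> antibiotic summaries into one reproducible run.
#' All outputs are plain CSV (plus a JSON manifest); a stage failure
#' aborts with the stage name.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return An object of class `run_manifest`: output paths, the config
#'   echo, seed, package version, and per-stage counts (admissions read,
#'   contact events enumerated, edges built). Also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$log_level == "info") message("[wardmix] ", ...)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- list()

  stage <- "input"
  manifest <- tryCatch(
    {
      if (!is.null(config$synthetic)) {
        say("simulate: archetype ", config$synthetic$archetype, ", n = ", config$synthetic$n_admissions)
        hcfg <- archetype_config(
          config$synthetic$archetype,
          config$synthetic$n_admissions,
          seed = config$seed
        )
        bundle <- generate_bundle(hcfg)
        paths$bundle <- write_bundle(bundle, file.path(out, "bundle"))
      } else {
        say("read: ", config$csv_dir)
        bundle <- read_bundle(
          file.path(config$csv_dir, "admissions.csv"),
          file.path(config$csv_dir, "unit_stays.csv"),
          file.path(config$csv_dir, "abx_exposures.csv")
        )
      }
      say("admissions read: ", nrow(bundle$admissions))

      hospitals <- config$hospitals %||% sort(unique(bundle$admissions$hospital_id))
      window <- config$window %||%
        c(min(bundle$stays$entry_date), max(bundle$stays$exit_date))

      stage <- "network"
      metrics_rows <- list()
      multiward_rows <- list()
      none_rows <- list()
      counts <- list(admissions = nrow(bundle$admissions), events = 0L, edges = 0L)
      for (h in hospitals) {
        net <- build_network(bundle, h, window)
        say(
          "network ", h, ": ", nrow(net$nodes), " nodes, ", nrow(net$edges),
          " edges, ", nrow(net$events), " events"
        )
        counts$events <- counts$events + nrow(net$events)
        counts$edges <- counts$edges + nrow(net$edges)
        paths[[paste0("network_", h)]] <-
          write_network(net, file.path(out, paste0("network_", h)))

        stage <- "metrics"
        metrics_rows[[h]] <- compute_metrics(net)
        multiward_rows[[h]] <- dplyr::bind_cols(
          tibble::tibble(hospital_id = h),
          multiward_summary(net, bundle$stays)
        )

        stage <- "mixing"
        for (axis in config$axes) {
          scope <- mixing_scope(hospital_id = h, window = window)
          m <- switch(axis,
            age = age_mixing(bundle, scope),
            elixhauser = elixhauser_mixing(bundle, scope),
            abx = abx_mixing(bundle, scope, timing_policy = config$timing_policy)
          )
          m <- normalize_mixing(m)
          p <- file.path(out, sprintf("mixing_%s_%s.csv", h, axis))
          write_mixing(m, p)
          paths[[sprintf("mixing_%s_%s", h, axis)]] <- p
          if (axis == "abx") {
            none_rows[[h]] <- dplyr::bind_cols(
              tibble::tibble(hospital_id = h),
              abx_none_ratio(bundle, scope)
            )
          }
        }
        stage <- "network"
      }

      stage <- "write"
      metrics <- dplyr::bind_rows(metrics_rows)
      paths$metrics <- file.path(out, "metrics.csv")
      readr::write_csv(metrics, paths$metrics, na = "NA")
      paths$multiward <- file.path(out, "multiward.csv")
      readr::write_csv(dplyr::bind_rows(multiward_rows), paths$multiward, na = "NA")
      if (length(none_rows) > 0) {
        paths$abx_none_ratio <- file.path(out, "abx_none_ratio.csv")
        readr::write_csv(dplyr::bind_rows(none_rows), paths$abx_none_ratio, na = "NA")
      }

      structure(
        list(
          paths = paths,
          config = config,
          seed = config$seed,
          package_version = as.character(utils::packageVersion("wardmix")),
          counts = counts
        ),
        class = "run_manifest"
      )
    },
    error = function(e) {
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE)
    }
  )

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(
      paths = lapply(manifest$paths, unname),
      seed = manifest$seed,
      package_version = manifest$package_version,
      counts = manifest$counts,
      axes = config$axes,
      timing_policy = config$timing_policy,
      input_mode = if (is.null(config$synthetic)) "csv" else "synthetic",
      synthetic = config$synthetic,
      csv_dir = config$csv_dir
    ),
    manifest_path,
    auto_unbox = TRUE, null = "null"
  )
  manifest$paths$manifest <- manifest_path
  say("done: ", length(manifest$paths), " artifact(s) in ", out)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(
    "<run_manifest> seed ", x$seed, ", wardmix ", x$package_version, "; ",
    x$counts$admissions, " admissions, ", x$counts$events, " contact events, ",
    x$counts$edges, " edges; ", length(x$paths), " artifact(s)\n",
    sep = ""
  )
  invisible(x)
}
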