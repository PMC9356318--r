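#' Unit generative profile
#'
#' Describes how one hospital unit generates synthetic admissions: its mean
#' daily census (which, scaled by turnover, sets how many admissions it
#' receives), a log-normal length-of-stay distribution, a truncated-normal
#' mixture over patient age, a zero-inflated Poisson model for the
#' Elixhauser score, independent per-rank daily antibiotic exposure
#' probabilities, and the probability of transferring to another unit at
#' the end of a stay.
#'
#' Age-mixture components may carry a length-of-stay multiplier
#' (`los_mult`), which is how a long-LOS elderly subgroup is expressed:
#' a component at age 90 with `los_mult = 10` stays ten times longer than
#' the modal patient and therefore dominates contact (not headcount)
#' statistics.
#'
#' @param unit_type NHSN-style unit label, e.g. `"adult medical ward"`.
#' @param bed_pressure Mean daily census (positive real).
#' @param los Length-of-stay spec: `list(dist = "lognormal", meanlog, sdlog)`;
#'   sampled stays are rounded up to whole days (minimum 1).
#' @param age_model Data frame with columns `weight`, `mean`, `sd` and
#'   optionally `los_mult` (default 1): a normal mixture truncated and
#'   top-coded to ages 0-90. Weights must sum to 1.
#' @param elix_model `list(p_zero, lambda)`: with probability `p_zero` the
#'   score is 0, otherwise Poisson(`lambda`) capped at 16.
#' @param abx_model Named numeric vector of daily exposure probabilities for
#'   the four spectrum ranks (`narrow`, `broad`, `extended`, `protected`),
#'   sampled independently per rank per day, so a patient can carry several
#'   ranks the same day.
#' @param transfer_out_prob Probability that a patient moves to another unit
#'   when a stay ends (given the window has room).
#' @return An object of class `unit_profile`.
#' @export
unit_profile <- function(unit_type,
                         bed_pressure,
                         los = list(dist = "lognormal", meanlog = log(3), sdlog = 0.6),
                         age_model = data.frame(weight = 1, mean = 50, sd = 15),
                         elix_model = list(p_zero = 0.5, lambda = 2),
                         abx_model = c(narrow = 0.1, broad = 0.1, extended = 0.05, protected = 0.005),
                         transfer_out_prob = 0.1) {
  stopifnot(is.character(unit_type), length(unit_type) == 1)
  if (!is.numeric(bed_pressure) || bed_pressure <= 0) {
    stop("`bed_pressure` must be a positive real", call. = FALSE)
  }
  if (!identical(los$dist, "lognormal")) {
    stop("only `lognormal` length-of-stay distributions are supported", call. = FALSE)
  }
  if (!is.finite(los$meanlog) || !is.finite(los$sdlog) || los$sdlog < 0) {
    stop("`los` parameters must be finite with sdlog >= 0", call. = FALSE)
  }
  age_model <- tibble::as_tibble(age_model)
  if (!"los_mult" %in% names(age_model)) age_model$los_mult <- 1
  stopifnot(all(c("weight", "mean", "sd") %in% names(age_model)))
  if (abs(sum(age_model$weight) - 1) > 1e-8) {
    stop("age mixture weights must sum to 1", call. = FALSE)
  }
  if (any(age_model$sd < 0) || any(age_model$los_mult <= 0)) {
    stop("age mixture sd must be >= 0 and los_mult > 0", call. = FALSE)
  }
  if (!all(ABX_RANKS %in% names(abx_model))) {
    stop("`abx_model` must name all four ranks: ", paste(ABX_RANKS, collapse = ", "),
      call. = FALSE
    )
  }
  abx_model <- abx_model[ABX_RANKS]
  if (any(abx_model < 0 | abx_model > 1)) {
    stop("`abx_model` probabilities must lie in [0,1]", call. = FALSE)
  }
  p0 <- elix_model$p_zero
  if (is.null(p0) || p0 < 0 || p0 > 1 || is.null(elix_model$lambda) || elix_model$lambda < 0) {
    stop("`elix_model` needs p_zero in [0,1] and lambda >= 0", call. = FALSE)
  }
  if (transfer_out_prob < 0 || transfer_out_prob > 1) {
    stop("`transfer_out_prob` must lie in [0,1]", call. = FALSE)
  }
  structure(
    list(
      unit_type = unit_type, bed_pressure = bed_pressure, los = los,
      age_model = age_model, elix_model = elix_model, abx_model = abx_model,
      transfer_out_prob = transfer_out_prob
    ),
    class = "unit_profile"
  )
}

#' Hospital generator configuration
#'
#' Bundles the unit profiles, target admission count, simulation window and
#' seed for one synthetic hospital.
#'
#' @param hospital_id Hospital identifier string.
#' @param unit_profiles List of [unit_profile()] objects (one unit each).
#' @param n_admissions Total admissions to generate (>= 0).
#' @param window Length-2 date vector `c(start, end)`, inclusive.
#' @param seed Integer seed; one pseudo-random stream per hospital, split
#'   deterministically per unit, so edits to one unit's profile leave the
#'   other units' draws untouched.
#' @return An object of class `hospital_config`.
#' @export
hospital_config <- function(hospital_id, unit_profiles, n_admissions, window, seed) {
  stopifnot(length(unit_profiles) >= 1)
  if (!all(vapply(unit_profiles, inherits, logical(1), "unit_profile"))) {
    stop("`unit_profiles` must be a list of unit_profile objects", call. = FALSE)
  }
  if (n_admissions < 0) stop("`n_admissions` must be >= 0", call. = FALSE)
  window <- as_window(window)
  structure(
    list(
      hospital_id = hospital_id,
      unit_profiles = unit_profiles,
      n_units = length(unit_profiles),
      n_admissions = as.integer(n_admissions),
      window = window,
      seed = as.integer(seed)
    ),
    class = "hospital_config"
  )
}

#' @export
print.hospital_config <- function(x, ...) {
  cat(
    "<hospital_config> ", x$hospital_id, ": ", x$n_units, " units, ",
    x$n_admissions, " admissions, ",
    format(x$window[1]), " to ", format(x$window[2]),
    ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

mix_age <- function(weight, mean, sd, los_mult = rep(1, length(weight))) {
  tibble::tibble(weight = weight, mean = mean, sd = sd, los_mult = los_mult)
}

FLAT_ADULT_AGE <- mix_age(c(1, 1, 1) / 3, c(30, 50, 70), c(12, 12, 10))

#' Archetype hospital configurations
#'
#' Fully specified [hospital_config()]s for four qualitative hospital
#' archetypes seen in multi-hospital encounter data:
#'
#' * `uniform_adult` — community hospital with roughly uniform mixing across
#'   adult ages.
#' * `young_skew` — hospital serving primarily younger adults (obstetric and
#'   behavioral-health heavy).
#' * `elderly_small` — small hospital (4 units) dominated by elderly
#'   patients, including a small age-90 subgroup with 10x length of stay
#'   that dominates contact weight despite its small headcount.
#' * `academic_pediatric` — large academic center with pediatric units,
#'   including a neonatal critical care unit with high daily narrow- and
#'   extended-spectrum exposure probabilities (combination empirical
#'   therapy) and a pediatric ward prescribing narrow, broad and extended
#'   agents.
#'
#' All parameter values are plausibility choices for these qualitative
#' patterns, not estimates from any particular hospital system.
#'
#' @param name One of `"uniform_adult"`, `"young_skew"`, `"elderly_small"`,
#'   `"academic_pediatric"`.
#' @param n_admissions Total admissions to generate.
#' @param seed Integer seed.
#' @return A [hospital_config()]; `generate_bundle()` on it is fully
#'   reproducible from (`name`, `n_admissions`, `seed`).
#' @export
#' @examples
#' cfg <- archetype_config("elderly_small", 200, seed = 7)
#' b <- generate_bundle(cfg)
#' summarize_bundle(b)
archetype_config <- function(name, n_admissions, seed) {
  window <- as.Date(c("2017-01-01", "2017-01-30"))
  profiles <- switch(name,
    uniform_adult = list(
      unit_profile("emergency department",
        bed_pressure = 20,
        los = list(dist = "lognormal", meanlog = log(1), sdlog = 0.3),
        age_model = FLAT_ADULT_AGE,
        elix_model = list(p_zero = 0.6, lambda = 1.5),
        abx_model = c(narrow = 0.05, broad = 0.08, extended = 0.05, protected = 0.002),
        transfer_out_prob = 0.25
      ),
      unit_profile("adult medical ward",
        bed_pressure = 25,
        los = list(dist = "lognormal", meanlog = log(4), sdlog = 0.6),
        age_model = FLAT_ADULT_AGE,
        elix_model = list(p_zero = 0.45, lambda = 2),
        abx_model = c(narrow = 0.15, broad = 0.12, extended = 0.06, protected = 0.005),
        transfer_out_prob = 0.1
      ),
      unit_profile("adult medical ward",
        bed_pressure = 25,
        los = list(dist = "lognormal", meanlog = log(4), sdlog = 0.6),
        age_model = FLAT_ADULT_AGE,
        elix_model = list(p_zero = 0.45, lambda = 2),
        abx_model = c(narrow = 0.15, broad = 0.12, extended = 0.06, protected = 0.005),
        transfer_out_prob = 0.1
      ),
      unit_profile("adult surgical ward",
        bed_pressure = 20,
        los = list(dist = "lognormal", meanlog = log(3), sdlog = 0.5),
        age_model = FLAT_ADULT_AGE,
        elix_model = list(p_zero = 0.5, lambda = 2),
        abx_model = c(narrow = 0.25, broad = 0.08, extended = 0.04, protected = 0.003),
        transfer_out_prob = 0.1
      ),
      unit_profile("telemetry ward",
        bed_pressure = 15,
        los = list(dist = "lognormal", meanlog = log(3), sdlog = 0.5),
        age_model = mix_age(c(0.4, 0.6), c(55, 72), c(10, 8)),
        elix_model = list(p_zero = 0.35, lambda = 3),
        abx_model = c(narrow = 0.05, broad = 0.2, extended = 0.15, protected = 0.005),
        transfer_out_prob = 0.15
      ),
      unit_profile("adult critical care",
        bed_pressure = 10,
        los = list(dist = "lognormal", meanlog = log(5), sdlog = 0.7),
        age_model = mix_age(c(0.3, 0.7), c(50, 68), c(12, 10)),
        elix_model = list(p_zero = 0.2, lambda = 4),
        abx_model = c(narrow = 0.05, broad = 0.1, extended = 0.35, protected = 0.02),
        transfer_out_prob = 0.5
      )
    ),
    young_skew = list(
      unit_profile("emergency department",
        bed_pressure = 15,
        los = list(dist = "lognormal", meanlog = log(1), sdlog = 0.3),
        age_model = mix_age(c(0.7, 0.3), c(30, 45), c(7, 10)),
        elix_model = list(p_zero = 0.75, lambda = 1),
        abx_model = c(narrow = 0.05, broad = 0.08, extended = 0.04, protected = 0.002),
        transfer_out_prob = 0.2
      ),
      unit_profile("labor and delivery ward",
        bed_pressure = 12,
        los = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
        age_model = mix_age(1, 28, 5),
        elix_model = list(p_zero = 0.9, lambda = 0.5),
        abx_model = c(narrow = 0.3, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.5
      ),
      unit_profile("postpartum ward",
        bed_pressure = 12,
        los = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
        age_model = mix_age(1, 28, 5),
        elix_model = list(p_zero = 0.9, lambda = 0.5),
        abx_model = c(narrow = 0.15, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.02
      ),
      unit_profile("behavioral health ward",
        bed_pressure = 15,
        los = list(dist = "lognormal", meanlog = log(6), sdlog = 0.5),
        age_model = mix_age(c(0.6, 0.4), c(28, 40), c(6, 10)),
        elix_model = list(p_zero = 0.7, lambda = 1),
        abx_model = c(narrow = 0.02, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.02
      ),
      unit_profile("adult medical ward",
        bed_pressure = 18,
        los = list(dist = "lognormal", meanlog = log(3.5), sdlog = 0.5),
        age_model = mix_age(c(0.6, 0.4), c(32, 50), c(8, 12)),
        elix_model = list(p_zero = 0.55, lambda = 1.5),
        abx_model = c(narrow = 0.12, broad = 0.1, extended = 0.05, protected = 0.004),
        transfer_out_prob = 0.08
      )
    ),
    elderly_small = list(
      unit_profile("emergency department",
        bed_pressure = 8,
        los = list(dist = "lognormal", meanlog = log(1), sdlog = 0.3),
        age_model = mix_age(c(0.8, 0.2), c(70, 78), c(8, 6)),
        elix_model = list(p_zero = 0.4, lambda = 2),
        abx_model = c(narrow = 0.05, broad = 0.1, extended = 0.06, protected = 0.003),
        transfer_out_prob = 0.3
      ),
      unit_profile("adult medical ward",
        bed_pressure = 32,
        los = list(dist = "lognormal", meanlog = log(3), sdlog = 0.5),
        age_model = mix_age(c(0.92, 0.08), c(72, 92), c(6, 2), los_mult = c(1, 10)),
        elix_model = list(p_zero = 0.35, lambda = 3),
        abx_model = c(narrow = 0.1, broad = 0.15, extended = 0.1, protected = 0.005),
        transfer_out_prob = 0.08
      ),
      unit_profile("adult critical care",
        bed_pressure = 6,
        los = list(dist = "lognormal", meanlog = log(4), sdlog = 0.6),
        age_model = mix_age(c(0.9, 0.1), c(74, 85), c(7, 4)),
        elix_model = list(p_zero = 0.15, lambda = 5),
        abx_model = c(narrow = 0.05, broad = 0.1, extended = 0.3, protected = 0.02),
        transfer_out_prob = 0.4
      )
    ),
    academic_pediatric = list(
      unit_profile("emergency department",
        bed_pressure = 25,
        los = list(dist = "lognormal", meanlog = log(1), sdlog = 0.3),
        age_model = mix_age(c(0.3, 0.4, 0.3), c(8, 35, 65), c(6, 12, 12)),
        elix_model = list(p_zero = 0.6, lambda = 1.5),
        abx_model = c(narrow = 0.05, broad = 0.12, extended = 0.12, protected = 0.003),
        transfer_out_prob = 0.25
      ),
      unit_profile("pediatric medical surgical ward",
        bed_pressure = 15,
        los = list(dist = "lognormal", meanlog = log(3), sdlog = 0.5),
        age_model = mix_age(c(0.5, 0.5), c(1, 9), c(2, 5)),
        elix_model = list(p_zero = 0.85, lambda = 1),
        abx_model = c(narrow = 0.25, broad = 0.25, extended = 0.25, protected = 0.01),
        transfer_out_prob = 0.1
      ),
      unit_profile("pediatric critical care",
        bed_pressure = 8,
        los = list(dist = "lognormal", meanlog = log(5), sdlog = 0.6),
        age_model = mix_age(c(0.5, 0.5), c(2, 10), c(3, 5)),
        elix_model = list(p_zero = 0.5, lambda = 3),
        abx_model = c(narrow = 0.2, broad = 0.25, extended = 0.3, protected = 0.05),
        transfer_out_prob = 0.3
      ),
      unit_profile("neonatal critical care",
        bed_pressure = 10,
        los = list(dist = "lognormal", meanlog = log(10), sdlog = 0.6),
        age_model = mix_age(1, 0, 0.5),
        elix_model = list(p_zero = 0.95, lambda = 0.5),
        abx_model = c(narrow = 0.5, broad = 0.02, extended = 0.5, protected = 0.005),
        transfer_out_prob = 0.1
      ),
      unit_profile("well baby nursery",
        bed_pressure = 8,
        los = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
        age_model = mix_age(1, 0, 0.5),
        elix_model = list(p_zero = 0.98, lambda = 0.2),
        abx_model = c(narrow = 0.3, broad = 0.01, extended = 0.3, protected = 0.002),
        transfer_out_prob = 0.05
      ),
      unit_profile("labor and delivery ward",
        bed_pressure = 10,
        los = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
        age_model = mix_age(1, 28, 5),
        elix_model = list(p_zero = 0.9, lambda = 0.5),
        abx_model = c(narrow = 0.3, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.4
      ),
      unit_profile("postpartum ward",
        bed_pressure = 10,
        los = list(dist = "lognormal", meanlog = log(2), sdlog = 0.3),
        age_model = mix_age(1, 28, 5),
        elix_model = list(p_zero = 0.9, lambda = 0.5),
        abx_model = c(narrow = 0.15, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.02
      ),
      unit_profile("adult medical ward",
        bed_pressure = 20,
        los = list(dist = "lognormal", meanlog = log(4), sdlog = 0.6),
        age_model = FLAT_ADULT_AGE,
        elix_model = list(p_zero = 0.45, lambda = 2),
        abx_model = c(narrow = 0.15, broad = 0.12, extended = 0.06, protected = 0.005),
        transfer_out_prob = 0.1
      ),
      unit_profile("adult critical care",
        bed_pressure = 10,
        los = list(dist = "lognormal", meanlog = log(5), sdlog = 0.7),
        age_model = mix_age(c(0.3, 0.7), c(50, 68), c(12, 10)),
        elix_model = list(p_zero = 0.2, lambda = 4),
        abx_model = c(narrow = 0.05, broad = 0.1, extended = 0.35, protected = 0.02),
        transfer_out_prob = 0.5
      ),
      unit_profile("behavioral health ward",
        bed_pressure = 12,
        los = list(dist = "lognormal", meanlog = log(6), sdlog = 0.5),
        age_model = mix_age(c(0.6, 0.4), c(28, 45), c(8, 12)),
        elix_model = list(p_zero = 0.7, lambda = 1),
        abx_model = c(narrow = 0.02, broad = 0.02, extended = 0.01, protected = 0.001),
        transfer_out_prob = 0.02
      )
    ),
    stop(
      "unknown archetype ", sQuote(name), "; options are: ",
      "uniform_adult, young_skew, elderly_small, academic_pediatric",
      call. = FALSE
    )
  )
  hospital_config(
    hospital_id = paste0("H-", name),
    unit_profiles = profiles,
    n_admissions = n_admissions,
    window = window,
    seed = seed
  )
}

#' Generate a synthetic encounter bundle
#'
#' Simulates admissions for one hospital according to its
#' [hospital_config()]. Admissions are allocated to units in proportion to
#' unit turnover (census divided by mean length of stay), arrive uniformly
#' over the window (a homogeneous Poisson process conditioned on the
#' total), and draw age, sex, Elixhauser score and a length of stay from
#' the unit's profile. At the end of each stay the patient transfers to
#' another unit with the unit's `transfer_out_prob`, producing multi-unit
#' chains whose consecutive stays share the boundary day; stays are
#' truncated at the window end. Antibiotic exposure is sampled
#' independently per rank per hospitalized day with the probabilities of
#' the unit occupied that day.
#'
#' One random stream is used per hospital (unit allocation), split
#' deterministically into one substream per unit, so the output is
#' byte-identical for identical configs and a unit's draws do not shift
#' when another unit's profile is edited.
#'
#' @param config A [hospital_config()], e.g. from [archetype_config()].
#' @return A validated [encounter_bundle()] with exactly
#'   `config$n_admissions` admissions, each with at least one unit stay.
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "hospital_config")) {
    stop("`config` must be a hospital_config", call. = FALSE)
  }
  n <- config$n_admissions
  if (n == 0L) return(encounter_bundle())

  turnover <- vapply(config$unit_profiles, function(p) {
    mean_los <- exp(p$los$meanlog + p$los$sdlog^2 / 2) *
      sum(p$age_model$weight * p$age_model$los_mult)
    p$bed_pressure / mean_los
  }, numeric(1))

  alloc <- withr::with_seed(
    substream_seed(config$seed, 0L),
    as.vector(stats::rmultinom(1, n, prob = turnover / sum(turnover)))
  )
  offsets <- cumsum(c(0L, alloc[-length(alloc)]))

  parts <- purrr::map(seq_along(config$unit_profiles), function(i) {
    if (alloc[i] == 0L) return(NULL)
    withr::with_seed(
      substream_seed(config$seed, i),
      generate_unit_admissions(config, unit_index = i, n_unit = alloc[i], id_offset = offsets[i])
    )
  })
  parts <- purrr::compact(parts)

  encounter_bundle(
    admissions = dplyr::bind_rows(purrr::map(parts, "admissions")),
    stays = dplyr::bind_rows(purrr::map(parts, "stays")),
    exposures = dplyr::bind_rows(purrr::map(parts, "exposures"))
  )
}

unit_id_for <- function(config, i) sprintf("%s-U%02d", config$hospital_id, i)

# Transfer destinations respect case mix: candidate units (never the
# current one, never an emergency department — those are entry points)
# are weighted by their age-mixture density at the patient's age, so
# neonates land in nurseries and elderly patients in elderly wards.
transfer_destination <- function(config, current, age) {
  cand <- setdiff(seq_len(config$n_units), current)
  cand <- cand[!grepl("emergency", vapply(
    config$unit_profiles[cand], function(p) p$unit_type, character(1)
  ))]
  if (length(cand) == 0) return(NA_integer_)
  w <- vapply(cand, function(i) {
    am <- config$unit_profiles[[i]]$age_model
    sum(am$weight * stats::dnorm(age, am$mean, pmax(am$sd, 0.5))) + 1e-6
  }, numeric(1))
  cand[sample.int(length(cand), 1, prob = w)]
}

generate_unit_admissions <- function(config, unit_index, n_unit, id_offset) {
  window <- config$window
  days <- seq(window[1], window[2], by = "day")
  profiles <- config$unit_profiles
  prof <- profiles[[unit_index]]

  adm_rows <- vector("list", n_unit)
  stay_rows <- list()
  exp_rows <- list()

  for (k in seq_len(n_unit)) {
    idx <- id_offset + k
    admission_id <- sprintf("%s-A%05d", config$hospital_id, idx)

    comp <- sample.int(nrow(prof$age_model), 1, prob = prof$age_model$weight)
    age <- round(rnorm(1, prof$age_model$mean[comp], prof$age_model$sd[comp]))
    age <- max(0L, min(AGE_MAX, as.integer(age)))
    los_mult <- prof$age_model$los_mult[comp]

    sex <- sample(c("F", "M", NA_character_), 1, prob = c(0.563, 0.398, 0.039))
    elix <- if (runif(1) < prof$elix_model$p_zero) {
      0L
    } else {
      min(ELIX_MAX, rpois(1, prof$elix_model$lambda))
    }

    # Transfer chain: consecutive stays share the boundary day (the patient
    # is on both units' rosters that day); truncated at the window end.
    current <- unit_index
    entry <- sample(days, 1)
    stays_k <- list()
    repeat {
      p_cur <- profiles[[current]]
      los <- max(1, ceiling(rlnorm(1, p_cur$los$meanlog, p_cur$los$sdlog) * los_mult))
      exit <- min(entry + los - 1, window[2])
      stays_k[[length(stays_k) + 1]] <- tibble::tibble(
        admission_id = admission_id,
        unit_id = unit_id_for(config, current),
        unit_type = p_cur$unit_type,
        entry_date = entry,
        exit_date = exit
      )
      chain_can_go_on <- exit < window[2] &&
        config$n_units > 1 &&
        length(stays_k) < 8 &&
        runif(1) < p_cur$transfer_out_prob
      if (!chain_can_go_on) break
      dest <- transfer_destination(config, current, age)
      if (is.na(dest)) break
      current <- dest
      entry <- exit
    }
    stays_k <- dplyr::bind_rows(stays_k)
    admit <- min(stays_k$entry_date)
    discharge <- max(stays_k$exit_date)

    adm_rows[[k]] <- tibble::tibble(
      admission_id = admission_id, patient_id = sprintf("%s-P%05d", config$hospital_id, idx),
      hospital_id = config$hospital_id, age = age, sex = sex, elixhauser = elix,
      admit_date = admit, discharge_date = discharge
    )
    stay_rows[[k]] <- stays_k

    # Per-day antibiotic exposure with the probabilities of the unit
    # occupied that day (first stay wins on shared boundary days).
    hosp_days <- seq(admit, discharge, by = "day")
    day_unit <- vapply(seq_along(hosp_days), function(j) {
      which(stays_k$entry_date <= hosp_days[j] & stays_k$exit_date >= hosp_days[j])[1]
    }, integer(1))
    probs <- do.call(rbind, lapply(day_unit, function(s) {
      profiles[[match(stays_k$unit_id[s], unit_id_for(config, seq_len(config$n_units)))]]$abx_model
    }))
    draws <- matrix(
      rbinom(length(hosp_days) * 4L, 1L, as.vector(probs)) == 1L,
      ncol = 4L, dimnames = list(NULL, ABX_RANKS)
    )
    hit <- which(draws, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      exp_rows[[k]] <- tibble::tibble(
        admission_id = admission_id,
        date = hosp_days[hit[, 1]],
        rank = ABX_RANKS[hit[, 2]]
      )
    }
  }

  list(
    admissions = dplyr::bind_rows(adm_rows),
    stays = dplyr::bind_rows(stay_rows),
    exposures = dplyr::bind_rows(exp_rows)
  )
}

#' Combine encounter bundles
#'
#' Binds the tables of several bundles (e.g. one per hospital) into one
#' multi-hospital bundle. Admission ids must not collide.
#'
#' @param ... Encounter bundles, or a single list of them.
#' @return An [encounter_bundle()].
#' @export
bind_bundles <- function(...) {
  bundles <- list(...)
  if (length(bundles) == 1 && !inherits(bundles[[1]], "encounter_bundle")) {
    bundles <- bundles[[1]]
  }
  purrr::walk(bundles, assert_bundle)
  encounter_bundle(
    admissions = dplyr::bind_rows(purrr::map(bundles, "admissions")),
    stays = dplyr::bind_rows(purrr::map(bundles, "stays")),
    exposures = dplyr::bind_rows(purrr::map(bundles, "exposures"))
  )
}

#' Summarize an encounter bundle per hospital
#'
#' @param bundle An [encounter_bundle()].
#' @return A tibble with one row per hospital: admission, patient and unit
#'   counts, median age, and the percentage of admissions with stays in two
#'   or more distinct units.
#' @export
summarize_bundle <- function(bundle) {
  assert_bundle(bundle)
  multi <- bundle$stays |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(multiunit = dplyr::n_distinct(.data$unit_id) >= 2L)
  units <- dplyr::distinct(bundle$stays, .data$admission_id, .data$unit_id)
  unit_counts <- bundle$admissions |>
    dplyr::left_join(units, by = "admission_id") |>
    dplyr::group_by(.data$hospital_id) |>
    dplyr::summarise(n_units = dplyr::n_distinct(.data$unit_id[!is.na(.data$unit_id)]))
  bundle$admissions |>
    dplyr::left_join(multi, by = "admission_id") |>
    dplyr::mutate(multiunit = dplyr::coalesce(.data$multiunit, FALSE)) |>
    dplyr::group_by(.data$hospital_id) |>
    dplyr::summarise(
      n_admissions = dplyr::n(),
      n_patients = dplyr::n_distinct(.data$patient_id),
      median_age = median(.data$age),
      pct_multiunit = 100 * mean(.data$multiunit)
    ) |>
    dplyr::left_join(unit_counts, by = "hospital_id")
}
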