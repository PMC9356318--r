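# Hand-built fixtures used across test files. All dates are in January
# 2017 to match the default archetype window.

d <- function(day) as.Date(sprintf("2017-01-%02d", day))

# An admission row with overridable fields.
adm_row <- function(id, hospital = "H1", age = 40L, sex = "F", elix = 0L,
                    admit = d(1), discharge = d(10), patient = paste0("P-", id)) {
  tibble::tibble(
    admission_id = id, patient_id = patient, hospital_id = hospital,
    age = as.integer(age), sex = sex, elixhauser = as.integer(elix),
    admit_date = admit, discharge_date = discharge
  )
}

stay_row <- function(id, unit = "U1", type = "adult medical ward",
                     entry = d(1), exit = d(10)) {
  tibble::tibble(
    admission_id = id, unit_id = unit, unit_type = type,
    entry_date = entry, exit_date = exit
  )
}

exp_row <- function(id, date, rank) {
  tibble::tibble(admission_id = id, date = date, rank = rank)
}

# Four patients sharing one unit for one day: the canonical kC2 example.
four_patient_bundle <- function() {
  encounter_bundle(
    admissions = dplyr::bind_rows(lapply(c("A", "B", "C", "D"), function(id) {
      adm_row(id, admit = d(1), discharge = d(1))
    })),
    stays = dplyr::bind_rows(lapply(c("A", "B", "C", "D"), function(id) {
      stay_row(id, entry = d(1), exit = d(1))
    }))
  )
}

# A random small bundle for property-style tests: admissions scattered
# over units and days, some with transfer chains. Pure base-R sampling.
random_bundle <- function(n_adm, n_units, window_days = 30, seed = 1,
                          hospital = "H1") {
  withr::with_seed(seed, {
    start <- d(1)
    adms <- list()
    stays <- list()
    exps <- list()
    for (i in seq_len(n_adm)) {
      id <- sprintf("%s-A%03d", hospital, i)
      entry <- start + sample.int(window_days, 1) - 1
      los <- sample.int(6, 1)
      exit <- min(entry + los - 1, start + window_days - 1)
      unit <- sprintf("U%02d", sample.int(n_units, 1))
      st <- stay_row(id, unit = unit, entry = entry, exit = exit)
      if (runif(1) < 0.3 && n_units > 1 && exit < start + window_days - 1) {
        unit2 <- sprintf("U%02d", sample(setdiff(seq_len(n_units), as.integer(sub("U", "", unit))), 1))
        exit2 <- min(exit + sample.int(4, 1), start + window_days - 1)
        st <- dplyr::bind_rows(st, stay_row(id, unit = unit2, entry = exit, exit = exit2))
      }
      admit <- min(st$entry_date)
      discharge <- max(st$exit_date)
      adms[[i]] <- adm_row(id,
        hospital = hospital, age = sample(0:90, 1),
        elix = sample(0:16, 1), admit = admit, discharge = discharge
      )
      stays[[i]] <- st
      days <- seq(admit, discharge, by = "day")
      exposed <- days[runif(length(days)) < 0.3]
      if (length(exposed) > 0) {
        exps[[i]] <- exp_row(id, exposed, sample(c("narrow", "broad", "extended", "protected"),
          length(exposed),
          replace = TRUE
        ))
      }
    }
    encounter_bundle(
      dplyr::bind_rows(adms), dplyr::bind_rows(stays), dplyr::bind_rows(exps)
    )
  })
}
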