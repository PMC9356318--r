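jan_window <- c(d(1), d(30))

# One-day colocation bundle with chosen ages.
ages_bundle <- function(ages, days = 1) {
  ids <- sprintf("A%02d", seq_along(ages))
  encounter_bundle(
    admissions = dplyr::bind_rows(purrr::map2(ids, ages, function(i, a) {
      adm_row(i, age = a, admit = d(1), discharge = d(days))
    })),
    stays = dplyr::bind_rows(lapply(ids, function(i) {
      stay_row(i, entry = d(1), exit = d(days))
    }))
  )
}

test_that("ordered-pair convention fills mirrored cells", {
  m <- age_mixing(ages_bundle(c(30, 40)))
  expect_equal(m$counts["30", "40"], 1)
  expect_equal(m$counts["40", "30"], 1)
  expect_equal(sum(m$counts), 2)

  # three same-age patients, one unit-day: 3 events, diagonal gets 6
  m2 <- age_mixing(ages_bundle(c(50, 50, 50)))
  expect_equal(m2$counts["50", "50"], 6)
  expect_equal(sum(m2$counts), 6)

  # co-location over 3 days mirrors edge weight 3 per ordered cell
  m3 <- age_mixing(ages_bundle(c(30, 40), days = 3))
  expect_equal(m3$counts["30", "40"], 3)
  expect_equal(m3$counts["40", "30"], 3)
})

test_that("conservation and symmetry hold on generated bundles", {
  for (name in c("uniform_adult", "elderly_small")) {
    b <- generate_bundle(archetype_config(name, 120, seed = 4))
    hid <- b$admissions$hospital_id[1]
    net <- build_network(b, hid, jan_window)
    for (m in list(age_mixing(b), elixhauser_mixing(b))) {
      expect_equal(sum(m$counts), 2 * nrow(net$events), info = name)
      expect_identical(m$counts, t(m$counts), info = name)
    }
  }
})

test_that("age matrix marginals equal weighted degrees of the network", {
  b <- generate_bundle(archetype_config("uniform_adult", 100, seed = 6))
  net <- build_network(b, "H-uniform_adult", jan_window)
  m <- age_mixing(b)
  # weighted degree per admission, rolled up by age
  wdeg <- c(
    tapply(net$edges$weight, net$edges$admission_a, sum),
    tapply(net$edges$weight, net$edges$admission_b, sum)
  )
  wdeg_by_id <- tapply(wdeg, names(wdeg), sum)
  age_of <- setNames(b$admissions$age, b$admissions$admission_id)
  expected <- tapply(as.vector(wdeg_by_id), as.character(age_of[names(wdeg_by_id)]), sum)
  got <- rowSums(m$counts)[names(expected)]
  expect_equal(unname(got), unname(as.vector(expected)))
})

test_that("elixhauser mixing uses the 17-level axis", {
  b <- ages_bundle(c(40, 40))
  b$admissions$elixhauser <- c(4L, 4L)
  m <- elixhauser_mixing(b)
  expect_equal(dim(m$counts), c(17, 17))
  expect_equal(m$counts["4", "4"], 2)
  expect_equal(sum(m$counts), 2)
})

test_that("abx per-day class sets contribute their full cross-product", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(
      adm_row("Aa", admit = d(1), discharge = d(1)),
      adm_row("Ab", admit = d(1), discharge = d(1))
    ),
    stays = dplyr::bind_rows(
      stay_row("Aa", entry = d(1), exit = d(1)),
      stay_row("Ab", entry = d(1), exit = d(1))
    ),
    exposures = dplyr::bind_rows(
      exp_row("Aa", d(1), "narrow"), exp_row("Aa", d(1), "extended"),
      exp_row("Ab", d(1), "narrow")
    )
  )
  m <- abx_mixing(b)
  expect_equal(m$counts["narrow", "narrow"], 2)
  expect_equal(m$counts["extended", "narrow"], 1)
  expect_equal(m$counts["narrow", "extended"], 1)
  expect_equal(sum(m$counts), 4)
  expect_equal(m$excluded_events, 0)

  # both on narrow only
  b2 <- b
  b2$exposures <- b2$exposures[b2$exposures$rank == "narrow", ]
  b2 <- encounter_bundle(b2$admissions, b2$stays, b2$exposures)
  m2 <- abx_mixing(b2)
  expect_equal(m2$counts["narrow", "narrow"], 2)
  expect_equal(sum(m2$counts), 2)

  # collapse to the highest rank: {narrow, extended} becomes extended
  mh <- abx_mixing(b, collapse = "highest")
  expect_equal(mh$counts["extended", "narrow"], 1)
  expect_equal(mh$counts["narrow", "extended"], 1)
  expect_equal(sum(mh$counts), 2)
})

test_that("whole-stay timing classifies by any exposure during the admission", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(
      adm_row("Aa", admit = d(1), discharge = d(2)),
      adm_row("Ab", admit = d(1), discharge = d(2))
    ),
    stays = dplyr::bind_rows(
      stay_row("Aa", entry = d(1), exit = d(2)),
      stay_row("Ab", entry = d(1), exit = d(2))
    ),
    # exposure on day 2 only
    exposures = dplyr::bind_rows(
      exp_row("Aa", d(2), "broad"), exp_row("Ab", d(2), "broad")
    )
  )
  per_day <- abx_mixing(b, timing_policy = "per_day")
  expect_equal(per_day$counts["broad", "broad"], 2) # only the day-2 event
  expect_equal(per_day$excluded_events, 1) # the day-1 event
  whole <- abx_mixing(b, timing_policy = "whole_stay")
  expect_equal(whole$counts["broad", "broad"], 4) # both events classified
  expect_equal(whole$excluded_events, 0)
})

test_that("unexposed events are excluded and tallied, or error under strict policy", {
  b <- ages_bundle(c(30, 40))
  m <- abx_mixing(b)
  expect_equal(sum(m$counts), 0)
  expect_equal(m$excluded_events, 1)

  # strict policy exercised through mixing_matrix directly
  events <- build_network(b, "H1", jan_window)$events
  expect_error(
    mixing_matrix(events,
      tibble::tibble(
        admission_id = "A01", date = d(1), class = "narrow"
      ),
      axis = c("narrow", "broad", "extended", "protected"), policy = "strict"
    ),
    "unclassifiable"
  )
})

test_that("none-ratio accounts for every event", {
  # 4 patients, 2 exposed, one unit-day: 6 pairs, 1 unexposed pair
  b <- ages_bundle(c(30, 40, 50, 60))
  b <- encounter_bundle(
    b$admissions, b$stays,
    dplyr::bind_rows(
      exp_row("A01", d(1), "narrow"), exp_row("A02", d(1), "extended")
    )
  )
  nr <- abx_none_ratio(b)
  expect_equal(nr$events_neither, 1)
  expect_equal(nr$events_any, 5)
  expect_equal(nr$ratio, 0.2)

  # no exposures at all: ratio flagged missing
  nr0 <- abx_none_ratio(ages_bundle(c(30, 40)))
  expect_true(nr0$no_exposed_flag)
  expect_true(is.na(nr0$ratio))

  # everyone exposed: ratio 0
  b2 <- ages_bundle(c(30, 40))
  b2 <- encounter_bundle(
    b2$admissions, b2$stays,
    dplyr::bind_rows(exp_row("A01", d(1), "narrow"), exp_row("A02", d(1), "narrow"))
  )
  expect_equal(abx_none_ratio(b2)$ratio, 0)

  # conservation on a generated bundle
  b3 <- generate_bundle(archetype_config("uniform_adult", 100, seed = 8))
  nr3 <- abx_none_ratio(b3)
  expect_equal(nr3$events_neither + nr3$events_any, nr3$events_total)
})

test_that("min-max normalization follows the printed formula", {
  m <- structure(
    list(
      axis = c("a", "b"), axis_name = "demo",
      counts = matrix(c(1, 3, 3, 5), 2, dimnames = list(c("a", "b"), c("a", "b"))),
      normalized = NULL, normalization_flag = NULL, scope = NULL,
      excluded_events = 0L
    ),
    class = "mixing_matrix"
  )
  n <- normalize_mixing(m)
  expect_equal(
    n$normalized,
    matrix(c(0, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  )
  expect_null(n$normalization_flag)

  # constant matrix: zeros plus flag
  m$counts[] <- 7
  nc <- normalize_mixing(m)
  expect_true(all(nc$normalized == 0))
  expect_equal(nc$normalization_flag, "constant")

  # generated case: min 0 and max 1 whenever not constant
  b <- generate_bundle(archetype_config("elderly_small", 100, seed = 9))
  na <- normalize_mixing(age_mixing(b))
  expect_equal(min(na$normalized), 0)
  expect_equal(max(na$normalized), 1)

  # idempotent: a matrix already spanning [0, 1] is left unchanged
  m01 <- na
  m01$counts <- na$normalized
  expect_equal(normalize_mixing(m01)$normalized, m01$counts)
})

test_that("scopes restrict mixing to units, types and windows", {
  b <- generate_bundle(archetype_config("academic_pediatric", 300, seed = 2))
  ld <- age_mixing(b, mixing_scope(unit_type = "labor and delivery ward"))
  ages <- as.integer(rownames(ld$counts))
  in_rng <- ages >= 15 & ages <= 45
  expect_gte(sum(ld$counts[in_rng, in_rng]) / sum(ld$counts), 0.95)

  icu <- elixhauser_mixing(b, mixing_scope(unit_type = "adult critical care"))
  ward <- elixhauser_mixing(b, mixing_scope(unit_type = "adult medical ward"))
  centroid <- function(m) {
    sum(as.integer(rownames(m$counts)) * rowSums(m$counts)) / sum(m$counts)
  }
  expect_gt(centroid(icu), centroid(ward))
})

test_that("pattern_contingency tabulates admissions once each", {
  mk <- function(sets) {
    ids <- sprintf("A%02d", seq_along(sets))
    expo <- purrr::imap(sets, function(rks, i) {
      if (length(rks) == 0) return(NULL)
      exp_row(ids[i], d(1) + seq_along(rks) - 1, rks)
    })
    encounter_bundle(
      admissions = dplyr::bind_rows(lapply(ids, function(i) adm_row(i, discharge = d(5)))),
      stays = dplyr::bind_rows(lapply(ids, function(i) stay_row(i, exit = d(5)))),
      exposures = dplyr::bind_rows(purrr::compact(expo))
    )
  }
  # 10 admissions all narrow-only: one category at 100%
  pc1 <- pattern_contingency(mk(rep(list("narrow"), 10)))
  expect_equal(pc1$category, "narrow")
  expect_equal(pc1$pct, 100)

  # {n}, {e}, {n,e}, {}: four categories at 25% each
  pc2 <- pattern_contingency(mk(list("narrow", "extended", c("narrow", "extended"), character())))
  expect_setequal(pc2$category, c("narrow", "extended", "narrow+extended", "none"))
  expect_true(all(pc2$pct == 25))

  # highest-rank grouping collapses combinations
  pc3 <- pattern_contingency(
    mk(list(c("narrow", "extended"), "narrow")),
    grouping = "by_highest_rank"
  )
  expect_setequal(pc3$category, c("extended", "narrow"))

  # empty scope yields an empty table
  pc4 <- pattern_contingency(mk(list("narrow")), mixing_scope(unit_type = "no such unit"))
  expect_equal(nrow(pc4), 0)
})

test_that("tidy and autoplot expose the matrix in long form", {
  b <- ages_bundle(c(30, 40))
  m <- normalize_mixing(age_mixing(b))
  long <- tidy(m)
  expect_equal(nrow(long), 91 * 91)
  expect_equal(sum(long$count), 2)
  expect_true(all(c("class_a", "class_b", "count", "normalized") %in% names(long)))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})
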