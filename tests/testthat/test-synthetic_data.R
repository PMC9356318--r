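test_that("archetype_config returns fully specified, deterministic configs", {
  cfg <- archetype_config("elderly_small", 500, seed = 7)
  expect_s3_class(cfg, "hospital_config")
  expect_lte(cfg$n_units, 8)
  non_ed <- Filter(function(p) p$unit_type != "emergency department", cfg$unit_profiles)
  for (p in non_ed) {
    expect_gte(sum(p$age_model$weight * p$age_model$mean), 60)
  }
  expect_identical(cfg, archetype_config("elderly_small", 500, seed = 7))
  expect_error(archetype_config("megahospital", 10, 1), "uniform_adult")
})

test_that("a zero-admission config yields a valid empty bundle", {
  b <- generate_bundle(archetype_config("uniform_adult", 0, seed = 1))
  expect_equal(nrow(b$admissions), 0)
  expect_equal(nrow(validate_bundle(b)), 0)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- archetype_config("young_skew", 100, seed = 42)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1, b2)
})

test_that("generated bundles satisfy every structural invariant", {
  for (name in c("uniform_adult", "young_skew", "elderly_small", "academic_pediatric")) {
    b <- generate_bundle(archetype_config(name, 150, seed = 3))
    expect_equal(nrow(b$admissions), 150)
    expect_equal(nrow(validate_bundle(b)), 0, info = name)
    # every admission has at least one stay, and chains have no gaps
    per_adm <- split(b$stays, b$stays$admission_id)
    expect_setequal(names(per_adm), b$admissions$admission_id)
    gapless <- vapply(per_adm, function(st) {
      st <- st[order(st$entry_date), ]
      nrow(st) == 1 || all(st$entry_date[-1] <= st$exit_date[-nrow(st)])
    }, logical(1))
    expect_true(all(gapless), info = name)
  }
})

test_that("zero transfer probability forces single-unit admissions", {
  cfg <- archetype_config("uniform_adult", 120, seed = 5)
  cfg$unit_profiles <- lapply(cfg$unit_profiles, function(p) {
    p$transfer_out_prob <- 0
    p
  })
  b <- generate_bundle(cfg)
  n_units_per_adm <- tapply(b$stays$unit_id, b$stays$admission_id, function(u) length(unique(u)))
  expect_true(all(n_units_per_adm == 1))
})

test_that("configured age structure is recovered in the sample", {
  b_old <- generate_bundle(archetype_config("elderly_small", 1000, seed = 11))
  b_young <- generate_bundle(archetype_config("young_skew", 1000, seed = 11))
  expect_gt(mean(b_old$admissions$age), mean(b_young$admissions$age))

  # per-unit empirical age mean within 3 SE of the configured mixture mean
  cfg <- archetype_config("young_skew", 2000, seed = 13)
  b <- generate_bundle(cfg)
  first_stays <- b$stays[!duplicated(b$stays$admission_id), ]
  joined <- merge(b$admissions, first_stays[, c("admission_id", "unit_id")])
  for (i in seq_len(cfg$n_units)) {
    uid <- sprintf("%s-U%02d", cfg$hospital_id, i)
    ages <- joined$age[joined$unit_id == uid]
    if (length(ages) < 30) next
    am <- cfg$unit_profiles[[i]]$age_model
    mu <- sum(am$weight * am$mean)
    sigma2 <- sum(am$weight * (am$sd^2 + am$mean^2)) - mu^2
    se <- sqrt(sigma2 / length(ages))
    expect_lt(abs(mean(ages) - mu), 3 * se + 0.5) # 0.5 allows rounding/top-coding
  }
})

test_that("summarize_bundle counts match bundle cardinalities", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(adm_row("A1"), adm_row("A2"), adm_row("A3")),
    stays = dplyr::bind_rows(
      stay_row("A1"), stay_row("A1", unit = "U2", entry = d(5), exit = d(10)),
      stay_row("A2"), stay_row("A3")
    )
  )
  s <- summarize_bundle(b)
  expect_equal(s$n_admissions, 3)
  expect_equal(s$pct_multiunit, 100 / 3, tolerance = 1e-12)

  expect_equal(sum(summarize_bundle(encounter_bundle())$n_admissions), 0)

  big <- generate_bundle(archetype_config("uniform_adult", 80, seed = 2))
  expect_equal(sum(summarize_bundle(big)$n_admissions), nrow(big$admissions))
})

test_that("multi-hospital bundles combine and summarize per hospital", {
  b1 <- generate_bundle(archetype_config("uniform_adult", 50, seed = 1))
  b2 <- generate_bundle(archetype_config("elderly_small", 50, seed = 2))
  both <- bind_bundles(b1, b2)
  s <- summarize_bundle(both)
  expect_equal(nrow(s), 2)
  expect_equal(sum(s$n_admissions), 100)
})
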