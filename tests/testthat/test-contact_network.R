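jan_window <- c(d(1), d(30))

test_that("daily rosters follow the inclusive-day convention", {
  stays <- stay_row("A1", unit = "U", entry = d(1), exit = d(3))
  r <- daily_rosters(stays, jan_window)
  expect_equal(nrow(r), 3)
  expect_equal(r$date, c(d(1), d(2), d(3)))

  # stay entirely outside the window contributes nothing
  r2 <- daily_rosters(stay_row("A1", entry = d(1), exit = d(3)), c(d(10), d(20)))
  expect_equal(nrow(r2), 0)

  # window clipping keeps only in-window days
  r3 <- daily_rosters(stay_row("A1", entry = d(1), exit = d(10)), c(d(8), d(30)))
  expect_equal(r3$date, c(d(8), d(9), d(10)))
})

test_that("same-day dual-unit presence puts the admission on both rosters", {
  stays <- dplyr::bind_rows(
    stay_row("A1", unit = "U", entry = d(1), exit = d(2)),
    stay_row("A1", unit = "V", entry = d(2), exit = d(4))
  )
  r <- daily_rosters(stays, jan_window)
  on_jan2 <- r[r$date == d(2), ]
  expect_setequal(on_jan2$unit_id, c("U", "V"))
})

test_that("a k-member roster cell yields exactly k-choose-2 contacts", {
  mk_cell <- function(ids) {
    daily_rosters(
      dplyr::bind_rows(lapply(ids, function(i) stay_row(i, entry = d(1), exit = d(1)))),
      jan_window
    )
  }
  e4 <- enumerate_contacts(mk_cell(c("A", "B", "C", "D")))
  expect_equal(nrow(e4), 6)
  expect_setequal(
    paste(e4$admission_a, e4$admission_b),
    c("A B", "A C", "A D", "B C", "B D", "C D")
  )
  expect_equal(nrow(enumerate_contacts(mk_cell("A"))), 0)
  expect_equal(nrow(enumerate_contacts(mk_cell(c("A", "B", "C", "D", "E")))), 10)
})

test_that("kC2 conservation holds on random bundles", {
  for (seed in 1:5) {
    b <- random_bundle(40, 4, seed = seed)
    r <- daily_rosters(b$stays, jan_window)
    ev <- enumerate_contacts(r)
    k <- table(paste(r$unit_id, r$date))
    expect_equal(nrow(ev), sum(choose(k, 2)))
  }
})

test_that("edge weights count shared unit-days and isolates are retained", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(adm_row("A1"), adm_row("A2"), adm_row("A3")),
    stays = dplyr::bind_rows(
      stay_row("A1", entry = d(1), exit = d(3)),
      stay_row("A2", entry = d(1), exit = d(3)),
      stay_row("A3", unit = "U9", entry = d(5), exit = d(6))
    )
  )
  net <- build_network(b, "H1", jan_window)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_equal(nrow(net$nodes), 3) # A3 is an isolate but present
  expect_error(build_network(b, "H99", jan_window), "H99")
})

test_that("build_network matches the brute-force co-presence oracle", {
  for (seed in 1:4) {
    b <- random_bundle(25, 3, seed = seed + 100)
    net <- build_network(b, "H1", jan_window)
    oracle <- oracle_edge_weights(b, "H1", jan_window)
    got <- as.data.frame(net$edges)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got$admission_a, oracle$admission_a)
    expect_equal(got$admission_b, oracle$admission_b)
    expect_equal(got$weight, as.integer(oracle$weight))
  }
})

test_that("enlarging the window never removes an edge nor lowers a weight", {
  b <- random_bundle(30, 3, seed = 77)
  small <- build_network(b, "H1", c(d(5), d(15)))$edges
  big <- build_network(b, "H1", c(d(1), d(30)))$edges
  merged <- merge(small, big, by = c("admission_a", "admission_b"), all.x = TRUE)
  expect_false(any(is.na(merged$weight.y)))
  expect_true(all(merged$weight.y >= merged$weight.x))
})

test_that("two admissions of one patient are distinct nodes that may share an edge", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(
      adm_row("A1", patient = "P1"), adm_row("A2", patient = "P1")
    ),
    stays = dplyr::bind_rows(
      stay_row("A1", entry = d(1), exit = d(2)),
      stay_row("A2", entry = d(2), exit = d(3))
    )
  )
  net <- build_network(b, "H1", jan_window)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$edges$weight, 1) # shared day Jan 2
})

test_that("same-day dual-unit co-location double-counts unless deduped", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(adm_row("A1"), adm_row("A2")),
    stays = dplyr::bind_rows(
      stay_row("A1", unit = "U", entry = d(1), exit = d(1)),
      stay_row("A1", unit = "V", entry = d(1), exit = d(1)),
      stay_row("A2", unit = "U", entry = d(1), exit = d(1)),
      stay_row("A2", unit = "V", entry = d(1), exit = d(1))
    )
  )
  expect_equal(build_network(b, "H1", jan_window)$edges$weight, 2)
  expect_equal(build_network(b, "H1", jan_window, dedupe_same_day = TRUE)$edges$weight, 1)
})

test_that("multiward percentages match hand counts", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(
      adm_row("A1"), adm_row("A2"), adm_row("A3"), adm_row("A4")
    ),
    stays = dplyr::bind_rows(
      stay_row("A1", unit = "U1", entry = d(1), exit = d(2)),
      stay_row("A1", unit = "U2", entry = d(2), exit = d(4)),
      stay_row("A2", unit = "U1", entry = d(1), exit = d(3)),
      stay_row("A3", unit = "U2", entry = d(2), exit = d(3)),
      stay_row("A4", unit = "U3", entry = d(1), exit = d(2))
    )
  )
  net <- build_network(b, "H1", jan_window)
  mw <- multiward_summary(net, b$stays)
  expect_equal(mw$pct_multiunit_admissions, 25) # only A1
  # edges: A1-A2 (U1), A1-A3 (U2); both touch A1
  expect_equal(mw$pct_edges_touching_multiunit, 100)

  # all single-unit: both percentages zero
  b2 <- encounter_bundle(
    admissions = dplyr::bind_rows(adm_row("A1"), adm_row("A2")),
    stays = dplyr::bind_rows(stay_row("A1"), stay_row("A2"))
  )
  mw2 <- multiward_summary(build_network(b2, "H1", jan_window), b2$stays)
  expect_equal(mw2$pct_multiunit_admissions, 0)
  expect_equal(mw2$pct_edges_touching_multiunit, 0)

  # zero-edge network flagged
  b3 <- encounter_bundle(
    admissions = dplyr::bind_rows(adm_row("A1"), adm_row("A2")),
    stays = dplyr::bind_rows(
      stay_row("A1", entry = d(1), exit = d(2)),
      stay_row("A2", entry = d(10), exit = d(12))
    )
  )
  mw3 <- multiward_summary(build_network(b3, "H1", jan_window), b3$stays)
  expect_true(mw3$no_edges_flag)
  expect_equal(mw3$pct_edges_touching_multiunit, 0)
})

test_that("edges never cross hospitals even for shared patients", {
  b <- encounter_bundle(
    admissions = dplyr::bind_rows(
      adm_row("A1", hospital = "H1", patient = "P1"),
      adm_row("A2", hospital = "H2", patient = "P1")
    ),
    stays = dplyr::bind_rows(
      stay_row("A1", unit = "H1-U1"), stay_row("A2", unit = "H2-U1")
    )
  )
  net <- build_network(b, "H1", jan_window)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(nrow(net$edges), 0)
})
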