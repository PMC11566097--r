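test_that("CESD-8 scoring applies the cutoff-3 rule", {
  expect_identical(score_cesd(rep(0, 8)), 1L)
  expect_identical(score_cesd(c(1, 1, 1, 0, 0, 0, 0, 0)), 2L)
  expect_identical(score_cesd(c(1, 1, 0, 0, 0, 0, 0, 0)), 1L)
  expect_identical(score_cesd(rep(1, 8)), 2L)
  # any missing included item gives a missing state, no prorating
  expect_identical(score_cesd(c(NA, 1, 1, 1, 1, 1, 1, 1)), NA_integer_)
  # ... but not if the missing item is excluded from the score
  expect_identical(score_cesd(c(NA, 1, 1, 1, 0, 0, 0, 0),
                              included_items = 2:8), 2L)
  # matrix input scores row-wise
  expect_identical(score_cesd(rbind(rep(0, 8), rep(1, 8))), c(1L, 2L))
})

test_that("CESD scoring validates its configuration", {
  expect_error(score_cesd(rep(0, 8), cutoff = 9), "cutoff")
  expect_error(score_cesd(rep(0, 8), included_items = 2:4, cutoff = 4),
               "cutoff")
  expect_error(score_cesd(rep(0, 8), included_items = c(1, 1, 2)), "subset")
  expect_error(score_cesd(rep(2, 8)), "0, 1 or missing")
})

test_that("inclusion filters remove the documented toy cases in order", {
  panel <- toy_filter_panel()
  filtered <- apply_inclusion_filters(panel)
  rep <- filter_report(filtered)
  expect_identical(rep$rule, c("underage", "no_valid_interview",
                               "marital_change", "entry_state_missing"))
  expect_identical(rep$n_persons_removed, c(1L, 0L, 1L, 1L))
  expect_identical(attr(rep, "n_retained"), 2L)
  expect_setequal(unique(filtered$person_id), c("cleanA", "cleanB"))
  # removed + retained = input persons
  expect_identical(sum(rep$n_persons_removed) + attr(rep, "n_retained"),
                   length(unique(panel$person_id)))
})

test_that("filters are idempotent and leave clean panels untouched", {
  filtered <- apply_inclusion_filters(toy_filter_panel())
  twice <- apply_inclusion_filters(filtered)
  expect_equal(tibble::as_tibble(twice)[names(filtered)],
               tibble::as_tibble(filtered)[names(filtered)],
               ignore_attr = TRUE)
  expect_identical(filter_report(twice)$n_persons_removed, rep(0L, 4))
})

test_that("synthetic panels with entry ages 50+ pass all filters", {
  truth <- generate_panel(synthetic_config(n_individuals = 200, seed = 5))
  filtered <- apply_inclusion_filters(truth$panel)
  expect_identical(filter_report(filtered)$n_persons_removed, rep(0L, 4))
})

test_that("pair extraction follows consecutive observations, missed waves and deaths", {
  panel <- apply_inclusion_filters(toy_filter_panel())
  pairs <- extract_pairs(panel)
  a <- pairs[pairs$person_id == "cleanA", ]
  expect_identical(nrow(a), 2L)
  expect_identical(a$age_start, c(720L, 744L))
  expect_identical(a$age_end, c(744L, 768L))
  expect_identical(a$state_start, c(1L, 1L))
  expect_identical(a$state_end, c(1L, 2L))
  b <- pairs[pairs$person_id == "cleanB", ]
  # alive pair then a death pair ending at the exact death age
  expect_identical(b$state_end, c(2L, 3L))
  expect_identical(b$age_end, c(804L, 810L))
  expect_true(b$is_death[2])
})

test_that("missing states are skipped as endpoints without breaking the chain", {
  panel <- tibble::tibble(
    person_id = "p1", sex = "female", z = 0L, birth_month = -720L,
    obs_month = c(0L, 24L, 49L), vital = "alive",
    death_month = NA_integer_, state = c(1L, NA_integer_, 2L)
  )
  pairs <- extract_pairs(panel)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$age_start, 720L)
  expect_identical(pairs$age_end, 769L)
  expect_identical(pairs$state_end, 2L)
})

test_that("same-month death yields a one-month death pair", {
  panel <- tibble::tibble(
    person_id = "p1", sex = "male", z = 1L, birth_month = -800L,
    obs_month = c(0L, 24L, 24L), vital = c("alive", "alive", "dead"),
    death_month = c(NA_integer_, NA_integer_, 24L),
    state = c(1L, 2L, 3L)
  )
  pairs <- extract_pairs(panel)
  death <- pairs[pairs$is_death, ]
  expect_identical(death$age_start, 824L)
  expect_identical(death$age_end, 825L)
})

test_that("duplicate same-month records error or dedupe per configuration", {
  panel <- tibble::tibble(
    person_id = "p1", sex = "female", z = 0L, birth_month = -720L,
    obs_month = c(0L, 0L, 24L), vital = "alive",
    death_month = NA_integer_, state = c(1L, 2L, 1L)
  )
  expect_error(extract_pairs(panel), "duplicate")
  pairs <- extract_pairs(panel, on_duplicate = "first")
  expect_identical(pairs$state_start, 1L)
})

test_that("pair counts and chaining hold on a generated panel", {
  truth <- generate_panel(synthetic_config(n_individuals = 300, seed = 17))
  filtered <- apply_inclusion_filters(truth$panel)
  pairs <- extract_pairs(filtered)
  by_person <- split(pairs, pairs$person_id)
  panel_by_person <- split(filtered, filtered$person_id)
  for (pid in names(by_person)) {
    pp <- by_person[[pid]]
    rec <- panel_by_person[[pid]]
    n_valid <- sum(rec$vital == "alive" & !is.na(rec$state))
    n_dead <- as.integer(any(rec$vital == "dead"))
    expect_identical(nrow(pp), n_valid - 1L + n_dead)
    if (nrow(pp) > 1) {
      expect_identical(pp$age_start[-1], pp$age_end[-nrow(pp)])
    }
    # no pair may start after a death
    if (n_dead == 1) expect_identical(pp$state_end[nrow(pp)], 3L)
  }
})

test_that("panel CSV round trip preserves the column contract", {
  truth <- generate_panel(synthetic_config(n_individuals = 30, seed = 2,
                                           cesd_mode = "items"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(truth$panel, path)
  back <- read_panel(path)
  expect_identical(nrow(back), nrow(truth$panel))
  expect_identical(back$obs_month, as.integer(truth$panel$obs_month))
  expect_identical(back$cesd1, as.integer(truth$panel$cesd1))
})
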