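test_that("trajectories honour the no-transition and certain-death limits", {
  frozen <- frozen_kernel()
  path <- simulate_trajectory(frozen, 700, 2, 0, 760)
  expect_identical(path, rep(2L, 61))
  doomed <- certain_death_kernel()
  set.seed(1)
  path <- simulate_trajectory(doomed, 700, 1, 0, 760)
  expect_identical(path, c(1L, 3L))
  expect_error(simulate_trajectory(frozen, 700, 3, 0, 760), "living state")
})

test_that("mean lifetime under constant survival matches the geometric series", {
  s <- 0.99
  k <- constant_survival_kernel(s)
  set.seed(2024)
  n <- 100000
  occ <- microsim_expectancy(k, 600, 1, 0, n_paths = n, max_age = 600 + 1200)
  # trapezoid-weighted total lifetime: (1/12) (s/(1-s) + 1/2) years
  expected <- (s / (1 - s) + 0.5) / 12
  tot <- occ[occ$state == "total", ]
  expect_lt(abs(tot$years - expected), 3 * tot$se)
})

test_that("microsim occupancies are additive and collapse under certain death", {
  k <- transition_kernel(example_params("female"))
  set.seed(7)
  occ <- microsim_expectancy(k, 700, 2, 1, n_paths = 5000)
  expect_equal(occ$years[occ$state == "total"],
               sum(occ$years[occ$state != "total"]), tolerance = 1e-12)
  set.seed(8)
  doomed <- microsim_expectancy(certain_death_kernel(), 700, 1, 0,
                                n_paths = 100)
  # only the half-credit first month counts
  expect_equal(doomed$years[doomed$state == "nondepressed"], 0.5 / 12,
               tolerance = 1e-12)
  expect_identical(doomed$se[doomed$state == "total"], 0)
})

test_that("panel generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_individuals = 150, seed = 33, cesd_mode = "items")
  t1 <- generate_panel(cfg)
  t2 <- generate_panel(cfg)
  expect_identical(t1$panel, t2$panel)
  expect_identical(t1$trajectories, t2$trajectories)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(t1$panel, f1)
  write_panel(t2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("no jitter and no missed waves give a regular interview grid", {
  cfg <- synthetic_config(n_individuals = 100, seed = 9, wave_jitter_sd = 0,
                          p_missed_wave = 0)
  truth <- generate_panel(cfg)
  survivors <- dplyr::filter(
    dplyr::group_by(truth$panel, person_id),
    !any(vital == "dead"))
  counts <- dplyr::summarise(survivors, n = dplyr::n(),
                             ok = all(obs_month == (seq_len(dplyr::n()) - 1) * 24))
  expect_true(all(counts$n == 4))
  expect_true(all(counts$ok))
})

test_that("interview states equal the latent trajectory at those months", {
  truth <- generate_panel(synthetic_config(n_individuals = 200, seed = 12))
  traj <- truth$trajectories
  alive <- truth$panel[truth$panel$vital == "alive", ]
  idx <- as.integer(sub("P", "", alive$person_id))
  for (r in seq_len(nrow(alive))) {
    tr <- traj[[idx[r]]]
    expect_identical(alive$state[r], tr$states[alive$obs_month[r] + 1L])
  }
})

test_that("death is absorbing in the panel and exactly dated", {
  truth <- generate_panel(synthetic_config(n_individuals = 400, seed = 13))
  by_p <- split(truth$panel, truth$panel$person_id)
  for (rec in by_p) {
    rec <- rec[order(rec$obs_month), ]
    if (any(rec$vital == "dead")) {
      expect_identical(rec$vital[nrow(rec)], "dead")
      expect_identical(sum(rec$vital == "dead"), 1L)
      expect_identical(rec$obs_month[nrow(rec)], rec$death_month[nrow(rec)])
      tr <- truth$trajectories[[as.integer(sub("P", "", rec$person_id[1]))]]
      expect_identical(tr$states[length(tr$states)], 3L)
      expect_identical(rec$death_month[nrow(rec)],
                       as.integer(length(tr$states) - 1L))
    }
  }
})

test_that("one-month transition frequencies match the kernel probabilities", {
  k <- transition_kernel(example_params("female"))
  age <- 780
  z <- 1
  n <- 50000
  M <- monthly_matrix(k, age, z)
  set.seed(55)
  ends <- vapply(seq_len(n), function(i) {
    simulate_trajectory(k, age, 1, z, age + 1)[2]
  }, integer(1))
  for (s1 in 1:3) {
    p <- M[1, s1]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(ends == s1) - p), 3 * se + 1e-12)
  }
})

test_that("a no-mortality variant reaches the two-state stationary share", {
  # monthly onset 0.01 and recovery 0.02 give stationary depressed share 1/3
  k <- two_state_kernel(0.01, 0.02)
  cfg <- synthetic_config(
    n_individuals = 2000, seed = 77,
    true_params = list(female = k$params, male = k$params)
  )
  truth <- generate_panel(cfg)
  last_wave <- truth$panel[truth$panel$obs_month >= 60, ]
  share <- mean(last_wave$state == 2)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(last_wave))
  expect_lt(abs(share - 1 / 3), 3 * se)
})

test_that("CESD item mode reproduces the latent state exactly on scoring", {
  truth <- generate_panel(synthetic_config(n_individuals = 150, seed = 21,
                                           cesd_mode = "items"))
  alive <- truth$panel[truth$panel$vital == "alive", ]
  expect_true(all(is.na(alive$state)))
  scored <- score_cesd(alive[paste0("cesd", 1:8)])
  idx <- as.integer(sub("P", "", alive$person_id))
  latent <- vapply(seq_len(nrow(alive)), function(r) {
    truth$trajectories[[idx[r]]]$states[alive$obs_month[r] + 1L]
  }, integer(1))
  expect_identical(scored, latent)
})

test_that("the truth sidecar round-trips config and parameters", {
  truth <- generate_panel(synthetic_config(n_individuals = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_sidecar(truth, path)
  back <- yaml::read_yaml(path)
  expect_identical(back$seed, 3L)
  expect_equal(unlist(back$true_params$female),
               setNames(as.numeric(example_params("female")),
                        names(example_params("female"))))
})
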