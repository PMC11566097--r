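test_that("constant-survival life expectancy matches the geometric closed form", {
  s <- 0.99
  k <- constant_survival_kernel(s)
  occ <- suppressWarnings(occupancy_curve(k, 600, 1, 0, max_age = 600 + 3000))
  e <- state_expectancies(occ)
  expect_equal(e$e_total, (s / (1 - s) + 0.5) / 12, tolerance = 1e-8)
  expect_equal(e$e_dep, 0, tolerance = 1e-12)
})

test_that("occupancy limits: certain death and frozen kernels", {
  occ <- occupancy_curve(certain_death_kernel(), 700, 1, 0, max_age = 760)
  expect_identical(occ$p_dead[-1], rep(1, 60))
  expect_warning(
    occ2 <- occupancy_curve(frozen_kernel(), 700, 2, 0, max_age = 760),
    "leakage")
  expect_identical(occ2$p_dep, rep(1, 61))
  expect_equal(attr(occ2, "leakage"), 1)
})

test_that("occupancy equals brute-force path sums for short horizons", {
  k <- random_kernel(61)
  occ <- suppressWarnings(occupancy_curve(k, 800, 2, 1, max_age = 806))
  for (t in 1:6) {
    for (j in 1:3) {
      expect_equal(unlist(occ[t + 1, j + 1], use.names = FALSE),
                   brute_interval_prob(k, 800, 800 + t, 1, 2, j),
                   tolerance = 1e-10)
    }
  }
})

test_that("death occupancy is monotone and rows stay distributions", {
  k <- transition_kernel(example_params("male"))
  occ <- occupancy_curve(k, 650, 1, 1)
  expect_true(all(diff(occ$p_dead) >= -1e-15))
  expect_equal(occ$p_nondep + occ$p_dep + occ$p_dead,
               rep(1, nrow(occ)), tolerance = 1e-10)
})

test_that("implied prevalence reaches the two-state stationary distribution", {
  k <- two_state_kernel(0.01, 0.02)
  prev <- implied_prevalence(k, 0, target_ages = 840, base_age = 840 - 1800)
  expect_equal(prev$prev_dep, 0.01 / 0.03, tolerance = 1e-8)
  # no onset at all: the depressed share is zero from a non-depressed start
  k0 <- two_state_kernel(1e-22, 0.02)
  prev0 <- implied_prevalence(k0, 0, 840, on_fail = "first_init")
  expect_equal(prev0$prev_dep, 0, tolerance = 1e-10)
})

test_that("implied prevalence is initialisation-independent after burn-in", {
  k <- transition_kernel(example_params("female"))
  targets <- seq(600, 960, 60)
  p1 <- depmslt:::cpp_prevalence(k$params, 1, 0L, as.integer(targets), 1L,
                                 k$age_center, k$age_scale,
                                 k$age_range[1], k$age_range[2])
  p2 <- depmslt:::cpp_prevalence(k$params, 1, 0L, as.integer(targets), 2L,
                                 k$age_center, k$age_scale,
                                 k$age_range[1], k$age_range[2])
  expect_lt(max(abs(p1 - p2)), 1e-8)
  prev <- implied_prevalence(k, 1, targets)
  expect_true(all(prev$prev_dep >= 0 & prev$prev_dep <= 1))
})

test_that("weighted expectancies are the prevalence-weighted mixtures", {
  ex <- tibble::tibble(age_months = 600, e11 = 2, e12 = 1, e21 = 1, e22 = 2)
  w <- weighted_expectancies(ex, 0.5)
  expect_equal(w$dep_fle, 1.5)
  expect_equal(w$dep_le, 1.5)
  expect_equal(w$tle, 3)
  # degenerate weights recover the conditionals
  expect_equal(weighted_expectancies(ex, 0)$dep_fle, ex$e11)
  expect_equal(weighted_expectancies(ex, 1)$dep_le, ex$e22)
  expect_error(weighted_expectancies(ex, tibble::tibble(age_months = 612,
                                                        prev_dep = 0.2)),
               "600")
})

test_that("analytic expectancies agree with the microsimulation oracle", {
  k <- transition_kernel(example_params("female"))
  for (origin in 1:2) {
    e <- cbind(depmslt:::cpp_expectancies(k$params, 600L, 1, 1320L,
                                          k$age_center, k$age_scale,
                                          k$age_range[1], k$age_range[2]))
    analytic <- if (origin == 1) e[1:2] else e[3:4]
    set.seed(origin)
    ms <- microsim_expectancy(k, 600, origin, 1, n_paths = 20000)
    expect_lt(abs(ms$years[1] - analytic[1]), 3 * ms$se[1])
    expect_lt(abs(ms$years[2] - analytic[2]), 3 * ms$se[2])
  }
})

test_that("life tables are additive with valid proportions and uncertainty", {
  truth <- generate_panel(synthetic_config(n_individuals = 1200, seed = 321,
                                           p_female = 1))
  pairs <- extract_pairs(apply_inclusion_filters(truth$panel))
  fit <- fit_transitions(pairs)
  lt <- suppressWarnings(life_table(fit, z = 0, B = 150, seed = 99))
  expect_s3_class(lt, "mslt_lifetable")
  expect_equal(lt$tle, lt$dep_fle + lt$dep_le, tolerance = 1e-9)
  wt <- lt[lt$origin == "weighted", ]
  expect_true(all(wt$prev_dep >= 0 & wt$prev_dep <= 1))
  expect_true(all(lt$dep_fle >= 0 & lt$dep_le >= 0))
  expect_true(all(lt$se_tle > 0))
  expect_true(all(lt$ci_lo_tle < lt$tle & lt$tle < lt$ci_hi_tle))
  # remaining-life consistency across start ages (weighted rows)
  expect_true(all(diff(wt$tle) < 0))
  expect_true(all(wt$tle[-nrow(wt)] < wt$tle[-1] + 5))
})

test_that("raising a death rate never increases total life expectancy", {
  for (seed in c(71, 72, 73)) {
    k <- random_kernel(seed)
    e0 <- depmslt:::cpp_expectancies(k$params, 600L, 0, 1320L, k$age_center,
                                     k$age_scale, k$age_range[1],
                                     k$age_range[2])
    for (idx in c("1->3:intercept", "2->3:intercept")) {
      p2 <- k$params
      p2[idx] <- p2[idx] + 0.5
      k2 <- transition_kernel(p2)
      e1 <- depmslt:::cpp_expectancies(k2$params, 600L, 0, 1320L,
                                       k$age_center, k$age_scale,
                                       k$age_range[1], k$age_range[2])
      expect_lte(e1[1] + e1[2], e0[1] + e0[2] + 1e-12)
      expect_lte(e1[3] + e1[4], e0[3] + e0[4] + 1e-12)
    }
  }
})

test_that("degenerate covariance collapses bootstrap intervals to points", {
  truth <- generate_panel(synthetic_config(n_individuals = 600, seed = 3210,
                                           p_female = 1))
  pairs <- extract_pairs(apply_inclusion_filters(truth$panel))
  fit <- fit_transitions(pairs)
  fit$covariance[] <- 0
  lt <- suppressWarnings(life_table(fit, z = 0, start_ages_years = 50,
                                    B = 100, seed = 1))
  expect_equal(lt$se_tle, rep(0, 3), tolerance = 1e-12)
  expect_equal(lt$ci_lo_tle, lt$tle, tolerance = 1e-12)
})
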