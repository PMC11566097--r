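# 100-rep reduced study under a covariate-null truth, shared by the
# coverage and false-rejection acceptance checks (computed once, memoised)
coverage_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    truth <- example_params("female")
    truth[grep(":cov$", names(truth))] <- 0
    truth_kernel <- transition_kernel(truth)

    # true weighted TLE at age 50 under the null truth
    prev <- implied_prevalence(truth_kernel, 0, 600)$prev_dep
    e <- depmslt:::cpp_expectancies(truth_kernel$params, 600L, 0, 1320L,
                                    840, 120, 600, 1320)
    tle_true <- (1 - prev) * (e[1] + e[2]) + prev * (e[3] + e[4])

    n_reps <- 100
    covered <- matrix(NA, n_reps, 12)
    rejected <- matrix(NA, n_reps, 4)
    tle_covered <- rep(NA, n_reps)
    gamma_idx <- grep(":cov$", names(truth))
    for (r in seq_len(n_reps)) {
      cfg <- synthetic_config(n_individuals = 800, seed = 40000 + r,
                              p_female = 1,
                              true_params = list(female = truth,
                                                 male = truth))
      sim <- generate_panel(cfg)
      pairs <- extract_pairs(apply_inclusion_filters(sim$panel))
      fit <- fit_transitions(pairs)
      td <- tidy(fit)
      covered[r, ] <- abs(td$estimate - as.numeric(truth)) <=
        1.96 * td$std.error
      rejected[r, ] <- abs(td$statistic[gamma_idx]) > 1.96
      lt <- suppressWarnings(
        life_table(fit, z = 0, start_ages_years = 50, B = 200,
                   seed = 50000 + r))
      wt <- lt[lt$origin == "weighted", ]
      tle_covered[r] <- wt$ci_lo_tle <= tle_true && tle_true <= wt$ci_hi_tle
    }
    cache <<- list(truth = truth, tle_true = tle_true,
                   param_coverage = colMeans(covered),
                   gamma_rejection = colMeans(rejected),
                   tle_coverage = mean(tle_covered))
    cache
  }
})
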