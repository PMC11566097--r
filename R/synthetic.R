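#' Reference parameter sets for the synthetic population
#'
#' Monthly-transition parameters (on the conditioned scale of the default
#' kernel: age centred at 70 years, scaled per decade) chosen to emulate an
#' ageing-survey population aged 50+: depression onset rising with age and
#' higher among the widowed and among women, recovery falling with age,
#' Gompertz-like mortality that is higher from the depressed state, higher
#' for men, and higher among the widowed.
#'
#' @param sex `"female"` or `"male"`.
#' @return A named length-12 parameter vector (see [mslt_params()]).
#' @examples
#' transition_kernel(example_params("female"))
#' @export
example_params <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female") {
    mslt_params(intercepts  = c(-5.3, -6.6, -3.5, -5.9),
                age_slopes  = c(0.30, 1.10, -0.30, 1.10),
                cov_effects = c(0.70, 0.05, -0.20, 0.10))
  } else {
    mslt_params(intercepts  = c(-5.8, -6.2, -3.3, -5.5),
                age_slopes  = c(0.30, 1.10, -0.30, 1.10),
                cov_effects = c(1.05, 0.40, -0.20, 0.45))
  }
}

#' Configuration of the synthetic panel generator
#'
#' Defines the study conditions the generator emulates: a biennial panel
#' over four waves (a 7-year window), entry ages 50+, a time-constant
#' binary covariate (married / widowed), depression states scored from
#' CESD-8 with cutoff 3, occasional missed waves, and exactly dated deaths.
#'
#' @param n_individuals Number of persons.
#' @param entry_age_range Entry-age range in months, minimum 600 (age 50).
#' @param wave_spacing Months between scheduled waves (default 24).
#' @param n_waves Number of scheduled waves (default 4).
#' @param wave_jitter_sd SD in months of the integer scheduling jitter of
#'   waves after the first (default 2); intervals are kept >= 1 month.
#' @param p_missed_wave Probability that a non-first wave is missed
#'   (default 0.05), independently per wave.
#' @param covariate_prevalence Probability that `z = 1` (widowed); default
#'   0.23.
#' @param p_female Probability a person is female (default 0.546).
#' @param true_params Either a single length-12 parameter vector (one sex)
#'   or a named list `list(female =, male =)`; default [example_params()]
#'   for both sexes.
#' @param cesd_mode `"state"` writes the latent state directly; `"items"`
#'   writes 8 CESD items whose score reproduces the latent state exactly
#'   (depressed: uniform score 3--8; not depressed: uniform 0--2).
#' @param entry_state `"prevalence"` draws the entry state from the
#'   kernel's implied prevalence at entry age; `"nondepressed"` starts
#'   everyone in state 1.
#' @param seed Integer seed; every draw of the generator flows through it.
#' @param age_center,age_scale,age_range Kernel conditioning, see
#'   [transition_kernel()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_individuals = 1000,
                             entry_age_range = c(600, 1080),
                             wave_spacing = 24, n_waves = 4,
                             wave_jitter_sd = 2, p_missed_wave = 0.05,
                             covariate_prevalence = 0.23,
                             p_female = 0.546,
                             true_params = NULL,
                             cesd_mode = c("state", "items"),
                             entry_state = c("prevalence", "nondepressed"),
                             seed = 1L,
                             age_center = 840, age_scale = 120,
                             age_range = c(600, 1320)) {
  cesd_mode <- match.arg(cesd_mode)
  entry_state <- match.arg(entry_state)
  if (entry_age_range[1] < 600) stop("entry_age_range minimum is 600 months (age 50)")
  if (p_missed_wave < 0 || p_missed_wave >= 1) stop("p_missed_wave must lie in [0, 1)")
  if (wave_spacing <= 0) stop("wave_spacing must be positive")
  if (n_individuals < 1) stop("n_individuals must be at least 1")
  if (is.null(true_params)) {
    true_params <- list(female = example_params("female"),
                        male = example_params("male"))
  }
  if (is.numeric(true_params)) {
    true_params <- list(female = true_params, male = true_params)
  }
  stopifnot(all(c("female", "male") %in% names(true_params)))
  structure(
    list(n_individuals = n_individuals, entry_age_range = entry_age_range,
         wave_spacing = wave_spacing, n_waves = n_waves,
         wave_jitter_sd = wave_jitter_sd, p_missed_wave = p_missed_wave,
         covariate_prevalence = covariate_prevalence, p_female = p_female,
         true_params = true_params, cesd_mode = cesd_mode,
         entry_state = entry_state, seed = as.integer(seed),
         age_center = age_center, age_scale = age_scale,
         age_range = age_range),
    class = "synthetic_config"
  )
}

config_kernel <- function(config, sex) {
  transition_kernel(config$true_params[[sex]],
                    age_center = config$age_center,
                    age_scale = config$age_scale,
                    age_range = config$age_range)
}

#' Simulate one latent monthly state trajectory
#'
#' Draws each monthly step from the kernel row of the current state,
#' stopping at death (state 3) or at `max_age`.
#'
#' @inheritParams monthly_matrix
#' @param start_age Age in months at the start.
#' @param start_state Living state 1 or 2.
#' @param max_age Final age in months.
#' @return Integer vector of states at ages `start_age, start_age + 1, ...`
#'   ending at absorption or `max_age`.
#' @export
simulate_trajectory <- function(kernel, start_age, start_state, z, max_age) {
  stopifnot(inherits(kernel, "mslt_kernel"))
  if (!start_state %in% 1:2) stop("start_state must be a living state (1 or 2)")
  stopifnot(max_age >= start_age)
  cpp_simulate_path(kernel$params, as.integer(start_age),
                    as.integer(start_state), as.numeric(z),
                    as.integer(max_age), kernel$age_center, kernel$age_scale,
                    kernel$age_range[1], kernel$age_range[2])
}

# draw CESD-8 items consistent with a latent state: the scored state
# (sum >= 3 -> depressed) reproduces the latent state with probability 1
draw_cesd_items <- function(states) {
  n <- length(states)
  score <- ifelse(states == 2L, sample(3:8, n, replace = TRUE),
                  sample(0:2, n, replace = TRUE))
  items <- matrix(0L, n, 8)
  for (i in seq_len(n)) {
    if (score[i] > 0) items[i, sample.int(8, score[i])] <- 1L
  }
  colnames(items) <- paste0("cesd", 1:8)
  items
}

#' Generate an interval-censored synthetic panel
#'
#' For each person: entry age, sex and covariate are drawn; a latent
#' monthly trajectory is simulated from the true kernel; interviews are
#' scheduled every `wave_spacing` months with integer jitter, each
#' non-first wave independently missed with `p_missed_wave`; interviews
#' record the latent state (or CESD-8 items scoring to it); a death inside
#' the follow-up window yields one final exactly dated death record.
#' Reproducible: the same config (including seed) yields an identical
#' panel.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_truth` list: `panel` (tibble in the [read_panel()]
#'   column contract), `config`, `params_true`, and `trajectories` (per
#'   person: start age, sex, z, latent monthly states) retained for tests.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  entry_age <- sample(seq(config$entry_age_range[1], config$entry_age_range[2]),
                      n, replace = TRUE)
  sex <- ifelse(runif(n) < config$p_female, "female", "male")
  z <- as.integer(runif(n) < config$covariate_prevalence)
  follow_up <- (config$n_waves - 1) * config$wave_spacing

  kernels <- list(female = config_kernel(config, "female"),
                  male = config_kernel(config, "male"))

  # entry-state distribution from the implied prevalence at entry age
  entry_state <- rep(1L, n)
  if (config$entry_state == "prevalence") {
    for (s in c("female", "male")) {
      for (zz in 0:1) {
        idx <- which(sex == s & z == zz)
        if (!length(idx)) next
        ages <- sort(unique(entry_age[idx]))
        prev <- implied_prevalence(kernels[[s]], z = zz, target_ages = ages)
        pv <- prev$prev_dep[match(entry_age[idx], prev$age_months)]
        entry_state[idx] <- ifelse(runif(length(idx)) < pv, 2L, 1L)
      }
    }
  }

  obs_l <- vector("list", n)
  state_l <- vector("list", n)
  vital_l <- vector("list", n)
  death_l <- vector("list", n)
  nrec <- integer(n)
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    k <- kernels[[sex[i]]]
    # wave schedule in months since entry; first wave at 0, no jitter
    sched <- (seq_len(config$n_waves) - 1L) * config$wave_spacing
    if (config$wave_jitter_sd > 0 && config$n_waves > 1) {
      jit <- as.integer(round(rnorm(config$n_waves - 1, 0, config$wave_jitter_sd)))
      sched[-1] <- sched[-1] + jit
      # keep interviews strictly increasing with gaps >= 1 month
      for (w in 2:config$n_waves) sched[w] <- max(sched[w], sched[w - 1] + 1L)
    }
    end_month <- sched[config$n_waves]
    missed <- c(FALSE, runif(config$n_waves - 1) < config$p_missed_wave)

    path <- simulate_trajectory(k, entry_age[i], entry_state[i], z[i],
                                entry_age[i] + end_month)
    trajectories[[i]] <- list(start_age = entry_age[i], sex = sex[i],
                              z = z[i], states = path)
    death_offset <- if (path[length(path)] == 3L) length(path) - 1L else NA_integer_

    keep <- !missed & (is.na(death_offset) | sched < death_offset)
    obs <- sched[keep]
    st <- path[obs + 1L]
    vt <- rep("alive", length(obs))
    dm <- rep(NA_integer_, length(obs))
    if (!is.na(death_offset)) {
      obs <- c(obs, death_offset)
      st <- c(st, 3L)
      vt <- c(vt, "dead")
      dm <- c(dm, death_offset)
    }
    obs_l[[i]] <- obs
    state_l[[i]] <- st
    vital_l[[i]] <- vt
    death_l[[i]] <- dm
    nrec[i] <- length(obs)
  }
  idx <- rep.int(seq_len(n), nrec)
  panel <- tibble::tibble(
    person_id = sprintf("P%05d", idx),
    sex = sex[idx], z = z[idx],
    birth_month = -entry_age[idx],  # entry interview at calendar month 0
    obs_month = as.integer(unlist(obs_l)),
    vital = unlist(vital_l),
    death_month = as.integer(unlist(death_l)),
    state = as.integer(unlist(state_l))
  )

  if (config$cesd_mode == "items") {
    alive <- panel$vital == "alive"
    items <- draw_cesd_items(panel$state[alive])
    for (j in 1:8) {
      panel[[paste0("cesd", j)]] <- NA_integer_
      panel[[paste0("cesd", j)]][alive] <- items[, j]
    }
    panel$state[alive] <- NA_integer_
  }

  structure(
    list(panel = panel, config = config, params_true = config$true_params,
         trajectories = trajectories),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", x$config$n_individuals, "persons,",
      x$config$n_waves, "waves,", nrow(x$panel), "records\n")
  invisible(x)
}

#' Write the truth sidecar of a synthetic panel
#'
#' Stores the generating configuration and true parameters next to the
#' panel CSV as structured text (YAML), so a recovery analysis can be
#' re-run from files alone.
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @export
write_truth_sidecar <- function(truth, path) {
  cfg <- truth$config
  cfg$true_params <- lapply(cfg$true_params, function(p) as.list(setNames(as.numeric(p), names(p))))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Monte-Carlo microsimulation of state expectancies
#'
#' Simulates `n_paths` monthly trajectories and returns the mean years
#' lived in each living state, with Monte-Carlo standard errors.  Months
#' are weighted by the trapezoid convention (half credit for the first and
#' last month of the window), so the estimator is unbiased for the
#' analytic [state_expectancies()] and the two living-state occupancies add
#' to total survival time path by path.
#'
#' @inheritParams simulate_trajectory
#' @param n_paths Number of simulated paths.
#' @return A tibble with one row per living state: `state`, `years`
#'   (mean), `se` (Monte-Carlo standard error), plus a `total` row.
#' @export
microsim_expectancy <- function(kernel, start_age, start_state, z,
                                n_paths = 1e5, max_age = 1320) {
  stopifnot(inherits(kernel, "mslt_kernel"), n_paths >= 1)
  if (!start_state %in% 1:2) stop("start_state must be a living state (1 or 2)")
  occ <- cpp_microsim(kernel$params, as.integer(start_age),
                      as.integer(start_state), as.numeric(z),
                      as.integer(n_paths), as.integer(max_age),
                      kernel$age_center, kernel$age_scale,
                      kernel$age_range[1], kernel$age_range[2])
  yrs <- occ / 12
  tot <- rowSums(yrs)
  tibble::tibble(
    state = c("nondepressed", "depressed", "total"),
    years = c(mean(yrs[, 1]), mean(yrs[, 2]), mean(tot)),
    se = c(sd(yrs[, 1]), sd(yrs[, 2]), sd(tot)) / sqrt(n_paths)
  )
}
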