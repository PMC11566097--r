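# Independent oracles and fixtures shared across the suite.

# Brute-force interval transition probability by exhaustive enumeration of
# intermediate state sequences (independent of the matrix-product code).
brute_interval_prob <- function(kernel, age_start, age_end, z, s0, s1) {
  h <- age_end - age_start
  if (h == 0) return(as.numeric(s0 == s1))
  monthlies <- lapply(seq(age_start, age_end - 1), function(a) {
    monthly_matrix(kernel, a, z)
  })
  total <- 0
  # state sequences between the fixed endpoints
  mids <- if (h == 1) list(integer(0)) else {
    do.call(expand.grid, rep(list(1:3), h - 1)) |> asplit(1)
  }
  for (mid in mids) {
    states <- c(s0, as.integer(mid), s1)
    p <- 1
    for (t in seq_len(h)) p <- p * monthlies[[t]][states[t], states[t + 1]]
    total <- total + p
  }
  total
}

# random kernel with plausible magnitudes, reproducible by seed
random_kernel <- function(seed, zero_cov = FALSE) {
  set.seed(seed)
  transition_kernel(mslt_params(
    intercepts = runif(4, -7, -2),
    age_slopes = runif(4, -0.5, 1.2),
    cov_effects = if (zero_cov) rep(0, 4) else runif(4, -0.5, 0.8)
  ))
}

# kernel with no depression transitions and constant monthly survival s
constant_survival_kernel <- function(s) {
  transition_kernel(mslt_params(
    intercepts = c(-50, log((1 - s) / s), -50, log((1 - s) / s))
  ))
}

# kernel with certain death every month from both living states
certain_death_kernel <- function() {
  transition_kernel(mslt_params(intercepts = c(-50, 50, -50, 50)))
}

# kernel with no transitions at all (self-transition ~ 1)
frozen_kernel <- function() {
  transition_kernel(mslt_params(intercepts = rep(-50, 4)))
}

# time-homogeneous two-living-state kernel with monthly onset p12 and
# recovery p21 and no mortality
two_state_kernel <- function(p12, p21) {
  transition_kernel(mslt_params(
    intercepts = c(log(p12 / (1 - p12)), -50, log(p21 / (1 - p21)), -50)
  ))
}

# five-person toy panel: one under age 50 at entry, one marital changer,
# one with missing depression state at the entry wave, two clean persons
toy_filter_panel <- function() {
  rec <- function(id, z, birth, obs, state, vital = "alive",
                  death = NA_integer_) {
    tibble::tibble(person_id = id, sex = "female", z = as.integer(z),
                   birth_month = as.integer(birth),
                   obs_month = as.integer(obs), vital = vital,
                   death_month = as.integer(death), state = state)
  }
  dplyr::bind_rows(
    rec("underage", 0L, -588, c(0, 24), c(1L, 1L)),          # age 49 at entry
    rec("changer", c(0L, 1L), -700, c(0, 24), c(1L, 2L)),    # z flips
    rec("nobase", 0L, -720, c(0, 24), c(NA_integer_, 1L)),   # entry state missing
    rec("cleanA", 0L, -720, c(0, 24, 48), c(1L, 1L, 2L)),
    dplyr::bind_rows(rec("cleanB", 1L, -780, c(0, 24), c(1L, 2L)),
                     rec("cleanB", 1L, -780, 30, 3L, vital = "dead",
                         death = 30L))
  )
}
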