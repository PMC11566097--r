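#' Monthly occupancy probabilities from one starting state
#'
#' Propagates the starting state forward through the monthly matrices:
#' row `start_state` of the interval matrix from `start_age` to each later
#' age.  The death column is monotone non-decreasing.  If survival at
#' `max_age` exceeds 1e-6 a closure-leakage warning is raised and recorded
#' in the `"leakage"` attribute.
#'
#' @inheritParams monthly_matrix
#' @param start_age Starting age in months.
#' @param start_state Living state 1 or 2.
#' @param max_age Closure age in months (default 1320, age 110).
#' @return A tibble `age_months, p_nondep, p_dep, p_dead` with attributes
#'   `start_state` and `leakage` (survival probability at closure).
#' @export
occupancy_curve <- function(kernel, start_age, start_state, z,
                            max_age = 1320) {
  stopifnot(inherits(kernel, "mslt_kernel"))
  if (!start_state %in% 1:2) stop("start_state must be a living state (1 or 2)")
  occ <- cpp_occupancy(kernel$params, as.integer(start_age),
                       as.integer(start_state), as.numeric(z),
                       as.integer(max_age), kernel$age_center,
                       kernel$age_scale, kernel$age_range[1],
                       kernel$age_range[2])
  leak <- 1 - occ[nrow(occ), 3]
  if (leak > 1e-6) {
    warning(sprintf("closure leakage: survival %.2e at age %d months",
                    leak, max_age))
  }
  out <- tibble::tibble(
    age_months = seq(start_age, max_age),
    p_nondep = occ[, 1], p_dep = occ[, 2], p_dead = occ[, 3]
  )
  attr(out, "start_state") <- start_state
  attr(out, "leakage") <- leak
  class(out) <- c("mslt_occupancy", class(out))
  out
}

#' State expectancies from occupancy curves
#'
#' Trapezoidal sum over months of the occupancy probability of each living
#' state (half credit for the first and last month), divided by 12.
#'
#' @param occupancy An occupancy tibble from [occupancy_curve()].
#' @return A one-row tibble `e_nondep, e_dep, e_total` in years.
#' @export
state_expectancies <- function(occupancy) {
  stopifnot(all(c("p_nondep", "p_dep") %in% names(occupancy)))
  n <- nrow(occupancy)
  w <- c(0.5, rep(1, max(n - 2, 0)), if (n > 1) 0.5)
  e1 <- sum(w * occupancy$p_nondep) / 12
  e2 <- sum(w * occupancy$p_dep) / 12
  tibble::tibble(e_nondep = e1, e_dep = e2, e_total = e1 + e2)
}

#' Implied (period) prevalence of depression
#'
#' Runs the fitted chain forward from a base age, renormalising the state
#' distribution among the living each month, and reports the depressed
#' share at the target ages.  After the burn-in the result is independent
#' of the initial distribution; both extreme initialisations are computed
#' and an error is raised if they disagree beyond 1e-8 at any target.
#'
#' @inheritParams monthly_matrix
#' @param target_ages Integer ages (months) at which to report.
#' @param burn_in Months of burn-in before the first target (default 600:
#'   long enough for the two extreme initialisations to agree to 1e-8 at
#'   plausible onset and recovery rates); doubled automatically, up to
#'   64-fold, when the fitted rates mix more slowly.
#' @param base_age Start of the propagation; overrides the adaptive
#'   burn-in (matrices below the supported age range are evaluated at the
#'   range boundary).
#' @param tol Maximum tolerated disagreement between the two
#'   initialisations at the target ages (default 1e-8).
#' @param on_fail What to do when the initialisations still disagree:
#'   `"error"` (default) or `"first_init"`, which returns the propagation
#'   started all non-depressed (used for parametric-bootstrap draws whose
#'   onset rate can be degenerate).
#' @return A tibble `age_months, prev_dep`.
#' @export
implied_prevalence <- function(kernel, z, target_ages, burn_in = 600,
                               base_age = NULL, tol = 1e-8,
                               on_fail = c("error", "first_init")) {
  on_fail <- match.arg(on_fail)
  stopifnot(inherits(kernel, "mslt_kernel"), length(target_ages) >= 1)
  target_ages <- as.integer(sort(unique(target_ages)))
  if (!is.null(base_age) && base_age > min(target_ages)) {
    stop("base_age must not exceed the first target age")
  }
  run <- function(base) {
    lapply(1:2, function(init) {
      cpp_prevalence(kernel$params, as.numeric(z), as.integer(base),
                     target_ages, as.integer(init), kernel$age_center,
                     kernel$age_scale, kernel$age_range[1],
                     kernel$age_range[2])
    })
  }
  if (!is.null(base_age)) {
    pv <- run(base_age)
    gap <- max(abs(pv[[1]] - pv[[2]]))
  } else {
    # weakly mixing kernels (low onset + recovery rates) need a longer
    # burn-in; double it until the two initialisations agree
    bi <- burn_in
    repeat {
      pv <- run(min(target_ages) - bi)
      gap <- max(abs(pv[[1]] - pv[[2]]))
      if (gap <= tol || bi >= 64 * burn_in) break
      bi <- 2 * bi
    }
  }
  if (gap > tol && on_fail == "error") {
    stop("implied prevalence did not mix: initialisations disagree by ",
         format(gap), "; increase burn_in")
  }
  tibble::tibble(age_months = target_ages, prev_dep = pv[[1]])
}

#' Prevalence-weighted expectancies
#'
#' Weights the origin-conditional expectancies by the depressed share at
#' each starting age:
#' \eqn{e^{\cdot j}(x) = (1-\pi_2(x))\,e^{1j}(x) + \pi_2(x)\,e^{2j}(x)};
#' Dep-FLE is \eqn{e^{\cdot 1}}, DepLE \eqn{e^{\cdot 2}}, TLE their sum.
#'
#' @param expectancies Tibble with columns `age_months, e11, e12, e21, e22`
#'   (origin-conditional years in each state).
#' @param prevalence Either a numeric vector of depressed shares aligned
#'   with the rows, or a tibble `age_months, prev_dep` covering every age
#'   (an error names any missing age).
#' @return A tibble `age_months, prev_dep, dep_fle, dep_le, tle,
#'   prop_depfree`.
#' @export
weighted_expectancies <- function(expectancies, prevalence) {
  stopifnot(all(c("age_months", "e11", "e12", "e21", "e22") %in%
                  names(expectancies)))
  if (is.data.frame(prevalence)) {
    idx <- match(expectancies$age_months, prevalence$age_months)
    if (any(is.na(idx))) {
      stop("no prevalence supplied for age(s) ",
           paste(expectancies$age_months[is.na(idx)], collapse = ", "))
    }
    pi2 <- prevalence$prev_dep[idx]
  } else {
    stopifnot(length(prevalence) == nrow(expectancies))
    pi2 <- as.numeric(prevalence)
  }
  if (any(pi2 < 0 | pi2 > 1)) stop("prevalence must lie in [0, 1]")
  dplyr::transmute(
    expectancies,
    age_months = .data$age_months,
    prev_dep = pi2,
    dep_fle = (1 - pi2) * .data$e11 + pi2 * .data$e21,
    dep_le = (1 - pi2) * .data$e12 + pi2 * .data$e22,
    tle = .data$dep_fle + .data$dep_le,
    prop_depfree = .data$dep_fle / .data$tle
  )
}

# origin-conditional expectancies at each start age for one parameter vector
point_expectancies <- function(params, start_ages, z, max_age,
                               age_center, age_scale, age_range) {
  e <- t(vapply(start_ages, function(x) {
    cpp_expectancies(params, as.integer(x), as.numeric(z),
                     as.integer(max_age), age_center, age_scale,
                     age_range[1], age_range[2])
  }, numeric(4)))
  tibble::tibble(age_months = start_ages,
                 e11 = e[, 1], e12 = e[, 2], e21 = e[, 3], e22 = e[, 4])
}

lt_point <- function(params, start_ages, z, max_age, prevalence_source,
                     observed_prevalence, burn_in,
                     age_center, age_scale, age_range, strict = TRUE) {
  ex <- point_expectancies(params, start_ages, z, max_age,
                           age_center, age_scale, age_range)
  prev <- if (prevalence_source == "implied") {
    k <- transition_kernel(params, age_center, age_scale, age_range)
    implied_prevalence(k, z, start_ages, burn_in = burn_in,
                       on_fail = if (strict) "error" else "first_init")
  } else {
    observed_prevalence
  }
  wt <- weighted_expectancies(ex, prev)
  list(ex = ex, wt = wt)
}

#' Multistate life table from a fitted model
#'
#' Converts a fitted transition model into a life table at the requested
#' starting ages, for one covariate value: origin-conditional expectancies
#' (years without / with depression from each starting state), the
#' prevalence-weighted depression-free life expectancy (Dep-FLE), life
#' expectancy with depression (DepLE) and total life expectancy (TLE), and
#' parametric-bootstrap standard errors and confidence intervals.
#'
#' @param fit An `mslt_fit`.
#' @param z Covariate value (0 = married, 1 = widowed).
#' @param start_ages_years Starting ages in years (default 50 to 80 by 5).
#' @param max_age_years Closure age (default 110); survivors beyond it are
#'   ignored (a leakage warning fires if they exceed 1e-6).
#' @param prevalence `"implied"` (default) weights by the period prevalence
#'   implied by the fitted chain; `"observed"` weights by
#'   `observed_prevalence`.
#' @param observed_prevalence Tibble `age_months, prev_dep` (required when
#'   `prevalence = "observed"`).
#' @param burn_in Burn-in months for the implied prevalence (default 600).
#' @param B Parametric-bootstrap draws (default 500; set `B = 0` to skip
#'   uncertainty).
#' @param ci_level Confidence level (default 0.95).
#' @param ci_type `"normal"` (mean +/- z * SE, the default) or
#'   `"percentile"`.
#' @param seed Optional seed for the bootstrap draws.
#' @param sex Optional label stored with the result.
#' @return A tibble of class `mslt_lifetable`: one row per (starting age,
#'   origin), origin `"1"` and `"2"` for the conditional rows and
#'   `"weighted"` for the prevalence-weighted row, with columns `dep_fle,
#'   dep_le, tle, prop_depfree, prev_dep` and, when `B > 0`, `se_*` and
#'   `ci_lo_* / ci_hi_*`.  Bootstrap draws are kept in attributes for
#'   paired contrasts.
#' @export
life_table <- function(fit, z, start_ages_years = seq(50, 80, 5),
                       max_age_years = 110,
                       prevalence = c("implied", "observed"),
                       observed_prevalence = NULL, burn_in = 600,
                       B = 500, ci_level = 0.95,
                       ci_type = c("normal", "percentile"),
                       seed = NULL, sex = NULL) {
  stopifnot(inherits(fit, "mslt_fit"))
  prevalence <- match.arg(prevalence)
  ci_type <- match.arg(ci_type)
  if (prevalence == "observed" && is.null(observed_prevalence)) {
    stop("observed_prevalence must be supplied when prevalence = 'observed'")
  }
  start_ages <- as.integer(round(start_ages_years * 12))
  max_age <- as.integer(round(max_age_years * 12))

  pt <- lt_point(fit$params, start_ages, z, max_age, prevalence,
                 observed_prevalence, burn_in,
                 fit$age_center, fit$age_scale, fit$age_range)

  long <- dplyr::bind_rows(
    dplyr::transmute(pt$ex, age_months = .data$age_months, origin = "1",
                     dep_fle = .data$e11, dep_le = .data$e12,
                     tle = .data$e11 + .data$e12),
    dplyr::transmute(pt$ex, age_months = .data$age_months, origin = "2",
                     dep_fle = .data$e21, dep_le = .data$e22,
                     tle = .data$e21 + .data$e22),
    dplyr::transmute(pt$wt, age_months = .data$age_months,
                     origin = "weighted", dep_fle = .data$dep_fle,
                     dep_le = .data$dep_le, tle = .data$tle)
  )
  long <- dplyr::mutate(long, age_years = .data$age_months / 12,
                        prop_depfree = .data$dep_fle / .data$tle,
                        .after = "age_months")
  prev_col <- setNames(pt$wt$prev_dep, pt$wt$age_months)
  long$prev_dep <- ifelse(long$origin == "weighted",
                          prev_col[as.character(long$age_months)], NA_real_)

  draws_arr <- NULL
  param_draws <- NULL
  if (B > 0) {
    if (is.null(fit$covariance)) {
      stop("covariance unavailable: ", fit$covariance_note)
    }
    if (B < 100) stop("B must be at least 100 (or 0 to skip uncertainty)")
    if (!is.null(seed)) set.seed(seed)
    param_draws <- MASS::mvrnorm(B, mu = fit$params, Sigma = fit$covariance)
    measures <- c("dep_fle", "dep_le", "tle")
    draws_arr <- array(
      NA_real_, dim = c(B, nrow(long), 3),
      dimnames = list(NULL, paste(long$origin, long$age_months), measures)
    )
    for (b in seq_len(B)) {
      pb <- lt_point(param_draws[b, ], start_ages, z, max_age, prevalence,
                     observed_prevalence, burn_in,
                     fit$age_center, fit$age_scale, fit$age_range,
                     strict = FALSE)
      vals <- rbind(
        cbind(pb$ex$e11, pb$ex$e12, pb$ex$e11 + pb$ex$e12),
        cbind(pb$ex$e21, pb$ex$e22, pb$ex$e21 + pb$ex$e22),
        cbind(pb$wt$dep_fle, pb$wt$dep_le, pb$wt$tle)
      )
      draws_arr[b, , ] <- vals
    }
    zq <- qnorm(1 - (1 - ci_level) / 2)
    for (m in measures) {
      se <- as.numeric(apply(draws_arr[, , m, drop = FALSE], 2, sd))
      long[[paste0("se_", m)]] <- se
      if (ci_type == "normal") {
        long[[paste0("ci_lo_", m)]] <- long[[m]] - zq * se
        long[[paste0("ci_hi_", m)]] <- long[[m]] + zq * se
      } else {
        qs <- apply(draws_arr[, , m, drop = FALSE], 2, stats::quantile,
                    probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2))
        long[[paste0("ci_lo_", m)]] <- as.numeric(qs[1, ])
        long[[paste0("ci_hi_", m)]] <- as.numeric(qs[2, ])
      }
    }
  }

  attr(long, "z") <- z
  attr(long, "sex") <- sex
  attr(long, "draws") <- draws_arr
  attr(long, "param_draws") <- param_draws
  attr(long, "ci_level") <- ci_level
  attr(long, "fit_id") <- fit$loglik  # cheap identity check for paired draws
  class(long) <- c("mslt_lifetable", class(long))
  long
}

#' Parametric-bootstrap uncertainty for expectancies
#'
#' Convenience wrapper around [life_table()] returning only the weighted
#' expectancies with SEs and CIs; draws B parameter vectors from the
#' multivariate normal with the fitted mean and covariance and recomputes
#' the life table per draw.
#'
#' @inheritParams life_table
#' @return An `mslt_lifetable` restricted to the weighted rows.
#' @export
expectancy_uncertainty <- function(fit, z, start_ages_years = seq(50, 80, 5),
                                   B = 500, seed = NULL, ...) {
  lt <- life_table(fit, z, start_ages_years = start_ages_years, B = B,
                   seed = seed, ...)
  keep <- lt$origin == "weighted"
  out <- tibble::as_tibble(lt)[keep, ]
  for (a in c("z", "sex", "param_draws", "ci_level", "fit_id")) {
    attr(out, a) <- attr(lt, a)
  }
  attr(out, "draws") <- attr(lt, "draws")[, keep, , drop = FALSE]
  class(out) <- c("mslt_lifetable", class(out))
  out
}

#' Write a life table to CSV
#'
#' @param lifetable An `mslt_lifetable`.
#' @param path Output path.
#' @export
write_lifetable <- function(lifetable, path) {
  out <- dplyr::mutate(tibble::as_tibble(lifetable),
                       sex = attr(lifetable, "sex") %||% NA_character_,
                       z = attr(lifetable, "z"), .before = 1)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
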