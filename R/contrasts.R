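contrast_measures <- c("dep_fle", "dep_le", "tle")

check_grids <- function(a, b) {
  if (!identical(a$age_months, b$age_months) ||
      !identical(a$origin, b$origin)) {
    stop("life tables have mismatching age grids or origin rows")
  }
}

#' Sex gap table: female minus male expectancies
#'
#' Cell-wise differences (F minus M) of Dep-FLE, DepLE and TLE with
#' standard errors propagated under the independent-models assumption
#' (`se = sqrt(se_F^2 + se_M^2)`, the two sexes being fitted separately);
#' a gap is flagged significant when `|estimate| > z * se`.
#'
#' @param lt_female,lt_male `mslt_lifetable`s on matching age grids, fitted
#'   at the same covariate value.
#' @param z_crit Critical value (default `qnorm(0.975)`, two-sided 5%).
#' @return A tibble: `age_years, origin, measure, estimate, se, ci_lo,
#'   ci_hi, significant`.
#' @export
sex_gap_table <- function(lt_female, lt_male, z_crit = qnorm(0.975)) {
  check_grids(lt_female, lt_male)
  out <- purrr::map_dfr(contrast_measures, function(m) {
    est <- lt_female[[m]] - lt_male[[m]]
    se_f <- lt_female[[paste0("se_", m)]]
    se_m <- lt_male[[paste0("se_", m)]]
    se <- if (is.null(se_f) || is.null(se_m)) NA_real_ else sqrt(se_f^2 + se_m^2)
    tibble::tibble(
      age_years = lt_female$age_years, origin = lt_female$origin,
      measure = m, estimate = est, se = se,
      ci_lo = est - z_crit * se, ci_hi = est + z_crit * se,
      significant = abs(est) > z_crit * se
    )
  })
  dplyr::arrange(out, .data$measure, .data$origin, .data$age_years)
}

#' Marital gap table: widowed minus married expectancies within one sex
#'
#' Both life tables come from the same fitted model (the covariate effect
#' is within-model), so the bootstrap draws are correlated: standard errors
#' are taken from the paired draw-wise differences when both tables carry
#' draws from identical parameter draws.  Otherwise the independence
#' formula is used with a warning.
#'
#' @param lt_widowed,lt_married `mslt_lifetable`s from the same `mslt_fit`
#'   at `z = 1` and `z = 0`.
#' @inheritParams sex_gap_table
#' @return A tibble as in [sex_gap_table()].
#' @export
marital_gap_table <- function(lt_widowed, lt_married,
                              z_crit = qnorm(0.975)) {
  check_grids(lt_widowed, lt_married)
  dw <- attr(lt_widowed, "draws")
  dm <- attr(lt_married, "draws")
  paired <- !is.null(dw) && !is.null(dm) &&
    identical(attr(lt_widowed, "param_draws"), attr(lt_married, "param_draws"))
  if (!paired) {
    warning("no shared bootstrap draws; falling back to the independence SE formula")
  }
  out <- purrr::map_dfr(contrast_measures, function(m) {
    est <- lt_widowed[[m]] - lt_married[[m]]
    se <- if (paired) {
      apply(dw[, , m, drop = FALSE] - dm[, , m, drop = FALSE], 2, sd)
    } else {
      se_w <- lt_widowed[[paste0("se_", m)]]
      se_m <- lt_married[[paste0("se_", m)]]
      if (is.null(se_w) || is.null(se_m)) NA_real_ else sqrt(se_w^2 + se_m^2)
    }
    tibble::tibble(
      age_years = lt_widowed$age_years, origin = lt_widowed$origin,
      measure = m, estimate = est, se = se,
      ci_lo = est - z_crit * se, ci_hi = est + z_crit * se,
      significant = abs(est) > z_crit * se
    )
  })
  dplyr::arrange(out, .data$measure, .data$origin, .data$age_years)
}
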