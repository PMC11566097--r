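#' Plot an occupancy curve
#'
#' Stacked state-occupancy probabilities by age.
#'
#' @param object An `mslt_occupancy` from [occupancy_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mslt_occupancy <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("p_nondep", "p_dep", "p_dead"),
                              names_to = "state", values_to = "probability")
  long$state <- factor(long$state, levels = c("p_dead", "p_dep", "p_nondep"),
                       labels = c("dead", "depressed", "no depression"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_months / 12,
                                     y = .data$probability,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "age (years)", y = "occupancy probability",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a life table
#'
#' Weighted Dep-FLE, DepLE and TLE across starting ages, with confidence
#' ribbons when the table carries bootstrap uncertainty.
#'
#' @param object An `mslt_lifetable` from [life_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mslt_lifetable <- function(object, ...) {
  wt <- tibble::as_tibble(object)[object$origin == "weighted", ]
  long <- tidyr::pivot_longer(wt, cols = dplyr::all_of(c("dep_fle", "dep_le", "tle")),
                              names_to = "measure", values_to = "years")
  has_ci <- all(c("ci_lo_tle", "ci_hi_tle") %in% names(wt))
  if (has_ci) {
    lo <- tidyr::pivot_longer(wt, cols = dplyr::all_of(
      c("ci_lo_dep_fle", "ci_lo_dep_le", "ci_lo_tle")),
      names_to = "measure", values_to = "lo")
    hi <- tidyr::pivot_longer(wt, cols = dplyr::all_of(
      c("ci_hi_dep_fle", "ci_hi_dep_le", "ci_hi_tle")),
      names_to = "measure", values_to = "hi")
    long$lo <- lo$lo
    long$hi <- hi$hi
  }
  long$measure <- factor(long$measure, levels = c("tle", "dep_fle", "dep_le"),
                         labels = c("TLE", "Dep-FLE", "DepLE"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$age_years,
                                          y = .data$years,
                                          colour = .data$measure))
  if (has_ci) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$measure),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "starting age (years)", y = "remaining years",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Annual transition probabilities implied by a fitted model
#'
#' One-year transition probabilities (12-month matrix products) by age and
#' covariate value, for the four living-origin transitions.
#'
#' @param fit An `mslt_fit` (or an `mslt_kernel`).
#' @param ages_years Ages at which to evaluate (default 50 to 90).
#' @return A ggplot.
#' @export
plot_annual_transitions <- function(fit, ages_years = 50:90) {
  kernel <- if (inherits(fit, "mslt_fit")) fitted_kernel(fit) else fit
  stopifnot(inherits(kernel, "mslt_kernel"))
  grid <- tidyr::expand_grid(age = ages_years, z = 0:1)
  rows <- purrr::pmap_dfr(grid, function(age, z) {
    M <- interval_matrix(kernel, age * 12, age * 12 + 12, z)
    tibble::tibble(
      age = age, z = z,
      transition = c("onset (1->2)", "death, no depression (1->3)",
                     "recovery (2->1)", "death, depressed (2->3)"),
      probability = c(M[1, 2], M[1, 3], M[2, 1], M[2, 3])
    )
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$age, y = .data$probability,
                                     colour = factor(.data$z))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~transition, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "annual probability",
                  colour = "z (widowed)") +
    ggplot2::theme_minimal()
}
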