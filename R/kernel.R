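#' Model parameters for the monthly transition model
#'
#' Builds the 12-parameter vector of the multinomial-logit transition model
#' among the living states *no depression* (1) and *depression* (2) and the
#' absorbing state *death* (3).  For each ordered living-origin transition
#' (1\eqn{\to}2, 1\eqn{\to}3, 2\eqn{\to}1, 2\eqn{\to}3) the linear predictor
#' is
#' \deqn{\eta_{ij} = \alpha_{ij} + \beta_{ij}\,(x - c)/s + \gamma_{ij} z,}
#' where \eqn{x} is age in months, \eqn{c} and \eqn{s} the conditioning
#' centre and scale carried by the kernel, and \eqn{z} a binary covariate
#' (0 = married, 1 = widowed in the motivating application).  The reference
#' category of each origin row is staying put (\eqn{\eta_{ii} \equiv 0}).
#'
#' @param intercepts,age_slopes,cov_effects Numeric length-4 vectors in the
#'   transition order `1->2, 1->3, 2->1, 2->3`.  Age slopes are per
#'   `age_scale` months of age (per decade under the default kernel).
#' @return A named numeric vector of length 12 in the fixed ordering
#'   (transition) x (intercept, age, cov).
#' @examples
#' mslt_params(intercepts = c(-5.5, -6.7, -3.5, -6.0),
#'             age_slopes = c(0.3, 0.9, -0.3, 0.9),
#'             cov_effects = c(0.7, 0.35, -0.2, 0.35))
#' @export
mslt_params <- function(intercepts, age_slopes = rep(0, 4),
                        cov_effects = rep(0, 4)) {
  stopifnot(length(intercepts) == 4, length(age_slopes) == 4,
            length(cov_effects) == 4)
  p <- as.vector(rbind(intercepts, age_slopes, cov_effects))
  if (any(!is.finite(p))) stop("model parameters must be finite")
  setNames(p, param_names())
}

#' Transition kernel: parameters plus age conditioning
#'
#' A kernel maps (age in months, covariate z) to a 3x3 row-stochastic
#' monthly transition matrix.  Ages are conditioned internally as
#' `(age - age_center) / age_scale` so that the optimiser works on
#' comparably scaled coordinates; ages outside `age_range` are clamped to
#' the nearest boundary before evaluation (used by the prevalence burn-in
#' below the supported range and by life-table closure above it).
#'
#' @param params Length-12 parameter vector from [mslt_params()] (or any
#'   named vector in the same ordering).
#' @param age_center,age_scale Conditioning constants in months (defaults:
#'   centre at age 70, scale one decade).
#' @param age_range Supported age range in months; default 600--1320
#'   (ages 50--110).
#' @return An object of class `mslt_kernel`.
#' @export
transition_kernel <- function(params, age_center = 840, age_scale = 120,
                              age_range = c(600, 1320)) {
  stopifnot(length(params) == 12, is.numeric(params),
            length(age_range) == 2, age_range[1] < age_range[2],
            age_scale > 0)
  if (any(!is.finite(params))) stop("model parameters must be finite")
  structure(
    list(params = setNames(as.numeric(params), param_names()),
         age_center = age_center, age_scale = age_scale,
         age_range = as.numeric(age_range)),
    class = "mslt_kernel"
  )
}

#' @export
print.mslt_kernel <- function(x, ...) {
  cat("<mslt_kernel> monthly 3-state transition kernel\n")
  cat("  age centre", x$age_center, "months, scale", x$age_scale,
      "months, range", x$age_range[1], "-", x$age_range[2], "\n")
  m <- matrix(x$params, nrow = 4, byrow = TRUE,
              dimnames = list(.transitions, .terms))
  print(round(m, 4))
  invisible(x)
}

#' Monthly transition matrix at one age
#'
#' @param kernel An [transition_kernel()] object.
#' @param age Age in months.
#' @param z Covariate value, 0 or 1.
#' @return A 3x3 row-stochastic matrix; row 3 is the absorbing death row
#'   `(0, 0, 1)` exactly.
#' @examples
#' k <- transition_kernel(mslt_params(c(-2, -4, -3, -3)))
#' monthly_matrix(k, age = 840, z = 0)
#' @export
monthly_matrix <- function(kernel, age, z) {
  stopifnot(inherits(kernel, "mslt_kernel"), z %in% c(0, 1))
  p <- cpp_monthly_probs(kernel$params, as.numeric(age), as.numeric(z),
                         kernel$age_center, kernel$age_scale,
                         kernel$age_range[1], kernel$age_range[2])
  rbind(matrix(p[1, ], nrow = 2, byrow = TRUE), c(0, 0, 1))
}

#' Interval transition matrix as an ordered product of monthly matrices
#'
#' The matrix over `[age_start, age_end)` is the ordered product of the
#' monthly matrices at ages `age_start, age_start + 1, ..., age_end - 1`;
#' a zero-length interval gives the identity.
#'
#' @inheritParams monthly_matrix
#' @param age_start,age_end Integer ages in months, `age_end >= age_start`.
#' @return A 3x3 matrix.
#' @export
interval_matrix <- function(kernel, age_start, age_end, z) {
  stopifnot(age_end >= age_start)
  M <- diag(3)
  if (age_end > age_start) {
    for (a in seq(age_start, age_end - 1)) {
      M <- M %*% monthly_matrix(kernel, a, z)
    }
  }
  M
}

#' Log-likelihood contributions of transition pairs
#'
#' One contribution per pair.  A pair observed alive at both ends
#' contributes the log of the corresponding interval-matrix entry; a pair
#' ending in death in month `age_end` contributes the log probability of
#' surviving in some living state to `age_end - 1` and dying in that month.
#' Probabilities are floored at 1e-300 before the log, so structurally
#' impossible pairs surface as very large negative contributions rather
#' than `-Inf`.
#'
#' @inheritParams monthly_matrix
#' @param pairs A transition-pair data frame as produced by
#'   [extract_pairs()]: columns `age_start`, `age_end`, `state_start`,
#'   `state_end`, `z`, `is_death`.
#' @return Numeric vector of per-pair log-likelihood contributions.
#' @export
pair_loglik <- function(kernel, pairs) {
  stopifnot(inherits(kernel, "mslt_kernel"))
  req <- c("age_start", "age_end", "state_start", "state_end", "z", "is_death")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) stop("pairs is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(pairs) == 0) return(numeric(0))
  stopifnot(all(pairs$age_end > pairs$age_start),
            all(pairs$state_start %in% 1:2),
            all(pairs$is_death == (pairs$state_end == 3)))
  cpp_pair_loglik(kernel$params,
                  as.integer(pairs$age_start), as.integer(pairs$age_end),
                  as.integer(pairs$state_start), as.integer(pairs$state_end),
                  as.integer(pairs$z), as.logical(pairs$is_death),
                  kernel$age_center, kernel$age_scale,
                  as.integer(kernel$age_range[1]),
                  as.integer(kernel$age_range[2]))
}
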