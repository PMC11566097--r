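# crude-frequency initial values: per-month transition fractions, intervals
# divided by their length, converted to logits relative to staying put
crude_init <- function(pairs) {
  par <- setNames(rep(0, 12), param_names())
  for (origin in 1:2) {
    sub <- pairs[pairs$state_start == origin, , drop = FALSE]
    months <- sum(sub$age_end - sub$age_start)
    if (months == 0) next
    other <- if (origin == 1) 2L else 1L
    p_other <- max(sum(sub$state_end == other) / months, 1e-6)
    p_death <- max(sum(sub$state_end == 3L) / months, 1e-6)
    p_stay <- max(1 - p_other - p_death, 1e-6)
    if (origin == 1) {
      par["1->2:intercept"] <- log(p_other / p_stay)
      par["1->3:intercept"] <- log(p_death / p_stay)
    } else {
      par["2->1:intercept"] <- log(p_other / p_stay)
      par["2->3:intercept"] <- log(p_death / p_stay)
    }
  }
  par
}

numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- x
    e[k] <- x[k] + h
    up <- f(e)
    e[k] <- x[k] - h
    (up - f(e)) / (2 * h)
  }, numeric(1))
}

# observed information by central second differences, symmetrised
numeric_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  shift <- function(i, d) {
    y <- x
    y[i] <- y[i] + d
    y
  }
  for (i in seq_len(p)) {
    H[i, i] <- (f(shift(i, h)) - 2 * f0 + f(shift(i, -h))) / h^2
    if (i < p) {
      for (j in seq((i + 1), p)) {
        y <- x
        y[i] <- y[i] + h; y[j] <- y[j] + h; fpp <- f(y)
        y[j] <- x[j] - h; fpm <- f(y)
        y[i] <- x[i] - h; fmm <- f(y)
        y[j] <- x[j] + h; fmp <- f(y)
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h^2)
      }
    }
  }
  (H + t(H)) / 2
}

#' Fit the monthly transition model to interval-censored pairs
#'
#' Maximises the interval-censored log-likelihood of [pair_loglik()] over
#' the 12 multinomial-logit parameters by quasi-Newton (BFGS) with
#' numerically differenced gradients, then computes the parameter
#' covariance as the inverse of the observed information (central second
#' differences, symmetrised).  Fit one model per sex, as the motivating
#' analysis does: pass pre-stratified pairs (see [run_pipeline()]).
#'
#' @param pairs Transition-pair tibble from [extract_pairs()]; must carry a
#'   single sex or be intended as one stratum.
#' @param age_center,age_scale,age_range Kernel conditioning, see
#'   [transition_kernel()].
#' @param init `"crude"` (default) starts intercepts at crude per-month
#'   frequency logits with zero slopes; `"zeros"` starts everything at 0;
#'   or a length-12 numeric vector.
#' @param constrain_cov If `TRUE`, all covariate effects \eqn{\gamma} are
#'   fixed at 0 (the covariate-null model).
#' @param control Passed to [stats::optim()] on top of the defaults
#'   `maxit = 1000, reltol = 1e-10, ndeps = 1e-6`.
#' @return An object of class `mslt_fit`: estimates, covariance,
#'   log-likelihood, counts, convergence flag and optimiser metadata.
#'   Non-convergence is flagged, not thrown; a singular information matrix
#'   leaves `covariance = NULL` with a diagnostic message in
#'   `$covariance_note`.
#' @export
fit_transitions <- function(pairs, age_center = 840, age_scale = 120,
                            age_range = c(600, 1320),
                            init = c("crude", "zeros"),
                            constrain_cov = FALSE, control = list()) {
  if (nrow(pairs) == 0) stop("pairs must be non-empty")
  for (origin in 1:2) {
    if (!any(pairs$state_start == origin)) {
      stop("no observed pairs from origin state ", origin,
           "; its transition parameters are inestimable")
    }
  }
  if (is.numeric(init)) {
    start <- setNames(as.numeric(init), param_names())
    stopifnot(length(start) == 12)
  } else {
    init <- match.arg(init)
    start <- if (init == "crude") crude_init(pairs) else setNames(rep(0, 12), param_names())
  }
  free <- rep(TRUE, 12)
  if (constrain_cov) {
    free[grep(":cov$", param_names())] <- FALSE
    start[!free] <- 0
  }

  x0 <- as.integer(pairs$age_start)
  x1 <- as.integer(pairs$age_end)
  s0 <- as.integer(pairs$state_start)
  s1 <- as.integer(pairs$state_end)
  zz <- as.integer(pairs$z)
  dth <- as.logical(pairs$is_death)
  lo <- as.integer(age_range[1])
  hi <- as.integer(age_range[2])

  full <- start
  negll <- function(theta) {
    full[free] <- theta
    -sum(cpp_pair_loglik(full, x0, x1, s0, s1, zz, dth,
                         age_center, age_scale, lo, hi))
  }

  ctl <- modifyList(list(maxit = 1000, reltol = 1e-10,
                         ndeps = rep(1e-6, sum(free))), control)
  opt <- optim(start[free], negll, method = "BFGS", control = ctl)
  # polish: restart BFGS from the optimum (resets the Hessian approximation)
  opt2 <- optim(opt$par, negll, method = "BFGS", control = ctl)
  if (opt2$value < opt$value) opt <- opt2

  params <- start
  params[free] <- opt$par
  loglik <- -opt$value
  loglik0 <- -negll(start[free])

  grad <- numeric_gradient(negll, opt$par)
  converged <- opt$convergence == 0 &&
    max(abs(grad)) < 1e-5 * max(1, abs(loglik))

  info <- numeric_hessian(negll, opt$par)
  covariance <- matrix(0, 12, 12, dimnames = list(param_names(), param_names()))
  cov_note <- NULL
  cv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cv) || any(diag(cv) <= 0)) {
    covariance <- NULL
    cov_note <- "observed information is singular or not positive definite"
  } else {
    covariance[free, free] <- (cv + t(cv)) / 2
  }

  structure(
    list(params = params, covariance = covariance,
         covariance_note = cov_note, loglik = loglik,
         loglik_init = loglik0,
         n_pairs = nrow(pairs),
         n_persons = dplyr::n_distinct(pairs$person_id),
         converged = converged, max_gradient = max(abs(grad)),
         counts = opt$counts, free = free,
         age_center = age_center, age_scale = age_scale,
         age_range = age_range),
    class = "mslt_fit"
  )
}

#' Extract the transition kernel of a fitted model
#'
#' @param fit An `mslt_fit`.
#' @param params Optional replacement parameter vector (used by the
#'   parametric bootstrap).
#' @return An `mslt_kernel`.
#' @export
fitted_kernel <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "mslt_fit"))
  transition_kernel(params %||% fit$params, age_center = fit$age_center,
                    age_scale = fit$age_scale, age_range = fit$age_range)
}

#' @export
print.mslt_fit <- function(x, ...) {
  cat("<mslt_fit> interval-censored 3-state transition model\n")
  cat("  log-likelihood", format(x$loglik), "on", x$n_pairs, "pairs /",
      x$n_persons, "persons;",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(tidy(x), n = 12)
  invisible(x)
}

#' @describeIn fit_transitions Tidy the fitted parameters: one row per
#'   (transition, term) with estimate, standard error, Wald statistic and
#'   p-value.  Age slopes are per `age_scale` months of age (per decade
#'   under the default); `estimate_per_month` re-expresses them per month.
#' @param x An `mslt_fit`.
#' @param ... Unused.
#' @export
tidy.mslt_fit <- function(x, ...) {
  se <- if (is.null(x$covariance)) rep(NA_real_, 12) else sqrt(diag(x$covariance))
  out <- tibble::tibble(
    transition = rep(.transitions, each = 3),
    term = rep(.terms, 4),
    estimate = unname(x$params),
    std.error = unname(se),
    statistic = estimate / std.error,
    p.value = 2 * pnorm(-abs(statistic))
  )
  out$estimate_per_month <- ifelse(out$term == "age",
                                   out$estimate / x$age_scale, NA_real_)
  out
}

#' @describeIn fit_transitions One-row model summary.
#' @export
glance.mslt_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_pairs = x$n_pairs, n_persons = x$n_persons,
    n_parameters = sum(x$free), converged = x$converged,
    max_gradient = x$max_gradient
  )
}

#' Wald test of a linear contrast of the fitted parameters
#'
#' @param fit An `mslt_fit` with an available covariance.
#' @param contrast Numeric length-12 contrast vector (the parameter
#'   ordering of [mslt_params()]); must not be all zero.
#' @return A one-row tibble: `estimate, std.error, statistic, p.value`.
#' @export
wald_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "mslt_fit"), length(contrast) == 12)
  if (is.null(fit$covariance)) stop("covariance unavailable: ", fit$covariance_note)
  if (all(contrast == 0)) stop("contrast must not be all zero")
  est <- sum(contrast * fit$params)
  se <- sqrt(drop(t(contrast) %*% fit$covariance %*% contrast))
  z <- est / se
  tibble::tibble(estimate = est, std.error = se, statistic = z,
                 p.value = 2 * pnorm(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
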