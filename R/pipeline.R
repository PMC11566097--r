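default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_individuals = 2000),
    input = NULL,
    filters = list(min_entry_age = 600, cutoff = 3, included_items = 1:8),
    model = list(age_center = 840, age_scale = 120,
                 age_range = c(600, 1320), constrain_cov = FALSE),
    lifetable = list(start_ages_years = seq(50, 80, 5), max_age_years = 110,
                     prevalence = "implied", B = 500, burn_in = 600),
    report = list(z_crit = qnorm(0.975))
  )
}

merge_config <- function(config) {
  base <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      base[[k]] <- modifyList(base[[k]], config[[k]])
    } else {
      base[[k]] <- config[[k]]
    }
  }
  base
}

write_params_csv <- function(fit, path) {
  td <- tidy(fit)
  readr::write_csv(
    tibble::tibble(transition = td$transition, term = td$term,
                   estimate = td$estimate, se = td$std.error),
    path, na = "", progress = FALSE)
}

#' Run the full estimation pipeline
#'
#' Orchestrates simulate (or read) -> CESD scoring and filters -> pair
#' extraction -> per-sex model fits -> life tables per sex and covariate
#' value -> sex-gap and marital-gap contrast tables, persisting every
#' artifact as CSV (plus YAML reports and a run log) in `outdir`.  The two
#' life tables of one sex share parametric-bootstrap draws, so the
#' widowed-minus-married contrasts are paired.  Reruns with the same
#' config and seed produce identical CSVs.
#'
#' @param config A configuration list or path to a YAML file; unset keys
#'   fall back to defaults (see the vignette).  Keys: `seed`, `simulate`
#'   (arguments of [synthetic_config()]) or `input` (panel CSV path),
#'   `filters`, `model`, `lifetable`, `report`.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the panel, pairs, filter report, fits,
#'   life tables, contrast tables and output paths.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("mslt_run_")) {
  cfg <- merge_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      say("stage %-10s FAILED: %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    attr(res, "runtime") <- proc.time()[3] - t0
    res
  }
  say("depmslt pipeline | seed %s | R %s", cfg$seed,
      paste(R.version$major, R.version$minor, sep = "."))

  truth <- NULL
  panel <- stage("input", {
    if (!is.null(cfg$input)) {
      read_panel(cfg$input)
    } else {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      truth <- generate_panel(do.call(synthetic_config, sim_args))
      write_panel(truth$panel, file.path(outdir, "panel.csv"))
      write_truth_sidecar(truth, file.path(outdir, "truth.yaml"))
      truth$panel
    }
  })
  say("stage input      | %d records, %d persons", nrow(panel),
      dplyr::n_distinct(panel$person_id))

  filtered <- stage("prep", {
    apply_inclusion_filters(panel, min_entry_age = cfg$filters$min_entry_age,
                            included_items = cfg$filters$included_items,
                            cutoff = cfg$filters$cutoff)
  })
  freport <- filter_report(filtered)
  yaml::write_yaml(list(removed = setNames(as.list(freport$n_persons_removed),
                                           freport$rule),
                        retained = attr(freport, "n_retained")),
                   file.path(outdir, "filter_report.yaml"))
  pairs <- stage("pairs", extract_pairs(filtered))
  readr::write_csv(pairs, file.path(outdir, "pairs.csv"), progress = FALSE)
  say("stage prep       | retained %d persons, %d pairs",
      attr(freport, "n_retained"), nrow(pairs))

  sexes <- sort(unique(pairs$sex))
  fits <- list()
  lifetables <- list()
  gaps_marital <- list()
  for (s in sexes) {
    fit <- stage(paste0("fit_", s), {
      fit_transitions(pairs[pairs$sex == s, ],
                      age_center = cfg$model$age_center,
                      age_scale = cfg$model$age_scale,
                      age_range = cfg$model$age_range,
                      constrain_cov = isTRUE(cfg$model$constrain_cov))
    })
    fits[[s]] <- fit
    write_params_csv(fit, file.path(outdir, paste0("params_", s, ".csv")))
    say("stage fit_%-6s | loglik %.4f | %d pairs | converged %s", s,
        fit$loglik, fit$n_pairs, fit$converged)
    for (zz in 0:1) {
      # same seed across z within a sex: shared draws make paired contrasts
      lt <- stage(paste0("lifetable_", s, "_z", zz), {
        life_table(fit, z = zz,
                   start_ages_years = cfg$lifetable$start_ages_years,
                   max_age_years = cfg$lifetable$max_age_years,
                   prevalence = cfg$lifetable$prevalence,
                   burn_in = cfg$lifetable$burn_in,
                   B = cfg$lifetable$B,
                   seed = cfg$seed + 1000L + match(s, sexes), sex = s)
      })
      lifetables[[paste0(s, "_z", zz)]] <- lt
    }
    if (cfg$lifetable$B > 0) {
      gaps_marital[[s]] <- dplyr::mutate(
        marital_gap_table(lifetables[[paste0(s, "_z1")]],
                          lifetables[[paste0(s, "_z0")]],
                          z_crit = cfg$report$z_crit),
        sex = s, .before = 1)
    }
  }

  lt_all <- purrr::map_dfr(names(lifetables), function(nm) {
    lt <- lifetables[[nm]]
    dplyr::mutate(tibble::as_tibble(lt), sex = attr(lt, "sex"),
                  z = attr(lt, "z"), .before = 1)
  })
  readr::write_csv(lt_all, file.path(outdir, "lifetable.csv"), na = "",
                   progress = FALSE)

  gaps_sex <- NULL
  if (all(c("female", "male") %in% sexes)) {
    gaps_sex <- purrr::map_dfr(0:1, function(zz) {
      dplyr::mutate(
        sex_gap_table(lifetables[[paste0("female_z", zz)]],
                      lifetables[[paste0("male_z", zz)]],
                      z_crit = cfg$report$z_crit),
        z = zz, .before = 1)
    })
    readr::write_csv(gaps_sex, file.path(outdir, "sex_gaps.csv"), na = "",
                     progress = FALSE)
  }
  if (length(gaps_marital)) {
    readr::write_csv(dplyr::bind_rows(gaps_marital),
                     file.path(outdir, "marital_gaps.csv"), na = "",
                     progress = FALSE)
  }

  summary_path <- file.path(outdir, "summary.txt")
  write_summary(summary_path, filtered, pairs, fits, lifetables,
                gaps_sex, dplyr::bind_rows(gaps_marital))
  say("stage report     | artifacts in %s", outdir)

  invisible(list(config = cfg, outdir = outdir, truth = truth,
                 panel = panel, filtered = filtered,
                 filter_report = freport, pairs = pairs, fits = fits,
                 lifetables = lifetables, sex_gaps = gaps_sex,
                 marital_gaps = if (length(gaps_marital))
                   dplyr::bind_rows(gaps_marital) else NULL,
                 converged = all(vapply(fits, `[[`, TRUE, "converged"))))
}

write_summary <- function(path, filtered, pairs, fits, lifetables,
                          gaps_sex, gaps_marital) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("Multistate life table summary")
  w("=============================")
  w("")
  w("Observed sample (after filters)")
  smp <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(filtered, .data$person_id,
                                    .keep_all = TRUE), .data$sex),
    n = dplyr::n(), widowed_share = mean(.data$z), .groups = "drop")
  for (i in seq_len(nrow(smp))) {
    w(sprintf("  %-6s n = %5d  widowed share = %.3f", smp$sex[i],
              smp$n[i], smp$widowed_share[i]))
  }
  dep <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(filtered, .data$vital == "alive",
                                  !is.na(.data$state)), .data$sex),
    depressed_share = mean(.data$state == 2), .groups = "drop")
  for (i in seq_len(nrow(dep))) {
    w(sprintf("  %-6s observed depressed share = %.3f", dep$sex[i],
              dep$depressed_share[i]))
  }
  w("")
  w("Weighted expectancies by sex, covariate and age (years)")
  for (nm in names(lifetables)) {
    lt <- lifetables[[nm]]
    wt <- tibble::as_tibble(lt)[lt$origin == "weighted", ]
    w(sprintf("  %s (z = %d)", attr(lt, "sex"), attr(lt, "z")))
    for (i in seq_len(nrow(wt))) {
      ci <- if (!is.null(wt$se_tle)) {
        sprintf(" | TLE CI (%.1f-%.1f)", wt$ci_lo_tle[i], wt$ci_hi_tle[i])
      } else ""
      w(sprintf("    age %2.0f: Dep-FLE %6.2f  DepLE %5.2f  TLE %6.2f  prop %.3f%s",
                wt$age_years[i], wt$dep_fle[i], wt$dep_le[i], wt$tle[i],
                wt$prop_depfree[i], ci))
    }
  }
  if (!is.null(gaps_sex)) {
    w("")
    w("Sex gaps (female minus male), weighted rows")
    gs <- gaps_sex[gaps_sex$origin == "weighted", ]
    for (i in seq_len(nrow(gs))) {
      w(sprintf("  z=%d %-8s age %2.0f: %+6.2f (se %.2f)%s", gs$z[i],
                gs$measure[i], gs$age_years[i], gs$estimate[i], gs$se[i],
                ifelse(isTRUE(gs$significant[i]), " *", "")))
    }
  }
  if (!is.null(gaps_marital) && nrow(gaps_marital)) {
    w("")
    w("Marital gaps (widowed minus married), weighted rows")
    gm <- gaps_marital[gaps_marital$origin == "weighted", ]
    for (i in seq_len(nrow(gm))) {
      w(sprintf("  %-6s %-8s age %2.0f: %+6.2f (se %.2f)%s", gm$sex[i],
                gm$measure[i], gm$age_years[i], gm$estimate[i], gm$se[i],
                ifelse(isTRUE(gm$significant[i]), " *", "")))
    }
  }
  invisible(path)
}
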