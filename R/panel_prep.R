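#' Score the CESD-8 depression scale into a two-level state
#'
#' Sums the included binary items; a score at or above the cutoff classifies
#' clinically significant depressive symptoms (state 2), otherwise state 1.
#' If any included item is missing the state is missing (no prorating).
#'
#' @param items A length-8 0/1 vector, or an n x 8 matrix / data frame of
#'   items (one row per interview).
#' @param included_items Integer indices of the items entering the score;
#'   defaults to all 8.  Sensitivity analyses that drop single symptoms
#'   (e.g. feeling sad, restless sleep) pass a 7-item subset here.
#' @param cutoff Integer cutoff; score `>= cutoff` is depressed.  Must lie
#'   in `[0, length(included_items)]`.
#' @return Integer vector of states in `{1, 2}`, `NA` where any included
#'   item is missing.
#' @examples
#' score_cesd(c(1, 1, 1, 0, 0, 0, 0, 0))  # score 3 -> depressed
#' score_cesd(c(1, 1, 0, 0, 0, 0, 0, 0))  # score 2 -> not depressed
#' @export
score_cesd <- function(items, included_items = 1:8, cutoff = 3) {
  if (!all(included_items %in% 1:8) || anyDuplicated(included_items)) {
    stop("included_items must be a subset of 1:8 without duplicates")
  }
  if (cutoff < 0 || cutoff > length(included_items)) {
    stop("cutoff must lie in [0, ", length(included_items), "]")
  }
  m <- if (is.matrix(items) || is.data.frame(items)) {
    as.matrix(items)
  } else {
    matrix(as.numeric(items), nrow = 1)
  }
  if (ncol(m) != 8) stop("items must have 8 columns")
  if (any(!(m %in% c(0, 1, NA)))) stop("items must be 0, 1 or missing")
  sub <- m[, included_items, drop = FALSE]
  score <- rowSums(sub)
  as.integer(ifelse(is.na(score), NA, ifelse(score >= cutoff, 2L, 1L)))
}

panel_columns <- function() {
  c("person_id", "sex", "z", "birth_month", "obs_month", "vital",
    "death_month", "state", paste0("cesd", 1:8))
}

check_panel <- function(panel) {
  miss <- setdiff(setdiff(panel_columns(), paste0("cesd", 1:8)), names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (!all(panel$vital %in% c("alive", "dead"))) {
    stop("vital must be 'alive' or 'dead'")
  }
  bad <- panel$vital == "dead" & is.na(panel$death_month)
  if (any(bad)) stop("dead records must carry death_month")
  if (any(panel$obs_month <= panel$birth_month)) {
    stop("obs_month must exceed birth_month")
  }
  invisible(panel)
}

#' Read / write the long-format panel CSV
#'
#' One row per interview or death record.  Columns, exactly:
#' `person_id, sex, z, birth_month, obs_month, vital, death_month, state,
#' cesd1..cesd8`; all months are integer calendar-month indices, `state` or
#' the CESD items may be blank.
#'
#' @param path File path.
#' @return A tibble with the panel column contract.
#' @export
read_panel <- function(path) {
  spec <- readr::cols(
    person_id = readr::col_character(),
    sex = readr::col_character(),
    z = readr::col_integer(),
    birth_month = readr::col_integer(),
    obs_month = readr::col_integer(),
    vital = readr::col_character(),
    death_month = readr::col_integer(),
    state = readr::col_integer(),
    .default = readr::col_integer()
  )
  panel <- readr::read_csv(path, col_types = spec, progress = FALSE)
  check_panel(panel)
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  for (col in setdiff(panel_columns(), names(panel))) panel[[col]] <- NA_integer_
  readr::write_csv(panel[panel_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

# score CESD items into `state` wherever state is missing on alive records
fill_states <- function(panel, included_items = 1:8, cutoff = 3) {
  items_present <- all(paste0("cesd", 1:8) %in% names(panel))
  need <- is.na(panel$state) & panel$vital == "alive"
  if (items_present && any(need)) {
    items <- as.matrix(panel[need, paste0("cesd", 1:8)])
    panel$state[need] <- score_cesd(items, included_items, cutoff)
  }
  panel$state[panel$vital == "dead"] <- 3L
  panel
}

#' Apply the study's inclusion and exclusion filters
#'
#' Removes persons, in order and with counts: (a) under age 50 (600 months)
#' at the entry interview; (b) with no valid interview during follow-up;
#' (c) whose covariate (marital status) changes during follow-up, covering
#' both incident widowhood and remarriage; (d) with missing depression state
#' at the entry wave.  CESD items are scored into states first if `state`
#' is blank.
#'
#' @param panel Panel tibble (see [read_panel()] for the column contract).
#' @param min_entry_age Minimum entry age in months (default 600).
#' @param included_items,cutoff Passed to [score_cesd()].
#' @return The filtered panel, with the filter report available through
#'   [filter_report()] as attribute `"filter_report"`: a tibble of rule
#'   names and persons removed, in application order.
#' @export
apply_inclusion_filters <- function(panel, min_entry_age = 600,
                                    included_items = 1:8, cutoff = 3) {
  check_panel(panel)
  panel <- fill_states(panel, included_items, cutoff)
  panel <- dplyr::arrange(panel, .data$person_id, .data$obs_month)

  summarise_persons <- function(p) {
    dplyr::summarise(
      dplyr::group_by(p, .data$person_id),
      entry_age = dplyr::first(.data$obs_month - .data$birth_month),
      n_alive = sum(.data$vital == "alive"),
      z_changes = dplyr::n_distinct(.data$z) > 1L,
      entry_state_missing = is.na(dplyr::first(.data$state[.data$vital == "alive"])[1]),
      .groups = "drop"
    )
  }

  rules <- list(
    underage = function(info) info$entry_age < min_entry_age,
    no_valid_interview = function(info) info$n_alive == 0L,
    marital_change = function(info) info$z_changes,
    entry_state_missing = function(info) info$entry_state_missing
  )

  removed <- integer(0)
  for (rule in names(rules)) {
    info <- summarise_persons(panel)
    drop <- info$person_id[rules[[rule]](info)]
    removed[rule] <- length(drop)
    if (length(drop)) panel <- panel[!(panel$person_id %in% drop), ]
  }
  if (nrow(panel) == 0) warning("no persons remain after filtering")

  report <- tibble::tibble(
    rule = names(rules),
    n_persons_removed = unname(removed)
  )
  attr(report, "n_retained") <- dplyr::n_distinct(panel$person_id)
  attr(panel, "filter_report") <- report
  panel
}

#' @rdname apply_inclusion_filters
#' @export
filter_report <- function(panel) {
  rep <- attr(panel, "filter_report")
  if (is.null(rep)) stop("panel carries no filter report; run apply_inclusion_filters() first")
  rep
}

#' Extract analysis-ready transition pairs
#'
#' Consecutive valid state observations of one person form one pair each;
#' intervals spanning missed waves become single long pairs; a death
#' appends a final pair ending at the exact death age; records with missing
#' state are skipped as endpoints but do not break the chain.  A death
#' dated in the same month as the last interview is treated as a one-month
#' pair (the death interval is never zero length).
#'
#' @param panel Filtered panel tibble.
#' @param on_duplicate What to do when one person has two records in the
#'   same month: `"error"` (default) or `"first"` (keep the first).
#' @return A tibble of transition pairs: `person_id, sex, z, age_start,
#'   age_end, state_start, state_end, is_death`, ages in months.
#' @export
extract_pairs <- function(panel, on_duplicate = c("error", "first")) {
  on_duplicate <- match.arg(on_duplicate)
  check_panel(panel)
  panel <- fill_states(panel)
  panel <- dplyr::arrange(panel, .data$person_id, .data$obs_month)
  # a death record may legitimately share its month with the last interview
  alive_idx <- which(panel$vital == "alive")
  dup <- alive_idx[duplicated(panel[alive_idx, c("person_id", "obs_month")])]
  if (length(dup)) {
    if (on_duplicate == "error") {
      stop("duplicate records in one month for person(s): ",
           paste(unique(panel$person_id[dup]), collapse = ", "))
    }
    panel <- panel[-dup, ]
  }

  obs <- dplyr::filter(panel, .data$vital == "alive", !is.na(.data$state),
                       .data$state %in% 1:2)
  obs <- dplyr::mutate(obs, age = .data$obs_month - .data$birth_month)
  obs <- dplyr::group_by(obs, .data$person_id)
  live <- dplyr::ungroup(dplyr::mutate(
    obs,
    age_next = dplyr::lead(.data$age),
    state_next = dplyr::lead(.data$state)
  ))
  live_pairs <- dplyr::transmute(
    dplyr::filter(live, !is.na(.data$age_next)),
    person_id = .data$person_id, sex = .data$sex, z = .data$z,
    age_start = .data$age, age_end = .data$age_next,
    state_start = as.integer(.data$state),
    state_end = as.integer(.data$state_next),
    is_death = FALSE
  )

  last_obs <- dplyr::slice_tail(dplyr::group_by(
    dplyr::mutate(obs, age = .data$age), .data$person_id), n = 1)
  deaths <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(panel, .data$vital == "dead"), .data$person_id),
    death_age = dplyr::first(.data$death_month - .data$birth_month),
    .groups = "drop"
  )
  death_pairs <- dplyr::inner_join(dplyr::ungroup(last_obs), deaths,
                                   by = "person_id")
  death_pairs <- dplyr::transmute(
    death_pairs,
    person_id = .data$person_id, sex = .data$sex, z = .data$z,
    age_start = .data$age,
    age_end = pmax(.data$death_age, .data$age + 1L),
    state_start = as.integer(.data$state),
    state_end = 3L,
    is_death = TRUE
  )

  pairs <- dplyr::arrange(dplyr::bind_rows(live_pairs, death_pairs),
                          .data$person_id, .data$age_start)
  if (any(pairs$age_end <= pairs$age_start)) {
    stop("non-increasing ages within a person; check obs_month values")
  }
  pairs
}
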