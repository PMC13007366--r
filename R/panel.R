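# Canonical monthly panel: one row per observed person-month. This is the
# data model every estimator consumes; episodic care records are converted
# to it with episodes_to_panel() using the "highest care level occupied at
# any time in the month" rule.

PANEL_COLS <- c("person_id", "population", "sex", "birth_date", "obs_start",
                "obs_end", "end_reason", "month", "state")
END_REASONS <- c("death", "censored", "end")

as_ltc_panel <- function(df, baseline_date = NULL) {
  if (!is.null(baseline_date)) attr(df, "baseline_date") <- as.Date(baseline_date)
  class(df) <- c("ltc_panel", "data.frame")
  df
}

#' Read and write monthly panel CSV files
#'
#' The panel format has columns `person_id, population, sex, birth_date,
#' obs_start, obs_end, end_reason, month, state` with ISO-8601 dates,
#' `month` the first day of the calendar month the row describes,
#' `end_reason` one of `death`/`censored`/`end`, and `state` coded 0 =
#' no care, 1 = home care, 2 = care home (see [ltc_states()]).
#' `write_panel(read_panel(f))` reproduces `f` byte-identically for files in
#' canonical column order.
#'
#' @param path CSV file path.
#' @return `read_panel`: an `ltc_panel` data frame grouped by person;
#'   `write_panel`: `path`, invisibly.
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(person_id = "character", population = "character",
                                sex = "character", end_reason = "character"))
  missing_cols <- setdiff(PANEL_COLS, names(df))
  if (length(missing_cols)) {
    stop("panel file lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, PANEL_COLS]
  if (nrow(df) == 0) {
    for (col in c("birth_date", "obs_start", "obs_end", "month")) df[[col]] <- as.Date(character())
    df$state <- integer()
    return(as_ltc_panel(df))
  }
  for (col in c("birth_date", "obs_start", "obs_end", "month")) {
    parsed <- as.Date(df[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed %s at line(s) %s (ISO-8601 dates required)",
                   col, paste(head(bad + 1L, 5), collapse = ", ")))
    }
    df[[col]] <- parsed
  }
  bad_state <- setdiff(unique(df$state), unname(STATE_CODES[TRANSIENT_IDX]))
  if (length(bad_state)) {
    stop("unknown state code(s) in panel: ", paste(bad_state, collapse = ", "),
         " (expected 0/1/2)")
  }
  bad_reason <- setdiff(unique(df$end_reason), END_REASONS)
  if (length(bad_reason)) {
    stop("unknown end_reason value(s): ", paste(bad_reason, collapse = ", "))
  }
  dup <- duplicated(df[, c("person_id", "month")])
  if (any(dup)) {
    stop(sprintf("duplicate (person_id, month) row(s), first at line %d",
                 which(dup)[1] + 1L))
  }
  as_ltc_panel(df)
}

#' @rdname read_panel
#' @param panel An `ltc_panel` data frame.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, PANEL_COLS]
  for (col in c("birth_date", "obs_start", "obs_end", "month")) {
    df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert episodic care records to a monthly panel
#'
#' Episodes are intervals `[start, end]` in a given care state. Each observed
#' month is assigned the highest care level occupied at any time during that
#' month; months with no episode are `no_care`. This is the rule used for the
#' baseline-state classification when care use changes mid-month.
#'
#' @param persons Data frame with one row per person: `person_id, population,
#'   sex, birth_date, obs_start, obs_end, end_reason`.
#' @param episodes Data frame `person_id, start, end, state` with state codes
#'   1 (home care) or 2 (care home); may be empty.
#' @return An `ltc_panel` covering every month of each person's observation
#'   window (months whose first day is on or before `obs_end`).
#' @export
episodes_to_panel <- function(persons, episodes) {
  rows <- lapply(seq_len(nrow(persons)), function(i) {
    p <- persons[i, ]
    months <- seq(month_start(p$obs_start), month_start(p$obs_end), by = "month")
    st <- integer(length(months))
    ep <- episodes[episodes$person_id == p$person_id, , drop = FALSE]
    if (nrow(ep)) {
      mk <- month_key(months)
      for (e in seq_len(nrow(ep))) {
        cover <- mk >= month_key(ep$start[e]) & mk <= month_key(ep$end[e])
        st[cover] <- pmax(st[cover], ep$state[e])
      }
    }
    data.frame(person_id = p$person_id, population = p$population, sex = p$sex,
               birth_date = p$birth_date, obs_start = p$obs_start,
               obs_end = p$obs_end, end_reason = p$end_reason,
               month = months, state = st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_ltc_panel(out)
}

# one row per person with the fixed attributes
panel_persons <- function(panel) {
  first <- !duplicated(panel$person_id)
  out <- as.data.frame(panel)[first, c("person_id", "population", "sex",
                                       "birth_date", "obs_start", "obs_end",
                                       "end_reason")]
  rownames(out) <- NULL
  out
}

#' Baseline long-term-care state
#'
#' Classifies every person by the state occupied in the calendar month
#' immediately preceding the baseline month (e.g. March 2017 for a baseline
#' of 2017-04-01). A person with no panel row for that month but under
#' observation is `no_care`; persons not under observation in the reference
#' month, or not at risk (alive and under observation) at baseline, are
#' excluded (`NA` state).
#'
#' @param panel An `ltc_panel`.
#' @param baseline_date Baseline date; defaults to the panel's
#'   `baseline_date` attribute.
#' @return Data frame with one row per person: `person_id, population, sex,
#'   age, age_group, state` (`age` is continuous age at baseline; `state` is
#'   `NA` for excluded persons).
#' @export
baseline_states <- function(panel, baseline_date = attr(panel, "baseline_date")) {
  if (is.null(baseline_date)) stop("baseline_date must be supplied")
  baseline_date <- as.Date(baseline_date)
  ref_key <- month_key(baseline_date) - 1L
  pp <- panel_persons(panel)
  pp$age <- age_at(baseline_date, pp$birth_date)
  pp$age_group <- age_group(pp$age)

  observed_ref <- month_key(pp$obs_start) <= ref_key & month_key(pp$obs_end) >= ref_key
  at_risk <- pp$obs_start <= baseline_date & pp$obs_end >= baseline_date
  keep <- observed_ref & at_risk

  key <- paste(panel$person_id, month_key(panel$month))
  st <- panel$state[match(paste(pp$person_id, ref_key), key)]
  st[is.na(st) & keep] <- STATE_CODES[["no_care"]]
  st[!keep] <- NA_integer_
  pp$state <- st
  pp[, c("person_id", "population", "sex", "age", "age_group", "state")]
}

#' Person-years at risk over a follow-up window
#'
#' Exact elapsed years from baseline to the earliest of death, censoring and
#' the end of the follow-up window, for persons at risk at baseline.
#'
#' @inheritParams baseline_states
#' @param follow_up_years Window length in years.
#' @return Data frame `person_id, population, sex, person_years, died`
#'   (`died` marks deaths inside the window; persons not at risk at baseline
#'   get `person_years = 0`).
#' @export
person_years <- function(panel, baseline_date = attr(panel, "baseline_date"),
                         follow_up_years = 3) {
  if (is.null(baseline_date)) stop("baseline_date must be supplied")
  baseline_date <- as.Date(baseline_date)
  window_end <- baseline_date + round(follow_up_years * DAYS_PER_YEAR)
  pp <- panel_persons(panel)
  at_risk <- pp$obs_start <= baseline_date & pp$obs_end >= baseline_date
  end <- pmin(pp$obs_end, window_end)
  py <- pmax(as.numeric(end - baseline_date) / DAYS_PER_YEAR, 0)
  py[!at_risk] <- 0
  died <- at_risk & pp$end_reason == "death" & pp$obs_end <= window_end
  data.frame(person_id = pp$person_id, population = pp$population, sex = pp$sex,
             person_years = py, died = died, stringsAsFactors = FALSE)
}
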