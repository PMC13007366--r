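# Fixed state coding shared by every matrix operation in the package.
# Transient states are 0..2, death (3) is absorbing; matrix index = code + 1.
STATE_CODES <- c(no_care = 0L, home_care = 1L, care_home = 2L, dead = 3L)
STATE_LABELS <- names(STATE_CODES)
TRANSIENT_IDX <- 1:3
DEAD_IDX <- 4L
N_STATES <- 4L

DAYS_PER_YEAR <- 365.25

#' Long-term-care state space
#'
#' The ordered state space used throughout the package: `no_care` (0),
#' `home_care` (1), `care_home` (2) and the absorbing state `dead` (3).
#' Panel files store the integer codes; matrices index states as code + 1.
#'
#' @return Named integer vector of state codes.
#' @examples
#' ltc_states()
#' @export
ltc_states <- function() STATE_CODES

state_label <- function(code) STATE_LABELS[code + 1L]

# --- date / age helpers -----------------------------------------------------

age_at <- function(date, birth) as.numeric(date - birth) / DAYS_PER_YEAR

date_at_age <- function(birth, age) birth + round(age * DAYS_PER_YEAR)

month_start <- function(d) {
  lt <- as.POSIXlt(d)
  lt$mday <- 1L
  as.Date(lt)
}

# integer month key: months since 1900-01
month_key <- function(d) {
  lt <- as.POSIXlt(d)
  12L * lt$year + lt$mon
}

month_key_to_date <- function(k) {
  as.Date(sprintf("%d-%02d-01", k %/% 12L + 1900L, k %% 12L + 1L))
}

# --- 5-year age groups ------------------------------------------------------

DEFAULT_AGE_BREAKS <- c(75, 80, 85, 90, 95, 100, Inf)

age_group_labels <- function(breaks = DEFAULT_AGE_BREAKS) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.finite(hi), sprintf("%g-%g", lo, hi - 1), sprintf("%g+", lo))
}

#' Assign 5-year age groups
#'
#' Half-open intervals `[75, 80), [80, 85), ..., [100, Inf)` formed from
#' (continuous) age at baseline.
#'
#' @param age Numeric vector of ages in years.
#' @param breaks Left endpoints plus terminal `Inf` (default 75, 80, ..., 100, Inf).
#' @return Factor of age-group labels (`"75-79"`, ..., `"100+"`).
#' @examples
#' age_group(c(75, 79.9, 80, 101))
#' @export
age_group <- function(age, breaks = DEFAULT_AGE_BREAKS) {
  cut(age, breaks = breaks, labels = age_group_labels(breaks), right = FALSE)
}

# --- age grid ---------------------------------------------------------------

#' Interval start ages for the estimation grid
#'
#' 3-month (by default) interval start ages on `[lower, upper)`; `upper` is
#' the terminal age omega.
#'
#' @param lower,upper,step Grid bounds and interval width in years.
#' @return Numeric vector of interval start ages.
#' @export
grid_ages <- function(lower = 70, upper = 105, step = 0.25) {
  seq(lower, upper - step, by = step)
}

# map an exact age to the nearest grid interval start index, NA outside
grid_index <- function(age, ages, step) {
  i <- round((age - ages[1]) / step) + 1L
  i[i < 1L | i > length(ages)] <- NA_integer_
  i
}
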