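# Synthetic-cohort scenario: hazard parameterisation, defaults, validation,
# and the exact analytic oracles (true transition surface, true life
# expectancy) used in parameter-recovery tests.

# Default baseline age distributions (share of the 75+ cohort in each 5-year
# group) and state-given-age distributions, by population and sex. Values are
# register-plausible defaults for a Japan-like population (A) and a
# Sweden-like population (B): B has more care-home use, A more home care.
default_age_dist <- function() {
  g <- age_group_labels()
  list(
    A = list(
      male   = stats::setNames(c(0.4535, 0.3220, 0.1599, 0.0541, 0.0094, 0.0011), g),
      female = stats::setNames(c(0.3692, 0.3044, 0.1961, 0.0953, 0.0297, 0.0053), g)),
    B = list(
      male   = stats::setNames(c(0.4614, 0.2917, 0.1676, 0.0652, 0.0132, 0.0009), g),
      female = stats::setNames(c(0.3816, 0.2798, 0.2015, 0.1037, 0.0299, 0.0035), g))
  )
}

default_init_state <- function() {
  g <- age_group_labels()
  mk <- function(m) {
    m <- matrix(m, ncol = 3, byrow = TRUE,
                dimnames = list(g, STATE_LABELS[TRANSIENT_IDX]))
    sweep(m, 1, rowSums(m), "/")
  }
  list(
    A = list(
      male = mk(c(0.932, 0.055, 0.013,
                  0.862, 0.108, 0.030,
                  0.740, 0.195, 0.065,
                  0.590, 0.269, 0.141,
                  0.473, 0.304, 0.223,
                  0.378, 0.370, 0.252)),
      female = mk(c(0.905, 0.075, 0.020,
                    0.768, 0.176, 0.056,
                    0.571, 0.290, 0.139,
                    0.410, 0.330, 0.260,
                    0.317, 0.308, 0.375,
                    0.280, 0.248, 0.472))),
    B = list(
      male = mk(c(0.941, 0.039, 0.020,
                  0.854, 0.096, 0.050,
                  0.713, 0.187, 0.100,
                  0.521, 0.295, 0.184,
                  0.333, 0.366, 0.301,
                  0.214, 0.383, 0.403)),
      female = mk(c(0.922, 0.055, 0.023,
                    0.789, 0.143, 0.068,
                    0.589, 0.261, 0.150,
                    0.371, 0.352, 0.277,
                    0.211, 0.355, 0.434,
                    0.144, 0.279, 0.577)))
  )
}

# Per 3-month-interval hazard parameters at age 75, log-linear in age
# (q(age) = q75 * exp(slope * (age - 75))). Population B carries higher
# mortality inside the LTC states and more care-home entry; population A
# has slightly steeper no-care mortality so that its no-care death rates
# overtake B's at the oldest ages.
default_hazards <- function() {
  hz <- function(death, death_slope, entry, entry_slope, recovery) {
    list(
      death = stats::setNames(death, STATE_LABELS[TRANSIENT_IDX]),
      death_slope = stats::setNames(death_slope, STATE_LABELS[TRANSIENT_IDX]),
      entry = stats::setNames(entry, c("no_home", "no_ch", "home_ch")),
      entry_slope = stats::setNames(entry_slope, c("no_home", "no_ch", "home_ch")),
      recovery = stats::setNames(recovery, c("home_no", "ch_home", "ch_no")))
  }
  list(
    A = list(
      male = hz(death = c(0.0038, 0.018, 0.048), death_slope = c(0.115, 0.065, 0.045),
                entry = c(0.0085, 0.0013, 0.011), entry_slope = c(0.085, 0.085, 0.085),
                recovery = c(0.035, 0.006, 0.003)),
      female = hz(death = c(0.0017, 0.0090, 0.027), death_slope = c(0.115, 0.070, 0.050),
                  entry = c(0.0130, 0.0018, 0.011), entry_slope = c(0.085, 0.085, 0.085),
                  recovery = c(0.035, 0.006, 0.003))),
    B = list(
      male = hz(death = c(0.0036, 0.023, 0.062), death_slope = c(0.105, 0.065, 0.045),
                entry = c(0.0070, 0.0026, 0.018), entry_slope = c(0.085, 0.085, 0.085),
                recovery = c(0.030, 0.006, 0.003)),
      female = hz(death = c(0.0016, 0.0135, 0.039), death_slope = c(0.105, 0.070, 0.050),
                  entry = c(0.0110, 0.0035, 0.018), entry_slope = c(0.085, 0.085, 0.085),
                  recovery = c(0.030, 0.006, 0.003)))
  )
}

#' Synthetic-cohort scenario configuration
#'
#' Defines two populations of older adults followed from a fixed baseline
#' date across the long-term-care states. Hazards are specified as per
#' 3-month-interval exit probabilities at age 75 with log-linear age slopes
#' for death and care entry; recovery probabilities are age-constant.
#' Defaults describe a Japan-like population `A` (lower mortality inside LTC
#' states, more home care) and a Sweden-like population `B` (higher in-LTC
#' mortality, more care-home use); baseline age and state-given-age
#' distributions are register-plausible 5-year-group mixtures.
#'
#' @param populations Character vector of two population labels.
#' @param sexes Character vector of sex labels (default `male`, `female`).
#' @param cohort_size Persons per population x sex stratum.
#' @param baseline_date Baseline calendar date (`Date` or ISO string).
#' @param follow_up_years Follow-up length in whole years (default 3; use 5
#'   for the extended-follow-up sensitivity setting).
#' @param omega Terminal age in years (default 105).
#' @param emigration_rate Annual probability of censoring by emigration,
#'   state-independent.
#' @param hazards,age_dist,init_state Nested lists keyed by the *internal*
#'   population keys `A`/`B` (mapped in order to `populations`) and by sex;
#'   see the package vignette for the schema. Defaults as described above.
#' @param seed Master RNG seed for [simulate_cohort()].
#' @return Object of class `ltc_scenario`.
#' @seealso [simulate_cohort()], [true_transition_surface()],
#'   [true_life_expectancy()], [write_scenario()]
#' @examples
#' sc <- ltc_scenario(cohort_size = 100, seed = 1)
#' sc
#' @export
ltc_scenario <- function(populations = c("JPN", "SWE"),
                         sexes = c("male", "female"),
                         cohort_size = 10000,
                         baseline_date = as.Date("2017-04-01"),
                         follow_up_years = 3,
                         omega = 105,
                         emigration_rate = 0.005,
                         hazards = default_hazards(),
                         age_dist = default_age_dist(),
                         init_state = default_init_state(),
                         seed = 20170401) {
  baseline_date <- as.Date(baseline_date)
  cfg <- structure(list(populations = populations, sexes = sexes,
                        cohort_size = cohort_size, baseline_date = baseline_date,
                        follow_up_years = follow_up_years, omega = omega,
                        emigration_rate = emigration_rate, hazards = hazards,
                        age_dist = age_dist, init_state = init_state,
                        seed = as.integer(seed)),
                   class = "ltc_scenario")
  validate_scenario(cfg)
  cfg
}

#' @export
print.ltc_scenario <- function(x, ...) {
  cat("LTC synthetic-cohort scenario\n")
  cat(sprintf("  populations: %s (keys A, B); sexes: %s\n",
              paste(x$populations, collapse = ", "), paste(x$sexes, collapse = ", ")))
  cat(sprintf("  cohort size: %d per stratum; baseline %s; follow-up %g y; omega %g\n",
              x$cohort_size, format(x$baseline_date), x$follow_up_years, x$omega))
  cat(sprintf("  emigration rate: %g / year; seed: %d\n", x$emigration_rate, x$seed))
  invisible(x)
}

pop_key <- function(config, population) {
  i <- match(population, config$populations)
  if (is.na(i)) stop(sprintf("unknown population label '%s'", population))
  c("A", "B")[i]
}

validate_scenario <- function(config) {
  stopifnot(length(config$populations) == 2, config$cohort_size >= 0,
            config$follow_up_years > 0, config$omega > 75,
            config$emigration_rate >= 0, config$emigration_rate < 1)
  for (pk in c("A", "B")) for (sx in config$sexes) {
    h <- config$hazards[[pk]][[sx]]
    if (is.null(h)) stop(sprintf("hazards missing for population key %s, sex %s", pk, sx))
    ages <- seq(70, config$omega, by = 0.25)
    for (s in STATE_LABELS[TRANSIENT_IDX]) {
      ex <- exit_probs_3m(h, ages)[[s]]
      tot <- rowSums(ex)
      if (any(tot > 1)) {
        bad <- ages[which(tot > 1)[1]]
        stop(sprintf("per-interval exit probabilities from state '%s' exceed 1 at age %.2f (population key %s, %s)",
                     s, bad, pk, sx))
      }
    }
    ad <- config$age_dist[[pk]][[sx]]
    stopifnot(abs(sum(ad) - 1) < 1e-6, all(ad >= 0))
    ist <- config$init_state[[pk]][[sx]]
    stopifnot(all(abs(rowSums(ist) - 1) < 1e-6), all(ist >= 0))
  }
  invisible(config)
}

# 3-month exit probabilities from each transient state at given ages.
# Returns list by origin state of an (age x destination) matrix with columns
# in state order plus "dead" last; destinations in matrix-index order.
exit_probs_3m <- function(h, ages) {
  q <- function(q75, slope) pmin(q75 * exp(slope * (ages - 75)), 1)
  list(
    no_care = cbind(home_care = q(h$entry["no_home"], h$entry_slope["no_home"]),
                    care_home = q(h$entry["no_ch"], h$entry_slope["no_ch"]),
                    dead      = q(h$death["no_care"], h$death_slope["no_care"])),
    home_care = cbind(no_care   = rep(h$recovery[["home_no"]], length(ages)),
                      care_home = q(h$entry["home_ch"], h$entry_slope["home_ch"]),
                      dead      = q(h$death["home_care"], h$death_slope["home_care"])),
    care_home = cbind(no_care   = rep(h$recovery[["ch_no"]], length(ages)),
                      home_care = rep(h$recovery[["ch_home"]], length(ages)),
                      dead      = q(h$death["care_home"], h$death_slope["care_home"]))
  )
}

# nominal 3-month transition matrix at one age
three_month_matrix <- function(h, age) {
  ex <- exit_probs_3m(h, age)
  M <- diag(N_STATES)
  dimnames(M) <- list(STATE_LABELS, STATE_LABELS)
  for (s in STATE_LABELS[TRANSIENT_IDX]) {
    row <- ex[[s]][1, ]
    M[s, names(row)] <- row
    M[s, s] <- 1 - sum(row)
  }
  M
}

# Monthly kernel derived from the 3-month parameters: total monthly exit
# probability 1 - (1 - p)^(1/3), allocated to destinations proportionally
# (competing-risks-proportional). Total exit capped just below 1 so the
# allocation stays defined when hazards are extrapolated past omega.
monthly_matrix <- function(h, age) {
  ex <- exit_probs_3m(h, age)
  M <- diag(N_STATES)
  dimnames(M) <- list(STATE_LABELS, STATE_LABELS)
  for (s in STATE_LABELS[TRANSIENT_IDX]) {
    row <- ex[[s]][1, ]
    tot <- min(sum(row), 0.999999)
    if (tot > 0) {
      pm <- 1 - (1 - tot)^(1 / 3)
      row <- row * (pm / sum(row))
      M[s, names(row)] <- row
      M[s, s] <- 1 - sum(row)
    }
  }
  M
}

#' Exact transition surface implied by a scenario
#'
#' Returns, for every 3-month grid interval, the exact law of the scenario's
#' monthly-clock generator: the product of the three monthly kernels inside
#' the interval. This is the quantity empirical 3-month transition
#' frequencies from simulated cohorts converge to, and therefore the oracle
#' for parameter-recovery tests.
#'
#' @param config An [ltc_scenario()].
#' @param population,sex Stratum labels (population must be one of
#'   `config$populations`).
#' @param lower,step Grid start age and interval width.
#' @return An [ltc_surface()] of type `"true"` on `[lower, omega)`.
#' @export
true_transition_surface <- function(config, population, sex,
                                    lower = 70, step = 0.25) {
  pk <- pop_key(config, population)
  if (!sex %in% config$sexes) stop(sprintf("unknown sex label '%s'", sex))
  h <- config$hazards[[pk]][[sex]]
  ages <- grid_ages(lower, config$omega, step)
  P <- array(NA_real_, c(N_STATES, N_STATES, length(ages)))
  for (k in seq_along(ages)) {
    a <- ages[k]
    P[, , k] <- monthly_matrix(h, a) %*% monthly_matrix(h, a + 1 / 12) %*%
      monthly_matrix(h, a + 2 / 12)
  }
  ltc_surface(P, ages, step = step, omega = config$omega, type = "true")
}

#' Exact life expectancy implied by a scenario
#'
#' Evaluates the life-table algebra of [state_expectancies()] on the exact
#' surface from [true_transition_surface()]; the recovery target for
#' estimates obtained from simulated cohorts.
#'
#' @inheritParams true_transition_surface
#' @param index_age Index age on the grid, in `[70, omega)`.
#' @param initial Distribution over transient states at `index_age`; default
#'   is the scenario's state-given-age distribution for the 5-year group
#'   containing `index_age`.
#' @param half_interval Passed to [state_expectancies()].
#' @return An `ltc_expectancy` object.
#' @export
true_life_expectancy <- function(config, population, sex, index_age = 75,
                                 initial = NULL, half_interval = FALSE) {
  surf <- true_transition_surface(config, population, sex)
  if (is.null(initial)) {
    pk <- pop_key(config, population)
    grp <- as.character(age_group(index_age))
    if (is.na(grp)) grp <- age_group_labels()[1]
    initial <- config$init_state[[pk]][[sex]][grp, ]
  }
  state_expectancies(surf, index_age, initial, half_interval = half_interval)
}

# --- scenario file I/O ------------------------------------------------------

#' Write / read a scenario configuration file
#'
#' Serializes an [ltc_scenario()] to a YAML file (nested keys mirroring the
#' constructor arguments) and reads it back.
#'
#' @param config An [ltc_scenario()].
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` the
#'   reconstructed [ltc_scenario()].
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  x$baseline_date <- format(x$baseline_date)
  x$hazards <- lapply(x$hazards, function(p) lapply(p, function(h) lapply(h, as.list)))
  x$age_dist <- lapply(x$age_dist, function(p) lapply(p, as.list))
  x$init_state <- lapply(x$init_state, function(p) lapply(p, function(m) {
    lapply(stats::setNames(rownames(m), rownames(m)), function(g) as.list(m[g, ]))
  }))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  relist_named <- function(l) stats::setNames(as.numeric(unlist(l)), names(l))
  x$age_dist <- lapply(x$age_dist, function(p) lapply(p, relist_named))
  x$init_state <- lapply(x$init_state, function(p) lapply(p, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
    rownames(m) <- names(rows)
    m
  }))
  x$hazards <- lapply(x$hazards, function(p) lapply(p, function(h) lapply(h, relist_named)))
  ltc_scenario(populations = unlist(x$populations), sexes = unlist(x$sexes),
               cohort_size = x$cohort_size, baseline_date = x$baseline_date,
               follow_up_years = x$follow_up_years, omega = x$omega,
               emigration_rate = x$emigration_rate, hazards = x$hazards,
               age_dist = x$age_dist, init_state = x$init_state, seed = x$seed)
}
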