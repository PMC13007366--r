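# Shared fixture builders. Everything is generated in code; no binary data.

state_names <- names(ltc_states())[1:3]

# Hazard set with every exit probability constant in age (slopes 0).
flat_hazards <- function(death = c(0, 0, 0), entry = c(0, 0, 0),
                         recovery = c(0, 0, 0)) {
  h <- list(death = setNames(death, state_names),
            death_slope = setNames(c(0, 0, 0), state_names),
            entry = setNames(entry, c("no_home", "no_ch", "home_ch")),
            entry_slope = setNames(c(0, 0, 0), c("no_home", "no_ch", "home_ch")),
            recovery = setNames(recovery, c("home_no", "ch_home", "ch_no")))
  list(A = list(male = h, female = h), B = list(male = h, female = h))
}

# Small scenario with flat hazards applied to every stratum; everyone starts
# without care so trajectories are fully driven by the configured hazards.
flat_scenario <- function(death = c(0, 0, 0), entry = c(0, 0, 0),
                          recovery = c(0, 0, 0), cohort_size = 200,
                          emigration_rate = 0, seed = 1, ...) {
  groups <- c("75-79", "80-84", "85-89", "90-94", "95-99", "100+")
  all_no_care <- matrix(c(1, 0, 0), nrow = 6, ncol = 3, byrow = TRUE,
                        dimnames = list(groups, state_names))
  init <- list(A = list(male = all_no_care, female = all_no_care),
               B = list(male = all_no_care, female = all_no_care))
  ltc_scenario(cohort_size = cohort_size, emigration_rate = emigration_rate,
               hazards = flat_hazards(death, entry, recovery),
               init_state = init, seed = seed, ...)
}

# Constant-matrix surface: same 4x4 row-stochastic matrix at every interval.
constant_surface <- function(M, lower = 70, upper = 105, step = 0.25) {
  ages <- grid_ages(lower, upper, step)
  P <- array(rep(M, length(ages)), c(4, 4, length(ages)))
  ltc_surface(P, ages, step = step, omega = upper, type = "true")
}

# Smooth random surface: logit-linear exit probabilities per transition.
random_surface <- function(seed, lower = 70, upper = 105, step = 0.25) {
  set.seed(seed)
  ages <- grid_ages(lower, upper, step)
  P <- array(0, c(4, 4, length(ages)))
  P[4, 4, ] <- 1
  for (i in 1:3) {
    ex <- sapply(1:3, function(d) {
      plogis(runif(1, -6, -3) + runif(1, 0, 0.08) * (ages - 75))
    })
    tot <- rowSums(ex)
    scl <- ifelse(tot > 0.9, 0.9 / tot, 1)
    ex <- ex * scl
    dests <- setdiff(1:4, i)
    for (d in 1:3) P[i, dests[d], ] <- ex[, d]
    P[i, i, ] <- 1 - rowSums(ex)
  }
  ltc_surface(P, ages, step = step, omega = upper, type = "true")
}

# Subset one population x sex stratum keeping panel attributes.
stratum_panel <- function(panel, population, sex) {
  keep <- panel$population == population & panel$sex == sex
  out <- as.data.frame(panel)[keep, ]
  rownames(out) <- NULL
  attr(out, "baseline_date") <- attr(panel, "baseline_date")
  class(out) <- c("ltc_panel", "data.frame")
  out
}

# Hand-built single-month-per-person panel: fast fixtures for baseline /
# bootstrap mechanics. Ages are exact at the baseline date.
point_panel <- function(ages, states, population = "P1", sex = "female",
                        baseline = as.Date("2017-04-01"),
                        end_reason = "end", obs_end = NULL) {
  n <- length(ages)
  if (is.null(obs_end)) obs_end <- rep(baseline + 1096, n)
  ref_month <- as.Date(format(baseline - 1, "%Y-%m-01"))
  df <- data.frame(
    person_id = sprintf("p%04d", seq_len(n)),
    population = population, sex = sex,
    birth_date = baseline - round(ages * 365.25),
    obs_start = ref_month, obs_end = obs_end,
    end_reason = end_reason, month = ref_month,
    state = as.integer(states), stringsAsFactors = FALSE)
  attr(df, "baseline_date") <- baseline
  class(df) <- c("ltc_panel", "data.frame")
  df
}

# Synthetic transition-count object with constant at-risk and given event
# counts (lists indexed by "origin->destination"); remaining mass on stay.
synthetic_counts <- function(at_risk, events, lower = 70, upper = 105,
                             step = 0.25) {
  ages <- grid_ages(lower, upper, step)
  K <- length(ages)
  labs <- names(ltc_states())
  counts <- array(0, c(3, 4, K), dimnames = list(labs[1:3], labs, NULL))
  risk <- matrix(at_risk, 3, K, dimnames = list(labs[1:3], NULL))
  for (key in names(events)) {
    od <- strsplit(key, "->", fixed = TRUE)[[1]]
    counts[od[1], od[2], ] <- events[[key]]
  }
  for (i in 1:3) {
    exits <- colSums(counts[i, , ])  # 4 x K slice -> per-interval exit total
    counts[i, i, ] <- risk[i, ] - exits
    stopifnot(all(counts[i, i, ] >= 0))
  }
  structure(list(ages = ages, step = step, omega = upper,
                 at_risk = risk, counts = counts),
            class = "transition_counts")
}
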