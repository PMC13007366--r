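# Monthly-clock trajectory simulation. Transition parameters are per 3-month
# interval; monthly probabilities use the competing-risks-proportional
# 1 - (1 - p)^(1/3) conversion, so the generator's clock is deliberately not
# the 3-month estimation grid.

#' Simulate a synthetic two-population cohort
#'
#' Draws, for every person, a continuous baseline age from the scenario's
#' 5-year-group mixture, an initial state from the state-given-age
#' distribution, and then a month-by-month trajectory through
#' \{no care, home care, care home\} until death, emigration-censoring or
#' the end of follow-up. Observation starts one calendar month before the
#' baseline month so the baseline-state rule (state in the month preceding
#' baseline) is evaluable. Deaths and censorings are dated mid-month.
#' Output is reproducible given `config$seed`.
#'
#' @param config An [ltc_scenario()].
#' @return An `ltc_panel`: a data frame with one row per observed
#'   person-month and columns `person_id, population, sex, birth_date,
#'   obs_start, obs_end, end_reason, month, state` (state codes per
#'   [ltc_states()]), with the baseline date attached as attribute
#'   `baseline_date`.
#' @examples
#' pan <- simulate_cohort(ltc_scenario(cohort_size = 50, seed = 7))
#' head(pan)
#' @export
simulate_cohort <- function(config) {
  validate_scenario(config)
  set.seed(config$seed)
  parts <- list()
  for (pop in config$populations) {
    for (sx in config$sexes) {
      parts[[paste(pop, sx)]] <- simulate_stratum(config, pop, sx)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "baseline_date") <- config$baseline_date
  class(out) <- c("ltc_panel", "data.frame")
  out
}

simulate_stratum <- function(config, pop, sx) {
  pk <- pop_key(config, pop)
  n <- config$cohort_size
  if (n == 0) return(NULL)
  h <- config$hazards[[pk]][[sx]]
  baseline <- config$baseline_date
  fu_months <- as.integer(round(config$follow_up_years * 12))

  # baseline age: mixture over 5-year groups, uniform within group
  breaks <- DEFAULT_AGE_BREAKS
  grp <- sample.int(length(breaks) - 1L, n, replace = TRUE,
                    prob = config$age_dist[[pk]][[sx]])
  lo <- breaks[grp]
  width <- ifelse(is.finite(breaks[grp + 1L]), breaks[grp + 1L] - lo, 4)
  age0 <- lo + runif(n) * width
  birth <- baseline - round(age0 * DAYS_PER_YEAR)

  # initial state from state-given-age distribution (matrix index 1..3)
  ist <- config$init_state[[pk]][[sx]]
  cum <- t(apply(ist, 1, cumsum))
  u0 <- runif(n)
  state <- 1L + (u0 > cum[grp, 1]) + (u0 > cum[grp, 2])

  # months: offset -1 (pre-baseline reference month) .. fu_months - 1
  offsets <- seq(-1L, fu_months - 1L)
  md <- seq(month_start(baseline - 1), by = "month", length.out = length(offsets))
  pc_month <- 1 - (1 - config$emigration_rate)^(1 / 12)

  # destination matrix-index lookup per origin: two transient exits then dead
  dest1 <- c(2L, 1L, 1L)
  dest2 <- c(3L, 3L, 2L)

  Smat <- matrix(NA_integer_, n, length(offsets))
  last <- integer(n)           # last observed month column per person
  end_reason <- rep("end", n)
  end_date <- rep(baseline + round(config$follow_up_years * DAYS_PER_YEAR), n)
  active <- rep(TRUE, n)

  for (j in seq_along(offsets)) {
    if (!any(active)) break
    idx <- which(active)
    Smat[idx, j] <- state[idx]
    last[idx] <- j
    age_m <- age0[idx] + offsets[j] / 12

    # emigration censoring, independent of state
    uc <- runif(length(idx))
    cen <- uc < pc_month
    if (any(cen)) {
      ci <- idx[cen]
      end_reason[ci] <- "censored"
      end_date[ci] <- md[j] + 14
      active[ci] <- FALSE
    }
    keep <- idx[!cen]
    if (!length(keep)) next
    age_k <- age_m[!cen]
    s_k <- state[keep]

    # per-person monthly exit probabilities given current state
    p1 <- p2 <- pd <- numeric(length(keep))
    for (s in 1:3) {
      in_s <- s_k == s
      if (!any(in_s)) next
      ex <- exit_probs_3m(h, age_k[in_s])[[STATE_LABELS[s]]]
      tot <- pmin(rowSums(ex), 0.999999)
      pm <- 1 - (1 - tot)^(1 / 3)
      scale <- ifelse(tot > 0, pm / pmax(rowSums(ex), 1e-300), 0)
      p1[in_s] <- ex[, 1] * scale
      p2[in_s] <- ex[, 2] * scale
      pd[in_s] <- ex[, 3] * scale
    }
    u <- runif(length(keep))
    to1 <- u < p1
    to2 <- !to1 & u < p1 + p2
    die <- !to1 & !to2 & u < p1 + p2 + pd
    if (any(die)) {
      di <- keep[die]
      end_reason[di] <- "death"
      end_date[di] <- md[j] + 14
      active[di] <- FALSE
    }
    state[keep[to1]] <- dest1[s_k[to1]]
    state[keep[to2]] <- dest2[s_k[to2]]
  }

  counts <- last
  rows_person <- rep.int(seq_len(n), counts)
  rows_month <- sequence(counts)
  ids <- sprintf("%s_%s_%06d", pop, substr(sx, 1, 1), seq_len(n))
  data.frame(
    person_id = ids[rows_person],
    population = pop,
    sex = sx,
    birth_date = birth[rows_person],
    obs_start = md[1],
    obs_end = end_date[rows_person],
    end_reason = end_reason[rows_person],
    month = md[rows_month],
    state = Smat[cbind(rows_person, rows_month)] - 1L,
    stringsAsFactors = FALSE)
}
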