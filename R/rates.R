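# Baseline proportions, death rates by baseline LTC state, age
# standardization to the combined cohort, and rate/proportion comparisons.
# All CIs are Wald-based: Bernoulli variance for proportions, Poisson
# variance for rates (natural scale for differences, log scale for ratios).

Z95 <- qnorm(0.975)

#' Wald proportion with Bernoulli-variance confidence interval
#'
#' `p = x / n`, `CI = p +/- 1.96 sqrt(p (1 - p) / n)`, clipped to `[0, 1]`.
#'
#' @param x Event count(s).
#' @param n Denominator(s).
#' @param level Confidence level.
#' @return Data frame `proportion, se, lower, upper`.
#' @examples
#' wald_proportion(306740, 364498)  # 84.2%
#' @export
wald_proportion <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  se <- sqrt(p * (1 - p) / n)
  data.frame(proportion = p, se = se,
             lower = pmax(p - z * se, 0), upper = pmin(p + z * se, 1))
}

#' Baseline long-term-care state proportions
#'
#' Shares of the baseline population in each state, per population x sex x
#' 5-year age group (and marginally over age with `by_age = FALSE`), with
#' Wald/Bernoulli 95% CIs. Denominator = persons at risk at baseline with a
#' classifiable reference-month state.
#'
#' @param panel An `ltc_panel`.
#' @param baseline_date Baseline date (default: panel attribute).
#' @param breaks Age-group breaks (see [age_group()]).
#' @param by_age Stratify by age group (default) or report totals per
#'   population x sex.
#' @return Data frame with columns `population, sex, age_group, state,
#'   count, denom, proportion, se, lower, upper`; proportions over states
#'   sum to 1 within each cell group.
#' @export
baseline_proportions <- function(panel, baseline_date = attr(panel, "baseline_date"),
                                 breaks = DEFAULT_AGE_BREAKS, by_age = TRUE) {
  bs <- baseline_states(panel, baseline_date)
  bs <- bs[!is.na(bs$state), ]
  bs$age_group <- age_group(bs$age, breaks)
  if (!by_age) bs$age_group <- factor("total")
  grp <- interaction(bs$population, bs$sex, bs$age_group, drop = TRUE, sep = "\r")
  cells <- lapply(levels(grp), function(g) {
    rows <- bs[grp == g, ]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    cnt <- vapply(0:2, function(s) sum(rows$state == s), numeric(1))
    den <- nrow(rows)
    ci <- wald_proportion(cnt, den)
    data.frame(population = parts[1], sex = parts[2], age_group = parts[3],
               state = STATE_LABELS[TRANSIENT_IDX], count = cnt, denom = den,
               ci, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Death rates by baseline long-term-care state
#'
#' Deaths and person-years over the follow-up window accumulated within
#' population x sex x age-group x baseline-state cells (the state is fixed
#' at baseline, not updated over follow-up), rate per 1000 person-years with
#' Wald/Poisson CI `rate +/- 1.96 * 1000 * sqrt(deaths) / PY`. Rows with
#' `state = "all"` pool the three baseline states. Cells with no deaths are
#' flagged `low_information`.
#'
#' @inheritParams baseline_proportions
#' @param follow_up_years Follow-up window in years (3 default; 5 for the
#'   extended-follow-up sensitivity setting).
#' @return Data frame `population, sex, age_group, state, deaths,
#'   person_years, rate, se, lower, upper, low_information` (rate scale:
#'   per 1000 person-years).
#' @export
death_rates <- function(panel, baseline_date = attr(panel, "baseline_date"),
                        follow_up_years = 3, breaks = DEFAULT_AGE_BREAKS,
                        by_age = TRUE) {
  bs <- baseline_states(panel, baseline_date)
  py <- person_years(panel, baseline_date, follow_up_years)
  stopifnot(identical(bs$person_id, py$person_id))
  bs$person_years <- py$person_years
  bs$died <- py$died
  bs <- bs[!is.na(bs$state) & bs$person_years > 0, ]
  bs$age_group <- age_group(bs$age, breaks)
  if (!by_age) bs$age_group <- factor("total")
  bs$state_lab <- state_label(bs$state)

  cell_rates <- function(rows, state_lab) {
    D <- sum(rows$died)
    PY <- sum(rows$person_years)
    rate <- 1000 * D / PY
    se <- 1000 * sqrt(D) / PY
    data.frame(state = state_lab, deaths = D, person_years = PY, rate = rate,
               se = se, lower = max(rate - Z95 * se, 0), upper = rate + Z95 * se,
               low_information = D == 0, stringsAsFactors = FALSE)
  }
  grp <- interaction(bs$population, bs$sex, bs$age_group, drop = TRUE, sep = "\r")
  cells <- lapply(levels(grp), function(g) {
    rows <- bs[grp == g, ]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    per_state <- lapply(STATE_LABELS[TRANSIENT_IDX], function(s) {
      sub <- rows[rows$state_lab == s, ]
      if (!nrow(sub)) return(NULL)
      cell_rates(sub, s)
    })
    res <- do.call(rbind, c(per_state, list(cell_rates(rows, "all"))))
    cbind(data.frame(population = parts[1], sex = parts[2], age_group = parts[3],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Standard weights from the combined cohort age structure
#'
#' Weight per age group = share of the combined (both populations) baseline
#' count, within sex (and within baseline state when `by_state = TRUE`, the
#' stratification used for state-specific rate standardization). A
#' `state = "all"` set of weights over the whole baseline population is
#' always included.
#'
#' @inheritParams baseline_proportions
#' @param by_state Also compute per-state weight sets.
#' @return Data frame `sex, state, age_group, weight`; weights sum to 1
#'   within each (sex, state).
#' @export
standard_weights <- function(panel, baseline_date = attr(panel, "baseline_date"),
                             breaks = DEFAULT_AGE_BREAKS, by_state = TRUE) {
  bs <- baseline_states(panel, baseline_date)
  bs <- bs[!is.na(bs$state), ]
  bs$age_group <- age_group(bs$age, breaks)
  bs$state_lab <- state_label(bs$state)
  sets <- list()
  for (sx in unique(bs$sex)) {
    sub <- bs[bs$sex == sx, ]
    states <- if (by_state) c(STATE_LABELS[TRANSIENT_IDX], "all") else "all"
    for (s in states) {
      rows <- if (s == "all") sub else sub[sub$state_lab == s, ]
      tab <- table(rows$age_group)
      w <- as.numeric(tab) / sum(tab)
      sets[[paste(sx, s)]] <- data.frame(sex = sx, state = s,
                                         age_group = names(tab), weight = w,
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}

#' Age-standardize a rate or proportion table
#'
#' Weighted sum of age-group-specific values with variance
#' `sum(w^2 var_cell)`; works on [death_rates()] tables (column `rate`) and
#' [baseline_proportions()] tables (column `proportion`). Standardizing a
#' population with its own weights returns its crude value exactly.
#'
#' @param table A rates or proportions table with an `age_group` column.
#' @param weights A [standard_weights()] table (matched on sex and, when the
#'   table has per-state rows, on state; proportion tables use the `"all"`
#'   weight set).
#' @param level Confidence level.
#' @return One row per population x sex x state with `age_group = "std"`,
#'   the standardized estimate, `se`, and Wald CI.
#' @export
standardize <- function(table, weights, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  value_col <- if ("rate" %in% names(table)) "rate" else "proportion"
  grp <- interaction(table$population, table$sex, table$state, drop = TRUE, sep = "\r")
  rows <- lapply(levels(grp), function(g) {
    sub <- table[grp == g, ]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    wstate <- if (value_col == "rate" && parts[3] %in% weights$state) parts[3] else "all"
    w <- weights[weights$sex == parts[2] & weights$state == wstate, ]
    miss <- setdiff(w$age_group[w$weight > 0], as.character(sub$age_group))
    if (length(miss)) {
      stop(sprintf("standardize: population %s sex %s state %s lacks age group(s) %s",
                   parts[1], parts[2], parts[3], paste(miss, collapse = ", ")))
    }
    wv <- w$weight[match(as.character(sub$age_group), w$age_group)]
    wv[is.na(wv)] <- 0
    est <- sum(wv * sub[[value_col]])
    se <- sqrt(sum(wv^2 * sub$se^2))
    lo <- est - z * se
    hi <- est + z * se
    if (value_col == "proportion") { lo <- max(lo, 0); hi <- min(hi, 1) } else lo <- max(lo, 0)
    out <- data.frame(population = parts[1], sex = parts[2], age_group = "std",
                      state = parts[3], stringsAsFactors = FALSE)
    out[[value_col]] <- est
    out$se <- se
    out$lower <- lo
    out$upper <- hi
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare rates or proportions between the two populations
#'
#' Differences on the natural scale (`A - B`, variance sum) and rate ratios
#' (`A / B`) with log-scale Wald CIs (`var(log ratio) = 1/D_A + 1/D_B` for
#' rates). The population order is explicit and echoed in the output.
#'
#' @param table A [death_rates()], [baseline_proportions()] or
#'   [standardize()] output covering both populations.
#' @param populations Length-2 character vector `(A, B)`: the comparison is
#'   `A - B` (or `A / B`).
#' @param mode `"difference"` or `"ratio"`.
#' @param level Confidence level.
#' @return Data frame per matched stratum with `estimate, lower, upper`,
#'   the `comparison` label, and a `flag` column (`"zero_denominator"` for
#'   undefined ratios).
#' @export
compare_populations <- function(table, populations, mode = c("difference", "ratio"),
                                level = 0.95) {
  mode <- match.arg(mode)
  z <- qnorm(1 - (1 - level) / 2)
  stopifnot(length(populations) == 2, all(populations %in% table$population))
  value_col <- if ("rate" %in% names(table)) "rate" else "proportion"
  A <- table[table$population == populations[1], ]
  B <- table[table$population == populations[2], ]
  key <- function(d) paste(d$sex, d$age_group, d$state, sep = "\r")
  m <- match(key(A), key(B))
  ok <- !is.na(m)
  A <- A[ok, ]
  B <- B[m[ok], ]
  out <- data.frame(sex = A$sex, age_group = A$age_group, state = A$state,
                    comparison = paste(populations[1],
                                       if (mode == "difference") "-" else "/",
                                       populations[2]),
                    stringsAsFactors = FALSE)
  out$flag <- ""
  if (mode == "difference") {
    out$estimate <- A[[value_col]] - B[[value_col]]
    se <- sqrt(A$se^2 + B$se^2)
    out$lower <- out$estimate - z * se
    out$upper <- out$estimate + z * se
  } else {
    zero <- B[[value_col]] == 0
    est <- ifelse(zero, NA_real_, A[[value_col]] / B[[value_col]])
    if (value_col == "rate" && all(c("deaths") %in% names(A))) {
      se_log <- sqrt(1 / A$deaths + 1 / B$deaths)
    } else {
      se_log <- sqrt((A$se / A[[value_col]])^2 + (B$se / B[[value_col]])^2)
    }
    out$estimate <- est
    out$lower <- est * exp(-z * se_log)
    out$upper <- est * exp(z * se_log)
    out$flag[zero] <- "zero_denominator"
  }
  rownames(out) <- NULL
  out
}
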