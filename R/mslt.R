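#' Fit a discrete-time multistate life table for one stratum
#'
#' The central estimator: counts 3-month transitions among
#' \{no care, home care, care home, death\} from a monthly panel, forms raw
#' transition probabilities, and smooths them with penalized-spline binomial
#' GAMs on the logit scale. The fitted object carries both surfaces and is
#' consumed by [summary.mslt()] (life expectancies), [predict.mslt()]
#' (transition probabilities / occupancy), [simulate.mslt()] (Monte-Carlo
#' trajectories) and [residuals.mslt()].
#'
#' @param panel An `ltc_panel` (see [read_panel()], [simulate_cohort()]).
#' @param population,sex Optional stratum filters; supply both when the panel
#'   holds several strata.
#' @param lower,upper,step Age grid (default 3-month intervals on
#'   `[70, 105)`, terminal age omega = `upper`).
#' @param control An [mslt_control()] with the P-spline settings.
#' @param smooth Fit the smoothed surface (set `FALSE` to keep only raw
#'   probabilities, e.g. for diagnostics).
#' @return An object of class `mslt`: list with `counts`
#'   ([count_transitions()]), `raw` and `smoothed` ([ltc_surface()]s),
#'   stratum labels, `n_persons` and the call.
#' @examples
#' pan <- simulate_cohort(ltc_scenario(cohort_size = 400, seed = 3))
#' fit <- mslt(pan, population = "JPN", sex = "female",
#'             control = mslt_control(k = 8))
#' summary(fit, index_age = 75)
#' @export
mslt <- function(panel, population = NULL, sex = NULL,
                 lower = 70, upper = 105, step = 0.25,
                 control = mslt_control(), smooth = TRUE) {
  cl <- match.call()
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(population)) keep <- keep & panel$population == population
  if (!is.null(sex)) keep <- keep & panel$sex == sex
  sub <- as_ltc_panel(as.data.frame(panel)[keep, , drop = FALSE],
                      attr(panel, "baseline_date"))
  if (!nrow(sub)) stop("no panel rows in the requested stratum")
  if (length(unique(sub$population)) > 1 || length(unique(sub$sex)) > 1) {
    stop("panel contains multiple strata; supply population= and sex=")
  }
  counts <- count_transitions(sub, lower = lower, upper = upper, step = step)
  raw <- raw_probabilities(counts)
  smoothed <- if (smooth) smooth_probabilities(counts, control) else NULL
  structure(list(call = cl, counts = counts, raw = raw, smoothed = smoothed,
                 population = unique(sub$population), sex = unique(sub$sex),
                 n_persons = length(unique(sub$person_id)),
                 control = control, step = step, omega = upper),
            class = "mslt")
}

# preferred surface: smoothed when available
mslt_surface <- function(object) {
  if (!is.null(object$smoothed)) object$smoothed else object$raw
}

# observed composition of the at-risk population at a grid age
observed_initial <- function(object, index_age) {
  k <- grid_index(index_age, object$counts$ages, object$step)
  if (is.na(k)) stop("index_age off grid")
  n <- object$counts$at_risk[, k]
  if (sum(n) == 0) stop(sprintf("no one at risk at age %g; supply initial=", index_age))
  n / sum(n)
}

#' @export
print.mslt <- function(x, ...) {
  cat(sprintf("Multistate life table fit: population %s, sex %s\n",
              x$population, x$sex))
  cat(sprintf("  %d persons, %d person-intervals at risk on [%g, %g) by %g\n",
              x$n_persons, as.integer(sum(x$counts$at_risk)),
              x$counts$ages[1], x$omega, x$step))
  cat(sprintf("  surfaces: raw%s\n",
              if (!is.null(x$smoothed)) " + P-spline smoothed" else " only"))
  invisible(x)
}

#' Life expectancies from a fitted multistate life table
#'
#' Computes total remaining life expectancy and expected years in each care
#' state at `index_age` from the smoothed transition surface.
#'
#' @param object An [mslt()] fit.
#' @param index_age Index age (default 75).
#' @param initial Distribution over transient states at `index_age`.
#'   Default: the observed composition of the at-risk cohort at that age
#'   (population-based expectancy); `conditional = TRUE` instead conditions
#'   on starting in `no_care`.
#' @param conditional Start everyone in `no_care`.
#' @param half_interval Passed to [state_expectancies()].
#' @param ... Unused.
#' @return An object of class `summary.mslt` wrapping the
#'   [state_expectancies()] result.
#' @export
summary.mslt <- function(object, index_age = 75, initial = NULL,
                         conditional = FALSE, half_interval = FALSE, ...) {
  if (is.null(initial)) {
    initial <- if (conditional) c(1, 0, 0) else observed_initial(object, index_age)
  }
  ex <- state_expectancies(mslt_surface(object), index_age, initial,
                           half_interval = half_interval)
  structure(list(population = object$population, sex = object$sex,
                 n_persons = object$n_persons, expectancy = ex,
                 conditional = conditional),
            class = "summary.mslt")
}

#' @export
print.summary.mslt <- function(x, digits = 3, ...) {
  cat(sprintf("Population %s, sex %s (%d persons)%s\n", x$population, x$sex,
              x$n_persons,
              if (x$conditional) ", conditional on starting without care" else ""))
  print(x$expectancy, digits = digits)
  invisible(x)
}

#' @describeIn mslt smoothed transition probabilities in tidy long form
#'   (`age, origin, destination, probability`).
#' @param object,... Method arguments.
#' @export
coef.mslt <- function(object, ...) {
  df <- as.data.frame(mslt_surface(object))
  df[df$origin != "dead", c("age", "origin", "destination", "probability")]
}

#' Predict transition probabilities or state occupancy
#'
#' @param object An [mslt()] fit.
#' @param ages Grid ages at which to return transition probabilities
#'   (`type = "transition"`), or the index age for `type = "occupancy"`.
#' @param type `"transition"` (tidy probabilities at the requested grid ages)
#'   or `"occupancy"` (state-occupancy curve from `ages[1]`).
#' @param initial Initial distribution for occupancy (default observed).
#' @param ... Unused.
#' @return A data frame.
#' @export
predict.mslt <- function(object, ages = NULL, type = c("transition", "occupancy"),
                         initial = NULL, ...) {
  type <- match.arg(type)
  surf <- mslt_surface(object)
  if (type == "transition") {
    df <- as.data.frame(surf)
    if (!is.null(ages)) df <- df[df$age %in% ages, ]
    rownames(df) <- NULL
    return(df)
  }
  index_age <- if (is.null(ages)) 75 else ages[1]
  if (is.null(initial)) initial <- observed_initial(object, index_age)
  occupancy(surf, index_age, initial)
}

#' Simulate lifetimes from a fitted multistate life table
#'
#' Monte-Carlo trajectories on the fitted (smoothed) transition surface;
#' the independent oracle for the life-table algebra.
#'
#' @param object An [mslt()] fit.
#' @param nsim Number of trajectories.
#' @param seed Optional RNG seed.
#' @param index_age Start age.
#' @param initial Initial distribution (default observed composition).
#' @param ... Unused.
#' @return See [surface_simulate()].
#' @export
simulate.mslt <- function(object, nsim = 1000, seed = NULL, index_age = 75,
                          initial = NULL, ...) {
  if (is.null(initial)) initial <- observed_initial(object, index_age)
  surface_simulate(mslt_surface(object), nsim, index_age, initial, seed = seed)
}

#' @describeIn mslt response residuals raw minus smoothed probability at every
#'   informative (age, origin, destination) cell, with at-risk counts.
#' @export
residuals.mslt <- function(object, ...) {
  if (is.null(object$smoothed)) stop("fit with smooth = TRUE to get residuals")
  raw <- as.data.frame(object$raw)
  fit <- as.data.frame(object$smoothed)
  df <- data.frame(age = raw$age, origin = raw$origin, destination = raw$destination,
                   raw = raw$probability, fitted = fit$probability)
  df <- df[df$origin != "dead" & !is.na(df$raw), ]
  k <- grid_index(df$age, object$counts$ages, object$step)
  df$at_risk <- object$counts$at_risk[cbind(match(df$origin, STATE_LABELS), k)]
  df$residual <- df$raw - df$fitted
  rownames(df) <- NULL
  df
}

#' Plot raw and smoothed transition probabilities
#'
#' One panel per origin state: smoothed curves per destination with raw
#' probabilities overplotted as points.
#'
#' @param x An [mslt()] fit.
#' @param log_scale Plot on log probability axis.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mslt <- function(x, log_scale = FALSE, ...) {
  old <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  surf <- mslt_surface(x)
  for (i in TRANSIENT_IDX) {
    dests <- setdiff(seq_len(N_STATES), i)
    sm <- t(surf$P[i, dests, ])
    rawp <- t(x$raw$P[i, dests, ])
    matplot(surf$ages, sm, type = "l", lty = 1, col = seq_along(dests),
            xlab = "age", ylab = "3-month probability",
            main = paste("from", STATE_LABELS[i]),
            log = if (log_scale) "y" else "", ...)
    matpoints(x$raw$ages, rawp, pch = 20, cex = 0.4, col = seq_along(dests))
    legend("topleft", legend = STATE_LABELS[dests], col = seq_along(dests),
           lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
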