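# Transition counting on the 3-month age grid and P-spline smoothing.

#' Count 3-month transitions on the age grid
#'
#' For every grid interval `[a, a + step)` and origin state, counts persons
#' at risk and their destinations. A person contributes to an interval if
#' they are alive and under observation when they reach exact age `a`; the
#' origin is the state recorded for the calendar month containing that
#' moment. The destination is the state in the month containing age
#' `a + step`, or death if the death date falls inside the interval; persons
#' whose observation ends inside the interval without death (censoring,
#' administrative end) contribute to neither numerator nor denominator.
#'
#' @param panel An `ltc_panel` (a single population x sex stratum; subset
#'   first, or use [mslt()]).
#' @param lower,upper,step Age grid: interval starts `lower, lower + step,
#'   ..., upper - step`; `upper` is the terminal age omega.
#' @return Object of class `transition_counts`: list with `ages`, `step`,
#'   `omega`, `at_risk` (3 x K matrix) and `counts` (3 x 4 x K array,
#'   origin x destination x interval). Destination counts sum to the at-risk
#'   count in every cell.
#' @export
count_transitions <- function(panel, lower = 70, upper = 105, step = 0.25) {
  ages <- grid_ages(lower, upper, step)
  if (!length(ages)) stop("empty age grid: check lower/upper/step")
  K <- length(ages)
  at_risk <- matrix(0, 3, K, dimnames = list(STATE_LABELS[TRANSIENT_IDX], NULL))
  counts <- array(0, c(3, N_STATES, K),
                  dimnames = list(STATE_LABELS[TRANSIENT_IDX], STATE_LABELS, NULL))
  pp <- panel_persons(panel)
  if (!nrow(pp)) {
    return(structure(list(ages = ages, step = step, omega = upper,
                          at_risk = at_risk, counts = counts),
                     class = "transition_counts"))
  }

  # state lookup matrix: person x month offset from the earliest panel month
  mk0 <- min(month_key(panel$month))
  moff <- month_key(panel$month) - mk0 + 1L
  M <- max(moff)
  pidx <- match(panel$person_id, pp$person_id)
  S <- matrix(NA_integer_, nrow(pp), M)
  S[cbind(pidx, moff)] <- panel$state

  birth <- as.numeric(pp$birth_date)
  obs_start <- as.numeric(pp$obs_start)
  obs_end <- as.numeric(pp$obs_end)
  death <- ifelse(pp$end_reason == "death", obs_end, Inf)

  # candidate (person, interval) pairs limited to each person's age span
  a_first <- ceiling(age_at(pp$obs_start, pp$birth_date) / step) * step
  a_last <- floor(age_at(pp$obs_end, pp$birth_date) / step) * step
  k_first <- pmax(as.integer(round((a_first - lower) / step)) + 1L, 1L)
  k_last <- pmin(as.integer(round((a_last - lower) / step)) + 1L, K)
  npairs <- pmax(k_last - k_first + 1L, 0L)
  if (sum(npairs) == 0) {
    return(structure(list(ages = ages, step = step, omega = upper,
                          at_risk = at_risk, counts = counts),
                     class = "transition_counts"))
  }
  pi_ <- rep.int(seq_len(nrow(pp)), npairs)
  ki <- sequence(npairs) - 1L + rep.int(k_first, npairs)
  a <- ages[ki]
  t_a <- birth[pi_] + a * DAYS_PER_YEAR
  t_b <- birth[pi_] + (a + step) * DAYS_PER_YEAR

  # at risk at interval start: under observation and alive strictly before death
  ok <- t_a >= obs_start[pi_] & t_a <= obs_end[pi_] & t_a < death[pi_]
  pi_ <- pi_[ok]; ki <- ki[ok]; t_a <- t_a[ok]; t_b <- t_b[ok]

  m_a <- month_key(as.Date(t_a, origin = "1970-01-01")) - mk0 + 1L
  origin <- rep(NA_integer_, length(m_a))
  in_range <- m_a >= 1L & m_a <= ncol(S)
  origin[in_range] <- S[cbind(pi_[in_range], m_a[in_range])]
  ok <- !is.na(origin)
  pi_ <- pi_[ok]; ki <- ki[ok]; t_a <- t_a[ok]; t_b <- t_b[ok]; origin <- origin[ok]

  died_in <- death[pi_] > t_a & death[pi_] <= t_b
  cens_in <- !died_in & obs_end[pi_] < t_b
  keep <- !cens_in
  pi_ <- pi_[keep]; ki <- ki[keep]; t_b <- t_b[keep]
  origin <- origin[keep]; died_in <- died_in[keep]

  m_b <- month_key(as.Date(t_b, origin = "1970-01-01")) - mk0 + 1L
  m_b <- pmin(m_b, ncol(S))
  dest <- ifelse(died_in, STATE_CODES[["dead"]], S[cbind(pi_, m_b)])
  ok <- !is.na(dest)
  ki <- ki[ok]; origin <- origin[ok]; dest <- dest[ok]

  tab <- table(factor(origin, levels = 0:2), factor(dest, levels = 0:3),
               factor(ki, levels = seq_len(K)))
  counts[] <- as.numeric(tab)
  at_risk[] <- apply(counts, c(1, 3), sum)
  structure(list(ages = ages, step = step, omega = upper,
                 at_risk = at_risk, counts = counts),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("3-month transition counts\n")
  cat(sprintf("  grid: %.2f-%.2f by %.2f (%d intervals)\n",
              x$ages[1], x$omega, x$step, length(x$ages)))
  tot <- rowSums(x$at_risk)
  for (s in rownames(x$at_risk)) {
    cat(sprintf("  %-9s %d person-intervals at risk\n", paste0(s, ":"), as.integer(tot[s])))
  }
  invisible(x)
}

#' Raw (unsmoothed) transition probabilities
#'
#' `P[i, j] = count(i -> j) / at_risk(i)` per interval; rows with zero
#' at-risk are left `NA` (flagged missing, not imputed).
#'
#' @param counts A [count_transitions()] result.
#' @return An [ltc_surface()] of type `"raw"`.
#' @export
raw_probabilities <- function(counts) {
  K <- length(counts$ages)
  P <- array(NA_real_, c(N_STATES, N_STATES, K))
  for (k in seq_len(K)) {
    M <- matrix(0, N_STATES, N_STATES)
    M[DEAD_IDX, DEAD_IDX] <- 1
    for (i in TRANSIENT_IDX) {
      nr <- counts$at_risk[i, k]
      M[i, ] <- if (nr > 0) counts$counts[i, , k] / nr else NA_real_
    }
    P[, , k] <- M
  }
  ltc_surface(P, counts$ages, step = counts$step, omega = counts$omega, type = "raw")
}

#' P-spline smoothing control parameters
#'
#' Defaults follow standard P-spline practice: cubic B-spline basis with
#' `k` basis functions over the age grid, second-order difference penalty,
#' smoothing parameter chosen by REML.
#'
#' @param k Basis dimension per transition curve.
#' @param bs mgcv smooth class (default `"ps"`).
#' @param m Spline/penalty order as in [mgcv::s()] (default cubic basis,
#'   2nd-order difference penalty).
#' @param method Smoothing-parameter selection criterion.
#' @param sp Fixed smoothing parameter(s): `NULL` (estimate by `method`), a
#'   single value applied to every transition, or a named vector keyed
#'   `"origin->destination"` (e.g. the vector a previous
#'   [smooth_probabilities()] fit attached as attribute `"sp"`, which lets a
#'   bootstrap hold the smoothing parameters fixed at the values selected on
#'   the original sample).
#' @return A list of class `mslt_control`.
#' @export
mslt_control <- function(k = 15, bs = "ps", m = c(2, 2), method = "REML", sp = NULL) {
  structure(list(k = k, bs = bs, m = m, method = method, sp = sp),
            class = "mslt_control")
}

#' Smooth transition probabilities with penalized-spline binomial GAMs
#'
#' For each origin state and each off-diagonal destination (two care moves
#' plus death), fits a binomial P-spline GAM of event counts against age on
#' the logit scale, weighted by at-risk counts, and predicts on the full
#' grid (ages without data are predicted from the fit). Stay probabilities
#' are set to one minus the fitted exits; if fitted exits sum above 1
#' anywhere they are rescaled proportionally with a warning.
#'
#' @param counts A [count_transitions()] result.
#' @param control An [mslt_control()].
#' @return An [ltc_surface()] of type `"smoothed"` (no missing rows), with
#'   the selected smoothing parameters attached as attribute `"sp"` (named
#'   `"origin->destination"`).
#' @export
smooth_probabilities <- function(counts, control = mslt_control()) {
  ages <- counts$ages
  K <- length(ages)
  P <- array(0, c(N_STATES, N_STATES, K))
  P[DEAD_IDX, DEAD_IDX, ] <- 1
  sp_used <- numeric(0)
  for (i in TRANSIENT_IDX) {
    n_i <- counts$at_risk[i, ]
    has <- n_i > 0
    if (sum(has) < control$k) {
      stop(sprintf("only %d distinct ages with at-risk data for origin '%s' but basis dimension k = %d; reduce k in mslt_control()",
                   sum(has), STATE_LABELS[i], control$k))
    }
    fitted_exits <- matrix(0, K, 0)
    dests <- setdiff(seq_len(N_STATES), i)
    for (j in dests) {
      key <- paste0(STATE_LABELS[i], "->", STATE_LABELS[j])
      sp_j <- control$sp
      if (!is.null(sp_j) && !is.null(names(sp_j))) {
        sp_j <- unname(sp_j[key])
        if (is.na(sp_j)) sp_j <- NULL
      }
      ev <- counts$counts[i, j, has]
      dat <- data.frame(age = ages[has], ev = ev, n = n_i[has])
      fit <- suppressWarnings(mgcv::gam(
        cbind(ev, n - ev) ~ s(age, k = control$k, bs = control$bs, m = control$m),
        family = stats::binomial(), data = dat, method = control$method,
        sp = sp_j))
      sp_used[key] <- fit$sp
      pj <- as.numeric(predict(fit, newdata = data.frame(age = ages),
                               type = "response"))
      fitted_exits <- cbind(fitted_exits, pj)
    }
    tot <- rowSums(fitted_exits)
    over <- tot > 1
    if (any(over)) {
      warning(sprintf("fitted exit probabilities from '%s' exceed 1 at %d age(s); rescaling proportionally",
                      STATE_LABELS[i], sum(over)))
      fitted_exits[over, ] <- fitted_exits[over, ] / tot[over]
      tot[over] <- 1
    }
    for (d in seq_along(dests)) P[i, dests[d], ] <- fitted_exits[, d]
    P[i, i, ] <- 1 - tot
  }
  out <- ltc_surface(P, ages, step = counts$step, omega = counts$omega,
                     type = "smoothed")
  attr(out, "sp") <- sp_used
  out
}
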