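#' Transition surface over the long-term-care state space
#'
#' A transition surface is the collection of per-age-interval stochastic
#' matrices governing movement among \{no care, home care, care home, dead\}:
#' for every 3-month grid age `a` a 4x4 matrix `P` with `P[i, j]` the
#' probability of occupying state `j` at `a + step` given state `i` at `a`.
#' The dead row is exactly (0, 0, 0, 1). Raw (unsmoothed) surfaces may carry
#' `NA` rows where no one was at risk.
#'
#' @param P Numeric array `4 x 4 x K` of transition matrices, one per grid
#'   interval start age.
#' @param ages Interval start ages (length `K`), equally spaced by `step`.
#' @param step Interval width in years (default 0.25 = 3 months).
#' @param omega Terminal age: the life-table closure forces death at `omega`.
#' @param type One of `"raw"`, `"smoothed"`, `"true"`.
#' @return An object of class `ltc_surface`.
#' @seealso [occupancy()], [state_expectancies()], [surface_simulate()]
#' @export
ltc_surface <- function(P, ages, step = 0.25, omega = max(ages) + step,
                        type = c("raw", "smoothed", "true")) {
  type <- match.arg(type)
  stopifnot(length(dim(P)) == 3, dim(P)[1] == N_STATES, dim(P)[2] == N_STATES,
            dim(P)[3] == length(ages))
  validate_surface_rows(P, allow_na = (type == "raw"))
  structure(list(P = P, ages = ages, step = step, omega = omega, type = type),
            class = "ltc_surface")
}

validate_surface_rows <- function(P, allow_na = FALSE, tol = 1e-9) {
  K <- dim(P)[3]
  for (k in seq_len(K)) {
    M <- P[, , k]
    if (any(abs(M[DEAD_IDX, ] - c(0, 0, 0, 1)) > 0)) {
      stop("dead state must be absorbing: row 'dead' must be (0,0,0,1)")
    }
    for (i in TRANSIENT_IDX) {
      row <- M[i, ]
      if (anyNA(row)) {
        if (!allow_na) stop("NA transition row in a surface that must be complete")
        next
      }
      if (any(row < -tol) || any(row > 1 + tol)) {
        stop("transition probabilities must lie in [0, 1]")
      }
      if (abs(sum(row) - 1) > tol) {
        stop(sprintf("row %s at interval %d sums to %.12f, not 1",
                     STATE_LABELS[i], k, sum(row)))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.ltc_surface <- function(x, ...) {
  cat(sprintf("LTC transition surface (%s)\n", x$type))
  cat(sprintf("  grid: ages %.2f-%.2f by %.2f (%d intervals), omega = %g\n",
              x$ages[1], x$ages[length(x$ages)], x$step, length(x$ages), x$omega))
  nmiss <- sum(vapply(seq_along(x$ages),
                      function(k) anyNA(x$P[TRANSIENT_IDX, , k]), logical(1)))
  if (nmiss > 0) cat(sprintf("  %d interval(s) with missing (no at-risk) rows\n", nmiss))
  invisible(x)
}

#' @describeIn ltc_surface tidy long form: one row per
#'   (age, origin, destination) with the transition probability.
#' @param x,row.names,optional,... Usual [as.data.frame()] arguments.
#' @export
as.data.frame.ltc_surface <- function(x, row.names = NULL, optional = FALSE, ...) {
  K <- length(x$ages)
  out <- expand.grid(destination = STATE_LABELS, origin = STATE_LABELS,
                     age = x$ages, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out <- out[, c("age", "origin", "destination")]
  out$probability <- as.vector(aperm(x$P, c(2, 1, 3)))
  out$type <- x$type
  out
}

#' Write / read a transition surface as tidy CSV
#'
#' Serializes to columns `age, origin, destination, probability, type` for
#' inspection and reuse.
#'
#' @param surface An [ltc_surface()].
#' @param path File path.
#' @return `write_surface` returns `path` invisibly; `read_surface` returns
#'   the reconstructed [ltc_surface()].
#' @export
write_surface <- function(surface, path) {
  df <- as.data.frame(surface)
  df$probability <- format(df$probability, digits = 17, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @param step,omega Grid metadata (not stored in the CSV body).
#' @param type Surface type flag for the reconstructed object.
#' @export
read_surface <- function(path, step = 0.25, omega = NULL, type = "smoothed") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ages <- sort(unique(df$age))
  K <- length(ages)
  P <- array(NA_real_, c(N_STATES, N_STATES, K))
  i <- match(df$origin, STATE_LABELS)
  j <- match(df$destination, STATE_LABELS)
  k <- match(df$age, ages)
  P[cbind(i, j, k)] <- df$probability
  if (is.null(omega)) omega <- max(ages) + step
  ltc_surface(P, ages, step = step, omega = omega, type = type)
}

# --- occupancy and expectancies --------------------------------------------

#' State-occupancy probabilities from a transition surface
#'
#' Iterates `pi(t + step) = pi(t) %*% P(t)` from `index_age` to the terminal
#' age `omega`, at which all remaining probability mass is moved to death
#' (life-table closure).
#'
#' @param surface An [ltc_surface()] with no missing rows on
#'   `[index_age, omega)`.
#' @param index_age Start age; must lie on the grid.
#' @param initial Probability distribution over the three transient states at
#'   `index_age` (length 3, sums to 1).
#' @return Data frame with one row per grid age from `index_age` to `omega`
#'   and columns `age, no_care, home_care, care_home, dead`.
#' @examples
#' P <- array(rep(diag(4), 140), c(4, 4, 140))
#' s <- ltc_surface(P, grid_ages(), type = "true")
#' head(occupancy(s, 75, c(1, 0, 0)))
#' @export
occupancy <- function(surface, index_age, initial) {
  stopifnot(inherits(surface, "ltc_surface"))
  k0 <- grid_index(index_age, surface$ages, surface$step)
  if (is.na(k0) || abs(surface$ages[k0] - index_age) > 1e-8) {
    stop(sprintf("index_age %.3f is not on the %g-year grid", index_age, surface$step))
  }
  initial <- as.numeric(initial)
  stopifnot(length(initial) == 3, abs(sum(initial) - 1) < 1e-8, all(initial >= 0))
  K <- length(surface$ages)
  ks <- k0:K
  if (any(vapply(ks, function(k) anyNA(surface$P[TRANSIENT_IDX, , k]), logical(1)))) {
    stop("surface has missing (no at-risk) rows in [index_age, omega); ",
         "smooth the probabilities first")
  }
  occ <- matrix(0, nrow = length(ks) + 1L, ncol = N_STATES,
                dimnames = list(NULL, STATE_LABELS))
  pi_t <- c(initial, 0)
  for (r in seq_along(ks)) {
    occ[r, ] <- pi_t
    pi_t <- as.numeric(pi_t %*% surface$P[, , ks[r]])
  }
  # closure at omega: force death
  occ[length(ks) + 1L, ] <- c(0, 0, 0, 1)
  data.frame(age = c(surface$ages[ks], surface$omega), occ)
}

#' State-specific and total remaining life expectancy
#'
#' Expected time in transient state `s` from `index_age` is
#' `step * sum_t Pr(in s at t)` over interval start ages `t` in
#' `[index_age, omega)`; total remaining life expectancy is the sum over the
#' three states. By the default occupancy convention a person present at an
#' interval start is credited the full interval; `half_interval = TRUE`
#' replaces this with the trapezoidal (half-interval) correction
#' `step * (sum_t pi_s(t) - (pi_s(index_age) - pi_s(omega)) / 2)`.
#'
#' @inheritParams occupancy
#' @param half_interval Apply the trapezoidal correction (default `FALSE`).
#' @return An object of class `ltc_expectancy`: list with `index_age`,
#'   `initial`, `by_state` (expected years in each transient state),
#'   `total` and the convention flags.
#' @examples
#' P <- array(rep(diag(4), 140), c(4, 4, 140))
#' s <- ltc_surface(P, grid_ages(), type = "true")
#' state_expectancies(s, 75, c(1, 0, 0))$total  # 30 years to omega = 105
#' @export
state_expectancies <- function(surface, index_age, initial, half_interval = FALSE) {
  occ <- occupancy(surface, index_age, initial)
  n <- nrow(occ)
  transient <- as.matrix(occ[, STATE_LABELS[TRANSIENT_IDX]])
  e <- surface$step * colSums(transient[-n, , drop = FALSE])
  if (half_interval) {
    e <- e - surface$step / 2 * (transient[1, ] - transient[n, ])
  }
  structure(list(index_age = index_age, initial = stats::setNames(initial, STATE_LABELS[TRANSIENT_IDX]),
                 by_state = e, total = sum(e), omega = surface$omega,
                 half_interval = half_interval, lower = NULL, upper = NULL),
            class = "ltc_expectancy")
}

#' @export
print.ltc_expectancy <- function(x, digits = 3, ...) {
  cat(sprintf("Remaining life expectancy at age %g (omega = %g)\n",
              x$index_age, x$omega))
  cat(sprintf("  total: %.*f years\n", digits, x$total))
  for (s in names(x$by_state)) {
    cat(sprintf("  %-9s %.*f years\n", paste0(s, ":"), digits, x$by_state[[s]]))
  }
  invisible(x)
}

#' @export
as.data.frame.ltc_expectancy <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(quantity = c("total", names(x$by_state)),
                   estimate = c(x$total, unname(x$by_state)))
  if (!is.null(x$lower)) {
    df$lower <- c(x$lower[["total"]], x$lower[names(x$by_state)])
    df$upper <- c(x$upper[["total"]], x$upper[names(x$by_state)])
  }
  df
}

# --- Monte-Carlo chain simulation (oracle for the life-table algebra) -------

#' Simulate trajectories directly on a transition surface
#'
#' Runs `n` independent discrete-time chains on the surface's per-interval
#' matrices from `index_age` until death or the terminal age, crediting
#' `step` years in the occupied state per interval started alive (the same
#' convention as [state_expectancies()]). Used as an independent Monte-Carlo
#' oracle for the life-table algebra.
#'
#' @inheritParams occupancy
#' @param n Number of trajectories.
#' @param seed Optional RNG seed.
#' @return Data frame with `n` rows: years in `no_care`, `home_care`,
#'   `care_home`, and `total` lifetime from `index_age`.
#' @export
surface_simulate <- function(surface, n, index_age, initial, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k0 <- grid_index(index_age, surface$ages, surface$step)
  if (is.na(k0)) stop("index_age off grid")
  state <- sample.int(3L, n, replace = TRUE, prob = initial)
  time_in <- matrix(0, n, 3, dimnames = list(NULL, STATE_LABELS[TRANSIENT_IDX]))
  K <- length(surface$ages)
  for (k in k0:K) {
    alive <- state < 4L
    if (!any(alive)) break
    idx <- cbind(seq_len(n)[alive], state[alive])
    time_in[idx] <- time_in[idx] + surface$step
    C <- t(apply(surface$P[, , k], 1, cumsum))
    u <- runif(sum(alive))
    s <- state[alive]
    state[alive] <- 1L + (u > C[cbind(s, 1)]) + (u > C[cbind(s, 2)]) + (u > C[cbind(s, 3)])
  }
  out <- as.data.frame(time_in)
  out$total <- rowSums(time_in)
  out
}
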