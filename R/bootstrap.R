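#' Percentile bootstrap over individuals
#'
#' Resamples whole individual trajectories with replacement, stratified by
#' population x sex (per-stratum sample sizes are preserved exactly in every
#' replicate), recomputes an arbitrary statistic of the panel per replicate,
#' and returns empirical percentile confidence intervals. Replicates on
#' which the statistic fails are recorded and excluded with a warning when
#' they are under 1% of the total, otherwise the failure is an error.
#'
#' @param panel An `ltc_panel`.
#' @param statistic Function `panel -> numeric vector` (a pure function of
#'   the record collection; names are preserved).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional master RNG seed (replicates are drawn from one
#'   seeded stream, so results are reproducible).
#' @param strata Panel columns defining resampling strata.
#' @param percentiles CI percentiles (default 2.5 and 97.5).
#' @return Object of class `ltc_bootstrap`: list with `t0` (statistic on the
#'   original panel), `replicates` (matrix, one row per successful
#'   replicate), `ci` (matrix with `lower`/`upper` rows), `n_failed`.
#' @examples
#' pan <- simulate_cohort(ltc_scenario(cohort_size = 60, seed = 2))
#' b <- ltc_bootstrap(pan, function(p) c(mean_age = mean(baseline_states(p)$age)),
#'                    replicates = 20, seed = 1)
#' b$ci
#' @export
ltc_bootstrap <- function(panel, statistic, replicates = 1000, seed = NULL,
                          strata = c("population", "sex"),
                          percentiles = c(2.5, 97.5)) {
  stopifnot(replicates >= 2, all(percentiles > 0), all(percentiles < 100),
            percentiles[1] < percentiles[2])
  if (!is.null(seed)) set.seed(seed)
  t0 <- statistic(panel)
  pp <- panel_persons(panel)
  stratum <- do.call(paste, c(pp[, strata, drop = FALSE], sep = "\r"))
  rows_by_person <- split(seq_len(nrow(panel)), match(panel$person_id, pp$person_id))
  persons_by_stratum <- split(seq_len(nrow(pp)), stratum)
  baseline <- attr(panel, "baseline_date")
  df <- as.data.frame(panel)

  reps <- vector("list", replicates)
  failures <- character(0)
  for (r in seq_len(replicates)) {
    sel <- unlist(lapply(persons_by_stratum, function(ix) {
      ix[sample.int(length(ix), length(ix), replace = TRUE)]
    }), use.names = FALSE)
    nrows <- lengths(rows_by_person)[sel]
    boot <- df[unlist(rows_by_person[sel], use.names = FALSE), , drop = FALSE]
    # duplicated draws of the same person must count as distinct individuals
    boot$person_id <- rep.int(paste0("b", seq_along(sel)), nrows)
    boot <- as_ltc_panel(boot, baseline)
    res <- tryCatch(statistic(boot), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
    } else {
      reps[[r]] <- res
    }
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (length(failures)) {
    if (length(failures) > 0.01 * replicates) {
      stop(sprintf("statistic failed on %d/%d bootstrap replicates; first error: %s",
                   length(failures), replicates, failures[1]))
    }
    warning(sprintf("statistic failed on %d/%d bootstrap replicates (excluded); first error: %s",
                    length(failures), replicates, failures[1]))
  }
  R <- do.call(rbind, reps[ok])
  colnames(R) <- names(t0)
  ci <- apply(R, 2, quantile, probs = percentiles / 100, names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(t0 = t0, replicates = R, ci = ci,
                 n_failed = length(failures), percentiles = percentiles),
            class = "ltc_bootstrap")
}

#' @export
print.ltc_bootstrap <- function(x, digits = 4, ...) {
  cat(sprintf("Percentile bootstrap: %d replicates%s\n", nrow(x$replicates),
              if (x$n_failed) sprintf(" (%d failed, excluded)", x$n_failed) else ""))
  tab <- rbind(estimate = x$t0, x$ci)
  print(round(t(tab), digits))
  invisible(x)
}
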