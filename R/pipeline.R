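# End-to-end pipeline: simulate (or load) -> estimate -> life table ->
# rates -> decomposition, writing a deterministic report bundle of plain
# CSV files plus a manifest and a human-readable summary.

#' Pipeline run configuration
#'
#' @param output_dir Directory the report bundle is written to.
#' @param scenario An [ltc_scenario()] used when no `panel_path` is given.
#' @param panel_path Optional path to an existing panel CSV ([read_panel()]).
#' @param baseline_date,follow_up_years Analysis window (defaults from the
#'   scenario).
#' @param index_age Index age for life expectancies.
#' @param lower,upper,step Estimation age grid.
#' @param breaks Age-group breaks for rates/proportions.
#' @param bootstrap_replicates Bootstrap replicates for life-expectancy CIs
#'   (0 disables the bootstrap stage).
#' @param comparison Length-2 population order `(A, B)` for differences
#'   `A - B`; defaults to the scenario's population order.
#' @param control [mslt_control()] for the smoothing stage.
#' @param seed Seed recorded in the manifest and used for the bootstrap.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir, scenario = ltc_scenario(), panel_path = NULL,
                       baseline_date = scenario$baseline_date,
                       follow_up_years = scenario$follow_up_years,
                       index_age = 75, lower = 70, upper = 105, step = 0.25,
                       breaks = DEFAULT_AGE_BREAKS, bootstrap_replicates = 0,
                       comparison = scenario$populations,
                       control = mslt_control(), seed = scenario$seed) {
  stopifnot(follow_up_years > 0, lower < upper, length(comparison) == 2)
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    stop("panel_path does not exist: ", panel_path)
  }
  structure(list(output_dir = output_dir, scenario = scenario,
                 panel_path = panel_path, baseline_date = as.Date(baseline_date),
                 follow_up_years = follow_up_years, index_age = index_age,
                 lower = lower, upper = upper, step = step, breaks = breaks,
                 bootstrap_replicates = bootstrap_replicates,
                 comparison = comparison, control = control,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_report_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    format(x, digits = 15, trim = TRUE, scientific = FALSE)
  })
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) the panel, fits [mslt()] per population x sex, and
#' writes five report files to `config$output_dir`:
#' `baseline_composition.csv` (counts/proportions per state, totals and by
#' age group), `life_expectancy.csv` (total and state-specific expectancies,
#' with percentile-bootstrap CIs when enabled), `proportions_by_age.csv`
#' (age-specific and standardized proportions plus between-population
#' differences), `death_rates.csv` (age-specific and standardized rates plus
#' differences and ratios), `decomposition.csv` (age-specific and
#' standardized Kitagawa components), together with `manifest.yaml` and
#' `summary.txt`. Outputs are deterministic: rerunning with the same
#' configuration reproduces the files byte-identically.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all report tables and the file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  say("[1/6] cohort: %s", if (is.null(config$panel_path)) "simulating" else config$panel_path)
  panel <- if (is.null(config$panel_path)) {
    simulate_cohort(config$scenario)
  } else {
    as_ltc_panel(read_panel(config$panel_path), config$baseline_date)
  }
  pops <- unique(panel$population)
  sexes <- unique(panel$sex)

  say("[2/6] baseline composition")
  comp_total <- baseline_proportions(panel, config$baseline_date,
                                     breaks = config$breaks, by_age = FALSE)
  comp_age <- baseline_proportions(panel, config$baseline_date, breaks = config$breaks)
  composition <- rbind(comp_total, comp_age)

  say("[3/6] multistate estimation + life expectancy")
  le_rows <- list()
  for (pop in pops) for (sx in sexes) {
    fit <- tryCatch(
      mslt(panel, pop, sx, lower = config$lower, upper = config$upper,
           step = config$step, control = config$control),
      error = function(e) stop(sprintf("estimation stage failed for %s/%s: %s",
                                       pop, sx, conditionMessage(e)))
    )
    ex <- summary(fit, index_age = config$index_age)$expectancy
    row <- data.frame(population = pop, sex = sx, as.data.frame(ex),
                      stringsAsFactors = FALSE)
    if (config$bootstrap_replicates > 0) {
      stat <- local({
        pop_ <- pop; sx_ <- sx; cfg <- config
        function(p) {
          f <- mslt(p, pop_, sx_, lower = cfg$lower, upper = cfg$upper,
                    step = cfg$step, control = cfg$control)
          e <- summary(f, index_age = cfg$index_age)$expectancy
          c(total = e$total, e$by_state)
        }
      })
      sub <- as_ltc_panel(as.data.frame(panel)[panel$population == pop &
                                                 panel$sex == sx, ],
                          config$baseline_date)
      b <- ltc_bootstrap(sub, stat, replicates = config$bootstrap_replicates,
                         seed = config$seed)
      row$lower <- b$ci["lower", c("total", STATE_LABELS[TRANSIENT_IDX])]
      row$upper <- b$ci["upper", c("total", STATE_LABELS[TRANSIENT_IDX])]
    }
    le_rows[[paste(pop, sx)]] <- row
  }
  life_expectancy <- do.call(rbind, le_rows)
  rownames(life_expectancy) <- NULL

  say("[4/6] proportions and death rates")
  weights <- standard_weights(panel, config$baseline_date, breaks = config$breaks)
  prop_std <- standardize(comp_age, restrict_weights(weights, comp_age,
                                                     config$comparison))
  prop_diff <- compare_populations(prop_std, config$comparison, "difference")
  proportions <- merge_report(comp_age, prop_std, prop_diff)

  rates <- death_rates(panel, config$baseline_date, config$follow_up_years,
                       breaks = config$breaks)
  rates_std <- standardize(rates, restrict_weights(weights, rates,
                                                   config$comparison))
  rate_diff <- compare_populations(rates_std, config$comparison, "difference")
  rate_ratio <- compare_populations(rates_std, config$comparison, "ratio")
  rates_report <- merge_report(rates, rates_std, rate_diff, rate_ratio)

  say("[5/6] decomposition")
  ok_groups <- complete_decomposition_groups(rates, comp_age, config$comparison)
  dec_rates <- rates[paste(rates$sex, rates$age_group) %in%
                       paste(ok_groups$sex, ok_groups$age_group), ]
  dec_props <- comp_age[paste(comp_age$sex, comp_age$age_group) %in%
                          paste(ok_groups$sex, ok_groups$age_group), ]
  decomp_age <- decompose_rates(dec_rates, dec_props, config$comparison)
  dec_w <- restrict_weights(weights[weights$state == "all", ], dec_rates,
                            config$comparison)
  decomp_std <- decompose_standardized(dec_rates, dec_props, config$comparison,
                                       dec_w)
  decomposition <- rbind(decomp_age, decomp_std)

  say("[6/6] writing reports to %s", config$output_dir)
  paths <- c(
    write_report_csv(composition, config$output_dir, "baseline_composition.csv"),
    write_report_csv(life_expectancy, config$output_dir, "life_expectancy.csv"),
    write_report_csv(proportions, config$output_dir, "proportions_by_age.csv"),
    write_report_csv(rates_report, config$output_dir, "death_rates.csv"),
    write_report_csv(decomposition, config$output_dir, "decomposition.csv"))

  manifest <- list(
    seed = config$seed,
    baseline_date = format(config$baseline_date),
    follow_up_years = config$follow_up_years,
    index_age = config$index_age,
    grid = list(lower = config$lower, upper = config$upper, step = config$step),
    bootstrap_replicates = config$bootstrap_replicates,
    comparison = config$comparison,
    n_persons = length(unique(panel$person_id)),
    package_version = as.character(utils::packageVersion("carestates")),
    config_hash = config_hash(config))
  manifest_path <- file.path(config$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  summary_path <- write_text_summary(config, life_expectancy, rates_std,
                                     decomp_std)
  invisible(list(panel = panel, composition = composition,
                 life_expectancy = life_expectancy, proportions = proportions,
                 rates = rates_report, decomposition = decomposition,
                 weights = weights,
                 paths = c(paths, manifest_path, summary_path)))
}

# Restrict a weight set to age groups observed for every population in the
# table (per sex x state), renormalizing. At registry scale every cell is
# populated and this is a no-op; small demonstration cohorts can leave the
# rarest cells (e.g. care home at 100+) empty, and a standardized estimate
# is then only defined over the common support.
restrict_weights <- function(weights, table, populations) {
  sets <- split(weights, paste(weights$sex, weights$state, sep = "\r"))
  out <- lapply(sets, function(w) {
    sx <- w$sex[1]; st <- w$state[1]
    present <- lapply(populations, function(p) {
      rows <- table[table$population == p & table$sex == sx, ]
      if (st %in% unique(table$state)) rows <- rows[rows$state == st, ]
      unique(as.character(rows$age_group))
    })
    common <- Reduce(intersect, present)
    w <- w[w$age_group %in% common, ]
    if (!nrow(w) || sum(w$weight) == 0) return(NULL)
    w$weight <- w$weight / sum(w$weight)
    w
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# age groups (per sex) with all three state cells in rates and proportions
# for both populations: the support on which the decomposition is defined
complete_decomposition_groups <- function(rates, props, populations) {
  need <- STATE_LABELS[TRANSIENT_IDX]
  strata <- unique(rates[, c("sex", "age_group")])
  ok <- vapply(seq_len(nrow(strata)), function(i) {
    all(vapply(populations, function(p) {
      r <- rates[rates$population == p & rates$sex == strata$sex[i] &
                   rates$age_group == strata$age_group[i], ]
      pr <- props[props$population == p & props$sex == strata$sex[i] &
                    props$age_group == strata$age_group[i], ]
      all(need %in% r$state) && all(need %in% pr$state)
    }, logical(1)))
  }, logical(1))
  strata[ok, , drop = FALSE]
}

merge_report <- function(...) {
  tables <- list(...)
  cols <- unique(unlist(lapply(tables, names)))
  out <- do.call(rbind, lapply(tables, function(t) {
    for (cc in setdiff(cols, names(t))) t[[cc]] <- NA
    t[, cols]
  }))
  rownames(out) <- NULL
  out
}

# hash of the analysis-relevant configuration (the output location does not
# affect report content, so two runs into different directories still match)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$output_dir <- NULL
  dput(lapply(x, function(e) if (is.function(e)) "function" else e), file = tmp)
  unname(tools::md5sum(tmp))
}

write_text_summary <- function(config, le, rates_std, decomp_std) {
  path <- file.path(config$output_dir, "summary.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w("Long-term-care multistate mortality report")
  w("baseline %s, follow-up %g years, index age %g, seed %d",
    format(config$baseline_date), config$follow_up_years, config$index_age,
    config$seed)
  w("")
  w("Remaining life expectancy at age %g (years):", config$index_age)
  for (i in seq_len(nrow(le))) {
    if (le$quantity[i] == "total") {
      w("  %-4s %-6s total %6.2f (no care %5.2f)", le$population[i], le$sex[i],
        le$estimate[i], le$estimate[le$population == le$population[i] &
                                      le$sex == le$sex[i] &
                                      le$quantity == "no_care"])
    }
  }
  w("")
  w("Age-standardized death rates per 1000 person-years (%s):",
    paste(config$comparison, collapse = " vs "))
  for (i in seq_len(nrow(rates_std))) {
    w("  %-4s %-6s %-9s %8.1f", rates_std$population[i], rates_std$sex[i],
      rates_std$state[i], rates_std$rate[i])
  }
  w("")
  w("Standardized decomposition of the total rate difference (%s):",
    decomp_std$comparison[1])
  for (i in seq_len(nrow(decomp_std))) {
    w("  %-6s total %7.1f = composition %6.1f + no care %6.1f + home care %6.1f + care home %6.1f",
      decomp_std$sex[i], decomp_std$total_difference[i], decomp_std$composition[i],
      decomp_std$rate_no_care[i], decomp_std$rate_home_care[i],
      decomp_std$rate_care_home[i])
  }
  path
}
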