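# Hand-built cohort: 10 persons in home care at exact age 80.0; by 80.25,
# 2 are in no care, 1 in a care home, 1 dead, 6 remain.
worked_example_panel <- function() {
  t80 <- as.Date("2017-04-01")           # everyone reaches age 80.0 on this date
  birth <- t80 - round(80 * 365.25)
  months <- seq(as.Date("2017-03-01"), as.Date("2017-08-01"), by = "month")
  # destination state occupied from May onward (age 80.25 falls in early July)
  dest <- c(0, 0, 2, rep(1, 6))          # person 10 dies instead
  rows <- lapply(1:10, function(i) {
    if (i == 10) {
      obs_end <- as.Date("2017-05-15")
      reason <- "death"
      mo <- months[months <= obs_end]
      st <- rep(1L, length(mo))
    } else {
      obs_end <- as.Date("2017-09-01")
      reason <- "end"
      mo <- months
      st <- c(1L, 1L, rep(as.integer(dest[i]), length(mo) - 2))
    }
    data.frame(person_id = sprintf("w%02d", i), population = "P", sex = "male",
               birth_date = birth, obs_start = months[1], obs_end = obs_end,
               end_reason = reason, month = mo, state = st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_date") <- as.Date("2017-04-01")
  class(out) <- c("ltc_panel", "data.frame")
  out
}

test_that("the home-care-at-80 worked example is counted cell by cell", {
  cnt <- count_transitions(worked_example_panel())
  k <- which(abs(cnt$ages - 80) < 1e-9)
  expect_equal(unname(cnt$at_risk["home_care", k]), 10)
  expect_equal(unname(cnt$counts["home_care", , k]), c(2, 6, 1, 1))

  raw <- raw_probabilities(cnt)
  expect_equal(unname(raw$P[2, , k]), c(0.2, 0.6, 0.1, 0.1))
})

test_that("a cohort without care or death puts all mass on the diagonal", {
  pan <- simulate_cohort(flat_scenario(cohort_size = 150, seed = 44))
  cnt <- count_transitions(stratum_panel(pan, "JPN", "male"))
  expect_equal(sum(cnt$counts["no_care", c("home_care", "care_home", "dead"), ]), 0)
  expect_equal(sum(cnt$at_risk["home_care", ]), 0)
  raw <- raw_probabilities(cnt)
  informative <- which(cnt$at_risk["no_care", ] > 0)
  expect_true(all(raw$P[1, 1, informative] == 1))
})

test_that("destination counts always sum to the at-risk count", {
  pan <- simulate_cohort(ltc_scenario(cohort_size = 300, seed = 45))
  cnt <- count_transitions(stratum_panel(pan, "SWE", "female"))
  for (i in 1:3) {
    expect_equal(unname(colSums(cnt$counts[i, , ])), unname(cnt$at_risk[i, ]))
  }
})

test_that("counting is equivariant to merging identical sub-cohorts", {
  pan <- stratum_panel(simulate_cohort(ltc_scenario(cohort_size = 150, seed = 46)),
                       "JPN", "female")
  twin <- as.data.frame(pan)
  twin$person_id <- paste0(twin$person_id, "_twin")
  both <- rbind(as.data.frame(pan), twin)
  attr(both, "baseline_date") <- attr(pan, "baseline_date")
  class(both) <- class(pan)
  c1 <- count_transitions(pan)
  c2 <- count_transitions(both)
  expect_equal(c2$counts, c1$counts * 2)
  expect_equal(raw_probabilities(c2)$P, raw_probabilities(c1)$P)
})

test_that("zero at-risk rows are missing in raw and imputed by smoothing", {
  ev <- list("no_care->dead" = rep(5, 140))
  cnt <- synthetic_counts(at_risk = 100, events = ev)
  cnt$at_risk[, 1:8] <- 0      # ages 70-71.75 unobserved
  cnt$counts[, , 1:8] <- 0
  raw <- raw_probabilities(cnt)
  expect_true(all(is.na(raw$P[1, , 1])))
  sm <- smooth_probabilities(cnt, mslt_control(k = 8))
  expect_false(anyNA(sm$P))
  expect_equal(sm$P[1, 4, 1], 0.05, tolerance = 0.01)
})

test_that("constant-signal counts are recovered within 0.01 everywhere", {
  set.seed(71)
  n <- 5000
  ev <- list("no_care->home_care" = rbinom(140, n, 0.10),
             "no_care->dead" = rbinom(140, n, 0.02),
             "home_care->dead" = rbinom(140, n, 0.05),
             "care_home->dead" = rbinom(140, n, 0.08))
  cnt <- synthetic_counts(at_risk = n, events = ev)
  sm <- smooth_probabilities(cnt)
  expect_lt(max(abs(sm$P[1, 2, ] - 0.10)), 0.01)
  expect_lt(max(abs(sm$P[1, 4, ] - 0.02)), 0.01)
  expect_lt(max(abs(sm$P[2, 4, ] - 0.05)), 0.01)
  expect_lt(max(abs(sm$P[3, 4, ] - 0.08)), 0.01)
  # smoothed rows are exactly stochastic and death stays absorbing
  expect_lt(max(abs(apply(sm$P, c(1, 3), sum) - 1)), 1e-9)
  expect_true(all(sm$P[4, 1:3, ] == 0))
})

test_that("a smooth logit-linear signal is reproduced within sampling error", {
  set.seed(72)
  ages <- grid_ages()
  p_true <- plogis(-4 + 0.08 * (ages - 75))
  n <- 10000
  ev <- list("no_care->dead" = rbinom(140, n, p_true))
  cnt <- synthetic_counts(at_risk = n, events = ev)
  sm <- smooth_probabilities(cnt)
  se <- sqrt(p_true * (1 - p_true) / n)
  within2 <- abs(sm$P[1, 4, ] - p_true) <= 2 * se
  expect_gte(mean(within2), 0.95)
})

test_that("the heavy-penalty limit is a straight line on the logit scale", {
  set.seed(73)
  ev <- list("no_care->dead" = rbinom(140, 2000, 0.05))
  cnt <- synthetic_counts(at_risk = 2000, events = ev)
  sm <- smooth_probabilities(cnt, mslt_control(sp = 1e8))
  lg <- qlogis(sm$P[1, 4, ])
  curvature <- diff(diff(lg))
  expect_lt(max(abs(curvature)), 1e-6)
})

test_that("too small a data span for the basis is a clear error", {
  ev <- list("no_care->dead" = rep(2, 140))
  cnt <- synthetic_counts(at_risk = 50, events = ev)
  cnt$at_risk[, 11:140] <- 0
  cnt$counts[, , 11:140] <- 0
  expect_error(smooth_probabilities(cnt, mslt_control(k = 15)), "basis|reduce k")
})

test_that("surfaces serialize to tidy CSV and back", {
  surf <- random_surface(3)
  path <- tempfile(fileext = ".csv")
  write_surface(surf, path)
  back <- read_surface(path, type = "true")
  expect_equal(back$P, surf$P, tolerance = 1e-12)
  expect_equal(back$ages, surf$ages)
})
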