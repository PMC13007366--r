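test_that("Wald proportion matches the Bernoulli closed form", {
  ci <- wald_proportion(50, 100)
  expect_equal(ci$proportion, 0.5)
  expect_equal(ci$lower, 0.402, tolerance = 5e-4)
  expect_equal(ci$upper, 0.598, tolerance = 5e-4)
  # bounds are clipped to [0, 1]
  lowp <- wald_proportion(1, 1000)
  expect_gte(lowp$lower, 0)
  expect_equal(wald_proportion(1, 1)$upper, 1)
})

test_that("baseline proportions partition each cell and handle extremes", {
  pan <- simulate_cohort(ltc_scenario(cohort_size = 400, seed = 61))
  pt <- baseline_proportions(pan)
  sums <- tapply(pt$proportion, paste(pt$population, pt$sex, pt$age_group), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(pt$lower >= 0 & pt$upper <= 1))

  solo <- point_panel(ages = 80, states = 1)
  ps <- baseline_proportions(solo, by_age = FALSE)
  expect_equal(ps$proportion[ps$state == "home_care"], 1)
  expect_equal(ps$proportion[ps$state == "no_care"], 0)
})

test_that("death rates follow the Poisson closed form per 1000 person-years", {
  baseline <- as.Date("2017-04-01")
  n_die <- 100; n_live <- 250
  ages <- rep(80, n_die + n_live)
  pan <- point_panel(ages, rep(0, n_die + n_live),
                     end_reason = c(rep("death", n_die), rep("end", n_live)),
                     obs_end = c(rep(baseline + round(2.5 * 365.25), n_die),
                                 rep(baseline + 1096, n_live)))
  rt <- death_rates(pan, baseline, 3, by_age = FALSE)
  row <- rt[rt$state == "no_care", ]
  expect_equal(row$deaths, 100)
  expect_equal(row$person_years, 1000, tolerance = 0.5)
  expect_equal(row$rate, 100, tolerance = 0.05)
  expect_equal(row$lower, 80.4, tolerance = 0.1)
  expect_equal(row$upper, 119.6, tolerance = 0.1)
  # no-death cell is flagged low information with a degenerate lower bound
  all_row <- rt[rt$state == "all", ]
  expect_false(all_row$low_information)
})

test_that("a constant-hazard cohort recovers its true rate within 3 SE", {
  # exponential death hazard 0.05 / year in no care only
  q3 <- 1 - exp(-0.05 / 4)
  pan <- simulate_cohort(flat_scenario(death = c(q3, 0, 0), cohort_size = 5000,
                                       seed = 62))
  rt <- death_rates(pan, follow_up_years = 3, by_age = FALSE)
  row <- rt[rt$population == "JPN" & rt$sex == "male" & rt$state == "no_care", ]
  se <- 1000 * sqrt(row$deaths) / row$person_years
  expect_lt(abs(row$rate - 50), 3 * se)
})

test_that("standardization reduces to weighted sums and own-weight identities", {
  tab <- data.frame(population = "A", sex = "female",
                    age_group = c("75-79", "80-84"), state = "all",
                    deaths = c(10, 20), person_years = c(1000, 1000),
                    rate = c(10, 20), se = c(1, 2),
                    lower = NA, upper = NA, low_information = FALSE)
  w_eq <- data.frame(sex = "female", state = "all",
                     age_group = c("75-79", "80-84"), weight = c(0.5, 0.5))
  expect_equal(standardize(tab, w_eq)$rate, 15)
  w_one <- transform(w_eq, weight = c(1, 0))
  expect_equal(standardize(tab, w_one)$rate, 10)
  expect_error(standardize(tab, transform(w_eq, age_group = c("75-79", "85-89"))),
               "lacks age group")

  # own person-years weights reproduce the crude rate exactly
  pan <- simulate_cohort(ltc_scenario(cohort_size = 300, seed = 63))
  rt_age <- death_rates(pan)
  rt_tot <- death_rates(pan, by_age = FALSE)
  sub <- rt_age[rt_age$population == "JPN" & rt_age$sex == "female" &
                  rt_age$state == "all", ]
  w_own <- data.frame(sex = "female", state = "all", age_group = sub$age_group,
                      weight = sub$person_years / sum(sub$person_years))
  std <- standardize(sub, w_own)
  crude <- rt_tot[rt_tot$population == "JPN" & rt_tot$sex == "female" &
                    rt_tot$state == "all", ]
  expect_equal(std$rate, crude$rate, tolerance = 1e-12)

  # own count weights reproduce the crude proportion exactly
  pt_age <- baseline_proportions(pan)
  pt_tot <- baseline_proportions(pan, by_age = FALSE)
  subp <- pt_age[pt_age$population == "SWE" & pt_age$sex == "male", ]
  denoms <- subp[subp$state == "no_care", c("age_group", "denom")]
  w_cnt <- data.frame(sex = "male", state = "all", age_group = denoms$age_group,
                      weight = denoms$denom / sum(denoms$denom))
  stdp <- standardize(subp, w_cnt)
  crudep <- pt_tot[pt_tot$population == "SWE" & pt_tot$sex == "male", ]
  expect_equal(stdp$proportion[match(crudep$state, stdp$state)],
               crudep$proportion, tolerance = 1e-12)
})

test_that("combined-cohort weights sum to one within sex and state", {
  pan <- simulate_cohort(ltc_scenario(cohort_size = 300, seed = 64))
  w <- standard_weights(pan)
  sums <- tapply(w$weight, paste(w$sex, w$state), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
})

test_that("population comparisons honor the closed forms and conventions", {
  mk_rate <- function(pop, rate, deaths) {
    data.frame(population = pop, sex = "male", age_group = "std", state = "all",
               deaths = deaths, person_years = 1000 * deaths / rate,
               rate = rate, se = 1000 * sqrt(deaths) / (1000 * deaths / rate),
               lower = NA, upper = NA, low_information = FALSE)
  }
  tab <- rbind(mk_rate("A", 100, 100), mk_rate("B", 50, 50))
  d <- compare_populations(tab, c("A", "B"), "difference")
  expect_equal(d$estimate, 50)
  expect_equal(d$comparison, "A - B")
  halfwidth <- 1.96 * 1000 * sqrt(100 + 50) / 1000
  expect_equal(d$upper - d$estimate, halfwidth, tolerance = 1e-3)

  r <- compare_populations(tab, c("A", "B"), "ratio")
  expect_equal(r$estimate, 2)

  same <- compare_populations(rbind(mk_rate("A", 80, 64), mk_rate("B", 80, 64)),
                              c("A", "B"), "difference")
  expect_equal(same$estimate, 0)
  same_r <- compare_populations(rbind(mk_rate("A", 80, 64), mk_rate("B", 80, 64)),
                                c("A", "B"), "ratio")
  expect_equal(same_r$estimate, 1)

  zero <- rbind(mk_rate("A", 10, 10),
                transform(mk_rate("B", 10, 10), rate = 0, deaths = 0))
  zr <- compare_populations(zero, c("A", "B"), "ratio")
  expect_true(is.na(zr$estimate))
  expect_equal(zr$flag, "zero_denominator")
})

test_that("death rates are additive under cohort concatenation", {
  pan1 <- simulate_cohort(ltc_scenario(cohort_size = 200, seed = 65))
  pan2 <- simulate_cohort(ltc_scenario(cohort_size = 200, seed = 66))
  p2 <- as.data.frame(pan2)
  p2$person_id <- paste0(p2$person_id, "_b")
  both <- rbind(as.data.frame(pan1), p2)
  attr(both, "baseline_date") <- attr(pan1, "baseline_date")
  class(both) <- class(pan1)
  r1 <- death_rates(pan1, by_age = FALSE)
  r2 <- death_rates(pan2, by_age = FALSE)
  rb <- death_rates(both, by_age = FALSE)
  key <- function(d) paste(d$population, d$sex, d$state)
  m1 <- match(key(rb), key(r1)); m2 <- match(key(rb), key(r2))
  ok <- !is.na(m1) & !is.na(m2)
  expect_equal(rb$deaths[ok], r1$deaths[m1[ok]] + r2$deaths[m2[ok]])
  expect_equal(rb$person_years[ok], r1$person_years[m1[ok]] + r2$person_years[m2[ok]],
               tolerance = 1e-9)
})
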