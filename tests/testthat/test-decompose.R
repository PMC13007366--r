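test_that("the two-state toy decomposition reproduces direct arithmetic", {
  kc <- kitagawa_components(c(0.9, 0.1), c(10, 100), c(0.8, 0.2), c(12, 140))
  expect_equal(kc$total, -18.6, tolerance = 1e-12)
  expect_equal(kc$composition + sum(kc$rate), kc$total, tolerance = 1e-12)
  expect_equal(kc$rate, c(-1.7, -6), tolerance = 1e-12)
  expect_equal(kc$composition, -10.9, tolerance = 1e-12)
})

test_that("identical inputs give identically zero components", {
  kc <- kitagawa_components(c(0.5, 0.3, 0.2), c(5, 50, 200),
                            c(0.5, 0.3, 0.2), c(5, 50, 200))
  expect_equal(kc$total, 0)
  expect_equal(kc$composition, 0)
  expect_equal(kc$rate, c(0, 0, 0))
})

test_that("equal rates put the whole difference into composition", {
  kc <- kitagawa_components(c(0.7, 0.2, 0.1), c(10, 60, 150),
                            c(0.5, 0.3, 0.2), c(10, 60, 150))
  expect_equal(kc$rate, c(0, 0, 0))
  expect_equal(kc$composition, kc$total, tolerance = 1e-12)
})

test_that("additivity and antisymmetry hold on 1000 random fixtures", {
  set.seed(81)
  worst_add <- 0
  for (r in 1:1000) {
    piA <- as.numeric(stats::rexp(3)); piA <- piA / sum(piA)
    piB <- as.numeric(stats::rexp(3)); piB <- piB / sum(piB)
    mA <- stats::runif(3, 0, 400)
    mB <- stats::runif(3, 0, 400)
    kc <- kitagawa_components(piA, mA, piB, mB)
    worst_add <- max(worst_add,
                     abs(kc$composition + sum(kc$rate) - kc$total))
    swap <- kitagawa_components(piB, mB, piA, mA)
    expect_equal(swap$total, -kc$total, tolerance = 1e-9)
    expect_equal(swap$composition, -kc$composition, tolerance = 1e-9)
    expect_equal(swap$rate, -kc$rate, tolerance = 1e-9)
    st <- kitagawa_components(piA, mA, piB, mB, method = "stepwise")
    expect_equal(st$rate, kc$rate, tolerance = 1e-9)
    expect_equal(st$composition, kc$composition, tolerance = 1e-9)
  }
  expect_lt(worst_add, 1e-9)
})

mk_tables <- function(rates_list, props_list, sexes = "male", ages = "75-79") {
  states <- c("no_care", "home_care", "care_home")
  rows_r <- list(); rows_p <- list()
  for (pop in names(rates_list)) {
    for (sx in sexes) for (ag in ages) {
      m <- rates_list[[pop]][[paste(sx, ag)]]
      pi <- props_list[[pop]][[paste(sx, ag)]]
      rows_r[[paste(pop, sx, ag)]] <- data.frame(
        population = pop, sex = sx, age_group = ag,
        state = c(states, "all"), deaths = 10, person_years = 100,
        rate = c(m, sum(pi * m)), se = 1, lower = NA, upper = NA,
        low_information = FALSE)
      rows_p[[paste(pop, sx, ag)]] <- data.frame(
        population = pop, sex = sx, age_group = ag, state = states,
        count = round(pi * 1000), denom = 1000, proportion = pi,
        se = 0.01, lower = NA, upper = NA)
    }
  }
  list(rates = do.call(rbind, rows_r), props = do.call(rbind, rows_p))
}

test_that("decompose_rates validates inputs and matches the kernel arithmetic", {
  pi_A <- c(0.8, 0.15, 0.05); m_A <- c(10, 80, 200)
  pi_B <- c(0.7, 0.18, 0.12); m_B <- c(11, 110, 260)
  tb <- mk_tables(list(A = list("male 75-79" = m_A), B = list("male 75-79" = m_B)),
                  list(A = list("male 75-79" = pi_A), B = list("male 75-79" = pi_B)))
  d <- decompose_rates(tb$rates, tb$props, c("A", "B"))
  kc <- kitagawa_components(pi_A, m_A, pi_B, m_B)
  expect_equal(d$total_difference, kc$total)
  expect_equal(d$composition, kc$composition)
  expect_equal(c(d$rate_no_care, d$rate_home_care, d$rate_care_home), kc$rate)

  # missing state cell names the stratum
  broken <- tb$rates[!(tb$rates$population == "B" & tb$rates$state == "home_care"), ]
  expect_error(decompose_rates(broken, tb$props, c("A", "B")), "home_care.*B|missing")

  # shares not summing to one are a hard error
  bad_props <- tb$props
  bad_props$proportion[1] <- bad_props$proportion[1] + 0.05
  expect_error(decompose_rates(tb$rates, bad_props, c("A", "B")), "sum to")
})

test_that("standardized decomposition is the weighted sum of age-specific rows", {
  set.seed(82)
  ages <- c("75-79", "80-84", "85-89")
  rates_list <- list(); props_list <- list()
  for (pop in c("A", "B")) {
    rates_list[[pop]] <- list(); props_list[[pop]] <- list()
    for (ag in ages) {
      pi <- as.numeric(stats::rexp(3)); pi <- pi / sum(pi)
      rates_list[[pop]][[paste("male", ag)]] <- stats::runif(3, 5, 300)
      props_list[[pop]][[paste("male", ag)]] <- pi
    }
  }
  tb <- mk_tables(rates_list, props_list, ages = ages)
  w <- data.frame(sex = "male", state = "all", age_group = ages,
                  weight = c(0.5, 0.3, 0.2))
  std <- decompose_standardized(tb$rates, tb$props, c("A", "B"), w)
  agewise <- decompose_rates(tb$rates, tb$props, c("A", "B"))
  for (cc in c("total_difference", "composition", "rate_no_care",
               "rate_home_care", "rate_care_home")) {
    manual <- sum(w$weight * agewise[[cc]][match(ages, agewise$age_group)])
    expect_equal(std[[cc]], manual, tolerance = 1e-9)
  }
  expect_equal(std$composition + std$rate_no_care + std$rate_home_care +
                 std$rate_care_home, std$total_difference, tolerance = 1e-9)

  # single age group with unit weight degenerates to the age-specific row
  w1 <- data.frame(sex = "male", state = "all", age_group = ages,
                   weight = c(1, 0, 0))
  std1 <- decompose_standardized(tb$rates, tb$props, c("A", "B"), w1)
  expect_equal(std1$total_difference,
               agewise$total_difference[agewise$age_group == "75-79"])
})
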