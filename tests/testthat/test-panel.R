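demo_panel_path <- system.file("extdata", "demo_panel.csv", package = "carestates")

test_that("panel reading handles empty and single-person files", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(paste(c("person_id", "population", "sex", "birth_date", "obs_start",
                     "obs_end", "end_reason", "month", "state"), collapse = ","), tmp)
  empty <- read_panel(tmp)
  expect_s3_class(empty, "ltc_panel")
  expect_equal(nrow(empty), 0)

  months <- seq(as.Date("2017-04-01"), by = "month", length.out = 36)
  df <- data.frame(person_id = "a", population = "P", sex = "male",
                   birth_date = as.Date("1940-01-15"),
                   obs_start = months[1], obs_end = as.Date("2020-03-20"),
                   end_reason = "death", month = months, state = 0L)
  write_panel(as_panel <- structure(df, class = c("ltc_panel", "data.frame")), tmp)
  got <- read_panel(tmp)
  expect_equal(length(unique(got$person_id)), 1)
  expect_equal(nrow(got), 36)
})

test_that("panel files round-trip byte-identically", {
  pan <- read_panel(demo_panel_path)
  tmp <- tempfile(fileext = ".csv")
  write_panel(pan, tmp)
  expect_identical(readLines(tmp), readLines(demo_panel_path))
})

test_that("malformed panels are rejected with informative errors", {
  pan <- utils::read.csv(demo_panel_path, stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")

  dup <- rbind(pan, pan[1, ])
  utils::write.csv(dup, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_panel(tmp), "duplicate")

  bad <- pan
  bad$state[3] <- 7L
  utils::write.csv(bad, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_panel(tmp), "7")

  bad2 <- pan
  bad2$birth_date[2] <- "15/01/1940"
  utils::write.csv(bad2, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_panel(tmp), "line")
})

test_that("mid-month care episodes classify baseline by highest care level", {
  baseline <- as.Date("2017-04-01")
  persons <- data.frame(
    person_id = c("march_home", "march_ch_entry", "never_care"),
    population = "P", sex = "female", birth_date = as.Date("1937-06-15"),
    obs_start = as.Date("2017-01-01"), obs_end = as.Date("2020-04-01"),
    end_reason = "end", stringsAsFactors = FALSE)
  episodes <- data.frame(
    person_id = c("march_home", "march_ch_entry", "march_ch_entry"),
    start = as.Date(c("2017-02-10", "2017-01-05", "2017-03-15")),
    end = as.Date(c("2017-05-30", "2017-03-14", "2020-04-01")),
    state = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  pan <- episodes_to_panel(persons, episodes)
  bs <- baseline_states(pan, baseline)
  expect_equal(bs$state[bs$person_id == "march_home"], 1L)
  # entered a care home on March 15: highest level in the reference month wins
  expect_equal(bs$state[bs$person_id == "march_ch_entry"], 2L)
  expect_equal(bs$state[bs$person_id == "never_care"], 0L)
})

test_that("persons outside observation at baseline are excluded, not errored", {
  baseline <- as.Date("2017-04-01")
  persons <- data.frame(
    person_id = c("late_entry", "in_time"),
    population = "P", sex = "male", birth_date = as.Date("1935-01-01"),
    obs_start = as.Date(c("2017-06-01", "2016-12-01")),
    obs_end = as.Date("2020-04-01"),
    end_reason = "end", stringsAsFactors = FALSE)
  pan <- episodes_to_panel(persons,
                           data.frame(person_id = character(), start = as.Date(character()),
                                      end = as.Date(character()), state = integer()))
  bs <- baseline_states(pan, baseline)
  expect_true(is.na(bs$state[bs$person_id == "late_entry"]))
  expect_equal(bs$state[bs$person_id == "in_time"], 0L)
})

test_that("person-years follow death, censoring and window end exactly", {
  baseline <- as.Date("2017-04-01")
  mk <- function(id, obs_end, end_reason) {
    data.frame(person_id = id, population = "P", sex = "male",
               birth_date = as.Date("1940-01-01"), obs_start = as.Date("2017-03-01"),
               obs_end = obs_end, end_reason = end_reason, stringsAsFactors = FALSE)
  }
  persons <- rbind(mk("survivor", baseline + round(3 * 365.25), "end"),
                   mk("dies", baseline + round(1.5 * 365.25), "death"),
                   mk("moves", baseline + round(2 * 365.25), "censored"))
  pan <- episodes_to_panel(persons,
                           data.frame(person_id = character(), start = as.Date(character()),
                                      end = as.Date(character()), state = integer()))
  py <- person_years(pan, baseline, 3)
  expect_equal(py$person_years[py$person_id == "survivor"], 3, tolerance = 2e-3)
  expect_equal(py$person_years[py$person_id == "dies"], 1.5, tolerance = 2e-3)
  expect_equal(py$person_years[py$person_id == "moves"], 2, tolerance = 2e-3)
  expect_equal(py$died[match(c("survivor", "dies", "moves"), py$person_id)],
               c(FALSE, TRUE, FALSE))
})

test_that("cohort person-time and baseline partition invariants hold", {
  pan <- simulate_cohort(ltc_scenario(cohort_size = 250, seed = 14))
  py <- person_years(pan, follow_up_years = 3)
  n <- length(unique(pan$person_id))
  expect_lte(sum(py$person_years), n * 3 + 1e-9)
  bs <- baseline_states(pan)
  bs <- bs[!is.na(bs$state), ]
  expect_equal(sum(table(bs$state)), nrow(bs))
  expect_true(all(bs$state %in% 0:2))
})
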