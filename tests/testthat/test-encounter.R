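toy_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("a toy file parses into records and a session calendar", {
  f <- toy_csv(c("id,date,sex,x,y,wing",
                 "a1,2016-07-20,M,10,20,1",
                 "a1,2016-07-22,M,30,40,2",
                 "b2,2016-07-22,F,5,5,1"))
  cap <- read_captures(f)
  expect_equal(nrow(cap$records), 3)
  expect_equal(nrow(cap$sessions), 2)
  expect_equal(cap$sessions$gap_days, c(2L, NA))
  expect_equal(cap$records$sex, c("male", "male", "female"))
  expect_equal(cap$records$session, c(1L, 2L, 2L))
})

test_that("schema and row-level validation errors are specific", {
  f <- toy_csv(c("id,date,sex,x,y",
                 "a1,2016-07-20,M,10,20"))
  expect_error(read_captures(f), "wing", class = "mrrkit_schema_error")

  f <- toy_csv(c("id,date,sex,x,y,wing",
                 "a1,2016-07-20,M,10,20,1",
                 "a2,2016-07-20,M,10,20,5"))
  expect_error(read_captures(f), "row\\(s\\): 2", class = "mrrkit_validation_error")

  f <- toy_csv(c("id,date,sex,x,y,wing",
                 "a1,2016-07-20,Q,10,20,1"))
  expect_error(read_captures(f), "sex", class = "mrrkit_validation_error")

  f <- toy_csv(c("id,date,sex,x,y,wing,behaviour,family,genus",
                 "a1,2016-07-20,M,10,20,1,flying,Asteraceae,Taraxacum"))
  expect_error(read_captures(f), "non-feeding", class = "mrrkit_validation_error")
})

test_that("geodetic coordinates project to local metres, or propagate flagged", {
  # ~68.37N: one longitude degree is about 41 km, one latitude degree ~111 km
  f <- toy_csv(c("id,date,sex,x,y,wing,crs",
                 "a1,2016-07-20,M,18.7000,68.3700,1,geodetic",
                 "a1,2016-07-22,M,18.7010,68.3700,1,geodetic",
                 "a1,2016-07-25,M,18.7000,68.3709,2,geodetic"))
  cap <- read_captures(f)
  expect_true(all(cap$records$crs == "metric"))
  h <- build_histories(cap$records, cap$sessions)
  mv <- movement_distances(h)
  expect_equal(mv$distance[1], 41.0, tolerance = 0.02)
  expect_equal(mv$distance[2], sqrt(41.0^2 + 100.1^2), tolerance = 0.02)

  capg <- read_captures(f, project = FALSE)
  expect_true(all(capg$records$crs == "geodetic"))
  hg <- build_histories(capg$records, capg$sessions)
  expect_error(movement_distances(hg), class = "mrrkit_geodetic_error")
})

test_that("histories collapse duplicates, are order-independent and idempotent", {
  rec <- tibble::tibble(
    id = c("a", "a", "a", "b", "b"),
    date = as.Date(c("2016-07-20", "2016-07-24", "2016-07-24",
                     "2016-07-20", "2016-07-28")),
    sex = c("male", "male", "male", "female", "female"),
    x = 1:5, y = 1:5, wing = c(1L, 2L, 3L, 1L, 2L))
  sessions <- tibble::tibble(session = 1:4,
                             date = as.Date("2016-07-20") + c(0, 4, 6, 8),
                             hours = rep(3, 4),
                             gap_days = c(4L, 2L, 2L, NA))
  expect_message(h <- build_histories(rec, sessions), "collapsed 1")
  expect_equal(sort(h$ch), sort(c("1100", "1001")))
  expect_equal(attr(h, "n_collapsed"), 1L)
  # first payload kept for the collapsed detection
  a <- h[h$id == "a", ]$detections[[1]]
  expect_equal(a$wing, c(1L, 2L))
  # order independence
  for (s in 1:3) {
    sh <- rec[withr::with_seed(s, sample(nrow(rec))), ]
    h2 <- suppressMessages(build_histories(sh, sessions))
    expect_equal(dplyr::arrange(tibble::as_tibble(h2)[, c("id", "ch")], id),
                 dplyr::arrange(tibble::as_tibble(h)[, c("id", "ch")], id))
  }
})

test_that("conflicting sex codes are a hard error and empty input warns", {
  sessions <- tibble::tibble(session = 1:2,
                             date = as.Date("2016-07-20") + c(0, 2),
                             hours = c(3, 3), gap_days = c(2L, NA))
  rec <- tibble::tibble(id = c("a", "a"),
                        date = sessions$date,
                        sex = c("male", "female"), x = 1:2, y = 1:2,
                        wing = c(1L, 2L))
  expect_error(build_histories(rec, sessions), "a",
               class = "mrrkit_sex_conflict")
  expect_warning(h0 <- build_histories(rec[0, ], sessions), "empty")
  expect_equal(nrow(h0), 0)
})

test_that("capture summary counts marked, recaptured and frequencies", {
  sessions <- tibble::tibble(session = 1:4,
                             date = as.Date("2016-07-20") + 0:3,
                             hours = rep(3, 4), gap_days = c(1L, 1L, 1L, NA))
  mk <- function(id, ch) {
    det <- which(strsplit(ch, "")[[1]] == "1")
    tibble::tibble(id = id, date = sessions$date[det], sex = "male",
                   x = 0, y = 0, wing = 1L)
  }
  rec <- dplyr::bind_rows(mk("a", "1010"), mk("b", "1000"), mk("c", "1111"))
  h <- build_histories(rec, sessions)
  s <- summarize_captures(h)
  male <- s$summary[s$summary$sex == "male", ]
  expect_equal(male$marked, 3)
  expect_equal(male$recaptured, 2)
  expect_equal(s$frequencies$n_recaptures, c(1L, 3L))
  expect_equal(s$frequencies$n_individuals, c(1L, 1L))
  # conservation: sum(multiplicity x count) + marked = total capture events
  expect_equal(sum(s$frequencies$n_recaptures * s$frequencies$n_individuals) +
                 male$marked, male$capture_events)
  # all singletons
  h1 <- build_histories(dplyr::bind_rows(mk("a", "1000"), mk("b", "0100")),
                        sessions)
  s1 <- summarize_captures(h1)
  expect_equal(s1$summary$recaptured[s1$summary$sex == "male"], 0)
})

test_that("capture summary agrees with the simulator's ground-truth log", {
  sim <- simulate_mrr(toy_popan_config(seed = 1))
  h <- build_histories(sim$records, sim$sessions)
  s <- summarize_captures(h)
  truth_marked <- length(unique(unlist(sim$truth$captured_ids)))
  expect_equal(s$summary$marked[s$summary$sex == "all"], truth_marked)
  expect_equal(sum(s$summary$capture_events[s$summary$sex == "all"]),
               sum(lengths(sim$truth$captured_ids)))
})

test_that("MARK .inp export round-trips through the reader", {
  sessions <- tibble::tibble(session = 1:3,
                             date = as.Date("2016-07-20") + 0:2,
                             hours = rep(3, 3), gap_days = c(1L, 1L, NA))
  rec <- tibble::tibble(
    id = c("m1", "m1", "f1"),
    date = sessions$date[c(1, 3, 2)],
    sex = c("male", "male", "female"),
    x = 0, y = 0, wing = 1L)
  h <- build_histories(rec, sessions)
  lines <- export_inp(h)
  expect_setequal(lines, c("101 1 0;", "010 0 1;"))

  sim <- simulate_mrr(toy_popan_config(seed = 4, n_super = 60))
  hs <- build_histories(sim$records, sim$sessions)
  back <- read_inp(export_inp(hs))
  expect_equal(sort(paste(back$sex, back$ch)), sort(paste(hs$sex, hs$ch)))
})

test_that("written records re-read identically (round trip)", {
  sim <- simulate_mrr(toy_popan_config(seed = 2, n_super = 50))
  f <- write_captures_csv(sim$records[, c("id", "date", "sex", "x", "y", "crs",
                                          "wing", "behaviour", "family", "genus")])
  eff <- tibble::tibble(date = sim$sessions$date, hours = sim$sessions$hours)
  cap <- read_captures(f, effort = eff)
  expect_equal(cap$records$id, sim$records$id)
  expect_equal(cap$records$wing, sim$records$wing)
  expect_equal(cap$records$x, sim$records$x, tolerance = 1e-12)
  expect_equal(cap$records$behaviour, sim$records$behaviour)
  expect_equal(cap$records$session, sim$records$session)
})
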