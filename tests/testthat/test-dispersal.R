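sessions4 <- tibble::tibble(session = 1:4,
                            date = as.Date("2016-07-20") + c(0, 2, 5, 9),
                            hours = rep(3, 4), gap_days = c(2L, 3L, 4L, NA))

hist_from_points <- function(pts) {
  # pts: list(id = list(sex, sessions, x, y))
  rec <- purrr::map_dfr(names(pts), function(id) {
    p <- pts[[id]]
    tibble::tibble(id = id, date = sessions4$date[p$sessions], sex = p$sex,
                   x = p$x, y = p$y, wing = 1L)
  })
  build_histories(rec, sessions4)
}

test_that("movement distances are Euclidean, one per consecutive pair", {
  h <- hist_from_points(list(
    a = list(sex = "male", sessions = c(1, 2), x = c(0, 3), y = c(0, 4)),
    b = list(sex = "female", sessions = 1:4, x = c(0, 1, 1, 5),
             y = c(0, 1, 2, 2))))
  mv <- movement_distances(h)
  expect_equal(mv$distance[mv$id == "a"], 5)           # 3-4-5 triangle
  expect_equal(sum(mv$id == "b"), 3)                   # 4 detections, 3 moves
  expect_equal(mv$days[mv$id == "a"], 2)
  s <- movement_summary(mv)
  expect_equal(s$n[s$sex == "female"], 3)
})

test_that("simulated moves reproduce the configured kernel mean", {
  mu <- 140
  for (s in 1:5) {
    d <- withr::with_seed(100 + s, rexp(200, 1 / mu))
    expect_lt(abs(mean(d) - mu), 2 * sd(d) / sqrt(length(d)))
  }
})

test_that("the sex comparison matches exact and permutation references", {
  mk_moves <- function(male, female) {
    structure(tibble::tibble(
      id = seq_along(c(male, female)),
      sex = rep(c("male", "female"), c(length(male), length(female))),
      distance = c(male, female)), class = c("movement_set", "tbl_df",
                                             "tbl", "data.frame"))
  }
  # complete separation
  r <- compare_sexes(mk_moves(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$U, 0)
  # identical samples: U = n1 n2 / 2, p = 1
  r2 <- compare_sexes(mk_moves(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r2$U, 4.5)
  expect_equal(r2$p_value, 1)
  # exact p equals the full permutation distribution
  x <- c(12, 35, 47, 81); y <- c(25, 56, 90, 110, 140)
  r3 <- compare_sexes(mk_moves(x, y))
  expect_equal(r3$method, "exact")
  expect_equal(r3$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
  # one empty sex errors
  expect_error(compare_sexes(mk_moves(c(1, 2), numeric(0))),
               class = "mrrkit_validation_error")
})

test_that("ICP tables enumerate classes with the >= lower-bound rule", {
  icp <- icp_table(c(10, 60, 120), width = 50)
  expect_equal(icp$icp, c(1, 2 / 3, 1 / 3))
  expect_equal(icp$lower, c(0, 50, 100))
  # all moves below the width: single class
  expect_equal(icp_table(c(5, 10), width = 50)$icp, 1)
  # scale invariance
  icp10 <- icp_table(c(100, 600, 1200), width = 500)
  expect_equal(icp10$icp, icp$icp)
  expect_error(icp_table(c(1, 2), width = 0), class = "mrrkit_validation_error")
  # properties on random draws: I1 = 1 and monotone non-increasing
  for (s in 1:10) {
    d <- withr::with_seed(s, rexp(50, 1 / 80))
    tab <- icp_table(d, width = 30)
    expect_equal(tab$icp[1], 1)
    expect_true(all(diff(tab$icp) <= 0))
    expect_true(all(tab$icp > 0))
  }
})

test_that("per-individual ICP uses only the first move of each individual", {
  h <- hist_from_points(list(
    a = list(sex = "male", sessions = 1:3, x = c(0, 30, 300), y = c(0, 0, 0))))
  mv <- movement_distances(h)
  t_all <- icp_table(mv, width = 50)
  t_first <- icp_table(mv, width = 50, per_individual = TRUE)
  expect_equal(attr(t_all, "n_moves"), 2)
  expect_equal(attr(t_first, "n_moves"), 1)
  expect_equal(nrow(t_first), 1)
})

test_that("exact-model ICP inputs recover kernel parameters to 1e-10", {
  i <- 1:8
  nef <- icp_table(c(1, 2), 50)  # placeholder shell, replaced below
  tab_nef <- structure(tibble::tibble(class = i, lower = (i - 1) * 50,
                                      icp = exp(-0.5 * i)),
                       class = class(nef), width = 50)
  f_nef <- fit_kernel(tab_nef, "NEF")
  expect_equal(f_nef$k, 0.5, tolerance = 1e-10)
  expect_equal(f_nef$r2_adj, 1, tolerance = 1e-10)
  tab_ipf <- structure(tibble::tibble(class = i, lower = (i - 1) * 50,
                                      icp = i^(-2)),
                       class = class(nef), width = 50)
  f_ipf <- fit_kernel(tab_ipf, "IPF")
  expect_equal(f_ipf$k, 2, tolerance = 1e-10)
  expect_equal(f_ipf$r2_adj, 1, tolerance = 1e-10)
  expect_error(fit_kernel(tab_nef[1:2, ], "NEF"),
               class = "mrrkit_insufficient_data")
})

test_that("NEF beats IPF on exponential data and tails order correctly", {
  wins <- 0; checked <- 0
  for (s in 1:30) {
    d <- withr::with_seed(s, rexp(65, 1 / 140))
    icp <- icp_table(d, width = 20)
    fn <- tryCatch(fit_kernel(icp, "NEF"), error = function(e) NULL)
    fi <- tryCatch(fit_kernel(icp, "IPF"), error = function(e) NULL)
    if (is.null(fn) || is.null(fi)) next
    checked <- checked + 1
    wins <- wins + (fn$r2_adj > fi$r2_adj)
    # fitted NEF predictions strictly decreasing; same for IPF
    xs <- 1:30
    expect_true(all(diff(predict(fn, xs)) < 0))
    expect_true(all(diff(predict(fi, xs)) < 0))
    # far beyond the data the exponential tail is below the power tail
    expect_lt(predict(fn, 200), predict(fi, 200))
  }
  expect_gte(wins / checked, 0.8)
})

test_that("extrapolation maps distances onto interval numbers and percentages", {
  i <- 1:10
  tab <- structure(tibble::tibble(class = i, lower = (i - 1) * 50,
                                  icp = exp(-0.3 * i)),
                   class = c("icp_table", class(tibble::tibble())), width = 50)
  f <- fit_kernel(tab, "NEF")
  ex <- extrapolate_kernel(f, c(1, 2, 3, 5))
  expect_equal(ex$interval, c(20, 40, 60, 100))
  # NEF a = 1, k = 0.3 at x = 20: e^-6 as a percentage
  expect_equal(ex$percent[1], 100 * exp(-6), tolerance = 1e-9)
  # IPF closed form: a = 1, k = 2 at x = 100 -> 0.01%
  tab_ipf <- structure(tibble::tibble(class = i, lower = (i - 1) * 50,
                                      icp = i^(-2)),
                       class = c("icp_table", class(tibble::tibble())),
                       width = 50)
  fi <- fit_kernel(tab_ipf, "IPF")
  expect_equal(extrapolate_kernel(fi, 5)$percent, 0.01, tolerance = 1e-9)
  expect_error(extrapolate_kernel(f, -1), class = "mrrkit_validation_error")
})
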