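test_that("Jacobs' index reproduces the published worked values", {
  # family level: visits (54, 3, 1, 1) of 59, printed availabilities
  expect_equal(round(jacobs_index(54 / 59, 0.265), 2), 0.94)
  expect_equal(round(jacobs_index(3 / 59, 0.060), 2), -0.09)
  expect_equal(round(jacobs_index(1 / 59, 0.220), 2), -0.88)
  expect_equal(round(jacobs_index(1 / 59, 0.070), 2), -0.63)
  # genus level
  expect_equal(round(jacobs_index(1 / 59, 0.025), 2), -0.20)
  expect_equal(round(jacobs_index(3 / 59, 0.045), 2), 0.06)
  expect_equal(round(jacobs_index(50 / 59, 0.070), 2), 0.97)
})

test_that("Jacobs' index obeys its limits and properties", {
  expect_equal(jacobs_index(0.5, 0.5), 0)
  expect_equal(jacobs_index(1, 0.3), 1)
  expect_equal(jacobs_index(0, 0.3), -1)
  expect_error(jacobs_index(0, 0), class = "mrrkit_degenerate_index")
  expect_error(jacobs_index(1.2, 0.5), class = "mrrkit_validation_error")
  # antisymmetry and monotonicity on a grid
  g <- seq(0.05, 0.95, by = 0.09)
  for (r in g) for (p in g) {
    expect_equal(jacobs_index(r, p), -jacobs_index(p, r), tolerance = 1e-12)
  }
  for (p in g) {
    expect_true(all(diff(jacobs_index(g, p)) > 0))     # increasing in r
    expect_true(all(diff(jacobs_index(p, g)) < 0))     # decreasing in p
  }
})

test_that("the rating thresholds are the closed neutral interval", {
  expect_equal(classify_jacobs(c(0.94, 0.06, -0.63, -0.88, -0.20, 0.97)),
               c("+", "=", "-", "-", "=", "+"))
  expect_equal(classify_jacobs(c(0.33, -0.33)), c("=", "="))
  expect_equal(classify_jacobs(c(0.3301, -0.3301)), c("+", "-"))
})

test_that("simultaneous intervals sit inside Bonferroni exact binomial bounds", {
  for (method in c("arcsine", "goodman")) {
    for (case in list(c(8, 12), c(3, 17), c(10, 10))) {
      n <- sum(case)
      ci <- bailey_cis(case, alpha = 0.05, method = method)
      for (i in 1:2) {
        ex <- oracle_binom_ci(case[i], n, alpha = 0.05 / 2)
        expect_gte(ci$lower[i], ex[["lower"]] - 1e-9)
        expect_lte(ci$upper[i], ex[["upper"]] + 1e-9)
      }
    }
  }
})

test_that("interval structure: zero counts, widths, errors", {
  ci <- bailey_cis(c(0, 5, 15), alpha = 0.05)
  expect_equal(ci$lower[1], 0)
  expect_true(all(ci$lower <= ci$upper))
  expect_true(all(ci$lower >= 0 & ci$upper <= 1))
  # widths shrink as n grows at fixed proportions
  w1 <- with(bailey_cis(c(10, 30)), upper - lower)
  w2 <- with(bailey_cis(c(100, 300)), upper - lower)
  expect_true(all(w2 < w1))
  expect_error(bailey_cis(5, k = 1), class = "mrrkit_validation_error")
  # rating against availability
  ci2 <- bailey_cis(c(54, 5), n = 59, k = 18, availability = c(0.265, 0.7))
  expect_equal(ci2$rating, c("+", "-"))
})

test_that("the chi-squared homogeneity test matches its definition", {
  expect_equal(chisq_homogeneity(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chisq_homogeneity(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  r <- chisq_homogeneity(rbind(c(20, 0), c(0, 20)))
  expect_equal(r$statistic, 40)
  expect_equal(r$df, 1)
  # definition oracle on random tables + invariances
  for (s in 1:10) {
    tab <- withr::with_seed(s, matrix(rpois(8, 12) + 1, nrow = 2))
    got <- chisq_homogeneity(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(got$df, 3)
    # row swap invariance
    expect_equal(chisq_homogeneity(tab[2:1, ])$statistic, got$statistic)
    # scaling counts by c scales the statistic by c
    expect_equal(chisq_homogeneity(tab * 3)$statistic, 3 * got$statistic,
                 tolerance = 1e-10)
  }
  expect_warning(chisq_homogeneity(rbind(c(5, 0, 3), c(4, 0, 2))), "zero")
  expect_error(chisq_homogeneity(rbind(5, 4)), class = "mrrkit_validation_error")
})

avail_family <- tibble::tibble(
  level = "family",
  taxon = c("Asteraceae", "Caryophyllaceae", "Ranunculaceae", "Rosaceae"),
  proportion = c(0.265, 0.060, 0.220, 0.070))

feeding_records <- function(counts, level_col, taxa, sex_split = 0.5) {
  n <- sum(counts)
  tx <- rep(taxa, counts)
  tibble::tibble(id = sprintf("v%03d", 1:n),
                 date = as.Date("2016-07-25"),
                 sex = rep(c("male", "female"), length.out = n),
                 x = 0, y = 0, wing = 1L, behaviour = "feeding",
                 family = if (level_col == "family") tx else "Asteraceae",
                 genus = if (level_col == "genus") tx else NA_character_)
}

test_that("the family-level selection table reproduces the worked example", {
  rec <- feeding_records(c(54, 3, 1, 1), "family", avail_family$taxon)
  res <- selection_pipeline(rec, avail_family, level = "family",
                            n_candidates = 18)
  res <- res[match(avail_family$taxon, res$taxon), ]
  expect_equal(round(res$jacobs_d, 2), c(0.94, -0.09, -0.88, -0.63))
  expect_equal(res$jacobs_rating, c("+", "=", "-", "-"))
  expect_equal(res$used, c(54, 3, 1, 1) / 59, tolerance = 1e-12)
  expect_equal(attr(res, "n_visits"), 59)
  expect_equal(attr(res, "k"), 18)
})

test_that("the genus-level table uses all visits as the denominator", {
  avail_genus <- tibble::tibble(
    level = "genus", taxon = c("Erigeron", "Saussurea", "Taraxacum"),
    proportion = c(0.025, 0.045, 0.070))
  # 54 Asteraceae-genus visits plus 5 visits on unlisted genera
  rec <- feeding_records(c(1, 3, 50, 3, 1, 1), "genus",
                         c("Erigeron", "Saussurea", "Taraxacum",
                           "Silene", "Ranunculus", "Potentilla"))
  expect_error(selection_pipeline(rec, avail_genus, level = "genus"),
               "Silene", class = "mrrkit_missing_availability")
  res <- selection_pipeline(rec, avail_genus, level = "genus",
                            n_candidates = 28, unlisted = "ignore")
  res <- res[match(c("Erigeron", "Saussurea", "Taraxacum"), res$taxon), ]
  expect_equal(round(res$jacobs_d, 2), c(-0.20, 0.06, 0.97))
  expect_equal(res$jacobs_rating, c("=", "=", "+"))
  expect_equal(attr(res, "n_visits"), 59)
})

test_that("degenerate and skewed selection cases behave", {
  avail1 <- tibble::tibble(level = "family", taxon = c("OnlyOne", "Other"),
                           proportion = c(0.4, 0.6))
  rec <- feeding_records(c(10, 0), "family", c("OnlyOne", "Other"))
  res <- selection_pipeline(rec, avail1, level = "family")
  expect_equal(res$jacobs_d[res$taxon == "OnlyOne"], 1)
  expect_equal(res$jacobs_rating[res$taxon == "OnlyOne"], "+")
  # zero-visit candidates hidden by default, shown on request
  expect_false("Other" %in% res$taxon)
  res_all <- selection_pipeline(rec, avail1, level = "family",
                                report_all = TRUE)
  expect_true("Other" %in% res_all$taxon)
})

test_that("behaviour tables use first captures only", {
  cfg <- toy_popan_config(seed = 31)
  sim <- simulate_mrr(cfg)
  h <- build_histories(sim$records, sim$sessions)
  bt <- behaviour_table(h)
  expect_equal(sum(bt$counts[, -1]), nrow(h))  # one observation per individual
  pr <- as.matrix(bt$proportions[, -1])
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)))
})
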