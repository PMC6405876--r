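#' Jacobs' index of selection
#'
#' `D = (r - p) / (r + p - 2 r p)` compares the used proportion `r` of a
#' resource against its available proportion `p`, ranging from -1 (complete
#' avoidance) to +1 (exclusive preference). Vectorized.
#'
#' @param r Used proportion(s) in `[0, 1]` (enter at full precision, e.g.
#'   `54/59`, not a rounded value).
#' @param p Available proportion(s) in `[0, 1]`.
#' @return Jacobs' D.
#' @export
#' @examples
#' jacobs_index(54/59, 0.265)
jacobs_index <- function(r, p) {
  if (any(r < 0 | r > 1) || any(p < 0 | p > 1))
    stop_mrr("r and p must lie in [0, 1]", "validation_error")
  den <- r + p - 2 * r * p
  if (any(abs(den) < 1e-12))
    stop_mrr("Jacobs' index undefined: degenerate denominator (r and p both 0 or both 1)",
             "degenerate_index")
  (r - p) / den
}

#' Classify Jacobs' D into preference / neutrality / avoidance
#'
#' Using the conventional thresholds: `D > 0.33` preference (`"+"`),
#' `D < -0.33` avoidance (`"-"`), otherwise neutrality (`"="`); the
#' boundaries themselves are neutral (closed interval).
#'
#' @param D Jacobs' index value(s) in `[-1, 1]`.
#' @return Character rating(s): `"+"`, `"="` or `"-"`.
#' @export
classify_jacobs <- function(D) {
  if (any(D < -1 - 1e-9 | D > 1 + 1e-9))
    stop_mrr("D must lie in [-1, 1]", "validation_error")
  dplyr::case_when(D > 0.33 ~ "+", D < -0.33 ~ "-", TRUE ~ "=")
}

#' Simultaneous multinomial confidence intervals (Bailey-style)
#'
#' Transformation-based simultaneous confidence intervals for multinomial
#' cell proportions with the familywise level split (Bonferroni) across the
#' `k` candidate categories. Two variants are provided: `"arcsine"`
#' (variance-stabilising angular transformation with the 3/8, 3/4
#' continuity adjustments) and `"goodman"` (Quesenberry-Hurst/Goodman
#' quadratic score intervals). Cells with zero counts get lower bound 0 and
#' cells with `x = n` upper bound 1.
#'
#' @param counts Non-negative integer visit counts per category (length at
#'   least 2, or supply `k`).
#' @param n Multinomial total; defaults to `sum(counts)` but can be larger
#'   when the candidate categories do not exhaust the observations.
#' @param alpha Familywise error level, default 0.05.
#' @param k Number of categories the familywise level is split across;
#'   defaults to `length(counts)` but conventionally counts every candidate
#'   category, including those never used.
#' @param availability Optional available proportions; when supplied a
#'   `rating` column compares them against the intervals (`"+"` preference
#'   when availability is below the interval, `"-"` avoidance when above,
#'   `"="` otherwise).
#' @param method `"arcsine"` (default) or `"goodman"`.
#' @return A tibble: `count`, `proportion`, `lower`, `upper` (and `rating`).
#' @export
bailey_cis <- function(counts, n = sum(counts), alpha = 0.05,
                       k = length(counts), availability = NULL,
                       method = c("arcsine", "goodman")) {
  method <- match.arg(method)
  if (k < 2) stop_mrr("need at least 2 categories", "validation_error")
  if (n <= 0) stop_mrr("total count must be positive", "validation_error")
  if (any(counts < 0) || sum(counts) > n)
    stop_mrr("counts must be non-negative and sum to at most n", "validation_error")
  x <- counts
  if (method == "arcsine") {
    z <- qnorm(1 - alpha / (2 * k))
    theta <- asin(sqrt((x + 3 / 8) / (n + 3 / 4)))
    half <- z / (2 * sqrt(n))
    lower <- sin(pmax(theta - half, 0))^2
    upper <- sin(pmin(theta + half, pi / 2))^2
  } else {
    A <- qchisq(1 - alpha / k, df = 1)
    lower <- (A + 2 * x - sqrt(A * (A + 4 * x * (n - x) / n))) / (2 * (n + A))
    upper <- (A + 2 * x + sqrt(A * (A + 4 * x * (n - x) / n))) / (2 * (n + A))
  }
  lower[x == 0] <- 0
  upper[x == n] <- 1
  out <- tibble::tibble(count = x, proportion = x / n,
                        lower = pmax(0, lower), upper = pmin(1, upper))
  if (!is.null(availability)) {
    out$rating <- dplyr::case_when(availability < out$lower ~ "+",
                                   availability > out$upper ~ "-",
                                   TRUE ~ "=")
  }
  out
}

#' Chi-squared homogeneity test of a sex-by-category table
#'
#' Pearson chi-squared test of equal category distributions across the two
#' sexes (no continuity correction); `df = k - 1` for a 2-by-k table.
#' Categories with zero total are dropped with a warning; zero cells within
#' a non-empty category are allowed.
#'
#' @param tab A 2-by-k matrix or data frame of counts (rows: sexes).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
chisq_homogeneity <- function(tab) {
  m <- as.matrix(tab)
  if (nrow(m) != 2) stop_mrr("expected a 2-row (sex by category) table", "validation_error")
  empty <- colSums(m) == 0
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " categor(ies) with zero total"))
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) < 2)
    stop_mrr("need at least 2 non-empty categories", "validation_error")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, n = sum(m))
}

#' Behaviour contingency table from first captures
#'
#' Counts the four behavioural categories (flying, resting, feeding,
#' interaction) by sex using only each individual's first capture, so
#' individual preferences cannot inflate the sample, and runs the
#' chi-squared homogeneity test.
#'
#' @param histories An `encounter_histories` whose detections carry
#'   `behaviour`.
#' @return A list of class `behaviour_table`: `counts` (tibble sex by
#'   category), `proportions`, and `test` (from [chisq_homogeneity()]).
#' @export
behaviour_table <- function(histories) {
  h <- tibble::as_tibble(histories)
  first <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
    d <- h$detections[[i]]
    d <- d[order(d$session), ]
    tibble::tibble(sex = h$sex[i], behaviour = d$behaviour[1])
  }) |> dplyr::filter(!is.na(.data$behaviour))
  cats <- c("flying", "resting", "feeding", "interaction")
  counts <- first |>
    dplyr::count(.data$sex, behaviour = factor(.data$behaviour, levels = cats),
                 .drop = FALSE, name = "n") |>
    tidyr::pivot_wider(names_from = "behaviour", values_from = "n",
                       values_fill = 0L)
  m <- as.matrix(counts[, cats])
  rownames(m) <- counts$sex
  props <- sweep(m, 1, rowSums(m), "/")
  test <- if (nrow(m) == 2) chisq_homogeneity(m) else NULL
  structure(list(counts = counts,
                 proportions = tibble::as_tibble(props, rownames = "sex"),
                 test = test),
            class = "behaviour_table")
}

#' @export
print.behaviour_table <- function(x, ...) {
  cat("First-capture behaviour by sex\n")
  print(x$counts)
  print(x$test)
  invisible(x)
}

#' Nectar-source selection analysis
#'
#' Full selection pipeline at the plant family or genus level: a sex
#' homogeneity chi-squared test over the observed taxa decides pooling (the
#' sexes are pooled when non-significant at `pool_alpha`; a significant test
#' triggers a warning that sex-specific analyses are advisable). For every
#' candidate taxon in the availability table the used proportion is the
#' full-precision `x / n` with `n` the total number of feeding visits at
#' that level; Jacobs' D with its rating and the simultaneous (Bailey-style)
#' interval with its rating against availability are reported.
#'
#' @param records Capture records (feeding rows carry `family` / `genus`).
#' @param availability Tibble with columns `level`, `taxon`, `proportion`
#'   (expected available proportion per candidate taxon).
#' @param level `"family"` or `"genus"`.
#' @param alpha Familywise level for the simultaneous intervals.
#' @param n_candidates Number of candidate categories for the Bonferroni
#'   split; defaults to the number of availability rows at `level`.
#' @param unlisted How to treat observed taxa missing from the availability
#'   table: `"error"` (default) or `"ignore"` (they still count towards `n`,
#'   as when the candidate set is restricted to one family's genera).
#' @param pool_alpha Significance level of the pooling test, default 0.05.
#' @param report_all Also report candidate taxa with zero observed visits
#'   (default `FALSE`; they always participate in the candidate count).
#' @param method Interval variant, see [bailey_cis()].
#' @return A tibble of class `selection_result` mirroring the conventional
#'   selection-table layout: `level`, `taxon`, `observed`, `availability`,
#'   `used`, `jacobs_d`, `jacobs_rating`, `ci_lower`, `ci_upper`,
#'   `bailey_rating`; attributes `homogeneity` (pooling test), `n_visits`,
#'   `k`.
#' @export
selection_pipeline <- function(records, availability,
                               level = c("family", "genus"), alpha = 0.05,
                               n_candidates = NULL,
                               unlisted = c("error", "ignore"),
                               pool_alpha = 0.05, report_all = FALSE,
                               method = c("arcsine", "goodman")) {
  level <- match.arg(level)
  unlisted <- match.arg(unlisted)
  method <- match.arg(method)
  avail <- availability |>
    dplyr::filter(.data$level == !!level)
  if (nrow(avail) == 0)
    stop_mrr(paste0("no availability rows at level ", level), "validation_error")
  if (sum(avail$proportion) > 1 + 1e-9)
    stop_mrr("availability proportions sum to more than 1", "validation_error")

  visits <- records |>
    dplyr::filter(.data$behaviour == "feeding", !is.na(.data[[level]]))
  n <- nrow(visits)
  if (n == 0) stop_mrr("no feeding visits with a recorded taxon", "no_visits")

  # sex homogeneity over all observed taxa at this level
  homog <- NULL
  if (dplyr::n_distinct(visits$sex) == 2) {
    tab <- table(visits$sex, visits[[level]])
    homog <- tryCatch(chisq_homogeneity(tab), error = function(e) NULL)
    if (!is.null(homog) && homog$p_value < pool_alpha)
      warn(sprintf("sexes differ in %s-level nectar use (chi2 = %.2f, p = %.3g); pooled results may mask sex-specific selection",
                   level, homog$statistic, homog$p_value))
  }

  observed <- visits |> dplyr::count(taxon = .data[[level]], name = "x")
  extra <- setdiff(observed$taxon, avail$taxon)
  if (length(extra) > 0 && unlisted == "error")
    stop_mrr(paste0("observed taxa missing from the availability table: ",
                    paste(extra, collapse = ", ")), "missing_availability")

  res <- avail |>
    dplyr::select(taxon = "taxon", availability = "proportion") |>
    dplyr::left_join(observed, by = "taxon") |>
    dplyr::mutate(x = dplyr::coalesce(.data$x, 0L))
  k <- n_candidates %||% nrow(res)
  ci <- bailey_cis(res$x, n = n, alpha = alpha, k = k,
                   availability = res$availability, method = method)
  out <- tibble::tibble(
    level = level, taxon = res$taxon, observed = res$x,
    availability = res$availability, used = res$x / n,
    jacobs_d = jacobs_index(res$x / n, res$availability),
    ci_lower = ci$lower, ci_upper = ci$upper,
    bailey_rating = ci$rating)
  out$jacobs_rating <- classify_jacobs(out$jacobs_d)
  out <- out[, c("level", "taxon", "observed", "availability", "used",
                 "jacobs_d", "jacobs_rating", "ci_lower", "ci_upper",
                 "bailey_rating")]
  if (!report_all) out <- out[out$observed > 0, ]
  structure(out, class = c("selection_result", class(out)),
            homogeneity = homog, n_visits = n, k = k)
}

#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot(d, aes(x = stats::reorder(.data$taxon, .data$jacobs_d),
                y = .data$jacobs_d)) +
    geom_hline(yintercept = c(-0.33, 0.33), linetype = 3) +
    geom_segment(aes(xend = .data$taxon, yend = 0)) +
    geom_point(aes(colour = .data$jacobs_rating), size = 3) +
    coord_flip() +
    labs(x = NULL, y = "Jacobs' D", colour = "rating") +
    theme_minimal()
}
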