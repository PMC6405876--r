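#' Daily mean wing condition per sex
#'
#' Unweighted daily means of the ordinal wing-wear score (1 pristine to 4
#' seriously damaged). Days with fewer than `threshold` scored individuals
#' of a sex are excluded for that sex, so single captures cannot dominate a
#' daily mean.
#'
#' @param records Capture records carrying `date`, `sex` and `wing`.
#' @param threshold Minimum scored individuals per day and sex (default 5).
#' @return A tibble: `date`, `sex`, `n`, `mean_wing`.
#' @export
daily_mean_wing <- function(records, threshold = 5) {
  records |>
    dplyr::filter(!is.na(.data$wing)) |>
    dplyr::group_by(.data$date, .data$sex) |>
    dplyr::summarise(n = dplyr::n(), mean_wing = mean(.data$wing),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= threshold) |>
    dplyr::arrange(.data$sex, .data$date)
}

#' Population-level wing-wear ageing trend
#'
#' Ordinary least squares of the daily mean wing score on the calendar-day
#' serial number (days since epoch). Using the serial day as the regressor
#' reproduces the conventional presentation with large negative intercepts;
#' only the slope (score units per day) is biologically meaningful.
#'
#' @param daily_means Output of [daily_mean_wing()].
#' @param sex Optional subset of sexes; default fits every sex present.
#' @return A tibble of class `wing_model`: `sex`, `scope`, `slope`,
#'   `se_slope`, `intercept`, `r2_adj`, `f_stat`, `p_value`, `n`. The input
#'   daily means are kept as attribute `"data"`.
#' @export
wing_trend <- function(daily_means, sex = NULL) {
  sexes <- sex %||% unique(daily_means$sex)
  rows <- purrr::map_dfr(sexes, function(s) {
    d <- daily_means |> dplyr::filter(.data$sex == s)
    if (nrow(d) < 3)
      stop_mrr(paste0("fewer than 3 retained days for sex ", s),
               "insufficient_data")
    day <- as.numeric(d$date)
    fit <- lm(d$mean_wing ~ day)
    sm <- summary(fit)
    sst <- sum((d$mean_wing - mean(d$mean_wing))^2)
    if (sst < .Machine$double.eps) {
      # flat series: zero slope, no explainable variance
      return(tibble::tibble(sex = s, scope = "population_daily_mean",
                            slope = 0, se_slope = NA_real_,
                            intercept = mean(d$mean_wing), r2_adj = NA_real_,
                            f_stat = 0, p_value = 1, n = nrow(d)))
    }
    tibble::tibble(sex = s, scope = "population_daily_mean",
                   slope = coef(fit)[[2]], se_slope = sm$coefficients[2, 2],
                   intercept = coef(fit)[[1]], r2_adj = sm$adj.r.squared,
                   f_stat = unname(sm$fstatistic[1]),
                   p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                                       sm$fstatistic[3], lower.tail = FALSE)),
                   n = nrow(d))
  })
  structure(rows, class = c("wing_model", class(rows)), data = daily_means)
}

#' Individual wing-decay rate from recaptures
#'
#' For every recaptured individual with wing scores at two or more
#' detections, the wing condition and day of first capture are set to zero
#' and each later detection contributes one pair (days since first capture,
#' score difference). The per-sex decay rate is the regression through the
#' origin of score difference on elapsed days
#' (`slope = sum(x y) / sum(x^2)`); the mean of the per-pair daily rates
#' with its standard error is reported alongside. Score decreases over time
#' are biologically impossible (wing wear cannot heal) and trigger a
#' data-quality warning but are retained.
#'
#' @param histories An `encounter_histories` whose detections carry `date`
#'   and `wing`.
#' @param sex Optional subset of sexes.
#' @return A tibble of class `wing_model`: per sex `slope`, `se_slope`,
#'   `mean_rate`, `se_rate`, `n_pairs`; the pair data are attached as
#'   attribute `"pairs"`.
#' @export
individual_decay <- function(histories, sex = NULL) {
  h <- tibble::as_tibble(histories)
  if (!is.null(sex)) h <- h[h$sex %in% sex, ]
  pairs <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
    d <- h$detections[[i]]
    d <- d[!is.na(d$wing), ]
    if (nrow(d) < 2) return(NULL)
    d <- d[order(d$date), ]
    tibble::tibble(id = h$id[i], sex = h$sex[i],
                   dt = as.numeric(d$date[-1] - d$date[1]),
                   dw = as.numeric(d$wing[-1] - d$wing[1]))
  })
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_mrr("no recaptured individuals with wing scores at 2+ detections",
             "insufficient_data")
  pairs <- pairs |> dplyr::filter(.data$dt > 0)
  n_neg <- sum(pairs$dw < 0)
  if (n_neg > 0)
    warn(paste0(n_neg, " recapture pair(s) with decreasing wing score: ",
                "wing wear cannot heal, check the scores"))
  rows <- pairs |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      scope = "individual_delta",
      slope = sum(.data$dt * .data$dw) / sum(.data$dt^2),
      se_slope = {
        s <- sum(.data$dt * .data$dw) / sum(.data$dt^2)
        r <- .data$dw - s * .data$dt
        sqrt(sum(r^2) / (dplyr::n() - 1) / sum(.data$dt^2))
      },
      mean_rate = mean(.data$dw / .data$dt),
      se_rate = sd(.data$dw / .data$dt) / sqrt(dplyr::n()),
      n_pairs = dplyr::n(), .groups = "drop")
  structure(rows, class = c("wing_model", class(rows)), pairs = pairs)
}

#' @method autoplot wing_model
#' @export
autoplot.wing_model <- function(object, ...) {
  d <- attr(object, "data")
  if (is.null(d)) {
    p <- attr(object, "pairs")
    return(ggplot(p, aes(x = .data$dt, y = .data$dw, colour = .data$sex)) +
             geom_jitter(width = 0.1, height = 0.05, alpha = 0.6) +
             geom_smooth(method = "lm", formula = y ~ 0 + x, se = FALSE) +
             labs(x = "days since first capture", y = "wing-score change",
                  colour = NULL) +
             theme_minimal())
  }
  ggplot(d, aes(x = .data$date, y = .data$mean_wing, colour = .data$sex)) +
    geom_point(aes(size = .data$n), alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    scale_size_continuous(guide = "none") +
    labs(x = "date", y = "mean wing score", colour = NULL) +
    theme_minimal()
}
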