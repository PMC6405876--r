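#' Consecutive-capture movement distances
#'
#' One Euclidean distance per consecutive detection pair per individual,
#' from the planar metric capture locations carried by the encounter
#' histories. Geodetic (unprojected) locations are refused: re-ingest with
#' `read_captures(project = TRUE)`.
#'
#' @param histories An `encounter_histories` tibble whose detection payloads
#'   carry `x`, `y` (metres) and `date`.
#' @return A tibble of class `movement_set` with one row per move: `id`,
#'   `sex`, `from_session`, `to_session`, `days`, `distance` (metres).
#' @export
movement_distances <- function(histories) {
  h <- tibble::as_tibble(histories)
  moves <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
    d <- h$detections[[i]]
    if (nrow(d) < 2) return(NULL)
    if (!is.null(d$crs) && any(d$crs == "geodetic"))
      stop_mrr("geodetic locations are not projected; re-ingest with read_captures(project = TRUE)",
               "geodetic_error")
    d <- d[order(d$session), ]
    k <- nrow(d)
    tibble::tibble(
      id = h$id[i], sex = h$sex[i],
      from_session = d$session[-k], to_session = d$session[-1],
      days = as.numeric(d$date[-1] - d$date[-k]),
      distance = sqrt(diff(d$x)^2 + diff(d$y)^2))
  })
  if (is.null(moves) || nrow(moves) == 0) {
    moves <- tibble::tibble(id = character(), sex = character(),
                            from_session = integer(), to_session = integer(),
                            days = numeric(), distance = numeric())
  }
  structure(moves, class = c("movement_set", class(moves)))
}

#' Per-sex movement summary
#'
#' @param moves A `movement_set` tibble from [movement_distances()].
#' @return A tibble per sex: `n`, `mean`, `se` (= sd/sqrt(n)), `max`.
#' @export
movement_summary <- function(moves) {
  tibble::as_tibble(moves) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$distance),
                     se = sd(.data$distance) / sqrt(dplyr::n()),
                     max = max(.data$distance), .groups = "drop")
}

#' Mann-Whitney U comparison of male and female movement distances
#'
#' Exact two-sided test for combined sample sizes up to 20 without ties;
#' normal approximation with tie correction otherwise. The reported U is for
#' the male sample.
#'
#' @param moves A `movement_set` with both sexes present.
#' @return A one-row tibble: `U`, `p_value`, `n_male`, `n_female`, `method`.
#' @export
compare_sexes <- function(moves) {
  x <- moves$distance[moves$sex == "male"]
  y <- moves$distance[moves$sex == "female"]
  if (length(x) == 0 || length(y) == 0)
    stop_mrr("both sexes must have at least one movement", "validation_error")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 n_male = length(x), n_female = length(y),
                 method = if (exact) "exact" else "normal approximation")
}

#' Inverse cumulative proportion table of movement distances
#'
#' Class `i` (1-based) has lower bound `(i - 1) * width`; its inverse
#' cumulative proportion is the fraction of moves with distance at or beyond
#' that bound. The first class is always 1; classes are enumerated until the
#' proportion reaches zero (zero classes are excluded, they are never
#' log-transformed downstream).
#'
#' @param moves A `movement_set`, or a numeric vector of distances in metres.
#' @param width Interval width in metres (conventionally 20, 30 or 50).
#' @param per_individual Use only each individual's first move (capture to
#'   first recapture) rather than all consecutive moves. Default `FALSE`.
#' @return A tibble of class `icp_table`: `class`, `lower` (metres), `icp`,
#'   with attributes `width` and `n_moves`.
#' @export
icp_table <- function(moves, width, per_individual = FALSE) {
  if (width <= 0) stop_mrr("width must be positive", "validation_error")
  if (is.numeric(moves)) {
    d <- moves
  } else {
    m <- tibble::as_tibble(moves)
    if (per_individual) {
      m <- m |> dplyr::group_by(.data$id) |>
        dplyr::arrange(.data$from_session, .by_group = TRUE) |>
        dplyr::slice(1) |> dplyr::ungroup()
    }
    d <- m$distance
  }
  if (length(d) == 0) stop_mrr("no movements", "validation_error")
  n_cls <- floor(max(d) / width) + 1
  i <- seq_len(n_cls)
  lower <- (i - 1) * width
  icp <- vapply(lower, function(b) mean(d >= b), 0)
  keep <- icp > 0
  out <- tibble::tibble(class = i[keep], lower = lower[keep], icp = icp[keep])
  structure(out, class = c("icp_table", class(out)),
            width = width, n_moves = length(d))
}

#' Fit a dispersal kernel to an inverse-cumulative-proportion table
#'
#' Least squares on the linearised kernel over class indices `x`:
#' the negative exponential function (NEF) `I = a exp(-k x)` is fitted as
#' `ln I ~ x`, and the inverse power function (IPF) `I = a x^(-k)` as
#' `ln I ~ ln x`. At least 3 usable classes (positive proportions) are
#' required. `R2_adj = 1 - (1 - R2)(n - 1)/(n - 2)`; the F statistic tests
#' the slope. An optional nonlinear refinement (`nonlinear = TRUE`, via
#' [stats::nls()]) is provided for sensitivity checks only.
#'
#' @param icp An `icp_table`.
#' @param model `"NEF"` or `"IPF"`.
#' @param nonlinear Refine by nonlinear least squares on the untransformed
#'   proportions (default `FALSE`; the linearised fit is the reference
#'   method).
#' @return An object of class `kernel_fit`: `model`, `width`, `a`, `k`,
#'   `r2_adj`, `f_stat`, `p_value`, `n_classes`, `data`.
#' @export
fit_kernel <- function(icp, model = c("NEF", "IPF"), nonlinear = FALSE) {
  model <- match.arg(model)
  df <- tibble::as_tibble(icp) |> dplyr::filter(.data$icp > 0)
  if (nrow(df) < 3)
    stop_mrr("need at least 3 distance classes with positive proportions",
             "insufficient_data")
  x <- df$class
  y <- log(df$icp)
  xr <- if (model == "NEF") x else log(x)
  fit <- lm(y ~ xr)
  sm <- summary(fit)
  a <- exp(coef(fit)[[1]])
  k <- -coef(fit)[[2]]
  f_stat <- unname(sm$fstatistic[1])
  p_value <- pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
  if (nonlinear) {
    nl <- tryCatch(
      stats::nls(icp ~ a * if (model == "NEF") exp(-k * class) else class^(-k),
                 data = df, start = list(a = a, k = k)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      a <- coef(nl)[["a"]]
      k <- coef(nl)[["k"]]
    }
  }
  structure(list(model = model, width = attr(icp, "width"),
                 a = a, k = k,
                 r2_adj = sm$adj.r.squared,
                 f_stat = f_stat, p_value = unname(p_value),
                 n_classes = nrow(df), nonlinear = nonlinear,
                 data = df),
            class = "kernel_fit")
}

#' @export
predict.kernel_fit <- function(object, x, ...) {
  if (object$model == "NEF") object$a * exp(-object$k * x)
  else object$a * x^(-object$k)
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("%s kernel (width %s m): a = %.4g, k = %.4g, R2_adj = %.3f, F = %.2f, p = %.3g (%d classes)\n",
              x$model, format(x$width), x$a, x$k, x$r2_adj, x$f_stat,
              x$p_value, x$n_classes))
  invisible(x)
}

#' @method tidy kernel_fit
#' @export
tidy.kernel_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "k"), estimate = c(x$a, x$k))
}

#' @method glance kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(model = x$model, width = x$width, a = x$a, k = x$k,
                 r2_adj = x$r2_adj, f_stat = x$f_stat, p_value = x$p_value,
                 n_classes = x$n_classes)
}

#' Extrapolate a fitted kernel to long distances
#'
#' Maps a distance in kilometres onto its class index
#' `x = 1000 d / width` (e.g. 1 km is interval number 20 at 50 m width) and
#' returns the kernel prediction as a percentage of moving individuals.
#'
#' @param fit A `kernel_fit`.
#' @param distances_km Positive distances in kilometres.
#' @return A tibble: `distance_km`, `interval`, `percent`.
#' @export
extrapolate_kernel <- function(fit, distances_km = c(1, 2, 3, 5)) {
  if (any(distances_km <= 0))
    stop_mrr("distances must be positive", "validation_error")
  x <- 1000 * distances_km / fit$width
  tibble::tibble(distance_km = distances_km, interval = x,
                 percent = 100 * predict(fit, x))
}

#' @method autoplot icp_table
#' @export
autoplot.icp_table <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$class, y = .data$icp)) +
    geom_point() +
    geom_line(linetype = 3) +
    labs(x = sprintf("distance class (%g m intervals)", attr(object, "width")),
         y = "inverse cumulative proportion") +
    theme_minimal()
}

#' @method autoplot kernel_fit
#' @export
autoplot.kernel_fit <- function(object, ...) {
  grid <- tibble::tibble(class = seq(min(object$data$class),
                                     max(object$data$class), length.out = 200))
  grid$icp <- predict(object, grid$class)
  ggplot(object$data, aes(x = .data$class, y = .data$icp)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    labs(title = sprintf("%s kernel, width %g m", object$model, object$width),
         x = "distance class index", y = "inverse cumulative proportion") +
    theme_minimal()
}
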