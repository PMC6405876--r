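#' Derived daily abundance from a POPAN fit
#'
#' Converts the fitted superpopulation and entry parameters into per-session
#' recruitment and abundance: `B_t = N_super * pent_t`, `N_1 = B_1`,
#' `N_{t+1} = N_t * phi_t^gap + B_{t+1}`. Standard errors come from the delta
#' method through the beta covariance. Recruitment conserves the
#' superpopulation: `sum_t B_t = N_super` exactly.
#'
#' @param fit A converged `popan_fit`.
#' @param area_ha Optional study-area size in hectares; when supplied,
#'   per-hectare densities are attached (rounded to the nearest integer, as
#'   conventionally reported); when missing, densities are omitted, never
#'   defaulted.
#' @return A tibble of class `popan_abundance` with columns `session`,
#'   `date`, `sex`, `N`, `se`, `B`, `se_B`, and attribute `"totals"`: a
#'   tibble with per-sex `N_super`, `se`, and (if `area_ha` given) `density`.
#' @export
derived_abundance <- function(fit, area_ha = NULL) {
  design <- fit$design
  S <- design$S
  G <- length(design$sexes)
  flatten <- function(beta) {
    r <- popan_real(design, beta, fit$n_obs)
    out <- matrix(0, nrow = S, ncol = G)
    B <- r$pent * rep(r$N, each = S)
    out[1, ] <- B[1, ]
    if (S > 1) for (t in 2:S) {
      out[t, ] <- out[t - 1, ] * r$phi_int[t - 1, ] + B[t, ]
    }
    c(as.vector(out), as.vector(B), r$N)
  }
  est <- flatten(fit$beta)
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov)) {
    J <- pracma::jacobian(flatten, fit$beta)
    se <- sqrt(pmax(0, diag(J %*% fit$vcov %*% t(J))))
  }
  iN <- seq_len(S * G)
  iB <- S * G + seq_len(S * G)
  iT <- 2 * S * G + seq_len(G)
  out <- tibble::tibble(
    session = rep(seq_len(S), G),
    date = rep(design$sessions$date, G),
    sex = rep(design$sexes, each = S),
    N = est[iN], se = se[iN],
    B = est[iB], se_B = se[iB])
  totals <- tibble::tibble(sex = design$sexes,
                           N_super = unname(est[iT]), se = unname(se[iT]))
  if (!is.null(area_ha)) {
    totals$density <- round(totals$N_super / area_ha)
  }
  structure(out, class = c("popan_abundance", class(out)), totals = totals,
            area_ha = area_ha)
}

#' Demographic summary from superpopulation estimates
#'
#' Densities, total population size, and the female/male ratio from per-sex
#' superpopulation estimates and the study-area size. This is pure
#' demographic arithmetic and can also be applied to published estimates.
#' Densities are rounded to the nearest integer per hectare.
#'
#' @param n_super Named numeric vector of superpopulation sizes, e.g.
#'   `c(male = 434, female = 291)`.
#' @param area_ha Study-area size in hectares.
#' @return A one-row tibble with per-sex densities, `total`, `total_density`
#'   and `female_male_ratio_pct`.
#' @export
#' @examples
#' abundance_summary(c(male = 434, female = 291), area_ha = 5.7)
abundance_summary <- function(n_super, area_ha) {
  if (is.null(names(n_super)) || !all(nzchar(names(n_super))))
    stop_mrr("n_super must be a named vector", "validation_error")
  dens <- round(n_super / area_ha)
  out <- tibble::tibble(total = sum(n_super),
                        total_density = round(sum(n_super) / area_ha))
  for (s in names(n_super)) {
    out[[paste0("N_", s)]] <- n_super[[s]]
    out[[paste0("density_", s)]] <- dens[[s]]
  }
  if (all(c("male", "female") %in% names(n_super))) {
    out$female_male_ratio_pct <- 100 * n_super[["female"]] / n_super[["male"]]
  }
  out
}

#' @method autoplot popan_abundance
#' @export
autoplot.popan_abundance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$date, y = .data$N, colour = .data$sex)) +
    geom_line() +
    geom_pointrange(aes(ymin = pmax(0, .data$N - .data$se),
                        ymax = .data$N + .data$se)) +
    labs(x = "date", y = "estimated population size",
         colour = NULL) +
    theme_minimal()
}
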