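# POPAN (Schwarz-Arnason superpopulation) log-likelihood.
#
# Per group g with S sessions, daily survival phi_day raised to the calendar
# gap between sessions, capture probabilities p_t, entry probabilities pent_t
# (a simplex over sessions) and superpopulation size N:
#   psi_1 = pent_1;  psi_{t+1} = psi_t (1 - p_t) phi_t + pent_{t+1}
#   pi0   = 1 - sum_t psi_t p_t                    (never detected)
#   chi_S = 1;  chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}
# and the log-likelihood is
#   log C(N, n) + (N - n) log pi0
#     + sum_h [ log psi_{f_h} + log p_{f_h}
#               + sum_{t=f_h+1}^{l_h} ( log phi_{t-1} + y_t log p_t
#                                       + (1-y_t) log(1-p_t) )
#               + log chi_{l_h} ]
# with f_h, l_h the first/last detection of history h. N is continuous
# (shifted-log link), so C(N, n) is evaluated through lgamma.

# aggregate histories into per-group unique detection matrices with counts
aggregate_histories <- function(histories, sexes) {
  lapply(setNames(sexes, sexes), function(s) {
    hh <- histories[histories$sex == s, , drop = FALSE]
    if (nrow(hh) == 0) {
      return(list(n = 0L, ch = matrix(0L, 0, 0), counts = integer()))
    }
    tab <- table(hh$ch)
    ch <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
    first <- apply(ch, 1, function(y) which(y == 1)[1])
    last <- apply(ch, 1, function(y) max(which(y == 1)))
    list(n = nrow(hh), ch = ch, counts = as.integer(tab),
         first = first, last = last)
  })
}

# group-level log-likelihood from real parameters
popan_loglik_group <- function(agg, phi_int, p, pent, N) {
  eps <- 1e-12
  if (any(p <= eps) || any(p >= 1 - eps)) return(-Inf)
  if (any(phi_int <= eps) || any(phi_int >= 1 - eps)) return(-Inf)
  S <- length(p)
  psi <- numeric(S)
  psi[1] <- pent[1]
  if (S > 1) {
    for (t in 2:S) psi[t] <- psi[t - 1] * (1 - p[t - 1]) * phi_int[t - 1] + pent[t]
  }
  pi0 <- 1 - sum(psi * p)
  if (!is.finite(pi0) || pi0 <= 0) return(-Inf)
  chi <- numeric(S)
  chi[S] <- 1
  if (S > 1) {
    for (t in (S - 1):1) {
      chi[t] <- (1 - phi_int[t]) + phi_int[t] * (1 - p[t + 1]) * chi[t + 1]
    }
  }
  n <- agg$n
  if (N < n - 1 + eps) return(-Inf)
  ll <- lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1) + (N - n) * log(pi0)
  if (n > 0) {
    lp <- log(p); lq <- log1p(-p); lphi <- log(phi_int)
    if (is.null(agg$first)) {
      agg$first <- apply(agg$ch, 1, function(y) which(y == 1)[1])
      agg$last <- apply(agg$ch, 1, function(y) max(which(y == 1)))
    }
    f <- agg$first; l <- agg$last
    # vectorized per-history terms: survival over (f, l], detections via
    # matrix products (histories are 0 outside [f, l] by construction)
    cs_phi <- c(0, cumsum(lphi))          # sum lphi[f..l-1] = cs_phi[l]-cs_phi[f]
    cs_q <- c(0, cumsum(lq))              # sum lq[f..l]     = cs_q[l+1]-cs_q[f]
    det_p <- drop(agg$ch %*% lp)
    det_q <- drop(agg$ch %*% lq)
    term <- log(psi[f]) + log(chi[l]) + (cs_phi[l] - cs_phi[f]) +
      det_p + (cs_q[l + 1] - cs_q[f]) - det_q
    ll <- ll + sum(agg$counts * term)
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

#' POPAN superpopulation log-likelihood
#'
#' Evaluates the Jolly-Seber POPAN log-likelihood at a beta vector on the
#' link scale, summed over the modelled groups. Survival between consecutive
#' sessions is the daily survival raised to the calendar gap in days. Real
#' parameters that hit 0 or 1 within machine tolerance yield `-Inf` rather
#' than `NaN`.
#'
#' @param beta Numeric vector of link-scale coefficients (length `design$K`).
#' @param design A `popan_design` from [build_design()].
#' @param histories An `encounter_histories` tibble (or any data frame with
#'   `sex` and `ch` columns).
#' @return The log-likelihood (scalar; `-Inf` on the boundary).
#' @export
popan_loglik <- function(beta, design, histories) {
  agg <- aggregate_histories(histories, design$sexes)
  popan_loglik_agg(beta, design, agg)
}

popan_loglik_agg <- function(beta, design, agg) {
  n_obs <- vapply(agg, `[[`, 0L, "n")
  real <- popan_real(design, beta, n_obs)
  ll <- 0
  for (gi in seq_along(design$sexes)) {
    a <- agg[[gi]]
    ll <- ll + popan_loglik_group(a, real$phi_int[, gi], real$p[, gi],
                                  real$pent[, gi], real$N[gi])
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}
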