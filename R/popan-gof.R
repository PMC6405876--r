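#' Parametric-bootstrap goodness-of-fit for a POPAN fit
#'
#' Simulates `n_boot` datasets from the fitted model (rounded
#' superpopulation, multinomial entry, interval survival, per-session
#' capture), refits the same structure to each, and reports the percentile
#' of the observed deviance (`-2 logL` at the MLE) within the bootstrap
#' distribution. Under a well-specified model the percentile is
#' approximately uniform. This is a generic replacement for
#' contingency-table GOF machinery tied to particular legacy software.
#'
#' @param fit A converged `popan_fit`.
#' @param n_boot Number of bootstrap replicates (at least 20).
#' @param seed Seed for the bootstrap stream.
#' @param n_restarts Restarts used for each bootstrap refit (kept small for
#'   speed).
#' @return A list of class `popan_gof`: `percentile`, `observed_deviance`,
#'   `boot_deviance`, `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_gof <- function(fit, n_boot = 100L, seed = 1L, n_restarts = 1L) {
  if (n_boot < 20)
    stop_mrr("n_boot must be at least 20 for a meaningful percentile", "gof_error")
  design <- fit$design
  real <- popan_real(design, fit$beta, fit$n_obs)
  obs_dev <- -2 * fit$logLik
  boot_dev <- with_seed(sub_seed(seed, 23L), {
    seeds <- sample.int(2147483000L, n_boot)
    vapply(seq_len(n_boot), function(b) {
      h <- with_seed(seeds[b], simulate_from_real(real, design))
      if (is.null(h) || nrow(h) == 0) return(NA_real_)
      f <- tryCatch(
        fit_popan(design$spec, h, sessions = design$sessions,
                  sexes = design$sexes, seed = seeds[b],
                  n_restarts = n_restarts, hessian = FALSE),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else -2 * f$logLik
    }, 0)
  })
  ok <- is.finite(boot_dev)
  structure(list(percentile = mean(boot_dev[ok] <= obs_dev),
                 observed_deviance = obs_dev,
                 boot_deviance = boot_dev,
                 n_boot = n_boot, n_failed = sum(!ok), seed = seed),
            class = "popan_gof")
}

#' @export
print.popan_gof <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap GOF: deviance %.2f at percentile %.3f (%d boot, %d failed)\n",
              x$observed_deviance, x$percentile, x$n_boot, x$n_failed))
  invisible(x)
}

# simulate an encounter-history set from real POPAN parameters
simulate_from_real <- function(real, design) {
  S <- design$S
  rows <- list()
  for (gi in seq_along(design$sexes)) {
    N <- max(1L, round(real$N[gi]))
    entry <- sample.int(S, N, replace = TRUE, prob = real$pent[, gi])
    ch <- matrix(0L, N, S)
    alive <- matrix(FALSE, N, S)
    for (t in seq_len(S)) {
      if (t == 1) {
        alive[, 1] <- entry == 1
      } else {
        alive[, t] <- (alive[, t - 1] &
                         runif(N) < real$phi_int[t - 1, gi]) | entry == t
      }
      ch[, t] <- as.integer(alive[, t] & runif(N) < real$p[t, gi])
    }
    seen <- rowSums(ch) > 0
    if (any(seen)) {
      rows[[gi]] <- tibble::tibble(
        sex = design$sexes[gi],
        ch = apply(ch[seen, , drop = FALSE], 1, paste, collapse = ""))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$id <- sprintf("b%05d", seq_len(nrow(out)))
  out$n_det <- nchar(gsub("0", "", out$ch))
  out[, c("id", "sex", "ch", "n_det")]
}
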