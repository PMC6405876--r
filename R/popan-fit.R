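#' Fit a POPAN model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation of the POPAN superpopulation likelihood
#' from a default start (logit 0 for rates, uniform entry, log-scale
#' superpopulation at twice the observed count), followed by seeded jittered
#' restarts. Convergence requires a gradient norm below `grad_tol` at the
#' best point; otherwise a diagnostic error carrying the best point and its
#' gradient norm is raised. Standard errors come from the inverse observed
#' information; `K_est` is the numerical rank of the observed information at
#' tolerance `1e-6` relative to its largest eigenvalue.
#'
#' @param spec A `popan_model` or model string.
#' @param histories An `encounter_histories` tibble.
#' @param sessions Session calendar; defaults to `attr(histories, "sessions")`.
#' @param sexes Modelled groups; defaults to the sexes present, in
#'   male/female order.
#' @param seed Seed controlling the jittered restarts (reproducible fits).
#' @param n_restarts Number of jittered restarts after the default start.
#' @param grad_tol Gradient-norm convergence tolerance.
#' @param maxit Maximum BFGS iterations per start.
#' @param hessian Compute the observed information (needed for SEs); set
#'   `FALSE` to skip in bulk simulation work.
#' @return An object of class `popan_fit` with elements `spec`, `design`,
#'   `beta`, `vcov`, `logLik`, `K` (structural), `K_est` (estimable), `aicc`,
#'   `ess` (effective sample size = total capture events), `real` (tibbles of
#'   real-parameter estimates with SEs), `n_obs`, and convergence
#'   diagnostics.
#' @export
fit_popan <- function(spec, histories, sessions = NULL,
                      sexes = NULL, seed = 1L, n_restarts = 5L,
                      grad_tol = 1e-6, maxit = 500L, hessian = TRUE) {
  if (is.character(spec)) spec <- parse_model(spec)
  sessions <- sessions %||% attr(histories, "sessions")
  if (is.null(sessions)) stop_mrr("no session calendar supplied", "validation_error")
  sexes <- sexes %||% intersect(sex_levels, unique(histories$sex))
  if (length(sexes) == 0) stop_mrr("no histories to fit", "validation_error")
  missing_grp <- setdiff(sexes, unique(histories$sex))
  if (length(missing_grp) > 0)
    stop_mrr(paste0("no histories for modelled group(s): ",
                    paste(missing_grp, collapse = ", ")), "validation_error")
  design <- build_design(spec, sessions, sexes)
  agg <- aggregate_histories(histories, sexes)
  n_obs <- vapply(agg, `[[`, 0L, "n")

  negll <- function(b) {
    v <- popan_loglik_agg(b, design, agg)
    if (!is.finite(v)) 1e10 else -v
  }

  start <- numeric(design$K)
  # log-N intercept so that N ~= 2 * n_observed from the shifted-log link
  icol <- which(colnames(design$X$N) == "(Intercept)")
  if (length(icol) == 1) {
    start[design$idx$N[icol]] <- log(max(n_obs) + 1)
  } else {
    start[design$idx$N] <- log(max(n_obs) + 1)
  }

  fits <- with_seed(sub_seed(seed, 11L), {
    starts <- c(list(start), lapply(seq_len(n_restarts), function(i) {
      start + rnorm(design$K, sd = 0.5)
    }))
    lapply(starts, function(s0) {
      tryCatch(optim(s0, negll, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop_mrr("all optimizer starts failed", "optim_error")
  vals <- vapply(fits, `[[`, 0, "value")
  gnorms <- vapply(fits, function(f) {
    g <- tryCatch(pracma::grad(negll, f$par), error = function(e) rep(Inf, design$K))
    sqrt(sum(g^2))
  }, 0)
  converged <- is.finite(vals) & vals < 1e9 & gnorms < grad_tol * max(1, abs(vals))
  cand <- if (any(converged)) which(converged) else which.min(vals)
  best <- cand[which.min(vals[cand])]
  if (!any(converged)) {
    rlang::abort(
      paste0("POPAN fit did not converge after ", n_restarts,
             " restarts (best gradient norm ", signif(min(gnorms), 3), ")"),
      class = "mrrkit_nonconvergence",
      best_beta = fits[[best]]$par, grad_norm = min(gnorms),
      logLik = -vals[best])
  }
  beta <- fits[[best]]$par
  ll <- -vals[best]

  vcov <- NULL
  K_est <- NA_integer_
  if (hessian) {
    H <- pracma::hessian(negll, beta)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    K_est <- sum(ev > 1e-6 * max(abs(ev), 1))
    vcov <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    vcov <- (vcov + t(vcov)) / 2
  }

  ess <- sum(vapply(agg, function(a) {
    if (a$n == 0) 0 else sum(a$counts * rowSums(a$ch))
  }, 0))
  fit <- structure(list(
    spec = design$spec, design = design, beta = beta, vcov = vcov,
    logLik = ll, K = design$K, K_est = K_est, ess = ess,
    n_obs = n_obs, seed = seed,
    grad_norm = gnorms[best], n_converged = sum(converged)),
    class = "popan_fit")
  fit$aicc <- aicc(fit)
  fit$real <- real_param_tables(fit)
  fit
}

# real-parameter tables with delta-method SEs
real_param_tables <- function(fit) {
  design <- fit$design
  S <- design$S
  G <- length(design$sexes)
  flatten <- function(beta) {
    r <- popan_real(design, beta, fit$n_obs)
    c(as.vector(r$phi_day), as.vector(r$p), as.vector(r$pent), r$N)
  }
  est <- flatten(fit$beta)
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov)) {
    J <- pracma::jacobian(flatten, fit$beta)
    se <- sqrt(pmax(0, diag(J %*% fit$vcov %*% t(J))))
  }
  split_mat <- function(vals, nrow_) matrix(vals, nrow = nrow_, ncol = G,
                                            dimnames = list(NULL, design$sexes))
  i1 <- seq_len((S - 1) * G)
  i2 <- max(i1) + seq_len(S * G)
  i3 <- max(i2) + seq_len(S * G)
  i4 <- max(i3) + seq_len(G)
  long <- function(m, se_m, what, occ) {
    tibble::tibble(parameter = what,
                   occasion = rep(occ, G),
                   sex = rep(design$sexes, each = length(occ)),
                   estimate = as.vector(m), se = as.vector(se_m))
  }
  list(
    phi = long(split_mat(est[i1], S - 1), split_mat(se[i1], S - 1),
               "phi_daily", seq_len(S - 1)),
    p = long(split_mat(est[i2], S), split_mat(se[i2], S), "p", seq_len(S)),
    pent = long(split_mat(est[i3], S), split_mat(se[i3], S), "pent", seq_len(S)),
    N = tibble::tibble(parameter = "N_super", sex = design$sexes,
                       estimate = unname(est[i4]), se = unname(se[i4]))
  )
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logL + 2K + 2K(K + 1) / (ess - K - 1)`. The default effective
#' sample size is the total number of capture events (captures plus
#' recaptures), stored on the fit.
#'
#' @param x A `popan_fit`, or a numeric log-likelihood.
#' @param ess Effective sample size; defaults to the fit's stored value.
#' @param K Structural parameter count (required when `x` is numeric).
#' @return The AICc value.
#' @export
aicc <- function(x, ess = NULL, K = NULL) {
  if (inherits(x, "popan_fit")) {
    ll <- x$logLik
    K <- K %||% x$K
    ess <- ess %||% x$ess
  } else {
    ll <- x
    if (is.null(K) || is.null(ess))
      stop_mrr("K and ess are required for a numeric log-likelihood", "validation_error")
  }
  if (ess <= K + 1)
    stop_mrr("AICc undefined: effective sample size must exceed K + 1",
             "ess_error")
  -2 * ll + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

#' Rank fitted POPAN models by AICc
#'
#' Sorts fits ascending by AICc and applies parsimony selection: among all
#' models within `delta < 2` of the best AICc, the one with the fewest
#' structural parameters is flagged as selected (ties broken by lower AICc,
#' then by canonical model string).
#'
#' @param fits A list of `popan_fit` objects, or a data frame with columns
#'   `model`, `aicc` and `K` (useful for published model tables).
#' @param delta_max Width of the equal-support band, default 2.
#' @return A tibble with `model`, `K`, `logLik`, `aicc`, `delta`, `selected`.
#' @export
rank_models <- function(fits, delta_max = 2) {
  if (is.data.frame(fits)) {
    tab <- tibble::tibble(model = fits$model, K = fits$K,
                          logLik = fits$logLik %||% rep(NA_real_, nrow(fits)),
                          aicc = fits$aicc)
  } else {
    if (inherits(fits, "popan_fit")) fits <- list(fits)
    tab <- tibble::tibble(
      model = vapply(fits, function(f) format(f$spec), character(1)),
      K = vapply(fits, `[[`, 0L, "K"),
      logLik = vapply(fits, `[[`, 0, "logLik"),
      aicc = vapply(fits, `[[`, 0, "aicc"))
  }
  tab <- tab |>
    dplyr::mutate(delta = .data$aicc - min(.data$aicc)) |>
    dplyr::arrange(.data$aicc, .data$K, .data$model)
  band <- which(tab$delta < delta_max)
  pick <- band[order(tab$K[band], tab$aicc[band], tab$model[band])][1]
  tab$selected <- seq_len(nrow(tab)) == pick
  tab
}

#' @export
print.popan_fit <- function(x, ...) {
  cat("POPAN fit ", format(x$spec), "\n", sep = "")
  cat(sprintf("  logLik %.3f  K %d (estimable %s)  AICc %.2f  ess %d\n",
              x$logLik, x$K, as.character(x$K_est), x$aicc, as.integer(x$ess)))
  print(x$real$N)
  invisible(x)
}

#' @method tidy popan_fit
#' @export
tidy.popan_fit <- function(x, ...) {
  dplyr::bind_rows(x$real$phi, x$real$p, x$real$pent,
                   dplyr::mutate(x$real$N, occasion = NA_integer_))
}

#' @method glance popan_fit
#' @export
glance.popan_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, K = x$K, K_est = x$K_est,
                 AICc = x$aicc, ess = x$ess, n = sum(x$n_obs),
                 grad_norm = x$grad_norm)
}
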