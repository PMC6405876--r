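# Independent oracles used across the suite. These deliberately use brute
# force (exhaustive enumeration / tail summation / permutation) and stay
# independent of the code paths they check.

# POPAN group log-likelihood by exhaustive enumeration over every
# (entry session, last-alive session) pair per individual, including the
# never-seen ones.
oracle_popan_ll <- function(ch, counts, phi_int, p, pent, N) {
  S <- length(p)
  pr_history <- function(y) {
    f <- which(y == 1)[1]
    l <- max(which(y == 1))
    tot <- 0
    for (e in seq_len(S)) {
      if (e > f) next
      for (d in e:S) {
        if (d < l) next
        pr <- pent[e]
        if (d > e) pr <- pr * prod(phi_int[e:(d - 1)])
        if (d < S) pr <- pr * (1 - phi_int[d])
        pr <- pr * prod(ifelse(y[e:d] == 1, p[e:d], 1 - p[e:d]))
        if (any(y[setdiff(seq_len(S), e:d)] == 1)) pr <- 0
        tot <- tot + pr
      }
    }
    tot
  }
  pi0 <- 0
  for (e in seq_len(S)) {
    for (d in e:S) {
      pr <- pent[e]
      if (d > e) pr <- pr * prod(phi_int[e:(d - 1)])
      if (d < S) pr <- pr * (1 - phi_int[d])
      pi0 <- pi0 + pr * prod(1 - p[e:d])
    }
  }
  n <- sum(counts)
  ll <- lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1) + (N - n) * log(pi0)
  for (i in seq_len(nrow(ch))) {
    ll <- ll + counts[i] * log(pr_history(ch[i, ]))
  }
  ll
}

# exact (Clopper-Pearson style) binomial interval by exhaustive tail
# summation over dbinom, at confidence level 1 - alpha
oracle_binom_ci <- function(x, n, alpha) {
  lower <- 0
  if (x > 0) {
    f <- function(p) sum(dbinom(x:n, n, p)) - alpha / 2
    lower <- uniroot(f, c(1e-12, 1 - 1e-12))$root
  }
  upper <- 1
  if (x < n) {
    f <- function(p) sum(dbinom(0:x, n, p)) - alpha / 2
    upper <- uniroot(f, c(1e-12, 1 - 1e-12))$root
  }
  c(lower = lower, upper = upper)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  U_of <- function(ix) {
    xx <- all_v[ix]; yy <- all_v[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- U_of(seq_len(n1))
  combs <- utils::combn(length(all_v), n1)
  us <- apply(combs, 2, U_of)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# shared small single-sex simulation configuration for fitting tests
toy_popan_config <- function(seed, n_super = 150, p_intercept = qlogis(0.45),
                             phi = 0.85, S = 5, pent = NULL) {
  sessions <- tibble::tibble(
    date = as.Date("2016-07-20") + seq(0, by = 3, length.out = S),
    hours = rep(4, S))
  pent <- pent %||% rep(1 / S, S)
  sim_config(
    sessions = sessions, n_super = c(male = n_super),
    pent = list(male = pent),
    survival = list(intercept = qlogis(phi), female_offset = 0, day_slope = 0),
    capture = list(intercept = c(male = p_intercept), hours_slope = c(male = 0)),
    movement = list(kernel = "NEF", mean_step = c(male = 60)),
    wing = list(rate = c(male = 0.1), sigma = 0.15),
    behaviour = list(male = c(0.7, 0.12, 0.12, 0.06)),
    flowers = tibble::tibble(family = "Asteraceae", genus = "Taraxacum",
                             prob = 1),
    arena = c(500, 200), seed = seed)
}

`%||%` <- rlang::`%||%`

# write a records tibble to a temp csv in the ingestion dialect
write_captures_csv <- function(records) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(records, f, na = "")
  f
}
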