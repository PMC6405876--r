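#' Parse a POPAN model-structure string
#'
#' Parses the MARK-style dependency grammar
#' `"{Phi(...) p(...) pent(...) N(...)}"` in which each parameter block is an
#' expression over the vocabulary `.` (constant), `g` (sex), `t` (factorial
#' time), `T` (linear time, centred elapsed calendar days) and `hours`
#' (session sampling effort), combined additively with `+` or interactively
#' with `x` (or `*`/`×`). `hours` is only permitted in the capture
#' probability `p`; the superpopulation `N` may only be `.` or `g`.
#'
#' @param spec_string The model string; whitespace-tolerant.
#' @return An object of class `popan_model` that prints in canonical form.
#' @export
#' @examples
#' parse_model("{Phi(g+T) p(g x hours) pent(t) N(.)}")
parse_model <- function(spec_string) {
  s <- spec_string
  m <- regmatches(s, regexec(
    "^\\s*\\{\\s*Phi\\s*\\(([^)]*)\\)\\s*p\\s*\\(([^)]*)\\)\\s*pent\\s*\\(([^)]*)\\)\\s*N\\s*\\(([^)]*)\\)\\s*\\}\\s*$",
    s, ignore.case = TRUE))[[1]]
  if (length(m) != 5) {
    stop_mrr(paste0("malformed model string (expected \"{Phi(...) p(...) pent(...) N(...)}\"): ",
                    spec_string), "parse_error")
  }
  blocks <- list(phi = parse_structure(m[2], "Phi"),
                 p = parse_structure(m[3], "p"),
                 pent = parse_structure(m[4], "pent"),
                 N = parse_structure(m[5], "N"))
  if ("hours" %in% blocks$phi$atoms)
    stop_mrr("'hours' is only permitted in the capture probability p, not Phi",
             "semantic_error")
  if ("hours" %in% blocks$pent$atoms)
    stop_mrr("'hours' is only permitted in the capture probability p, not pent",
             "semantic_error")
  if (!identical(blocks$N$atoms, ".") && !identical(blocks$N$atoms, "g"))
    stop_mrr("N structure must be '.' or 'g'", "semantic_error")
  out <- structure(blocks, class = "popan_model")
  attr(out, "string") <- format(out)
  out
}

# parse one parameter-block expression into atoms + operators
parse_structure <- function(expr, where) {
  e <- gsub("×", "x", expr)
  e <- gsub("\\*", "x", e)
  e <- gsub("\\s+", "", e)
  if (e == "")
    stop_mrr(paste0("empty structure for ", where), "parse_error")
  # tokenize on + and x separators, protecting the literal 'hours'
  prot <- gsub("hours", "H", e)
  atoms <- strsplit(prot, "[+x]")[[1]]
  atoms[atoms == "H"] <- "hours"
  ops <- regmatches(prot, gregexpr("[+x]", prot))[[1]]
  vocab <- c(".", "g", "t", "T", "hours")
  bad <- setdiff(atoms, vocab)
  if (length(bad) > 0 || length(atoms) != length(ops) + 1)
    stop_mrr(paste0("unparseable structure '", expr, "' in ", where,
                    " (vocabulary: ., g, t, T, hours)"), "parse_error")
  if ("." %in% atoms && length(atoms) > 1)
    stop_mrr(paste0("'.' cannot be combined with other terms in ", where),
             "parse_error")
  if (anyDuplicated(atoms) > 0)
    stop_mrr(paste0("repeated term in ", where, ": ", expr), "parse_error")
  list(atoms = atoms, ops = ops)
}

structure_string <- function(block) {
  if (length(block$atoms) == 1) return(block$atoms)
  out <- block$atoms[1]
  for (i in seq_along(block$ops)) {
    out <- paste(out, block$ops[i], block$atoms[i + 1])
  }
  out
}

#' @export
format.popan_model <- function(x, ...) {
  paste0("{Phi(", structure_string(x$phi), ") p(", structure_string(x$p),
         ") pent(", structure_string(x$pent), ") N(", structure_string(x$N), ")}")
}

#' @export
print.popan_model <- function(x, ...) {
  cat("POPAN model ", format(x), "\n", sep = "")
  invisible(x)
}

# translate a structure block into an R model formula over the design frame
structure_formula <- function(block) {
  if (identical(block$atoms, ".")) return(~1)
  map <- c(g = "sex", t = "occf", T = "dayc", hours = "hours")
  terms <- map[block$atoms]
  ops <- ifelse(block$ops == "x", "*", "+")
  rhs <- terms[1]
  for (i in seq_along(ops)) rhs <- paste(rhs, ops[i], terms[i + 1])
  stats::as.formula(paste("~", rhs))
}

#' Build POPAN design matrices
#'
#' Maps a parsed model structure onto design matrices that carry the beta
#' vector (link scale) to the real parameters: logit links for daily survival
#' `Phi` and capture probability `p`, a multinomial-logit link with the last
#' session as reference cell for the entry probabilities `pent`, and a
#' shifted-log link for the superpopulation `N`
#' (`N = n_observed - 1 + exp(eta)`), which enforces the lower bound at the
#' number of distinct individuals observed. Linear time `T` enters as centred
#' elapsed calendar days; `hours` as the session's effort value. Daily
#' survival applies between sessions raised to the calendar gap in days.
#'
#' @param spec A `popan_model` (or a string passed to [parse_model()]).
#' @param sessions Session calendar tibble (`session`, `date`, `hours`,
#'   `gap_days`) with at least 2 sessions.
#' @param sexes Modelled groups, default `c("male", "female")`.
#' @return A list of class `popan_design`: design matrices `X` per block,
#'   column index map `idx`, total structural parameter count `K`, the
#'   calendar, and bookkeeping vectors.
#' @export
build_design <- function(spec, sessions, sexes = c("male", "female")) {
  if (is.character(spec)) spec <- parse_model(spec)
  S <- nrow(sessions)
  if (S < 2) stop_mrr("need at least 2 sessions", "dimension_error")
  uses_g <- vapply(spec, function(b) "g" %in% b$atoms, logical(1))
  if (length(sexes) < 2 && any(uses_g))
    stop_mrr("sex-dependent structure with fewer than 2 groups", "dimension_error")
  day <- as.numeric(sessions$date - sessions$date[1])
  dayc <- day - mean(day)
  gap <- sessions$gap_days[-S]
  if (any(is.na(gap))) gap <- c(diff(day))
  hours <- sessions$hours
  if (any(is.na(hours)) && "hours" %in% spec$p$atoms)
    stop_mrr("model uses 'hours' but the calendar has no effort values",
             "validation_error")

  frame <- function(occ, hrs = NA_real_) {
    tidyr::expand_grid(sex = factor(sexes, levels = sexes), occ = occ) |>
      dplyr::mutate(occf = factor(.data$occ),
                    dayc = dayc[.data$occ],
                    hours = if (all(is.na(hrs))) NA_real_ else hrs[.data$occ])
  }
  f_phi <- frame(seq_len(S - 1))
  f_p <- frame(seq_len(S), hours)
  f_pent <- frame(seq_len(S - 1))   # reference cell: last session
  f_N <- tibble::tibble(sex = factor(sexes, levels = sexes))

  mm <- function(block, fr, what) {
    X <- stats::model.matrix(structure_formula(block), fr)
    if (nrow(X) < ncol(X))
      stop_mrr(paste0("too few sessions for the ", what, " structure"),
               "dimension_error")
    X
  }
  X <- list(phi = mm(spec$phi, f_phi, "Phi"),
            p = mm(spec$p, f_p, "p"),
            pent = mm(spec$pent, f_pent, "pent"),
            N = mm(spec$N, f_N, "N"))
  sizes <- vapply(X, ncol, 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  idx <- Map(seq, starts, ends)
  names(idx) <- names(X)
  structure(list(spec = spec, sessions = sessions, sexes = sexes,
                 S = S, gap = gap, dayc = dayc,
                 X = X, idx = idx, K = sum(sizes),
                 frames = list(phi = f_phi, p = f_p, pent = f_pent, N = f_N)),
            class = "popan_design")
}

# real parameters from beta: list with matrices phi_day [S-1 x G],
# phi_int (gap-powered), p [S x G], pent [S x G], and N vector per group
popan_real <- function(design, beta, n_obs) {
  S <- design$S
  G <- length(design$sexes)
  sp <- function(block) {
    drop(design$X[[block]] %*% beta[design$idx[[block]]])
  }
  phi_day <- matrix(plogis(sp("phi")), nrow = S - 1, ncol = G)
  phi_int <- phi_day ^ design$gap
  p <- matrix(plogis(sp("p")), nrow = S, ncol = G)
  eta_pent <- matrix(sp("pent"), nrow = S - 1, ncol = G)
  pent <- apply(rbind(eta_pent, 0), 2, function(e) {
    e <- e - max(e)
    exp(e) / sum(exp(e))
  })
  pent <- matrix(pent, nrow = S, ncol = G)
  eta_N <- drop(design$X$N %*% beta[design$idx$N])
  N <- n_obs - 1 + exp(eta_N)
  colnames(phi_day) <- colnames(phi_int) <- colnames(p) <- colnames(pent) <-
    design$sexes
  names(N) <- design$sexes
  list(phi_day = phi_day, phi_int = phi_int, p = p, pent = pent, N = N)
}
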