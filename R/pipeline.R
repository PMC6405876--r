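#' Assemble a pipeline run configuration
#'
#' Collects the inputs and tuning parameters for a full analysis run. Input
#' tables may be given as file paths (delimited text) or in-memory data
#' frames; paths are checked at construction.
#'
#' @param captures Capture-record table or path (see [read_captures()]).
#' @param effort Sampling-effort table or path (`date`, `hours`).
#' @param availability Plant-availability table or path (`level`, `taxon`,
#'   `proportion`); optional, selection stage is skipped without it.
#' @param models Character vector of POPAN model strings to rank.
#' @param widths Distance-class widths in metres, default `c(20, 30, 50)`.
#' @param wing_threshold Minimum individuals per day and sex for the daily
#'   wing means, default 5.
#' @param levels Selection levels to analyse, subset of
#'   `c("family", "genus")`.
#' @param alpha Familywise level for the simultaneous intervals.
#' @param area_ha Optional study-area size in hectares.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all randomness in the run flows from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(captures, effort = NULL, availability = NULL,
                       models = "{Phi(.) p(.) pent(t) N(.)}",
                       widths = c(20, 30, 50), wing_threshold = 5,
                       levels = "family", alpha = 0.05, area_ha = NULL,
                       out_dir = tempfile("mrr_run_"), seed = 1L) {
  for (p in list(captures, effort, availability)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop_mrr(paste0("input path does not exist: ", p), "config_error")
  }
  if (alpha <= 0 || alpha >= 1) stop_mrr("alpha must lie in (0, 1)", "config_error")
  structure(list(captures = captures, effort = effort,
                 availability = availability, models = models,
                 widths = widths, wing_threshold = wing_threshold,
                 levels = levels, alpha = alpha, area_ha = area_ha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (table inputs as paths).
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_run_inputs <- function(cfg) {
  if (is.character(cfg$captures)) {
    cap <- read_captures(cfg$captures, effort = cfg$effort)
  } else {
    records <- tibble::as_tibble(cfg$captures)
    records$date <- as.Date(records$date)
    eff <- cfg$effort
    if (is.character(eff)) eff <- readr::read_csv(eff, show_col_types = FALSE)
    if (!is.null(eff)) {
      eff <- dplyr::arrange(tibble::tibble(date = as.Date(eff$date),
                                           hours = as.numeric(eff$hours)), date)
      sessions <- tibble::tibble(session = seq_len(nrow(eff)), date = eff$date,
                                 hours = eff$hours,
                                 gap_days = c(as.integer(diff(eff$date)), NA))
    } else {
      dts <- sort(unique(records$date))
      sessions <- tibble::tibble(session = seq_along(dts), date = dts,
                                 hours = NA_real_,
                                 gap_days = c(as.integer(diff(dts)), NA))
    }
    records$session <- match(records$date, sessions$date)
    cap <- list(records = records, sessions = sessions)
  }
  avail <- cfg$availability
  if (is.character(avail)) avail <- readr::read_csv(avail, show_col_types = FALSE)
  list(records = cap$records, sessions = cap$sessions, availability = avail)
}

#' Run the demography stage: model ranking and derived abundance
#'
#' Fits every model in the configuration's list, ranks them by AICc with
#' the parsimony rule, and writes `ranking.csv` plus the derived daily
#' abundance of the selected model to `abundance.csv`.
#'
#' @param cfg A `run_config`.
#' @return A list: `ranking` tibble, `abundance` (of the selected model),
#'   `fits` (named list of `popan_fit`s, failures as `NULL` with the error
#'   message in `failures`).
#' @export
run_demography <- function(cfg) {
  inp <- load_run_inputs(cfg)
  hist <- build_histories(inp$records, inp$sessions)
  fits <- list(); failures <- character()
  for (m in cfg$models) {
    f <- tryCatch(fit_popan(m, hist, seed = cfg$seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failures[m] <- conditionMessage(f)
    } else {
      fits[[format(f$spec)]] <- f
    }
  }
  if (length(fits) == 0)
    stop_mrr(paste0("all models failed:\n",
                    paste(names(failures), failures, sep = ": ",
                          collapse = "\n")), "all_models_failed")
  ranking <- rank_models(fits)
  best <- fits[[ranking$model[ranking$selected]]]
  abund <- derived_abundance(best, area_ha = cfg$area_ha)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(ranking, file.path(cfg$out_dir, "ranking.csv"))
    readr::write_csv(tibble::as_tibble(abund),
                     file.path(cfg$out_dir, "abundance.csv"))
  }
  list(ranking = ranking, abundance = abund, fits = fits, failures = failures)
}

#' Run the full analysis pipeline
#'
#' Executes every stage — demography (model ranking, abundance), dispersal
#' (distances, sex comparison, ICP tables, kernel fits, extrapolation),
#' wing wear (daily means, population trend, individual decay) and nectar
#' selection — writing each stage's tabular output, a machine-readable
#' manifest with content hashes, and a plain-text summary of the headline
#' quantities. A stage failure yields a partial bundle with the failure
#' recorded in the manifest; `ok` is `TRUE` only when every requested stage
#' succeeded.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the per-stage results, `manifest` tibble
#'   and `ok` flag.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_run_inputs(cfg)
  hist <- build_histories(inp$records, inp$sessions)
  results <- list()
  failures <- list()
  files <- character()
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) {
      failures[[name]] <<- conditionMessage(r)
      NULL
    } else {
      results[[name]] <<- r
      r
    }
  }
  save_csv <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_csv(tibble::as_tibble(x), path)
    files <<- c(files, path)
  }

  demo <- stage("demography", {
    d <- run_demography(cfg)
    files <- c(file.path(cfg$out_dir, c("ranking.csv", "abundance.csv")))
    d
  })
  if (!is.null(demo)) {
    files <- c(files, file.path(cfg$out_dir, c("ranking.csv", "abundance.csv")))
  }

  disp <- stage("dispersal", {
    moves <- movement_distances(hist)
    save_csv(moves, "moves.csv")
    save_csv(movement_summary(moves), "movement_summary.csv")
    comp <- tryCatch(compare_sexes(moves), error = function(e) NULL)
    if (!is.null(comp)) save_csv(comp, "movement_sex_test.csv")
    kernels <- list()
    for (s in unique(moves$sex)) for (w in cfg$widths) {
      icp <- icp_table(moves[moves$sex == s, ], width = w)
      save_csv(icp, sprintf("icp_%s_%dm.csv", s, w))
      for (mdl in c("NEF", "IPF")) {
        kf <- tryCatch(fit_kernel(icp, mdl), error = function(e) NULL)
        if (!is.null(kf)) {
          kernels[[sprintf("%s_%s_%d", s, mdl, w)]] <-
            dplyr::mutate(glance(kf), sex = s)
        }
      }
    }
    ktab <- dplyr::bind_rows(kernels)
    save_csv(ktab, "kernels.csv")
    extrap <- purrr::map_dfr(names(kernels), function(nm) {
      parts <- strsplit(nm, "_")[[1]]
      icp <- icp_table(moves[moves$sex == parts[1], ],
                       width = as.numeric(parts[3]))
      kf <- tryCatch(fit_kernel(icp, parts[2]), error = function(e) NULL)
      if (is.null(kf) || kf$width != max(cfg$widths)) return(NULL)
      dplyr::mutate(extrapolate_kernel(kf), sex = parts[1], model = parts[2])
    })
    if (nrow(extrap) > 0) save_csv(extrap, "extrapolation.csv")
    list(moves = moves, summary = movement_summary(moves), test = comp,
         kernels = ktab, extrapolation = extrap)
  })

  wings <- stage("wings", {
    dm <- daily_mean_wing(inp$records, threshold = cfg$wing_threshold)
    save_csv(dm, "wing_daily_means.csv")
    trend <- wing_trend(dm)
    save_csv(trend, "wing_trend.csv")
    decay <- individual_decay(hist)
    save_csv(decay, "wing_decay.csv")
    list(daily = dm, trend = trend, decay = decay)
  })

  sel <- NULL
  has_flowers <- !is.null(inp$availability) &&
    any(!is.na(inp$records$family) | !is.na(inp$records$genus))
  if (has_flowers) {
    sel <- stage("selection", {
      out <- purrr::map(cfg$levels, function(lv) {
        r <- selection_pipeline(inp$records, inp$availability, level = lv,
                                alpha = cfg$alpha)
        save_csv(r, sprintf("selection_%s.csv", lv))
        r
      })
      names(out) <- cfg$levels
      out
    })
  } else {
    failures$selection <- "skipped: no flower/availability data"
  }

  beh <- stage("behaviour", {
    b <- behaviour_table(hist)
    save_csv(b$counts, "behaviour_counts.csv")
    b
  })

  summary_path <- file.path(cfg$out_dir, "summary.txt")
  writeLines(run_summary_lines(results, failures, cfg), summary_path)
  files <- c(files, summary_path)
  files <- unique(files[file.exists(files)])
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  manifest_all <- list(seed = cfg$seed,
                       files = manifest,
                       failures = failures)
  jsonlite::write_json(manifest_all, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- length(setdiff(names(failures), "selection")) == 0 &&
    (!has_flowers || is.null(failures$selection))
  invisible(list(results = results, failures = failures,
                 manifest = manifest, ok = ok, out_dir = cfg$out_dir))
}

run_summary_lines <- function(results, failures, cfg) {
  lines <- c("MRR analysis summary", paste0("seed: ", cfg$seed), "")
  if (!is.null(results$demography)) {
    r <- results$demography
    tot <- attr(r$abundance, "totals")
    lines <- c(lines, "Demography:",
               paste0("  selected model: ",
                      r$ranking$model[r$ranking$selected]),
               sprintf("  N_super %s: %.1f (SE %.1f)%s", tot$sex, tot$N_super,
                       tot$se,
                       if ("density" %in% names(tot))
                         sprintf(", %d per ha", tot$density) else ""),
               "")
  }
  if (!is.null(results$dispersal)) {
    s <- results$dispersal$summary
    lines <- c(lines, "Dispersal:",
               sprintf("  %s: n = %d, mean %.1f m (SE %.1f), max %.0f m",
                       s$sex, s$n, s$mean, s$se, s$max), "")
  }
  if (!is.null(results$wings)) {
    d <- results$wings$decay
    lines <- c(lines, "Wing decay (individual):",
               sprintf("  %s: %.3f per day (SE %.3f, %d pairs)",
                       d$sex, d$slope, d$se_slope, d$n_pairs), "")
  }
  if (!is.null(results$selection)) {
    for (lv in names(results$selection)) {
      r <- results$selection[[lv]]
      lines <- c(lines, paste0("Selection (", lv, "):"),
                 sprintf("  %s: D = %.2f %s", r$taxon, r$jacobs_d,
                         r$jacobs_rating), "")
    }
  }
  if (length(failures) > 0) {
    lines <- c(lines, "Failures:",
               paste0("  ", names(failures), ": ", unlist(failures)))
  }
  lines
}
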