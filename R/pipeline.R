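#' Default pipeline parameters
#'
#' One place for every stage's tunables, with the values used in the
#' week-long-trial analyses. Override any subset via `pipeline_config()`.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(
    detrend_window = 43200,   # 12 h diurnal moving average
    floor_frac = 1e-6,        # positive floor for the rate conversion
    s = 2, gamma = 1,         # Kleinberg automaton
    artificial_tol = 300,     # s around a cleaning time
    min_gap = 60,             # s of absence that counts as a trip
    follow_radius = 600,      # px
    min_follow = 3,           # s
    f_window = c(600, 1000),  # forager return window before the peak, s
    pre_window = 1000,        # dance/follow attachment window, s
    bin_widths = c(120, 300, 600, 1800, 3600),
    q = 3,                    # discretization alphabet
    n_shuffles = 300,         # ETE surrogates
    half_width = 1000,        # NMF window half-width, s
    r_range = 2:10,
    runs_per_rank = 20,
    nmf_iter = 500,
    nmf_restarts = 50,
    stress_target = 0.2,
    n_draws = 500,            # random-pioneer null
    early_days = 5, late_days = 2)
}

#' Assemble and validate a pipeline configuration
#'
#' @param tracking A `tracking_table` or a tracking CSV path.
#' @param meta A [trial_metadata()] or a metadata YAML path.
#' @param out_dir Optional output directory; when given, every stage's
#'   table and a JSON manifest are written there.
#' @param seed Integer seed driving all stochastic stages.
#' @param params Named list overriding entries of [default_params()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("kinetics","bursts","behaviors","infoflow","pioneers",
#'   "similarity")` (default all; later stages require earlier ones).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(tracking, meta, out_dir = NULL, seed = 1,
                            params = list(),
                            stages = c("kinetics", "bursts", "behaviors",
                                       "infoflow", "pioneers",
                                       "similarity")) {
  p <- default_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(params)] <- params
  if (p$s <= 1) stop("invalid config: s must exceed 1")
  if (p$gamma < 0) stop("invalid config: gamma must be nonnegative")
  if (p$detrend_window <= 0) stop("invalid config: detrend_window <= 0")
  if (p$min_gap < 1) stop("invalid config: min_gap < 1")
  if (any(diff(p$f_window) <= 0)) stop("invalid config: f_window")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(tracking = tracking, meta = meta, out_dir = out_dir,
                 seed = as.integer(seed), params = p, stages = stages),
            class = "pipeline_config")
}

#' Run the full burst-analysis pipeline
#'
#' Stage order follows the analysis logic: activity kinetics, burst
#' detection, behavioral event detection, K/D/O information flow, pioneer
#' extraction, burst similarity. Each stage's outputs are collected in the
#' returned report (and written as CSV plus a JSON manifest when `out_dir`
#' is set). The whole run is a deterministic function of (inputs, config,
#' seed).
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with one element per executed stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  p <- config$params
  meta <- if (inherits(config$meta, "trial_metadata")) config$meta
          else read_trial_metadata(config$meta)
  input_path <- NULL
  table <- if (inherits(config$tracking, "tracking_table")) config$tracking
           else {
             input_path <- config$tracking
             read_tracking(config$tracking, meta)
           }
  report <- list(params = p, seed = config$seed,
                 trial_id = meta$trial_id)
  want <- function(s) s %in% config$stages

  if (want("kinetics")) {
    k_raw <- global_ke(table)
    k_det <- detrend_diurnal(k_raw, window = p$detrend_window)
    k_pos <- clamp_positive(k_det, floor_frac = p$floor_frac)
    report$kinetics <- list(raw = k_raw, detrended = k_det,
                            clamped = k_pos)
  }

  if (want("bursts")) {
    gaps <- rate_to_gaps(report$kinetics$clamped)
    levels <- kleinberg_levels(gaps, s = p$s, gamma = p$gamma)
    bursts <- extract_bursts(levels, report$kinetics$clamped)
    bursts <- mark_artificial(bursts, meta, tol = p$artificial_tol)
    report$bursts <- list(levels = levels, table = bursts,
                          n_bursts = nrow(bursts),
                          n_spontaneous = sum(!bursts$artificial))
  }

  if (want("behaviors")) {
    dances <- detect_dances(table)
    follows <- detect_followers(table, dances, radius = p$follow_radius,
                                min_follow = p$min_follow)
    trips <- detect_trips(table, meta, min_gap = p$min_gap)
    trips <- annotate_orientation(trips, meta)
    roles <- label_burst_roles(report$bursts$table, trips, dances, follows,
                               f_window = p$f_window,
                               pre_window = p$pre_window)
    report$behaviors <- list(dances = dances, follows = follows,
                             trips = trips, roles = roles)
  }

  if (want("infoflow")) {
    report$infoflow <- kdo_scan(report$kinetics$raw,
                                report$behaviors$dances,
                                report$behaviors$trips,
                                bin_widths = p$bin_widths, q = p$q,
                                n_shuffles = p$n_shuffles)
  }

  if (want("pioneers")) {
    bursts <- report$bursts$table
    use <- bursts[!bursts$artificial, , drop = FALSE]
    pioneers <- list()
    ranks <- integer(0)
    for (i in seq_len(nrow(use))) {
      win <- extract_window(table, use[i, ], half_width = p$half_width)
      r <- select_rank(win, r_range = p$r_range,
                       runs_per_rank = p$runs_per_rank,
                       n_iter = p$nmf_iter)
      fit <- run_nmf(win, r = r, n_iter = p$nmf_iter,
                     n_restarts = p$nmf_restarts)
      pioneers[[as.character(use$burst_id[i])]] <-
        classify_pioneers(fit, win)
      ranks <- c(ranks, as.integer(r))
    }
    roster <- bee_roster(table)
    PM <- build_pioneer_matrix(pioneers, roster)
    overlap <- role_overlap(pioneers, report$behaviors$roles, roster,
                            dances = report$behaviors$dances,
                            follows = report$behaviors$follows)
    report$pioneers <- list(sets = pioneers, matrix = PM, ranks = ranks,
                            overlap = overlap)
  }

  if (want("similarity")) {
    PM <- report$pioneers$matrix
    nonempty <- sum(colSums(PM) > 0)
    if (nonempty >= 4) {
      report$similarity <- dispersion_comparison(
        PM, report$bursts$table, meta,
        early_days = p$early_days, late_days = p$late_days,
        n_draws = p$n_draws, stress_target = p$stress_target)
    } else {
      message("similarity stage skipped: only ", nonempty,
              " burst(s) with pioneers")
    }
  }

  if (!is.null(config$out_dir))
    write_report(report, config, meta, input_path)
  class(report) <- "pipeline_report"
  report
}

write_report <- function(report, config, meta, input_path) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(name) file.path(config$out_dir, name)
  if (!is.null(report$kinetics))
    write.csv(as.data.frame(report$kinetics$detrended),
              outp("k_detrended.csv"), row.names = FALSE)
  if (!is.null(report$bursts))
    write.csv(as.data.frame(report$bursts$table), outp("bursts.csv"),
              row.names = FALSE)
  if (!is.null(report$behaviors)) {
    write.csv(report$behaviors$dances, outp("dances.csv"),
              row.names = FALSE)
    write.csv(report$behaviors$follows, outp("follows.csv"),
              row.names = FALSE)
    write.csv(report$behaviors$trips, outp("trips.csv"),
              row.names = FALSE)
    write.csv(report$behaviors$roles, outp("roles.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$infoflow))
    write.csv(report$infoflow, outp("infoflow.csv"), row.names = FALSE)
  if (!is.null(report$pioneers)) {
    PM <- report$pioneers$matrix
    write.csv(data.frame(bee_id = rownames(PM), PM, check.names = FALSE),
              outp("pioneer_matrix.csv"), row.names = FALSE)
  }
  manifest <- list(
    trial_id = meta$trial_id,
    seed = config$seed,
    params = lapply(config$params, I),
    stages = config$stages,
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)),
    counts = list(
      bursts = report$bursts$n_bursts,
      dances = if (!is.null(report$behaviors))
        nrow(report$behaviors$dances),
      follows = if (!is.null(report$behaviors))
        nrow(report$behaviors$follows),
      trips = if (!is.null(report$behaviors))
        nrow(report$behaviors$trips),
      pioneer_bees = if (!is.null(report$pioneers))
        sum(rowSums(report$pioneers$matrix) > 0)))
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$bursts))
    cat(sprintf("  bursts: %d (%d spontaneous)\n", x$bursts$n_bursts,
                x$bursts$n_spontaneous))
  if (!is.null(x$behaviors))
    cat(sprintf("  dances: %d, follows: %d, trips: %d\n",
                nrow(x$behaviors$dances), nrow(x$behaviors$follows),
                nrow(x$behaviors$trips)))
  if (!is.null(x$pioneers))
    cat(sprintf("  pioneer bees (ever): %d\n",
                sum(rowSums(x$pioneers$matrix) > 0)))
  if (!is.null(x$similarity))
    cat(sprintf("  late/early dispersion: %.3f / %.3f (null pct %.2f)\n",
                x$similarity$var_late, x$similarity$var_early,
                x$similarity$null_percentile))
  invisible(x)
}
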