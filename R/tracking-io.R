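#' Trial metadata
#'
#' Bundles the wall-clock anchor and arena geometry of a tracking trial.
#' Times elsewhere in the package are integer seconds since trial start;
#' the wall-clock mapping (needed e.g. for the before-noon rule in forager
#' classification) goes through `start_datetime`.
#'
#' @param trial_id Character label for the trial.
#' @param start_datetime POSIXct wall-clock time of `t = 0`. Defaults to
#'   midnight UTC of an arbitrary date; pass the real value when clock-based
#'   rules matter.
#' @param entrance_open_t Seconds since start at which the hive entrance was
#'   opened. Absences before this are tracking loss, not trips.
#' @param cleaning_times Numeric vector of seconds at which the observation
#'   glass was cleaned (used to flag artificial bursts).
#' @param arena_width,arena_height Arena bounds in pixels. The defaults are
#'   the bCode camera field (6576 x 4384).
#' @param t_total Total trial length in seconds.
#' @return An object of class `trial_metadata`.
#' @export
trial_metadata <- function(trial_id = "trial",
                           start_datetime = as.POSIXct("2012-07-04 00:00:00",
                                                       tz = "UTC"),
                           entrance_open_t,
                           cleaning_times = numeric(0),
                           arena_width = 6576,
                           arena_height = 4384,
                           t_total) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L,
            inherits(start_datetime, "POSIXct"),
            is.numeric(entrance_open_t), length(entrance_open_t) == 1L,
            is.numeric(t_total), length(t_total) == 1L,
            arena_width > 0, arena_height > 0)
  if (!(entrance_open_t > 0 && entrance_open_t < t_total))
    stop("entrance_open_t must lie strictly inside (0, t_total)")
  structure(list(trial_id = trial_id,
                 start_datetime = start_datetime,
                 entrance_open_t = as.numeric(entrance_open_t),
                 cleaning_times = as.numeric(cleaning_times),
                 arena_width = as.numeric(arena_width),
                 arena_height = as.numeric(arena_height),
                 t_total = as.numeric(t_total)),
            class = "trial_metadata")
}

#' Read / write trial metadata as YAML
#'
#' @param path File path.
#' @param meta A [trial_metadata()] object.
#' @return `read_trial_metadata` returns a `trial_metadata`;
#'   `write_trial_metadata` returns `path` invisibly.
#' @export
read_trial_metadata <- function(path) {
  y <- yaml::read_yaml(path)
  trial_metadata(trial_id = y$trial_id,
                 start_datetime = as.POSIXct(y$start_datetime, tz = "UTC"),
                 entrance_open_t = y$entrance_open_t,
                 cleaning_times = if (is.null(y$cleaning_times)) numeric(0)
                                  else as.numeric(y$cleaning_times),
                 arena_width = y$arena_width,
                 arena_height = y$arena_height,
                 t_total = y$t_total)
}

#' @rdname read_trial_metadata
#' @export
write_trial_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "trial_metadata"))
  out <- meta
  out$start_datetime <- format(meta$start_datetime, "%Y-%m-%d %H:%M:%S",
                               tz = "UTC")
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}

new_tracking_table <- function(df, meta) {
  df <- df[order(df$bee_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, meta = meta,
            class = c("tracking_table", "data.frame"))
}

#' Construct a validated tracking table
#'
#' A tracking table holds one row per detected bee per second: `bee_id`,
#' integer time `t` (seconds since trial start), pixel position `x`, `y`,
#' and the head-direction unit vector `nx`, `ny`. Rows outside the arena or
#' with a heading norm outside \[0.99, 1.01\] are rejected (and counted);
#' headings inside that band are renormalized to unit length. Duplicate
#' `(bee_id, t)` pairs are an integrity error.
#'
#' @param df Data frame with columns `bee_id`, `t`, `x`, `y`, `nx`, `ny`.
#' @param meta A [trial_metadata()] object.
#' @return A `tracking_table` (a data frame) with attributes `meta` and
#'   `n_rejected`.
#' @export
tracking_table <- function(df, meta) {
  req <- c("bee_id", "t", "x", "y", "nx", "ny")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("tracking format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- df[req]
  df$bee_id <- as.character(df$bee_id)
  df$t <- as.integer(df$t)
  if (any(df$t < 0)) stop("tracking integrity error: negative time")

  dup <- duplicated(df[c("bee_id", "t")])
  if (any(dup)) {
    first <- df[which(dup)[1L], ]
    stop(sprintf(
      "tracking integrity error: duplicate record for bee %s at t = %d",
      first$bee_id, first$t))
  }

  nrm <- sqrt(df$nx^2 + df$ny^2)
  bad_heading <- !is.finite(nrm) | nrm < 0.99 | nrm > 1.01
  out_of_arena <- df$x < 0 | df$x > meta$arena_width |
                  df$y < 0 | df$y > meta$arena_height
  reject <- bad_heading | out_of_arena
  n_rejected <- sum(reject)
  if (n_rejected > 0) {
    message(sprintf(
      "tracking_table: rejected %d row(s) (%d out-of-arena, %d bad heading)",
      n_rejected, sum(out_of_arena), sum(bad_heading & !out_of_arena)))
    df <- df[!reject, , drop = FALSE]
    nrm <- nrm[!reject]
  }
  df$nx <- df$nx / nrm
  df$ny <- df$ny / nrm

  tb <- new_tracking_table(df, meta)
  attr(tb, "n_rejected") <- n_rejected
  tb
}

#' Read a per-second tracking CSV
#'
#' Expects the dialect `bee_id,t,x,y,nx,ny` (UTF-8, comma separated,
#' `t` integer). Validation as in [tracking_table()].
#'
#' @param path CSV file path.
#' @param meta A [trial_metadata()] object.
#' @return A `tracking_table`.
#' @export
read_tracking <- function(path, meta) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  tracking_table(df, meta)
}

#' Write a tracking table to CSV
#'
#' Round-trips with [read_tracking()]: integer fields exactly, floats to
#' better than 1e-9 relative (15 significant digits are written).
#'
#' @param table A `tracking_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(table, path) {
  df <- as.data.frame(table)
  for (col in c("x", "y", "nx", "ny"))
    df[[col]] <- formatC(df[[col]], format = "g", digits = 15)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Roster of a tracking table
#' @param table A `tracking_table`.
#' @return Character vector of distinct bee ids, sorted.
#' @export
bee_roster <- function(table) sort(unique(table$bee_id))

#' Maximal presence intervals for one bee
#'
#' Runs of consecutive detected seconds, as closed integer intervals.
#' These are the substrate for trip (absence) detection.
#'
#' @param table A `tracking_table`.
#' @param bee_id A single bee id present in the roster.
#' @return Data frame with columns `start`, `end`; zero rows if the bee has
#'   no detections is impossible (unknown ids are an error).
#' @export
presence_intervals <- function(table, bee_id) {
  if (!bee_id %in% table$bee_id)
    stop("unknown bee_id: ", bee_id)
  ts <- sort(unique(table$t[table$bee_id == bee_id]))
  runs_from_times(ts)
}

# maximal runs of consecutive integers -> data.frame(start, end)
runs_from_times <- function(ts) {
  if (length(ts) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(TRUE, diff(ts) != 1L)
  grp <- cumsum(brk)
  data.frame(start = as.integer(tapply(ts, grp, min)),
             end = as.integer(tapply(ts, grp, max)),
             row.names = NULL)
}

#' @export
print.tracking_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<tracking_table> %d records, %d bees, t in [%d, %d]\n",
              nrow(x), length(unique(x$bee_id)),
              if (nrow(x)) min(x$t) else NA_integer_,
              if (nrow(x)) max(x$t) else NA_integer_))
  if (!is.null(meta))
    cat(sprintf("  trial %s, arena %g x %g px, entrance opens at %g s\n",
                meta$trial_id, meta$arena_width, meta$arena_height,
                meta$entrance_open_t))
  invisible(x)
}
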