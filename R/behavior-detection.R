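#' Detect waggle-dance events
#'
#' A bee is dancing in a 5-second window when (A) each of the 4 consecutive
#' heading pairs turns by more than 90 degrees (dot product of successive
#' unit headings negative) and (B) the turn directions strictly alternate
#' left/right (signs of the scalar cross products alternate; a zero cross
#' product, collinear headings, breaks the alternation). Overlapping or
#' adjacent qualifying windows of one bee merge into a single event, so
#' every event spans at least 5 consecutive seconds.
#'
#' @param table A `tracking_table`.
#' @return Data frame `bee_id,start,end` of dance events.
#' @export
detect_dances <- function(table) {
  out <- list()
  by_bee <- split(table[c("t", "nx", "ny")], table$bee_id)
  for (bee in names(by_bee)) {
    ev <- dance_windows_one(by_bee[[bee]])
    if (nrow(ev)) {
      ev <- cbind(bee_id = bee, ev)
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(bee_id = character(0), start = numeric(0),
                      end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

dance_windows_one <- function(sub) {
  o <- order(sub$t)
  t <- sub$t[o]; nx <- sub$nx[o]; ny <- sub$ny[o]
  n <- length(t)
  none <- data.frame(start = numeric(0), end = numeric(0))
  if (n < 5L) return(none)
  # consecutive-second heading pairs, indexed by their first second
  consec <- diff(t) == 1L
  dot <- nx[-n] * nx[-1L] + ny[-n] * ny[-1L]
  crs <- nx[-n] * ny[-1L] - ny[-n] * nx[-1L]
  ok <- consec & dot < 0
  sgn <- sign(crs)
  sgn[abs(crs) < 1e-9] <- 0  # collinear headings: no turn direction
  m <- length(ok)
  if (m < 4L) return(none)
  i <- seq_len(m - 3L)
  allneg <- ok[i] & ok[i + 1L] & ok[i + 2L] & ok[i + 3L]
  altern <- sgn[i] * sgn[i + 1L] == -1 &
            sgn[i + 1L] * sgn[i + 2L] == -1 &
            sgn[i + 2L] * sgn[i + 3L] == -1
  # window must sit on 5 consecutive seconds
  contig <- consec[i] & consec[i + 1L] & consec[i + 2L] & consec[i + 3L]
  starts <- t[i][allneg & altern & contig]
  if (!length(starts)) return(none)
  merge_windows(starts, 4L)
}

# merge windows [s, s+len] that overlap or touch
merge_windows <- function(starts, len) {
  starts <- sort(starts)
  ends <- starts + len
  brk <- c(TRUE, starts[-1L] > ends[-length(ends)] + 1L)
  grp <- cumsum(brk)
  data.frame(start = as.numeric(tapply(starts, grp, min)),
             end = as.numeric(tapply(ends, grp, max)),
             row.names = NULL)
}

#' Detect dance followers
#'
#' A follower is a bee within `radius` pixels (default 600, about one bee
#' length) of a dancing bee whose head direction stays within 90 degrees of
#' the direction towards the dancer, for at least `min_follow` consecutive
#' detected seconds of the dance.
#'
#' @param table A `tracking_table`.
#' @param dances Dance events from [detect_dances()].
#' @param radius Proximity radius in pixels (default 600).
#' @param min_follow Minimum run length in seconds (default 3).
#' @return Data frame `follower_id,dancer_id,start,end`. Each event's
#'   interval lies inside its dance event.
#' @export
detect_followers <- function(table, dances, radius = 600, min_follow = 3) {
  none <- data.frame(follower_id = character(0), dancer_id = character(0),
                     start = numeric(0), end = numeric(0))
  if (nrow(dances) == 0L) return(none)
  out <- list()
  for (d in seq_len(nrow(dances))) {
    dancer <- dances$bee_id[d]
    win <- table[table$t >= dances$start[d] & table$t <= dances$end[d], ]
    dpos <- win[win$bee_id == dancer, c("t", "x", "y")]
    cand <- win[win$bee_id != dancer, ]
    if (nrow(cand) == 0L || nrow(dpos) == 0L) next
    ix <- match(cand$t, dpos$t)
    have <- !is.na(ix)
    cand <- cand[have, ]; ix <- ix[have]
    dx <- dpos$x[ix] - cand$x
    dy <- dpos$y[ix] - cand$y
    close_enough <- dx * dx + dy * dy <= radius^2
    facing <- cand$nx * dx + cand$ny * dy >= 0
    good <- cand[close_enough & facing, c("bee_id", "t")]
    if (nrow(good) == 0L) next
    for (bee in unique(good$bee_id)) {
      runs <- runs_from_times(sort(good$t[good$bee_id == bee]))
      runs <- runs[runs$end - runs$start + 1L >= min_follow, , drop = FALSE]
      if (nrow(runs))
        out[[length(out) + 1L]] <- data.frame(
          follower_id = bee, dancer_id = dancer,
          start = runs$start, end = runs$end)
    }
  }
  if (!length(out)) return(none)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect foraging trips from tracking absences
#'
#' A trip is a detection gap of at least `min_gap` seconds beginning after
#' the entrance opened; shorter absences are treated as tracking dropouts,
#' and absences before the entrance opened are tracking loss (the door was
#' closed). `exit_t` is the last detection before the gap and `entry_t` the
#' first after it. This absence rule is the main inferential gap relative
#' to data with an instrumented exit tunnel; `min_gap` is the knob that
#' trades dropout robustness against missing short trips.
#'
#' @param table A `tracking_table`.
#' @param meta A [trial_metadata()] (for `entrance_open_t`).
#' @param min_gap Minimum absence duration in seconds (default 60).
#' @return Data frame `bee_id,exit_t,entry_t,is_orientation`
#'   (`is_orientation` is `NA` until [annotate_orientation()] fills it).
#' @export
detect_trips <- function(table, meta, min_gap = 60) {
  out <- list()
  for (bee in bee_roster(table)) {
    iv <- presence_intervals(table, bee)
    if (nrow(iv) < 2L) next
    k <- seq_len(nrow(iv) - 1L)
    gap_start <- iv$end[k] + 1L
    gap_len <- iv$start[k + 1L] - iv$end[k] - 1L
    keep <- gap_len >= min_gap & gap_start >= meta$entrance_open_t
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        bee_id = bee,
        exit_t = as.numeric(iv$end[k][keep]),
        entry_t = as.numeric(iv$start[k + 1L][keep]))
  }
  if (!length(out))
    return(data.frame(bee_id = character(0), exit_t = numeric(0),
                      entry_t = numeric(0), is_orientation = logical(0)))
  res <- do.call(rbind, out)
  res$is_orientation <- NA
  rownames(res) <- NULL
  res
}

#' First foraging day of a bee
#'
#' Orientation flights (early exploratory flights) are excluded from
#' foraging by a per-day rule: the first foraging day is the earliest
#' wall-clock day with at least `min_trips` trips of which more than
#' `noon_frac` departed before 12:00 local time (orientation flights
#' cluster in the afternoon). Trips before that day are orientation
#' flights. The alternative `"first_six"` rule simply discards the bee's
#' first six trips.
#'
#' @param trips Trips of one bee (rows of [detect_trips()] output).
#' @param meta A [trial_metadata()] (for the wall clock).
#' @param method `"day_rule"` (default) or `"first_six"`.
#' @param min_trips,noon_frac Day-rule parameters (defaults 6 and 0.25).
#' @return The qualifying day as a `Date`, or `NA` if none (for
#'   `"first_six"`, the day of the seventh trip).
#' @export
first_foraging_day <- function(trips, meta, method = c("day_rule",
                                                       "first_six"),
                               min_trips = 6, noon_frac = 0.25) {
  method <- match.arg(method)
  if (nrow(trips) == 0L) return(as.Date(NA))
  trips <- trips[order(trips$exit_t), ]
  wall <- meta$start_datetime + trips$exit_t
  tz <- attr(meta$start_datetime, "tzone")
  if (is.null(tz) || !nzchar(tz[1L])) tz <- "UTC"
  day <- as.Date(format(wall, "%Y-%m-%d", tz = tz))
  if (method == "first_six") {
    if (nrow(trips) <= 6L) return(as.Date(NA))
    return(day[7L])
  }
  hour <- as.integer(format(wall, "%H", tz = tz))
  for (d in sort(unique(day))) {
    sel <- day == d
    if (sum(sel) >= min_trips && mean(hour[sel] < 12) > noon_frac)
      return(as.Date(d, origin = "1970-01-01"))
  }
  as.Date(NA)
}

#' Flag orientation flights for every bee
#'
#' Applies [first_foraging_day()] per bee and fills `is_orientation`:
#' trips departing before the bee's first foraging day are orientation
#' flights; bees with no qualifying day have all trips flagged.
#'
#' @inheritParams first_foraging_day
#' @param trips Full trips table from [detect_trips()].
#' @return The trips table with `is_orientation` filled in.
#' @export
annotate_orientation <- function(trips, meta, method = "day_rule",
                                 min_trips = 6, noon_frac = 0.25) {
  if (nrow(trips) == 0L) return(trips)
  tz <- attr(meta$start_datetime, "tzone")
  if (is.null(tz) || !nzchar(tz[1L])) tz <- "UTC"
  day <- as.Date(format(meta$start_datetime + trips$exit_t,
                        "%Y-%m-%d", tz = tz))
  trips$is_orientation <- TRUE
  for (bee in unique(trips$bee_id)) {
    sel <- trips$bee_id == bee
    fday <- first_foraging_day(trips[sel, ], meta, method = method,
                               min_trips = min_trips, noon_frac = noon_frac)
    if (!is.na(fday))
      trips$is_orientation[sel] <- day[sel] < fday
  }
  trips
}

#' Attach behavioral roles to each burst
#'
#' For each burst with peak time p: foragers `F_b` are bees with a
#' non-orientation trip whose hive re-entry falls in
#' `[p - f_window[2], p - f_window[1]]` (default 600-1000 s before the
#' peak); dancers `W_b` and dance followers `DF_b` are bees with a dance /
#' follow event overlapping the pre-peak window `[p - pre_window, p]`.
#'
#' @param bursts A `bursts` data frame.
#' @param trips Trips with `is_orientation` filled
#'   (see [annotate_orientation()]).
#' @param dances Dance events.
#' @param follows Follow events.
#' @param f_window Return-window bounds in seconds before the peak
#'   (default `c(600, 1000)`).
#' @param pre_window Dance/follow attachment window before the peak
#'   (default 1000 s).
#' @return Long data frame `burst_id,role,bee_id` with
#'   `role` in `{"F","W","DF"}`.
#' @export
label_burst_roles <- function(bursts, trips, dances, follows,
                              f_window = c(600, 1000), pre_window = 1000) {
  out <- list()
  add <- function(burst_id, role, bees) {
    if (length(bees))
      out[[length(out) + 1L]] <<- data.frame(burst_id = burst_id,
                                             role = role, bee_id = bees)
  }
  for (i in seq_len(nrow(bursts))) {
    p <- bursts$peak_t[i]
    b <- bursts$burst_id[i]
    if (nrow(trips)) {
      sel <- !trips$is_orientation %in% TRUE &
        trips$entry_t >= p - f_window[2] & trips$entry_t <= p - f_window[1]
      add(b, "F", unique(trips$bee_id[sel]))
    }
    if (nrow(dances)) {
      sel <- dances$start <= p & dances$end >= p - pre_window
      add(b, "W", unique(dances$bee_id[sel]))
    }
    if (nrow(follows)) {
      sel <- follows$start <= p & follows$end >= p - pre_window
      add(b, "DF", unique(follows$follower_id[sel]))
    }
  }
  if (!length(out))
    return(data.frame(burst_id = integer(0), role = character(0),
                      bee_id = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bees holding a role at a given burst
#' @param roles Output of [label_burst_roles()].
#' @param burst_id Burst id.
#' @param role One of `"F"`, `"W"`, `"DF"`.
#' @return Character vector of bee ids.
#' @export
role_set <- function(roles, burst_id, role) {
  unique(roles$bee_id[roles$burst_id == burst_id & roles$role == role])
}
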