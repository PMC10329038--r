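#' Kinetic-energy series
#'
#' The locomotor activity of bee i at second t is its squared per-second
#' displacement, K_i(t) = (x_{t+1} - x_t)^2 + (y_{t+1} - y_t)^2, in px^2/s^2.
#' Seconds where either endpoint is missing carry `NA` (absent, not zero).
#' The hive-level series K_G(t) is the unweighted mean of the K_i(t) defined
#' at t; the averaging set is the bees detected at both t and t+1, so
#' tracking gaps do not create spurious dips.
#'
#' @param table A `tracking_table`.
#' @param bee_id Single bee id for `individual_ke`.
#' @return A `kinetic_series`: data frame with columns `t`, `K` covering
#'   every second of the table's span, with attributes `bee_id` ("GLOBAL"
#'   for the hive series), `kind` ("raw") and, for the global series, a
#'   column `n` with the averaging-set size.
#' @export
individual_ke <- function(table, bee_id) {
  if (!bee_id %in% table$bee_id) stop("unknown bee_id: ", bee_id)
  span <- series_span(table)
  sub <- table[table$bee_id == bee_id, ]
  k <- ke_vector(sub$t, sub$x, sub$y, span)
  new_kinetic_series(data.frame(t = span, K = k), bee_id = bee_id,
                     kind = "raw")
}

series_span <- function(table) {
  if (nrow(table) == 0L) return(integer(0))
  meta <- attr(table, "meta")
  t_max <- if (!is.null(meta)) meta$t_total - 1L else max(table$t)
  seq.int(min(table$t), t_max - 1L)  # K(t) needs t and t+1
}

# K over an integer time grid, NA where either endpoint is undetected
ke_vector <- function(ts, xs, ys, span) {
  if (length(span) == 0L) return(numeric(0))
  off <- span[1L]
  n <- length(span) + 1L
  px <- rep(NA_real_, n); py <- rep(NA_real_, n)
  idx <- ts - off + 1L
  keep <- idx >= 1L & idx <= n
  px[idx[keep]] <- xs[keep]; py[idx[keep]] <- ys[keep]
  (px[-1L] - px[-n])^2 + (py[-1L] - py[-n])^2
}

new_kinetic_series <- function(df, bee_id, kind, bin_width = 1) {
  structure(df, bee_id = bee_id, kind = kind, bin_width = bin_width,
            class = c("kinetic_series", "data.frame"))
}

#' @rdname individual_ke
#' @export
global_ke <- function(table) {
  span <- series_span(table)
  if (length(span) == 0L)
    return(new_kinetic_series(data.frame(t = integer(0), K = numeric(0),
                                         n = integer(0)),
                              bee_id = "GLOBAL", kind = "raw"))
  off <- span[1L]
  m <- length(span)
  tot <- numeric(m); cnt <- integer(m)
  for (sub in split(table[c("t", "x", "y")], table$bee_id)) {
    k <- ke_vector(sub$t, sub$x, sub$y, span)
    ok <- !is.na(k)
    tot[ok] <- tot[ok] + k[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  K <- ifelse(cnt > 0L, tot / pmax(cnt, 1L), NA_real_)
  new_kinetic_series(data.frame(t = span, K = K, n = cnt),
                     bee_id = "GLOBAL", kind = "raw")
}

#' Remove the diurnal cycle from an activity series
#'
#' Subtracts a centered moving average (window truncated at the series
#' edges, `NA`s ignored) from the series. The default 12-h window removes
#' the daily activity cycle while leaving burst-scale structure intact.
#' The operation is linear and maps constant series to zero.
#'
#' @param series A `kinetic_series`.
#' @param window Moving-average window in seconds (default 43200 = 12 h).
#' @return A `kinetic_series` with `kind = "detrended"`. Values may be
#'   negative; see [clamp_positive()] before burst detection.
#' @export
detrend_diurnal <- function(series, window = 43200) {
  if (window <= 0) stop("window must be positive")
  n <- nrow(series)
  if (n <= window)
    stop("series length (", n, ") must exceed the window (", window, ")")
  ma <- running_mean(series$K, window)
  out <- series
  out$K <- series$K - ma
  new_kinetic_series(as.data.frame(out), bee_id = attr(series, "bee_id"),
                     kind = "detrended")
}

# centered moving average, truncated at edges, NA-ignoring
running_mean <- function(x, window) {
  h <- floor(window / 2)
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v)); cc <- c(0, cumsum(cnt))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cc[hi + 1L] - cc[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' Clamp a detrended series to a positive floor
#'
#' The inverse-rate conversion behind burst detection needs strictly
#' positive rates; detrended activity can be negative or zero. Values below
#' `floor_frac` times the mean of the positive part are raised to that
#' floor; `NA` seconds (no tracked bee) are set to the floor as well.
#'
#' @param series A `kinetic_series` (typically detrended).
#' @param floor_frac Floor as a fraction of the positive-part mean
#'   (default 1e-6).
#' @return A `kinetic_series` with all values positive.
#' @export
clamp_positive <- function(series, floor_frac = 1e-6) {
  pos <- series$K[!is.na(series$K) & series$K > 0]
  if (length(pos) == 0L) stop("series has no positive values to anchor floor")
  eps <- floor_frac * mean(pos)
  out <- series
  out$K <- pmax(ifelse(is.na(series$K), eps, series$K), eps)
  new_kinetic_series(as.data.frame(out), bee_id = attr(series, "bee_id"),
                     kind = attr(series, "kind"))
}

#' Bin hive activity, dancer counts and out-of-hive counts
#'
#' Builds the K/D/O triple analysed by the transfer-entropy scan: per bin,
#' `K` is the mean of the hive activity series, `D` the number of distinct
#' bees with a dance event overlapping the bin, and `O` the number of
#' distinct bees out of the hive (on a trip) during the bin. A trailing
#' partial bin is dropped so series are comparable across bin widths.
#'
#' @param k A `kinetic_series` (hive-level).
#' @param dances Data frame `bee_id,start,end` of dance events (may have
#'   zero rows).
#' @param trips Data frame `bee_id,exit_t,entry_t` of trips (may have zero
#'   rows). A bee counts as out of hive during `(exit_t, entry_t)`
#'   exclusive, i.e. the undetected seconds.
#' @param bin_width Bin width in seconds.
#' @return A `kdo_series`: data frame `bin_start,K,D,O` with attribute
#'   `bin_width`.
#' @export
bin_kdo <- function(k, dances, trips, bin_width) {
  stopifnot(bin_width >= 1)
  n <- nrow(k)
  n_bins <- floor(n / bin_width)
  if (n_bins == 0L)
    return(structure(data.frame(bin_start = numeric(0), K = numeric(0),
                                D = integer(0), O = integer(0)),
                     bin_width = bin_width,
                     class = c("kdo_series", "data.frame")))
  t0 <- k$t[1L]
  starts <- t0 + (seq_len(n_bins) - 1L) * bin_width
  grp <- rep(seq_len(n_bins), each = bin_width)
  used <- seq_len(n_bins * bin_width)
  K <- as.numeric(tapply(k$K[used], grp, mean, na.rm = TRUE))

  D <- count_overlapping_bees(dances, "start", "end", starts, bin_width)
  if (!is.null(trips) && nrow(trips)) {
    tr <- data.frame(bee_id = trips$bee_id,
                     start = trips$exit_t + 1, end = trips$entry_t - 1)
    O <- count_overlapping_bees(tr, "start", "end", starts, bin_width)
  } else O <- integer(n_bins)

  structure(data.frame(bin_start = starts, K = K, D = D, O = O),
            bin_width = bin_width,
            class = c("kdo_series", "data.frame"))
}

# distinct bees whose [start,end] interval overlaps each bin
count_overlapping_bees <- function(events, from, to, starts, bin_width) {
  n_bins <- length(starts)
  out <- integer(n_bins)
  if (is.null(events) || nrow(events) == 0L) return(out)
  ends <- starts + bin_width - 1
  for (b in seq_len(n_bins)) {
    hit <- events[[from]] <= ends[b] & events[[to]] >= starts[b]
    out[b] <- length(unique(events$bee_id[hit]))
  }
  out
}
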