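#' Convert an activity series to pseudo-event gaps
#'
#' Kleinberg's automaton consumes inter-event gaps. A frequency-based
#' activity series is converted by taking one pseudo-event gap per second,
#' the inverse of the rate: activity 1 means one event per second (gap 1 s),
#' activity 10 means an event every 0.1 s. The total event count is the sum
#' of the series and the baseline rate is events per second over the span.
#' Keeping one gap per second preserves the time alignment that burst-period
#' extraction needs.
#'
#' @param series A strictly positive `kinetic_series` (detrended and
#'   clamped; see [clamp_positive()]).
#' @return A `gap_series`: list with `gaps`, `times`, `lambda_bar`
#'   (= mean rate N/T), `N`, `T`.
#' @export
rate_to_gaps <- function(series) {
  K <- series$K
  if (any(is.na(K)) || any(K <= 0))
    stop("series must be strictly positive; clamp it first")
  structure(list(gaps = 1 / K,
                 times = series$t,
                 lambda_bar = sum(K) / length(K),
                 N = sum(K),
                 T = length(K)),
            class = "gap_series")
}

#' Kleinberg burst levels by exact dynamic programming
#'
#' The infinite-state burst automaton of Kleinberg (2003), truncated at
#' `max_level`: state i emits gaps as Exp(lambda_bar * s^i); the cost of
#' emitting gap x at state i is -ln f_i(x); raising the level from j to
#' i > j costs `gamma * (i - j) * ln(n)` (n = number of gaps), lowering is
#' free. The minimum-cost state sequence is found exactly by dynamic
#' programming. The paper-level reading "level rises when the rate exceeds
#' lambda_bar * s^level" is the gamma = 0 limit of this automaton; gamma
#' penalises rapid level switching around a threshold.
#'
#' @param gaps A `gap_series` (or bare positive numeric vector, in which
#'   case `lambda_bar` is the inverse mean gap).
#' @param s Rate ratio between adjacent levels (default 2).
#' @param gamma Transition-cost coefficient (default 1).
#' @param max_level Level cap; default
#'   `ceiling(log(max rate / lambda_bar, s)) + 1` (at least 1).
#' @return A `burst_levels` object: list with integer vector `bl` (one level
#'   per gap), `times`, `s`, `gamma`, `max_level`, `cost` (total optimal
#'   cost).
#' @export
kleinberg_levels <- function(gaps, s = 2, gamma = 1, max_level = NULL) {
  if (s <= 1) stop("s must exceed 1")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (inherits(gaps, "gap_series")) {
    x <- gaps$gaps; lambda_bar <- gaps$lambda_bar; times <- gaps$times
  } else {
    x <- as.numeric(gaps); lambda_bar <- 1 / mean(x)
    times <- seq_along(x) - 1L
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 gaps")
  if (any(x <= 0)) stop("gaps must be positive")

  if (is.null(max_level)) {
    rate_ratio <- max(1 / x) / lambda_bar
    max_level <- max(1L, ceiling(log(rate_ratio, base = s)) + 1L)
  }
  L <- as.integer(max_level)
  lam <- lambda_bar * s^(0:L)            # per-level rates
  trans_unit <- gamma * log(n)           # cost per level raised

  # emission cost e[i+1, t] = -ln(lam_i) + lam_i * x_t
  # DP over states; prev[] tracks argmin for backtracking
  cost <- -log(lam) + lam * x[1L] + trans_unit * (0:L)  # start at level 0
  back <- matrix(0L, nrow = L + 1L, ncol = n)
  lev_idx <- 0:L
  for (t in 2:n) {
    new_cost <- numeric(L + 1L)
    for (i in 0:L) {
      trans <- ifelse(lev_idx < i, (i - lev_idx) * trans_unit, 0)
      tot <- cost + trans
      j <- which.min(tot)
      back[i + 1L, t] <- j
      new_cost[i + 1L] <- tot[j] - log(lam[i + 1L]) + lam[i + 1L] * x[t]
    }
    cost <- new_cost
  }
  bl <- integer(n)
  bl[n] <- which.min(cost) - 1L
  for (t in n:2) bl[t - 1L] <- back[bl[t] + 1L, t] - 1L

  structure(list(bl = bl, times = times, s = s, gamma = gamma,
                 max_level = L, cost = min(cost)),
            class = "burst_levels")
}

#' Extract burst periods from a level sequence
#'
#' A burst is a maximal run with burst level >= 1. Its peak is the time of
#' the maximum of the (detrended) activity series within the period,
#' earliest on ties.
#'
#' @param levels A `burst_levels` object.
#' @param series The aligned `kinetic_series` the levels were computed from.
#' @return A `bursts` data frame: `burst_id,start,end,peak_t,peak_value`
#'   (and `artificial = FALSE`), possibly zero rows.
#' @export
extract_bursts <- function(levels, series) {
  if (length(levels$bl) != nrow(series))
    stop("levels and series are not aligned")
  runs <- runs_from_times(which(levels$bl >= 1L))
  if (nrow(runs) == 0L)
    return(empty_bursts())
  out <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    pk <- idx[which.max(series$K[idx])]
    data.frame(burst_id = i,
               start = series$t[runs$start[i]],
               end = series$t[runs$end[i]],
               peak_t = series$t[pk],
               peak_value = series$K[pk])
  })
  out <- do.call(rbind, out)
  out$artificial <- FALSE
  structure(out, class = c("bursts", "data.frame"))
}

empty_bursts <- function() {
  structure(data.frame(burst_id = integer(0), start = numeric(0),
                       end = numeric(0), peak_t = numeric(0),
                       peak_value = numeric(0), artificial = logical(0)),
            class = c("bursts", "data.frame"))
}

#' Flag bursts caused by recorded disturbances
#'
#' Bursts whose period intersects `[c - tol, c + tol]` around any recorded
#' glass-cleaning time c are flagged artificial; the rest are spontaneous.
#'
#' @param bursts A `bursts` data frame.
#' @param meta A [trial_metadata()] with `cleaning_times`.
#' @param tol Tolerance in seconds around each cleaning time (default 300).
#' @return The `bursts` data frame with `artificial` filled in.
#' @export
mark_artificial <- function(bursts, meta, tol = 300) {
  if (nrow(bursts) == 0L) return(bursts)
  art <- rep(FALSE, nrow(bursts))
  for (c_t in meta$cleaning_times)
    art <- art | (bursts$start <= c_t + tol & bursts$end >= c_t - tol)
  bursts$artificial <- art
  bursts
}

#' Fit a continuous power law by the Clauset MLE
#'
#' For each candidate lower cutoff `xmin`, the tail exponent is the
#' closed-form MLE `alpha = 1 + m / sum(log(x_i/xmin))`; the chosen `xmin`
#' minimises the Kolmogorov-Smirnov distance between the empirical tail and
#' the fitted power law. The goodness-of-fit p-value comes from
#' semi-parametric bootstrap replicates: each replicate resamples the body
#' and draws the tail from the fitted law, is refitted from scratch, and
#' contributes its KS distance; `p_boot` is the fraction of replicates with
#' KS at least the observed one.
#'
#' @param x Positive sample (e.g. inter-burst intervals in seconds).
#' @param n_boot Bootstrap replicates for the p-value (default 1000; Clauset
#'   recommends at least 1000 for 0.01 precision). `n_boot = 0` skips it.
#' @param n_candidates Cap on the number of distinct candidate xmins scanned
#'   (quantile-spaced; default 100).
#' @param min_tail Minimum tail size for a candidate xmin (default 10).
#' @return A `powerlaw_fit`: list with `alpha`, `xmin`, `ks`, `p_boot`,
#'   `n_tail`, `n`, `n_boot`.
#' @export
fit_powerlaw <- function(x, n_boot = 1000, n_candidates = 100,
                         min_tail = 10) {
  x <- as.numeric(x)
  if (any(x <= 0)) stop("power-law fit needs positive data")
  if (length(x) < min_tail)
    stop("fit refused: need at least ", min_tail, " values, got ", length(x))
  fit <- plfit_once(sort(x), n_candidates, min_tail)
  p_boot <- NA_real_
  if (n_boot > 0) {
    n <- length(x)
    body <- x[x < fit$xmin]
    p_tail <- fit$n_tail / n
    ks_boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      from_tail <- runif(n) < p_tail
      m <- sum(from_tail)
      smp <- numeric(n)
      if (m > 0)  # inverse-CDF draw from the fitted tail
        smp[from_tail] <- fit$xmin * runif(m)^(-1 / (fit$alpha - 1))
      if (m < n)
        smp[!from_tail] <- if (length(body))
          sample(body, n - m, replace = TRUE)
        else fit$xmin * runif(n - m)^(-1 / (fit$alpha - 1))
      ks_boot[b] <- plfit_once(sort(smp), n_candidates, min_tail)$ks
    }
    p_boot <- mean(ks_boot >= fit$ks)
  }
  structure(c(fit, list(p_boot = p_boot, n = length(x), n_boot = n_boot)),
            class = "powerlaw_fit")
}

# single Clauset scan on sorted data
plfit_once <- function(xs, n_candidates, min_tail) {
  n <- length(xs)
  ux <- unique(xs)
  first_idx <- match(ux, xs)          # xs sorted: first occurrence
  tail_n <- n - first_idx + 1L
  # candidates must leave a tail of at least min_tail (fall back to >= 2)
  keep <- tail_n >= max(2L, min_tail)
  if (!any(keep)) keep[1L] <- TRUE
  cand <- which(keep)
  if (length(cand) > n_candidates)
    cand <- cand[unique(round(seq(1, length(cand),
                                  length.out = n_candidates)))]
  logx <- log(xs)
  suf <- rev(cumsum(rev(logx)))       # suffix sums of log x
  best <- NULL
  for (ci in cand) {
    xm <- ux[ci]
    i0 <- first_idx[ci]
    m <- tail_n[ci]
    slog <- suf[i0] - m * log(xm)
    if (slog <= 0) next
    alpha <- 1 + m / slog
    tail <- xs[i0:n]
    Ftheo <- 1 - (tail / xm)^(1 - alpha)
    i <- seq_len(m)
    ks <- max(pmax(abs(i / m - Ftheo), abs((i - 1) / m - Ftheo)))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = xm, ks = ks, n_tail = m)
  }
  if (is.null(best)) stop("degenerate sample: no valid xmin candidate")
  best
}

#' Fit a power law to inter-burst intervals
#'
#' Intervals are peak-to-peak differences of consecutive spontaneous bursts
#' (artificial bursts excluded).
#'
#' @param bursts A `bursts` data frame (with `artificial` filled in).
#' @param ... Passed to [fit_powerlaw()].
#' @return A `powerlaw_fit`.
#' @export
fit_ibi_powerlaw <- function(bursts, ...) {
  sp <- bursts[!bursts$artificial, ]
  ibi <- diff(sort(sp$peak_t))
  if (length(ibi) < 10)
    stop("fit refused: need >= 10 inter-burst intervals, have ", length(ibi))
  fit <- fit_powerlaw(ibi, ...)
  fit$intervals <- ibi
  fit
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.3f, xmin = %.3g, KS = %.4f, n_tail = %d/%d\n",
    x$alpha, x$xmin, x$ks, x$n_tail, x$n))
  if (!is.na(x$p_boot))
    cat(sprintf("  bootstrap goodness-of-fit p = %.3f (%d replicates)\n",
                x$p_boot, x$n_boot))
  invisible(x)
}
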