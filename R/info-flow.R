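#' Discretize a real-valued series into equiprobable symbols
#'
#' Empirical-quantile binning into `q` symbols `0..q-1`. A value equal to a
#' bin edge is assigned to the lower bin, so heavily tied series (e.g.
#' count series with many zeros) keep all tied values in one symbol. A
#' constant series is flagged degenerate (single symbol; transfer entropy
#' downstream is 0).
#'
#' @param x Numeric vector.
#' @param q Alphabet size (default 3).
#' @return A `symbolic_series`: list with integer `symbols` (0-based), `q`,
#'   `edges`, and `degenerate` flag.
#' @export
discretize <- function(x, q = 3) {
  x <- as.numeric(x)
  if (length(x) < q) stop("series shorter than the alphabet size")
  edges <- quantile(x, probs = seq_len(q - 1) / q, names = FALSE, type = 7)
  sym <- rowSums(outer(x, edges, ">"))
  degenerate <- length(unique(sym)) < 2L
  structure(list(symbols = as.integer(sym), q = as.integer(q),
                 edges = edges, degenerate = degenerate),
            class = "symbolic_series")
}

sym_vec <- function(x) {
  if (inherits(x, "symbolic_series")) x$symbols
  else {
    v <- as.integer(x)
    if (any(v < 0)) stop("symbols must be nonnegative integers")
    v
  }
}

sym_q <- function(x) {
  if (inherits(x, "symbolic_series")) x$q else max(as.integer(x)) + 1L
}

# integer codes of length-k backward embeddings ending at each index
embed_codes <- function(v, k, q) {
  n <- length(v)
  code <- integer(n - k + 1L)
  for (j in 0:(k - 1L))
    code <- code + v[(k - j):(n - j)] * q^j
  code  # code[i] encodes v[(i) .. (i+k-1)] ending at index i+k-1
}

#' Plug-in transfer entropy between symbolic series
#'
#' Shannon transfer entropy from `source` to `target`,
#' `TE = sum p(x_{t+1}, x_t^(k), y_t^(l)) log2 p(x_{t+1} | x_t^(k), y_t^(l))
#' / p(x_{t+1} | x_t^(k))`, with x the target and y the source, estimated
#' by empirical frequencies (`0 log 0 := 0`), in bits.
#'
#' @param source,target `symbolic_series` (or bare nonnegative integer
#'   vectors) of equal length.
#' @param k Target (receiver) history length (default 1).
#' @param l Source history length (default 1).
#' @return Transfer entropy in bits (nonnegative).
#' @export
transfer_entropy <- function(source, target, k = 1, l = 1) {
  y <- sym_vec(source); x <- sym_vec(target)
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  h <- max(k, l)
  if (n < h + 1L) stop("series too short for the embedding")
  qx <- sym_q(target); qy <- sym_q(source)

  # histories ending at t = h .. n-1, future x_{t+1}
  xk <- embed_codes(x, k, qx)           # ends at index i+k-1
  yl <- embed_codes(y, l, qy)
  t_idx <- h:(n - 1L)                   # 1-based: predict x[t_idx + 1]
  b <- xk[t_idx - k + 1L]               # x_t^(k)
  cc <- yl[t_idx - l + 1L]              # y_t^(l)
  a <- x[t_idx + 1L]

  # joint counts via a single integer code
  nb <- qx^k; nc <- qy^l
  code <- a + qx * (b + nb * cc)
  n_abc <- tabulate(code + 1L, nbins = qx * nb * nc)
  n_ab <- tabulate(a + qx * b + 1L, nbins = qx * nb)
  n_bc <- tabulate(b + nb * cc + 1L, nbins = nb * nc)
  n_b <- tabulate(b + 1L, nbins = nb)

  idx <- which(n_abc > 0L)
  code0 <- idx - 1L
  a0 <- code0 %% qx
  rest <- code0 %/% qx
  b0 <- rest %% nb
  c0 <- rest %/% nb
  M <- length(a)
  p_abc <- n_abc[idx] / M
  ratio <- (n_abc[idx] * n_b[b0 + 1L]) /
           (n_bc[b0 + nb * c0 + 1L] * n_ab[a0 + qx * b0 + 1L])
  max(0, sum(p_abc * log2(ratio)))
}

#' Effective transfer entropy with shuffle correction
#'
#' The plug-in transfer entropy estimate is biased upward in finite
#' samples. ETE subtracts the mean TE over `n_shuffles` surrogates in which
#' the source series is fully time-permuted (destroying its auto- and
#' cross-structure while keeping its marginal distribution). The empirical
#' p-value uses the add-one permutation convention,
#' `p = (1 + #{shuffled >= observed}) / (1 + n_shuffles)`.
#'
#' @inheritParams transfer_entropy
#' @param n_shuffles Number of source permutations (default 300).
#' @param seed Optional integer seed for reproducible shuffles.
#' @return A `te_result`: list with `te`, `ete`, `shuffle_mean`,
#'   `shuffle_sd`, `p_emp`, `n_shuffles`, `k`, `l` (all entropies in bits),
#'   and `note` if `n_shuffles < 20`.
#' @export
effective_te <- function(source, target, k = 1, l = 1, n_shuffles = 300,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- sym_vec(source); x <- sym_vec(target)
  te <- transfer_entropy(y, x, k = k, l = l)
  sh <- vapply(seq_len(n_shuffles), function(i)
    transfer_entropy(sample(y), x, k = k, l = l), numeric(1))
  structure(list(te = te,
                 ete = te - mean(sh),
                 shuffle_mean = mean(sh),
                 shuffle_sd = sd(sh),
                 p_emp = (1 + sum(sh >= te)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, k = k, l = l,
                 note = if (n_shuffles < 20)
                   "n_shuffles < 20: shuffle correction is unreliable"),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf(
    "<te_result> TE = %.4f bits, ETE = %.4f bits (shuffle %.4f +- %.4f), p = %.4f\n",
    x$te, x$ete, x$shuffle_mean, x$shuffle_sd, x$p_emp))
  invisible(x)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
}

#' Net information-flow scan over K/D/O bin widths
#'
#' For each bin width, bins the hive activity (K), distinct-dancer count
#' (D) and out-of-hive count (O) series, discretizes each into `q`
#' equiprobable symbols, and computes the effective transfer entropy in
#' both directions for every ordered pair. The net flow
#' `ETE(X->Y) - ETE(Y->X)` localizes the timescale at which one series
#' drives another (e.g. dance activity leading hive activity).
#'
#' @param k A hive-level `kinetic_series`.
#' @param dances,trips Event tables as in [bin_kdo()].
#' @param bin_widths Bin widths in seconds (default
#'   `c(120, 300, 600, 1800, 3600)`, i.e. 2/5/10/30/60 min).
#' @param q Alphabet size for discretization (default 3).
#' @param n_shuffles Shuffles per ETE (default 300).
#' @param min_bins Widths yielding fewer bins are skipped with a message
#'   (default 50).
#' @param seed Optional seed.
#' @return Data frame `bin_width,pair,ete_xy,ete_yx,net,p_xy,p_yx,
#'   stars_xy,stars_yx`, one row per width and unordered pair, where `xy`
#'   is the direction named by `pair` ("D->K" etc.).
#' @export
kdo_scan <- function(k, dances, trips,
                     bin_widths = c(120, 300, 600, 1800, 3600), q = 3,
                     n_shuffles = 300, min_bins = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- list(c("D", "K"), c("K", "O"), c("D", "O"))
  rows <- list()
  for (bw in bin_widths) {
    kdo <- bin_kdo(k, dances, trips, bw)
    if (nrow(kdo) < min_bins) {
      message("kdo_scan: bin width ", bw, " leaves ", nrow(kdo),
              " bins (< ", min_bins, "), skipped")
      next
    }
    sym <- list(K = discretize(kdo$K, q), D = discretize(kdo$D, q),
                O = discretize(kdo$O, q))
    for (pr in pairs) {
      xy <- effective_te(sym[[pr[1]]], sym[[pr[2]]], n_shuffles = n_shuffles)
      yx <- effective_te(sym[[pr[2]]], sym[[pr[1]]], n_shuffles = n_shuffles)
      rows[[length(rows) + 1L]] <- data.frame(
        bin_width = bw, pair = paste0(pr[1], "->", pr[2]),
        ete_xy = xy$ete, ete_yx = yx$ete, net = xy$ete - yx$ete,
        p_xy = xy$p_emp, p_yx = yx$p_emp,
        stars_xy = signif_stars(xy$p_emp),
        stars_yx = signif_stars(yx$p_emp))
    }
  }
  if (!length(rows))
    return(data.frame(bin_width = numeric(0), pair = character(0),
                      ete_xy = numeric(0), ete_yx = numeric(0),
                      net = numeric(0), p_xy = numeric(0), p_yx = numeric(0),
                      stars_xy = character(0), stars_yx = character(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Group-level information flow (FP / NFP / NP)
#'
#' Computes the mean kinetic-energy series of each bee group (e.g. foraged
#' pioneers, non-foraged pioneers, non-pioneers), bins them, discretizes,
#' and reports pairwise effective transfer entropy in both directions.
#' Groups must be disjoint; empty groups cause their pairs to be skipped.
#'
#' @param table A `tracking_table`.
#' @param groups Named list of disjoint character vectors of bee ids.
#' @param bin_width Bin width in seconds.
#' @param q Alphabet size (default 3).
#' @param n_shuffles Shuffles per ETE (default 300).
#' @param seed Optional seed.
#' @return Data frame `from,to,te,ete,p_emp,stars`.
#' @export
group_flow <- function(table, groups, bin_width, q = 3, n_shuffles = 300,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids)) stop("groups must be disjoint")
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  span <- series_span(table)
  series <- lapply(groups, function(g)
    group_ke_binned(table, g, bin_width, span))
  sym <- lapply(series, discretize, q = q)
  rows <- list()
  nm <- names(groups)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    r <- effective_te(sym[[i]], sym[[j]], n_shuffles = n_shuffles)
    rows[[length(rows) + 1L]] <- data.frame(
      from = nm[i], to = nm[j], te = r$te, ete = r$ete, p_emp = r$p_emp,
      stars = signif_stars(r$p_emp))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# mean K over a bee group on a common time span, binned by mean;
# seconds where no group member is tracked contribute zero activity
group_ke_binned <- function(table, bees, bin_width, span) {
  sub <- table[table$bee_id %in% bees, c("bee_id", "t", "x", "y")]
  m <- length(span)
  tot <- numeric(m); cnt <- integer(m)
  for (s in split(sub[c("t", "x", "y")], sub$bee_id)) {
    kv <- ke_vector(s$t, s$x, s$y, span)
    ok <- !is.na(kv)
    tot[ok] <- tot[ok] + kv[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  K <- ifelse(cnt > 0L, tot / pmax(cnt, 1L), 0)
  n_bins <- floor(m / bin_width)
  grp <- rep(seq_len(n_bins), each = bin_width)
  as.numeric(tapply(K[seq_len(n_bins * bin_width)], grp, mean))
}
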