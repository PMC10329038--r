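#' Jaccard distances between bursts' pioneer sets
#'
#' `d(a, b) = 1 - |P_a & P_b| / |P_a | P_b|` over the columns of the
#' pioneer-bee binary matrix. Bursts with an empty pioneer set are excluded
#' (with a message); the Jaccard distance is a metric on the remaining
#' sets.
#'
#' @param PM Binary matrix, rows = bees, columns = bursts.
#' @return Symmetric matrix of distances in `[0, 1]` with zero diagonal and
#'   attribute `metric_name = "jaccard"`; columns excluded are recorded in
#'   attribute `excluded`.
#' @export
jaccard_distances <- function(PM) {
  sz <- colSums(PM != 0)
  empty <- sz == 0
  if (any(empty))
    message("jaccard_distances: excluding ", sum(empty),
            " burst(s) with empty pioneer sets")
  M <- (PM[, !empty, drop = FALSE] != 0) + 0
  if (ncol(M) < 2) stop("need at least 2 bursts with pioneers")
  inter <- crossprod(M)
  sz <- colSums(M)
  uni <- outer(sz, sz, "+") - inter
  D <- 1 - inter / uni
  diag(D) <- 0
  structure(D, metric_name = "jaccard",
            excluded = colnames(PM)[empty])
}

#' Non-metric MDS embedding of burst distances
#'
#' Kruskal non-metric multidimensional scaling (stress-1, monotone
#' regression, via `vegan::monoMDS`) into `dim` dimensions, restarted from
#' random configurations until the stress drops below `stress_target`
#' (default 0.2) or `max_restarts` is exhausted, in which case the
#' best-effort embedding is returned flagged as not converged.
#'
#' @param D Symmetric distance matrix (e.g. from [jaccard_distances()]).
#' @param dim Embedding dimension (default 2).
#' @param stress_target Acceptance threshold on the stress (default 0.2).
#' @param max_restarts Maximum random restarts (default 100).
#' @param seed Optional seed.
#' @return An `nmds_embedding`: list with `coords` (points x dim, rownames
#'   from D), `stress`, `converged`, `n_restarts_used`, `degenerate`.
#' @export
nmds_embed <- function(D, dim = 2, stress_target = 0.2, max_restarts = 100,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- as.dist(D)
  n <- attr(d, "Size")
  if (n < 4) stop("need at least 4 points for a meaningful embedding")
  degenerate <- max(d) - min(d) < .Machine$double.eps^0.5
  if (degenerate)
    message("nmds_embed: all distances (nearly) equal; embedding is degenerate")
  best <- NULL
  n_used <- 0L
  for (i in seq_len(max_restarts)) {
    n_used <- i
    fit <- if (i == 1L)
      vegan::monoMDS(d, k = dim, model = "global")
    else
      vegan::monoMDS(d, y = matrix(rnorm(n * dim), n, dim), k = dim,
                     model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
    if (best$stress < stress_target) break
  }
  coords <- best$points
  rownames(coords) <- labels(d)
  structure(list(coords = coords, stress = best$stress,
                 converged = best$stress < stress_target,
                 n_restarts_used = n_used, degenerate = degenerate),
            class = "nmds_embedding")
}

#' Dispersion of a subset of embedded bursts
#'
#' Mean squared Euclidean distance to the subset centroid (population
#' convention: equals the sum of per-coordinate population variances).
#'
#' @param embedding An `nmds_embedding` (or a coordinate matrix).
#' @param subset Indices or rownames of the points to include; default all.
#' @return Nonnegative scalar; 0 (with a message) for singletons.
#' @export
dispersion <- function(embedding, subset = NULL) {
  coords <- if (inherits(embedding, "nmds_embedding")) embedding$coords
            else as.matrix(embedding)
  if (!is.null(subset)) coords <- coords[subset, , drop = FALSE]
  if (nrow(coords) == 0L) stop("empty subset")
  if (nrow(coords) == 1L) {
    message("dispersion: singleton subset, dispersion is 0")
    return(0)
  }
  ctr <- colMeans(coords)
  mean(rowSums(sweep(coords, 2, ctr)^2))
}

#' Observed dispersion of a pioneer matrix subset
#'
#' Runs the full similarity pipeline (Jaccard distances, nMDS embedding,
#' subset dispersion) on a pioneer matrix. This is the same code path the
#' random-pioneer null uses, so observed and null values are directly
#' comparable.
#'
#' @param PM Pioneer-bee binary matrix.
#' @param subset Burst ids (column names of `PM`) or indices of the subset
#'   whose dispersion is measured (e.g. the last-two-days bursts).
#' @param seed Optional seed (the embedding has random restarts).
#' @param ... Passed to [nmds_embed()].
#' @return List with `dispersion`, `embedding`.
#' @export
pm_dispersion <- function(PM, subset, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(subset) && !is.null(colnames(PM)))
    subset <- colnames(PM)[subset]
  D <- jaccard_distances(PM)
  emb <- nmds_embed(D, ...)
  keep <- if (is.character(subset))
    intersect(subset, rownames(emb$coords)) else subset
  list(dispersion = dispersion(emb, keep), embedding = emb)
}

#' Random-pioneer null distribution of subset dispersion
#'
#' For each draw, every burst's pioneer set is replaced by a uniform draw
#' (without replacement) from the roster with the same cardinality, and the
#' full pipeline (Jaccard distances, fresh nMDS embedding, subset
#' dispersion) is recomputed. The observed dispersion can then be compared
#' against the resulting null distribution.
#'
#' @param PM Pioneer-bee binary matrix.
#' @param subset Burst ids (column names) of the subset.
#' @param n_draws Number of random draws (default 500).
#' @param seed Optional seed.
#' @param max_restarts Restarts per null embedding (default 10; random
#'   pioneer sets produce near-uniform Jaccard matrices whose best
#'   attainable stress often exceeds the observed data's, so restarting
#'   hundreds of times per draw buys little).
#' @param ... Further arguments to [nmds_embed()].
#' @return Numeric vector of `n_draws` null dispersions. Draws whose
#'   embedding missed the stress target are kept (dropping them would
#'   silently bias the null towards its most structured draws); their
#'   count is reported in the attribute `n_not_converged`.
#' @export
null_dispersion <- function(PM, subset, n_draws = 500, seed = NULL,
                            max_restarts = 10, ...) {
  if (!is.null(seed)) set.seed(seed)
  roster <- rownames(PM)
  sizes <- colSums(PM != 0)
  if (any(sizes > length(roster)))
    stop("pioneer count exceeds roster size")
  vals <- numeric(n_draws)
  n_bad <- 0L
  for (i in seq_len(n_draws)) {
    PMr <- PM
    PMr[] <- 0L
    for (j in seq_len(ncol(PM)))
      if (sizes[j] > 0)
        PMr[sample.int(length(roster), sizes[j]), j] <- 1L
    res <- suppressMessages(
      pm_dispersion(PMr, subset, max_restarts = max_restarts, ...))
    if (!res$embedding$converged) n_bad <- n_bad + 1L
    vals[i] <- res$dispersion
  }
  attr(vals, "n_not_converged") <- n_bad
  vals
}

#' Brunner-Munzel rank test
#'
#' Nonparametric two-sample test of the null `P(A < B) + 0.5 P(A = B) =
#' 0.5` that assumes neither normality nor equal variances. Returns the
#' studentized statistic, Satterthwaite-type degrees of freedom, the
#' two-sided p-value from the t distribution, and the stochastic
#' superiority estimate `p_hat = P(A < B) + 0.5 P(A = B)`.
#'
#' @param a,b Numeric samples (at least 5 each; a warning is given below
#'   10, where the t approximation is rough).
#' @return List with `statistic`, `df`, `p_value`, `p_hat`, `n_a`, `n_b`.
#' @export
brunner_munzel <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 5 || n2 < 5) stop("each sample needs at least 5 values")
  if (n1 < 10 || n2 < 10)
    warning("small samples: the t approximation may be rough")
  r <- rank(c(a, b))
  r1 <- rank(a); r2 <- rank(b)
  m1 <- mean(r[seq_len(n1)]); m2 <- mean(r[n1 + seq_len(n2)])
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled <= 0) {
    # both samples internally constant: either complete separation or
    # identical constants
    if (m1 == m2)
      return(list(statistic = 0, df = NA_real_, p_value = 1, p_hat = 0.5,
                  n_a = n1, n_b = n2))
    return(list(statistic = sign(m2 - m1) * Inf, df = NA_real_,
                p_value = 0, p_hat = p_hat, n_a = n1, n_b = n2))
  }
  stat <- n1 * n2 * (m2 - m1) / (n1 + n2) / sqrt(pooled)
  df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, p_hat = p_hat,
       n_a = n1, n_b = n2)
}

#' Early-vs-late dispersion comparison with a random-pioneer null
#'
#' Splits bursts into an early and a late subset by wall-clock day of their
#' peak, measures the dispersion of each subset in a common nMDS embedding,
#' and builds the random-pioneer null for the late subset. Shrinking late
#' dispersion relative to both the early bursts and the null indicates that
#' pioneer membership converges over time.
#'
#' @param PM Pioneer-bee binary matrix (columns named by burst id).
#' @param bursts The `bursts` data frame (for peak times).
#' @param meta A [trial_metadata()] (for the wall clock).
#' @param early_days,late_days Day windows counted from the trial start
#'   (defaults: first 5 days, last 2 days of the span).
#' @param n_draws Null draws (default 500).
#' @param seed Optional seed.
#' @param ... Passed to [nmds_embed()].
#' @return List with `var_early`, `var_late`, `null_vars`,
#'   `null_percentile` (of the observed late dispersion), `embedding`,
#'   `early_ids`, `late_ids`.
#' @export
dispersion_comparison <- function(PM, bursts, meta, early_days = 5,
                                  late_days = 2, n_draws = 500,
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  day <- floor(bursts$peak_t / 86400)
  last_day <- floor((meta$t_total - 1) / 86400)
  early_ids <- as.character(bursts$burst_id[day < early_days])
  late_ids <- as.character(bursts$burst_id[day > last_day - late_days])
  obs <- pm_dispersion(PM, late_ids, ...)
  ve <- dispersion(obs$embedding,
                   intersect(early_ids, rownames(obs$embedding$coords)))
  nulls <- null_dispersion(PM, late_ids, n_draws = n_draws, ...)
  list(var_early = ve, var_late = obs$dispersion, null_vars = nulls,
       null_percentile = mean(nulls <= obs$dispersion),
       embedding = obs$embedding,
       early_ids = early_ids, late_ids = late_ids)
}
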