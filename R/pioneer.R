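#' Per-bee activity matrix around a burst peak
#'
#' Builds the nonnegative matrix decomposed by NMF: rows are the seconds in
#' `peak_t +- half_width`, columns are all bees in the roster, entries are
#' raw individual kinetic energies (missing detections contribute 0).
#' Windows overlapping the trial edges are truncated and flagged. The
#' default half-width of 1000 s reflects about half the minimum inter-peak
#' spacing observed in week-long trials; for denser burst trains use the
#' same rule (half the minimum inter-peak interval) so neighbouring bursts
#' do not leak into each other's windows.
#'
#' @param table A `tracking_table`.
#' @param burst One row of a `bursts` data frame.
#' @param half_width Window half-width in seconds (default 1000).
#' @return A `burst_window`: list with matrix `A` (time x bees), `times`,
#'   `bees`, `burst_id`, `burst_start`, `peak_t`, `truncated`.
#' @export
extract_window <- function(table, burst, half_width = 1000) {
  if (is.na(burst$peak_t)) stop("burst has no defined peak")
  span <- series_span(table)
  lo <- max(burst$peak_t - half_width, min(span))
  hi <- min(burst$peak_t + half_width, max(span))
  truncated <- (lo > burst$peak_t - half_width) ||
               (hi < burst$peak_t + half_width)
  if (truncated)
    message("extract_window: window truncated to [", lo, ", ", hi,
            "] for burst ", burst$burst_id)
  times <- seq.int(lo, hi)
  bees <- bee_roster(table)
  A <- matrix(0, nrow = length(times), ncol = length(bees),
              dimnames = list(NULL, bees))
  sub <- table[table$t >= lo & table$t <= hi + 1L, ]
  for (bee in unique(sub$bee_id)) {
    s <- sub[sub$bee_id == bee, ]
    kv <- ke_vector(s$t, s$x, s$y, times)
    kv[is.na(kv)] <- 0
    A[, bee] <- kv
  }
  structure(list(A = A, times = times, bees = bees,
                 burst_id = burst$burst_id, burst_start = burst$start,
                 peak_t = burst$peak_t, truncated = truncated),
            class = "burst_window")
}

#' Nonnegative matrix factorization with Kullback-Leibler loss
#'
#' Factorizes a nonnegative matrix `A` (time x bees) as `G %*% B` with `G`
#' (time x r) holding basis time courses and `B` (r x bees) holding bee
#' memberships, by multiplicative updates minimising the generalized KL
#' divergence. Factors are initialised uniform-random positive; the best of
#' `n_restarts` runs (lowest final loss) is returned. Multiplicative
#' updates never increase the loss; the per-iteration loss trace is kept so
#' this can be verified.
#'
#' @param A Nonnegative matrix (or a `burst_window`).
#' @param r Rank, `r < min(dim(A))`.
#' @param n_iter Update iterations per restart (default 500; the loss has
#'   converged well before that on burst windows).
#' @param n_restarts Random restarts (default 50).
#' @param seed Optional integer seed.
#' @param track_loss Keep the full loss trace of each restart's winner
#'   (default TRUE).
#' @return An `nmf_result`: list with `G`, `B`, `r`, `kl_loss`,
#'   `loss_trace`, `n_iter`, `restart_index`.
#' @export
run_nmf <- function(A, r, n_iter = 500, n_restarts = 50, seed = NULL,
                    track_loss = TRUE) {
  if (inherits(A, "burst_window")) A <- A$A
  if (!is.matrix(A) || any(A < 0)) stop("A must be a nonnegative matrix")
  if (r >= min(dim(A))) stop("r must be smaller than both dimensions of A")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(A); n <- ncol(A)
  scale <- sqrt(mean(A) / r + 1e-12)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    W0 <- matrix(runif(m * r, min = 1e-4) * scale, m, r)
    H0 <- matrix(runif(r * n, min = 1e-4) * scale, r, n)
    fit <- .nmf_kl_cpp(A, W0, H0, as.integer(n_iter), 1e-12, track_loss)
    if (is.null(best) || fit$loss < best$loss) {
      best <- fit
      best$restart_index <- rs
    }
  }
  structure(list(G = best$W, B = best$H, r = as.integer(r),
                 kl_loss = best$loss, loss_trace = best$loss_trace,
                 n_iter = as.integer(n_iter),
                 restart_index = best$restart_index),
            class = "nmf_result")
}

#' Choose the NMF rank by the cophenetic criterion
#'
#' For each candidate rank, runs several factorizations from random starts,
#' records which bees share a dominant basis (connectivity), averages the
#' connectivity matrices into a consensus matrix, and computes the
#' cophenetic correlation between consensus distances and their
#' average-linkage dendrogram. Following Brunet's rule, the chosen rank is
#' the one preceding the first drop of the cophenetic coefficient; if the
#' coefficient never drops, the argmax is returned.
#'
#' @param A Nonnegative matrix (or `burst_window`).
#' @param r_range Candidate ranks (default `2:10`).
#' @param runs_per_rank Factorizations per rank (default 20; must be >= 2
#'   for the consensus to be defined).
#' @param n_iter Iterations per run (default 500).
#' @param tol Drops of the cophenetic coefficient smaller than `tol` are
#'   treated as a plateau, not a decrease (default 0.005). With finitely
#'   many runs per rank the consensus matrix is itself noisy; without a
#'   tolerance a sub-millesimal dip at the true rank truncates the search
#'   one rank too early.
#' @param seed Optional seed.
#' @return Chosen rank (integer) with attribute `cophenetic` (named vector
#'   of coefficients per candidate rank).
#' @export
select_rank <- function(A, r_range = 2:10, runs_per_rank = 20,
                        n_iter = 500, tol = 0.005, seed = NULL) {
  if (inherits(A, "burst_window")) A <- A$A
  if (runs_per_rank < 2) stop("runs_per_rank must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(A)
  if (qr(A)$rank < 2) {
    message("select_rank: matrix is numerically rank-deficient; returning ",
            min(r_range))
    out <- min(r_range)
    attr(out, "cophenetic") <- NULL
    return(out)
  }
  r_range <- r_range[r_range < min(dim(A))]
  coph <- numeric(length(r_range))
  names(coph) <- r_range
  for (ri in seq_along(r_range)) {
    r <- r_range[ri]
    consensus <- matrix(0, n, n)
    for (run in seq_len(runs_per_rank)) {
      fit <- run_nmf(A, r, n_iter = n_iter, n_restarts = 1,
                     track_loss = FALSE)
      dom <- dominant_basis(fit)
      consensus <- consensus + outer(dom, dom, "==")
    }
    consensus <- consensus / runs_per_rank
    d <- as.dist(1 - consensus)
    if (max(d) == 0) { coph[ri] <- 1; next }  # perfectly consistent
    hc <- hclust(d, method = "average")
    coph[ri] <- suppressWarnings(cor(d, cophenetic(hc)))
    if (is.na(coph[ri])) coph[ri] <- 1
  }
  drop_at <- which(diff(coph) < -tol)
  out <- if (length(drop_at)) r_range[drop_at[1L]]
         else r_range[which.max(coph)]
  attr(out, "cophenetic") <- coph
  out
}

#' Dominant basis index of each bee
#' @param nmf An `nmf_result`.
#' @return Integer vector over columns (bees): the basis with the largest
#'   membership weight.
#' @export
dominant_basis <- function(nmf) {
  apply(nmf$B, 2, which.max)
}

#' Classify the pioneer bees of a burst
#'
#' Pioneer bases are basis time courses whose maximum occurs strictly
#' before the burst period's onset (the level >= 1 start found by the
#' burst detector). Candidate pioneers are the bees whose dominant basis is
#' a pioneer basis; of these, bees whose reconstructed activity
#' (`G %*% B`, their column) never reaches the mean entry of the window
#' matrix are discarded (the amplitude filter removes near-idle bees
#' assigned to a pioneer basis by noise).
#'
#' @param nmf An `nmf_result` for the window.
#' @param window The `burst_window` the factorization was run on (supplies
#'   times, bee ids and the burst onset).
#' @param amplitude_ref `"matrix"` (default) compares each bee's
#'   reconstructed maximum against the mean over all entries of the window
#'   matrix; `"bee"` uses the bee's own column mean instead.
#' @param earliest_only If TRUE, only the earliest-peaking pre-onset basis
#'   contributes pioneers; by default all pre-onset bases do.
#' @return Character vector of pioneer bee ids (possibly empty).
#' @export
classify_pioneers <- function(nmf, window,
                              amplitude_ref = c("matrix", "bee"),
                              earliest_only = FALSE) {
  amplitude_ref <- match.arg(amplitude_ref)
  peaks <- window$times[apply(nmf$G, 2, which.max)]
  pioneer_bases <- which(peaks < window$burst_start)
  if (!length(pioneer_bases)) return(character(0))
  if (earliest_only)
    pioneer_bases <- pioneer_bases[which.min(peaks[pioneer_bases])]
  dom <- dominant_basis(nmf)
  cand <- which(dom %in% pioneer_bases)
  if (!length(cand)) return(character(0))
  recon <- nmf$G %*% nmf$B[, cand, drop = FALSE]
  thresh <- if (amplitude_ref == "matrix") mean(window$A)
            else colMeans(window$A[, cand, drop = FALSE])
  keep <- apply(recon, 2, max) >= thresh
  window$bees[cand[keep]]
}

#' Pioneer-bee binary incidence matrix
#'
#' @param pioneers Named list (by burst id) of pioneer bee-id vectors.
#' @param roster Character vector of all bee ids (rows).
#' @return Binary matrix, rows = bees, columns = bursts.
#' @export
build_pioneer_matrix <- function(pioneers, roster) {
  PM <- matrix(0L, nrow = length(roster), ncol = length(pioneers),
               dimnames = list(roster, names(pioneers)))
  for (j in seq_along(pioneers))
    PM[match(intersect(pioneers[[j]], roster), roster), j] <- 1L
  PM
}

#' Overlap between pioneers and behavioral roles
#'
#' Per burst: the fraction of pioneers holding each role
#' (`|X_b & P_b| / |P_b|`) and the same fraction among non-pioneers; per
#' trial: overlap of the trial-level sets (bees holding the role at least
#' once vs. bees pioneering at least once). When `dances`/`follows` are
#' supplied, per-bee event counts are returned for pioneer-ever vs.
#' never-pioneer bees (for frequency comparisons).
#'
#' @param pioneers Named list (by burst id) of pioneer sets.
#' @param roles Output of [label_burst_roles()].
#' @param roster All bee ids.
#' @param dances,follows Optional event tables for the frequency analysis.
#' @return List with `per_burst` (data frame), `per_trial` (list of overlap
#'   ratios and set sizes), and optionally `frequencies`.
#' @export
role_overlap <- function(pioneers, roles, roster, dances = NULL,
                         follows = NULL) {
  role_names <- c("F", "W", "DF")
  per_burst <- list()
  for (b in names(pioneers)) {
    P <- pioneers[[b]]
    NP <- setdiff(roster, P)
    for (rn in role_names) {
      X <- role_set(roles, as_burst_id(b), rn)
      per_burst[[length(per_burst) + 1L]] <- data.frame(
        burst_id = b, role = rn,
        frac_pioneer = if (length(P)) length(intersect(X, P)) / length(P)
                       else NA_real_,
        frac_nonpioneer = if (length(NP))
          length(intersect(X, NP)) / length(NP) else NA_real_)
    }
  }
  per_burst <- if (length(per_burst)) do.call(rbind, per_burst)
               else data.frame(burst_id = character(0), role = character(0),
                               frac_pioneer = numeric(0),
                               frac_nonpioneer = numeric(0))

  P_trial <- unique(unlist(pioneers, use.names = FALSE))
  per_trial <- list(P_trial = P_trial)
  for (rn in role_names) {
    X_trial <- unique(roles$bee_id[roles$role == rn])
    per_trial[[paste0(rn, "_trial")]] <- X_trial
    per_trial[[paste0(rn, "_overlap")]] <-
      if (length(X_trial)) length(intersect(X_trial, P_trial)) /
                           length(X_trial) else NA_real_
  }

  out <- list(per_burst = per_burst, per_trial = per_trial)
  if (!is.null(dances) || !is.null(follows)) {
    NP_trial <- setdiff(roster, P_trial)
    count_by <- function(events, col) {
      if (is.null(events) || nrow(events) == 0L)
        return(setNames(rep(0, length(roster)), roster))
      tab <- table(factor(events[[col]], levels = roster))
      setNames(as.numeric(tab), roster)
    }
    out$frequencies <- list(
      dance = list(pioneer = count_by(dances, "bee_id")[P_trial],
                   nonpioneer = count_by(dances, "bee_id")[NP_trial]),
      follow = list(pioneer = count_by(follows, "follower_id")[P_trial],
                    nonpioneer = count_by(follows, "follower_id")[NP_trial]))
  }
  out
}

as_burst_id <- function(b) {
  v <- suppressWarnings(as.integer(b))
  if (is.na(v)) b else v
}
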