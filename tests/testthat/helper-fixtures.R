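# Small in-code fixtures shared across test files.

tiny_meta <- function(t_total = 100, entrance_open_t = NULL, ...) {
  if (is.null(entrance_open_t))
    entrance_open_t <- min(10, t_total / 2)
  trial_metadata(trial_id = "test", entrance_open_t = entrance_open_t,
                 t_total = t_total, ...)
}

# one bee walking a given path; headings unit-normalized from angles
bee_path <- function(bee_id, t, x, y, angle = rep(0, length(t))) {
  data.frame(bee_id = bee_id, t = t, x = x, y = y,
             nx = cos(angle), ny = sin(angle))
}

# a stationary crowd of n bees at distinct spots, seconds 0..(t_total-1)
crowd_table <- function(n = 3, t_total = 20, meta = NULL) {
  if (is.null(meta)) meta <- tiny_meta(t_total)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    bee_path(sprintf("B%03d", i), 0:(t_total - 1),
             x = rep(100 * i, t_total), y = rep(200, t_total))))
  tracking_table(df, meta)
}

# kinetic series from a bare numeric vector
as_kseries <- function(K, t0 = 0) {
  structure(data.frame(t = t0 + seq_along(K) - 1, K = K),
            bee_id = "GLOBAL", kind = "detrended", bin_width = 1,
            class = c("kinetic_series", "data.frame"))
}

# planted 3-group nonnegative matrix: disjoint bee blocks active in
# disjoint time bumps, plus small positive noise
planted_three_groups <- function(m = 90, n = 60, noise = 0.05) {
  G0 <- matrix(0, m, 3)
  G0[1:30, 1] <- dnorm(1:30, 15, 5)
  G0[31:60, 2] <- dnorm(1:30, 15, 5)
  G0[61:90, 3] <- dnorm(1:30, 15, 5)
  B0 <- matrix(0, 3, n)
  B0[1, 1:20] <- 1; B0[2, 21:40] <- 1; B0[3, 41:60] <- 1
  A <- G0 %*% B0 * 50 + matrix(runif(m * n, 0, noise), m, n)
  list(A = A, G0 = G0, B0 = B0,
       groups = rep(1:3, each = 20))
}

# random pioneer matrix: n_bursts columns, each a random set of size k
random_pm <- function(n_bees = 100, n_bursts = 30, k = 15) {
  roster <- sprintf("B%03d", seq_len(n_bees))
  sets <- lapply(seq_len(n_bursts), function(j)
    sample(roster, k))
  names(sets) <- as.character(seq_len(n_bursts))
  build_pioneer_matrix(sets, roster)
}

# pioneer matrix whose late bursts share members drawn from a small pool
converging_pm <- function(n_bees = 100, n_early = 22, n_late = 8,
                          k = 15, pool = 20) {
  roster <- sprintf("B%03d", seq_len(n_bees))
  sets <- c(
    lapply(seq_len(n_early), function(j) sample(roster, k)),
    lapply(seq_len(n_late), function(j) sample(roster[seq_len(pool)], k)))
  names(sets) <- as.character(seq_along(sets))
  build_pioneer_matrix(sets, roster)
}

# pioneer matrix with temporal drift: each burst replaces a few members of
# the previous burst's set, so nearby bursts are similar and distant ones
# diverge (the gradient structure an embedding can capture)
drifting_pm <- function(n_bees = 80, n_bursts = 25, k = 12,
                        n_replace = 3) {
  roster <- sprintf("B%03d", seq_len(n_bees))
  sets <- vector("list", n_bursts)
  sets[[1]] <- sample(roster, k)
  for (j in 2:n_bursts) {
    keep <- sample(sets[[j - 1]], k - n_replace)
    sets[[j]] <- c(keep, sample(setdiff(roster, keep), n_replace))
  }
  names(sets) <- as.character(seq_len(n_bursts))
  build_pioneer_matrix(sets, roster)
}
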