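test_that("burst windows have the right shape and flag truncation", {
  meta <- tiny_meta(t_total = 1000)
  df <- do.call(rbind, lapply(1:3, function(i)
    bee_path(sprintf("B%d", i), 0:999, x = runif(1000, 0, 100),
             y = runif(1000, 0, 100))))
  tb <- tracking_table(df, meta)
  burst <- data.frame(burst_id = 1L, start = 480, end = 520, peak_t = 500,
                      peak_value = 1)
  win <- extract_window(tb, burst, half_width = 100)
  expect_equal(dim(win$A), c(201L, 3L))
  expect_equal(win$times, 400:600)
  expect_false(win$truncated)
  expect_true(all(win$A >= 0))

  expect_message(
    wt <- extract_window(tb, transform(burst, peak_t = 50),
                         half_width = 100),
    "truncated")
  expect_true(wt$truncated)
  expect_equal(nrow(wt$A), 151L)
})

test_that("a bee absent from the whole window keeps a zero column", {
  meta <- tiny_meta(t_total = 400)
  df <- rbind(
    bee_path("A", 0:399, x = runif(400, 0, 50), y = runif(400, 0, 50)),
    bee_path("Z", 0:49, x = rep(1, 50), y = rep(1, 50)))  # gone after t=49
  tb <- tracking_table(df, meta)
  burst <- data.frame(burst_id = 1L, start = 290, end = 310, peak_t = 300,
                      peak_value = 1)
  win <- extract_window(tb, burst, half_width = 50)
  expect_true(all(win$A[, "Z"] == 0))
})

test_that("KL multiplicative updates never increase the loss", {
  set.seed(21)
  A <- matrix(runif(40 * 25), 40, 25)
  fit <- run_nmf(A, r = 3, n_iter = 500, n_restarts = 1, seed = 1)
  expect_true(all(diff(fit$loss_trace) <= 1e-8))
  expect_true(all(fit$G >= 0) && all(fit$B >= 0))
})

test_that("a planted rank-1 matrix is reconstructed almost exactly", {
  set.seed(22)
  g <- runif(50, 0.5, 2); b <- runif(30, 0.5, 2)
  A <- outer(g, b)
  fit <- run_nmf(A, r = 1, n_iter = 400, n_restarts = 3, seed = 2)
  rel_err <- norm(A - fit$G %*% fit$B, "F") / norm(A, "F")
  expect_lt(rel_err, 1e-3)
})

test_that("the same seed reproduces the same factorization", {
  set.seed(23)
  A <- matrix(runif(30 * 20), 30, 20)
  f1 <- run_nmf(A, r = 2, n_iter = 50, n_restarts = 2, seed = 7)
  f2 <- run_nmf(A, r = 2, n_iter = 50, n_restarts = 2, seed = 7)
  expect_identical(f1, f2)
  expect_error(run_nmf(A, r = 25), "smaller")
})

test_that("rank selection recovers a planted 3-group structure", {
  set.seed(24)
  ok <- 0L
  for (rep in 1:3) {
    pl <- planted_three_groups()
    r <- select_rank(pl$A, r_range = 2:5, runs_per_rank = 8, n_iter = 150)
    if (r == 3L) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})

test_that("rank selection guards its preconditions", {
  A <- matrix(runif(100), 20, 5)
  expect_error(select_rank(A, runs_per_rank = 1), "at least 2")
  degen <- outer(rep(1, 20), rep(1, 8))
  expect_message(r <- select_rank(degen, r_range = 2:4, runs_per_rank = 2,
                                  n_iter = 20),
                 "rank-deficient")
  expect_equal(as.integer(r), 2L)
})

test_that("pioneers are the pre-onset bases, amplitude-filtered", {
  # hand-built window: pioneer group active before onset, main group after
  set.seed(25)
  m <- 120; onset_row <- 61
  times <- 0:(m - 1)
  bees <- sprintf("B%02d", 1:30)
  A <- matrix(0.01, m, 30, dimnames = list(NULL, bees))
  A[41:70, 1:8] <- 5 + runif(30 * 8)        # pioneers: peak before onset
  A[61:110, 9:25] <- 6 + runif(50 * 17)     # main group: after onset
  win <- structure(list(A = A, times = times, bees = bees, burst_id = 1L,
                        burst_start = times[onset_row], peak_t = 80,
                        truncated = FALSE), class = "burst_window")
  fit <- run_nmf(A, r = 2, n_iter = 300, n_restarts = 5, seed = 3)
  P <- classify_pioneers(fit, win)
  expect_setequal(P, bees[1:8])

  # bees 26:30 are near-silent: whatever basis they land on, the
  # amplitude filter must keep them out
  expect_length(intersect(P, bees[26:30]), 0)
})

test_that("no pre-onset basis peak means no pioneers", {
  set.seed(26)
  m <- 100
  bees <- sprintf("B%02d", 1:20)
  A <- matrix(0.01, m, 20, dimnames = list(NULL, bees))
  A[61:90, 1:10] <- 4; A[71:100, 11:20] <- 5
  win <- structure(list(A = A, times = 0:(m - 1), bees = bees,
                        burst_id = 1L, burst_start = 50, peak_t = 80,
                        truncated = FALSE), class = "burst_window")
  fit <- run_nmf(A, r = 2, n_iter = 200, n_restarts = 3, seed = 4)
  expect_length(classify_pioneers(fit, win), 0)
})

test_that("pioneer classification is invariant to bee column permutation", {
  set.seed(27)
  m <- 120
  bees <- sprintf("B%02d", 1:25)
  A <- matrix(0.01, m, 25, dimnames = list(NULL, bees))
  A[31:60, 1:6] <- 5 + runif(30 * 6)
  A[61:110, 7:20] <- 6 + runif(50 * 14)
  mkwin <- function(A, bees) structure(
    list(A = A, times = 0:(m - 1), bees = bees, burst_id = 1L,
         burst_start = 60, peak_t = 80, truncated = FALSE),
    class = "burst_window")
  p1 <- classify_pioneers(run_nmf(A, 2, n_iter = 300, n_restarts = 5,
                                  seed = 5), mkwin(A, bees))
  perm <- sample(25)
  Ap <- A[, perm]
  p2 <- classify_pioneers(run_nmf(Ap, 2, n_iter = 300, n_restarts = 5,
                                  seed = 6), mkwin(Ap, bees[perm]))
  expect_setequal(p1, p2)
})

test_that("the pioneer matrix is the binary incidence of the sets", {
  roster <- c("a", "b", "c", "d")
  PM <- build_pioneer_matrix(list(`1` = c("a", "b"), `2` = c("c", "d")),
                             roster)
  expect_equal(colSums(PM), c(`1` = 2, `2` = 2))
  expect_true(all(rowSums(PM) <= 1))

  PM2 <- build_pioneer_matrix(list(`1` = c("a", "b"), `2` = c("b", "c")),
                              roster)
  expect_equal(rowSums(PM2)[["b"]], 2)

  PM3 <- build_pioneer_matrix(list(`1` = c("a"), `2` = character(0)),
                              roster)
  expect_equal(unname(colSums(PM3)), c(1, 0))
})

test_that("role overlap ratios behave at the extremes", {
  roster <- sprintf("B%d", 1:10)
  roles <- data.frame(burst_id = 1L, role = "F", bee_id = roster[1:3])
  ov1 <- role_overlap(list(`1` = roster[1:3]), roles, roster)
  pb <- ov1$per_burst
  expect_equal(pb$frac_pioneer[pb$role == "F"], 1.0)
  ov2 <- role_overlap(list(`1` = roster[4:6]), roles, roster)
  expect_equal(ov2$per_burst$frac_pioneer[pb$role == "F"], 0.0)
  expect_equal(ov1$per_trial$F_overlap, 1.0)
})
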