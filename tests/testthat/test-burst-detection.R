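test_that("inverse-rate conversion maps activity to pseudo-event gaps", {
  g1 <- rate_to_gaps(as_kseries(rep(1, 100)))
  expect_equal(g1$gaps, rep(1, 100))   # activity 1 -> one event per second
  expect_equal(g1$lambda_bar, 1)

  g10 <- rate_to_gaps(as_kseries(c(rep(1, 99), 10)))
  expect_equal(g10$gaps[100], 0.1)     # activity 10 -> events every 0.1 s

  gc <- rate_to_gaps(as_kseries(rep(2.5, 50)))
  expect_equal(gc$lambda_bar, 2.5)
  expect_equal(gc$N, 125)

  expect_error(rate_to_gaps(as_kseries(c(1, -1, 1))), "positive")
})

test_that("constant-rate series stays at burst level zero", {
  lv <- kleinberg_levels(rate_to_gaps(as_kseries(rep(3, 200))))
  expect_equal(lv$bl, rep(0L, 200))
  expect_equal(nrow(extract_bursts(lv, as_kseries(rep(3, 200)))), 0L)
})

test_that("parameter contracts are enforced", {
  g <- rate_to_gaps(as_kseries(rep(1, 10)))
  expect_error(kleinberg_levels(g, s = 1), "s must")
  expect_error(kleinberg_levels(g, gamma = -0.5), "gamma")
})

test_that("the DP matches exhaustive minimization on small instances", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    x <- rexp(n, rate = sample(c(0.5, 1, 2), 1)) + 0.01
    lb <- 1 / mean(x)
    gs <- structure(list(gaps = x, lambda_bar = lb,
                         times = seq_len(n) - 1, N = n, T = sum(x)),
                    class = "gap_series")
    dp <- kleinberg_levels(gs, s = 2, gamma = 1, max_level = 3)
    or <- oracle_kleinberg(x, lb, 2, 1, 3)
    expect_equal(dp$bl, or$bl)
    expect_equal(dp$cost, or$cost, tolerance = 1e-9)
  }
})

test_that("a sustained rate doubling is flagged at level >= 1 throughout most of it", {
  K <- rep(1, 3000)
  K[1000:1599] <- 2
  lv <- kleinberg_levels(rate_to_gaps(as_kseries(K)))
  expect_gt(mean(lv$bl[1000:1599] >= 1), 0.9)
  expect_equal(sum(lv$bl[1:900] >= 1), 0L)
})

test_that("the optimal level sequence is invariant to rescaling time", {
  set.seed(13)
  x <- rexp(80) + 0.05
  lb <- 1 / mean(x)
  mk <- function(x, lb) structure(
    list(gaps = x, lambda_bar = lb, times = seq_along(x) - 1,
         N = length(x), T = sum(x)), class = "gap_series")
  for (c_scale in c(0.1, 7)) {
    a <- kleinberg_levels(mk(x, lb), max_level = 4)
    b <- kleinberg_levels(mk(c_scale * x, lb / c_scale), max_level = 4)
    expect_equal(a$bl, b$bl)
  }
})

test_that("raising gamma never increases the time spent at level >= 1", {
  set.seed(17)
  K <- exp(rnorm(600, 0, 0.5))
  K[200:280] <- K[200:280] * 3
  g <- rate_to_gaps(as_kseries(K))
  burst_time <- vapply(c(0, 0.5, 1, 2, 4), function(gam)
    sum(kleinberg_levels(g, gamma = gam)$bl >= 1), numeric(1))
  expect_true(all(diff(burst_time) <= 0))
})

test_that("burst extraction finds maximal runs with earliest-tie peaks", {
  K <- rep(1, 500)
  K[100:200] <- 4
  K[150] <- 9; K[160] <- 9  # tie: earliest wins
  s <- as_kseries(K)
  lv <- kleinberg_levels(rate_to_gaps(s))
  b <- extract_bursts(lv, s)
  expect_equal(nrow(b), 1L)
  expect_lte(b$start, 100)
  expect_gte(b$end, 199)
  expect_equal(b$peak_t, 149)  # t starts at 0
  expect_equal(b$peak_value, 9)
  # burst periods disjoint and sorted by construction
  expect_error(extract_bursts(lv, as_kseries(rep(1, 10))), "aligned")
})

test_that("bursts intersecting recorded disturbances are flagged artificial", {
  b <- structure(data.frame(burst_id = 1:2, start = c(100, 1000),
                            end = c(200, 1100), peak_t = c(150, 1050),
                            peak_value = c(5, 5),
                            artificial = FALSE),
                 class = c("bursts", "data.frame"))
  no_clean <- tiny_meta(t_total = 5000)
  expect_false(any(mark_artificial(b, no_clean)$artificial))

  m1 <- trial_metadata(trial_id = "t", entrance_open_t = 10,
                       cleaning_times = 150, t_total = 5000)
  expect_equal(mark_artificial(b, m1, tol = 0)$artificial, c(TRUE, FALSE))

  # burst ending 1 s before cleaning, tol = 0 -> spontaneous
  m2 <- trial_metadata(trial_id = "t", entrance_open_t = 10,
                       cleaning_times = 201, t_total = 5000)
  expect_equal(mark_artificial(b, m2, tol = 0)$artificial, c(FALSE, FALSE))
})

test_that("the Clauset fit recovers a planted exponent", {
  set.seed(23)
  xs <- runif(2000)^(-1 / 1.5)  # Pareto(alpha = 2.5, xmin = 1)
  f <- fit_powerlaw(xs, n_boot = 0)
  expect_gt(f$alpha, 2.35)
  expect_lt(f$alpha, 2.65)
  expect_lt(f$xmin, 1.5)
})

test_that("the closed-form exponent equals numerical likelihood maximization", {
  set.seed(29)
  xs <- 2 * runif(500)^(-1 / 1.2)
  f <- fit_powerlaw(xs, n_boot = 0)
  tail <- xs[xs >= f$xmin]
  nll <- function(al) -sum(log(al - 1) - log(f$xmin) -
                             al * log(tail / f$xmin))
  num <- optimize(nll, c(1.001, 10), tol = 1e-10)$minimum
  expect_equal(f$alpha, num, tolerance = 1e-6)
})

test_that("exponential data is rejected by the bootstrap goodness-of-fit", {
  set.seed(31)
  xs <- rexp(2000, 1) + 1
  f <- fit_powerlaw(xs, n_boot = 100)
  expect_lt(f$p_boot, 0.1)
})

test_that("inter-burst-interval fitting excludes artificial bursts and needs >= 10 gaps", {
  set.seed(37)
  n <- 40
  peaks <- cumsum(c(100, runif(n - 1)^(-1 / 1.5) * 50))
  b <- structure(data.frame(burst_id = seq_len(n), start = peaks - 5,
                            end = peaks + 5, peak_t = peaks,
                            peak_value = 1,
                            artificial = rep(c(FALSE, TRUE), c(n - 5, 5))),
                 class = c("bursts", "data.frame"))
  f <- fit_ibi_powerlaw(b, n_boot = 0)
  expect_equal(length(f$intervals), n - 5 - 1)
  expect_true(all(f$intervals > 0))

  few <- b[1:5, ]
  expect_error(fit_ibi_powerlaw(few), "refused")
})
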