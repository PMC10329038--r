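# a bee that turns by `turns[i]` radians between second i and i+1
turning_bee <- function(bee_id, turns, t0 = 0, x = 500, y = 500) {
  ang <- cumsum(c(0, turns))
  bee_path(bee_id, t0 + seq_along(ang) - 1, x = rep(x, length(ang)),
           y = rep(y, length(ang)), angle = ang)
}

test_that("alternating near-reversals are detected as a dance", {
  meta <- tiny_meta(t_total = 50)
  d170 <- 170 * pi / 180
  tb <- tracking_table(turning_bee("A", rep(c(d170, -d170), 4)), meta)
  ev <- detect_dances(tb)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$bee_id, "A")
  expect_gte(ev$end - ev$start + 1, 5)  # a dance spans >= 5 s
})

test_that("smooth rotation and same-sign spinning are not dances", {
  meta <- tiny_meta(t_total = 50)
  # smooth 30 deg/s rotation: dot products positive
  smooth <- tracking_table(turning_bee("A", rep(pi / 6, 10)), meta)
  expect_equal(nrow(detect_dances(smooth)), 0L)
  # +170 deg every second: all dots negative but every turn is a left
  # turn, so the alternation condition fails
  spin <- tracking_table(turning_bee("A", rep(170 * pi / 180, 10)), meta)
  expect_equal(nrow(detect_dances(spin)), 0L)
})

test_that("collinear headings (zero cross product) break the alternation", {
  meta <- tiny_meta(t_total = 50)
  # exact reversals: dot = -1 but cross = 0
  rev_only <- tracking_table(turning_bee("A", rep(c(pi, -pi), 4)), meta)
  expect_equal(nrow(detect_dances(rev_only)), 0L)
})

test_that("overlapping dance windows merge into one event", {
  meta <- tiny_meta(t_total = 50)
  d170 <- 170 * pi / 180
  tb <- tracking_table(turning_bee("A", rep(c(d170, -d170), 10)), meta)
  ev <- detect_dances(tb)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 0)
  expect_equal(ev$end, 20)
})

test_that("followers must be close, facing, and persistent", {
  meta <- tiny_meta(t_total = 50)
  d170 <- 170 * pi / 180
  dancer <- turning_bee("D", rep(c(d170, -d170), 5), x = 1000, y = 1000)
  near_facing <- bee_path("F1", 0:10, x = rep(1300, 11), y = rep(1000, 11),
                          angle = rep(pi, 11))       # 300 px, facing dancer
  near_away <- bee_path("F2", 0:10, x = rep(1300, 11), y = rep(1000, 11),
                        angle = rep(0, 11))          # facing away
  far_facing <- bee_path("F3", 0:10, x = rep(1701, 11), y = rep(1000, 11),
                         angle = rep(pi, 11))        # 701 px away
  tb <- tracking_table(rbind(dancer, near_facing, near_away, far_facing),
                       meta)
  dances <- detect_dances(tb)
  expect_equal(dances$bee_id, "D")
  f <- detect_followers(tb, dances)
  expect_equal(unique(f$follower_id), "F1")
  expect_equal(f$start, dances$start)
  expect_equal(f$end, dances$end)
})

test_that("every follow event lies inside its dancer's dance", {
  set.seed(3)
  sim <- simulate_hive(preset_config("dance_demo", n_bees = 50,
                                     duration = 2000, seed = 3))
  dances <- detect_dances(sim$table)
  follows <- detect_followers(sim$table, dances)
  for (i in seq_len(nrow(follows))) {
    host <- dances[dances$bee_id == follows$dancer_id[i] &
                     dances$start <= follows$start[i] &
                     dances$end >= follows$end[i], ]
    expect_gte(nrow(host), 1)
  }
})

test_that("follower detection is invariant to rigid motions of the arena", {
  meta <- trial_metadata(trial_id = "t", entrance_open_t = 10,
                         arena_width = 1e7, arena_height = 1e7,
                         t_total = 50)
  d170 <- 170 * pi / 180
  dancer <- turning_bee("D", rep(c(d170, -d170), 5), x = 5000, y = 5000)
  fol <- bee_path("F", 0:10, x = rep(5300, 11), y = rep(5000, 11),
                  angle = rep(pi, 11))
  tb1 <- tracking_table(rbind(dancer, fol), meta)
  phi <- 0.7; shift <- c(2000, 3000)
  rot <- function(df) {
    xr <- cos(phi) * df$x - sin(phi) * df$y + shift[1]
    yr <- sin(phi) * df$x + cos(phi) * df$y + shift[2]
    nxr <- cos(phi) * df$nx - sin(phi) * df$ny
    nyr <- sin(phi) * df$nx + cos(phi) * df$ny
    data.frame(bee_id = df$bee_id, t = df$t, x = xr, y = yr,
               nx = nxr, ny = nyr)
  }
  tb2 <- tracking_table(rot(rbind(dancer, fol)), meta)
  f1 <- detect_followers(tb1, detect_dances(tb1))
  f2 <- detect_followers(tb2, detect_dances(tb2))
  expect_equal(f1, f2)
})

test_that("trips are long absences beginning after the entrance opened", {
  meta <- tiny_meta(t_total = 1200, entrance_open_t = 600)
  # absent 100..500 (before opening), present otherwise
  ts_a <- c(0:99, 501:1199)
  a <- bee_path("A", ts_a, x = rep(1, length(ts_a)),
                y = rep(1, length(ts_a)))
  # absent 700..819 (120 s, after opening)
  ts_b <- c(0:699, 820:1199)
  b <- bee_path("B", ts_b, x = rep(2, length(ts_b)),
                y = rep(2, length(ts_b)))
  # absent 900..929 (30 s < min_gap)
  ts_c <- c(0:899, 930:1199)
  cc <- bee_path("C", ts_c, x = rep(3, length(ts_c)),
                 y = rep(3, length(ts_c)))
  tb <- tracking_table(rbind(a, b, cc), meta)
  tr <- detect_trips(tb, meta, min_gap = 60)
  expect_equal(tr$bee_id, "B")
  expect_equal(tr$exit_t, 699)
  expect_equal(tr$entry_t, 820)
})

test_that("the first foraging day needs six trips with enough before noon", {
  meta <- trial_metadata(trial_id = "t",
                         start_datetime = as.POSIXct("2012-07-04 00:00:00",
                                                     tz = "UTC"),
                         entrance_open_t = 3600, t_total = 10 * 86400)
  mk_trips <- function(hours, day = 0) {
    ex <- day * 86400 + hours * 3600
    data.frame(bee_id = "A", exit_t = ex, entry_t = ex + 600,
               is_orientation = NA)
  }
  # 6 trips, 2 before noon (33% > 25%) -> qualifies
  q <- mk_trips(c(8, 10, 13, 14, 15, 16))
  expect_equal(first_foraging_day(q, meta), as.Date("2012-07-04"))
  # 6 trips, only 1 before noon (16.7%) -> does not qualify
  nq <- mk_trips(c(10, 13, 14, 15, 16, 17))
  expect_true(is.na(first_foraging_day(nq, meta)))
  # never more than 5 trips a day -> none; all trips orientation
  few <- mk_trips(c(8, 9, 10, 11, 12))
  expect_true(is.na(first_foraging_day(few, meta)))
  ann <- annotate_orientation(few, meta)
  expect_true(all(ann$is_orientation))
})

test_that("adding morning trips never delays the first foraging day", {
  # note the rule is NOT monotone under arbitrary additions: extra
  # afternoon trips can dilute a day's before-noon fraction below the
  # threshold; only before-noon additions are guaranteed to help
  meta <- trial_metadata(trial_id = "t",
                         start_datetime = as.POSIXct("2012-07-04 00:00:00",
                                                     tz = "UTC"),
                         entrance_open_t = 3600, t_total = 10 * 86400)
  set.seed(19)
  informative <- 0L
  for (rep in 1:20) {
    ex <- sort(sample(0:(3 * 86400), 20))
    tr <- data.frame(bee_id = "A", exit_t = ex, entry_t = ex + 300,
                     is_orientation = NA)
    d_base <- first_foraging_day(tr, meta)
    # add morning trips (08:00-11:00) on random days
    add_day <- sample(0:2, 4, replace = TRUE)
    add_ex <- add_day * 86400 + sample(8:10, 4, TRUE) * 3600
    tr2 <- rbind(tr, data.frame(bee_id = "A", exit_t = add_ex,
                                entry_t = add_ex + 300,
                                is_orientation = NA))
    d_more <- first_foraging_day(tr2, meta)
    if (!is.na(d_base)) {
      informative <- informative + 1L
      expect_true(!is.na(d_more) && d_more <= d_base)
    }
  }
  expect_gt(informative, 0L)
})

test_that("the six-flight rule is available as an alternative", {
  meta <- tiny_meta(t_total = 86400)
  ex <- seq(1000, 8000, by = 1000)
  tr <- data.frame(bee_id = "A", exit_t = ex, entry_t = ex + 100,
                   is_orientation = NA)
  expect_false(is.na(first_foraging_day(tr, meta, method = "first_six")))
  expect_true(is.na(first_foraging_day(tr[1:6, ], meta,
                                       method = "first_six")))
})

test_that("burst roles use the prescribed pre-peak windows", {
  bursts <- structure(data.frame(burst_id = 1L, start = 4900, end = 5200,
                                 peak_t = 5000, peak_value = 10,
                                 artificial = FALSE),
                      class = c("bursts", "data.frame"))
  trips <- data.frame(
    bee_id = c("in_window", "too_late", "orient"),
    exit_t = c(3000, 4500, 3000),
    entry_t = c(4300, 4700, 4300),     # peak-700, peak-300, peak-700
    is_orientation = c(FALSE, FALSE, TRUE))
  dances <- data.frame(bee_id = "W1", start = 4100, end = 4150)
  follows <- data.frame(follower_id = "DF1", dancer_id = "W1",
                        start = 4100, end = 4140)
  roles <- label_burst_roles(bursts, trips, dances, follows)
  expect_equal(role_set(roles, 1L, "F"), "in_window")
  expect_equal(role_set(roles, 1L, "W"), "W1")
  expect_equal(role_set(roles, 1L, "DF"), "DF1")
})
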