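#' Configuration for the synthetic hive simulator
#'
#' An agent-based model with the statistical structure the analysis
#' pipeline assumes: agents alternate between a quiet and an active
#' locomotor state (correlated random walks with small vs. large step
#' scales), activity spreads by physical contact (a quiet agent with at
#' least `activation_threshold` active agents within `contact_radius`
#' becomes active with probability `p_contact_activation` per second) or
#' arises spontaneously; active agents revert after an exponential holding
#' time and are then refractory to contact for a while (which lets
#' cascades die out instead of smouldering forever). Scripted plans add
#' trips (literal removals from the table, matching the absence-based trip
#' detector), waggle dances (alternating near-reversal turns), followers,
#' and planned mass-activation events with a planted "pioneer" group
#' pre-activated `lead` seconds earlier.
#'
#' @param n_bees Number of agents (default 100).
#' @param duration Simulated seconds at 1 Hz (default 7200).
#' @param arena_width,arena_height Arena in pixels (defaults 6576 x 4384).
#' @param sigma_quiet,sigma_active Step scales, px/s (defaults 2 and 30; a
#'   bee is about 600 px, so active bees cover body lengths per second).
#' @param turn_sd_quiet,turn_sd_active Heading-change SD per second,
#'   radians.
#' @param heading_jitter SD of the noise on emitted headings (radians).
#' @param contact_radius Contact distance in px (default 600, one bee
#'   length).
#' @param activation_threshold Active neighbours needed for contact
#'   activation (default 1).
#' @param p_contact_activation Per-second activation probability given
#'   enough contacts (default 0.3).
#' @param p_spontaneous Per-second spontaneous activation probability
#'   (default 0).
#' @param active_duration_mean Mean of the exponential active holding time,
#'   seconds (default 60).
#' @param refractory_mean Mean refractory period after activity, seconds
#'   (default 300).
#' @param entrance Entrance position, px (default bottom centre).
#' @param entrance_open_t Seconds at which the entrance opens (default
#'   600, capped at half the duration).
#' @param diurnal_amplitude Relative sinusoidal modulation of the quiet
#'   step scale (default 0; set > 0 to exercise the diurnal detrend).
#' @param diurnal_period Period of that modulation, seconds (default
#'   86400).
#' @param trips_plan Data frame `bee,exit_t,entry_t` (agent indices): the
#'   agent is absent for seconds `exit_t + 1 .. entry_t - 1` and
#'   re-inserted at the entrance, active, at `entry_t`.
#' @param dances_plan Data frame `bee,start,end` of scripted dances.
#' @param follows_plan Data frame `follower,dancer,start,end` of scripted
#'   followers.
#' @param bursts_plan Data frame `time,mass_n,lead` of planned
#'   mass-activation events (`mass_n` agents activated at `time`).
#' @param pioneers List (one element per `bursts_plan` row) of agent-index
#'   vectors pre-activated `lead` seconds before the event.
#' @param return_active_s Fixed excitation duration, in seconds, of an
#'   agent re-entering from a trip (default `NULL`: draw from the usual
#'   exponential holding time). Returning foragers have just flown; a
#'   fixed, longer excitation makes their cascade seeding reproducible.
#' @param contact_immune Agent indices that are never contact- or
#'   spontaneously activated (their activity is driven purely by scripted
#'   events). Used to plant strictly one-directional coupling for
#'   information-flow ground truths.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_bees = 100, duration = 7200,
                       arena_width = 6576, arena_height = 4384,
                       sigma_quiet = 2, sigma_active = 30,
                       turn_sd_quiet = 0.3, turn_sd_active = 0.6,
                       heading_jitter = 0.05,
                       contact_radius = 600, activation_threshold = 1,
                       p_contact_activation = 0.3, p_spontaneous = 0,
                       active_duration_mean = 60, refractory_mean = 300,
                       entrance = NULL, entrance_open_t = NULL,
                       diurnal_amplitude = 0, diurnal_period = 86400,
                       trips_plan = NULL, dances_plan = NULL,
                       follows_plan = NULL, bursts_plan = NULL,
                       pioneers = NULL, return_active_s = NULL,
                       contact_immune = integer(0), seed = 1) {
  stopifnot(n_bees >= 2, duration >= 10,
            sigma_active > sigma_quiet, sigma_quiet > 0,
            p_contact_activation >= 0, p_contact_activation <= 1,
            p_spontaneous >= 0, p_spontaneous <= 1,
            activation_threshold >= 1,
            active_duration_mean > 0, refractory_mean >= 0)
  if (is.null(entrance))
    entrance <- c(arena_width / 2, arena_height - 50)
  if (is.null(entrance_open_t))
    entrance_open_t <- min(600, floor(duration / 2))
  if (entrance_open_t <= 0 || entrance_open_t >= duration)
    stop("config error: entrance_open_t outside (0, duration)")
  if (!is.null(bursts_plan) && nrow(bursts_plan) > 1) {
    spacing <- diff(sort(bursts_plan$time))
    if (any(spacing < 2 * bursts_plan$lead[1L]))
      stop("config error: planned bursts closer than twice the lead time")
  }
  if (!is.null(bursts_plan) && !is.null(pioneers) &&
      length(pioneers) != nrow(bursts_plan))
    stop("config error: one pioneer set per planned burst required")
  structure(list(
    n_bees = n_bees, duration = duration,
    arena_width = arena_width, arena_height = arena_height,
    sigma_quiet = sigma_quiet, sigma_active = sigma_active,
    turn_sd_quiet = turn_sd_quiet, turn_sd_active = turn_sd_active,
    heading_jitter = heading_jitter,
    contact_radius = contact_radius,
    activation_threshold = activation_threshold,
    p_contact_activation = p_contact_activation,
    p_spontaneous = p_spontaneous,
    active_duration_mean = active_duration_mean,
    refractory_mean = refractory_mean,
    entrance = entrance, entrance_open_t = entrance_open_t,
    diurnal_amplitude = diurnal_amplitude,
    diurnal_period = diurnal_period,
    trips_plan = trips_plan, dances_plan = dances_plan,
    follows_plan = follows_plan, bursts_plan = bursts_plan,
    pioneers = pioneers, return_active_s = return_active_s,
    contact_immune = contact_immune,
    seed = seed), class = "sim_config")
}

bee_ids_for <- function(n) sprintf("B%03d", seq_len(n))

#' Simulate a synthetic hive
#'
#' Runs the agent-based model of [sim_config()] and returns the emitted
#' tracking table plus the ground truth every detector can be validated
#' against. At each second every agent is exactly one of tracked-quiet,
#' tracked-active, or on-trip (absent).
#'
#' @param config A [sim_config()].
#' @return List with `table` (a `tracking_table`), `meta`
#'   (a [trial_metadata()]), and `truth`: list with `states` (n x T 0/1
#'   activity matrix), `pioneer_sets` (bee-id vectors per planned burst),
#'   `planned_times`, `dances`, `follows`, `trips` (bee-id versions of the
#'   plans), `config`.
#' @export
simulate_hive <- function(config) {
  set.seed(config$seed)
  n <- config$n_bees
  TT <- config$duration
  ids <- bee_ids_for(n)
  w <- config$arena_width; h <- config$arena_height

  x <- runif(n, 0, w); y <- runif(n, 0, h)
  theta <- runif(n, -pi, pi)
  active <- logical(n)
  active_until <- numeric(n)
  refract_until <- numeric(n)

  absent <- matrix(FALSE, n, TT)
  tp <- config$trips_plan
  if (!is.null(tp) && nrow(tp))
    for (i in seq_len(nrow(tp))) {
      gap <- seq.int(tp$exit_t[i] + 1, tp$entry_t[i] - 1)
      gap <- gap[gap >= 0 & gap < TT]
      absent[tp$bee[i], gap + 1L] <- TRUE
    }

  dp <- config$dances_plan
  fp <- config$follows_plan
  bp <- config$bursts_plan
  # follower offsets fixed per scripted follow
  if (!is.null(fp) && nrow(fp)) {
    ang <- runif(nrow(fp), -pi, pi)
    rad <- runif(nrow(fp), 150, 400)
    f_off <- cbind(rad * cos(ang), rad * sin(ang))
  }

  X <- matrix(NA_real_, n, TT); Y <- matrix(NA_real_, n, TT)
  NX <- matrix(NA_real_, n, TT); NY <- matrix(NA_real_, n, TT)
  STATE <- matrix(0L, n, TT)

  r2 <- config$contact_radius^2
  for (t in 0:(TT - 1L)) {
    col <- t + 1L
    present <- !absent[, col]

    # state bookkeeping: revert expired actives into refractory
    expired <- active & t >= active_until
    if (any(expired)) {
      active[expired] <- FALSE
      refract_until[expired] <- t +
        if (config$refractory_mean > 0)
          rexp(sum(expired), 1 / config$refractory_mean) else 0
    }

    # scripted pioneer pre-activation and planned mass events
    if (!is.null(bp) && nrow(bp)) {
      for (j in seq_len(nrow(bp))) {
        if (!is.null(config$pioneers) && t == bp$time[j] - bp$lead[j]) {
          pi_set <- config$pioneers[[j]]
          active[pi_set] <- TRUE
          active_until[pi_set] <- t +
            rexp(length(pi_set), 1 / config$active_duration_mean)
        }
        if (t == bp$time[j] && bp$mass_n[j] > 0) {
          pool <- which(present & !active)  # can't activate the active
          pick <- sample(pool, min(bp$mass_n[j], length(pool)))
          active[pick] <- TRUE
          active_until[pick] <- t +
            rexp(length(pick), 1 / config$active_duration_mean)
        }
      }
    }

    # returning agents appear at the entrance, active
    if (!is.null(tp) && nrow(tp)) {
      backs <- tp$bee[tp$entry_t == t]
      if (length(backs)) {
        x[backs] <- pmin(pmax(config$entrance[1] +
                                runif(length(backs), -50, 50), 0), w)
        y[backs] <- pmin(pmax(config$entrance[2] +
                                runif(length(backs), -50, 50), 0), h)
        active[backs] <- TRUE
        active_until[backs] <- t +
          if (!is.null(config$return_active_s)) config$return_active_s
          else rexp(length(backs), 1 / config$active_duration_mean)
      }
    }

    # contact-induced activation
    if (config$p_contact_activation > 0) {
      act_idx <- which(present & active)
      quiet_idx <- which(present & !active & t >= refract_until)
      quiet_idx <- setdiff(quiet_idx, config$contact_immune)
      if (length(act_idx) && length(quiet_idx)) {
        dx <- outer(x[quiet_idx], x[act_idx], "-")
        dy <- outer(y[quiet_idx], y[act_idx], "-")
        n_contacts <- rowSums(dx * dx + dy * dy <= r2)
        hit <- n_contacts >= config$activation_threshold &
          runif(length(quiet_idx)) < config$p_contact_activation
        newly <- quiet_idx[hit]
        active[newly] <- TRUE
        active_until[newly] <- t +
          rexp(length(newly), 1 / config$active_duration_mean)
      }
    }

    # spontaneous activation
    if (config$p_spontaneous > 0) {
      quiet_idx <- which(present & !active & t >= refract_until)
      quiet_idx <- setdiff(quiet_idx, config$contact_immune)
      newly <- quiet_idx[runif(length(quiet_idx)) < config$p_spontaneous]
      if (length(newly)) {
        active[newly] <- TRUE
        active_until[newly] <- t +
          rexp(length(newly), 1 / config$active_duration_mean)
      }
    }

    # who is scripted right now
    dancing <- integer(0); dance_row <- integer(0)
    if (!is.null(dp) && nrow(dp)) {
      sel <- which(dp$start <= t & dp$end >= t)
      dancing <- dp$bee[sel]; dance_row <- sel
    }
    following <- integer(0); follow_row <- integer(0)
    if (!is.null(fp) && nrow(fp)) {
      sel <- which(fp$start <= t & fp$end >= t)
      following <- fp$follower[sel]; follow_row <- sel
    }

    # locomotion
    sq <- config$sigma_quiet *
      (1 + config$diurnal_amplitude * sin(2 * pi * t / config$diurnal_period))
    scripted <- c(dancing, following)
    free <- which(present & !(seq_len(n) %in% scripted))
    if (length(free)) {
      sig <- ifelse(active[free], config$sigma_active, sq)
      tsd <- ifelse(active[free], config$turn_sd_active,
                    config$turn_sd_quiet)
      theta[free] <- theta[free] + rnorm(length(free), 0, tsd)
      step <- abs(rnorm(length(free), 0, sig))
      x[free] <- x[free] + step * cos(theta[free])
      y[free] <- y[free] + step * sin(theta[free])
    }
    # dancers: alternating near-reversal turns, tiny drift
    if (length(dancing)) {
      phase <- (t - dp$start[dance_row]) %% 2L
      turn <- ifelse(phase == 0L, 1, -1) * (pi - 0.17)
      theta[dancing] <- theta[dancing] + turn
      x[dancing] <- x[dancing] + rnorm(length(dancing), 0, 3)
      y[dancing] <- y[dancing] + rnorm(length(dancing), 0, 3)
    }
    # followers: ride at a fixed offset, facing the dancer
    if (length(following)) {
      dn <- fp$dancer[follow_row]
      x[following] <- pmin(pmax(x[dn] + f_off[follow_row, 1], 0), w)
      y[following] <- pmin(pmax(y[dn] + f_off[follow_row, 2], 0), h)
      theta[following] <- atan2(y[dn] - y[following],
                                x[dn] - x[following])
    }
    # reflect at walls
    x <- reflect(x, w); y <- reflect(y, h)

    # emit
    pres_idx <- which(present)
    emit_theta <- theta[pres_idx] +
      rnorm(length(pres_idx), 0, config$heading_jitter)
    scripted_now <- pres_idx %in% scripted
    emit_theta[scripted_now] <- theta[pres_idx][scripted_now] +
      rnorm(sum(scripted_now), 0, 0.02)
    X[pres_idx, col] <- x[pres_idx]
    Y[pres_idx, col] <- y[pres_idx]
    NX[pres_idx, col] <- cos(emit_theta)
    NY[pres_idx, col] <- sin(emit_theta)
    STATE[, col] <- as.integer(active)
  }

  rec <- which(!is.na(X), arr.ind = TRUE)
  df <- data.frame(bee_id = ids[rec[, 1]],
                   t = rec[, 2] - 1L,
                   x = X[rec], y = Y[rec], nx = NX[rec], ny = NY[rec])
  meta <- trial_metadata(trial_id = "synthetic",
                         entrance_open_t = config$entrance_open_t,
                         t_total = TT)
  table <- tracking_table(df, meta)

  truth <- list(
    states = STATE,
    pioneer_sets = if (!is.null(config$pioneers))
      lapply(config$pioneers, function(ix) ids[ix]),
    planned_times = if (!is.null(bp)) bp$time,
    dances = if (!is.null(dp) && nrow(dp))
      data.frame(bee_id = ids[dp$bee], start = dp$start, end = dp$end),
    follows = if (!is.null(fp) && nrow(fp))
      data.frame(follower_id = ids[fp$follower], dancer_id = ids[fp$dancer],
                 start = fp$start, end = fp$end),
    trips = if (!is.null(tp) && nrow(tp))
      data.frame(bee_id = ids[tp$bee], exit_t = tp$exit_t,
                 entry_t = tp$entry_t),
    config = config)
  list(table = table, meta = meta, truth = truth)
}

reflect <- function(v, upper) {
  v <- abs(v)
  over <- v > upper
  v[over] <- 2 * upper - v[over]
  pmin(pmax(v, 0), upper)
}

#' Named simulator presets
#'
#' Deterministic study scenarios used throughout the test suite:
#' \describe{
#'   \item{null}{no activations at all; the burst detector should find
#'     nothing.}
#'   \item{contact_cascade}{rare spontaneous activations that spread by
#'     contact, producing a handful of spontaneous bursts per 2 h.}
#'   \item{forager_driven}{a fixed forager group repeatedly leaves and
#'     returns at irregular times; their return seeds contact cascades, so
#'     information flows from the forager group to the rest.}
#'   \item{dance_demo}{a quiet colony with scripted dances, followers and
#'     trips, for detector validation.}
#'   \item{pioneer_recovery}{20 planned mass-activation events, each with a
#'     20-bee planted pioneer group pre-activated 60 s ahead.}
#' }
#'
#' @param name Preset name.
#' @param n_bees,duration Scenario size (defaults 100 bees, 7200 s).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
preset_config <- function(name = c("null", "contact_cascade",
                                   "forager_driven", "dance_demo",
                                   "pioneer_recovery"),
                          n_bees = 100, duration = 7200, seed = 1) {
  name <- match.arg(name)
  set.seed(seed + 1000L)  # plan randomness, distinct from the sim stream
  switch(name,
    null = sim_config(n_bees = n_bees, duration = duration,
                      p_contact_activation = 0, p_spontaneous = 0,
                      seed = seed),
    contact_cascade = sim_config(n_bees = n_bees, duration = duration,
                                 p_contact_activation = 0.3,
                                 p_spontaneous = 2e-5,
                                 seed = seed),
    forager_driven = {
      foragers <- 1:15
      n_events <- 12
      times <- round(seq(900, duration - 400, length.out = n_events) +
                       runif(n_events, -100, 100))
      trips <- do.call(rbind, lapply(times, function(tm)
        data.frame(bee = foragers, exit_t = tm - 61, entry_t = tm)))
      # foragers are contact-immune so the coupling is strictly one-way:
      # returns seed cascades, cascades never re-excite the forager group.
      # A fixed 150-s post-flight excitation makes each return a reliable
      # cascade seed.
      sim_config(n_bees = n_bees, duration = duration,
                 p_contact_activation = 0.15, p_spontaneous = 0,
                 entrance_open_t = 600,
                 trips_plan = trips, return_active_s = 150,
                 contact_immune = foragers,
                 seed = seed)
    },
    dance_demo = {
      if (n_bees < 30) stop("dance_demo needs at least 30 bees")
      dancers <- 1:6
      starts <- round(seq(700, duration - 200, length.out = 12))
      dances <- data.frame(bee = rep(dancers, 2),
                           start = starts,
                           end = starts + 29)
      follows <- data.frame(follower = 10 + seq_len(nrow(dances)),
                            dancer = dances$bee,
                            start = dances$start + 2,
                            end = dances$end - 2)
      trip_bees <- (n_bees - 5):n_bees
      exits <- round(seq(800, duration - 500, length.out = 6))
      trips <- data.frame(bee = trip_bees, exit_t = exits,
                          entry_t = exits + round(runif(6, 100, 300)))
      sim_config(n_bees = n_bees, duration = duration,
                 p_contact_activation = 0, p_spontaneous = 0,
                 entrance_open_t = 600,
                 dances_plan = dances, follows_plan = follows,
                 trips_plan = trips, seed = seed)
    },
    pioneer_recovery = {
      times <- round(seq(400, duration - 400, length.out = 20))
      bp <- data.frame(time = times, mass_n = 50, lead = 60)
      pio <- lapply(times, function(tm) sample.int(n_bees, 20))
      sim_config(n_bees = n_bees, duration = duration,
                 p_contact_activation = 0, p_spontaneous = 0,
                 bursts_plan = bp, pioneers = pio, seed = seed)
    })
}

#' Write a deterministic fixture suite to disk
#'
#' Simulates the named presets and writes, per preset, the tracking CSV,
#' the trial metadata YAML, and the ground truth as JSON (activity states
#' run-length encoded per bee). Re-running with the same seed reproduces
#' the files byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param presets Preset names (default: all five).
#' @param n_bees,duration,seed Passed to [preset_config()].
#' @return Named list of the files written, invisibly.
#' @export
emit_fixture_suite <- function(dir, presets = c("null", "contact_cascade",
                                                "forager_driven",
                                                "dance_demo",
                                                "pioneer_recovery"),
                               n_bees = 100, duration = 7200, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (p in presets) {
    cfg <- preset_config(p, n_bees = n_bees, duration = duration,
                         seed = seed)
    sim <- simulate_hive(cfg)
    base <- file.path(dir, p)
    f_trk <- paste0(base, "_tracking.csv")
    f_meta <- paste0(base, "_meta.yaml")
    f_truth <- paste0(base, "_truth.json")
    write_tracking(sim$table, f_trk)
    write_trial_metadata(sim$meta, f_meta)
    truth <- sim$truth
    truth$config <- NULL
    truth$states <- apply(truth$states, 1, function(row) {
      r <- rle(row); list(lengths = r$lengths, values = r$values)
    })
    names(truth$states) <- bee_ids_for(nrow(sim$truth$states))
    jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
    out[[p]] <- c(tracking = f_trk, meta = f_meta, truth = f_truth)
  }
  invisible(out)
}
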