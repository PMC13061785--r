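test_that("pedaling angles map to the printed channel sets", {
  cfg <- build_pedaling_config()
  expect_identical(classify_phase(160, cfg), "flexion")
  expect_identical(fesloop:::phase_channels(cfg, "flexion"), c(1L, 2L))
  expect_identical(classify_phase(-160, cfg), "extension")
  expect_identical(fesloop:::phase_channels(cfg, "extension"), c(3L, 4L))
  expect_true(is.na(classify_phase(0, cfg)))
  # inclusive boundaries
  expect_identical(classify_phase(150, cfg), "flexion")
  expect_identical(classify_phase(175, cfg), "flexion")
  expect_true(is.na(classify_phase(149.99, cfg)))
})

test_that("overlapping or miscounted phase ranges fail at load time", {
  p1 <- phase_definition("a", 0, 90, 1L)
  p2 <- phase_definition("b", 80, 170, 2L)
  expect_error(task_config("pedaling", list(p1, p2)), "disjoint")
  expect_error(task_config("gait", list(p1)), "exactly 4")
  expect_error(task_config("pedaling",
                           list(p1, p2, phase_definition("c", -90, -10, 3L))),
               "exactly 2")
  expect_error(phase_definition("x", 0, 10, integer(0)), "nonempty")
  expect_error(phase_definition("x", 0, 10, c(1L, 1L)), "duplicate")
  expect_error(phase_definition("x", -190, 10, 1L), "-180")
})

test_that("a monotone sweep visits each pedaling phase exactly once", {
  cfg <- build_pedaling_config()
  log <- run_controller(sweep_trace(-179.9, 179.9, duration = 10), cfg)
  runs <- rle(log$phase)
  lab <- runs$values[runs$values != ""]
  expect_identical(lab, c("extension", "flexion"))
  expect_identical(sum(runs$values == "extension"), 1L)
  expect_identical(sum(runs$values == "flexion"), 1L)
  # channels match the active phase exactly
  expect_identical(unique(log$active_channels[log$phase == "flexion"]), "1;2")
  expect_identical(unique(log$active_channels[log$phase == "extension"]),
                   "3;4")
  expect_identical(unique(log$active_channels[log$phase == ""]), "")
})

test_that("gait phases are visited in cyclic order with no skips", {
  cfg <- build_gait_config()
  imu <- simulate_motion_imu(
    motion_sim_config("gait", 4, 12, imu_rate = 50, phase_deg = -179))
  log <- run_controller(imu, cfg)
  runs <- rle(log$phase)
  lab <- runs$values[runs$values != ""]
  want <- c("initial_contact", "mid_stance", "terminal_stance",
            "initial_swing")
  expect_identical(lab[seq_len(4)], want)
  expect_identical(lab, rep(want, length.out = length(lab)))
})

test_that("emergency stop is latched, all-off, idempotent and resettable", {
  cfg <- build_pedaling_config()
  st <- new_controller_state()
  in_phase <- list(t = 0, ax = sin(160 * pi / 180), ay = cos(160 * pi / 180))
  res <- step_controller(st, in_phase, cfg)
  expect_identical(res$command$active_channels, c(1L, 2L))

  st <- trigger_emergency_stop(res$state)
  expect_true(st$emergency_stopped)
  st2 <- trigger_emergency_stop(st)
  expect_identical(st2$emergency_stopped, st$emergency_stopped)

  later <- list(t = 5, ax = in_phase$ax, ay = in_phase$ay)
  res2 <- step_controller(st2, later, cfg)
  expect_identical(res2$command$active_channels, integer(0))

  st3 <- reset_emergency_stop(res2$state)
  res3 <- step_controller(st3, list(t = 6, ax = in_phase$ax,
                                    ay = in_phase$ay), cfg)
  expect_identical(res3$command$active_channels, c(1L, 2L))
})

test_that("no command after a stop carries channels until reset (property)", {
  cfg <- build_pedaling_config()
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- 120L
      t <- seq(0, by = 0.05, length.out = n)
      ang <- runif(n, -179, 180) * pi / 180
      df <- imu_df(t, sin(ang), cos(ang))
      stop_at <- t[sample.int(n - 20L, 1L)]
      reset_at <- if (rep %% 2 == 0) stop_at + 2 else NULL
      log <- run_controller(df, cfg, emergency_stop_at = stop_at,
                            reset_at = reset_at)
      dead <- log$t >= stop_at &
        (if (is.null(reset_at)) TRUE else log$t < reset_at)
      expect_true(all(log$active_channels[dead] == ""))
    }
  })
})

test_that("dwell debouncing limits transitions near a boundary", {
  cfg <- build_pedaling_config(min_dwell_s = 0.2)
  withr::with_seed(4, {
    n <- 200L
    t <- seq(0, by = 0.05, length.out = n)
    ang <- (175 + runif(n, -1, 1)) * pi / 180 # jitter around phase edge
    log <- run_controller(imu_df(t, sin(ang), cos(ang)), cfg)
    trans <- which(diff(as.integer(factor(log$phase,
                                          levels = c("", "flexion")))) != 0)
    if (length(trans) > 1)
      expect_true(all(diff(log$t[trans]) >= 0.2 - 1e-9))
  })
})

test_that("frequency lock clamps to the configured ceiling", {
  cfg <- build_pedaling_config(max_command_rate_hz = 50)
  expect_equal(enforce_frequency_lock(100, cfg), 50)
  expect_equal(enforce_frequency_lock(20, cfg), 20)
  expect_equal(enforce_frequency_lock(50, cfg), 50)
  expect_error(enforce_frequency_lock(-1, cfg), ">= 0")
})

test_that("builders encode the documented phase and muscle structure", {
  ped <- build_pedaling_config()
  expect_identical(ped$mode, "pedaling")
  expect_length(ped$phases, 2L)
  expect_equal(ped$stim[["1"]]$frequency_hz, 35)
  expect_equal(ped$stim[["1"]]$pulse_width_us, 300)
  expect_equal(ped$stim[["1"]]$intensity_pct, 75)

  gait <- build_gait_config()
  expect_identical(gait$mode, "gait")
  expect_length(gait$phases, 4L)
  mid <- Filter(function(p) p$name == "mid_stance", gait$phases)[[1]]
  expect_true(all(grepl("quadriceps", mid$muscles)))
  swing <- Filter(function(p) p$name == "initial_swing", gait$phases)[[1]]
  expect_true(any(grepl("hamstring", swing$muscles)))
  expect_true(any(grepl("tibialis", swing$muscles)))
  expect_error(build_gait_config(list(a = c(0, 1))), "4 ranges|named list")
})

test_that("identical inputs produce byte-identical command logs", {
  imu <- simulate_motion_imu(
    motion_sim_config("pedaling", 5 / 3, 20, noise_sigma = 0.03, seed = 8))
  cfg <- build_pedaling_config()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_command_log(run_controller(imu, cfg), f1)
  write_command_log(run_controller(imu, cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("task configs survive a YAML round trip", {
  for (cfg in list(build_pedaling_config(), build_gait_config())) {
    f <- tempfile(fileext = ".yaml")
    write_task_config(cfg, f)
    back <- read_task_config(f)
    expect_identical(back$mode, cfg$mode)
    expect_equal(length(back$phases), length(cfg$phases))
    for (i in seq_along(cfg$phases)) {
      expect_identical(back$phases[[i]]$name, cfg$phases[[i]]$name)
      expect_identical(back$phases[[i]]$channels, cfg$phases[[i]]$channels)
      expect_equal(back$phases[[i]]$theta_min, cfg$phases[[i]]$theta_min)
    }
  }
  expect_error(read_task_config(tempfile()), "not found")
})
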