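test_that("bottleneck scenario generation satisfies its invariants deterministically", {
  # single agent is fine
  sc1 <- make_bottleneck_scenario(n_agents = 1, n_disabled = 0, seed = 1,
                                  corridor_length = 24, end_width = 6,
                                  throat_width = 2, throat_center = 14,
                                  entry_length = 4)
  expect_s3_class(sc1, "scenario")
  expect_equal(nrow(sc1$positions), 1)

  # the standard crowd: 40 agents, one with disabilities
  sc <- make_bottleneck_scenario(seed = 2)
  expect_equal(nrow(sc$positions), 40)
  expect_equal(sum(sc$roles == "disabled"), 1)
  expect_equal(which(sc$roles == "disabled"), 5L) # reference layout: agent 5
  expect_gte(min(wall_clearance(sc$walls, sc$positions)), sc$wall_margin)
  D <- as.matrix(dist(sc$positions))
  diag(D) <- Inf
  expect_gte(min(D), sc$profile$r_min)
  expect_gt(wall_clearance(sc$walls, sc$target), 0)

  # seed determinism: bit-identical regeneration
  sc_again <- make_bottleneck_scenario(seed = 2)
  expect_identical(sc$positions, sc_again$positions)
  expect_identical(sc$walls$upper, sc_again$walls$upper)
  expect_false(identical(sc$positions,
                         make_bottleneck_scenario(seed = 3)$positions))
})

test_that("throat width equal to end width degenerates to a parallel corridor", {
  sc <- make_bottleneck_scenario(n_agents = 3, corridor_length = 24,
                                 end_width = 6, throat_width = 6,
                                 throat_center = 12, entry_length = 4,
                                 seed = 5)
  set.seed(5)
  for (i in 1:6) {
    p <- c(runif(1, 1, 23), runif(1, -2.5, 2.5))
    expect_equal(chord_for_agent(sc$walls, p)$chord_length, 6,
                 tolerance = 1e-6)
  }
})

test_that("infeasible packings are rejected with a feasibility error", {
  expect_error(
    make_bottleneck_scenario(n_agents = 50, corridor_length = 24,
                             end_width = 3, throat_width = 2,
                             throat_center = 14, entry_length = 2,
                             seed = 1, max_attempts = 500),
    "infeasible")
})

test_that("config files load with defaults, reject bad keys, and round-trip", {
  # minimal file: only n_agents; standard defaults fill in
  f <- tempfile(fileext = ".json")
  writeLines('{"n_agents": 12}', f)
  got <- load_config(f)
  expect_equal(got$config$n_agents, 12)
  expect_equal(got$config$mu, 0.05)
  expect_equal(got$config$mu_v, 0.05)
  expect_equal(got$config$lambda, 0.5)
  expect_equal(got$config$beta, 1)
  expect_equal(got$config$gamma, 1)
  expect_equal(got$config$alpha, 0.5)
  expect_true("mu" %in% got$defaulted)

  # empty file: full defaults
  writeLines("{}", f)
  got <- load_config(f)
  expect_equal(got$config$n_agents, 40)

  # out-of-range step size rejected
  writeLines('{"mu": 1.5}', f)
  expect_error(load_config(f), "invalid simulation setting")

  # unknown keys rejected by name
  writeLines('{"walking_speed": 2}', f)
  expect_error(load_config(f), "walking_speed")

  # round-trip: load(save(load(x))) is stable
  writeLines('{"simulation": {"mu": 0.1, "seed": 7}, "scenario": {"n_agents": 9}}', f)
  a <- load_config(f)
  f2 <- tempfile(fileext = ".json")
  save_config(a$config, f2, a$scenario_args)
  b <- load_config(f2)
  expect_equal(unclass(a$config), unclass(b$config))
  expect_equal(a$scenario_args$n_agents, b$scenario_args$n_agents)
  unlink(c(f, f2))
})

test_that("scenario files round-trip through CSV + JSON sidecar", {
  sc <- make_bottleneck_scenario(n_agents = 4, corridor_length = 24,
                                 end_width = 6, throat_width = 2,
                                 throat_center = 14, entry_length = 4,
                                 seed = 3,
                                 obstacles = list(obstacle(c(10, 1), 0.5)))
  prefix <- tempfile()
  write_scenario(sc, prefix)
  sc2 <- read_scenario(prefix)
  expect_equal(sc2$positions, sc$positions, ignore_attr = TRUE)
  expect_equal(sc2$roles, sc$roles)
  expect_equal(sc2$target, sc$target)
  expect_equal(sc2$obstacles[[1]]$position, c(10, 1))
  expect_equal(sc2$walls$upper[, 2], sc$walls$upper[, 2], tolerance = 1e-9)
  unlink(paste0(prefix, c("_walls.csv", "_scenario.json")))
})

test_that("trajectory CSV round-trips and summaries agree to machine precision", {
  sc <- make_bottleneck_scenario(n_agents = 5, corridor_length = 24,
                                 end_width = 6, throat_width = 2,
                                 throat_center = 14, entry_length = 4, seed = 4)
  cfg <- simulation_config(n_agents = 5, n_iterations = 20, seed = 4)
  traj <- run_simulation(sc, cfg)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  s1 <- summarize_trajectory(traj)
  s2 <- summarize_trajectory(back)
  expect_equal(s2$group_distance$mean_dist, s1$group_distance$mean_dist,
               tolerance = 1e-12)
  expect_equal(s2$agent_summary, s1$agent_summary, tolerance = 1e-12)
  unlink(c(f, paste0(f, ".config.json")))
})

test_that("replaying a simulated stream reproduces the simulator's advisories", {
  sc <- make_bottleneck_scenario(n_agents = 4, corridor_length = 24,
                                 end_width = 6, throat_width = 2,
                                 throat_center = 14, entry_length = 4, seed = 6)
  cfg <- simulation_config(n_agents = 4, n_iterations = 15, seed = 6)
  traj <- run_simulation(sc, cfg)
  stream <- trajectory_to_stream(traj)
  rep <- replay_stream(stream, sc, cfg)
  for (it in 1:15) {
    for (a in 1:4) {
      want <- traj$theta[traj$iteration == it & traj$agent == a]
      got <- rep$theta[rep$timestamp == it * cfg$dt & rep$agent_id == a]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("replay flags social-distance violations at the first violating timestamp", {
  walls <- wall_pair(function(x) 3 + 0 * x, function(x) -3 + 0 * x, c(0, 30))
  sc <- scenario(walls, target = c(28, 0),
                 positions = rbind(c(1, 1), c(1, -1)),
                 roles = c("general", "general"))
  # two agents converging: distance shrinks from 6 m to 0.5 m
  ts <- 0:10
  y1 <- seq(3, 0.25, length.out = 11)
  stream <- location_stream(data.frame(
    timestamp = rep(ts, each = 2), agent_id = rep(1:2, 11),
    x = 5, y = c(rbind(y1, -y1))))
  rep <- replay_stream(stream, sc, simulation_config(n_agents = 2))
  # brute-force oracle: first time pairwise distance < required distance
  viol <- vapply(ts[-1], function(tt)
    any(!rep$compliant[rep$timestamp == tt]), logical(1))
  d_pair <- 2 * y1[-1]
  r_req <- vapply(ts[-1], function(tt)
    max(rep$r_required[rep$timestamp == tt]), numeric(1))
  first_oracle <- min(which(d_pair < r_req))
  expect_equal(min(which(viol)), first_oracle)
  # an agent moving straight at the target reports theta ~ 0
  stream2 <- location_stream(data.frame(timestamp = rep(0:5, each = 1),
                                        agent_id = 1,
                                        x = seq(1, 11, by = 2), y = 0))
  sc1 <- scenario(walls, c(28, 0), rbind(c(1, 0)), "general")
  rep2 <- replay_stream(stream2, sc1, simulation_config(n_agents = 1))
  expect_lt(max(rep2$theta), 1e-9)
})

test_that("replay warns about gaps and skips the missing agent", {
  walls <- wall_pair(function(x) 3 + 0 * x, function(x) -3 + 0 * x, c(0, 30))
  sc <- scenario(walls, c(28, 0), rbind(c(1, 1), c(1, -1)),
                 c("general", "general"))
  stream <- location_stream(data.frame(
    timestamp = c(0, 0, 1, 1, 2), agent_id = c(1, 2, 1, 2, 1),
    x = c(1, 1, 2, 2, 3), y = c(1, -1, 1, -1, 1)))
  expect_warning(rep <- replay_stream(stream, sc, simulation_config(n_agents = 2)),
                 "gap")
  expect_false(any(rep$timestamp == 2 & rep$agent_id == 2))
  expect_true(any(rep$timestamp == 2 & rep$agent_id == 1))
})

test_that("the command-line interface drives simulate/summarize/validate end to end", {
  out <- file.path(tempfile(), "run")
  cfgf <- tempfile(fileext = ".json")
  writeLines(paste0('{"simulation": {"n_agents": 4, "n_iterations": 10, "seed": 5},',
                    ' "scenario": {"n_agents": 4, "corridor_length": 24,',
                    ' "end_width": 6, "throat_width": 2, "throat_center": 14,',
                    ' "entry_length": 4, "seed": 5}}'), cfgf)
  status <- crowdadapt_cli(c("simulate", "--config", cfgf, "--out-dir", out))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "summary_group_distance.csv")))
  expect_true(file.exists(file.path(out, "scenario_walls.csv")))

  # summarize round-trip: CSV summary equals in-memory summary
  out2 <- file.path(tempfile(), "sum")
  status <- crowdadapt_cli(c("summarize",
                             "--trajectory", file.path(out, "trajectory.csv"),
                             "--out-dir", out2))
  expect_equal(status, 0L)
  a <- read.csv(file.path(out, "summary_group_distance.csv"))
  b <- read.csv(file.path(out2, "summary_group_distance.csv"))
  expect_equal(a, b, tolerance = 1e-12)

  # validate passes on the genuine trajectory
  status <- suppressMessages(
    crowdadapt_cli(c("validate",
                     "--trajectory", file.path(out, "trajectory.csv"),
                     "--scenario", file.path(out, "scenario"))))
  expect_equal(status, 0L)

  # and fails, naming the culprit, on a corrupted one
  traj <- read.csv(file.path(out, "trajectory.csv"))
  traj$y[traj$iteration == 3 & traj$agent == 2] <- 50
  bad <- file.path(dirname(cfgf), "bad.csv")
  write.csv(traj, bad, row.names = FALSE)
  file.copy(paste0(file.path(out, "trajectory.csv"), ".config.json"),
            paste0(bad, ".config.json"))
  expect_message(
    status <- crowdadapt_cli(c("validate", "--trajectory", bad,
                               "--scenario", file.path(out, "scenario"))),
    "error")
  expect_equal(status, 1L)

  # unknown subcommand exits nonzero
  expect_message(status <- crowdadapt_cli("frobnicate"), "error")
  expect_equal(status, 1L)
  unlink(c(out, out2), recursive = TRUE)
})
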