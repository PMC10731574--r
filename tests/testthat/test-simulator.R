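# Kinematic chain simulator: minimum-jerk profile, forward kinematics,
# seeding, oracle agreement, presets.

test_that("minimum-jerk profile has the quintic's boundary behaviour", {
  expect_equal(minimum_jerk_profile(0, 0, 1), 0)
  expect_equal(minimum_jerk_profile(1, 0, 1), 1)
  expect_equal(minimum_jerk_profile(0.5, 0, 1), 0.5)   # symmetry
  expect_equal(minimum_jerk_profile(-5, 0, 1), 0)      # clamped before onset
  expect_equal(minimum_jerk_profile(9, 0, 1), 1)       # and after the end
  # rest-to-rest: numerical derivative ~ 0 at both ends
  eps <- 1e-6
  expect_lt(abs(minimum_jerk_profile(eps, 0, 1) / eps), 1e-4)
  expect_lt(abs((1 - minimum_jerk_profile(1 - eps, 0, 1)) / eps), 1e-4)
  # monotone
  s <- minimum_jerk_profile(seq(-0.2, 1.2, by = 0.01), 0, 1)
  expect_true(all(diff(s) >= 0))
  expect_error(minimum_jerk_profile(0.5, 0, 0), class = "reachcomp_parameter_error")
})

test_that("rest posture geometry matches the protocol start position", {
  cfg <- chain_config()
  p <- marker_positions_from_pose(cfg)
  # elbow at 90 deg: MP forward of the acromion by the forearm, below it by
  # the upper arm
  expect_equal(unname(p$MP_R - p$ACROMION_R),
               c(0, cfg$forearm_length, -cfg$upper_arm_length), tolerance = 1e-9)
  expect_equal(unname(p$C7), c(0, 0, cfg$trunk_length), tolerance = 1e-9)
  expect_equal(unname(p$ACROMION_R - p$C7), c(cfg$shoulder_offset, 0, 0),
               tolerance = 1e-9)
})

test_that("quarter-turn trunk flexion and rigid girdle ride-along behave", {
  cfg <- chain_config()
  bent <- marker_positions_from_pose(cfg, c(trunk_flexion = 90))
  expect_equal(unname(bent$C7), c(0, cfg$trunk_length, 0), tolerance = 1e-9)

  rest <- marker_positions_from_pose(cfg)
  up <- marker_positions_from_pose(cfg, c(girdle_elevation = 40))
  for (mk in c("ACROMION_R", "EPICONDYLE_R", "MP_R")) {
    expect_equal(unname(up[[mk]] - rest[[mk]]), c(0, 0, 40), tolerance = 1e-9)
  }
  expect_equal(unname(up$CHIN - rest$CHIN), c(0, 0, 0), tolerance = 1e-9)
})

test_that("abduction elevates the epicondyle preserving the upper-arm length", {
  cfg <- chain_config()
  rest <- marker_positions_from_pose(cfg)
  abd <- marker_positions_from_pose(cfg, c(shoulder_abduction = 30))
  # elevation = L * (1 - cos 30)
  expect_equal(abd$EPICONDYLE_R[["Z"]] - rest$EPICONDYLE_R[["Z"]],
               cfg$upper_arm_length * (1 - cos(pi / 6)), tolerance = 1e-9)
  expect_equal(sqrt(sum((abd$EPICONDYLE_R - abd$ACROMION_R)^2)),
               cfg$upper_arm_length, tolerance = 1e-9)
})

test_that("chain_config validates lengths against the declared arm length", {
  expect_error(chain_config(upper_arm_length = -1),
               class = "reachcomp_parameter_error")
  expect_error(chain_config(upper_arm_length = 100, forearm_length = 100),
               class = "reachcomp_parameter_error")
  scaled <- scale_chain(chain_config(), 650)
  expect_equal(scaled$upper_arm_length / scaled$forearm_length,
               300 / 330, tolerance = 1e-9)
  expect_equal(scaled$upper_extremity_length, 650)
})

test_that("simulate_trial honours the seeding contract", {
  cfg <- chain_config()
  prog <- joint_program(elbow_flexion = c(90, 20))
  a <- simulate_trial(cfg, prog, noise_sd = 2, seed = 99)
  b <- simulate_trial(cfg, prog, noise_sd = 2, seed = 99)
  c <- simulate_trial(cfg, prog, noise_sd = 2, seed = 100)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
  # noise-free: deterministic without a seed
  expect_identical(simulate_trial(cfg, prog)$positions,
                   simulate_trial(cfg, prog)$positions)
})

test_that("elbow-only extension decomposes to 100% shoulder_elbow", {
  cfg <- chain_config()
  tr <- simulate_trial(cfg, joint_program(elbow_flexion = c(90, 10)),
                       task = "forward_reach")
  d <- analyze_trial(tr, cutoff = NULL, threshold_fraction = 0)
  expect_equal(unname(d$percent), c(100, 0, 0), tolerance = 1e-6)
})

test_that("noise-free simulated trials match the analytic oracle", {
  cfg <- chain_config()
  set.seed(17)
  for (task in c("forward_reach", "hand_to_mouth")) {
    for (i in 1:5) {
      prog <- random_program(task)
      orc <- analytic_decomposition_oracle(cfg, prog, task)
      if (abs(orc$total) < 20) next
      tr <- simulate_trial(cfg, prog, task = task)
      d <- analyze_trial(tr, cutoff = NULL, threshold_fraction = 0)
      expect_equal(d$components, orc$components, tolerance = 1e-6)
      expect_equal(d$total, orc$total, tolerance = 1e-6)
      expect_equal(sum(orc$components), orc$total, tolerance = 1e-12)
    }
  }
})

test_that("shoulder flexion leaks into the abduction component as documented", {
  # Component 5 reads epicondyle elevation relative to the acromion; pure
  # shoulder flexion also elevates the epicondyle, so the approximation
  # assigns L*(1 - cos sf) to "abduction" even with zero abduction. This is
  # inherent to the marker-level definition; quantify rather than hide it.
  cfg <- chain_config()
  orc <- analytic_decomposition_oracle(
    cfg, joint_program(shoulder_flexion = 30, elbow_flexion = c(90, 150)),
    "hand_to_mouth")
  leak <- cfg$upper_arm_length * (1 - cos(30 * pi / 180))
  expect_equal(unname(orc$components[["shoulder_abduction"]]), leak,
               tolerance = 1e-9)
})

test_that("preset cohorts reproduce the published group directions", {
  tab <- local({
    s <- simulate_cohort(strategy_preset("stroke"), 10, seed = 1)
    h <- simulate_cohort(strategy_preset("healthy"), 20, seed = 2)
    cohort_table(c(s$trials, h$trials), rbind(s$subjects, h$subjects))
  })
  fw <- summarize_cohort(tab, "forward_reach")
  tf_s <- fw$mean_pct[fw$group == "stroke" & fw$component == "trunk_flexion"]
  tf_h <- fw$mean_pct[fw$group == "healthy" & fw$component == "trunk_flexion"]
  expect_gt(tf_s, tf_h)
  hm <- summarize_cohort(tab, "hand_to_mouth")
  ab_s <- hm$mean_pct[hm$group == "stroke" & hm$component == "shoulder_abduction"]
  ab_h <- hm$mean_pct[hm$group == "healthy" & hm$component == "shoulder_abduction"]
  expect_gt(ab_s, ab_h)
})

test_that("cohort generation is reproducible and respects degenerate presets", {
  p <- strategy_preset("healthy")
  a <- simulate_cohort(p, 3, seed = 8)
  b <- simulate_cohort(p, 3, seed = 8)
  expect_identical(lapply(a$trials, `[[`, "positions"),
                   lapply(b$trials, `[[`, "positions"))
  expect_identical(a$subjects, b$subjects)

  # all spread parameters zero: subjects identical up to marker noise
  p0 <- strategy_preset("healthy", noise_sd = 0, uel_sd = 0)
  for (task in c("forward_reach", "hand_to_mouth")) {
    p0[[task]] <- lapply(p0[[task]], function(s) { s$sd <- 0; s })
  }
  coh <- simulate_cohort(p0, 3, seed = 9, tasks = "forward_reach")
  ref <- coh$trials[[1]]$positions
  for (tr in coh$trials) expect_equal(tr$positions, ref, tolerance = 1e-12)
})

test_that("noise at device magnitude perturbs percents by about a point", {
  cfg <- chain_config()
  prog <- joint_program(shoulder_flexion = 60, elbow_flexion = c(90, 20),
                        trunk_flexion = 4, trunk_rotation = 8, duration = 1.2)
  clean <- analyze_trial(simulate_trial(cfg, prog, task = "forward_reach"),
                         cutoff = NULL, threshold_fraction = 0)
  dev <- vapply(1:40, function(s) {
    noisy <- simulate_trial(cfg, prog, task = "forward_reach",
                            noise_sd = c(2.4, 1.7, 1.7), seed = s)
    max(abs(analyze_trial(noisy)$percent - clean$percent))
  }, numeric(1))
  expect_gte(mean(dev < 3), 0.95)
})
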