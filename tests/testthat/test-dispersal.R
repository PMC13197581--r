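test_that("buoyancy stages follow the three-phase fall-velocity schedule", {
  cfg <- dispersal_config()
  expect_equal(buoyancy_velocity(72, cfg), 0.0049)    # day 3: rising
  expect_equal(buoyancy_velocity(240, cfg), 0)        # day 10: neutral
  expect_equal(buoyancy_velocity(480, cfg), -0.005)   # day 20: sinking
  expect_equal(buoyancy_velocity(c(0, 7 * 24, 14 * 24), cfg),
               c(0.0049, 0, -0.005))
})

test_that("cumulative survival pins the weekly schedule boundaries", {
  cfg <- dispersal_config()
  expect_equal(survival_probability(0, cfg), 1)
  expect_equal(survival_probability(7 * 24, cfg), 0.75)
  expect_equal(survival_probability(14 * 24, cfg), 0.75 * 0.5)
  expect_equal(survival_probability(28 * 24, cfg), 0)
  # monotone non-increasing over the full drift window
  s <- survival_probability(seq(0, 28 * 24, by = 6), cfg)
  expect_true(all(diff(s) <= 1e-12))
  # schedule validation
  expect_error(dispersal_config(weekly_mortality = c(0.25, 0.5)), "final entry 1")
})

test_that("a realised cohort loses one quarter in week one and no one outlives day 28", {
  surv <- simulate_survival(20000, seed = 1)
  expect_lt(abs(surv$dead_fraction[surv$day == 7] - 0.25), 0.01)
  expect_equal(surv$alive_fraction[surv$day == 28], 0)
})

test_that("single particle steps are analytic under uniform or zero flow", {
  cfg <- dispersal_config(mortality = FALSE)
  # uniform 0.1 m/s eastward: 360 m per hourly step
  f <- flat_field(u0 = 0.1)
  st <- list(x = 4000, y = 4000, z = 0, age = 300, status = "drifting")
  out <- step_particle(st, f, cfg, t_h = 0)
  expect_equal(out$x, 4360)
  expect_equal(out$y, 4000)
  # zero currents, neutral stage: position unchanged
  f0 <- flat_field()
  st0 <- list(x = 4000, y = 4000, z = 2, age = 200, status = "drifting")
  out0 <- step_particle(st0, f0, cfg, t_h = 0)
  expect_equal(out0$x, 4000)
  expect_equal(out0$z, 2)
  # sinking stage over 10 m water: 0.005 * 3600 = 18 m, clipped to the bed
  st2 <- list(x = 4000, y = 4000, z = 0, age = 400, status = "drifting")
  out2 <- step_particle(st2, f0, cfg, t_h = 0)
  expect_equal(out2$z, 10)
  # walking off the grid beaches the particle
  edge <- list(x = 7900, y = 4000, z = 0, age = 300, status = "drifting")
  outl <- step_particle(edge, flat_field(u0 = 0.2), cfg, t_h = 0)
  expect_equal(outl$status, "dead_beached")
})

test_that("with zero currents and immediate sinking every fragment self-recruits", {
  bay <- simulate_bay(nx = 24, ny = 24, duration_h = 24 * 32, n_patches = 3,
                      gyre_strength = 0, tidal_amplitude = 0, seed = 5)
  cfg <- dispersal_config(particles_per_release = 25, release_interval_h = 24,
                          season_days = 2, mortality = FALSE,
                          fall_velocity = c(-0.005, 0, -0.005), seed = 6)
  res <- run_dispersal(bay$field, bay$patches, cfg)
  expect_equal(unname(diag(res$probability)), rep(1, 3))
  expect_equal(res$fates$settled, res$fates$released)
})

test_that("fates are conserved and probability rows stay within one", {
  bay <- simulate_bay(nx = 24, ny = 24, duration_h = 24 * 36, n_patches = 4,
                      seed = 8)
  cfg <- dispersal_config(particles_per_release = 25, release_interval_h = 24,
                          season_days = 8, seed = 9)
  res <- run_dispersal(bay$field, bay$patches, cfg)
  with(res$fates,
       expect_equal(settled + beached + died + expired, released))
  expect_true(all(rowSums(res$probability) <= 1 + 1e-12))
  expect_true(all(res$probability >= 0))
  # flow = probability x source area, row-wise
  areas <- bay$patches$area[match(rownames(res$flow), bay$patches$patch)]
  expect_equal(res$flow, res$probability * areas)
})

test_that("with mortality on and no habitat all fragments are gone by day 28", {
  f <- flat_field(nx = 30, ny = 30, hours = 24 * 40, depth0 = 50)
  patches <- tibble::tibble(patch = "src", cell_x = c(15L, 16L),
                            cell_y = c(15L, 15L), area = 1e4)
  # settlement impossible: delay longer than the drift window
  cfg <- dispersal_config(particles_per_release = 200,
                          release_interval_h = 24, season_days = 1,
                          settlement_delay_h = 24 * 29, seed = 10)
  res <- run_dispersal(f, patches, cfg)
  expect_equal(res$fates$settled, 0)
  expect_equal(res$fates$died + res$fates$beached + res$fates$expired,
               res$fates$released)
  expect_equal(res$fates$expired, 0)  # S(28 d) = 0: none left to expire
})

test_that("flow scaling is linear and inflow is the off-diagonal column sum", {
  m <- matrix(c(0, 5, 1,
                2, 0, 4,
                3, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  inf <- relative_inflow(m)
  expect_equal(inf$inflow, c(5, 11, 5))  # hand column sums, no diagonal
  diag(m) <- 9
  expect_equal(relative_inflow(m, include_self = TRUE)$inflow[1], 5 + 9)
  expect_equal(relative_inflow(10 * m)$inflow, 10 * relative_inflow(m)$inflow)
  # single-source column
  one <- matrix(c(0, 5, 0, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(relative_inflow(one)$inflow, c(5, 0))
  expect_equal(relative_inflow(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))))$inflow, c(0, 0))
})

test_that("dispersal probabilities agree across seeds to Monte-Carlo error", {
  bay <- simulate_bay(nx = 24, ny = 24, duration_h = 24 * 36, n_patches = 3,
                      seed = 12)
  run_with <- function(s) {
    run_dispersal(bay$field, bay$patches,
      dispersal_config(particles_per_release = 60, release_interval_h = 12,
                       season_days = 8, seed = s))
  }
  r1 <- run_with(21); r2 <- run_with(22)
  n_rel <- r1$fates$released[1]
  p_bar <- (r1$probability + r2$probability) / 2
  se <- sqrt(pmax(p_bar * (1 - p_bar), 1e-9) / n_rel)
  expect_true(all(abs(r1$probability - r2$probability) <= 3 * se + 1e-9))
  # and identical seeds reproduce identical matrices
  expect_identical(run_with(21)$probability, r1$probability)
})

test_that("current fields round-trip through the stacked-CSV layout", {
  bay <- simulate_bay(nx = 20, ny = 20, duration_h = 12, n_patches = 2,
                      seed = 30)
  dir <- withr::local_tempdir()
  write_current_field(bay$field, dir)
  back <- read_current_field(dir)
  expect_equal(back$u, bay$field$u)
  expect_equal(back$depth, bay$field$depth)
  expect_equal(back$mask, bay$field$mask)
})
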