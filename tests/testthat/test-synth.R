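test_that("config validation rejects malformed scenarios", {
  expect_error(experiment_config(n_days = -1), "count|>= 1")
  expect_error(experiment_config(baseline_angle_sd = -2), "SD")
  expect_error(experiment_config(recovery_fraction = 1.3), "recovery")
  expect_error(experiment_config(wilt_onset_session = "D9E"), "session")
  expect_error(experiment_config(wilt_onset_session = "D2M"), "evening")
  expect_error(experiment_config(days_to_death_after_first_wilt = c(2, 1)),
               "increasing")
  expect_error(experiment_config(env_means = c(AH = 70)), "env")
  expect_s3_class(experiment_config(), "experiment_config")
  expect_s3_class(experiment_config(wilt_onset_session = NA,
                                    physio_effect_day = NA),
                  "experiment_config")
})

test_that("identical seed and config give bitwise identical output", {
  cfg <- tiny_config(seed = 5)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$ground_truth, e2$ground_truth)
  expect_identical(e1$env, e2$env)
  expect_identical(e1$physio, e2$physio)
  expect_identical(e1$annotations, e2$annotations)
  for (i in seq_along(e1$scenes)) {
    expect_identical(e1$scenes[[i]]$image, e2$scenes[[i]]$image)
    expect_identical(e1$thermal_maps[[i]], e2$thermal_maps[[i]])
  }
  ## different seed changes the draw
  e3 <- simulate_experiment(tiny_config(seed = 6))
  expect_false(identical(e1$ground_truth$theta_true,
                         e3$ground_truth$theta_true))
})

test_that("angle_trajectory: absorbing death, control stability, drop size", {
  cfg <- experiment_config(rng_seed = 1)
  st <- seedling_state(30)
  st$vitality <- "dead"; st$discoloration <- 0.8
  step <- angle_trajectory("drought", "D5M", st, cfg)
  expect_equal(step$state$vitality, "dead")
  expect_true(is.na(step$theta))
  expect_gte(step$state$discoloration, 0.8)

  ## control seedling at D6E: baseline distribution, no drop term
  set.seed(2)
  th <- replicate(400, angle_trajectory("control", "D6E",
                                        seedling_state(30), cfg)$theta)
  expect_lt(abs(mean(th) - 30), 3 * cfg$session_angle_sd / sqrt(400))
  expect_lt(abs(sd(th) - cfg$session_angle_sd), 1)

  ## drought draws at onset: mean BD-to-current drop matches wilt_drop_mean
  set.seed(3)
  n <- 4000
  drops <- replicate(n, {
    s <- angle_trajectory("drought", "D2E", seedling_state(30), cfg)
    30 - s$theta
  })
  se <- sqrt(cfg$wilt_drop_sd^2 + cfg$session_angle_sd^2) / sqrt(n)
  expect_lt(abs(mean(drops) - cfg$wilt_drop_mean), 3 * se)
})

test_that("vitality state machine is monotone and matches config rates", {
  cfg <- experiment_config(n_seedlings_per_treatment = 120,
                           n_imaged_per_treatment = 2, n_days = 5,
                           rng_seed = 31)
  exp <- simulate_experiment(cfg, render = FALSE)
  gt <- exp$ground_truth
  ## no dead -> alive transitions
  for (g in split(gt, gt$seedling)) {
    g <- g[order(session_info(g$session)$index), ]
    dead_at <- which(g$vitality == "dead")
    if (length(dead_at)) {
      expect_true(all(g$vitality[min(dead_at):nrow(g)] == "dead"))
    }
  }
  ## control never wilts; drought all wilt at onset
  expect_true(all(gt$vitality[gt$treatment == "control"] == "alive"))
  expect_true(all(gt$vitality[gt$treatment == "drought" &
                                gt$session == "D2E"] == "wilted"))
  ## recovery share at next morning ~ recovery_fraction
  rec <- gt[gt$treatment == "drought" & gt$session == "D3M", ]
  p <- mean(rec$vitality == "recovered")
  expect_lt(abs(p - cfg$recovery_fraction),
            3.5 * sqrt(0.7 * 0.3 / nrow(rec)))
})

test_that("null scenario leaves drought and control identical in law", {
  cfg <- experiment_config(n_seedlings_per_treatment = 200,
                           n_imaged_per_treatment = 2, n_days = 4,
                           wilt_onset_session = NA, physio_effect_day = NA,
                           rng_seed = 17)
  exp <- simulate_experiment(cfg, render = FALSE)
  gt <- exp$ground_truth
  expect_true(all(gt$vitality == "alive"))
  ## same generating distribution: group means within Monte-Carlo error
  a <- gt$theta_true[gt$treatment == "control"]
  b <- gt$theta_true[gt$treatment == "drought"]
  pooled_se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * pooled_se)
  expect_gt(stats::ks.test(a, b)$p.value, 1e-4)
})

test_that("environment series converges to the configured moments", {
  cfg <- experiment_config(n_seedlings_per_treatment = 2,
                           n_imaged_per_treatment = 2, n_days = 150,
                           rng_seed = 23)
  exp <- simulate_experiment(cfg, render = FALSE)
  env <- exp$env
  for (v in c("AH", "AT", "ST")) {
    expect_lt(abs(mean(env[[v]]) - cfg$env_means[[v]]),
              4 * cfg$env_sds[[v]] / sqrt(nrow(env)))
    expect_lt(abs(sd(env[[v]]) - cfg$env_sds[[v]]),
              0.15 * cfg$env_sds[[v]])
  }
  ## diurnal structure: morning humidity higher, morning temperature lower
  expect_gt(mean(env$AH[env$time == "M"]), mean(env$AH[env$time == "E"]))
  expect_lt(mean(env$AT[env$time == "M"]), mean(env$AT[env$time == "E"]))
})

test_that("rendered scenes: masks nonempty for living, dead tissue dark in ExG", {
  cfg <- tiny_config(seed = 12)
  exp <- simulate_experiment(cfg)
  sc <- exp$scenes[[1]]
  expect_true(all(lengths(sc$truth_pixels) > 0))
  ## each ROI holds its own seedling's pixels (mostly inside the rectangle)
  for (k in 1:4) {
    px <- sc$truth_pixels[[k]]
    cc <- ((px - 1L) %/% nrow(sc$image)) + 1L
    inside <- cc >= sc$rois$col1[k] & cc <= sc$rois$col2[k]
    expect_gt(mean(inside), 0.9)
  }
  ## dead-tissue colour sits outside the green (excess-green) plant range
  f <- 1
  dead_rgb <- (1 - f) * c(45, 140, 48) + f * c(150, 95, 40)
  exg_dead <- 2 * dead_rgb[2] - dead_rgb[1] - dead_rgb[3]
  exg_live <- 2 * 140 - 45 - 48
  expect_lt(exg_dead, 5)
  expect_gt(exg_live, 180)
})

test_that("rendered needle segments reproduce the requested mean angle", {
  ## request a +30 degree seedling and measure the rendered endpoints with
  ## the angle formula (the independent oracle)
  cfg <- experiment_config(n_seedlings_per_treatment = 2,
                           n_imaged_per_treatment = 2, n_days = 2,
                           wilt_onset_session = NA,
                           baseline_angle_mean = 30, baseline_angle_sd = 0,
                           session_angle_sd = 0, rng_seed = 41)
  exp <- simulate_experiment(cfg)
  ann <- exp$annotations[exp$annotations$rendered, ]
  measured <- needle_angle(cbind(ann$base_col, ann$base_row),
                           cbind(ann$tip_col, ann$tip_row))
  per_seedling <- tapply(measured, ann$seedling, mean)
  expect_true(all(abs(per_seedling - 30) <= 2))
  ## pixel rounding alone stays below ~1.5 degrees against the drawn truth
  expect_lt(mean(abs(measured - ann$theta_needle)), 1.5)
})

test_that("physiology departs from control only at the effect day", {
  cfg <- experiment_config(n_seedlings_per_treatment = 40,
                           n_imaged_per_treatment = 2, n_days = 7,
                           physio_effect_day = "D6", rng_seed = 19)
  exp <- simulate_experiment(cfg, render = FALSE)
  ph <- exp$physio
  pre <- ph[ph$day < 6, ]
  post <- ph[ph$day == 6, ]
  d_pre <- abs(mean(pre$PhiNPQ[pre$treatment == "drought"]) -
                 mean(pre$PhiNPQ[pre$treatment == "control"]))
  d_post <- mean(post$PhiNPQ[post$treatment == "drought"]) -
    mean(post$PhiNPQ[post$treatment == "control"])
  expect_lt(d_pre, 0.02)
  expect_gt(d_post, 0.08)
})
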