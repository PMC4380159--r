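test_that("level probabilities dilute the spike and conserve total mass", {
  p <- c(0.1, 0.1, 0.4, 0.4)
  s <- c("spike", "spike", "background", "background")
  # identity at the top level
  expect_equal(build_level_probs(p, s, 0.2, 0.2), p)
  # hand arithmetic at half the top level
  half <- build_level_probs(p, s, 0.1, 0.2)
  expect_equal(half, c(0.05, 0.05, 0.45, 0.45), tolerance = 1e-15)
  # full removal pushes all spike mass evenly onto the background
  none <- build_level_probs(p, s, 0, 0.2)
  expect_equal(none, c(0, 0, 0.5, 0.5), tolerance = 1e-15)
  expect_error(build_level_probs(p, s, 0.3, 0.2), "max_level")
})

test_that("level probabilities sum to one at every level", {
  cfg <- small_config()
  prof <- make_expression_profile(cfg)
  for (l in c(0, 0.001, 0.01, 0.05, 0.1, 0.15, 0.2)) {
    p <- build_level_probs(prof$probs, prof$species, l, 0.2)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("simulated libraries conserve depth and zero out the absent spike", {
  prof <- make_expression_profile(small_config())
  cfg <- sim_config(prof$probs, prof$species, depth = 5e4, seed = 21)
  tab <- simulate_counts(cfg)
  expect_equal(unname(library_depth(tab)), rep(5e4, 4))
  spike <- tab$species == "spike"
  expect_true(all(tab$counts[spike, 1] == 0L))  # level-0 library
  expect_identical(tab$counts, simulate_counts(cfg)$counts)  # seeded
})

test_that("multinomial marginals match the binomial mean", {
  probs <- c(0.5, 0.3, 0.15, 0.05)
  names(probs) <- paste0("Dvir\\g", 1:4)
  cfg <- sim_config(probs, rep("spike", 4), levels = c(0.2), depth = 1000,
                    seed = 1)
  draws <- vapply(1:500, function(s)
    simulate_counts(cfg, seed = s)$counts[1, 1], numeric(1))
  p <- probs[[1]]; D <- 1000
  se <- sqrt(p * (1 - p) * D) / sqrt(500)
  expect_lt(abs(mean(draws) - p * D), 3 * se)
})

test_that("a one-replicate ensemble gives percentile ranks of 0 or 100", {
  prof <- make_expression_profile(small_config())
  cfg <- sim_config(prof$probs, prof$species, depth = 2e5, n_reps = 1,
                    seed = 5)
  ens <- run_ensemble(cfg, observed = list(mean_r = 0.5, iqr_slope = 1e6))
  expect_equal(nrow(ens$metrics), 1L)
  expect_equal(unname(ens$ranks["mean_r"]), 100)   # replicate r beats 0.5
  expect_equal(unname(ens$ranks["iqr_slope"]), 0)  # nothing beats 1e6
})

test_that("percentile ranks agree with brute-force strict-greater counting", {
  prof <- make_expression_profile(small_config())
  cfg <- sim_config(prof$probs, prof$species, depth = 1e5, n_reps = 12,
                    seed = 17)
  ens0 <- run_ensemble(cfg)
  obs <- ens0$metrics$iqr_slope[5]  # an observed value equal to a replicate's
  ens <- run_ensemble(cfg, observed = list(iqr_slope = obs))
  brute <- 100 * sum(ens0$metrics$iqr_slope > obs) / nrow(ens0$metrics)
  expect_equal(unname(ens$ranks["iqr_slope"]), brute)
})

test_that("the ensemble is bit-reproducible under a fixed seed", {
  prof <- make_expression_profile(small_config())
  cfg <- sim_config(prof$probs, prof$species, depth = 1e5, n_reps = 4,
                    seed = 99)
  expect_identical(run_ensemble(cfg)$metrics, run_ensemble(cfg)$metrics)
})

test_that("ensemble slope bias shrinks as depth grows", {
  prof <- make_expression_profile(small_config(seed = 23))
  dev <- sapply(c(1e5, 1e6, 1e7), function(d) {
    cfg <- sim_config(prof$probs, prof$species, depth = d, n_reps = 10,
                      seed = 23)
    m <- run_ensemble(cfg)$metrics
    abs(mean(m$mean_slope) - 1)
  })
  # non-increasing within simulation error
  expect_true(all(diff(dev) < 0.01))
  expect_lt(dev[3], 0.005)
})

test_that("simulate() on a fit reproduces the observed design's null", {
  tab <- generate_experiment(small_config(seed = 31), run_seed = 31)
  fit <- spikelin(tab, min_count = 20)
  reps <- simulate(fit, nsim = 2, seed = 8)
  expect_length(reps, 2)
  for (r in reps) {
    expect_s3_class(r, "count_table")
    expect_equal(r$libraries$spike_fraction, tab$libraries$spike_fraction)
    expect_equal(length(unique(library_depth(r))), 1L)
  }
  expect_false(identical(reps[[1]]$counts, reps[[2]]$counts))
})
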