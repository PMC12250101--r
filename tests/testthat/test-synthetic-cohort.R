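test_that("group simulation is seed-deterministic and respects its parameters", {
  p <- zone_group_params(mean = c(46.8, 28.7, 15.2), sd = c(6.3, 4.1, 2.2))
  a <- simulate_group(p, 50, seed = 11)
  b <- simulate_group(p, 50, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_group(p, 50, seed = 12)))

  # near-degenerate SDs collapse every subject onto the mean vector
  tight <- zone_group_params(mean = c(50, 25, 15), sd = rep(1e-9, 3))
  d <- simulate_group(tight, 20, seed = 1)
  expect_equal(d$L, rep(50, 20), tolerance = 1e-6)
  expect_equal(d$a, rep(25, 20), tolerance = 1e-6)

  expect_error(zone_group_params(mean = c(1, 2, 3), sd = c(1, 0, 1)), "positive")
  expect_error(zone_group_params(mean = c(1, 2, 3), sd = c(1, 1, 1),
                                 corr = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive-definite")
})

test_that("simulated moments recover the configured parameters at large n", {
  p <- zone_group_params(mean = c(46.8, 28.7, 15.2), sd = c(6.3, 4.1, 2.2))
  d <- simulate_group(p, 10000, seed = 2)
  expect_equal(c(mean(d$L), mean(d$a), mean(d$b)), c(46.8, 28.7, 15.2),
               tolerance = 0.2 / 46)  # 0.2 absolute on the largest coordinate
  expect_lt(max(abs(c(sd(d$L), sd(d$a), sd(d$b)) - c(6.3, 4.1, 2.2))), 0.2)
  expect_true(all(d$L >= 0 & d$L <= 100))
})

test_that("paired simulation honours the within-subject correlation", {
  pre <- zone_group_params(mean = c(46.3, 27.2, 15.2), sd = c(5.7, 4.1, 2.0))
  post <- zone_group_params(mean = c(48.2, 26.5, 15.5), sd = c(4.0, 2.5, 2.2))

  # rho -> 1 limit with equal marginals: post tracks pre, paired dEab -> 0
  d1 <- simulate_paired(pre, pre, 1 - 1e-9, 200, seed = 3)
  de <- delta_e_ab(cbind(d1$L_pre, d1$a_pre, d1$b_pre),
                   cbind(d1$L_post, d1$a_post, d1$b_post))
  expect_lt(max(de), 1e-3)

  # rho = 0: variance of the paired L difference is the sum of the variances
  d0 <- simulate_paired(pre, post, 0, 40000, seed = 4)
  expect_equal(var(d0$L_pre - d0$L_post), 5.7^2 + 4.0^2, tolerance = 0.05)

  expect_identical(simulate_paired(pre, post, 0.5, 25, seed = 5),
                   simulate_paired(pre, post, 0.5, 25, seed = 5))
  expect_error(simulate_paired(pre, post, 1, 10), "rho")
})

test_that("rho calibration hits its target and is monotone", {
  pre <- zone_group_params(mean = c(46.3, 27.2, 15.2), sd = c(5.7, 4.1, 2.0))
  post <- zone_group_params(mean = c(48.2, 26.5, 15.5), sd = c(4.0, 2.5, 2.2))

  cal <- calibrate_rho(pre, post, 6.07, n_mc = 20000, seed = 6)
  expect_gt(cal$rho, 0)
  expect_lt(cal$rho, 1)
  expect_lt(abs(cal$achieved - 6.07), 0.1)
  # an independent paired draw at the calibrated rho reproduces the target
  sim <- simulate_paired(pre, post, cal$rho, 40000, seed = 7)
  de <- delta_e_ab(cbind(sim$L_pre, sim$a_pre, sim$b_pre),
                   cbind(sim$L_post, sim$a_post, sim$b_post))
  expect_lt(abs(mean(de) - 6.07), 0.15)

  # mean paired dEab is monotone non-increasing in rho (common random numbers)
  means <- sapply(c(0, 0.3, 0.6, 0.9), function(r) {
    s <- simulate_paired(pre, post, r, 20000, seed = 8)
    mean(delta_e_ab(cbind(s$L_pre, s$a_pre, s$b_pre),
                    cbind(s$L_post, s$a_post, s$b_post)))
  })
  expect_true(all(diff(means) < 0))

  # boundary: a target at the rho = 0 mean calibrates to rho ~ 0
  cal0 <- calibrate_rho(pre, post, means[1], n_mc = 20000, seed = 8)
  expect_lt(cal0$rho, 0.1)
  expect_error(calibrate_rho(pre, post, 50, n_mc = 5000, seed = 9),
               "attainable")
})

test_that("built cohorts reproduce the configured group structure exactly", {
  cfg <- simulation_config(seed = 42, rho = 0.6)
  ch <- build_cohort(cfg)
  g <- cohort_groups(ch)
  expect_equal(nrow(ch$subjects), 43)
  expect_equal(sum(g$biotype == "thin"), 18)
  expect_equal(sum(g$biotype == "thick"), 25)
  expect_equal(sum(g$plaque_group == "plaque"), 30)
  expect_equal(sum(g$plaque_group == "no_plaque"), 13)
  expect_equal(sum(g$severity_group == "moderate_severe"), 27)
  expect_equal(sum(g$severity_group == "mild"), 16)
  # 43 subjects x 4 zones x 2 timepoints x 3 replicates
  expect_equal(nrow(ch$measurements), 43 * 4 * 2 * 3)
  # aggregation consistency: site tuples always map back to assigned groups
  s <- ch$subjects
  expect_identical(
    unname(plaque_group(as.matrix(s[paste0("plaque_", c("distal_vestibular",
                                                        "vestibular",
                                                        "mesial_vestibular"))]))),
    g$plaque_group)
  grades <- as.matrix(s[paste0("grade_", c("distal_vestibular", "vestibular",
                                           "mesial_vestibular"))])
  expect_true(all(rowSums(grades) > 0))  # every subject shows inflammation
})

test_that("cohort building is deterministic and CSV output byte-identical", {
  cfg <- simulation_config(seed = 7, rho = 0.5)
  c1 <- build_cohort(cfg)
  c2 <- build_cohort(cfg)
  expect_identical(c1$measurements, c2$measurements)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1)
  write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("YAML configuration round-trips into a simulation config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 99",
    "n_thin: 4",
    "n_thick: 5",
    "n_plaque: 6",
    "n_moderate_severe: 5",
    "replicate_sd: 0.3",
    "rho:",
    "  distal_papilla: 0.5",
    "  free_gingival_margin: 0.5",
    "  middle_attached_gingiva: 0.5",
    "  mucogingival_line: 0.5"), path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$n_thin, 4)
  expect_equal(cfg$replicate_sd, 0.3)
  ch <- build_cohort(cfg)
  expect_equal(nrow(ch$subjects), 9)
  g <- cohort_groups(ch)
  expect_equal(sum(g$plaque_group == "plaque"), 6)
})
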