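test_that("cross-group pairing enumerates the full Cartesian product", {
  thin <- sprintf("T%02d", 1:18)
  thick <- sprintf("K%02d", 1:25)
  pairs <- cross_group_pairs(thin, thick)
  expect_equal(nrow(pairs), 450)
  expect_equal(nrow(cross_group_pairs("a", "b")), 1)
  # equals the brute-force double loop, in first-group-major order
  brute <- do.call(rbind, lapply(sprintf("A%d", 1:3), function(a) {
    data.frame(id_a = a, id_b = sprintf("B%d", 1:4))
  }))
  got <- cross_group_pairs(sprintf("A%d", 1:3), sprintf("B%d", 1:4))
  expect_equal(as.data.frame(got), brute, ignore_attr = TRUE)
  expect_error(cross_group_pairs(character(0), "b"), "non-empty")
  expect_error(cross_group_pairs(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("pairwise summaries match a brute-force recomputation", {
  cfg <- simulation_config(n_thin = 5, n_thick = 6, n_plaque = 7,
                           n_moderate_severe = 7, seed = 14, rho = 0.5)
  ch <- build_cohort(cfg)
  g <- cohort_groups(ch)
  pairs <- cross_group_pairs(g$subject_id[g$biotype == "thin"],
                             g$subject_id[g$biotype == "thick"])
  smry <- pairwise_difference_summary(ch, pairs, "distal_papilla", "pre", "both")
  expect_equal(nrow(smry), 2)
  expect_equal(smry$n_pairs, c(30, 30))

  de_brute <- list(eab = numeric(0), e00 = numeric(0))
  for (i in seq_len(nrow(pairs))) {
    x <- zone_value(ch, pairs$id_a[i], "distal_papilla", "pre")
    y <- zone_value(ch, pairs$id_b[i], "distal_papilla", "pre")
    de_brute$eab <- c(de_brute$eab, delta_e_ab(x, y))
    de_brute$e00 <- c(de_brute$e00, delta_e_00(x, y))
  }
  for (f in c("eab", "e00")) {
    row <- smry[smry$formula == f, ]
    expect_equal(row$mean, mean(de_brute[[f]]), tolerance = 1e-12)
    expect_equal(row$sd, sd(de_brute[[f]]), tolerance = 1e-12)
    expect_equal(row$min, min(de_brute[[f]]), tolerance = 1e-12)
    expect_equal(row$max, max(de_brute[[f]]), tolerance = 1e-12)
    th <- if (f == "eab") 3.1 else 2.1
    expect_equal(row$percent_perceptible, 100 * mean(de_brute[[f]] > th))
  }
  expect_true(all(smry$min <= smry$mean & smry$mean <= smry$max))
})

test_that("identical subjects yield all-zero summaries and no perceptible pairs", {
  ch <- tiny_cohort()
  # make B a copy of A's colours
  mA <- ch$measurements[ch$measurements$subject_id == "A", ]
  mB <- mA; mB$subject_id <- "B"
  ch$measurements <- rbind(mA, mB)
  smry <- pairwise_difference_summary(ch, cross_group_pairs("A", "B"),
                                      "distal_papilla", "pre", "both")
  expect_equal(smry$mean, c(0, 0))
  expect_equal(smry$min, c(0, 0))
  expect_equal(smry$max, c(0, 0))
  expect_equal(smry$percent_perceptible, c(0, 0))
})

test_that("paired treatment summary equals the per-subject brute force", {
  cfg <- simulation_config(n_thin = 4, n_thick = 5, n_plaque = 6,
                           n_moderate_severe = 6, seed = 15, rho = 0.7)
  ch <- build_cohort(cfg)
  smry <- paired_treatment_summary(ch, "free_gingival_margin", "both")
  expect_equal(smry$n_pairs, c(9, 9))
  de <- sapply(ch$subjects$subject_id, function(id) {
    delta_e_ab(zone_value(ch, id, "free_gingival_margin", "pre"),
               zone_value(ch, id, "free_gingival_margin", "post"))
  })
  expect_equal(smry$mean[smry$formula == "eab"], mean(de), tolerance = 1e-12)
  expect_equal(smry$max[smry$formula == "eab"], max(de), tolerance = 1e-12)
})

test_that("coordinate comparisons have the 4x3 structure and find planted effects", {
  set.seed(16)
  cfg <- simulation_config(seed = 16, rho = 0.5)
  ch <- build_cohort(cfg)
  cmp <- coordinate_comparisons(ch, "biotype")
  expect_equal(nrow(cmp), 12)
  expect_equal(as.integer(table(cmp$zone)), rep(3L, 4))
  expect_identical(unique(cmp$group1), "thin")

  # plant a large L* separation between biotypes and expect significance
  params <- reference_color_params("biotype")
  params$mean[params$group == "thin" & params$coord == "L"] <-
    params$mean[params$group == "thin" & params$coord == "L"] + 12
  cfg2 <- simulation_config(seed = 17, rho = 0.5, biotype_params = params)
  ch2 <- build_cohort(cfg2)
  cmp2 <- coordinate_comparisons(ch2, "biotype")
  lrows <- cmp2[cmp2$coord == "L", ]
  expect_true(all(lrows$significant))
  expect_true(all(lrows$d_band == "large"))
})

test_that("treatment comparisons recover a planted lightening with negative d", {
  params <- reference_color_params("treatment")
  # exaggerate the post-treatment lightening at the distal papilla
  params$mean[params$group == "post" & params$coord == "L" &
                params$zone == "distal_papilla"] <- 54
  cfg <- simulation_config(seed = 18, rho = 0.8, treatment_params = params)
  ch <- build_cohort(cfg)
  cmp <- treatment_comparisons(ch)
  expect_equal(nrow(cmp), 12)
  dp_L <- cmp[cmp$zone == "distal_papilla" & cmp$coord == "L", ]
  expect_true(dp_L$significant)
  expect_lt(dp_L$d, 0)  # pre - post convention: lightening is negative
})

test_that("subgroup invariance is null for identically treated subgroups", {
  cfg <- simulation_config(seed = 19, rho = 0.6)
  ch <- build_cohort(cfg)
  inv <- subgroup_invariance(ch, "biotype", "both")
  expect_equal(nrow(inv), 8)
  expect_equal(as.integer(table(inv$formula)), rep(4L, 2))
  # both biotypes share the same treatment process: effects should be small
  expect_true(all(abs(inv$d) < 1.5))
})

test_that("run_study writes a complete, deterministic, internally consistent bundle", {
  cfg <- simulation_config(seed = 20, rho = 0.6)
  ch <- build_cohort(cfg)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  tables <- run_study(ch, out1)
  run_study(ch, out2)

  expected_files <- c("group_coordinates_biotype.csv",
                      "pairwise_differences_biotype.csv",
                      "group_coordinates_plaque.csv",
                      "group_coordinates_severity.csv",
                      "treatment_coordinates.csv", "treatment_differences.csv",
                      "percent_perceptible.csv", "invariance_biotype.csv",
                      "invariance_severity.csv", "run_log.txt")
  expect_setequal(list.files(out1), expected_files)
  for (f in setdiff(expected_files, "run_log.txt")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }

  # integration: bundle tables equal direct module calls
  g <- cohort_groups(ch)
  pairs <- cross_group_pairs(g$subject_id[g$biotype == "thin"],
                             g$subject_id[g$biotype == "thick"])
  direct <- pairwise_difference_summary(ch, pairs, "distal_papilla", "pre", "both")
  bundled <- tables$pairwise_differences_biotype
  bundled <- bundled[bundled$zone == "distal_papilla", ]
  expect_equal(as.data.frame(bundled), as.data.frame(direct), ignore_attr = TRUE)
  expect_equal(nrow(tables$percent_perceptible), 16)  # 2 analyses x 4 zones x 2 formulas
  expect_true(all(tables$percent_perceptible$percent_perceptible >= 0 &
                    tables$percent_perceptible$percent_perceptible <= 100))
})

test_that("the command-line interface drives simulate and analyze end-to-end", {
  cli <- system.file("cli", "gingicol.R", package = "gingicol")
  expect_true(nzchar(cli))
  tmp <- withr::local_tempdir()
  cohort_csv <- file.path(tmp, "cohort.csv")
  cfg <- file.path(tmp, "cfg.yaml")
  writeLines(c("seed: 5", "n_thin: 4", "n_thick: 5", "n_plaque: 6",
               "n_moderate_severe: 5",
               "rho: {distal_papilla: 0.5, free_gingival_margin: 0.5,",
               "      middle_attached_gingiva: 0.5, mucogingival_line: 0.5}"), cfg)
  res <- system2("Rscript", c(cli, "simulate", "--config", cfg,
                              "--out", cohort_csv), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(cohort_csv))
  out_dir <- file.path(tmp, "report")
  system2("Rscript", c(cli, "analyze", "--cohort", cohort_csv, "--out", out_dir),
          stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "percent_perceptible.csv")))
})
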