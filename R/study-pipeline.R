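#' All cross-group subject pairs
#'
#' Forms the full Cartesian product of two disjoint subject groups in
#' deterministic order (first-group index major). With the reference group
#' sizes (18 thin x 25 thick) this yields the 450 cross-biotype pairs whose
#' colour differences quantify the biotype effect.
#'
#' @param group_a,group_b Character vectors of subject ids; must be
#'   disjoint and non-empty.
#' @return Tibble `id_a`, `id_b` with `length(group_a) * length(group_b)`
#'   rows.
#' @export
cross_group_pairs <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  g <- expand.grid(id_b = group_b, id_a = group_a, stringsAsFactors = FALSE)
  tibble::tibble(id_a = g$id_a, id_b = g$id_b)
}

summary_row <- function(zone, formula, de, threshold) {
  tibble::tibble(
    zone = zone, formula = formula, n_pairs = length(de),
    mean = mean(de), sd = stats::sd(de), min = min(de), max = max(de),
    percent_perceptible = 100 * mean(de > threshold)
  )
}

de_for_formula <- function(x, y, formula) {
  switch(formula, eab = delta_e_ab(x, y), e00 = delta_e_00(x, y),
         stop("formula must be 'eab' or 'e00'", call. = FALSE))
}

#' Summarise colour differences over cross-group pairs
#'
#' Computes the chosen colour-difference formula between the replicate-
#' averaged zone colours of every pair and summarises: mean, SD, min, max
#' and the percentage of pairs strictly above the perceptibility threshold
#' (same pair set for the moments and the percentage). Pairs in which either
#' subject lacks the zone/timepoint cell are excluded listwise and the count
#' reported via `message()`.
#'
#' @param cohort A [gingival_cohort()].
#' @param pairs Tibble `id_a`, `id_b` from [cross_group_pairs()].
#' @param zone One gingival zone.
#' @param timepoint `"pre"` (default; inflamed baseline) or `"post"`.
#' @param formula `"eab"`, `"e00"`, or `"both"`.
#' @param thresholds A [perceptibility_thresholds()].
#' @return Tibble with one row per formula: `zone`, `formula`, `n_pairs`,
#'   `mean`, `sd`, `min`, `max`, `percent_perceptible`.
#' @export
pairwise_difference_summary <- function(cohort, pairs, zone,
                                        timepoint = c("pre", "post"),
                                        formula = c("both", "eab", "e00"),
                                        thresholds = perceptibility_thresholds()) {
  timepoint <- match.arg(timepoint)
  formula <- match.arg(formula)
  zone <- as_gingival_zone(zone)
  zv <- suppressMessages(zone_values(cohort, zone, timepoint))
  ok <- pairs$id_a %in% zv$subject_id & pairs$id_b %in% zv$subject_id
  if (any(!ok)) {
    message(sprintf("pairwise_difference_summary: excluding %d pair(s) with missing (%s, %s) data",
                    sum(!ok), zone, timepoint))
  }
  pairs <- pairs[ok, ]
  if (!nrow(pairs)) stop("no complete pairs at this zone/timepoint", call. = FALSE)
  x <- zv[match(pairs$id_a, zv$subject_id), c("L", "a", "b")]
  y <- zv[match(pairs$id_b, zv$subject_id), c("L", "a", "b")]
  formulas <- if (formula == "both") c("eab", "e00") else formula
  out <- lapply(formulas, function(f) {
    th <- if (f == "eab") thresholds$t_eab else thresholds$t_e00
    summary_row(zone, f, de_for_formula(x, y, f), th)
  })
  do.call(rbind, out)
}

#' Summarise per-subject pre/post treatment colour differences
#'
#' Computes, for each subject with both timepoints at the zone, the colour
#' difference between their pre- and post-treatment replicate-averaged
#' colours, and summarises exactly as [pairwise_difference_summary()]
#' (`n_pairs` = number of subjects).
#'
#' @inheritParams pairwise_difference_summary
#' @return Tibble with one row per formula.
#' @export
paired_treatment_summary <- function(cohort, zone,
                                     formula = c("both", "eab", "e00"),
                                     thresholds = perceptibility_thresholds()) {
  formula <- match.arg(formula)
  zone <- as_gingival_zone(zone)
  pre <- suppressMessages(zone_values(cohort, zone, "pre"))
  post <- suppressMessages(zone_values(cohort, zone, "post"))
  ids <- intersect(pre$subject_id, post$subject_id)
  dropped <- length(unique(c(pre$subject_id, post$subject_id))) - length(ids)
  if (dropped > 0) {
    message(sprintf("paired_treatment_summary: excluding %d subject(s) missing a timepoint at %s",
                    dropped, zone))
  }
  if (!length(ids)) stop("no subjects with both timepoints at this zone", call. = FALSE)
  x <- pre[match(ids, pre$subject_id), c("L", "a", "b")]
  y <- post[match(ids, post$subject_id), c("L", "a", "b")]
  formulas <- if (formula == "both") c("eab", "e00") else formula
  out <- lapply(formulas, function(f) {
    th <- if (f == "eab") thresholds$t_eab else thresholds$t_e00
    summary_row(zone, f, de_for_formula(x, y, f), th)
  })
  do.call(rbind, out)
}

#' Zone-by-coordinate group comparisons
#'
#' For every zone and CIELAB coordinate, compares the two levels of a
#' grouping factor (biotype, plaque, or severity) with the pooled-variance
#' unpaired t-test and Cohen's d. Degenerate-variance cells propagate as
#' `NA` rows rather than failing the whole analysis.
#'
#' @param cohort A [gingival_cohort()].
#' @param grouping `"biotype"`, `"plaque"`, or `"severity"`.
#' @param timepoint `"pre"` (default) or `"post"`.
#' @return Tibble of 4 zones x 3 coordinates = 12 rows; columns `zone`,
#'   `coord` plus the [unpaired_t_cohen()] columns.
#' @export
coordinate_comparisons <- function(cohort,
                                   grouping = c("biotype", "plaque", "severity"),
                                   timepoint = c("pre", "post")) {
  grouping <- match.arg(grouping)
  timepoint <- match.arg(timepoint)
  g <- cohort_groups(cohort)
  lv <- switch(grouping,
               biotype = list(col = g$biotype, levels = c("thin", "thick")),
               plaque = list(col = g$plaque_group, levels = c("plaque", "no_plaque")),
               severity = list(col = g$severity_group,
                               levels = c("moderate_severe", "mild")))
  ids1 <- g$subject_id[lv$col == lv$levels[1]]
  ids2 <- g$subject_id[lv$col == lv$levels[2]]
  if (!length(ids1) || !length(ids2)) {
    stop("both grouping levels must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (z in gingival_zones()) {
    zv <- suppressMessages(zone_values(cohort, z, timepoint))
    for (coord in c("L", "a", "b")) {
      x <- zv[[coord]][zv$subject_id %in% ids1]
      y <- zv[[coord]][zv$subject_id %in% ids2]
      cmp <- tryCatch(unpaired_t_cohen(x, y, labels = lv$levels),
                      error = function(e) degenerate_row(lv$levels, x, y))
      rows[[length(rows) + 1L]] <- cbind(tibble::tibble(zone = z, coord = coord), cmp)
    }
  }
  do.call(rbind, rows)
}

degenerate_row <- function(labels, x, y) {
  tibble::tibble(group1 = labels[1], group2 = labels[2],
                 n1 = length(x), n2 = length(y),
                 mean1 = mean(x), sd1 = stats::sd(x),
                 mean2 = mean(y), sd2 = stats::sd(y),
                 t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
                 d_band = NA_character_, significant = NA, method = "degenerate")
}

#' Zone-by-coordinate pre/post treatment comparisons
#'
#' Paired t-test and Cohen's d (pre - post convention: lightening after
#' treatment gives negative d) for every zone and coordinate.
#'
#' @param cohort A [gingival_cohort()] with both timepoints.
#' @return Tibble of 12 rows; columns `zone`, `coord` plus the
#'   [paired_t_cohen()] columns.
#' @export
treatment_comparisons <- function(cohort) {
  rows <- list()
  for (z in gingival_zones()) {
    pre <- suppressMessages(zone_values(cohort, z, "pre"))
    post <- suppressMessages(zone_values(cohort, z, "post"))
    ids <- intersect(pre$subject_id, post$subject_id)
    for (coord in c("L", "a", "b")) {
      x <- pre[[coord]][match(ids, pre$subject_id)]
      y <- post[[coord]][match(ids, post$subject_id)]
      cmp <- tryCatch(paired_t_cohen(x, y),
                      error = function(e) degenerate_row(c("pre", "post"), x, y))
      rows[[length(rows) + 1L]] <- cbind(tibble::tibble(zone = z, coord = coord), cmp)
    }
  }
  do.call(rbind, rows)
}

#' Subgroup invariance of the treatment colour change
#'
#' Tests whether the magnitude of the per-subject pre/post colour difference
#' depends on a subgroup factor: for each zone (and formula), the
#' per-subject treatment dE values are compared between the two subgroup
#' levels with the unpaired t-test. A non-significant result means the
#' chromatic response to treatment is invariant to that factor.
#'
#' @param cohort A [gingival_cohort()] with both timepoints.
#' @param factor `"biotype"` or `"severity"`.
#' @param formula `"eab"`, `"e00"`, or `"both"`.
#' @return Tibble with one row per zone x formula; columns `zone`,
#'   `formula` plus the [unpaired_t_cohen()] columns.
#' @export
subgroup_invariance <- function(cohort, factor = c("biotype", "severity"),
                                formula = c("both", "eab", "e00")) {
  factor <- match.arg(factor)
  formula <- match.arg(formula)
  g <- cohort_groups(cohort)
  lv <- switch(factor,
               biotype = list(col = g$biotype, levels = c("thin", "thick")),
               severity = list(col = g$severity_group,
                               levels = c("moderate_severe", "mild")))
  formulas <- if (formula == "both") c("eab", "e00") else formula
  rows <- list()
  for (z in gingival_zones()) {
    pre <- suppressMessages(zone_values(cohort, z, "pre"))
    post <- suppressMessages(zone_values(cohort, z, "post"))
    ids <- intersect(pre$subject_id, post$subject_id)
    x <- pre[match(ids, pre$subject_id), c("L", "a", "b")]
    y <- post[match(ids, post$subject_id), c("L", "a", "b")]
    grp <- lv$col[match(ids, g$subject_id)]
    for (f in formulas) {
      de <- de_for_formula(x, y, f)
      cmp <- tryCatch(
        unpaired_t_cohen(de[grp == lv$levels[1]], de[grp == lv$levels[2]],
                         labels = lv$levels),
        error = function(e) degenerate_row(lv$levels, de[grp == lv$levels[1]],
                                           de[grp == lv$levels[2]]))
      rows[[length(rows) + 1L]] <- cbind(tibble::tibble(zone = z, formula = f), cmp)
    }
  }
  do.call(rbind, rows)
}

#' Run the full study analysis and write a report bundle
#'
#' Orchestrates the three analysis stages end-to-end from a cohort (object
#' or CSV path): (1) biotype effect on inflamed gingiva -- per-coordinate
#' group comparisons and the cross-biotype pairwise colour-difference
#' summary; (2) plaque and severity effects -- per-coordinate group
#' comparisons; (3) treatment effect -- paired per-coordinate comparisons,
#' per-subject pre/post colour-difference summaries, the percent-perceptible
#' table, and the subgroup-invariance tests by biotype and severity. Writes
#' one tidy CSV per table plus a run log and returns the tables invisibly.
#'
#' @param cohort A [gingival_cohort()] or a path to a cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [perceptibility_thresholds()].
#' @return Invisibly, a named list of the tables written.
#' @export
run_study <- function(cohort, out_dir,
                      thresholds = perceptibility_thresholds()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "gingival_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  g <- cohort_groups(cohort)
  pairs <- cross_group_pairs(g$subject_id[g$biotype == "thin"],
                             g$subject_id[g$biotype == "thick"])

  biotype_pairwise <- do.call(rbind, lapply(gingival_zones(), function(z) {
    pairwise_difference_summary(cohort, pairs, z, "pre", "both", thresholds)
  }))
  treatment_pairwise <- do.call(rbind, lapply(gingival_zones(), function(z) {
    paired_treatment_summary(cohort, z, "both", thresholds)
  }))
  percent_perceptible <- rbind(
    cbind(tibble::tibble(analysis = "biotype_pairs"),
          biotype_pairwise[c("zone", "formula", "n_pairs", "percent_perceptible")]),
    cbind(tibble::tibble(analysis = "treatment"),
          treatment_pairwise[c("zone", "formula", "n_pairs", "percent_perceptible")]))

  tables <- list(
    group_coordinates_biotype = coordinate_comparisons(cohort, "biotype"),
    pairwise_differences_biotype = biotype_pairwise,
    group_coordinates_plaque = coordinate_comparisons(cohort, "plaque"),
    group_coordinates_severity = coordinate_comparisons(cohort, "severity"),
    treatment_coordinates = treatment_comparisons(cohort),
    treatment_differences = treatment_pairwise,
    percent_perceptible = percent_perceptible,
    invariance_biotype = subgroup_invariance(cohort, "biotype"),
    invariance_severity = subgroup_invariance(cohort, "severity")
  )
  for (nm in names(tables)) {
    utils::write.csv(round_numeric(tables[[nm]]),
                     file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  }

  n_tests <- sum(vapply(tables[c("group_coordinates_biotype",
                                 "group_coordinates_plaque",
                                 "group_coordinates_severity",
                                 "treatment_coordinates",
                                 "invariance_biotype", "invariance_severity")],
                        nrow, integer(1)))
  log_lines <- c(
    "gingicol run_study log",
    sprintf("subjects: %d (%d thin / %d thick)", nrow(cohort$subjects),
            sum(g$biotype == "thin"), sum(g$biotype == "thick")),
    sprintf("plaque groups: %d/%d; severity groups: %d/%d",
            sum(g$plaque_group == "plaque"), sum(g$plaque_group == "no_plaque"),
            sum(g$severity_group == "moderate_severe"),
            sum(g$severity_group == "mild")),
    sprintf("thresholds: dEab > %g, dE00 > %g", thresholds$t_eab, thresholds$t_e00),
    sprintf("statistical tests performed: %d (alpha = 0.05, no multiplicity adjustment)",
            n_tests),
    if (length(cohort$provenance)) {
      sprintf("provenance: %s", paste(names(cohort$provenance),
                                      unlist(cohort$provenance),
                                      sep = "=", collapse = ", "))
    } else "provenance: unspecified"
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(tables)
}

# percentages to one decimal, colour differences and statistics to two --
# matching the precision the tables are reported at
round_numeric <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      digits <- if (nm == "percent_perceptible") 1L
      else if (nm == "p") 4L
      else 2L
      df[[nm]] <- round(df[[nm]], digits)
    }
  }
  df
}
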