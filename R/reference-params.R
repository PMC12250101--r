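#' Published zone/group colour parameters
#'
#' Zone-wise CIELAB means and standard deviations of inflamed gingiva as
#' published for each grouping of the reference cohort (n = 43): by gingival
#' biotype (18 thin / 25 thick), by plaque status under the all-three-sites
#' rule (30 plaque / 13 no-plaque), by inflammation severity under the
#' two-of-three rule (27 moderate-severe / 16 mild), and by treatment
#' timepoint (pre vs four weeks post debridement, n = 43 paired). These are
#' the default calibration targets of the synthetic-cohort generator.
#'
#' @param grouping One of `"biotype"`, `"plaque"`, `"severity"`,
#'   `"treatment"`.
#' @return A tibble with columns `zone`, `group`, `coord` (`"L"`, `"a"`,
#'   `"b"`), `mean`, `sd`.
#' @export
reference_color_params <- function(grouping = c("biotype", "plaque",
                                                "severity", "treatment")) {
  grouping <- match.arg(grouping)
  zones <- c("distal_papilla", "mucogingival_line",
             "middle_attached_gingiva", "free_gingival_margin")
  # rows per zone in the order above; per group: L, a, b as mean/sd pairs
  tables <- list(
    biotype = list(
      groups = c("thin", "thick"),
      n = c(thin = 18L, thick = 25L),
      values = rbind(
        c(46.8, 6.3, 28.7, 4.1, 15.2, 2.2,  46.1, 5.3, 26.0, 3.9, 15.2, 1.8),
        c(48.8, 5.2, 27.2, 5.2, 16.5, 2.5,  49.2, 4.8, 25.5, 2.4, 15.2, 2.1),
        c(50.4, 5.4, 26.9, 4.7, 16.9, 2.0,  49.6, 5.0, 25.9, 3.4, 15.6, 2.2),
        c(49.6, 6.3, 28.7, 4.9, 17.0, 1.9,  48.2, 6.5, 25.9, 3.7, 16.5, 1.9))),
    plaque = list(
      groups = c("plaque", "no_plaque"),
      n = c(plaque = 30L, no_plaque = 13L),
      values = rbind(
        c(46.3, 5.9, 28.0, 3.9, 15.0, 2.1,  46.5, 5.4, 25.2, 4.1, 15.7, 1.6),
        c(48.6, 5.0, 26.8, 4.2, 15.7, 2.7,  49.9, 4.9, 24.9, 2.8, 15.9, 1.7),
        c(49.7, 5.0, 27.0, 3.8, 16.0, 2.2,  50.5, 5.7, 24.8, 4.2, 16.4, 2.0),
        c(48.8, 5.8, 28.1, 4.2, 16.7, 2.0,  48.8, 7.8, 24.7, 4.1, 16.8, 1.8))),
    severity = list(
      groups = c("moderate_severe", "mild"),
      n = c(moderate_severe = 27L, mild = 16L),
      values = rbind(
        c(44.1, 6.2, 27.6, 4.2, 15.1, 1.7,  50.1, 6.2, 26.4, 4.0, 15.4, 2.5),
        c(47.2, 3.7, 26.2, 4.0, 15.5, 2.6,  52.0, 5.3, 26.2, 3.7, 16.1, 1.9),
        c(47.5, 3.6, 27.0, 3.9, 16.1, 2.4,  54.0, 4.8, 25.2, 3.9, 16.2, 1.6),
        c(46.1, 5.2, 27.6, 4.3, 16.8, 2.1,  53.4, 5.7, 26.1, 4.6, 16.5, 1.7))),
    treatment = list(
      groups = c("pre", "post"),
      n = c(pre = 43L, post = 43L),
      values = rbind(
        c(46.3, 5.7, 27.2, 4.1, 15.2, 2.0,  48.2, 4.0, 26.5, 2.5, 15.5, 2.2),
        c(49.0, 4.9, 26.2, 3.9, 15.8, 2.4,  49.7, 3.5, 26.2, 3.4, 15.6, 2.1),
        c(49.9, 5.2, 26.4, 4.0, 16.1, 2.2,  49.9, 3.9, 26.6, 3.4, 15.6, 2.2),
        c(48.8, 6.4, 27.1, 4.4, 16.7, 1.9,  50.7, 3.5, 26.5, 3.4, 16.9, 2.3)))
  )
  tb <- tables[[grouping]]
  rows <- expand.grid(coord = c("L", "a", "b"), zone = zones,
                      group = tb$groups, stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(seq_along(tb$groups), function(g) {
    do.call(rbind, lapply(seq_along(zones), function(z) {
      v <- tb$values[z, ((g - 1) * 6 + 1):(g * 6)]
      cbind(mean = v[c(1, 3, 5)], sd = v[c(2, 4, 6)])
    }))
  }))
  out <- tibble::tibble(zone = rows$zone, group = rows$group,
                        coord = rows$coord, mean = vals[, "mean"],
                        sd = vals[, "sd"])
  attr(out, "group_n") <- tb$n
  out
}

#' Published pre/post mean colour differences
#'
#' Zone-wise mean per-subject colour differences between pre- and
#' post-treatment gingiva (n = 43) under each formula, used as calibration
#' targets for the within-subject pre/post correlation of the synthetic
#' generator (see [calibrate_rho()]).
#'
#' @return A tibble `zone`, `formula` (`"eab"`/`"e00"`), `mean_de`.
#' @export
reference_treatment_deltas <- function() {
  zones <- c("distal_papilla", "mucogingival_line",
             "middle_attached_gingiva", "free_gingival_margin")
  tibble::tibble(
    zone = rep(zones, 2),
    formula = rep(c("eab", "e00"), each = 4),
    mean_de = c(6.07, 4.73, 5.20, 5.73, 4.51, 3.41, 3.77, 4.30)
  )
}

# zone/group slice of a reference table as a zone_group_params object
params_slice <- function(tbl, zone_id, group_id) {
  r <- tbl[tbl$zone == zone_id & tbl$group == group_id, ]
  r <- r[match(c("L", "a", "b"), r$coord), ]
  zone_group_params(mean = stats::setNames(r$mean, c("L", "a", "b")),
                    sd = stats::setNames(r$sd, c("L", "a", "b")))
}
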