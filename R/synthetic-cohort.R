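#' Distribution parameters for one zone/group cell
#'
#' The generator models the replicate-averaged CIELAB triplet of a
#' zone/group cell as multivariate normal. Only means and SDs are published,
#' so normality is the minimal assumption consistent with the t-tests used
#' downstream; cross-coordinate correlation defaults to none (identity) and
#' is configurable for sensitivity analysis.
#'
#' @param mean Named numeric `c(L, a, b)` of coordinate means.
#' @param sd Named numeric `c(L, a, b)` of coordinate SDs, all > 0.
#' @param corr Optional 3x3 cross-coordinate correlation matrix (symmetric
#'   positive-definite, unit diagonal). Default identity.
#' @return An object of class `zone_group_params`.
#' @export
zone_group_params <- function(mean, sd, corr = NULL) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != 3L || length(sd) != 3L) {
    stop("mean and sd must each have 3 components (L, a, b)", call. = FALSE)
  }
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0)) {
    stop("means must be finite and SDs strictly positive", call. = FALSE)
  }
  if (is.null(corr)) corr <- diag(3)
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr))) ||
      !isTRUE(all.equal(unname(diag(corr)), rep(1, 3))) ||
      any(eigen(corr, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("corr must be symmetric positive-definite with unit diagonal",
         call. = FALSE)
  }
  structure(list(mean = stats::setNames(mean, c("L", "a", "b")),
                 sd = stats::setNames(sd, c("L", "a", "b")), corr = corr),
            class = "zone_group_params")
}

# multivariate-normal CIELAB draws; out-of-range L* rows are resampled
# (not truncated) so configured means are preserved
draw_lab <- function(n, params) {
  sigma <- diag(params$sd) %*% params$corr %*% diag(params$sd)
  m <- MASS::mvrnorm(n, mu = params$mean, Sigma = sigma)
  if (n == 1L) m <- matrix(m, nrow = 1L)
  for (i in seq_len(100)) {
    bad <- m[, 1] < 0 | m[, 1] > 100
    if (!any(bad)) break
    m[bad, ] <- MASS::mvrnorm(sum(bad), mu = params$mean, Sigma = sigma)
  }
  colnames(m) <- c("L", "a", "b")
  m
}

#' Simulate one group's zone colours
#'
#' Draws `n` subjects' replicate-averaged colours, independently per zone,
#' from the multivariate normal defined by `params`.
#'
#' @param params A single [zone_group_params()] (one zone) or a named list
#'   of them keyed by zone.
#' @param n Number of subjects.
#' @param seed Optional integer seed (set when supplied; pass `NULL` to
#'   continue the current RNG stream).
#' @return Tibble `subject`, `zone`, `L`, `a`, `b`.
#' @export
simulate_group <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "zone_group_params")) params <- list(zone = params)
  out <- lapply(names(params), function(z) {
    m <- draw_lab(n, params[[z]])
    tibble::tibble(subject = seq_len(n), zone = z,
                   L = m[, "L"], a = m[, "a"], b = m[, "b"])
  })
  do.call(rbind, out)
}

#' Simulate paired pre/post colours for one zone
#'
#' Per subject and coordinate, the (pre, post) pair is drawn from a
#' bivariate normal with the supplied marginals and within-subject
#' correlation `rho`; coordinates are mutually independent unless the
#' params say otherwise.
#'
#' @param pre,post [zone_group_params()] of the pre- and post-treatment
#'   marginals.
#' @param rho Within-subject pre/post correlation, in `[0, 1)`.
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return Tibble `subject`, `L_pre`, `a_pre`, `b_pre`, `L_post`, `a_post`,
#'   `b_post`.
#' @export
simulate_paired <- function(pre, post, rho, n, seed = NULL) {
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  z1 <- draw_std_triplets(n)
  z2 <- draw_std_triplets(n)
  pair <- paired_from_z(pre, post, rho, z1, z2)
  tibble::tibble(subject = seq_len(n),
                 L_pre = pair$pre[, 1], a_pre = pair$pre[, 2], b_pre = pair$pre[, 3],
                 L_post = pair$post[, 1], a_post = pair$post[, 2], b_post = pair$post[, 3])
}

draw_std_triplets <- function(n) matrix(stats::rnorm(3 * n), ncol = 3)

# deterministic transform of standard-normal draws into a correlated
# pre/post pair; shared by simulate_paired and calibrate_rho (common random
# numbers make the calibration objective smooth in rho)
paired_from_z <- function(pre, post, rho, z1, z2) {
  pre_m <- sweep(sweep(z1, 2, pre$sd, `*`), 2, pre$mean, `+`)
  zc <- rho * z1 + sqrt(1 - rho^2) * z2
  post_m <- sweep(sweep(zc, 2, post$sd, `*`), 2, post$mean, `+`)
  list(pre = pre_m, post = post_m)
}

#' Calibrate the within-subject pre/post correlation
#'
#' The published pre/post difference statistics imply a within-subject
#' correlation whose exact value is unrecoverable from summary tables.
#' `calibrate_rho` makes the dependence explicit: it finds, by bisection on
#' `rho` in `[0, 1)`, the correlation at which the Monte-Carlo mean paired
#' Euclidean colour difference matches a target (e.g. a published zone mean)
#' to within `tol`. The mean paired difference is monotone non-increasing in
#' `rho`, and common random numbers across evaluations make the objective
#' smooth.
#'
#' @inheritParams simulate_paired
#' @param target_mean_de Target mean paired dEab; must lie within the range
#'   attainable as `rho` sweeps `[0, 1)`.
#' @param n_mc Monte-Carlo sample size per evaluation. Default 20000.
#' @param seed Integer seed for the common random numbers.
#' @param tol Calibration tolerance on the achieved mean. Default 0.1.
#' @return List with `rho`, `achieved` (Monte-Carlo mean at `rho`), and
#'   `attainable` (the `c(min, max)` mean over the rho range).
#' @export
calibrate_rho <- function(pre, post, target_mean_de, n_mc = 20000, seed = 1,
                          tol = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  z1 <- draw_std_triplets(n_mc)
  z2 <- draw_std_triplets(n_mc)
  mean_de <- function(rho) {
    pair <- paired_from_z(pre, post, rho, z1, z2)
    mean(sqrt(rowSums((pair$pre - pair$post)^2)))
  }
  hi_rho <- 1 - 1e-6
  f0 <- mean_de(0)
  f1 <- mean_de(hi_rho)
  if (target_mean_de > f0 + tol || target_mean_de < f1 - tol) {
    stop(sprintf(paste0("calibration target %.3f outside the attainable mean ",
                        "paired dEab range [%.3f, %.3f]"),
                 target_mean_de, f1, f0), call. = FALSE)
  }
  lo <- 0; hi <- hi_rho
  achieved <- f0
  rho <- 0
  for (i in seq_len(80)) {
    rho <- (lo + hi) / 2
    achieved <- mean_de(rho)
    if (abs(achieved - target_mean_de) <= tol / 4) break
    if (achieved > target_mean_de) lo <- rho else hi <- rho
  }
  if (abs(achieved - target_mean_de) > tol) {
    stop(sprintf("calibration failed: best mean %.3f vs target %.3f (tol %.3f)",
                 achieved, target_mean_de, tol), call. = FALSE)
  }
  list(rho = rho, achieved = achieved, attainable = c(f1, f0))
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of [build_cohort()]. Defaults reproduce the reference
#' cohort structure: 43 subjects (18 thin / 25 thick biotype), 30/13 plaque
#' groups and 27/16 severity groups under the clinical aggregation rules,
#' pre-treatment colours drawn biotype-conditionally from the published
#' zone parameters, and post-treatment colours correlated within subject
#' with `rho` calibrated per zone to the published mean pre/post colour
#' differences.
#'
#' @param n_thin,n_thick Biotype group sizes. Defaults 18 / 25.
#' @param n_plaque Subjects with plaque at all three sites. Default 30.
#' @param n_moderate_severe Subjects with moderate-or-severe inflammation at
#'   two or more sites. Default 27.
#' @param biotype_params,treatment_params Parameter tibbles in the format of
#'   [reference_color_params()].
#' @param rho Named numeric of per-zone within-subject pre/post
#'   correlations, or `NULL` (default) to calibrate each zone to
#'   `delta_targets` at build time.
#' @param delta_targets Tibble `zone`, `mean_de` of target mean paired dEab
#'   values used when `rho` is `NULL`. Default: the published zone means.
#' @param replicate_sd SD of independent replicate measurement noise per
#'   coordinate. Default 0.5.
#' @param n_replicates Replicate measurements per zone/timepoint. Default 3.
#' @param calib_n_mc Monte-Carlo size for [calibrate_rho()]. Default 20000.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_thin = 18, n_thick = 25, n_plaque = 30,
                              n_moderate_severe = 27,
                              biotype_params = reference_color_params("biotype"),
                              treatment_params = reference_color_params("treatment"),
                              rho = NULL,
                              delta_targets = NULL,
                              replicate_sd = 0.5, n_replicates = 3,
                              calib_n_mc = 20000, seed) {
  if (missing(seed) || !is.finite(seed)) {
    stop("a numeric seed is mandatory for reproducibility", call. = FALSE)
  }
  n <- n_thin + n_thick
  if (n_plaque > n || n_moderate_severe > n) {
    stop("group counts exceed the cohort size", call. = FALSE)
  }
  if (!is.null(rho) && (any(rho < 0) || any(rho >= 1))) {
    stop("rho values must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(delta_targets)) {
    dt <- reference_treatment_deltas()
    delta_targets <- dt[dt$formula == "eab", c("zone", "mean_de")]
  }
  structure(list(n_thin = n_thin, n_thick = n_thick, n_plaque = n_plaque,
                 n_moderate_severe = n_moderate_severe,
                 biotype_params = biotype_params,
                 treatment_params = treatment_params,
                 rho = rho, delta_targets = delta_targets,
                 replicate_sd = replicate_sd, n_replicates = n_replicates,
                 calib_n_mc = calib_n_mc, seed = as.integer(seed)),
            class = "simulation_config")
}

# split an integer total into parts proportional to `prop` (sums preserved)
proportional_counts <- function(total, prop) {
  prop <- prop / sum(prop)
  diff(c(0, round(cumsum(prop) * total)))
}

# site tuples for plaque: plaque subjects have all three sites; the
# no-plaque remainder mixes the published partial patterns (1,0,1)/(0,0,0)
plaque_site_tuples <- function(n_plaque, n_no_plaque) {
  cnt <- proportional_counts(n_no_plaque, c(6, 7))
  rbind(
    matrix(TRUE, nrow = n_plaque, ncol = 3),
    matrix(rep(c(TRUE, FALSE, TRUE), cnt[1]), ncol = 3, byrow = TRUE),
    matrix(FALSE, nrow = cnt[2], ncol = 3)
  )
}

# which sites carry grade >= 2; moderate-severe subjects get >= 2 such
# sites, mild subjects <= 1, with pattern mixes matching the published
# per-site moderate-severe margins (28/23/29 at the default sizes)
severity_site_flags <- function(n_ms, n_mild) {
  ms_cnt <- proportional_counts(n_ms, c(16, 3, 4, 4))
  ms_pat <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  mild_cnt <- proportional_counts(n_mild, c(5, 5, 6))
  mild_pat <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, 0))
  flags <- rbind(ms_pat[rep(seq_len(4), ms_cnt), , drop = FALSE],
                 mild_pat[rep(seq_len(3), mild_cnt), , drop = FALSE])
  flags == 1
}

#' Generate a full synthetic cohort
#'
#' Builds a [gingival_cohort()] with the configured group structure: group
#' labels are assigned first (exact counts by construction, not rejection
#' sampling), site-level index tuples are constructed so that they always
#' aggregate back to the assigned group under [plaque_group()] /
#' [severity_group()], pre-treatment colours are drawn per zone from the
#' biotype-conditional parameters, post-treatment colours are drawn
#' conditionally on the pre colours with the per-zone within-subject
#' correlation (calibrated on the fly when `config$rho` is `NULL`), and
#' replicate triplets add independent measurement noise.
#'
#' @param config A [simulation_config()].
#' @return A [gingival_cohort()] whose provenance records the seed and the
#'   per-zone correlations used.
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_thin + config$n_thick
  zones <- gingival_zones()

  # per-zone rho: configured or calibrated to the target mean paired dEab
  rho <- config$rho
  if (is.null(rho)) {
    rho <- vapply(zones, function(z) {
      pre <- params_slice(config$treatment_params, z, "pre")
      post <- params_slice(config$treatment_params, z, "post")
      target <- config$delta_targets$mean_de[config$delta_targets$zone == z]
      calibrate_rho(pre, post, target, n_mc = config$calib_n_mc,
                    seed = config$seed + 1000L)$rho
    }, numeric(1))
  } else if (is.null(names(rho))) {
    rho <- stats::setNames(rep_len(rho, length(zones)), zones)
  }

  set.seed(config$seed)
  ids <- sprintf("S%02d", seq_len(n))
  biotype <- sample(rep(c("thin", "thick"), c(config$n_thin, config$n_thick)))
  gender <- sample(rep(c("female", "male"),
                       c(round(n * 23 / 43), n - round(n * 23 / 43))))
  age <- round(pmin(79, pmax(20, stats::rnorm(n, 46.5, 14))))

  plaque <- plaque_site_tuples(config$n_plaque, n - config$n_plaque)
  plaque <- plaque[sample(n), , drop = FALSE]
  sev_flags <- severity_site_flags(config$n_moderate_severe,
                                   n - config$n_moderate_severe)
  sev_flags <- sev_flags[sample(n), , drop = FALSE]
  grades <- matrix(0L, n, 3)
  grades[sev_flags] <- sample(c(2L, 3L), sum(sev_flags), TRUE, prob = c(0.7, 0.3))
  grades[!sev_flags] <- sample(c(0L, 1L), sum(!sev_flags), TRUE, prob = c(0.15, 0.85))
  allzero <- rowSums(grades) == 0
  grades[allzero, 2] <- 1L  # every enrolled subject shows some inflammation

  subjects <- tibble::tibble(
    subject_id = ids, age = age, gender = gender, biotype = biotype,
    plaque_distal_vestibular = plaque[, 1], plaque_vestibular = plaque[, 2],
    plaque_mesial_vestibular = plaque[, 3],
    grade_distal_vestibular = grades[, 1], grade_vestibular = grades[, 2],
    grade_mesial_vestibular = grades[, 3])

  meas <- list()
  for (z in zones) {
    thin_p <- params_slice(config$biotype_params, z, "thin")
    thick_p <- params_slice(config$biotype_params, z, "thick")
    pre_pool <- params_slice(config$treatment_params, z, "pre")
    post_pool <- params_slice(config$treatment_params, z, "post")

    pre <- matrix(NA_real_, n, 3)
    pre[biotype == "thin", ] <- draw_lab(sum(biotype == "thin"), thin_p)
    pre[biotype == "thick", ] <- draw_lab(sum(biotype == "thick"), thick_p)

    # conditional draw of post given pre: regression against the pooled pre
    # marginal keeps the post marginal at its configured parameters
    zstd <- sweep(sweep(pre, 2, pre_pool$mean, `-`), 2, pre_pool$sd, `/`)
    eps <- draw_std_triplets(n)
    post <- sweep(sweep(rho[z] * zstd + sqrt(1 - rho[z]^2) * eps, 2,
                        post_pool$sd, `*`), 2, post_pool$mean, `+`)
    post[, 1] <- pmin(100, pmax(0, post[, 1]))

    for (tp in c("pre", "post")) {
      subj_val <- if (tp == "pre") pre else post
      for (r in seq_len(config$n_replicates)) {
        noise <- matrix(stats::rnorm(3 * n, 0, config$replicate_sd), ncol = 3)
        v <- subj_val + noise
        v[, 1] <- pmin(100, pmax(0, v[, 1]))
        meas[[length(meas) + 1L]] <- tibble::tibble(
          subject_id = ids, zone = z, timepoint = tp, replicate = r,
          L = v[, 1], a = v[, 2], b = v[, 3])
      }
    }
  }
  measurements <- do.call(rbind, meas)

  gingival_cohort(subjects, measurements,
                  provenance = list(label = "synthetic", seed = config$seed,
                                    rho = paste(sprintf("%s=%.3f", zones, rho[zones]),
                                                collapse = ";")))
}

#' Read a generator configuration from a YAML file
#'
#' Accepts top-level keys `n_thin`, `n_thick`, `n_plaque`,
#' `n_moderate_severe`, `replicate_sd`, `n_replicates`, `calib_n_mc`,
#' `seed`, an optional `rho` mapping of zone to correlation, and optional
#' nested `biotype_params` / `treatment_params` tables of the form
#' `zone: {group: {L: [mean, sd], a: [mean, sd], b: [mean, sd]}}`.
#'
#' @param path Path to a YAML configuration file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("n_thin", "n_thick", "n_plaque",
                                  "n_moderate_severe", "replicate_sd",
                                  "n_replicates", "calib_n_mc", "seed"))]
  if (!is.null(y$rho)) args$rho <- unlist(y$rho)
  for (tbl in c("biotype_params", "treatment_params")) {
    if (!is.null(y[[tbl]])) args[[tbl]] <- yaml_params_to_tibble(y[[tbl]])
  }
  do.call(simulation_config, args)
}

yaml_params_to_tibble <- function(x) {
  rows <- list()
  for (z in names(x)) {
    for (g in names(x[[z]])) {
      cell <- x[[z]][[g]]
      for (coord in c("L", "a", "b")) {
        v <- cell[[coord]]
        if (length(v) != 2L) {
          stop(sprintf("params for %s/%s/%s must be [mean, sd]", z, g, coord),
               call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          zone = as_gingival_zone(z), group = g, coord = coord,
          mean = v[[1]], sd = v[[2]])
      }
    }
  }
  do.call(rbind, rows)
}
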