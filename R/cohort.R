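#' Build a gingival study cohort
#'
#' A cohort bundles one row of clinical covariates per subject with the
#' replicate CIELAB measurements taken at each gingival zone and timepoint.
#'
#' @param subjects Tibble with one row per subject and columns `subject_id`,
#'   `age`, `gender`, `biotype` (`"thin"`/`"thick"`), the three plaque-site
#'   logicals `plaque_distal_vestibular`, `plaque_vestibular`,
#'   `plaque_mesial_vestibular`, and the three Loe-Silness grades
#'   `grade_distal_vestibular`, `grade_vestibular`, `grade_mesial_vestibular`.
#' @param measurements Tibble with one row per replicate measurement:
#'   `subject_id`, `zone` (see [gingival_zones()]), `timepoint`
#'   (`"pre"`/`"post"`), `replicate`, `L`, `a`, `b`.
#' @param provenance Optional list describing how the cohort was produced
#'   (free-text `label`, integer `seed` if synthetic).
#' @return An object of class `gingival_cohort`.
#' @export
gingival_cohort <- function(subjects, measurements, provenance = list()) {
  subjects <- tibble::as_tibble(subjects)
  measurements <- tibble::as_tibble(measurements)

  need_subj <- c("subject_id", "age", "gender", "biotype",
                 paste0("plaque_", index_sites()), paste0("grade_", index_sites()))
  missing_cols <- setdiff(need_subj, names(subjects))
  if (length(missing_cols)) {
    stop("subjects table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  need_meas <- c("subject_id", "zone", "timepoint", "replicate", "L", "a", "b")
  missing_cols <- setdiff(need_meas, names(measurements))
  if (length(missing_cols)) {
    stop("measurements table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject_id values must be unique", call. = FALSE)
  }
  if (!all(subjects$biotype %in% c("thin", "thick"))) {
    stop("biotype must be 'thin' or 'thick'", call. = FALSE)
  }
  grades <- as.matrix(subjects[paste0("grade_", index_sites())])
  if (any(!(grades %in% 0:3))) {
    stop("gingival grades must be integers in 0..3", call. = FALSE)
  }
  measurements$zone <- as_gingival_zone(measurements$zone)
  if (!all(measurements$timepoint %in% c("pre", "post"))) {
    stop("timepoint must be 'pre' or 'post'", call. = FALSE)
  }
  orphan <- setdiff(measurements$subject_id, subjects$subject_id)
  if (length(orphan)) {
    stop("measurements reference unknown subject(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  validate_lab(measurements$L, measurements$a, measurements$b)

  structure(list(subjects = subjects, measurements = measurements,
                 provenance = provenance),
            class = "gingival_cohort")
}

#' @export
print.gingival_cohort <- function(x, ...) {
  g <- cohort_groups(x)
  cat(sprintf("<gingival_cohort> %d subjects (%d thin / %d thick biotype)\n",
              nrow(x$subjects), sum(g$biotype == "thin"), sum(g$biotype == "thick")))
  cat(sprintf("  plaque groups:   %d plaque / %d no_plaque\n",
              sum(g$plaque_group == "plaque"), sum(g$plaque_group == "no_plaque")))
  cat(sprintf("  severity groups: %d moderate_severe / %d mild\n",
              sum(g$severity_group == "moderate_severe"),
              sum(g$severity_group == "mild")))
  cat(sprintf("  %d replicate colour measurements\n", nrow(x$measurements)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-subject analysis groups
#'
#' Applies the [plaque_group()] and [severity_group()] aggregation rules to
#' every subject.
#'
#' @param cohort A [gingival_cohort()].
#' @return Tibble with `subject_id`, `biotype`, `plaque_group`,
#'   `severity_group`.
#' @export
cohort_groups <- function(cohort) {
  s <- cohort$subjects
  tibble::tibble(
    subject_id = s$subject_id,
    biotype = s$biotype,
    plaque_group = plaque_group(as.matrix(s[paste0("plaque_", index_sites())])),
    severity_group = severity_group(as.matrix(s[paste0("grade_", index_sites())]))
  )
}

#' Averaged zone colour for one subject
#'
#' Returns the replicate-averaged CIELAB colour of one subject at one zone
#' and timepoint; this is the value used in all statistical analysis.
#'
#' @param cohort A [gingival_cohort()].
#' @param subject_id One subject identifier.
#' @param zone One gingival zone (aliases accepted, see [as_gingival_zone()]).
#' @param timepoint `"pre"` or `"post"`.
#' @return Named numeric vector `c(L, a, b)`.
#' @export
zone_value <- function(cohort, subject_id, zone, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  zone <- as_gingival_zone(zone)
  m <- cohort$measurements
  sel <- m$subject_id == subject_id & m$zone == zone & m$timepoint == timepoint
  if (!any(sel)) {
    stop(sprintf("no measurements for subject '%s' at (%s, %s)",
                 subject_id, zone, timepoint), call. = FALSE)
  }
  average_replicates(m[sel, c("L", "a", "b")])
}

#' Averaged zone colours for all subjects
#'
#' Vectorised companion to [zone_value()]: the replicate-averaged colour of
#' every subject at one zone/timepoint. Subjects with no measurements in that
#' cell are excluded listwise; their ids are attached as attribute
#' `"excluded"` and reported via `message()` so exclusions are always logged.
#'
#' @inheritParams zone_value
#' @return Tibble `subject_id`, `L`, `a`, `b` (one row per subject present).
#' @export
zone_values <- function(cohort, zone, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  zone <- as_gingival_zone(zone)
  m <- cohort$measurements
  m <- m[m$zone == zone & m$timepoint == timepoint, ]
  got <- unique(m$subject_id)
  excluded <- setdiff(cohort$subjects$subject_id, got)
  if (length(excluded)) {
    message(sprintf("zone_values: excluding %d subject(s) with no (%s, %s) data: %s",
                    length(excluded), zone, timepoint,
                    paste(utils::head(excluded, 5), collapse = ", ")))
  }
  ids <- intersect(cohort$subjects$subject_id, got)  # stable subject order
  validate_lab(m$L, m$a, m$b)
  sums <- rowsum(cbind(L = m$L, a = m$a, b = m$b), m$subject_id)
  counts <- as.vector(rowsum(rep(1, nrow(m)), m$subject_id))
  avg <- sums / counts
  avg <- avg[match(ids, rownames(avg)), , drop = FALSE]
  res <- tibble::tibble(subject_id = ids,
                        L = avg[, "L"], a = avg[, "a"], b = avg[, "b"])
  attr(res, "excluded") <- excluded
  res
}

#' Write a cohort to the long-format CSV schema
#'
#' One row per replicate colour measurement plus one row per index site;
#' columns `subject_id, age, gender, biotype, site, plaque, gingival_grade,
#' zone, timepoint, replicate, L, a, b`. Site-level index rows carry empty
#' colour fields and measurement rows carry empty index fields. Provenance
#' (label, seed) is recorded in `#`-prefixed header comment lines.
#'
#' @param cohort A [gingival_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  s <- cohort$subjects
  covar <- s[match(s$subject_id, s$subject_id), c("subject_id", "age", "gender", "biotype")]

  index_rows <- do.call(rbind, lapply(index_sites(), function(site) {
    data.frame(subject_id = s$subject_id, age = s$age, gender = s$gender,
               biotype = s$biotype, site = site,
               plaque = as.integer(s[[paste0("plaque_", site)]]),
               gingival_grade = s[[paste0("grade_", site)]],
               zone = "", timepoint = "", replicate = NA_integer_,
               L = NA_real_, a = NA_real_, b = NA_real_)
  }))
  m <- cohort$measurements
  i <- match(m$subject_id, s$subject_id)
  meas_rows <- data.frame(subject_id = m$subject_id, age = s$age[i],
                          gender = s$gender[i], biotype = s$biotype[i],
                          site = "", plaque = NA_integer_,
                          gingival_grade = NA_integer_,
                          zone = m$zone, timepoint = m$timepoint,
                          replicate = m$replicate, L = m$L, a = m$a, b = m$b)
  out <- rbind(index_rows, meas_rows)
  out <- out[order(match(out$subject_id, s$subject_id)), ]

  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gingicol cohort v1"), con)
  for (nm in names(cohort$provenance)) {
    writeLines(sprintf("# %s: %s", nm, cohort$provenance[[nm]]), con)
  }
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from the long-format CSV schema
#'
#' Counterpart of [write_cohort()]. Zone aliases (e.g.
#' `upper_attached_gingiva`) are canonicalised at parse time; `#` header
#' comment lines are parsed back into the provenance list.
#'
#' @param path Path to a cohort CSV.
#' @return A [gingival_cohort()].
#' @export
read_cohort <- function(path) {
  header <- character()
  con <- file(path, "r", encoding = "UTF-8")
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  prov <- list()
  for (h in header) {
    kv <- regmatches(h, regexec("^# *([^:]+): *(.*)$", h))[[1]]
    if (length(kv) == 3L) prov[[trimws(kv[2])]] <- trimws(kv[3])
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("subject_id", "age", "gender", "biotype", "site", "plaque",
            "gingival_grade", "zone", "timepoint", "replicate", "L", "a", "b")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  idx <- raw[!is.na(raw$site) & raw$site != "", ]
  meas <- raw[!is.na(raw$zone) & raw$zone != "", ]
  if (!nrow(idx)) stop("cohort CSV contains no site-index rows", call. = FALSE)
  if (!nrow(meas)) stop("cohort CSV contains no measurement rows", call. = FALSE)

  ids <- unique(raw$subject_id)
  subjects <- do.call(rbind, lapply(ids, function(id) {
    ri <- idx[idx$subject_id == id, ]
    if (!all(index_sites() %in% ri$site)) {
      stop(sprintf("subject '%s': index rows for all three sites required", id),
           call. = FALSE)
    }
    ri <- ri[match(index_sites(), ri$site), ]
    first <- raw[raw$subject_id == id, ][1, ]
    data.frame(subject_id = id, age = first$age, gender = first$gender,
               biotype = first$biotype,
               plaque_distal_vestibular = as.logical(ri$plaque[1]),
               plaque_vestibular = as.logical(ri$plaque[2]),
               plaque_mesial_vestibular = as.logical(ri$plaque[3]),
               grade_distal_vestibular = ri$gingival_grade[1],
               grade_vestibular = ri$gingival_grade[2],
               grade_mesial_vestibular = ri$gingival_grade[3])
  }))

  measurements <- tibble::tibble(
    subject_id = meas$subject_id, zone = as_gingival_zone(meas$zone),
    timepoint = tolower(meas$timepoint), replicate = meas$replicate,
    L = meas$L, a = meas$a, b = meas$b)

  gingival_cohort(subjects, measurements, provenance = prov)
}
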