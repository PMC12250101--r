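#' Gingival measurement zones
#'
#' Colour is measured in four anatomical zones adjacent to the maxillary
#' central incisor: the distal papilla, the free gingival margin, the middle
#' zone of the attached gingiva, and the mucogingival line (also called the
#' upper zone of the attached gingiva; that alias is accepted wherever a zone
#' is parsed).
#'
#' @return Character vector of the four canonical zone identifiers.
#' @export
gingival_zones <- function() {
  c("distal_papilla", "free_gingival_margin",
    "middle_attached_gingiva", "mucogingival_line")
}

ZONE_ALIASES <- c(upper_attached_gingiva = "mucogingival_line")

#' Canonicalise a gingival zone label
#'
#' @param zone Character vector of zone labels; case-insensitive, spaces and
#'   hyphens treated as underscores; `"upper_attached_gingiva"` is accepted
#'   as an alias for `"mucogingival_line"`.
#' @return Canonical zone identifiers (see [gingival_zones()]).
#' @export
as_gingival_zone <- function(zone) {
  z <- gsub("[ -]+", "_", tolower(trimws(as.character(zone))))
  z <- ifelse(z %in% names(ZONE_ALIASES), ZONE_ALIASES[z], z)
  bad <- !(z %in% gingival_zones())
  if (any(bad)) {
    stop("unknown gingival zone(s): ", paste(unique(zone[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(z)
}

# canonical site order for the three vestibular index sites
index_sites <- function() c("distal_vestibular", "vestibular", "mesial_vestibular")

#' Average replicate colour measurements
#'
#' Replicate spectrophotometer readings of one gingival site are averaged
#' coordinate-wise; the mean is what enters all statistical analysis, to
#' minimise measurement deviations.
#'
#' @param replicates Colours accepted by [as_lab()]: typically a data frame
#'   or matrix with one row per replicate.
#' @return A named numeric vector `c(L, a, b)`.
#' @examples
#' average_replicates(rbind(c(50, 25, 15), c(52, 27, 17), c(48, 23, 13)))
#' @export
average_replicates <- function(replicates) {
  m <- as_lab(replicates)
  if (nrow(m) == 0L) stop("no replicate measurements to average", call. = FALSE)
  colMeans(m)
}

#' Dichotomise a subject's plaque status
#'
#' A subject is classed as having plaque only when plaque is present at all
#' three vestibular sites examined (distal-vestibular, vestibular,
#' mesial-vestibular); plaque at one or two sites counts as `"no_plaque"`.
#' The rule is count-based, so site order is irrelevant.
#'
#' @param plaque_sites Three logicals (one subject), or a 3-column logical
#'   matrix (one row per subject).
#' @return `"plaque"` or `"no_plaque"`, one per subject.
#' @examples
#' plaque_group(c(TRUE, TRUE, TRUE))
#' plaque_group(c(TRUE, TRUE, FALSE))
#' @export
plaque_group <- function(plaque_sites) {
  m <- as_site_matrix(plaque_sites, "plaque_sites")
  if (any(is.na(m)) || !is.logical(m)) {
    storage.mode(m) <- "logical"
    if (any(is.na(m))) stop("plaque_sites must be three booleans", call. = FALSE)
  }
  ifelse(rowSums(m) == 3L, "plaque", "no_plaque")
}

#' Dichotomise a subject's inflammation severity
#'
#' Inflammation is classed as moderate-or-severe when a Loe-Silness grade of
#' 2 (moderate) or 3 (severe) is recorded at two or more of the three sites
#' examined; otherwise the subject is `"mild"`. Grade 0 and 1 sites count as
#' mild for grouping. Count-based, so site order is irrelevant. Note one
#' consequence of the two-of-three rule: a subject with a single grade-3 site
#' and no other site above grade 1 is grouped as `"mild"`.
#'
#' @param grades Three integers in `0:3` (one subject), or a 3-column
#'   integer matrix (one row per subject).
#' @return `"moderate_severe"` or `"mild"`, one per subject.
#' @examples
#' severity_group(c(2, 1, 2))
#' severity_group(c(1, 1, 3))
#' @export
severity_group <- function(grades) {
  m <- as_site_matrix(grades, "grades")
  if (any(is.na(m)) || any(!(m %in% 0:3))) {
    stop("gingival grades must be integers in 0..3", call. = FALSE)
  }
  ifelse(rowSums(m >= 2) >= 2L, "moderate_severe", "mild")
}

as_site_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop(what, " needs exactly three sites", call. = FALSE)
    return(x)
  }
  if (length(x) != 3L) stop(what, " needs exactly three sites", call. = FALSE)
  matrix(x, nrow = 1L)
}
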