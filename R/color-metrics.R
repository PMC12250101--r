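#' Euclidean CIELAB colour difference (dEab)
#'
#' The classic colour-difference metric: the Euclidean distance between two
#' points in CIELAB space,
#' \deqn{\Delta E_{ab} = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2}.}
#'
#' @param c1,c2 Colours accepted by [as_lab()]: a length-3 `(L, a, b)` vector,
#'   a 3-column matrix, or a data frame with columns `L`, `a`, `b`. Both
#'   inputs must describe the same number of colours (or one of them a single
#'   colour, which is recycled).
#' @return A non-negative numeric vector of colour differences, one per pair.
#' @examples
#' delta_e_ab(c(46.3, 27.2, 15.2), c(48.2, 26.5, 15.5))
#' @seealso [delta_e_00()] for the CIEDE2000 formula.
#' @export
delta_e_ab <- function(c1, c2) {
  m <- recycle_lab_pair(as_lab(c1), as_lab(c2))
  unname(sqrt(rowSums((m$x - m$y)^2)))
}

#' CIEDE2000 colour difference (dE00)
#'
#' The CIE's refined colour-difference formula, designed to align computed
#' differences with the visual perception of human observers. Relative to the
#' Euclidean [delta_e_ab()] it adds a chroma-dependent rescaling of the a*
#' axis (the G factor), lightness/chroma/hue weighting functions
#' (SL, SC, SH), and a rotation term (RT) coupling the chroma and hue
#' differences in the blue region. Hue angles are handled in degrees on
#' \[0, 360) via the two-argument arctangent; the hue of a neutral colour
#' (C' = 0) is defined as 0; the standard branch rules apply when the two hue
#' angles are more than 180 degrees apart.
#'
#' @inheritParams delta_e_ab
#' @param k Parametric factors `c(kL, kC, kH)`, all strictly positive.
#'   Default `c(1, 1, 1)` (the reference viewing conditions).
#' @return A non-negative numeric vector of CIEDE2000 differences.
#' @examples
#' delta_e_00(c(50, 0, 0), c(60, 0, 0))   # 10 / SL at mean L* 55
#' @export
delta_e_00 <- function(c1, c2, k = c(1, 1, 1)) {
  terms <- ciede2000_terms(c1, c2, k)
  with(terms, {
    tL <- dL_prime / (kL * SL)
    tC <- dC_prime / (kC * SC)
    tH <- dH_prime / (kH * SH)
    sqrt(tL^2 + tC^2 + tH^2 + RT * tC * tH)
  })
}

#' Intermediate terms of the CIEDE2000 formula
#'
#' Exposes every sub-term of the CIEDE2000 computation for inspection and
#' testing: the G chroma correction, adjusted chroma/hue, the three
#' difference terms, the SL/SC/SH weighting functions and the RT rotation
#' term. [delta_e_00()] is assembled from this table.
#'
#' @inheritParams delta_e_00
#' @return A tibble with one row per colour pair and columns `Lbar_prime`,
#'   `Cbar_prime`, `hbar_prime` (degrees in \[0, 360)), `dL_prime`,
#'   `dC_prime`, `dH_prime`, `SL`, `SC`, `SH`, `RT`, `G`, `kL`, `kC`, `kH`.
#' @export
ciede2000_terms <- function(c1, c2, k = c(1, 1, 1)) {
  if (length(k) != 3L || any(!is.finite(k)) || any(k <= 0)) {
    stop("parametric factors k must be three positive numbers", call. = FALSE)
  }
  m <- recycle_lab_pair(as_lab(c1), as_lab(c2))
  L1 <- unname(m$x[, "L"]); a1 <- unname(m$x[, "a"]); b1 <- unname(m$x[, "b"])
  L2 <- unname(m$y[, "L"]); a2 <- unname(m$y[, "a"]); b2 <- unname(m$y[, "b"])

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))

  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- hue_deg(a1p, b1)
  h2p <- hue_deg(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p

  # hue difference with the >180-degree branch rules; 0 when either chroma is 0
  dhp <- h2p - h1p
  dhp <- ifelse(dhp > 180, dhp - 360, ifelse(dhp < -180, dhp + 360, dhp))
  zero_chroma <- C1p * C2p == 0
  dhp[zero_chroma] <- 0
  dHp <- 2 * sqrt(C1p * C2p) * sin(deg2rad(dhp) / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2

  hsum <- h1p + h2p
  habs <- abs(h1p - h2p)
  hbp <- ifelse(habs <= 180, hsum / 2,
                ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2))
  hbp[zero_chroma] <- hsum[zero_chroma]

  Tt <- 1 - 0.17 * cos(deg2rad(hbp - 30)) + 0.24 * cos(deg2rad(2 * hbp)) +
    0.32 * cos(deg2rad(3 * hbp + 6)) - 0.20 * cos(deg2rad(4 * hbp - 63))
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))

  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(deg2rad(2 * dtheta)) * RC

  tibble::tibble(
    Lbar_prime = Lbp, Cbar_prime = Cbp, hbar_prime = hbp %% 360,
    dL_prime = dLp, dC_prime = dCp, dH_prime = dHp,
    SL = SL, SC = SC, SH = SH, RT = RT, G = G,
    kL = k[1], kC = k[2], kH = k[3]
  )
}

hue_deg <- function(a, b) {
  h <- atan2(b, a) * 180 / pi
  h <- ifelse(h < 0, h + 360, h)
  ifelse(a == 0 & b == 0, 0, h)
}

deg2rad <- function(x) x * pi / 180

recycle_lab_pair <- function(x, y) {
  if (nrow(x) != nrow(y)) {
    if (nrow(x) == 1L) x <- x[rep(1L, nrow(y)), , drop = FALSE]
    else if (nrow(y) == 1L) y <- y[rep(1L, nrow(x)), , drop = FALSE]
    else stop("colour inputs must have equal length (or one be a single colour)",
              call. = FALSE)
  }
  list(x = x, y = y)
}

#' Gingival 50:50% perceptibility thresholds
#'
#' A colour difference is called perceptible when half of human observers can
#' see it. For gingival tissue the published 50:50% perceptibility thresholds
#' are dEab = 3.1 and dE00 = 2.1; both are space-specific and therefore
#' configurable.
#'
#' @param t_eab Threshold applied to Euclidean differences. Default 3.1.
#' @param t_e00 Threshold applied to CIEDE2000 differences. Default 2.1.
#' @return An object of class `perceptibility_thresholds`.
#' @export
perceptibility_thresholds <- function(t_eab = 3.1, t_e00 = 2.1) {
  if (!is.finite(t_eab) || !is.finite(t_e00) || t_eab <= 0 || t_e00 <= 0) {
    stop("perceptibility thresholds must be strictly positive", call. = FALSE)
  }
  structure(list(t_eab = t_eab, t_e00 = t_e00),
            class = "perceptibility_thresholds")
}

#' @export
print.perceptibility_thresholds <- function(x, ...) {
  cat(sprintf("50:50%% perceptibility thresholds: dEab > %g, dE00 > %g\n",
              x$t_eab, x$t_e00))
  invisible(x)
}

#' Classify colour differences against perceptibility thresholds
#'
#' Flags each difference as perceptible when it STRICTLY exceeds the
#' corresponding threshold (a difference exactly at the threshold is not
#' perceptible).
#'
#' @param de_ab,de_00 Non-negative numeric vectors of Euclidean and CIEDE2000
#'   differences. Either may be `NULL` if only one formula was computed.
#' @param thresholds A [perceptibility_thresholds()] object.
#' @return A tibble with the supplied difference columns and logical
#'   `perceptible_ab` / `perceptible_00` flags.
#' @examples
#' classify_perceptible(de_ab = c(3.1, 9.09), de_00 = c(2.0, 6.77))
#' @export
classify_perceptible <- function(de_ab = NULL, de_00 = NULL,
                                 thresholds = perceptibility_thresholds()) {
  if (is.null(de_ab) && is.null(de_00)) {
    stop("supply at least one of de_ab, de_00", call. = FALSE)
  }
  check_nonneg <- function(x, nm) {
    if (!is.null(x) && (any(!is.finite(x)) || any(x < 0))) {
      stop(sprintf("%s must be non-negative and finite", nm), call. = FALSE)
    }
  }
  check_nonneg(de_ab, "de_ab")
  check_nonneg(de_00, "de_00")
  out <- tibble::tibble(.rows = max(length(de_ab), length(de_00)))
  if (!is.null(de_ab)) {
    out$de_ab <- de_ab
    out$perceptible_ab <- de_ab > thresholds$t_eab
  }
  if (!is.null(de_00)) {
    out$de_00 <- de_00
    out$perceptible_00 <- de_00 > thresholds$t_e00
  }
  out
}
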