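# Independent oracles used across the suite. These deliberately share no
# code with the package: the CIEDE2000 reference below works scalar-wise in
# radians with explicit branching, following the CIE standard text.

ciede2000_reference <- function(c1, c2, kL = 1, kC = 1, kH = 1) {
  L1 <- c1[1]; a1 <- c1[2]; b1 <- c1[3]
  L2 <- c2[1]; a2 <- c2[2]; b2 <- c2[3]
  pow7 <- function(x) x^7

  Cab1 <- sqrt(a1 * a1 + b1 * b1)
  Cab2 <- sqrt(a2 * a2 + b2 * b2)
  Cab <- 0.5 * (Cab1 + Cab2)
  G <- 0.5 * (1 - sqrt(pow7(Cab) / (pow7(Cab) + pow7(25))))

  ap1 <- (1 + G) * a1
  ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1 * ap1 + b1 * b1)
  Cp2 <- sqrt(ap2 * ap2 + b2 * b2)

  hp <- function(ap, b) {
    if (ap == 0 && b == 0) return(0)
    h <- atan2(b, ap)
    if (h < 0) h <- h + 2 * pi
    h
  }
  hp1 <- hp(ap1, b1)
  hp2 <- hp(ap2, b2)

  dLp <- L2 - L1
  dCp <- Cp2 - Cp1

  if (Cp1 * Cp2 == 0) {
    dhp <- 0
  } else {
    dhp <- hp2 - hp1
    if (dhp > pi) dhp <- dhp - 2 * pi
    if (dhp < -pi) dhp <- dhp + 2 * pi
  }
  dHp <- 2 * sqrt(Cp1 * Cp2) * sin(dhp / 2)

  Lbp <- 0.5 * (L1 + L2)
  Cbp <- 0.5 * (Cp1 + Cp2)
  if (Cp1 * Cp2 == 0) {
    hbp <- hp1 + hp2
  } else if (abs(hp1 - hp2) <= pi) {
    hbp <- 0.5 * (hp1 + hp2)
  } else if (hp1 + hp2 < 2 * pi) {
    hbp <- 0.5 * (hp1 + hp2 + 2 * pi)
  } else {
    hbp <- 0.5 * (hp1 + hp2 - 2 * pi)
  }

  Tt <- 1 - 0.17 * cos(hbp - pi / 6) + 0.24 * cos(2 * hbp) +
    0.32 * cos(3 * hbp + pi * 6 / 180) - 0.20 * cos(4 * hbp - pi * 63 / 180)
  dtheta <- (pi / 6) * exp(-((hbp * 180 / pi - 275) / 25)^2)
  RC <- 2 * sqrt(pow7(Cbp) / (pow7(Cbp) + pow7(25)))
  SL <- 1 + (0.015 * (Lbp - 50)^2) / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}

# zone_group_params for one zone/group cell of a reference parameter table
params_from_table <- function(tbl, zone_id, group_id) {
  r <- tbl[tbl$zone == zone_id & tbl$group == group_id, ]
  r <- r[match(c("L", "a", "b"), r$coord), ]
  zone_group_params(mean = r$mean, sd = r$sd)
}

random_lab <- function(n, L = c(0, 100), ab = c(-90, 90)) {
  cbind(runif(n, L[1], L[2]), runif(n, ab[1], ab[2]), runif(n, ab[1], ab[2]))
}

# exact two-sided permutation p-value for the two-sample difference of
# means, enumerating all assignments of the pooled data to group 1
permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  obs <- abs(mean(x) - mean(y))
  stats <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}

# minimal two-subject cohort fixture with deterministic measurements
tiny_cohort <- function() {
  subjects <- tibble::tibble(
    subject_id = c("A", "B"), age = c(30, 40),
    gender = c("female", "male"), biotype = c("thin", "thick"),
    plaque_distal_vestibular = c(TRUE, TRUE),
    plaque_vestibular = c(TRUE, FALSE),
    plaque_mesial_vestibular = c(TRUE, TRUE),
    grade_distal_vestibular = c(2L, 1L), grade_vestibular = c(2L, 1L),
    grade_mesial_vestibular = c(1L, 0L))
  rows <- list()
  for (id in c("A", "B")) {
    base <- if (id == "A") c(46, 28, 15) else c(50, 25, 16)
    for (z in gingival_zones()) {
      for (tp in c("pre", "post")) {
        shift <- if (tp == "post") 2 else 0
        for (r in 1:3) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject_id = id, zone = z, timepoint = tp, replicate = r,
            L = base[1] + shift + (r - 2) * 0.3, a = base[2] - (r - 2) * 0.2,
            b = base[3] + (r - 2) * 0.1)
        }
      }
    }
  }
  gingival_cohort(subjects, do.call(rbind, rows),
                  provenance = list(label = "fixture"))
}
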