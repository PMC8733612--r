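# 10-20 montage: canonical channel set, label aliases, idealized unit-sphere
# electrode coordinates.

#' The 19 standard 10-20 channels used for cross-site aggregation
#'
#' Channel order is fixed: Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2, F7, F8,
#' T3, T4, T5, T6, Fz, Cz, Pz.
#'
#' @return Character vector of 19 channel labels.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

# Modern 10-10 names mapped onto their classic 10-20 equivalents.
label_aliases <- function() {
  c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
}

#' Normalize electrode labels to classic 10-20 names
#'
#' Case-insensitive matching against the 10-20 set; the modern aliases
#' T7/T8/P7/P8 are mapped to T3/T4/T5/T6. Unknown labels are returned
#' unchanged (capitalization normalized where recognized).
#'
#' @param labels character vector of channel labels.
#' @return Character vector of normalized labels.
#' @export
normalize_labels <- function(labels) {
  known <- c(channels_1020(), names(label_aliases()))
  lut <- stats::setNames(known, toupper(known))
  out <- labels
  hit <- toupper(labels) %in% names(lut)
  out[hit] <- lut[toupper(labels[hit])]
  ali <- label_aliases()
  swap <- out %in% names(ali)
  out[swap] <- ali[out[swap]]
  out
}

#' Idealized unit-sphere coordinates for 10-20 electrodes
#'
#' Standard idealized positions on the unit sphere (x = right, y = anterior,
#' z = superior), from the nominal 10-20 inclination/azimuth angles. These
#' are the coordinates used by the spherical-spline interpolation; they are
#' schematic, not digitized head shapes.
#'
#' @param labels channel labels (10-20 names or their aliases).
#' @return Numeric matrix `length(labels)` x 3 with columns x, y, z.
#' @export
electrode_positions <- function(labels = channels_1020()) {
  ang <- montage_angles()
  lab <- normalize_labels(labels)
  miss <- setdiff(lab, rownames(ang))
  if (length(miss) > 0) {
    stop("no idealized position for channel(s): ", paste(miss, collapse = ", "))
  }
  a <- ang[lab, , drop = FALSE]
  incl <- a[, 1] * pi / 180
  az <- a[, 2] * pi / 180
  pos <- cbind(x = sin(incl) * cos(az),
               y = sin(incl) * sin(az),
               z = cos(incl))
  rownames(pos) <- labels
  pos
}

# (inclination from vertex, azimuth counterclockwise from the right ear,
# degrees); azimuth 90 = nose.
montage_angles <- function() {
  m <- rbind(
    Fp1 = c(90, 108), Fp2 = c(90, 72),
    F7  = c(90, 144), F8  = c(90, 36),
    T3  = c(90, 180), T4  = c(90, 0),
    T5  = c(90, 216), T6  = c(90, 324),
    O1  = c(90, 252), O2  = c(90, 288),
    F3  = c(60, 115), F4  = c(60, 65),
    C3  = c(45, 180), C4  = c(45, 0),
    P3  = c(60, 245), P4  = c(60, 295),
    Fz  = c(45, 90),  Cz  = c(0, 0),   Pz = c(45, 270)
  )
  colnames(m) <- c("incl", "az")
  m
}
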