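# 10-20 / 10-10 electrode geometry on a spherical head model.
#
# Electrodes live on a unit sphere with the vertex (Cz) at the pole; each is
# described by an inclination from the vertex and an azimuth measured from
# the nasion axis (positive toward the right ear). The 2D scalp projection
# maps inclination linearly to disc radius, so Cz sits at the origin and the
# 10% circumferential ring at radius 0.8 of the way to the equator; the nose
# points along +y. Left-hemisphere positions are defined explicitly and the
# right hemisphere is their exact mirror, which makes left/right symmetry a
# structural property rather than a tabulated one. Interior 10-10 positions
# (FC/CP rows) are spherical midpoints of their 10-20 neighbours - nominal
# placements, adequate for weighting and interpolation, not digitized
# coordinates.

sph_vec <- function(incl_deg, az_deg) {
  i <- incl_deg * pi / 180
  a <- az_deg * pi / 180
  c(x = sin(i) * sin(a), y = sin(i) * cos(a), z = cos(i))
}

slerp_mid <- function(u, v) {
  w <- u + v
  w / sqrt(sum(w^2))
}

vec_to_angles <- function(v) {
  incl <- acos(max(-1, min(1, v[3]))) * 180 / pi
  az <- atan2(v[1], v[2]) * 180 / pi
  c(incl = incl, az = az)
}

# label -> c(inclination, azimuth); midline + left side, right mirrored below
montage_table <- function() {
  base <- list(
    Cz  = c(0, 0),
    Fz  = c(36, 0), Pz = c(36, 180),
    Fpz = c(72, 0), Oz = c(72, 180),
    # 10% circumferential ring, left
    Fp1 = c(72, -18), F7 = c(72, -54), T3 = c(72, -90),
    T5  = c(72, -126), O1 = c(72, -162),
    # coronal arc
    C3  = c(36, -90),
    # ear-level row
    F9  = c(90, -54), T9 = c(90, -90), P9 = c(90, -126), A1 = c(90, -98)
  )
  derived <- list(
    F3  = c("Fz", "F7"),
    P3  = c("Pz", "T5"),
    Fc1 = c("Cz", "F3"), Fc5 = c("C3", "F7"),
    Cp1 = c("Cz", "P3"), Cp5 = c("C3", "T5")
  )
  tab <- base
  for (nm in names(derived)) {
    pr <- derived[[nm]]
    u <- sph_vec(tab[[pr[1]]][1], tab[[pr[1]]][2])
    v <- sph_vec(tab[[pr[2]]][1], tab[[pr[2]]][2])
    tab[[nm]] <- unname(vec_to_angles(slerp_mid(u, v)))
  }
  # mirror the left hemisphere (odd indices / left letters) to the right
  mirror <- c(Fp1 = "Fp2", F7 = "F8", T3 = "T4", T5 = "T6", O1 = "O2",
              C3 = "C4", F3 = "F4", P3 = "P4", F9 = "F10", T9 = "T10",
              P9 = "P10", A1 = "A2", Fc1 = "Fc2", Fc5 = "Fc6",
              Cp1 = "Cp2", Cp5 = "Cp6")
  for (nm in names(mirror))
    tab[[mirror[[nm]]]] <- c(tab[[nm]][1], -tab[[nm]][2])
  tab
}

# aliases between 10-20 and 10-10 temporal names
montage_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Standard 10-20 montage positions
#'
#' Looks up scalp positions for channel labels in 10-20/10-10 nomenclature on
#' a spherical head model. Returns both 3D unit-sphere coordinates and the
#' standard 2D disc projection (Cz at the origin, nose along +y, right ear
#' along +x; radius 1 at ear level).
#'
#' @param labels character vector of channel labels. Case-insensitive;
#'   T7/T8/P7/P8 are accepted as aliases of T3/T4/T5/T6.
#' @return an object of class `eeg_montage`: list with `labels`, `pos2d`
#'   (n x 2 matrix, columns x/y) and `pos3d` (n x 3 unit vectors).
#' @examples
#' m <- standard_montage(c("Cz", "Fp2", "O1"))
#' m$pos2d
#' @export
standard_montage <- function(labels) {
  labels <- as.character(labels)
  tab <- montage_table()
  canon <- names(tab)
  key <- vapply(labels, function(l) {
    hit <- canon[tolower(canon) == tolower(l)]
    if (length(hit)) return(hit[1])
    al <- names(montage_aliases)[tolower(names(montage_aliases)) == tolower(l)]
    if (length(al)) return(unname(montage_aliases[al[1]]))
    NA_character_
  }, character(1))
  if (anyNA(key))
    stop("unknown channel labels: ", paste(labels[is.na(key)], collapse = ", "))
  ang <- t(vapply(key, function(k) tab[[k]], numeric(2)))
  pos3d <- t(apply(ang, 1, function(a) sph_vec(a[1], a[2])))
  r <- ang[, 1] / 90
  pos2d <- cbind(x = r * sin(ang[, 2] * pi / 180),
                 y = r * cos(ang[, 2] * pi / 180))
  rownames(pos2d) <- rownames(pos3d) <- labels
  colnames(pos3d) <- c("x", "y", "z")
  structure(list(labels = labels, pos2d = pos2d, pos3d = pos3d),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes (10-20 spherical model)\n",
              length(x$labels)))
  invisible(x)
}

#' Standard 29-channel clinical label set
#'
#' The 29 scalp channels used throughout: the 10-20 set plus the FC/CP rows
#' and F9/F10, matching clinical long-term monitoring montages.
#' @return character vector of 29 labels.
#' @export
clinical_channels <- function() {
  c("Fp1", "F3", "C3", "P3", "O1", "F7", "T3", "T5",
    "Fc1", "Fc5", "Cp1", "Cp5", "F9", "Fz", "Cz", "Pz",
    "Fp2", "F4", "C4", "P4", "O2", "F8", "T4", "T6",
    "Fc2", "Fc6", "Cp2", "Cp6", "F10")
}
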