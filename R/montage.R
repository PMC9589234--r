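#' The 19-channel 10-20 montage used throughout the package
#' @export
MONTAGE_1020 <- c("FP1", "FP2", "F3", "F4", "F7", "F8", "Fz",
                  "T3", "T4", "T5", "T6", "P3", "P4", "Pz",
                  "O1", "O2", "C3", "C4", "Cz")

# Idealized unit-sphere electrode positions from the 10-20 construction:
# the outer ring (FP1/2, F7/8, T3/4, T5/6, O1/2) sits at 72 deg inclination
# from the vertex with 36 deg azimuthal spacing (18 deg off midline for the
# frontal-polar and occipital pairs); midline Fz/Pz at 36 deg; C3/C4 at 36 deg
# lateral; F3/4 and P3/4 are spherical midpoints of their 10-20 neighbours.
electrode_positions <- function(channels = MONTAGE_1020) {
  sph <- function(incl_deg, az_deg) {
    i <- incl_deg * pi / 180; a <- az_deg * pi / 180
    c(x = sin(i) * cos(a), y = sin(i) * sin(a), z = cos(i))
  }
  slerp_mid <- function(u, v) {
    m <- (u + v) / 2
    m / sqrt(sum(m^2))
  }
  # azimuth: 0 = nasion (front), positive toward the left ear
  pos <- list(
    FP1 = sph(72, 18),   FP2 = sph(72, -18),
    F7  = sph(72, 54),   F8  = sph(72, -54),
    T3  = sph(72, 90),   T4  = sph(72, -90),
    T5  = sph(72, 126),  T6  = sph(72, -126),
    O1  = sph(72, 162),  O2  = sph(72, -162),
    Fz  = sph(36, 0),    Pz  = sph(36, 180),
    C3  = sph(36, 90),   C4  = sph(36, -90),
    Cz  = sph(0, 0)
  )
  pos$F3 <- slerp_mid(pos$Fz, pos$F7)
  pos$F4 <- slerp_mid(pos$Fz, pos$F8)
  pos$P3 <- slerp_mid(pos$Pz, pos$T5)
  pos$P4 <- slerp_mid(pos$Pz, pos$T6)
  names(pos) <- toupper(names(pos))
  out <- t(vapply(channels, function(ch) {
    p <- pos[[toupper(ch)]]
    if (is.null(p)) stop("unknown 10-20 label: ", ch)
    p
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}
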