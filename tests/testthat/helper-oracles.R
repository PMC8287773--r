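# Independent oracles, written against the raw label arrays so they do
# not share code with the package implementation.

# Exhaustive minimum distance between facing femur/tibia boundary-voxel
# centers in one slice matrix (rows superior -> inferior).
oracle_slice_min_gap <- function(slice, spacing_rc) {
  lab <- c(femur = 1L, tibia = 3L)
  fem <- slice == lab[["femur"]]
  tib <- slice == lab[["tibia"]]
  nr <- nrow(slice); nc <- ncol(slice)
  fem_face <- fem
  fem_face[] <- FALSE
  for (r in seq_len(nr)) {
    below <- if (r < nr) fem[r + 1L, ] else rep(FALSE, nc)
    fem_face[r, ] <- fem[r, ] & !below
  }
  tib_face <- tib
  tib_face[] <- FALSE
  for (r in seq_len(nr)) {
    above <- if (r > 1L) tib[r - 1L, ] else rep(FALSE, nc)
    tib_face[r, ] <- tib[r, ] & !above
  }
  fi <- which(fem_face, arr.ind = TRUE)
  ti <- which(tib_face, arr.ind = TRUE)
  if (nrow(fi) == 0L || nrow(ti) == 0L) return(NA_real_)
  best <- Inf
  for (k in seq_len(nrow(fi))) {
    d2 <- ((ti[, 1] - fi[k, 1]) * spacing_rc[1])^2 +
      ((ti[, 2] - fi[k, 2]) * spacing_rc[2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

oracle_mbgft <- function(volume) {
  d <- vapply(seq_len(dim(volume$data)[1]), function(s) {
    oracle_slice_min_gap(volume$data[s, , ], volume$spacing[2:3])
  }, numeric(1))
  d
}

hertz_indentation <- function(force_n, radius_mm, E_mpa, nu) {
  Estar <- E_mpa / (1 - nu^2)
  (9 * force_n^2 / (16 * radius_mm * Estar^2))^(1 / 3)
}

# small, fast phantom parameter factory for tests
small_phantom <- function(gap_mm = 5, delta_mm = 0.5,
                          condyle_radius = Inf,
                          spacing = c(2, 0.4, 0.4),
                          shape = c(6L, 96L, 96L), ...) {
  phantom_params(shape = shape, spacing = spacing,
                 condyle_radius = condyle_radius, plateau_extent = 24,
                 cartilage_thickness = 1, meniscus_height = 1,
                 bone_height = 6, gap_mm = gap_mm, delta_mm = delta_mm,
                 ...)
}
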