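#' Facing boundary voxels of the femur and tibia in one slice
#'
#' The bone gap is measured bone-to-bone: only the femur bone label and
#' tibia bone label are used (the gap spans cartilage and meniscus).
#' To avoid shaft-to-shaft shortcuts, surfaces are restricted to
#' "facing" boundary voxels: femur voxels whose inferior (next-row)
#' neighbour is not femur, and tibia voxels whose superior (previous-row)
#' neighbour is not tibia.
#'
#' @param slice Integer label matrix (rows = superior to inferior).
#' @param labels Label code map.
#' @return List with logical matrices `femur` and `tibia`.
#' @keywords internal
facing_boundaries <- function(slice, labels = knee_labels()) {
  fem <- slice == labels[["femur"]]
  tib <- slice == labels[["tibia"]]
  nr <- nrow(slice)
  below <- rbind(fem[-1, , drop = FALSE],
                 matrix(FALSE, 1, ncol(slice)))   # neighbour at row + 1
  above <- rbind(matrix(FALSE, 1, ncol(slice)),
                 tib[-nr, , drop = FALSE])        # neighbour at row - 1
  list(femur = fem & !below, tibia = tib & !above)
}

roi_plane_window <- function(slice, roi) {
  rr <- if (is.null(roi$rows)) c(1L, nrow(slice)) else
    c(max(1L, roi$rows[1]), min(nrow(slice), roi$rows[2]))
  cc <- if (is.null(roi$cols)) c(1L, ncol(slice)) else
    c(max(1L, roi$cols[1]), min(ncol(slice), roi$cols[2]))
  slice[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

#' Minimum in-plane femur--tibia distance in one slice
#'
#' Returns the minimum Euclidean distance (mm, physical spacing) between
#' the facing femur-bone and tibia-bone boundary voxel centers of one
#' slice, or `NA` ("absent") when either surface is missing in the
#' slice. An out-of-range slice index is an error, distinct from the
#' absent case.
#'
#' When the in-plane spacing is isotropic and the EBImage package is
#' available, the distance is evaluated with a Euclidean distance
#' transform of the femur surface sampled at the tibia surface voxels;
#' otherwise a vectorized nearest-pair search over the two boundary
#' point sets is used. Both routes give the minimum over boundary-voxel
#' center pairs.
#'
#' @param volume A `label_volume`.
#' @param slice_index 1-based slice index (must lie within the RoI).
#' @param roi A [roi()]; only its in-plane window is applied here.
#' @return Distance in mm, or `NA_real_` if a surface is absent.
#' @export
slice_min_gap <- function(volume, slice_index, roi = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  sl <- get_slice(volume, slice_index)      # errors on invalid index
  if (!is.null(roi)) {
    if (slice_index < roi$slices[1] || slice_index > roi$slices[2]) {
      stop("slice ", slice_index, " is outside the RoI slice range [",
           roi$slices[1], ", ", roi$slices[2], "]")
    }
    sp <- attr(sl, "in_plane_spacing")
    sl <- roi_plane_window(sl, roi)
    attr(sl, "in_plane_spacing") <- sp
  }
  sp <- attr(sl, "in_plane_spacing")
  b <- facing_boundaries(sl, volume$labels)
  if (!any(b$femur) || !any(b$tibia)) return(NA_real_)

  iso <- abs(sp[1] - sp[2]) < 1e-12 * max(sp)
  if (iso && requireNamespace("EBImage", quietly = TRUE)) {
    # distance transform of the femur surface, sampled on the tibia surface
    dt <- EBImage::distmap(matrix(as.numeric(!b$femur), nrow(sl), ncol(sl)),
                           metric = "euclidean")
    return(min(dt[b$tibia]) * sp[1])
  }
  fi <- which(b$femur, arr.ind = TRUE)
  ti <- which(b$tibia, arr.ind = TRUE)
  fy <- fi[, 1] * sp[1]; fx <- fi[, 2] * sp[2]
  ty <- ti[, 1] * sp[1]; tx <- ti[, 2] * sp[2]
  best <- Inf
  step <- max(1L, floor(2e6 / max(1L, length(fy))))
  for (start in seq(1L, length(ty), by = step)) {
    idx <- start:min(length(ty), start + step - 1L)
    d2 <- outer(ty[idx], fy, "-")^2 + outer(tx[idx], fx, "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Mean bone gap (mBGFT) over a region of interest
#'
#' Applies [slice_min_gap()] to every slice of the RoI and averages the
#' per-slice minima. Slices where either surface is absent are excluded
#' from both numerator and denominator.
#'
#' @param volume A `label_volume`.
#' @param roi A [roi()] giving the slice range (and optional in-plane
#'   window).
#' @return An object of class `gap_measurement`: list with `per_slice_mm`
#'   (named by slice index, `NA` for absent slices), `mbgft_mm`,
#'   `n_slices` (contributing count).
#' @export
measure_mbgft <- function(volume, roi) {
  stopifnot(inherits(volume, "label_volume"), inherits(roi, "roi"))
  ns <- n_slices(volume)
  if (roi$slices[2] > ns) {
    stop("RoI slice range exceeds the volume (", ns, " slices)")
  }
  sl <- roi$slices[1]:roi$slices[2]
  d <- vapply(sl, function(s) slice_min_gap(volume, s, roi), numeric(1))
  names(d) <- sl
  ok <- !is.na(d)
  if (!any(ok)) {
    stop("empty measurement: no RoI slice contains both joint surfaces")
  }
  structure(list(per_slice_mm = d, mbgft_mm = mean(d[ok]),
                 n_slices = sum(ok)),
            class = "gap_measurement")
}

#' @export
print.gap_measurement <- function(x, ...) {
  cat(sprintf("mBGFT = %.3f mm over %d slice(s)\n", x$mbgft_mm, x$n_slices))
  invisible(x)
}

#' Joint compressive strain from paired gap measurements
#'
#' Computes the gap reduction ΔmBGFT = unloaded − loaded mBGFT and the
#' compressive strain ε = ΔmBGFT / unloaded mBGFT. A negative ΔmBGFT
#' (gap widening under load) is passed through with a warning, not
#' clamped — it is diagnostically meaningful.
#'
#' @param unloaded,loaded `gap_measurement` objects (or bare numeric
#'   mBGFT values in mm).
#' @return An object of class `strain_result`: list with
#'   `mbgft_unloaded_mm`, `mbgft_loaded_mm`, `delta_mbgft_mm`,
#'   `pct_delta_mbgft`, `strain`.
#' @export
#' @examples
#' compute_strain(5.92, 4.98)$strain   # 0.94 / 5.92
compute_strain <- function(unloaded, loaded) {
  g <- function(x) {
    if (inherits(x, "gap_measurement")) x$mbgft_mm
    else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
    else stop("expected a gap_measurement or a single numeric mBGFT")
  }
  u <- g(unloaded); l <- g(loaded)
  if (!is.finite(u) || u <= 0) {
    stop("unloaded mBGFT must be positive, got ", u)
  }
  d <- u - l
  if (d < 0) {
    warning("negative ΔmBGFT (", round(d, 4),
            " mm): bone gap widened under load")
  }
  structure(list(mbgft_unloaded_mm = u, mbgft_loaded_mm = l,
                 delta_mbgft_mm = d, pct_delta_mbgft = 100 * d / u,
                 strain = d / u),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf(
    "mBGFT %.3f -> %.3f mm; ΔmBGFT = %.3f mm (%.2f%%); strain = %.5f\n",
    x$mbgft_unloaded_mm, x$mbgft_loaded_mm, x$delta_mbgft_mm,
    x$pct_delta_mbgft, x$strain))
  invisible(x)
}
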