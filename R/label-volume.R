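#' Tissue label codes used throughout the package
#'
#' Fixed integer coding for segmentation label volumes: background = 0,
#' femur = 1, femoral cartilage = 2, tibia = 3, tibial cartilage = 4,
#' meniscus = 5.
#' @return Named integer vector.
#' @export
knee_labels <- function() {
  c(background = 0L, femur = 1L, femoral_cartilage = 2L,
    tibia = 3L, tibial_cartilage = 4L, meniscus = 5L)
}

#' Construct a label volume
#'
#' A light container for a 3-D integer segmentation map with physical
#' voxel spacing. By convention the first array axis indexes sagittal
#' slices; within a slice, rows run superior to inferior (femur above,
#' tibia below) and columns run anterior to posterior.
#'
#' @param data 3-D integer array of label codes.
#' @param spacing Numeric length-3, voxel spacing in mm per array axis
#'   (slice, row, column), all positive.
#' @param slice_axis Index of the slice axis (default 1).
#' @param labels Named integer vector of allowed codes
#'   (default [knee_labels()]).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, slice_axis = 1L,
                         labels = knee_labels()) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0),
            slice_axis %in% 1:3)
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(labels))
  if (length(bad) > 0) {
    stop("volume contains undeclared label codes: ",
         paste(bad, collapse = ", "))
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 slice_axis = as.integer(slice_axis), labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %s mm, slice axis %d\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "), x$slice_axis))
  invisible(x)
}

#' Number of slices of a label volume
#' @param volume A `label_volume`.
#' @return Integer slice count along the slice axis.
#' @export
n_slices <- function(volume) dim(volume$data)[volume$slice_axis]

#' Extract one slice as a 2-D label matrix
#'
#' Rows of the returned matrix are the in-plane vertical axis
#' (superior to inferior), columns the in-plane horizontal axis.
#' @param volume A `label_volume`.
#' @param slice_index 1-based slice index.
#' @return Integer matrix plus attribute `in_plane_spacing` (mm, length 2).
#' @export
get_slice <- function(volume, slice_index) {
  ns <- n_slices(volume)
  if (!is.numeric(slice_index) || length(slice_index) != 1L ||
      slice_index < 1L || slice_index > ns || slice_index != round(slice_index)) {
    stop("invalid slice index ", slice_index, " (volume has ", ns, " slices)")
  }
  ax <- volume$slice_axis
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx[[ax]] <- slice_index
  m <- do.call(`[`, c(list(volume$data), idx, list(drop = FALSE)))
  m <- array(m, dim = dim(m)[-ax])
  attr(m, "in_plane_spacing") <- volume$spacing[-ax]
  m
}

#' Write a label volume to NIfTI-1
#'
#' Integer data with voxel spacing stored in the header (mm units).
#' @param volume A `label_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  x <- volume$data
  attr(x, "pixdim") <- volume$spacing
  attr(x, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(x, path, datatype = "int16")
  invisible(path)
}

#' Read a label volume from NIfTI-1
#' @param path NIfTI file path.
#' @param slice_axis Slice axis of the stored volume (default 1).
#' @param labels Label code map (default [knee_labels()]).
#' @return A `label_volume`.
#' @export
read_label_volume <- function(path, slice_axis = 1L, labels = knee_labels()) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  label_volume(array(as.integer(round(img)), dim = dim(img)[1:3]),
               spacing = sp, slice_axis = slice_axis, labels = labels)
}

#' Region of interest for gap measurement
#'
#' Inclusive slice range, optionally restricted in-plane, over which the
#' per-slice bone gap is measured (anatomically: trochlea through the
#' femoral condyles).
#'
#' @param slices Integer length-2, inclusive first/last slice.
#' @param rows,cols Optional inclusive in-plane ranges (length-2) or
#'   `NULL` for the full plane.
#' @return An object of class `roi`.
#' @export
roi <- function(slices, rows = NULL, cols = NULL) {
  chk <- function(r, nm) {
    if (!is.null(r)) {
      stopifnot(length(r) == 2L, r[1] <= r[2], r[1] >= 1L)
    }
    r
  }
  stopifnot(length(slices) == 2L, slices[1] <= slices[2], slices[1] >= 1L)
  structure(list(slices = as.integer(slices), rows = chk(rows),
                 cols = chk(cols)), class = "roi")
}
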