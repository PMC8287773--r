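#' Parameters of the synthetic knee phantom
#'
#' Describes a digital phantom emulating a sagittally sliced knee
#' segmentation: a femur with a (spherically) curved distal condyle and
#' a femoral cartilage layer, above a flat tibial plateau with tibial
#' cartilage and a peripheral meniscus wedge, separated by a bone gap of
#' `gap_mm` at the contact apex. Under load the whole femur complex
#' translates rigidly and axially downward by `delta_mm` (no rotation),
#' quantized to the voxel grid.
#'
#' Defaults mirror a 3-D gradient-echo knee acquisition: 72 sagittal
#' slices of 2 mm, 512 x 512 in-plane matrix over a 140 mm field of
#' view (0.2734 mm pixels).
#'
#' @param shape Volume dimensions (slices, rows, cols).
#' @param spacing Voxel spacing in mm (slice, row, col).
#' @param condyle_radius Condyle radius of curvature in mm; `Inf` gives
#'   flat (parallel-plate) surfaces.
#' @param plateau_extent Full width of the tibial plateau in mm.
#' @param cartilage_thickness Thickness of each cartilage layer (mm).
#' @param meniscus_height Peak height of the meniscus wedge at the
#'   plateau rim (mm); 0 omits the meniscus.
#' @param bone_height Modelled shaft height of each bone segment (mm).
#' @param gap_mm Unloaded bone gap g0 at the apex (mm).
#' @param delta_mm True gap reduction under load (mm), `0 <= delta_mm < gap_mm`.
#' @param slice_range Optional inclusive slice range containing the
#'   joint; `NULL` selects all slices where both surfaces exist.
#' @param seed Random seed recorded with the phantom (the geometry
#'   itself is deterministic).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(72L, 512L, 512L),
                           spacing = c(2, 140 / 512, 140 / 512),
                           condyle_radius = 25,
                           plateau_extent = 35,
                           cartilage_thickness = 2,
                           meniscus_height = 4,
                           bone_height = 12,
                           gap_mm = 6,
                           delta_mm = 0.6,
                           slice_range = NULL,
                           seed = 0L) {
  stopifnot(length(shape) == 3L, all(shape >= 4), all(shape == round(shape)),
            length(spacing) == 3L, all(spacing > 0),
            condyle_radius > 0, plateau_extent > 0,
            cartilage_thickness > 0, meniscus_height >= 0, bone_height > 0,
            gap_mm > 0, delta_mm >= 0)
  if (delta_mm >= gap_mm) {
    stop("loaded gap reduction delta_mm (", delta_mm,
         ") must be smaller than the unloaded gap gap_mm (", gap_mm, ")")
  }
  if (gap_mm <= 2 * cartilage_thickness + delta_mm) {
    stop("gap_mm must exceed the two cartilage layers plus delta_mm, ",
         "otherwise the loaded femoral cartilage would overlap the tibial side")
  }
  if (!is.null(slice_range)) {
    stopifnot(length(slice_range) == 2L, slice_range[1] >= 1L,
              slice_range[2] <= shape[1], slice_range[1] <= slice_range[2])
  }
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            condyle_radius = condyle_radius,
            plateau_extent = plateau_extent,
            cartilage_thickness = cartilage_thickness,
            meniscus_height = meniscus_height, bone_height = bone_height,
            gap_mm = gap_mm, delta_mm = delta_mm,
            slice_range = slice_range, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_geometry(p)
  p
}

validate_phantom_geometry <- function(p) {
  fov <- p$shape * p$spacing                 # mm extents (slice, row, col)
  w <- p$plateau_extent / 2
  if (2 * w + 2 * p$spacing[3] > fov[3]) {
    # the slice stack may cover only part of the joint, but the plateau
    # must fit within the in-plane field of view
    stop("volume too small: plateau_extent ", p$plateau_extent,
         " mm does not fit in the in-plane field of view (",
         round(fov[3], 1), " mm)")
  }
  sag_max <- condyle_sagitta(p, condyle_half_extent(p))
  need_y <- 2 * p$bone_height + p$gap_mm + sag_max + 2 * p$spacing[2]
  if (need_y > fov[2]) {
    stop("volume too small vertically: need ", round(need_y, 1),
         " mm but field of view is ", round(fov[2], 1), " mm")
  }
  invisible(p)
}

condyle_half_extent <- function(p) {
  w <- p$plateau_extent / 2
  if (is.finite(p$condyle_radius)) min(w, 0.8 * p$condyle_radius) else w
}

condyle_sagitta <- function(p, rho) {
  if (!is.finite(p$condyle_radius)) return(rho * 0)
  R <- p$condyle_radius
  rho <- pmin(rho, R)
  R - sqrt(R^2 - rho^2)
}

#' Generate a paired loaded/unloaded knee phantom
#'
#' Builds two segmentation label volumes ([knee_labels()] coding) that
#' differ only by a rigid, purely axial, grid-quantized downward
#' translation of the femur complex (femur bone + femoral cartilage) by
#' `delta_mm`, together with the analytic ground truth of the per-slice
#' bone gap. Gaps are expressed, like the downstream morphometry,
#' as distances between boundary-voxel centers; sub-voxel surface
#' positions are quantized to the grid and the quantized values are what
#' the truth records.
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `knee_phantom`: list with `unloaded` and
#'   `loaded` (`label_volume`) and `truth` (per-slice gaps, quantized
#'   translation `delta_quantized_mm`, `mbgft_true_unloaded_mm`,
#'   `mbgft_true_loaded_mm`, `delta_mbgft_true_mm`, `strain_true`,
#'   `roi_slices`).
#' @export
#' @examples
#' p <- phantom_params(shape = c(8, 64, 64), spacing = c(2, 0.5, 0.5),
#'                     condyle_radius = Inf, plateau_extent = 24,
#'                     cartilage_thickness = 1, meniscus_height = 1,
#'                     bone_height = 5, gap_mm = 5, delta_mm = 0.5)
#' ph <- generate_knee_phantom(p)
#' ph$truth$delta_mbgft_true_mm
generate_knee_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  S <- p$shape[1]; Rr <- p$shape[2]; Cc <- p$shape[3]
  sp <- p$spacing
  lab <- knee_labels()

  z <- (seq_len(S) - 0.5) * sp[1]
  y <- (seq_len(Rr) - 0.5) * sp[2]
  x <- (seq_len(Cc) - 0.5) * sp[3]
  z0 <- S * sp[1] / 2; x0 <- Cc * sp[3] / 2

  w <- p$plateau_extent / 2
  wf <- condyle_half_extent(p)
  sag_max <- condyle_sagitta(p, wf)
  # the femur surface recedes superiorly away from the apex; place the
  # joint so femur shaft (above the receded edge), gap and tibia all fit
  y_apex <- p$bone_height + sag_max + sp[2]  # deepest femur-bone point
  tfc <- p$cartilage_thickness; ttc <- p$cartilage_thickness

  dq <- round(p$delta_mm / sp[2]) * sp[2]    # grid-quantized translation

  rm_in <- 0.5 * w                            # meniscus inner radius

  # nominal surfaces denote boundary-VOXEL-CENTER positions: each
  # interface is snapped to the nearest row center (half-up). The tibia
  # surface is placed a whole number of rows below the femoral apex so
  # the realized center-to-center bone gap (what the morphometry
  # measures) equals the requested gap quantized to the grid, i.e.
  # within half a voxel of g0.
  snapk <- function(yy) as.integer(floor(yy / sp[2] + 1 + 1e-9))
  yt0 <- (snapk(y_apex) + floor(p$gap_mm / sp[2] + 0.5 + 1e-9) - 0.5) * sp[2]

  build <- function(shift) {
    vol <- array(0L, dim = c(S, Rr, Cc))
    gaps <- rep(NA_real_, S)                 # per-slice quantized min gap
    for (s in seq_len(S)) {
      dzs <- z[s] - z0
      rho <- sqrt((x - x0)^2 + dzs^2)
      on_plate <- rho <= w
      on_cond <- rho <= wf
      yb <- ifelse(on_cond, y_apex - condyle_sagitta(p, rho) + shift, NA)
      yt <- ifelse(on_plate, yt0, NA)

      kb <- ifelse(is.na(yb), NA_integer_, snapk(yb))       # femur bottom row
      kbc <- ifelse(is.na(yb), NA_integer_, snapk(yb + tfc))
      kt <- ifelse(is.na(yt), NA_integer_, snapk(yt))       # tibia top row
      ktc <- ifelse(is.na(yt), NA_integer_, snapk(yt - ttc))
      kftop <- ifelse(is.na(yb), NA_integer_,
                      snapk(y_apex - sag_max - p$bone_height + shift))
      ktbot <- ifelse(is.na(yt), NA_integer_, snapk(yt + p$bone_height))

      rows <- matrix(seq_len(Rr), Rr, Cc)
      band <- function(klo, khi) {
        lo <- matrix(klo, Rr, Cc, byrow = TRUE)
        hi <- matrix(khi, Rr, Cc, byrow = TRUE)
        !is.na(lo) & !is.na(hi) & rows >= lo & rows <= hi
      }
      M <- matrix(0L, Rr, Cc)
      M[band(pmax(kftop, 1L), kb)] <- lab[["femur"]]
      M[band(kb + 1L, kbc)] <- lab[["femoral_cartilage"]]
      M[band(kt, pmin(ktbot, Rr))] <- lab[["tibia"]]
      M[band(ktc, kt - 1L)] <- lab[["tibial_cartilage"]]

      if (p$meniscus_height > 0 && w > rm_in) {
        hm <- p$meniscus_height * pmax(0, (rho - rm_in)) / (w - rm_in)
        hm[!on_plate] <- 0
        # keep clear of the femoral cartilage underside
        clear <- ifelse(is.na(yb), Inf, yt0 - ttc - (yb + tfc) - sp[2])
        hm <- pmin(hm, pmax(0, clear))
        kmen <- ifelse(is.na(yt) | hm <= 0, NA_integer_,
                       snapk(yt - ttc - hm))
        men <- band(kmen, ktc - 1L) & M == 0L
        M[men] <- lab[["meniscus"]]
      }
      vol[s, , ] <- M
      valid <- !is.na(kb) & !is.na(kt) & kb >= 1
      gap_c <- ifelse(valid, (kt - kb) * sp[2], NA)
      g <- suppressWarnings(min(gap_c, na.rm = TRUE))
      if (is.finite(g)) gaps[s] <- g
    }
    list(vol = vol, gaps = gaps)
  }

  unl <- build(0)
  lod <- build(dq)

  keep <- which(!is.na(unl$gaps) & !is.na(lod$gaps))
  if (!is.null(p$slice_range)) {
    keep <- keep[keep >= p$slice_range[1] & keep <= p$slice_range[2]]
  }
  if (length(keep) == 0L) stop("no slice contains both joint surfaces")

  gu <- unl$gaps; gl <- lod$gaps
  mu <- mean(gu[keep]); ml <- mean(gl[keep])
  truth <- list(
    per_slice_gap_unloaded_mm = gu,
    per_slice_gap_loaded_mm = gl,
    roi_slices = c(min(keep), max(keep)),
    contributing_slices = keep,
    delta_quantized_mm = dq,
    mbgft_true_unloaded_mm = mu,
    mbgft_true_loaded_mm = ml,
    delta_mbgft_true_mm = mu - ml,
    strain_true = (mu - ml) / mu
  )

  structure(
    list(unloaded = label_volume(unl$vol, sp),
         loaded = label_volume(lod$vol, sp),
         truth = truth, params = p),
    class = "knee_phantom"
  )
}

#' @export
print.knee_phantom <- function(x, ...) {
  t <- x$truth
  cat(sprintf(
    "knee_phantom: %s voxels; true mBGFT %.3f -> %.3f mm (delta %.3f mm, strain %.4f)\n",
    paste(dim(x$unloaded$data), collapse = " x "),
    t$mbgft_true_unloaded_mm, t$mbgft_true_loaded_mm,
    t$delta_mbgft_true_mm, t$strain_true))
  invisible(x)
}

#' Write a phantom pair to disk
#'
#' Writes `unloaded.nii.gz`, `loaded.nii.gz` and a `truth.json` sidecar
#' into `dir`.
#' @param phantom A `knee_phantom`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "knee_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_label_volume(phantom$unloaded, file.path(dir, "unloaded.nii.gz"))
  write_label_volume(phantom$loaded, file.path(dir, "loaded.nii.gz"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Specification of a synthetic noisy strain--stiffness sweep
#'
#' Describes a sweep table drawn from a known power law with
#' multiplicative log-normal noise:
#' \eqn{\varepsilon_i = a \, E_i^{b} \, e^{\eta_i}},
#' \eqn{\eta_i \sim N(0, sd^2)}.
#'
#' @param a_gen Generating scaling coefficient, positive.
#' @param b_gen Generating power coefficient, negative.
#' @param noise_sd Standard deviation of the multiplicative log-noise
#'   (0 gives an exact power law).
#' @param grid Stiffness grid in MPa, positive and strictly increasing.
#' @param seed Random seed.
#' @return An object of class `sweep_noise_spec`.
#' @export
sweep_noise_spec <- function(a_gen, b_gen, noise_sd = 0,
                             grid = c(1, 2, 3, 5, 10, 15, 20, 25, 30, 50),
                             seed = 0L) {
  stopifnot(is.numeric(a_gen), length(a_gen) == 1L, a_gen > 0,
            is.numeric(b_gen), length(b_gen) == 1L, b_gen < 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(grid), all(grid > 0), all(diff(grid) > 0))
  structure(list(a_gen = a_gen, b_gen = b_gen, noise_sd = noise_sd,
                 grid = as.numeric(grid), seed = as.integer(seed)),
            class = "sweep_noise_spec")
}

#' Generate a synthetic strain--stiffness sweep table
#'
#' Deterministic for a fixed seed; the R session's RNG state is left
#' untouched.
#' @param spec A [sweep_noise_spec()].
#' @return data.frame with columns `stiffness_mpa`, `strain`.
#' @export
generate_sweep_table <- function(spec) {
  stopifnot(inherits(spec, "sweep_noise_spec"))
  eta <- if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    stats::rnorm(length(spec$grid), 0, spec$noise_sd)
  } else {
    numeric(length(spec$grid))
  }
  data.frame(
    stiffness_mpa = spec$grid,
    strain = spec$a_gen * spec$grid^spec$b_gen * exp(eta)
  )
}
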