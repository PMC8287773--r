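#' Parametric geometry for the simplified contact FEM
#'
#' Defines the reduced-dimension (2-D) idealization of the tibiofemoral
#' joint used by the solver: a single spherical condyle with a femoral
#' cartilage layer above a flat tibial plateau carrying tibial cartilage
#' and a peripheral meniscus wedge (annular in the axisymmetric mode).
#' The coordinate frame is (r, z) with z up; z = 0 at the tibial
#' cartilage top surface.
#'
#' @param mode `"axisymmetric"` (single-condyle idealization, default)
#'   or `"plane_strain"`.
#' @param condyle_radius Effective relative-curvature radius of the
#'   articulation (mm). The default (600 mm) represents a congruent
#'   tibiofemoral contact: the femoral condyle (about 25 mm) articulates
#'   against a concave tibial socket completed by the meniscus, so the
#'   relative curvature of the load-bearing interface is an order of
#'   magnitude flatter than the bare condyle. Use about 25 mm for an
#'   unconforming condyle-on-plane contact, or `Inf` for the flat-punch
#'   limit.
#' @param plateau_radius Tibial plateau radius / half-width (mm).
#' @param condyle_extent Lateral half-extent of the femur complex (mm),
#'   must not exceed `plateau_radius` (nor 0.8 x condyle radius).
#' @param cartilage_thickness_femoral,cartilage_thickness_tibial
#'   Cartilage layer thicknesses (mm).
#' @param meniscus_inner_radius Inner radius of the meniscus wedge (mm);
#'   `NULL` drops the meniscus.
#' @param meniscus_height Meniscus height at the plateau rim (mm).
#' @param meniscus_min_height Height at the inner (tip) edge (mm, > 0 to
#'   avoid degenerate elements).
#' @param bone_height Modelled bone segment height (mm), femur and tibia.
#' @param apex_gap Initial vertical clearance between the femoral
#'   cartilage apex and the tibial cartilage surface (mm); 0 = touching.
#' @return An object of class `geometry_model` (kind `"knee"`).
#' @export
geometry_model <- function(mode = c("axisymmetric", "plane_strain"),
                           condyle_radius = 600,
                           plateau_radius = 20,
                           condyle_extent = 10,
                           cartilage_thickness_femoral = 2,
                           cartilage_thickness_tibial = 2,
                           meniscus_inner_radius = 10,
                           meniscus_height = 3,
                           meniscus_min_height = 0.2,
                           bone_height = 10,
                           apex_gap = 0) {
  mode <- match.arg(mode)
  stopifnot(condyle_radius > 0, plateau_radius > 0, condyle_extent > 0,
            cartilage_thickness_femoral > 0, cartilage_thickness_tibial > 0,
            bone_height > 0, apex_gap >= 0)
  if (is.finite(condyle_radius) && condyle_extent > 0.8 * condyle_radius) {
    stop("condyle_extent must not exceed 0.8 x condyle_radius")
  }
  if (condyle_extent > plateau_radius) {
    stop("condyle_extent must not exceed plateau_radius")
  }
  if (!is.null(meniscus_inner_radius)) {
    stopifnot(meniscus_inner_radius > 0,
              meniscus_inner_radius < plateau_radius,
              meniscus_height > 0, meniscus_min_height > 0,
              meniscus_min_height <= meniscus_height)
  }
  structure(list(kind = "knee", mode = mode,
                 condyle_radius = condyle_radius,
                 plateau_radius = plateau_radius,
                 condyle_extent = condyle_extent,
                 cartilage_thickness_femoral = cartilage_thickness_femoral,
                 cartilage_thickness_tibial = cartilage_thickness_tibial,
                 meniscus_inner_radius = meniscus_inner_radius,
                 meniscus_height = meniscus_height,
                 meniscus_min_height = meniscus_min_height,
                 bone_height = bone_height,
                 apex_gap = apex_gap),
            class = "geometry_model")
}

#' Uniform column geometry (verification case)
#'
#' A homogeneous circular column of cross-section `area_mm2` and height
#' `height_mm` loaded axially through a rigid platen: closed form
#' deformation is F h / (A E) (with nu = 0, or with a frictionless
#' roller support for any nu).
#' @param area_mm2 Cross-sectional area (mm^2).
#' @param height_mm Column height (mm).
#' @param mode Analysis mode.
#' @return A `geometry_model` (kind `"column"`).
#' @export
column_geometry <- function(area_mm2 = 100, height_mm = 4,
                            mode = c("axisymmetric", "plane_strain")) {
  mode <- match.arg(mode)
  stopifnot(area_mm2 > 0, height_mm > 0)
  structure(list(kind = "column", mode = mode, area_mm2 = area_mm2,
                 height_mm = height_mm,
                 radius = sqrt(area_mm2 / pi)),
            class = "geometry_model")
}

#' Elastic half-space indented by a rigid sphere (Hertz verification)
#'
#' Axisymmetric half-space of extent `domain_mm` (radially and in depth)
#' contacted by a rigid spherical indenter of radius `sphere_radius`.
#' The indenter profile is the paraboloid r^2/(2R) that Hertz theory
#' itself assumes, so the closed form
#' \eqn{\delta = (9 F^2 / (16 R E^{*2}))^{1/3}},
#' \eqn{E^* = E/(1-\nu^2)}, is the exact continuum limit. The mesh is
#' geometrically graded toward the contact region.
#'
#' @param sphere_radius Indenter radius R (mm).
#' @param domain_mm Half-space truncation extent (mm); large relative to
#'   the contact radius so the truncation error stays around 1%.
#' @param profile `"paraboloid"` (Hertz assumption, default) or
#'   `"sphere"` (exact circular sagitta).
#' @return A `geometry_model` (kind `"halfspace"`).
#' @export
halfspace_geometry <- function(sphere_radius = 20, domain_mm = 200,
                               profile = c("paraboloid", "sphere")) {
  profile <- match.arg(profile)
  stopifnot(sphere_radius > 0, domain_mm > 4 * sphere_radius)
  structure(list(kind = "halfspace", mode = "axisymmetric",
                 sphere_radius = sphere_radius, domain_mm = domain_mm,
                 profile = profile),
            class = "geometry_model")
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf("geometry_model kind '%s' (%s)\n", x$kind, x$mode))
  invisible(x)
}

#' Material set for the contact FEM
#'
#' Isotropic linear-elastic properties per tissue. Bone is fixed at
#' E = 1000 MPa, nu = 0.3; cartilage uses nu = 0.45 and meniscus
#' nu = 0.3. One sweep modulus (`soft_E`) is applied to cartilage and
#' meniscus simultaneously unless overridden.
#'
#' @param soft_E Weight-bearing soft-tissue Young's modulus (MPa),
#'   applied to cartilage and meniscus.
#' @param cartilage_E,meniscus_E Optional overrides (MPa).
#' @param bone_E,bone_nu,cartilage_nu,meniscus_nu Fixed constants with
#'   the stated defaults.
#' @return An object of class `material_set`: named list of
#'   `c(E, nu)` pairs per tissue.
#' @export
material_set <- function(soft_E = 10,
                         cartilage_E = NULL, meniscus_E = NULL,
                         bone_E = 1000, bone_nu = 0.3,
                         cartilage_nu = 0.45, meniscus_nu = 0.3) {
  Ec <- if (is.null(cartilage_E)) soft_E else cartilage_E
  Em <- if (is.null(meniscus_E)) soft_E else meniscus_E
  for (E in c(Ec, Em, bone_E)) stopifnot(is.finite(E), E > 0)
  for (nu in c(bone_nu, cartilage_nu, meniscus_nu)) {
    stopifnot(nu >= 0, nu < 0.5)
  }
  structure(list(
    bone = c(E = bone_E, nu = bone_nu),
    cartilage = c(E = Ec, nu = cartilage_nu),
    meniscus = c(E = Em, nu = meniscus_nu),
    soft = c(E = soft_E, nu = cartilage_nu)   # homogeneous test bodies
  ), class = "material_set")
}

#' Load case for the contact FEM
#'
#' Total axial force (50% body weight in the in-vivo protocol) applied
#' in equal substeps; the increment is `force_n / substeps` (400 N in 5
#' substeps gives the 80 N increment). The large-deflection flag
#' switches on updated-coordinate incremental loading and is meant for
#' soft-tissue stiffness below 5 MPa.
#'
#' @param force_n Total axial force (N), positive.
#' @param substeps Number of equal load substeps (default 5).
#' @param large_deflection Logical.
#' @return An object of class `load_case`.
#' @export
load_case <- function(force_n, substeps = 5L, large_deflection = FALSE) {
  stopifnot(is.numeric(force_n), length(force_n) == 1L, force_n > 0,
            substeps >= 1L, substeps == round(substeps))
  structure(list(force_n = force_n, substeps = as.integer(substeps),
                 increment_n = force_n / substeps,
                 large_deflection = isTRUE(large_deflection)),
            class = "load_case")
}
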