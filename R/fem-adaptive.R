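#' Adaptive mesh-convergence solve
#'
#' Solves the contact problem, uniformly refines the mesh (halving the
#' target element size), re-solves, and repeats until the signed
#' relative change of the monitored axial deformation between successive
#' refinement loops,
#' `100 * (delta_prev - delta_new) / delta_new` percent
#' (negative when refinement increases the deformation), has magnitude
#' at most `max_error_pct`.
#'
#' @param mesh A `fem_mesh` (its geometry is carried along for
#'   rebuilding at finer sizes), or a `geometry_model` plus
#'   `base_size`.
#' @param materials A [material_set()].
#' @param load A [load_case()].
#' @param max_error_pct Convergence-error bound in percent (default 5).
#' @param max_loops Maximum number of refinement loops.
#' @param base_size Element size used when `mesh` is a geometry.
#' @return List with `result` (the final [solve_contact()] output),
#'   `convergence_error_pct` (signed, of the last refinement), and
#'   `trace` (data.frame of element size, delta_z, error per loop).
#' @export
adaptive_solve <- function(mesh, materials, load, max_error_pct = 5,
                           max_loops = 3L, base_size = NULL) {
  if (inherits(mesh, "geometry_model")) {
    if (is.null(base_size)) stop("base_size is required with a geometry_model")
    mesh <- build_mesh(mesh, base_size)
  }
  stopifnot(inherits(mesh, "fem_mesh"))
  geom <- mesh$geom
  size <- mesh$target_size
  res_prev <- solve_contact(mesh, materials, load)
  trace <- data.frame(element_size_mm = size,
                      delta_z_mm = res_prev$delta_z_mm,
                      convergence_error_pct = NA_real_)
  err <- NA_real_
  for (loop in seq_len(max_loops)) {
    size <- size / 2
    mesh_f <- build_mesh(geom, size)
    res_new <- solve_contact(mesh_f, materials, load)
    err <- 100 * (res_prev$delta_z_mm - res_new$delta_z_mm) /
      res_new$delta_z_mm
    trace <- rbind(trace, data.frame(element_size_mm = size,
                                     delta_z_mm = res_new$delta_z_mm,
                                     convergence_error_pct = err))
    res_prev <- res_new
    if (abs(err) <= max_error_pct) {
      return(list(result = res_new, convergence_error_pct = err,
                  trace = trace))
    }
  }
  stop("adaptive refinement did not reach ", max_error_pct,
       "% within ", max_loops, " loops; error trace: ",
       paste(signif(trace$convergence_error_pct[-1], 4), collapse = ", "))
}

#' Run the soft-tissue stiffness sweep
#'
#' Performs one adaptive contact solve per stiffness value, with the
#' sweep modulus applied to cartilage and meniscus simultaneously, the
#' large-deflection flag set exactly for stiffness below 5 MPa, and the
#' simulated strain normalized by the unloaded mean bone gap:
#' `strain_i = delta_z_i / unloaded_gap_mm`. Stiffness values whose
#' solve fails are reported as `NA` rows rather than fabricated.
#'
#' @param geom A `geometry_model` (typically the default condyle
#'   geometry from [geometry_model()]).
#' @param load A [load_case()] (its large-deflection flag is overridden
#'   per stiffness value) or a single total force in N.
#' @param stiffness_grid Stiffness grid in MPa (default the ten-value
#'   grid 1--50 MPa).
#' @param unloaded_gap_mm Unloaded mBGFT used to normalize deformation
#'   into strain.
#' @param base_size Starting soft-tissue element size (mm).
#' @param max_error_pct Adaptive convergence bound (percent).
#' @param progress Print one line per stiffness value.
#' @return A `sweep_table` data.frame with columns `stiffness_mpa`,
#'   `deformation_mm`, `strain`, `convergence_error_pct` (attribute
#'   `traces` holds the per-value refinement traces).
#' @export
run_stiffness_sweep <- function(geom, load,
                                stiffness_grid = c(1, 2, 3, 5, 10, 15,
                                                   20, 25, 30, 50),
                                unloaded_gap_mm = 6,
                                base_size = 1.2,
                                max_error_pct = 5,
                                progress = FALSE) {
  stopifnot(inherits(geom, "geometry_model"),
            all(stiffness_grid > 0), unloaded_gap_mm > 0)
  if (is.numeric(load)) load <- load_case(load)
  stopifnot(inherits(load, "load_case"))

  n <- length(stiffness_grid)
  out <- data.frame(stiffness_mpa = stiffness_grid,
                    deformation_mm = NA_real_,
                    strain = NA_real_,
                    convergence_error_pct = NA_real_)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    E <- stiffness_grid[i]
    mats <- material_set(soft_E = E)
    lc <- load_case(load$force_n, load$substeps,
                    large_deflection = E < 5)
    ans <- tryCatch(
      adaptive_solve(geom, mats, lc, max_error_pct = max_error_pct,
                     base_size = base_size),
      error = function(e) e
    )
    if (inherits(ans, "error")) {
      warning("stiffness ", E, " MPa did not converge: ",
              conditionMessage(ans))
      next
    }
    out$deformation_mm[i] <- ans$result$delta_z_mm
    out$strain[i] <- ans$result$delta_z_mm / unloaded_gap_mm
    out$convergence_error_pct[i] <- ans$convergence_error_pct
    traces[[i]] <- ans$trace
    if (progress) {
      message(sprintf("E = %5.1f MPa: delta_z = %.4f mm (conv err %+.3f%%)",
                      E, out$deformation_mm[i],
                      out$convergence_error_pct[i]))
    }
  }
  attr(out, "traces") <- traces
  attr(out, "unloaded_gap_mm") <- unloaded_gap_mm
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Write / read a sweep table as CSV
#'
#' CSV with header `stiffness_mpa,deformation_mm,strain,convergence_error_pct`
#' (only the first and `strain` columns are required on read).
#' @param sweep A sweep table data.frame.
#' @param path CSV path.
#' @return `path` (write) or the sweep data.frame (read).
#' @export
write_sweep_table <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep)[, intersect(
    c("stiffness_mpa", "deformation_mm", "strain",
      "convergence_error_pct"), names(sweep))],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("stiffness_mpa", "strain") %in% names(tab))) {
    stop("sweep CSV must have columns stiffness_mpa and strain")
  }
  class(tab) <- c("sweep_table", "data.frame")
  tab
}
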