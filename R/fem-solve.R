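# Frictionless contact solver: linear elasticity + node-to-segment
# contact enforced by augmented-Lagrange iteration (outer multiplier
# augmentation, inner active-set Newton), load applied in substeps.

# Degree-of-freedom reduction: Dirichlet constraints are eliminated and
# the load-surface uz dofs are tied to a single master dof (rigid
# platen translating without rotation). Returns map (0 = fixed),
# number of reduced dofs, and indices of the special dofs.
reduce_dofs <- function(mesh) {
  nn <- nrow(mesh$nodes)
  ndof <- 2L * nn
  fixed <- rep(FALSE, ndof)
  fixed[2L * mesh$tags$axis_nodes - 1L] <- TRUE          # ur/ux = 0 on axis
  sup <- mesh$tags$support_nodes
  fixed[2L * sup] <- TRUE                                 # uz = 0
  if (identical(mesh$tags$support_type, "fixed")) {
    fixed[2L * sup - 1L] <- TRUE
  }
  map <- integer(ndof)
  tied_full <- integer(0)
  load_nodes <- mesh$tags$load_nodes
  if (length(load_nodes) > 0L) tied_full <- 2L * load_nodes

  free <- which(!fixed)
  free_plain <- setdiff(free, tied_full)
  map[free_plain] <- seq_along(free_plain)
  n_red <- length(free_plain)
  tied_dof <- NA_integer_
  if (length(tied_full) > 0L) {
    n_red <- n_red + 1L
    map[tied_full] <- n_red
    tied_dof <- n_red
  }
  indenter_dof <- NA_integer_
  if (!is.null(mesh$rigid)) {
    n_red <- n_red + 1L
    indenter_dof <- n_red
  }
  list(map = map, n_red = n_red, tied_dof = tied_dof,
       indenter_dof = indenter_dof, fixed = fixed)
}

# Reduced stiffness triplets from the full matrix
reduce_stiffness <- function(K_full, dofs) {
  tk <- methods::as(methods::as(K_full, "generalMatrix"), "TsparseMatrix")
  ri <- dofs$map[tk@i + 1L]; rj <- dofs$map[tk@j + 1L]
  keep <- ri > 0L & rj > 0L
  Matrix::sparseMatrix(i = ri[keep], j = rj[keep], x = tk@x[keep],
                       dims = c(dofs$n_red, dofs$n_red))
}

# Tributary contact area (length x circumference for axisymmetric) per
# slave node, from the ordered slave surface node list.
slave_areas <- function(mesh, slaves) {
  xy <- mesh$nodes[slaves, , drop = FALSE]
  ord <- order(xy[, 1])
  xy <- xy[ord, , drop = FALSE]
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  trib <- numeric(length(slaves))
  trib[1] <- seg[1] / 2
  trib[length(slaves)] <- seg[length(seg)] / 2
  if (length(slaves) > 2) {
    trib[2:(length(slaves) - 1)] <- (seg[-length(seg)] + seg[-1]) / 2
  }
  circ <- if (mesh$mode == "axisymmetric") 2 * pi * pmax(xy[, 1], trib / 4)
          else rep(1, length(slaves))
  a <- trib * circ
  a[order(ord)]                               # back to input order
}

# Build contact elements (linearized gap constraints) for the current
# state. Each element: reduced dof columns `cols`, gradient `vals`,
# constant `c0` such that penetration pi = c0 + vals . U.
contact_elements <- function(mesh, dofs, coords, U_full, d_cur, penalty) {
  out <- list()
  tags <- mesh$tags
  if (!is.null(mesh$rigid)) {
    # analytic rigid indenter: pi = d + uz - profile(r), solved in total
    # form (exact linear gap), so c0 = -profile(r)
    prof <- mesh$rigid$profile
    for (si in seq_along(tags$slave_nodes)) {
      s <- tags$slave_nodes[si]
      zdof <- dofs$map[2L * s]
      if (zdof == 0L) next
      out[[length(out) + 1L]] <- list(
        cols = c(zdof, dofs$indenter_dof), vals = c(1, 1),
        c0 = -prof(coords[s, 1]), k = penalty[si], id = si)
    }
    return(out)
  }
  if (length(tags$slave_nodes) == 0L || length(tags$master_nodes) == 0L) {
    return(out)
  }
  mn <- tags$master_nodes
  mxy <- coords[mn, , drop = FALSE] +
    cbind(U_full[2L * mn - 1L], U_full[2L * mn])
  for (si in seq_along(tags$slave_nodes)) {
    s <- tags$slave_nodes[si]
    p <- coords[s, ] + c(U_full[2L * s - 1L], U_full[2L * s])
    # closest point on the master polyline
    best <- NULL; bestd <- Inf
    for (k in seq_len(length(mn) - 1L)) {
      a <- mxy[k, ]; b <- mxy[k + 1L, ]
      ab <- b - a
      len2 <- sum(ab^2)
      if (len2 <= 0) next
      t <- min(1, max(0, sum((p - a) * ab) / len2))
      q <- a + t * ab
      d2 <- sum((p - q)^2)
      if (d2 < bestd) {
        bestd <- d2
        nrm <- c(-ab[2], ab[1]) / sqrt(len2)  # CCW rotation of tangent
        best <- list(k = k, t = t, q = q, n = nrm)
      }
    }
    if (is.null(best)) next
    n <- best$n; t <- best$t
    g <- sum((p - best$q) * n)                # signed gap (>0 separated)
    sd <- dofs$map[c(2L * s - 1L, 2L * s)]
    a_id <- mn[best$k]; b_id <- mn[best$k + 1L]
    ad <- dofs$map[c(2L * a_id - 1L, 2L * a_id)]
    bd <- dofs$map[c(2L * b_id - 1L, 2L * b_id)]
    cols <- c(sd, ad, bd)
    vals <- c(-n, (1 - t) * n, t * n)
    keep <- cols > 0L
    # pi(U) = -g(current) + vals . (U - U_current); fold state into c0
    Ustate <- c(U_full[c(2L * s - 1L, 2L * s)],
                U_full[c(2L * a_id - 1L, 2L * a_id)],
                U_full[c(2L * b_id - 1L, 2L * b_id)])
    c0 <- -g - sum(vals * Ustate)
    out[[length(out) + 1L]] <- list(cols = cols[keep], vals = vals[keep],
                                    c0 = c0, k = penalty[si], id = si)
  }
  out
}

expand_full <- function(U_red, dofs) {
  U_full <- numeric(length(dofs$map))
  nz <- dofs$map > 0L
  U_full[nz] <- U_red[dofs$map[nz]]
  U_full
}

# One substep: augmented-Lagrange solve of
#   K U + sum_c P_c grad_c = rhs_base,  P_c = max(0, lambda_c + k pi_c(U))
al_substep <- function(K_red, contacts, rhs_base, lambda, n_red,
                       tol_pen = 1e-3, max_outer = 30L, max_inner = 40L,
                       force_scale = 1) {
  U <- numeric(n_red)
  iters <- 0L
  nc <- length(contacts)
  if (nc == 0L) {
    U <- as.numeric(Matrix::solve(K_red, rhs_base))
    return(list(U = U, lambda = lambda, iterations = 1L,
                penetration = 0, converged = TRUE))
  }
  pen_gap <- function(U) {
    vapply(contacts, function(ce) ce$c0 + sum(ce$vals * U[ce$cols]),
           numeric(1))
  }
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    active_prev <- rep(NA, nc)
    for (inner in seq_len(max_inner)) {
      iters <- iters + 1L
      pi_c <- pen_gap(U)
      active <- (lambda + vapply(contacts, `[[`, numeric(1), "k") * pi_c) >= 0
      if (!any(active)) {
        # bodies held only by contact: seed the closest pair so the
        # system stays nonsingular
        active[which.max(pi_c)] <- TRUE
      }
      if (inner > 1L && identical(active, active_prev)) break
      active_prev <- active
      ci <- integer(0); cj <- integer(0); cx <- numeric(0)
      rhs <- rhs_base
      for (m in which(active)) {
        ce <- contacts[[m]]
        ci <- c(ci, rep(ce$cols, times = length(ce$cols)))
        cj <- c(cj, rep(ce$cols, each = length(ce$cols)))
        cx <- c(cx, ce$k * as.vector(outer(ce$vals, ce$vals)))
        rhs[ce$cols] <- rhs[ce$cols] -
          (lambda[m] + ce$k * ce$c0) * ce$vals
      }
      A <- K_red
      if (length(ci) > 0L) {
        A <- A + Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                                      dims = c(n_red, n_red))
      }
      U <- as.numeric(Matrix::solve(A, rhs))
    }
    pi_c <- pen_gap(U)
    kvec <- vapply(contacts, `[[`, numeric(1), "k")
    lambda_new <- pmax(0, lambda + kvec * pi_c)
    max_pen <- max(c(0, pi_c[lambda_new > 0]))
    dl <- max(abs(lambda_new - lambda)) / max(force_scale, sum(lambda_new))
    lambda <- lambda_new
    if (max_pen <= tol_pen && dl <= 1e-4) { converged <- TRUE; break }
  }
  list(U = U, lambda = lambda, iterations = iters,
       penetration = max(c(0, pen_gap(U))), converged = converged)
}

#' Solve a loaded contact configuration
#'
#' Small-strain isotropic linear elasticity with frictionless
#' node-to-segment contact enforced by augmented-Lagrange iteration.
#' The load is applied in equal substeps; with the large-deflection
#' flag the node coordinates are updated between substeps
#' (updated-coordinate incremental loading). The contact penalty is
#' auto-scaled to 100 x the softest contacting modulus per unit length
#' times the tributary contact area of each slave node.
#'
#' @param mesh A `fem_mesh` (from [build_mesh()]).
#' @param materials A [material_set()].
#' @param load A [load_case()].
#' @param tol_pen Penetration tolerance (mm).
#' @return An object of class `fem_result`: `displacement` (full nodal
#'   vector, ur/uz interleaved), `delta_z_mm` (axial deformation of the
#'   load surface, positive downward), `reaction_n` (support reaction),
#'   `applied_n`, `iterations`, `contact` (per-slave multipliers and
#'   active flags), `residual`, `converged`.
#' @export
solve_contact <- function(mesh, materials, load, tol_pen = 1e-3) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(materials, "material_set"),
            inherits(load, "load_case"))
  dofs <- reduce_dofs(mesh)
  nus <- nu_map(materials, mesh)

  has_contact <- !is.null(mesh$rigid) ||
    (length(mesh$tags$slave_nodes) > 0L &&
       length(mesh$tags$master_nodes) > 0L)
  penalty <- NULL
  if (has_contact) {
    soft_E <- min(vapply(unique(mesh$tissue), function(t)
      material_for_tissue(materials, t)[["E"]], numeric(1)))
    areas <- slave_areas(mesh, mesh$tags$slave_nodes)
    penalty <- 100 * soft_E * areas           # N/mm per unit penetration
  }

  force_dof <- if (!is.na(dofs$indenter_dof)) dofs$indenter_dof
               else dofs$tied_dof
  if (is.na(force_dof)) stop("mesh has neither a load surface nor an indenter")
  load_sign <- if (!is.na(dofs$indenter_dof)) 1 else -1  # indenter dof is
  # positive downward; the tied uz dof is positive upward, so a
  # compressive axial force enters with negative sign.

  coords <- mesh$nodes
  nn <- nrow(coords)
  U_total <- numeric(2L * nn)
  d_total <- 0
  reaction <- 0
  lambda <- if (has_contact) numeric(length(mesh$tags$slave_nodes)) else numeric(0)
  iters_total <- 0L
  incremental <- load$large_deflection

  K_unit <- assemble_unit_stiffness(mesh_with_coords(mesh, coords), nus)
  K_full <- combine_stiffness(K_unit, materials)
  K_red <- reduce_stiffness(K_full, dofs)

  sup_zrows <- 2L * mesh$tags$support_nodes
  contacts <- list()
  for (s in seq_len(load$substeps)) {
    F_s <- load$increment_n * s
    if (incremental && s > 1L) {
      # refresh geometry and stiffness on the updated coordinates
      K_unit <- assemble_unit_stiffness(mesh_with_coords(mesh, coords), nus)
      K_full <- combine_stiffness(K_unit, materials)
      K_red <- reduce_stiffness(K_full, dofs)
    }
    state_U <- if (incremental) numeric(2L * nn) else U_total
    if (has_contact) {
      contacts <- contact_elements(mesh, dofs,
                                   coords, state_U,
                                   if (incremental) 0 else d_total,
                                   penalty)
    }
    rhs <- numeric(dofs$n_red)
    F_apply <- if (incremental) load$increment_n else F_s
    rhs[force_dof] <- load_sign * F_apply
    if (incremental) {
      # previous total contact force re-enters the incremental balance
      for (m in seq_along(contacts)) {
        ce <- contacts[[m]]
        rhs[ce$cols] <- rhs[ce$cols] + lambda[ce$id] * ce$vals
      }
      lam_in <- lambda[vapply(contacts, `[[`, numeric(1), "id")]
    } else {
      lam_in <- if (length(contacts) > 0L)
        lambda[vapply(contacts, `[[`, numeric(1), "id")] else numeric(0)
    }
    sol <- al_substep(K_red, contacts, rhs,
                      lam_in, dofs$n_red,
                      tol_pen = tol_pen, force_scale = load$force_n)
    iters_total <- iters_total + sol$iterations
    if (!sol$converged) {
      stop("contact solver failed to converge at substep ", s,
           " (penetration ", signif(sol$penetration, 3), " mm)")
    }
    if (length(contacts) > 0L) {
      lambda[vapply(contacts, `[[`, numeric(1), "id")] <- sol$lambda
    }
    U_inc_full <- expand_full(sol$U, dofs)
    d_inc <- if (!is.na(dofs$indenter_dof)) sol$U[dofs$indenter_dof] else 0
    # support reaction increment from the full stiffness
    KU <- as.numeric(K_full %*% U_inc_full)
    if (incremental) {
      reaction <- reaction + sum(KU[sup_zrows])
      coords <- coords + cbind(U_inc_full[seq(1, 2 * nn, 2)],
                               U_inc_full[seq(2, 2 * nn, 2)])
      U_total <- U_total + U_inc_full
      d_total <- d_total + d_inc
    } else {
      reaction <- sum(KU[sup_zrows])
      U_total <- U_inc_full
      d_total <- d_inc
    }
  }

  delta_z <- if (!is.na(dofs$indenter_dof)) d_total
             else -U_total[2L * mesh$tags$load_nodes[1]]
  res <- structure(list(
    displacement = U_total,
    delta_z_mm = delta_z,
    reaction_n = abs(reaction),
    applied_n = load$force_n,
    iterations = iters_total,
    contact = if (has_contact)
      list(lambda = lambda, active = lambda > 0,
           total_force_n = sum(lambda)) else NULL,
    converged = TRUE,
    mesh = mesh
  ), class = "fem_result")
  res
}

mesh_with_coords <- function(mesh, coords) {
  m <- mesh
  m$nodes <- coords
  m
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf(
    "fem_result: delta_z = %.4f mm, reaction %.2f / applied %.2f N, %d contact iterations\n",
    x$delta_z_mm, x$reaction_n, x$applied_n, x$iterations))
  invisible(x)
}
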