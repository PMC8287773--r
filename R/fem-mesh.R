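# Structured 6-node-triangle meshing of mapped quadrilateral blocks.
# Blocks are fused into a conforming mesh by coordinate matching, so
# bonded interfaces share nodes (exactly rigid ties).

mesh_block <- function(nu, nv, mapfun, tissue) {
  nu <- as.integer(max(1L, nu)); nv <- as.integer(max(1L, nv))
  gu <- 2L * nu + 1L; gv <- 2L * nv + 1L
  uu <- rep(seq(0, 1, length.out = gu), times = gv)
  vv <- rep(seq(0, 1, length.out = gv), each = gu)
  nodes <- mapfun(uu, vv)                    # (gu*gv) x 2
  gid <- function(a, b) (b - 1L) * gu + a

  elems <- matrix(0L, nrow = 2L * nu * nv, ncol = 6L)
  k <- 0L
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) {
      a <- 2L * i - 1L; b <- 2L * j - 1L
      p00 <- gid(a, b);      p10 <- gid(a + 1L, b);      p20 <- gid(a + 2L, b)
      p01 <- gid(a, b + 1L); p11 <- gid(a + 1L, b + 1L); p21 <- gid(a + 2L, b + 1L)
      p02 <- gid(a, b + 2L); p12 <- gid(a + 1L, b + 2L); p22 <- gid(a + 2L, b + 2L)
      k <- k + 1L
      elems[k, ] <- c(p00, p20, p22, p10, p21, p11)
      k <- k + 1L
      elems[k, ] <- c(p00, p22, p02, p11, p12, p01)
    }
  }
  edges <- list(
    v0 = gid(seq_len(gu), 1L),               # v = 0, ordered by u
    v1 = gid(seq_len(gu), gv),               # v = 1
    u0 = gid(1L, seq_len(gv)),               # u = 0, ordered by v
    u1 = gid(gu, seq_len(gv))                # u = 1
  )
  list(nodes = nodes, elems = elems, tissue = rep(tissue, nrow(elems)),
       edges = edges)
}

fuse_blocks <- function(blocks, tol = 1e-7) {
  all_nodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  key <- paste(round(all_nodes[, 1] / tol), round(all_nodes[, 2] / tol))
  uid <- match(key, key[!duplicated(key)])
  nodes <- all_nodes[!duplicated(key), , drop = FALSE]

  offset <- 0L
  elems <- list(); tissue <- list(); edges <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    remap <- uid[offset + seq_len(nrow(b$nodes))]
    elems[[bi]] <- matrix(remap[b$elems], ncol = 6L)
    tissue[[bi]] <- b$tissue
    edges[[bi]] <- lapply(b$edges, function(e) remap[e])
    offset <- offset + nrow(b$nodes)
  }
  list(nodes = nodes, elems = do.call(rbind, elems),
       tissue = unlist(tissue), edges = edges)
}

new_fem_mesh <- function(nodes, elems, tissue, mode, tags,
                         target_size, rigid = NULL) {
  need <- c("support_nodes")
  for (nm in need) {
    if (length(tags[[nm]]) == 0L) stop("empty boundary tag: ", nm)
  }
  structure(list(nodes = nodes, elems = elems, tissue = tissue,
                 mode = mode, tags = tags, target_size = target_size,
                 rigid = rigid),
            class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf(
    "fem_mesh (%s): %d nodes, %d T6 elements [%s], target size %.3g mm\n",
    x$mode, nrow(x$nodes), nrow(x$elems),
    paste(names(table(x$tissue)), collapse = ", "), x$target_size))
  invisible(x)
}

# geometric grading: cumulative fraction at parameter t in [0,1] with N
# cells and cell-to-cell ratio q (first cell smallest)
grade_map <- function(t, N, q) {
  if (abs(q - 1) < 1e-9) return(t)
  (q^(N * t) - 1) / (q^N - 1)
}

#' Build a finite-element mesh for a parametric geometry
#'
#' Generates a conforming quadratic-triangle (T6) mesh for the given
#' [geometry_model()]. Soft-tissue regions are meshed at the target
#' element size and bone regions at four times that size through their
#' thickness (bonded interfaces keep matching in-plane divisions so the
#' mesh stays conforming and ties are exact). Boundary node sets
#' (support, load surface, contact surfaces, symmetry axis) are tagged
#' on the returned mesh.
#'
#' @param geom A `geometry_model`.
#' @param target_element_size Soft-tissue element size in mm.
#' @return A `fem_mesh`.
#' @export
build_mesh <- function(geom, target_element_size) {
  stopifnot(inherits(geom, "geometry_model"), target_element_size > 0)
  h <- target_element_size
  m <- switch(geom$kind,
              column = mesh_column(geom, h),
              halfspace = mesh_halfspace(geom, h),
              knee = mesh_knee(geom, h),
              stop("unknown geometry kind: ", geom$kind))
  m$geom <- geom
  m
}

mesh_column <- function(geom, h) {
  a <- geom$radius; hh <- geom$height_mm
  if (geom$mode == "plane_strain") a <- geom$area_mm2  # width per unit depth
  nu <- max(2L, ceiling(a / h)); nv <- max(2L, ceiling(hh / h))
  blk <- mesh_block(nu, nv, function(u, v) cbind(a * u, hh * v), "soft")
  f <- fuse_blocks(list(blk))
  tags <- list(
    support_nodes = f$edges[[1]]$v0,          # z = 0, roller (uz = 0)
    support_type = "roller",
    axis_nodes = f$edges[[1]]$u0,             # r = 0 symmetry
    load_nodes = f$edges[[1]]$v1              # rigid platen, tied uz
  )
  new_fem_mesh(f$nodes, f$elems, f$tissue, geom$mode, tags, h)
}

mesh_halfspace <- function(geom, h) {
  L <- geom$domain_mm
  q <- 1.3
  N <- max(6L, ceiling(log(1 + (q - 1) * L / h) / log(q)))
  mapfun <- function(u, v) {
    cbind(L * grade_map(u, N, q), -L * grade_map(1 - v, N, q))
  }
  blk <- mesh_block(N, N, mapfun, "soft")
  f <- fuse_blocks(list(blk))
  top <- f$edges[[1]]$v1                      # z = 0 surface, ordered by r
  r_top <- f$nodes[top, 1]
  prof <- if (geom$profile == "paraboloid") {
    local({R <- geom$sphere_radius; function(r) r^2 / (2 * R)})
  } else {
    local({R <- geom$sphere_radius
           function(r) R - sqrt(pmax(0, R^2 - pmin(r, R)^2))})
  }
  tags <- list(
    support_nodes = f$edges[[1]]$v0,          # z = -L, roller
    support_type = "roller",
    axis_nodes = f$edges[[1]]$u0,
    load_nodes = integer(0),                  # load goes to the indenter dof
    slave_nodes = top[r_top <= 0.45 * L]
  )
  new_fem_mesh(f$nodes, f$elems, f$tissue, geom$mode, tags, h,
               rigid = list(profile = prof))
}

knee_sagitta <- function(geom, r) {
  R <- geom$condyle_radius
  if (!is.finite(R)) return(r * 0)
  R - sqrt(pmax(0, R^2 - pmin(r, R)^2))
}

mesh_knee <- function(geom, h) {
  g <- geom
  hb <- 4 * h                                 # bone element size (thickness)
  tt <- g$cartilage_thickness_tibial
  tf <- g$cartilage_thickness_femoral
  Rp <- g$plateau_radius
  ce <- g$condyle_extent
  Hb <- g$bone_height
  has_men <- !is.null(g$meniscus_inner_radius)
  rm_in <- if (has_men) g$meniscus_inner_radius else Rp

  nr_in <- max(2L, ceiling(rm_in / h))
  nr_out <- max(2L, ceiling((Rp - rm_in) / h))
  nz_tc <- max(2L, ceiling(tt / h))
  nz_tb <- max(2L, ceiling(Hb / hb))
  nz_fc <- max(2L, ceiling(tf / h))
  nz_fb <- max(2L, ceiling(Hb / hb))
  nr_f <- max(3L, ceiling(ce / h))

  blocks <- list()
  # tibial cartilage, inner and outer in r (split at the meniscus tip)
  blocks$tc_in <- mesh_block(nr_in, nz_tc, function(u, v)
    cbind(rm_in * u, -tt + tt * v), "cartilage")
  # tibia bone
  blocks$tb_in <- mesh_block(nr_in, nz_tb, function(u, v)
    cbind(rm_in * u, -tt - Hb + Hb * v), "bone")
  if (has_men) {
    blocks$tc_out <- mesh_block(nr_out, nz_tc, function(u, v)
      cbind(rm_in + (Rp - rm_in) * u, -tt + tt * v), "cartilage")
    blocks$tb_out <- mesh_block(nr_out, nz_tb, function(u, v)
      cbind(rm_in + (Rp - rm_in) * u, -tt - Hb + Hb * v), "bone")
  }
  if (has_men) {
    hmin <- g$meniscus_min_height; hmax <- g$meniscus_height
    nz_m <- max(2L, ceiling(0.5 * (hmin + hmax) / h))
    blocks$men <- mesh_block(nr_out, nz_m, function(u, v) {
      r <- rm_in + (Rp - rm_in) * u
      hm <- hmin + (hmax - hmin) * (r - rm_in) / (Rp - rm_in)
      cbind(r, hm * v)
    }, "meniscus")
  }
  # femoral cartilage (curved underside) and femur bone
  zb <- function(r) g$apex_gap + knee_sagitta(g, r)
  ztop <- zb(ce) + tf + Hb
  blocks$fc <- mesh_block(nr_f, nz_fc, function(u, v) {
    r <- ce * u
    cbind(r, zb(r) + tf * v)
  }, "cartilage")
  blocks$fb <- mesh_block(nr_f, nz_fb, function(u, v) {
    r <- ce * u
    z0 <- zb(r) + tf
    cbind(r, z0 + (ztop - z0) * v)
  }, "bone")

  f <- fuse_blocks(blocks)
  bi <- seq_along(blocks); names(bi) <- names(blocks)
  ed <- function(nm, side) f$edges[[bi[[nm]]]][[side]]

  # master contact surface: tibial cartilage top (axis to meniscus tip),
  # then up the meniscus inner face and out along its top slope
  master <- ed("tc_in", "v1")              # spans [0, Rp] when no meniscus
  if (has_men) master <- c(master, ed("men", "u0"), ed("men", "v1"))
  master <- master[!duplicated(master)]

  axis_nodes <- unique(c(ed("tc_in", "u0"), ed("tb_in", "u0"),
                         ed("fc", "u0"), ed("fb", "u0")))
  support <- ed("tb_in", "v0")
  if (has_men) support <- unique(c(support, ed("tb_out", "v0")))
  tags <- list(
    support_nodes = support,
    support_type = "fixed",                   # fixed distal tibia
    axis_nodes = axis_nodes,
    load_nodes = ed("fb", "v1"),              # femur top: tied uz, force F
    slave_nodes = ed("fc", "v0"),             # femoral cartilage underside
    master_nodes = master
  )
  new_fem_mesh(f$nodes, f$elems, f$tissue, g$mode, tags, h)
}
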