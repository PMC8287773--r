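# T6 (quadratic triangle) element matrices for axisymmetric and
# plane-strain linear elasticity. Units: mm, N, MPa (1 N/mm^2 = 1 MPa).

# 6-point degree-4 Gauss rule on the unit triangle (weights sum to 1/2)
t6_gauss <- function() {
  a <- 0.445948490915965; b <- 0.091576213509771
  wa <- 0.111690794839005; wb <- 0.054975871827661
  list(
    L = rbind(c(a, a), c(1 - 2 * a, a), c(a, 1 - 2 * a),
              c(b, b), c(1 - 2 * b, b), c(b, 1 - 2 * b)),
    w = c(wa, wa, wa, wb, wb, wb)
  )
}

t6_shape <- function(L1, L2) {
  L3 <- 1 - L1 - L2
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
}

t6_dshape <- function(L1, L2) {
  L3 <- 1 - L1 - L2
  dL1 <- c(4 * L1 - 1, 0, -(4 * L3 - 1), 4 * L2, -4 * L2, 4 * (L3 - L1))
  dL2 <- c(0, 4 * L2 - 1, -(4 * L3 - 1), 4 * L1, 4 * (L3 - L2), -4 * L1)
  cbind(dL1, dL2)
}

elastic_D <- function(E, nu, mode) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  if (mode == "axisymmetric") {
    c1 * rbind(c(1 - nu, nu, nu, 0),
               c(nu, 1 - nu, nu, 0),
               c(nu, nu, 1 - nu, 0),
               c(0, 0, 0, (1 - 2 * nu) / 2))
  } else {
    c1 * rbind(c(1 - nu, nu, 0),
               c(nu, 1 - nu, 0),
               c(0, 0, (1 - 2 * nu) / 2))
  }
}

# Per-tissue unit stiffness matrices (assembled at E = 1 with the
# tissue's Poisson ratio); the stiffness for any modulus assignment is
# then K = sum_t E_t * K_t, which lets a stiffness sweep reuse one
# assembly per mesh.
assemble_unit_stiffness <- function(mesh, nu_by_tissue) {
  nodes <- mesh$nodes; elems <- mesh$elems
  nn <- nrow(nodes); ne <- nrow(elems)
  gauss <- t6_gauss()
  ngp <- length(gauss$w)
  mode <- mesh$mode
  ncomp <- if (mode == "axisymmetric") 4L else 3L

  tissues <- unique(mesh$tissue)
  D_unit <- lapply(tissues, function(t)
    elastic_D(1, nu_by_tissue[[t]], mode))
  names(D_unit) <- tissues

  dN_all <- lapply(seq_len(ngp), function(g)
    t6_dshape(gauss$L[g, 1], gauss$L[g, 2]))
  N_all <- lapply(seq_len(ngp), function(g)
    t6_shape(gauss$L[g, 1], gauss$L[g, 2]))

  nk <- 144L * ne
  out <- lapply(tissues, function(t)
    list(i = integer(0), j = integer(0), x = numeric(0)))
  names(out) <- tissues
  ii <- vector("list", ne); jj <- vector("list", ne); xx <- vector("list", ne)

  for (e in seq_len(ne)) {
    en <- elems[e, ]
    xy <- nodes[en, , drop = FALSE]           # 6 x 2 (r/x, z)
    tis <- mesh$tissue[e]
    D <- D_unit[[tis]]
    ke <- matrix(0, 12, 12)
    for (g in seq_len(ngp)) {
      dN <- dN_all[[g]]                       # 6 x 2 (d/dL1, d/dL2)
      J <- t(xy) %*% dN                       # 2 x 2
      detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (detJ <= 0) {
        stop("inverted element ", e, " (tissue ", tis,
             "): Jacobian ", signif(detJ, 3))
      }
      dNxy <- dN %*% solve(J)                 # 6 x 2 (d/dx, d/dz)
      B <- matrix(0, ncomp, 12)
      ix <- 2 * (1:6) - 1; iz <- 2 * (1:6)
      if (mode == "axisymmetric") {
        Ng <- N_all[[g]]
        r <- sum(Ng * xy[, 1])
        B[1, ix] <- dNxy[, 1]
        B[2, iz] <- dNxy[, 2]
        B[3, ix] <- Ng / r
        B[4, ix] <- dNxy[, 2]; B[4, iz] <- dNxy[, 1]
        wgt <- gauss$w[g] * detJ * 2 * pi * r
      } else {
        B[1, ix] <- dNxy[, 1]
        B[2, iz] <- dNxy[, 2]
        B[3, ix] <- dNxy[, 2]; B[3, iz] <- dNxy[, 1]
        wgt <- gauss$w[g] * detJ
      }
      ke <- ke + wgt * (t(B) %*% D %*% B)
    }
    gdof <- as.vector(rbind(2L * en - 1L, 2L * en))
    ii[[e]] <- rep(gdof, times = 12)
    jj[[e]] <- rep(gdof, each = 12)
    xx[[e]] <- as.vector(ke)
  }

  ivec <- unlist(ii); jvec <- unlist(jj); xvec <- unlist(xx)
  eltis <- rep(mesh$tissue, each = 144L)
  Ks <- lapply(tissues, function(t) {
    sel <- eltis == t
    Matrix::sparseMatrix(i = ivec[sel], j = jvec[sel], x = xvec[sel],
                         dims = c(2L * nn, 2L * nn))
  })
  names(Ks) <- tissues
  Ks
}

material_for_tissue <- function(materials, tissue) {
  m <- materials[[tissue]]
  if (is.null(m)) stop("no material for tissue '", tissue, "'")
  m
}

# Combine per-tissue unit matrices with a material set
combine_stiffness <- function(K_unit, materials) {
  K <- NULL
  for (t in names(K_unit)) {
    E <- material_for_tissue(materials, t)[["E"]]
    K <- if (is.null(K)) E * K_unit[[t]] else K + E * K_unit[[t]]
  }
  K
}

nu_map <- function(materials, mesh) {
  tissues <- unique(mesh$tissue)
  nus <- lapply(tissues, function(t) material_for_tissue(materials, t)[["nu"]])
  names(nus) <- tissues
  nus
}
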