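## Membrane mechanics: a triangulated periodic membrane carrying a Helfrich
## bending energy (cotangent discrete operator), harmonically coupled to a
## rigid pre-assembled clathrin cage through one virtual site per trimer.
## The minimization schedule stiffens the springs geometrically so the sheet
## is gradually drawn onto the cage, and reports bending cost per trimer.

#' Build a flat periodic triangulated membrane
#'
#' Approximately equilateral triangles on an x/y-periodic sheet of side `L`.
#'
#' @param L Box side, nm (default 700, area 490000 nm^2).
#' @param edge_nm Target edge length (refinement), nm.
#' @return A `tri_mesh`: `vertices` (n x 3), `faces` (nf x 3, 1-based),
#'   `periodic`, `L`, `area_nm2`.
#' @export
#' @examples
#' m <- build_flat_mesh(700, 25)
#' m$area_nm2  # 490000
build_flat_mesh <- function(L = 700, edge_nm = 20) {
  stopifnot(L > 0, edge_nm > 0, edge_nm < L / 3)
  nx <- max(3, round(L / edge_nm))
  dx <- L / nx
  ny <- max(3, round(L / (dx * sqrt(3) / 2)))
  dy <- L / ny
  vid <- function(i, j) (j %% ny) * nx + (i %% nx) + 1
  verts <- matrix(0, nx * ny, 3)
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    verts[vid(i, j), 1] <- (i + 0.5 * (j %% 2)) * dx
    verts[vid(i, j), 2] <- j * dy
  }
  faces <- matrix(0L, 2 * nx * ny, 3)
  f <- 1
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    faces[f, ] <- c(vid(i, j), vid(i + 1, j), vid(i, j + 1)); f <- f + 1
    faces[f, ] <- c(vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1))
    f <- f + 1
  }
  structure(list(vertices = verts, faces = faces, periodic = TRUE, L = L,
                 area_nm2 = mesh_area(verts, faces, TRUE, L)),
            class = "tri_mesh")
}

#' Build a closed icosphere mesh (analytic-oracle geometry)
#'
#' Subdivided icosahedron projected onto a sphere of radius `R`; closed and
#' non-periodic. The continuum Helfrich energy of a sphere at zero spontaneous
#' curvature is `8 pi kappa`, independent of radius.
#'
#' @param R Radius, nm. @param subdiv Subdivision level (0 = icosahedron).
#' @return A `tri_mesh` with `periodic = FALSE`.
#' @export
build_sphere_mesh <- function(R = 50, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    edge_mid <- new.env()
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "-")
      if (!is.null(edge_mid[[key]])) return(edge_mid[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      edge_mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * R / sqrt(rowSums(v^2))
  structure(list(vertices = v, faces = f, periodic = FALSE, L = NA_real_,
                 area_nm2 = mesh_area(v, f, FALSE, NA)),
            class = "tri_mesh")
}

mesh_area <- function(verts, faces, periodic, L) {
  a <- verts[faces[, 1], , drop = FALSE]
  e1 <- verts[faces[, 2], , drop = FALSE] - a
  e2 <- verts[faces[, 3], , drop = FALSE] - a
  if (periodic) {
    wrap <- function(d) d - L * round(d / L)
    e1[, 1:2] <- wrap(e1[, 1:2]); e2[, 1:2] <- wrap(e2[, 1:2])
  }
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Bending parameters
#' @param kappa Bending modulus, k_B T (plasma membrane ~20).
#' @param c0 Spontaneous curvature, nm^-1 (only 0 supported).
#' @return A `bending_params` list.
#' @export
bending_params <- function(kappa = 20, c0 = 0) {
  if (kappa <= 0) abort("kappa must be positive")
  if (c0 != 0) abort("only zero spontaneous curvature is supported")
  structure(list(kappa = kappa, c0 = c0), class = "bending_params")
}

#' Helfrich bending energy of a mesh
#'
#' Discrete `(kappa/2) * integral (2H)^2 dA` via the cotangent mean-curvature
#' operator with barycentric vertex areas.
#'
#' @param mesh A `tri_mesh`. @param params A [bending_params()].
#' @return Energy in k_B T.
#' @export
#' @examples
#' bending_energy(build_flat_mesh(700, 30))           # 0
#' bending_energy(build_sphere_mesh(40, 3)) / (8 * pi * 20)  # ~1
bending_energy <- function(mesh, params = bending_params()) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_mesh_quality(mesh)
  helfrich_energy_cpp(as.numeric(t(mesh$vertices)), mesh$faces - 1L,
                      params$kappa, mesh$periodic,
                      ifelse(is.na(mesh$L), 0, mesh$L),
                      ifelse(is.na(mesh$L), 0, mesh$L))
}

check_mesh_quality <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  if (mesh$periodic) {
    wrap <- function(d) d - mesh$L * round(d / mesh$L)
    e1[, 1:2] <- wrap(e1[, 1:2]); e2[, 1:2] <- wrap(e2[, 1:2])
  }
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  if (any(sqrt(cx^2 + cy^2 + cz^2) < 1e-9)) {
    abort("degenerate triangles in mesh")
  }
  invisible(TRUE)
}

#' Generate a rigid clathrin cage constraint
#'
#' Geometric construction: trimer centers on a sphere whose radius follows
#' from the pucker angle by the chord construction, `R = 17 / (2 sin(alpha -
#' 90 deg))` (lattice edge 17 nm dips below the local tangent plane by
#' `alpha - 90`); `alpha = 90` gives a flat patch. The `n` trimers tile a
#' spherical cap (Fibonacci spiral at the per-trimer lattice area); one
#' virtual site per trimer sits `offset_nm` (9 by default) from the trimer
#' COM toward the membrane.
#'
#' @param n Number of trimers (>= 3). @param alpha Pucker angle, degrees.
#' @param offset_nm Virtual-site offset from the trimer COM, nm.
#' @param clearance_nm Initial height of the lowest virtual site above the
#'   membrane plane.
#' @param center_xy Lateral cage position, nm (defaults to the box center for
#'   a 700 nm sheet).
#' @return A `cage_constraint`: `com` and `vsite` (n x 3 matrices), `alpha`,
#'   `R_nm`, plus the harmonic schedule parameters used by
#'   [minimize_coupled()].
#' @export
generate_cage <- function(n, alpha = 98, offset_nm = 9, clearance_nm = 2,
                          center_xy = c(350, 350)) {
  if (n < 3) abort("a cage needs at least 3 trimers")
  if (alpha < 90 || alpha > 110) abort("alpha must lie in [90, 110] degrees")
  a_t <- sqrt(3) / 2 * 17^2                     # lattice area per trimer
  if (alpha == 90) {
    # flat patch: hexagonal spiral of trimer COMs
    pts <- matrix(0, 1, 2)
    ringi <- 1
    while (nrow(pts) < n) {
      th <- seq(0, 2 * pi, length.out = 6 * ringi + 1)[-(6 * ringi + 1)]
      pts <- rbind(pts, 17 * ringi * cbind(cos(th), sin(th)))
      ringi <- ringi + 1
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    com <- cbind(pts[, 1] + center_xy[1], pts[, 2] + center_xy[2],
                 offset_nm + clearance_nm)
    vs <- com; vs[, 3] <- clearance_nm
    R_nm <- Inf
  } else {
    R_nm <- 17 / (2 * sin((alpha - 90) * pi / 180))
    cap <- n * a_t / (2 * pi * R_nm^2)          # 1 - cos(theta_max)
    if (cap > 1.95) abort("cage larger than the sphere for this alpha")
    golden <- pi * (3 - sqrt(5))
    k <- seq_len(n) - 0.5
    cth <- 1 - cap * k / n
    sth <- sqrt(pmax(0, 1 - cth^2))
    ph <- golden * (seq_len(n) - 1)
    # top cap: the membrane bud protrudes upward, the cage coats its
    # outside, and the virtual sites point radially inward (down, toward
    # the sphere center below the cap)
    dirs <- cbind(sth * cos(ph), sth * sin(ph), cth)
    com0 <- R_nm * dirs
    vs0 <- (R_nm - offset_nm) * dirs
    zshift <- clearance_nm - min(vs0[, 3])
    com <- cbind(com0[, 1] + center_xy[1], com0[, 2] + center_xy[2],
                 com0[, 3] + zshift)
    vs <- cbind(vs0[, 1] + center_xy[1], vs0[, 2] + center_xy[2],
                vs0[, 3] + zshift)
  }
  structure(list(com = com, vsite = vs, alpha = alpha, n = n, R_nm = R_nm,
                 offset_nm = offset_nm,
                 k_start_kcal = 3e-4, k_stop_kcal = 100, k_factor = 3,
                 sub_iterations = 50),
            class = "cage_constraint")
}

# nearest point on the mesh to each query point: nearest vertex, then the
# closest point on its incident faces, tagged as (face, barycentric coords)
tag_attachments <- function(mesh, pts) {
  V <- mesh$vertices
  L <- mesh$L
  wrap <- function(d) if (mesh$periodic) d - L * round(d / L) else d
  t(vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    d2 <- wrap(V[, 1] - p[1])^2 + wrap(V[, 2] - p[2])^2 + (V[, 3] - p[3])^2
    vi <- which.min(d2)
    fcs <- which(mesh$faces[, 1] == vi | mesh$faces[, 2] == vi |
                 mesh$faces[, 3] == vi)
    best <- c(fcs[1], 1, 0, 0); bestd <- Inf
    for (f in fcs) {
      tri <- mesh$faces[f, ]
      a <- V[tri[1], ]
      e1 <- V[tri[2], ] - a; e2 <- V[tri[3], ] - a
      e1[1:2] <- wrap(e1[1:2]); e2[1:2] <- wrap(e2[1:2])
      # solve for barycentric coords of the projection of p onto the plane
      w <- p - a; w[1:2] <- wrap(w[1:2])
      d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
      w1 <- sum(w * e1); w2 <- sum(w * e2)
      det <- d11 * d22 - d12^2
      u <- (d22 * w1 - d12 * w2) / det
      v <- (d11 * w2 - d12 * w1) / det
      u <- max(0, min(1, u)); v <- max(0, min(1 - u, v))
      q <- a + u * e1 + v * e2
      dd <- sum((wrap(q[1:2] - p[1:2]))^2) + (q[3] - p[3])^2
      if (dd < bestd) { bestd <- dd; best <- c(f, 1 - u - v, u, v) }
    }
    best
  }, numeric(4)))
}

#' Minimize membrane bending energy under a rigid cage constraint
#'
#' Staged quasi-Newton minimization: harmonic springs between each cage
#' virtual site and its nearest membrane point (re-tagged each stage in face /
#' barycentric coordinates) are stiffened geometrically from `k_start_kcal` to
#' `k_stop_kcal` kcal/mol/Angstrom^2 by factors of `k_factor`; at each stage
#' the vertex positions run `sub_iterations` L-BFGS-B iterations, and the cage
#' pose (rigid shift and rotation) is co-optimized against the springs.
#'
#' @param mesh A `tri_mesh` (flat periodic sheet).
#' @param cage A [generate_cage()] constraint.
#' @param params A [bending_params()].
#' @param optimize_pose Co-optimize the cage rigid pose.
#' @return A list: `energy_kBT` (bending only), `per_trimer_kBT`, `mesh`
#'   (deformed), `harmonic_kBT` (residual spring energy at the final stage),
#'   `trace` (per-stage tibble), `converged`.
#' @export
minimize_coupled <- function(mesh, cage, params = bending_params(),
                             optimize_pose = TRUE) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cage, "cage_constraint"))
  kconv <- 100 / unit_constants()$kcalmol_per_kBT   # kcal/mol/A^2 -> kBT/nm^2
  ks <- cage$k_start_kcal * cage$k_factor^(0:99)
  ks <- c(ks[ks < cage$k_stop_kcal], cage$k_stop_kcal)
  V <- mesh$vertices
  F1 <- mesh$faces
  L <- mesh$L
  pose <- c(0, 0, 0, 0, 0, 0)     # shift xyz + rotation vector
  vs0 <- cage$vsite
  cen <- colMeans(cage$com)
  pose_vs <- function(pose) {
    th <- sqrt(sum(pose[4:6]^2))
    R <- diag(3)
    if (th > 1e-12) {
      ax <- pose[4:6] / th
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                  3, 3)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    sweep((vs0 - matrix(cen, nrow(vs0), 3, byrow = TRUE)) %*% t(R), 2,
          cen + pose[1:3], "+")
  }
  trace <- list()
  kappa <- params$kappa
  wrapv <- function(d) d - L * round(d / L)
  for (si in seq_along(ks)) {
    kh <- ks[si] * kconv
    vs <- pose_vs(pose)
    tags <- tag_attachments(
      structure(list(vertices = V, faces = F1, periodic = mesh$periodic,
                     L = L), class = "tri_mesh"), vs)
    att_idx <- cbind(F1[tags[, 1], 1], F1[tags[, 1], 2], F1[tags[, 1], 3])
    bary <- tags[, 2:4, drop = FALSE]
    en <- function(x) {
      Vm <- matrix(x, ncol = 3, byrow = TRUE)
      eb <- helfrich_energy_cpp(x, F1 - 1L, kappa, mesh$periodic, L, L)
      ap <- att_point(Vm, att_idx, bary, L)
      d <- ap - vs; d[, 1:2] <- wrapv(d[, 1:2])
      eb + 0.5 * kh * sum(d^2)
    }
    gr <- function(x) {
      Vm <- matrix(x, ncol = 3, byrow = TRUE)
      g <- helfrich_gradient_cpp(x, F1 - 1L, kappa, mesh$periodic, L, L)
      g <- matrix(g, ncol = 3, byrow = TRUE)
      ap <- att_point(Vm, att_idx, bary, L)
      d <- ap - vs; d[, 1:2] <- wrapv(d[, 1:2])
      for (j in seq_len(nrow(d))) {
        for (cnr in 1:3) {
          g[att_idx[j, cnr], ] <- g[att_idx[j, cnr], ] +
            kh * bary[j, cnr] * d[j, ]
        }
      }
      as.numeric(t(g))
    }
    opt <- stats::optim(as.numeric(t(V)), en, gr, method = "L-BFGS-B",
                        control = list(maxit = cage$sub_iterations))
    V <- matrix(opt$par, ncol = 3, byrow = TRUE)
    if (optimize_pose) {
      ap <- att_point(V, att_idx, bary, L)
      zmin <- min(V[, 3])
      pfn <- function(p6) {
        vsp <- pose_vs(p6)
        d <- ap - vsp
        d[, 1:2] <- wrapv(d[, 1:2])
        # the membrane is impenetrable: virtual sites must stay above the
        # lowest sheet level, otherwise the pose buries the cage
        pen <- sum(pmax(0, zmin - vsp[, 3])^2) * 100
        sum(d^2) + pen
      }
      po <- stats::optim(pose, pfn, method = "Nelder-Mead",
                         control = list(maxit = 200))
      pose <- po$par
    }
    eb <- helfrich_energy_cpp(as.numeric(t(V)), F1 - 1L, kappa,
                              mesh$periodic, L, L)
    vsn <- pose_vs(pose)
    apn <- att_point(V, att_idx, bary, L)
    dd <- apn - vsn; dd[, 1:2] <- wrapv(dd[, 1:2])
    trace[[si]] <- tibble(stage = si, k_kcal = ks[si], bending_kBT = eb,
                          harmonic_kBT = 0.5 * kh * sum(dd^2),
                          rms_gap_nm = sqrt(mean(rowSums(dd^2))))
    }
  tr <- dplyr::bind_rows(trace)
  out_mesh <- structure(list(vertices = V, faces = F1,
                             periodic = mesh$periodic, L = L,
                             area_nm2 = mesh_area(V, F1, mesh$periodic, L)),
                        class = "tri_mesh")
  eb <- tr$bending_kBT[nrow(tr)]
  list(energy_kBT = eb, per_trimer_kBT = eb / cage$n, mesh = out_mesh,
       harmonic_kBT = tr$harmonic_kBT[nrow(tr)], trace = tr,
       converged = tr$rms_gap_nm[nrow(tr)] < 1)
}

att_point <- function(Vm, att_idx, bary, L) {
  # barycentric combination with minimum-image relative to the first corner
  a <- Vm[att_idx[, 1], , drop = FALSE]
  b <- Vm[att_idx[, 2], , drop = FALSE]
  c3 <- Vm[att_idx[, 3], , drop = FALSE]
  wb <- b - a; wc <- c3 - a
  wb[, 1:2] <- wb[, 1:2] - L * round(wb[, 1:2] / L)
  wc[, 1:2] <- wc[, 1:2] - L * round(wc[, 1:2] / L)
  a + bary[, 2] * wb + bary[, 3] * wc
}

#' Bending-energy-per-trimer sweep over cage size and curvature
#'
#' Runs [minimize_coupled()] over a grid of pucker angles and cage sizes on a
#' fresh flat sheet each time.
#'
#' @param alphas Pucker angles, degrees. @param sizes Cage sizes (trimers).
#' @param params A [bending_params()]. @param L,edge_nm Mesh construction.
#' @return A tibble `(alpha, n, energy_kBT, per_trimer_kBT, converged)`.
#' @export
energy_vs_size_curve <- function(alphas = c(96, 98), sizes = c(8, 17, 28),
                                 params = bending_params(), L = 700,
                                 edge_nm = 20) {
  grid <- tidyr::expand_grid(alpha = alphas, n = sizes)
  purrr::pmap_dfr(grid, function(alpha, n) {
    mesh <- build_flat_mesh(L, edge_nm)
    cage <- generate_cage(n, alpha, center_xy = c(L / 2, L / 2))
    fit <- minimize_coupled(mesh, cage, params)
    tibble(alpha = alpha, n = n, energy_kBT = fit$energy_kBT,
           per_trimer_kBT = fit$per_trimer_kBT, converged = fit$converged)
  })
}
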