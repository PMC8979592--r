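## Rigid-body geometry of the coarse molecular models: a clathrin trimer is a
## rigid tripod of binding interfaces (3 leg sites for clathrin-clathrin, 3
## adaptor sites), an adaptor is a rigid rod (1 clathrin site, 1 lipid site).
## Orientations are unit quaternions; binding "snaps" partners into a
## pre-specified relative pose at the binding radius.

# ---- quaternion helpers (scalar-first convention) ----------------------------

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(quat_identity())
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' @noRd
quat_rotate <- function(q, v) {
  # rotate column-wise 3 x n matrix (or length-3 vector) by unit quaternion
  v <- if (is.matrix(v)) v else matrix(v, nrow = 3)
  w <- q[1]; u <- q[2:4]
  uv <- rbind(u[2] * v[3, ] - u[3] * v[2, ],
              u[3] * v[1, ] - u[1] * v[3, ],
              u[1] * v[2, ] - u[2] * v[1, ])
  uuv <- rbind(u[2] * uv[3, ] - u[3] * uv[2, ],
               u[3] * uv[1, ] - u[1] * uv[3, ],
               u[1] * uv[2, ] - u[2] * uv[1, ])
  out <- v + 2 * (w * uv + uuv)
  if (ncol(out) == 1) drop(out) else out
}

# minimal rotation carrying unit vector u onto unit vector v
quat_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d > 1 - 1e-12) return(quat_identity())
  if (d < -1 + 1e-12) {  # antipodal: rotate pi about any perpendicular
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3],
            u[1] * p[2] - u[2] * p[1])
    return(quat_from_axis_angle(ax, pi))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  quat_normalize(c(1 + d, ax))
}

# ---- molecule templates ------------------------------------------------------

#' Define an interface site of a rigid molecule
#'
#' @param name Site label. @param class Reactive class label (pairs of classes
#'   define reactions). @param position Length-3 local coordinates, nm,
#'   relative to the molecule center of mass.
#' @param exclusion_nm Excluded-volume radius while the site is unbound, nm.
#' @return A one-row tibble.
#' @export
interface_spec <- function(name, class, position, exclusion_nm = 0) {
  stopifnot(length(position) == 3, all(is.finite(position)),
            exclusion_nm >= 0)
  tibble(site = name, class = class, x = position[1], y = position[2],
         z = position[3], exclusion_nm = exclusion_nm)
}

#' @noRd
new_molecule_template <- function(name, interfaces, D_trans, D_rot,
                                  com_exclusion_nm = 0, pucker = NA_real_) {
  stopifnot(length(D_trans) == 3, length(D_rot) == 3,
            all(D_trans >= 0), all(D_rot >= 0))
  structure(list(name = name, interfaces = interfaces,
                 D_trans = D_trans, D_rot = D_rot,
                 com_exclusion_nm = com_exclusion_nm, pucker = pucker),
            class = "molecule_template")
}

#' Rigid clathrin trimer template
#'
#' Three leg sites (clathrin-clathrin binding) at 120 degree azimuthal spacing,
#' radial distance 6 nm from the center of mass, at polar ("pucker") angle
#' `alpha` from +z; `alpha` = 90 gives flat lattices, > 90 curved cages. With
#' a clathrin-clathrin binding radius of 5 nm, two bound trimers sit at the
#' lattice center-to-center distance of 17 nm. Three adaptor-binding sites sit
#' at the leg azimuths, 4 nm below the leg plane, so a bound adaptor holds its
#' clathrin contact 4 nm above the membrane.
#'
#' @param alpha Pucker angle, degrees, in \[85, 110\].
#' @param leg_nm Leg-site radial distance (nm).
#' @param D_trans,D_rot Per-axis diffusion constants (um^2/s, rad^2/us).
#' @return A `molecule_template`.
#' @export
#' @examples
#' tpl <- build_clathrin_template(90)
#' tpl$interfaces
build_clathrin_template <- function(alpha = 90, leg_nm = 6,
                                    D_trans = c(13, 13, 13),
                                    D_rot = c(0.03, 0.03, 0.03)) {
  if (!is.finite(alpha) || alpha < 85 || alpha > 110) {
    abort("pucker angle alpha must lie in [85, 110] degrees")
  }
  a <- alpha * pi / 180
  az <- c(0, 2 * pi / 3, 4 * pi / 3)
  legs <- purrr::map2_dfr(az, seq_along(az) - 1, function(phi, i) {
    interface_spec(paste0("leg", i), "cla_leg",
                   leg_nm * c(sin(a) * cos(phi), sin(a) * sin(phi), cos(a)),
                   exclusion_nm = 5)
  })
  aps <- purrr::map2_dfr(az, seq_along(az) - 1, function(phi, i) {
    interface_spec(paste0("ap", i), "cla_ap",
                   c(leg_nm * sin(a) * cos(phi), leg_nm * sin(a) * sin(phi),
                     leg_nm * cos(a) - 4),
                   exclusion_nm = 1)
  })
  new_molecule_template("clathrin", dplyr::bind_rows(legs, aps),
                        D_trans, D_rot, com_exclusion_nm = 10,
                        pucker = alpha)
}

#' Rigid adaptor (AP-2-like) rod template
#'
#' A 4 nm rod with one clathrin-binding site at the top and one lipid-binding
#' site at the bottom; lipid-bound adaptors hold the clathrin site 4 nm above
#' the membrane plane.
#'
#' @param D_trans,D_rot Per-axis diffusion constants (um^2/s, rad^2/us).
#' @return A `molecule_template`.
#' @export
build_adaptor_template <- function(D_trans = c(25, 25, 25),
                                   D_rot = c(0.5, 0.5, 0.5)) {
  ifs <- dplyr::bind_rows(
    interface_spec("cla", "ap_cla", c(0, 0, 2), exclusion_nm = 1),
    interface_spec("lip", "ap_lip", c(0, 0, -2), exclusion_nm = 0))
  new_molecule_template("adaptor", ifs, D_trans, D_rot)
}

#' Single-site point species (fixture systems)
#'
#' @param name Template label. @param class Reactive class of its one site.
#' @param D Isotropic translational diffusion constant, um^2/s.
#' @param D_rot Isotropic rotational diffusion constant, rad^2/us.
#' @param exclusion_nm Excluded-volume radius of the unbound site (set to the
#'   binding radius so unbound pairs reflect at contact, as the
#'   radiation-boundary model assumes).
#' @return A `molecule_template` with one interface at the center of mass.
#' @export
build_point_template <- function(name, class, D, D_rot = 0.1,
                                 exclusion_nm = 0) {
  new_molecule_template(name,
                        interface_spec(class, class, c(0, 0, 0),
                                       exclusion_nm = exclusion_nm),
                        rep(D, 3), rep(D_rot, 3))
}

# ---- complexes ---------------------------------------------------------------

#' Create a single-molecule rigid complex
#'
#' A complex is a rigid assembly of molecule instances (positions in nm,
#' orientations as unit quaternions) plus the bond graph between interface
#' sites. Single molecules are one-member complexes.
#'
#' @param template A `molecule_template`. @param pos Length-3 position, nm.
#' @param quat Unit quaternion orientation (scalar first).
#' @return An `rd_complex`.
#' @export
new_complex <- function(template, pos = c(0, 0, 0), quat = quat_identity()) {
  structure(list(
    molecules = list(list(template = template, pos = as.numeric(pos),
                          quat = quat_normalize(quat))),
    bonds = tibble(mol1 = integer(), site1 = integer(),
                   mol2 = integer(), site2 = integer()),
    n_anchors = 0L),
    class = "rd_complex")
}

#' Global coordinates of every interface site of a complex
#'
#' @param cx An `rd_complex`.
#' @return A tibble with molecule index, site index/name/class, coordinates
#'   (nm), and a `bound` flag.
#' @export
site_positions <- function(cx) {
  purrr::imap_dfr(cx$molecules, function(m, i) {
    ifs <- m$template$interfaces
    loc <- t(as.matrix(ifs[, c("x", "y", "z")]))
    glob <- quat_rotate(m$quat, loc) + m$pos
    glob <- matrix(glob, nrow = 3)
    tibble(mol = i, site = seq_len(nrow(ifs)), name = ifs$site,
           class = ifs$class, x = glob[1, ], y = glob[2, ], z = glob[3, ],
           exclusion_nm = ifs$exclusion_nm,
           bound = purrr::map2_lgl(i, seq_len(nrow(ifs)), function(mm, ss) {
             any((cx$bonds$mol1 == mm & cx$bonds$site1 == ss) |
                 (cx$bonds$mol2 == mm & cx$bonds$site2 == ss))
           }))
  })
}

com_positions <- function(cx) {
  t(vapply(cx$molecules, function(m) m$pos, numeric(3)))
}

#' Aggregate diffusion coefficients of a rigid complex
#'
#' Translational coefficients combine as per-axis harmonic sums over members,
#' `Dx = [sum_i 1/Dx_i]^-1`; rotational coefficients as
#' `DRx = [sum_i DRx_i^(-1/3)]^-3` (hydrodynamic radii add). Membrane-anchored
#' complexes gain one lipid-like member per anchor (D = 0.5 um^2/s in-plane,
#' 0 in z) and have `Dz = 0`.
#'
#' @param cx An `rd_complex`.
#' @param n_anchors Number of membrane anchors (implicit-site bonds).
#' @param D_lipid,D_rot_lipid Transport of one lipid anchor.
#' @return List with `D_trans` and `D_rot`, per axis.
#' @export
#' @examples
#' ad <- new_complex(build_adaptor_template())
#' aggregate_diffusion(ad, n_anchors = 1)$D_trans[1]  # 0.49 um^2/s in-plane
aggregate_diffusion <- function(cx, n_anchors = cx$n_anchors,
                                D_lipid = c(0.5, 0.5, 0),
                                D_rot_lipid = c(0, 0, 0.01)) {
  Dt <- vapply(cx$molecules, function(m) m$template$D_trans, numeric(3))
  Dr <- vapply(cx$molecules, function(m) m$template$D_rot, numeric(3))
  if (n_anchors > 0) {
    Dt <- cbind(Dt, matrix(rep(D_lipid, n_anchors), 3))
    Dr <- cbind(Dr, matrix(rep(D_rot_lipid, n_anchors), 3))
  }
  harm <- function(v) if (any(v <= 0)) 0 else 1 / sum(1 / v)
  rot <- function(v) if (any(v <= 0)) 0 else sum(v^(-1 / 3))^(-3)
  list(D_trans = apply(Dt, 1, harm), D_rot = apply(Dr, 1, rot))
}

#' Excluded-volume check between two complexes
#'
#' Overlap if any cross-complex pair of molecule centers of mass is closer
#' than the larger of their COM exclusion radii (10 nm between clathrin
#' trimers), or any cross-complex pair of UNBOUND reactive sites of
#' complementary classes is closer than their exclusion radius. Bound sites do
#' not exclude volume.
#'
#' @param cA,cB Two `rd_complex` objects.
#' @return `TRUE` if the pair overlaps sterically.
#' @export
steric_check <- function(cA, cB) {
  comA <- com_positions(cA); comB <- com_positions(cB)
  exA <- vapply(cA$molecules, function(m) m$template$com_exclusion_nm, 0)
  exB <- vapply(cB$molecules, function(m) m$template$com_exclusion_nm, 0)
  for (i in seq_len(nrow(comA))) for (j in seq_len(nrow(comB))) {
    rex <- min(exA[i], exB[j])
    if (rex > 0 && sum((comA[i, ] - comB[j, ])^2) < rex^2) return(TRUE)
  }
  sA <- site_positions(cA); sB <- site_positions(cB)
  sA <- sA[!sA$bound & sA$exclusion_nm > 0, ]
  sB <- sB[!sB$bound & sB$exclusion_nm > 0, ]
  if (nrow(sA) == 0 || nrow(sB) == 0) return(FALSE)
  for (i in seq_len(nrow(sA))) for (j in seq_len(nrow(sB))) {
    if (!classes_react(sA$class[i], sB$class[j])) next
    rex <- min(sA$exclusion_nm[i], sB$exclusion_nm[j])
    d2 <- (sA$x[i] - sB$x[j])^2 + (sA$y[i] - sB$y[j])^2 +
      (sA$z[i] - sB$z[j])^2
    if (d2 < rex^2) return(TRUE)
  }
  FALSE
}

# which reactive classes pair up (mirrors the reaction network)
classes_react <- function(c1, c2) {
  pairs <- list(c("cla_leg", "cla_leg"), c("cla_ap", "ap_cla"),
                c("A", "B"))
  any(vapply(pairs, function(p)
    (c1 == p[1] && c2 == p[2]) || (c1 == p[2] && c2 == p[1]), TRUE))
}

#' Merge two complexes by a binding event ("snap")
#'
#' Moves complex `c2` rigidly so that the reacting sites sit at separation
#' `sigma` along the outward site axis of molecule `m1`, with the
#' pre-specified relative orientation: the partner's site axis anti-parallel
#' to the bond, and the partner's symmetry axis coplanar with the bond and the
#' anchor's axis on the same side (zero twist). Rejects the event (returning
#' `NULL`) if the merged complex violates excluded volume, or if the rotation
#' displaces any member COM of `c2` by more than `max_rotation_nm`.
#'
#' @param c1,c2 `rd_complex` objects (held / moved).
#' @param m1,s1,m2,s2 Molecule and site indices of the reacting interfaces.
#' @param sigma Binding radius, nm.
#' @param max_rotation_nm Rotation-rejection threshold: maximal allowed COM
#'   displacement of any member of `c2` attributable to the snap rotation
#'   (default one molecular diameter, 17 nm; `Inf` disables).
#' @param check_steric Perform the excluded-volume check.
#' @return The merged `rd_complex`, or `NULL` on rejection.
#' @export
snap_on_binding <- function(c1, m1, s1, c2, m2, s2, sigma,
                            max_rotation_nm = 17, check_steric = TRUE) {
  b1 <- c1$bonds; b2 <- c2$bonds
  if (any((b1$mol1 == m1 & b1$site1 == s1) |
          (b1$mol2 == m1 & b1$site2 == s1)) ||
      any((b2$mol1 == m2 & b2$site1 == s2) |
          (b2$mol2 == m2 & b2$site2 == s2))) {
    abort("cannot snap: an interface is already bound")
  }
  mol1 <- c1$molecules[[m1]]; mol2 <- c2$molecules[[m2]]
  p1 <- site_global(mol1, s1); p2 <- site_global(mol2, s2)
  d1 <- p1 - mol1$pos
  n1 <- sqrt(sum(d1^2))
  d1 <- if (n1 > 1e-9) d1 / n1 else c(0, 0, 1)  # point species: along +z
  target_site <- p1 + sigma * d1

  d2 <- p2 - mol2$pos
  n2 <- sqrt(sum(d2^2))
  if (n2 > 1e-9) {
    d2 <- d2 / n2
    q_align <- quat_between(d2, -d1)
    a2 <- quat_rotate(quat_multiply(q_align, mol2$quat), c(0, 0, 1))
    a1 <- quat_rotate(mol1$quat, c(0, 0, 1))
    # twist about the bond axis so both symmetry axes are coplanar with it
    nrm <- cross3(d1, a1)
    if (sqrt(sum(nrm^2)) > 1e-9) {
      nrm <- nrm / sqrt(sum(nrm^2))
      in_plane <- cross3(nrm, d1)                 # same side as a1
      phi <- atan2(sum(a2 * nrm), sum(a2 * in_plane))
      q_align <- quat_multiply(quat_from_axis_angle(d1, -phi), q_align)
    }
  } else {
    q_align <- quat_identity()
  }

  moved <- lapply(c2$molecules, function(m) {
    m$pos <- quat_rotate(q_align, m$pos - mol2$pos) + mol2$pos
    m$quat <- quat_normalize(quat_multiply(q_align, m$quat))
    m
  })
  rot_disp <- max(vapply(seq_along(moved), function(i)
    sqrt(sum((moved[[i]]$pos - c2$molecules[[i]]$pos)^2)), 0))
  if (rot_disp > max_rotation_nm) return(NULL)
  p2_new <- site_global(moved[[m2]], s2)
  shift <- target_site - p2_new
  moved <- lapply(moved, function(m) { m$pos <- m$pos + shift; m })

  merged <- c1
  off <- length(c1$molecules)
  merged$molecules <- c(c1$molecules, moved)
  if (nrow(c2$bonds)) {
    b2$mol1 <- b2$mol1 + off; b2$mol2 <- b2$mol2 + off
  }
  merged$bonds <- dplyr::bind_rows(
    c1$bonds, b2, tibble(mol1 = m1, site1 = s1,
                         mol2 = m2 + off, site2 = s2))
  merged$n_anchors <- c1$n_anchors + c2$n_anchors
  if (check_steric) {
    cm <- com_positions(merged)
    ex <- vapply(merged$molecules,
                 function(m) m$template$com_exclusion_nm, 0)
    for (i in seq_len(nrow(cm) - 1)) for (j in (i + 1):nrow(cm)) {
      bonded <- any((merged$bonds$mol1 == i & merged$bonds$mol2 == j) |
                    (merged$bonds$mol1 == j & merged$bonds$mol2 == i))
      rex <- min(ex[i], ex[j])
      if (!bonded && rex > 0 && sum((cm[i, ] - cm[j, ])^2) < rex^2 * (1 - 1e-9)) {
        return(NULL)
      }
    }
  }
  merged
}

site_global <- function(mol, s) {
  ifs <- mol$template$interfaces
  drop(quat_rotate(mol$quat,
                   c(ifs$x[s], ifs$y[s], ifs$z[s]))) + mol$pos
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Count clathrin members of a complex
#' @param cx An `rd_complex`.
#' @return Integer count of members built from the clathrin template.
#' @export
n_clathrin <- function(cx) {
  sum(vapply(cx$molecules, function(m)
    identical(m$template$name, "clathrin"), TRUE))
}
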