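test_that("clathrin template geometry follows the pucker angle", {
  tpl <- build_clathrin_template(90)
  legs <- dplyr::filter(tpl$interfaces, class == "cla_leg")
  expect_equal(nrow(legs), 3)
  expect_equal(nrow(dplyr::filter(tpl$interfaces, class == "cla_ap")), 3)
  # flat pucker: all leg sites in the COM plane, radial distance 6 nm
  expect_equal(legs$z, rep(0, 3), tolerance = 1e-12)
  expect_equal(sqrt(legs$x^2 + legs$y^2 + legs$z^2), rep(6, 3))
  # azimuthal 120-degree spacing
  az <- sort(atan2(legs$y, legs$x) %% (2 * pi))
  expect_equal(diff(az), rep(2 * pi / 3, 2))
  # curved pucker: leg z = 6 cos(alpha), direct trigonometry
  t98 <- build_clathrin_template(98)
  expect_equal(dplyr::filter(t98$interfaces, class == "cla_leg")$z,
               rep(6 * cos(98 * pi / 180), 3))
  expect_error(build_clathrin_template(80), "alpha")
  expect_error(build_clathrin_template(115), "alpha")
})

test_that("adaptor template is a 4 nm rod with one clathrin and one lipid site", {
  tpl <- build_adaptor_template()
  expect_setequal(tpl$interfaces$class, c("ap_cla", "ap_lip"))
  z <- tpl$interfaces$z
  expect_equal(abs(diff(z)), 4)
})

test_that("binding snap places bound trimers at the 17 nm lattice distance", {
  tpl <- build_clathrin_template(90)
  c1 <- new_complex(tpl, c(0, 0, 0))
  c2 <- new_complex(tpl, c(40, 5, -3))
  m <- snap_on_binding(c1, 1, 1, c2, 1, 1, sigma = 5)
  expect_false(is.null(m))
  d <- sqrt(sum((m$molecules[[2]]$pos - m$molecules[[1]]$pos)^2))
  expect_equal(d, 17, tolerance = 1e-9)
  # identity when already in the bound pose: re-snap from the bound geometry
  expect_error(snap_on_binding(m, 1, 1, new_complex(tpl), 1, 1, sigma = 5),
               "already bound")
})

test_that("six flat trimers close into the analytic regular hexagon", {
  tpl <- build_clathrin_template(90)
  cx <- new_complex(tpl, c(0, 0, 0))
  for (i in 1:5) {
    sp <- site_positions(cx)
    fl <- sp[sp$mol == i & sp$class == "cla_leg" & !sp$bound, ]
    cx <- snap_on_binding(cx, i, fl$site[1], new_complex(tpl), 1, 1,
                          sigma = 5)
    expect_false(is.null(cx))
  }
  coms <- clathrid:::com_positions(cx)
  # coplanarity
  expect_lt(max(abs(coms[, 3])), 1e-6)
  # all edges 17 nm, closing edge included
  edges <- vapply(1:6, function(i)
    sqrt(sum((coms[i, ] - coms[i %% 6 + 1, ])^2)), 0)
  expect_equal(edges, rep(17, 6), tolerance = 1e-9)
  # regular hexagon: all vertices equidistant from the centroid
  cen <- colMeans(coms)
  radii <- sqrt(rowSums(sweep(coms, 2, cen)^2))
  expect_equal(radii, rep(17, 6), tolerance = 1e-9)
  # the two dangling leg sites of the closing pair are within the
  # imperfect-contact cutoff in a perfect ring (they coincide at sigma)
  sp <- site_positions(cx)
  free_legs <- sp[sp$class == "cla_leg" & !sp$bound, ]
  expect_equal(nrow(free_legs), 8)  # 18 legs - 2*5 bound
})

test_that("steric overlap triggers on trimer COMs and unbound reactive sites", {
  tpl <- build_clathrin_template(90)
  a <- new_complex(tpl, c(0, 0, 0))
  b9 <- new_complex(tpl, c(9, 0, 0))
  expect_true(steric_check(a, b9))       # COM pair at 9 < 10 nm
  b11 <- new_complex(tpl, c(10.5, 80, 0))
  expect_false(steric_check(a, new_complex(tpl, c(80, 80, 0))))
  # bound partners are exempt: a snapped dimer COM distance is 17 nm and its
  # bound legs at separation 5 nm do not trigger
  m <- snap_on_binding(a, 1, 1, new_complex(tpl, c(40, 0, 0)), 1, 1,
                       sigma = 5)
  expect_false(is.null(m))
  expect_false(b11$molecules[[1]]$pos[1] < 10)
})

test_that("aggregate diffusion follows the harmonic-sum / radius-sum rules", {
  ad <- new_complex(build_adaptor_template())
  # membrane adaptor: rod + one lipid anchor -> 0.49 um^2/s in plane
  d <- aggregate_diffusion(ad, n_anchors = 1)
  expect_equal(d$D_trans[1], 1 / (1 / 25 + 1 / 0.5), tolerance = 1e-12)
  expect_equal(d$D_trans[3], 0)          # anchored: no z diffusion
  # single free molecule: its own template coefficients
  d1 <- aggregate_diffusion(ad, n_anchors = 0)
  expect_equal(d1$D_trans, c(25, 25, 25))
  # two trimers: harmonic sum 6.5; rotational radius-sum combination
  tpl <- build_clathrin_template(90)
  dim2 <- snap_on_binding(new_complex(tpl), 1, 1,
                          new_complex(tpl, c(40, 0, 0)), 1, 1, sigma = 5)
  d2 <- aggregate_diffusion(dim2)
  expect_equal(d2$D_trans[1], 6.5)
  expect_equal(d2$D_rot[1], (2 * 0.03^(-1 / 3))^(-3))
})

test_that("aggregate diffusion is permutation-invariant and non-increasing", {
  tpl <- build_clathrin_template(90)
  ad <- build_adaptor_template()
  cx <- new_complex(tpl)
  prev <- aggregate_diffusion(cx)$D_trans[1]
  for (i in 1:3) {
    sp <- site_positions(cx)
    fl <- sp[sp$class == "cla_leg" & !sp$bound, ]
    cx2 <- snap_on_binding(cx, fl$mol[1], fl$site[1],
                           new_complex(tpl, c(200, 0, 0)), 1, 1, sigma = 5)
    if (is.null(cx2)) break
    cx <- cx2
    cur <- aggregate_diffusion(cx)$D_trans[1]
    expect_lt(cur, prev)
    prev <- cur
  }
  # permutation invariance: mixed complex built in either order
  mix1 <- aggregate_diffusion(
    structure(list(molecules = list(list(template = tpl), list(template = ad)),
                   n_anchors = 0L), class = "rd_complex"))
  mix2 <- aggregate_diffusion(
    structure(list(molecules = list(list(template = ad), list(template = tpl)),
                   n_anchors = 0L), class = "rd_complex"))
  expect_equal(mix1, mix2)
})

test_that("snap rejection threshold limits rotational displacement", {
  tpl <- build_clathrin_template(90)
  # a long chain snapped onto a new anchor must rotate members far away;
  # with a tight threshold the snap is rejected, with a loose one accepted
  chain <- new_complex(tpl)
  for (i in 1:3) {
    sp <- site_positions(chain)
    fl <- sp[sp$class == "cla_leg" & !sp$bound, ]
    chain <- snap_on_binding(chain, fl$mol[nrow(fl)], fl$site[nrow(fl)],
                             new_complex(tpl, c(300, 0, 0)), 1, 1, sigma = 5,
                             max_rotation_nm = Inf)
  }
  anchor <- new_complex(tpl, c(-40, 0, 0))
  sp <- site_positions(chain)
  fl <- sp[sp$class == "cla_leg" & !sp$bound, ]
  pick <- which.max(fl$x)
  tight <- snap_on_binding(anchor, 1, 1, chain, fl$mol[pick], fl$site[pick],
                           sigma = 5, max_rotation_nm = 1)
  loose <- snap_on_binding(anchor, 1, 1, chain, fl$mol[pick], fl$site[pick],
                           sigma = 5, max_rotation_nm = Inf,
                           check_steric = FALSE)
  expect_null(tight)
  expect_false(is.null(loose))
})

test_that("bound pairs stay at the binding radius under rigid transforms", {
  tpl <- build_clathrin_template(96)
  m <- snap_on_binding(new_complex(tpl), 1, 1,
                       new_complex(tpl, c(50, 10, 5)), 1, 2, sigma = 5)
  # rotate the whole complex rigidly and re-measure the bond length
  q <- clathrid:::quat_from_axis_angle(c(1, 2, 3), 0.83)
  m$molecules <- lapply(m$molecules, function(mm) {
    mm$pos <- clathrid:::quat_rotate(q, mm$pos) + c(5, -3, 11)
    mm$quat <- clathrid:::quat_normalize(clathrid:::quat_multiply(q, mm$quat))
    mm
  })
  sp <- site_positions(m)
  bonded <- sp[sp$bound, ]
  d <- sqrt(sum((as.numeric(bonded[1, c("x", "y", "z")]) -
                 as.numeric(bonded[2, c("x", "y", "z")]))^2))
  expect_equal(d, 5, tolerance = 1e-6)
})
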