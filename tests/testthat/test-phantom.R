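test_that("phantom construction yields all shells with sane volumes", {
  geom <- head_geometry(c(85, 85, 85), scalp_mm = 7, skull_mm = 7,
                        csf_mm = 3, gm_mm = 5)
  vol <- build_head_phantom(geom, 2)
  present <- sort(unique(as.vector(vol$labels)))
  expect_setequal(present, TISSUE_LABELS[c("background", "scalp", "skull",
                                           "csf", "gm", "wm")])
  # WM is a 63 mm sphere: voxel count x voxel volume vs analytic volume
  wm_mm3 <- sum(vol$labels == TISSUE_LABELS[["wm"]]) * prod(vol$voxel_mm)
  expect_equal(wm_mm3, 4 / 3 * pi * 63^3, tolerance = 0.05)
  # deterministic
  expect_identical(vol$labels, build_head_phantom(geom, 2)$labels)
})

test_that("shells thinner than a voxel are rejected", {
  geom <- head_geometry()  # CSF shell is 3 mm
  expect_error(build_head_phantom(geom, 4), "thinnest shell")
  expect_error(build_head_phantom(geom, 0.5), "\\[1, 4\\]")
  expect_silent(vol <- build_head_phantom(geom, 3))
})

test_that("each shell spans at least one voxel along the principal axes", {
  geom <- head_geometry(c(84, 104, 96), scalp_mm = 6, skull_mm = 8,
                        csf_mm = 4, gm_mm = 6)
  vol <- build_head_phantom(geom, 2)
  d <- dim(vol$labels)
  mid <- (d + 1) %/% 2
  for (axis in 1:3) {
    line <- switch(axis, vol$labels[, mid[2], mid[3]],
                   vol$labels[mid[1], , mid[3]], vol$labels[mid[1], mid[2], ])
    counts <- table(line)
    for (lab in TISSUE_LABELS[c("scalp", "skull", "csf", "gm")])
      expect_gte(counts[[as.character(lab)]], 2 * 2)  # both sides of the head
  }
})

test_that("pathology carving matches its analytic solids and is local", {
  geom <- head_geometry()
  vol <- build_head_phantom(geom, 2)
  spec <- pathology_spec(geom)
  out <- insert_pathology(vol, spec)

  cav_mm3 <- sum(out$labels == TISSUE_LABELS[["resection_cavity"]]) *
    prod(out$voxel_mm)
  expect_equal(cav_mm3, 4 / 3 * pi * 12.5^3, tolerance = 0.10)
  tum_mm3 <- sum(out$labels == TISSUE_LABELS[["residual_tumor"]]) *
    prod(out$voxel_mm)
  expect_equal(tum_mm3, 4 / 3 * pi * 12.5^3, tolerance = 0.10)
  expect_gt(sum(out$labels == TISSUE_LABELS[["funnel"]]), 0)

  # locality: voxels outside the three solids keep their input label
  changed <- out$labels != vol$labels
  co <- voxel_coords(vol)
  r_cav <- spec$cavity_diameter_mm / 2 + sqrt(3)  # half-diagonal slack
  d_cav <- sqrt((co$X - spec$cavity_center[1])^2 +
                (co$Y - spec$cavity_center[2])^2 +
                (co$Z - spec$cavity_center[3])^2)
  d_tum <- sqrt((co$X - spec$tumor_center[1])^2 +
                (co$Y - spec$tumor_center[2])^2 +
                (co$Z - spec$tumor_center[3])^2)
  dc <- cbind(co$X - spec$cavity_center[1], co$Y - spec$cavity_center[2],
              co$Z - spec$cavity_center[3])
  tpar <- dc %*% spec$funnel_axis
  perp <- sqrt(pmax(rowSums(dc^2) - tpar^2, 0))
  near_funnel <- array(perp <= spec$funnel_diameter_mm / 2 + sqrt(3) & tpar > 0,
                       dim = dim(vol$labels))
  outside_all <- d_cav > r_cav & d_tum > r_cav & !near_funnel
  expect_false(any(changed & outside_all))
})

test_that("degenerate pathology specs are rejected", {
  geom <- head_geometry()
  expect_error(pathology_spec(geom, funnel_diameter_mm = 0), "positive")
  # cavity pushed outside the brain
  sp <- pathology_spec(geom)
  sp$cavity_center <- c(0, 0, 90)
  vol <- build_head_phantom(geom, 3)
  expect_error(insert_pathology(vol, sp), "protrudes")
})

test_that("SR surgery drills five piercing holes and touches only skull", {
  base <- study_base()
  q <- place_quincunx(base, "over_tumor")
  out <- apply_sr_surgery(base, q)

  burr <- out$labels == TISSUE_LABELS[["burr_hole"]]
  expect_equal(n_components(burr), 5L)
  # only skull voxels were relabeled
  changed <- out$labels != base$labels
  expect_true(all(base$labels[changed] == TISSUE_LABELS[["skull"]]))
  for (lab in TISSUE_LABELS[c("scalp", "csf", "gm", "wm", "residual_tumor")])
    expect_identical(sum(out$labels == lab), sum(base$labels == lab))
  # control path: no spec means no change
  expect_identical(apply_sr_surgery(base, NULL)$labels, base$labels)
})

test_that("total burr-hole cross-section approximates five 15 mm discs", {
  # finer grid for the area estimate: hole volume / skull thickness
  geom <- head_geometry()
  base2 <- insert_pathology(build_head_phantom(geom, 2))
  out2 <- apply_sr_surgery(base2, place_quincunx(base2, "over_tumor"))
  vol_mm3 <- sum(out2$labels == TISSUE_LABELS[["burr_hole"]]) * 8
  area_mm2 <- vol_mm3 / geom$thickness_mm[["skull"]]
  expect_equal(area_mm2, 5 * pi * 7.5^2, tolerance = 0.10)
})

test_that("quincunx placement variants land at the stated surface offsets", {
  base <- study_base()
  ax <- base$geom$semiaxes$skull
  ctr <- place_quincunx(base, "over_tumor")$center
  # over_tumor: center is the radial projection of the pathology centroid
  centroid <- pathology_centroid(base)
  proj <- ell_project(centroid, ax)
  expect_lt(sqrt(sum((ctr - proj)^2)), max(base$voxel_mm))

  d_sup <- surface_distance(ctr, place_quincunx(base, "sup3")$center, ax)
  expect_equal(d_sup, 30, tolerance = 2 / 30)
  d_post <- surface_distance(ctr, place_quincunx(base, "post3")$center, ax)
  expect_equal(d_post, 30, tolerance = 2 / 30)
  d_far <- surface_distance(ctr, place_quincunx(base, "far")$center, ax)
  expect_gte(d_far, 78)
  expect_null(place_quincunx(base, "none"))
  expect_error(place_quincunx(base, "sideways"), "unknown")
})

test_that("labeled solid volumes are stable under grid refinement", {
  geom <- head_geometry(c(80, 95, 88), scalp_mm = 6, skull_mm = 7,
                        csf_mm = 4, gm_mm = 5)
  v4 <- apply_sr_surgery(insert_pathology(build_head_phantom(geom, 4)),
                         quincunx_spec(ell_project(c(40, 25, 40),
                                                   geom$semiaxes$skull)))
  v2 <- apply_sr_surgery(insert_pathology(build_head_phantom(geom, 2)),
                         quincunx_spec(ell_project(c(40, 25, 40),
                                                   geom$semiaxes$skull)))
  for (lab in TISSUE_LABELS[c("skull", "wm", "resection_cavity",
                              "residual_tumor", "burr_hole")]) {
    m4 <- sum(v4$labels == lab) * prod(v4$voxel_mm)
    m2 <- sum(v2$labels == lab) * prod(v2$voxel_mm)
    expect_equal(m4, m2, tolerance = 0.05)
  }
})
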