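test_that("arrays have nine discs at 45 x 22 mm surface pitch", {
  geom <- head_geometry()
  arr <- make_array(geom, ring_point(geom$semiaxes$scalp, 60, 50))
  expect_equal(nrow(arr$centers), 9)
  ax <- geom$semiaxes$scalp
  # every disc center on the scalp surface
  for (k in 1:9)
    expect_equal(sum((arr$centers[k, ] / ax)^2), 1, tolerance = 1e-9)
  # nearest-neighbor surface distances are the two pitches
  for (k in 1:9) {
    d <- sapply(setdiff(1:9, k), function(j)
      surface_distance(arr$centers[k, ], arr$centers[j, ], ax))
    expect_equal(min(d), 22, tolerance = 2 / 22)
    expect_true(any(abs(d - 45) < 2))
  }
})

test_that("in-plane rotation by a full turn is the identity", {
  geom <- head_geometry()
  p <- ring_point(geom$semiaxes$scalp, 30, 50)
  a0 <- make_array(geom, p, in_plane_angle = 0)
  a360 <- make_array(geom, p, in_plane_angle = 360)
  expect_equal(a0$centers, a360$centers, tolerance = 1e-12)
})

test_that("antipodal arrays keep a large inter-array clearance", {
  geom <- head_geometry()
  pair <- layout_circumferential(geom, 0)
  dmin <- min(apply(pair$ipsi$centers, 1, function(p)
    min(sqrt(rowSums(sweep(pair$contra$centers, 2, p)^2)))))
  expect_gt(dmin, 100)
})

test_that("circumferential layouts oppose each other and cover the grid", {
  geom <- head_geometry()
  for (a in seq(0, 165, 15)) {
    pair <- layout_circumferential(geom, a)
    az <- function(p) atan2(p[1], p[2]) * 180 / pi
    sep <- (az(pair$ipsi$center) - az(pair$contra$center)) %% 360
    expect_equal(sep, 180, tolerance = 1 / 180)
  }
  expect_error(layout_circumferential(geom, 50), "multiple of 15")
  # the 60-degree ipsilateral array sits over the over-tumor quincunx
  base <- study_base()
  q <- place_quincunx(base, "over_tumor")
  pair60 <- layout_circumferential(geom, 60)
  d <- surface_distance(pair60$ipsi$center,
                        ell_project(q$center, geom$semiaxes$scalp),
                        geom$semiaxes$scalp)
  expect_lt(d, 10)
})

test_that("normal rotation moves only the ipsilateral array", {
  geom <- head_geometry()
  p0 <- layout_normal_rotation(geom, 0)
  p60c <- layout_circumferential(geom, 60)
  expect_equal(p0$ipsi$centers, p60c$ipsi$centers, tolerance = 1e-9)
  expect_equal(p0$contra$centers, p60c$contra$centers, tolerance = 1e-9)
  for (a in seq(15, 165, 15)) {
    pr <- layout_normal_rotation(geom, a)
    expect_identical(pr$contra$centers, p0$contra$centers)
    expect_equal(pr$ipsi$center, p0$ipsi$center, tolerance = 1e-9)
  }
  # 90-degree rotation swaps the roles of the two pitch axes
  p90 <- layout_normal_rotation(geom, 90)
  d0 <- surface_distance(p0$ipsi$centers[1, ], p0$ipsi$centers[9, ],
                         geom$semiaxes$scalp)
  d90 <- surface_distance(p90$ipsi$centers[1, ], p90$ipsi$centers[9, ],
                          geom$semiaxes$scalp)
  expect_equal(d0, d90, tolerance = 0.02)
})

test_that("vertex translation approaches and meets at the vertex", {
  geom <- head_geometry()
  ax <- geom$semiaxes$scalp
  expect_error(layout_vertex_translation(geom, 0), "\\[20, 150\\]")
  expect_error(layout_vertex_translation(geom, 160), "\\[20, 150\\]")
  d <- sapply(seq(20, 100, 20), function(tr) {
    p <- layout_vertex_translation(geom, tr)
    surface_distance(p$ipsi$center, p$contra$center, ax)
  })
  expect_true(all(diff(d) < 0))  # strictly approaching
  # at large travel the footprints abut/overlap near the vertex
  p140 <- layout_vertex_translation(geom, 140)
  dmin <- min(apply(p140$ipsi$centers, 1, function(p)
    min(sqrt(rowSums(sweep(p140$contra$centers, 2, p)^2)))))
  expect_lt(dmin, 20)  # closer than one disc diameter
})

test_that("layout generation is deterministic", {
  geom <- head_geometry()
  a <- layout_circumferential(geom, 45)
  b <- layout_circumferential(geom, 45)
  expect_identical(a$ipsi$centers, b$ipsi$centers)
  expect_identical(a$contra$normals, b$contra$normals)
})
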