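test_that("fiducial lattice has 57 spheres on the 40 mm grid with the central sphere at the origin", {
  f <- buildFiducialLattice()
  expect_equal(nrow(f), 57L)
  expect_true(all(f$inner_diameter == 10.0))
  # nearest-neighbour distance is exactly the lattice spacing
  d <- as.matrix(dist(f[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(40, 57))
  # numbering: central sphere is #29 and sits at the origin
  expect_equal(f$id[f$x == 0 & f$y == 0 & f$z == 0], 29L)
  # everything strictly inside the 200 mm shell
  expect_true(all(sqrt(f$x^2 + f$y^2 + f$z^2) + 5 < 100))
})

test_that("fiducial groups partition the lattice into 27 internal + six faces of 5", {
  lay <- phantomLayout()
  g <- groupFiducials(lay)
  expect_length(g, 7L)
  expect_equal(length(g$fiducial_internal), 27L)
  faces <- g[names(g) != "fiducial_internal"]
  expect_true(all(lengths(faces) == 5L))
  ids <- sort(unlist(g, use.names = FALSE))
  expect_equal(ids, 1:57)  # disjoint union of all ids
  # coordinate convention: the superior face group has the maximum Z
  f <- fiducials(lay)
  expect_equal(max(f$z), 80)
  expect_equal(f$z[f$group == "fiducial_face_pz"], rep(80, 5))
  expect_equal(f$z[f$group == "fiducial_face_mz"], rep(-80, 5))
})

test_that("parameter arrays hold 14 spheres: 10 on the 50 mm ring at 36 degrees, 4 inner on the 40 mm grid", {
  for (kind in c("NiCl2", "MnCl2", "PD")) {
    a <- buildParameterArray(kind)
    expect_equal(nrow(a), 14L)
    expect_true(all(a$inner_diameter == 15))
    ring <- a[a$ring == "outer", ]
    r <- sqrt(ring$x^2 + ring$z^2)
    expect_equal(r, rep(50, 10))
    ang <- sort(atan2(ring$z, ring$x) * 180 / pi)
    expect_equal(diff(ang), rep(36, 9))
    inner <- a[a$ring == "inner", ]
    expect_equal(sort(abs(inner$x)), rep(20, 4))
    expect_equal(sort(abs(inner$z)), rep(20, 4))
  }
  expect_error(buildParameterArray("CuSO4"))
})

test_that("resolution insets have 155 non-overlapping holes, 31 per size, one shared per block", {
  for (kind in c("coarse", "fine")) {
    h <- buildResolutionInset(kind)
    expect_equal(nrow(h), 155L)
    expect_equal(as.integer(table(h$size_mm)), rep(31L, 5))
    sizes <- sort(unique(h$diameter_mm))
    expect_equal(sizes, if (kind == "coarse") seq(0.6, 1.0, 0.1)
                        else seq(0.4, 0.8, 0.1))
    # exactly one shared hole per size, belonging to both angle groups
    expect_equal(as.integer(tapply(h$shared, h$size_mm, sum)), rep(1L, 5))
    # no two holes overlap
    d <- as.matrix(dist(h[, c("u", "v")]))
    diag(d) <- Inf
    lim <- outer(h$diameter_mm, h$diameter_mm, "+") / 2
    expect_true(all(d > lim))
    # each angle group (with the shared hole) is a full 4 x 4 grid
    for (s in sizes) {
      blk <- h[h$size_mm == s, ]
      expect_equal(sum(blk$group_angle_deg == 0), 16L)
      expect_equal(sum(blk$group_angle_deg == 10 | blk$shared), 16L)
    }
  }
})

test_that("layout serialization round-trips bit-exactly through JSON", {
  lay <- phantomLayout()
  path <- tempfile(fileext = ".json")
  layoutToJSON(lay, path)
  lay2 <- layoutFromJSON(path)
  expect_identical(fiducials(lay2), fiducials(lay))
  expect_identical(lay2@arrays, lay@arrays)
  expect_identical(lay2@insets$fine$u, lay@insets$fine$u)
  expect_identical(wedgeSpec(lay2)$centers, wedgeSpec(lay)$centers)
  unlink(path)
})
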