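test_that("volumes, areas and watertightness of analytic solids", {
  m <- make_cube()
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 1)
  expect_equal(mesh_area(m), 6)
  cyl <- make_cylinder(2, 0, 5, nseg = 256)
  expect_true(is_watertight(cyl))
  expect_equal(mesh_volume(cyl), pi * 4 * 5, tolerance = 1e-3)
})

test_that("degenerate input (collinear points) is rejected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(tri_mesh(V, rbind(c(1, 2, 3))), "degenerate")
  expect_error(tri_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), "empty")
})

test_that("rigid rotation matches the closed form and preserves volume", {
  expect_equal(rotate_points(c(2, 0, 0), c(0, 0, 1), 120, c(1, 0, 0)),
               c(1 + cos(2 * pi / 3), sin(2 * pi / 3), 0))
  m <- make_cube()
  expect_identical(rigid_rotate(m, c(0, 1, 0), 0)$vertices, m$vertices)
  # 90 deg about z through the centre permutes the vertex set
  r <- rigid_rotate(m, c(0, 0, 1), 90, c(0.5, 0.5, 0.5))
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = ","))
  expect_identical(key(r$vertices), key(m$vertices))
  # volume conserved to high relative accuracy under arbitrary rotations
  for (ang in c(17.3, 113.9, -42.1)) {
    r <- rigid_rotate(m, c(1, 2, 3), ang, c(-1, 0.5, 2))
    expect_equal(mesh_volume(r), 1, tolerance = 1e-9)
  }
  expect_error(rigid_rotate(m, c(0, 0, 0), 10), "non-zero")
})

test_that("overlap fraction: disjoint, identical, analytic box intersection", {
  a <- make_cube()
  expect_equal(overlap_fraction(a, make_cube(c(3, 0, 0))), 0)
  expect_equal(overlap_fraction(a, make_cube()), 1)
  expect_equal(overlap_fraction(a, make_cube(c(0.5, 0, 0))), 0.5,
               tolerance = 1e-9)
  # symmetry in the mesh arguments
  b <- make_cube(c(0.3, 0.2, -0.1))
  expect_equal(overlap_fraction(a, b), overlap_fraction(b, a))
  # self-overlap after a zero-angle rotation is exactly 1
  expect_identical(overlap_fraction(a, rigid_rotate(a, c(1, 1, 0), 0, c(2, 0, 0))),
                   1)
})

test_that("grid overlap agrees with exact boolean on box pairs within 2%", {
  a <- make_cube(side = 2)
  offs <- list(c(0.5, 0, 0), c(1.2, 0.7, 0), c(0.3, 0.3, 0.3))
  for (o in offs) {
    b <- make_cube(o, side = 2)
    exact <- prod(pmax(2 - abs(o), 0)) / 8  # fraction of mean volume 8
    # pitch 1/50 of the minimum box edge = 100 divisions of the 2 mm edge
    got <- overlap_fraction(a, b, grid_n = 100)
    expect_equal(got, exact, tolerance = 0.02)
  }
})

test_that("merging behaves as a union for measures and overlap", {
  a <- make_cube()
  expect_identical(merge_meshes(a, NULL), a)
  two <- merge_meshes(a, make_cube(c(3, 0, 0)))
  expect_equal(mesh_volume(two), 2)
  onehalf <- merge_meshes(a, make_cube(c(0.5, 0, 0)))
  expect_equal(mesh_volume(onehalf), 1.5, tolerance = 0.02)
  # overlap against a probe equals the union behaviour
  probe <- make_cube(c(0.25, 0, 0))
  expect_equal(intersection_volume(onehalf, probe),
               mesh_volume(probe), tolerance = 0.05)
})

test_that("planar cuts keep the correct side, re-capped watertight", {
  m <- make_cube()
  above <- cut_above_plane(m, c(0.5, 2, 0.5), c(0, 1, 0))
  expect_equal(mesh_volume(above), 1)
  half <- cut_above_plane(m, c(0.5, 0.5, 0.5), c(0, 1, 0))
  expect_true(is_watertight(half))
  expect_equal(mesh_volume(half), 0.5, tolerance = 1e-9)
  expect_lte(max(half$vertices[, 2]), 0.5 + 1e-12)
  # oblique cut of a cube: kept volume from the half-space formula
  ob <- cut_above_plane(m, c(0.5, 0.5, 0.5), c(1, 1, 0) / sqrt(2))
  expect_true(is_watertight(ob))
  expect_equal(mesh_volume(ob), 0.5, tolerance = 1e-9)
  expect_error(cut_above_plane(m, c(0, -1, 0), c(0, 1, 0)), "empty")
})

test_that("mesh files round-trip through OBJ, PLY and STL", {
  m <- make_cylinder(2, 0, 5, nseg = 12)
  for (ext in c("obj", "ply", "stl")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", ext))
    save_mesh(m, path)
    r <- load_mesh(path)
    expect_equal(nrow(r$faces), nrow(m$faces))
    expect_equal(mesh_volume(r), mesh_volume(m), tolerance = 1e-6)
  }
  expect_error(load_mesh("does-not-exist.obj"), "not found")
})

test_that("binary STL and ascii PLY from external writers parse", {
  # hand-written ascii PLY of a tetrahedron
  ply <- file.path(withr::local_tempdir(), "tet.ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), ply)
  m <- load_mesh(ply)
  expect_equal(mesh_volume(m), 1 / 6, tolerance = 1e-7)
  # binary STL of the same tetrahedron
  stl <- file.path(withr::local_tempdir(), "tet.stl")
  con <- file(stl, "wb")
  writeBin(raw(80), con)
  writeBin(4L, con, size = 4, endian = "little")
  tris <- list(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
               rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0)),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  for (t in tris) {
    writeBin(numeric(3), con, size = 4, endian = "little")
    writeBin(as.numeric(t(t)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  close(con)
  m2 <- load_mesh(stl)
  expect_equal(mesh_volume(m2), 1 / 6, tolerance = 1e-7)
})
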