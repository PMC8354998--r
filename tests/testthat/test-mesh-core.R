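test_that("construction cleans duplicates and degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0, 0, 0),          # exact duplicate of vertex 1
             c(1, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(4, 5, 6), # same triangle twice via duplicates
             c(1, 1, 2))             # degenerate
  m <- tri_mesh(v, f)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 2) # the two coincident triangles both survive
  expect_error(tri_mesh(matrix(numeric(0), 0, 3), f), "empty")
  expect_error(tri_mesh(v, rbind(c(1, 2, 99))), "out of range")
})

test_that("vertex normals are area-weighted face-normal means", {
  sheet <- grid_sheet(3, 3)
  expect_true(all(abs(sheet$vertex_normals[, 3] - 1) < 1e-12))
  expect_true(all(abs(sheet$vertex_normals[, 1:2]) < 1e-12))

  # icosahedron: by symmetry every vertex normal is exactly radial
  ico <- icosahedron()
  rad <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  ang <- acos(pmin(1, rowSums(rad * ico$vertex_normals))) * 180 / pi
  expect_true(all(ang < 5))

  # 90-degree patch with equal incident areas: edge-vertex normal sits at 45
  # degrees from both face normals
  ra <- right_angle_patch()
  shared <- which(ra$vertices[, 1] %in% c(0, 1) & ra$vertices[, 2] == 0 &
                    ra$vertices[, 3] == 0)
  flat <- which(ra$vertices[, 2] == 1)[1]
  wall <- which(ra$vertices[, 3] == 1)[1]
  expect_equal(unname(normal_angle(ra, shared[1], flat)), 45, tolerance = 1e-9)
  expect_equal(unname(normal_angle(ra, shared[1], wall)), 45, tolerance = 1e-9)
})

test_that("isolated vertices get zero normals and refuse angle queries", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  m <- tri_mesh(v, rbind(c(1, 2, 3)))
  expect_equal(unsegmentable_vertices(m), 4L)
  expect_equal(m$vertex_normals[4, ], c(0, 0, 0))
  expect_error(normal_angle(m, 1, 4), "unsegmentable")
})

test_that("adjacency is symmetric, sorted, and matches a brute-force scan", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_equal(lengths(vertex_adjacency(m)), c(2L, 2L, 2L))

  ico <- icosahedron()
  expect_true(all(lengths(vertex_adjacency(ico)) == 5L))

  fx <- random_small_fixture(11)
  adj <- vertex_adjacency(fx$mesh)
  # brute-force edge scan
  f <- fx$mesh$faces
  ed <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                     f[, 2:1], f[, 3:2], f[, c(1, 3)]))
  for (u in seq_along(adj)) {
    expect_identical(adj[[u]], sort(adj[[u]]))
    expect_setequal(adj[[u]], ed[ed[, 1] == u, 2])
  }
  # symmetry
  for (u in seq_along(adj)) {
    for (v in adj[[u]]) expect_true(u %in% adj[[v]])
  }
})

test_that("normal_angle is symmetric and hits the textbook cases", {
  sheet <- grid_sheet(2, 2)
  expect_equal(unname(normal_angle(sheet, 1, 5)), 0)

  ra <- right_angle_patch()
  flat <- which(ra$vertices[, 2] == 1)[1]
  wall <- which(ra$vertices[, 3] == 1)[1]
  expect_equal(unname(normal_angle(ra, flat, wall)), 90, tolerance = 1e-9)
  # two sheets with opposite winding: opposite normals
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
              c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  m2 <- tri_mesh(v2, rbind(c(1, 2, 3), c(4, 6, 5)))
  expect_equal(unname(normal_angle(m2, 1, 4)), 180)

  fx <- random_small_fixture(12)
  adj <- vertex_adjacency(fx$mesh)
  u <- rep(seq_along(adj), lengths(adj))
  v <- unlist(adj)
  expect_equal(normal_angle(fx$mesh, u, v), normal_angle(fx$mesh, v, u))
})

test_that("boundary loops: watertight meshes have none, sheets have a rim", {
  expect_length(find_boundary_loops(icosahedron()), 0)

  sheet <- grid_sheet(3, 3)
  loops <- find_boundary_loops(sheet)
  expect_length(loops, 1)
  expect_equal(length(loops[[1]]), 12) # rim of a 3x3-cell grid

  fx <- generate_chain(fixture_spec(n_lobes = 3, mesh_resolution = 2.5))
  expect_length(find_boundary_loops(fx$mesh), 0)

  holed <- generate_chain(fixture_spec(n_lobes = 3, mesh_resolution = 2.5,
                                       hole_fraction = 0.5))
  expect_gt(length(find_boundary_loops(holed$mesh)), 0)
})

test_that("non-manifold edges are reported, not fatal", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)) # 3 faces share edge 1-2
  m <- tri_mesh(v, f)
  expect_warning(loops <- find_boundary_loops(m), "non-manifold")
  expect_equal(nrow(attr(loops, "non_manifold_edges")), 1)
})

test_that("Euler characteristic of closed fixtures is 2", {
  for (m in list(icosahedron(),
                 generate_chain(fixture_spec(n_lobes = 2,
                                             mesh_resolution = 3))$mesh)) {
    ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
    ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
    expect_equal(nrow(m$vertices) - nrow(ed) + nrow(m$faces), 2)
  }
})
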