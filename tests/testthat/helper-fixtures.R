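# Small meshes built in code, shared across test files.

# flat grid sheet in the z = 0 plane, (nx+1) x (ny+1) vertices
grid_sheet <- function(nx = 4, ny = 4, z = 0, spacing = 1) {
  pts <- as.matrix(expand.grid(x = 0:nx, y = 0:ny))
  v <- cbind(pts[, 1] * spacing, pts[, 2] * spacing, z)
  vid <- function(i, j) i + 1L + j * (nx + 1L) # 0-based i, j
  f <- list()
  for (j in 0:(ny - 1)) {
    for (i in 0:(nx - 1)) {
      f[[length(f) + 1L]] <- rbind(
        c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
        c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
      )
    }
  }
  tri_mesh(v, do.call(rbind, f))
}

# regular icosahedron (closed platonic solid, 12 vertices / 20 faces)
icosahedron <- function(scale = 1) {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1)
  ) * scale
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  tri_mesh(v, f)
}

# two equal-area triangles meeting at a right angle along a shared edge, so
# each shared-edge vertex has equal incident area on both sides
right_angle_patch <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0),  # shared edge along x
    c(0.5, 1, 0),            # flat triangle apex, z = 0 plane (normal +z)
    c(0.5, 0, 1)             # wall triangle apex, y = 0 plane (normal +y)
  )
  f <- rbind(
    c(1, 2, 3),
    c(2, 1, 4)
  )
  tri_mesh(v, f)
}

# small random fixture below a vertex budget; deterministic in `seed`
random_small_fixture <- function(seed, max_vertices = 500) {
  set.seed(seed)
  repeat {
    spec <- fixture_spec(
      n_lobes = sample(1:3, 1),
      lobe_shape = sample(c("superellipsoid", "rounded_box"), 1),
      crease_angle = stats::runif(1, 40, 120),
      contact_radius = 2,
      noise_sd = stats::runif(1, 0, 0.3),
      hole_fraction = sample(c(0, 0.3), 1),
      random_seed = seed,
      mesh_resolution = 3.5,
      lobe_height = 12
    )
    fx <- generate_chain(spec)
    if (nrow(fx$mesh$vertices) <= max_vertices) return(fx)
  }
}

minimal_ascii_stl <- function(path) {
  writeLines(c(
    "solid one",
    "facet normal 0 0 1", "  outer loop",
    "    vertex 0 0 0", "    vertex 1 0 0", "    vertex 0 1 0",
    "  endloop", "endfacet",
    "endsolid one"
  ), path)
  path
}
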