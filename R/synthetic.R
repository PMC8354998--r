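#' Specification of a synthetic touching-lobe phantom
#'
#' Deterministic generator settings for ground-truth-labelled mesh phantoms
#' emulating a chain of convex bone segments (vertebra-like lobes) fused at
#' small contact patches. Round lobes are surfaces of revolution whose
#' profile meets the contact circle at exactly half the requested crease
#' angle, so the vertex-normal jump across the contact equals `crease_angle`;
#' smooth intra-lobe curvature keeps neighbouring-normal angles far below the
#' crease. Cube lobes are the minimal worked example (90-degree interior
#' edges, effectively 180-degree contact crease; `crease_angle` is ignored).
#'
#' @param n_lobes number of lobes (>= 1).
#' @param lobe_shape `"superellipsoid"` (smooth bulged barrel),
#'   `"rounded_box"` (flatter-sided variant) or `"cube"`.
#' @param crease_angle dihedral of the normal discontinuity at contact
#'   patches, degrees in (0, 180).
#' @param contact_radius radius of the contact patch, mm.
#' @param noise_sd vertex jitter along normals, mm (standard deviation).
#' @param hole_fraction fraction of contact-patch faces deleted (emulating
#'   the holes thresholded meshes show where facet joints touch).
#' @param random_seed integer seed driving all generator randomness.
#' @param mesh_resolution target edge length, mm.
#' @param lobe_height axial height of one lobe body, mm.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_lobes = 3,
                         lobe_shape = c("superellipsoid", "rounded_box",
                                        "cube"),
                         crease_angle = 60, contact_radius = 4,
                         noise_sd = 0, hole_fraction = 0, random_seed = 1,
                         mesh_resolution = 1.2, lobe_height = 20) {
  lobe_shape <- match.arg(lobe_shape)
  if (n_lobes < 1) stop("n_lobes must be >= 1", call. = FALSE)
  if (!(crease_angle > 0 && crease_angle < 180))
    stop("crease_angle must lie in (0, 180)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (hole_fraction < 0 || hole_fraction > 1)
    stop("hole_fraction must lie in [0, 1]", call. = FALSE)
  if (contact_radius <= 0 || mesh_resolution <= 0 || lobe_height <= 0)
    stop("contact_radius, mesh_resolution and lobe_height must be positive",
         call. = FALSE)
  spec <- structure(list(
    n_lobes = as.integer(n_lobes), lobe_shape = lobe_shape,
    crease_angle = crease_angle, contact_radius = contact_radius,
    noise_sd = noise_sd, hole_fraction = hole_fraction,
    random_seed = as.integer(random_seed),
    mesh_resolution = mesh_resolution, lobe_height = lobe_height
  ), class = "fixture_spec")
  geo <- .lobe_geometry(spec)
  if (n_lobes > 1) { # a single free lobe has no contact patch to validate
    if (spec$lobe_shape == "cube") {
      if (2 * contact_radius > 0.8 * lobe_height)
        stop("contact_radius too large to keep lobes separable", call. = FALSE)
    } else if (geo$A < 0.25 * contact_radius) {
      stop("contact_radius too large to keep lobes separable", call. = FALSE)
    }
  }
  spec
}

# bulge amplitude and max radius of the round lobe profile;
# rim slope is exactly tan(crease/2) so the normal jump across the weld
# equals the crease angle
.lobe_geometry <- function(spec) {
  b <- switch(spec$lobe_shape, superellipsoid = 0, rounded_box = 0.65, cube = 0)
  g2 <- spec$crease_angle / 2 * pi / 180
  A <- spec$lobe_height * tan(g2) * (1 - b) / pi
  list(b = b, A = A, R_max = spec$contact_radius + A)
}

#' Generate a labelled chain of touching lobes
#'
#' Builds `n_lobes` convex lobes stacked along the z axis, fused at small
#' contact patches where the surface normal jumps by the crease angle within
#' mesh resolution; the weld is a 0.005 mm band whose faces carry negligible
#' area, so the rim vertex normals on either side stay those of their own
#' lobe. Ground-truth label = lobe of origin. Suggested seeds mimic the
#' clinical placement logic: a 5-seed layout (1 body-centre vertex + 4
#' near-contact vertices) and an extended 12-seed layout (4 body vertices + 8
#' near-contact vertices) per lobe. Identical spec (including seed) gives
#' bit-identical output.
#'
#' @param spec a [fixture_spec()].
#' @return a list of class `vertseg_fixture` with elements `mesh`
#'   (a [tri_mesh()] whose `labels` field holds the ground truth), `labels`,
#'   `seeds` (tibble with `x`, `y`, `z`, `label`, `layout`), `spec`, and
#'   `contact_faces` (count of weld-band faces after hole punching).
#' @export
generate_chain <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  raw <- if (spec$lobe_shape == "cube") .build_cube_chain(spec)
         else .build_round_chain(spec)

  faces <- raw$faces
  contact <- raw$contact_faces # face indices of the weld bands
  if (spec$hole_fraction > 0 && length(contact)) {
    n_del <- round(spec$hole_fraction * length(contact))
    if (n_del > 0) {
      del <- withr::with_seed(spec$random_seed,
                              sample(contact, n_del))
      faces <- faces[-del, , drop = FALSE]
    }
  }
  mesh <- tri_mesh(raw$vertices, faces, labels = raw$labels)
  if (spec$noise_sd > 0)
    mesh <- perturb_mesh(mesh, spec$noise_sd, spec$random_seed)

  seeds <- .suggest_seeds(mesh, raw, spec)
  structure(list(mesh = mesh, labels = mesh$labels, seeds = seeds,
                 spec = spec,
                 contact_faces = length(raw$contact_faces) -
                   if (spec$hole_fraction > 0 && length(raw$contact_faces))
                     round(spec$hole_fraction * length(raw$contact_faces))
                   else 0L),
            class = "vertseg_fixture")
}

#' @export
print.vertseg_fixture <- function(x, ...) {
  cat(sprintf("<vertseg_fixture> %d lobes (%s), %d vertices, %d faces\n",
              x$spec$n_lobes, x$spec$lobe_shape, nrow(x$mesh$vertices),
              nrow(x$mesh$faces)))
  invisible(x)
}

# ---- round (surface-of-revolution) lobes ----

# ring sequences per lobe; each lobe is described by rings (z, r) bottom to
# top plus optional pole vertices; the rim rings (r = contact_radius) of
# consecutive lobes are joined by a thin band of triangles
.build_round_chain <- function(spec) {
  geo <- .lobe_geometry(spec)
  b <- geo$b
  A <- geo$A
  R_m <- geo$R_max
  cr <- spec$contact_radius
  h <- spec$lobe_height
  h_b <- h / 2
  res <- spec$mesh_resolution
  eps <- 0.005
  n_theta <- max(12L, ceiling(2 * pi * R_m / res))
  fshape <- function(u) u / ((1 - b) + b * u)

  barrel_rings <- function() { # full interior barrel, rim to rim
    m <- max(8L, ceiling(h / res))
    t <- seq(0, 1, length.out = m + 1)
    cbind(z = h * t, r = cr + A * fshape(sin(pi * t)))
  }
  half_rings_up <- function() { # rim (bottom) rising to max radius (top)
    m <- max(4L, ceiling(h_b / res))
    t <- seq(0, 1, length.out = m + 1)
    cbind(z = h_b * t, r = cr + A * fshape(sin(pi * t / 2)))
  }
  cap_rings_up <- function() { # equator (excluded) up to below the pole
    m <- max(4L, ceiling((pi / 2 * R_m) / res))
    psi <- (pi / 2) * seq_len(m - 1) / m
    cbind(z = R_m * sin(psi), r = R_m * cos(psi))
  }

  lobes <- vector("list", spec$n_lobes)
  for (k in seq_len(spec$n_lobes)) {
    closed_bottom <- k == 1L
    closed_top <- k == spec$n_lobes
    if (closed_bottom && closed_top) { # single free lobe: a sphere
      cap <- cap_rings_up()
      rings <- rbind(
        cbind(z = R_m - rev(cap[, "z"]), r = rev(cap[, "r"])),
        cbind(z = R_m, r = R_m),
        cbind(z = R_m + cap[, "z"], r = cap[, "r"])
      )
      lobes[[k]] <- list(rings = rings, bottom_pole = 0,
                         top_pole = 2 * R_m, height = 2 * R_m)
    } else if (closed_bottom) { # cap below, half barrel up to the top rim
      cap <- cap_rings_up()
      half <- half_rings_up()
      rings <- rbind(
        cbind(z = R_m - rev(cap[, "z"]), r = rev(cap[, "r"])),
        cbind(z = R_m, r = R_m),
        cbind(z = R_m + rev(h_b - half[-nrow(half), "z"]),
              r = rev(half[-nrow(half), "r"]))
      )
      lobes[[k]] <- list(rings = rings, bottom_pole = 0, top_pole = NULL,
                         height = R_m + h_b)
    } else if (closed_top) { # bottom rim, bulge, cap above
      cap <- cap_rings_up()
      half <- half_rings_up()
      rings <- rbind(
        half,
        cbind(z = h_b + cap[, "z"], r = cap[, "r"])
      )
      lobes[[k]] <- list(rings = rings, bottom_pole = NULL,
                         top_pole = h_b + R_m, height = h_b + R_m)
    } else {
      lobes[[k]] <- list(rings = barrel_rings(), bottom_pole = NULL,
                         top_pole = NULL, height = h)
    }
  }

  phi <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  cphi <- cos(phi)
  sphi <- sin(phi)
  verts <- list()
  labels <- list()
  faces <- list()
  contact_faces <- integer(0)
  nfaces <- 0L
  nv <- 0L
  add_faces <- function(m) {
    faces[[length(faces) + 1L]] <<- m
    nfaces <<- nfaces + nrow(m)
  }
  strip <- function(base_a, base_b) { # ring a below ring b, outward winding
    k1 <- seq_len(n_theta)
    k2 <- c(seq_len(n_theta - 1) + 1L, 1L)
    rbind(cbind(base_a + k1, base_a + k2, base_b + k2),
          cbind(base_a + k1, base_b + k2, base_b + k1))
  }

  z0 <- 0
  top_rim_base <- NA_integer_
  lobe_info <- vector("list", spec$n_lobes)
  for (k in seq_len(spec$n_lobes)) {
    lb <- lobes[[k]]
    ring_bases <- integer(nrow(lb$rings))
    bottom_pole_id <- NA_integer_
    top_pole_id <- NA_integer_
    if (!is.null(lb$bottom_pole)) {
      nv <- nv + 1L
      verts[[length(verts) + 1L]] <- matrix(c(0, 0, z0 + lb$bottom_pole), 1)
      labels[[length(labels) + 1L]] <- k
      bottom_pole_id <- nv
    }
    for (i in seq_len(nrow(lb$rings))) {
      ring_bases[i] <- nv
      verts[[length(verts) + 1L]] <-
        cbind(lb$rings[i, "r"] * cphi, lb$rings[i, "r"] * sphi,
              z0 + lb$rings[i, "z"])
      labels[[length(labels) + 1L]] <- rep(k, n_theta)
      nv <- nv + n_theta
    }
    if (!is.null(lb$top_pole)) {
      nv <- nv + 1L
      verts[[length(verts) + 1L]] <- matrix(c(0, 0, z0 + lb$top_pole), 1)
      labels[[length(labels) + 1L]] <- k
      top_pole_id <- nv
    }
    # fans and strips
    if (!is.na(bottom_pole_id)) {
      k1 <- seq_len(n_theta)
      k2 <- c(seq_len(n_theta - 1) + 1L, 1L)
      add_faces(cbind(bottom_pole_id, ring_bases[1] + k2, ring_bases[1] + k1))
    }
    for (i in seq_len(nrow(lb$rings) - 1L))
      add_faces(strip(ring_bases[i], ring_bases[i + 1L]))
    if (!is.na(top_pole_id)) {
      nr <- nrow(lb$rings)
      k1 <- seq_len(n_theta)
      k2 <- c(seq_len(n_theta - 1) + 1L, 1L)
      add_faces(cbind(top_pole_id, ring_bases[nr] + k1, ring_bases[nr] + k2))
    }
    # weld band to the previous lobe
    if (k > 1L) {
      f0 <- nfaces
      add_faces(strip(top_rim_base, ring_bases[1]))
      contact_faces <- c(contact_faces, (f0 + 1L):nfaces)
    }
    lobe_info[[k]] <- list(
      z_bottom = z0, z_top = z0 + lb$height,
      z_mid = z0 + if (!is.null(lb$bottom_pole) && is.null(lb$top_pole))
        lb$height - h_b else if (is.null(lb$bottom_pole) &&
                                 !is.null(lb$top_pole)) h_b
      else lb$height / 2,
      has_bottom_contact = is.null(lb$bottom_pole),
      has_top_contact = is.null(lb$top_pole),
      R_max = R_m
    )
    top_rim_base <- ring_bases[length(ring_bases)]
    z0 <- z0 + lb$height + 2 * eps
  }

  list(vertices = do.call(rbind, verts),
       faces = do.call(rbind, faces),
       labels = unlist(labels),
       contact_faces = contact_faces,
       lobe_info = lobe_info,
       n_theta = n_theta,
       near_contact_inset = max(1.5 * res, 2 * eps))
}

# ---- cube lobes ----

.build_cube_chain <- function(spec) {
  s <- spec$lobe_height
  res <- spec$mesh_resolution
  eps <- 0.005
  n <- max(4L, 2L * ceiling(s / (2 * res))) # even cell count per edge
  cell <- s / n
  hc <- max(1L, round(spec$contact_radius / cell)) # patch half-width, cells
  if (hc > n %/% 2 - 1L)
    stop("contact_radius too large to keep lobes separable", call. = FALSE)
  ctr <- n %/% 2
  patch <- (ctr - hc + 1L):(ctr + hc) # removed cells (1-based)
  g <- seq(0, n) * cell - s / 2 # grid point coords, centred

  verts <- list()
  labels <- list()
  faces <- list()
  contact_faces <- integer(0)
  nfaces <- 0L
  nv <- 0L
  lobe_info <- vector("list", spec$n_lobes)
  prev_rim <- NULL

  # ordered perimeter (counter-clockwise from +z) of the patch, grid points
  a <- ctr - hc
  bb <- ctr + hc
  perim <- rbind(
    cbind(a:(bb - 1L), a),          # bottom edge, left to right
    cbind(bb, a:(bb - 1L)),         # right edge, up
    cbind(bb:(a + 1L), bb),         # top edge, right to left
    cbind(a, bb:(a + 1L))           # left edge, down
  )

  for (k in seq_len(spec$n_lobes)) {
    z0 <- (k - 1) * (s + 2 * eps)
    has_bottom <- k > 1L
    has_top <- k < spec$n_lobes
    # surface grid points of this cube
    id <- array(0L, dim = c(n + 1L, n + 1L, n + 1L))
    pts <- as.matrix(expand.grid(seq_len(n + 1L), seq_len(n + 1L),
                                 seq_len(n + 1L)))
    on_surf <- pts[, 1] %in% c(1L, n + 1L) | pts[, 2] %in% c(1L, n + 1L) |
      pts[, 3] %in% c(1L, n + 1L)
    pts <- pts[on_surf, , drop = FALSE]
    # grid points strictly inside a removed contact patch lie in the weld
    # tunnel, not on the surface: drop them
    gi <- pts[, 1] - 1L
    gj <- pts[, 2] - 1L
    gk <- pts[, 3] - 1L
    in_patch <- gi > a & gi < bb & gj > a & gj < bb
    drop <- (has_bottom & gk == 0L & in_patch) |
      (has_top & gk == n & in_patch)
    pts <- pts[!drop, , drop = FALSE]
    id[pts] <- nv + seq_len(nrow(pts))
    verts[[k]] <- cbind(g[pts[, 1]], g[pts[, 2]], z0 + (pts[, 3] - 1L) * cell)
    labels[[k]] <- rep(k, nrow(pts))
    nv <- nv + nrow(pts)

    vid <- function(i, j, kk) id[cbind(i + 1L, j + 1L, kk + 1L)] # 0-based
    quads <- function(iu, iv, fixed, axis, flip) {
      # grid of cells (iu x iv) on the face; returns triangles with
      # outward winding controlled by `flip`
      uu <- rep(iu, times = length(iv))
      vv <- rep(iv, each = length(iu))
      c00 <- switch(axis, x = vid(fixed, uu - 1L, vv - 1L),
                    y = vid(uu - 1L, fixed, vv - 1L),
                    z = vid(uu - 1L, vv - 1L, fixed))
      c10 <- switch(axis, x = vid(fixed, uu, vv - 1L),
                    y = vid(uu, fixed, vv - 1L),
                    z = vid(uu, vv - 1L, fixed))
      c11 <- switch(axis, x = vid(fixed, uu, vv),
                    y = vid(uu, fixed, vv),
                    z = vid(uu, vv, fixed))
      c01 <- switch(axis, x = vid(fixed, uu - 1L, vv),
                    y = vid(uu - 1L, fixed, vv),
                    z = vid(uu - 1L, vv, fixed))
      if (flip) rbind(cbind(c00, c01, c11), cbind(c00, c11, c10))
      else rbind(cbind(c00, c10, c11), cbind(c00, c11, c01))
    }
    all_c <- seq_len(n)
    add <- function(m) {
      faces[[length(faces) + 1L]] <<- m
      nfaces <<- nfaces + nrow(m)
    }
    # side faces (normals -x, +x, -y, +y)
    add(quads(all_c, all_c, 0L, "x", flip = TRUE))
    add(quads(all_c, all_c, n, "x", flip = FALSE))
    add(quads(all_c, all_c, 0L, "y", flip = FALSE))
    add(quads(all_c, all_c, n, "y", flip = TRUE))
    # bottom face (-z): full unless welded below
    keep_b <- if (has_bottom) !(all_c %in% patch) else rep(TRUE, n)
    if (has_bottom) {
      add(quads(all_c[keep_b], all_c, 0L, "z", flip = TRUE))
      add(quads(all_c[!keep_b], all_c[keep_b], 0L, "z", flip = TRUE))
    } else {
      add(quads(all_c, all_c, 0L, "z", flip = TRUE))
    }
    # top face (+z)
    keep_t <- if (has_top) !(all_c %in% patch) else rep(TRUE, n)
    if (has_top) {
      add(quads(all_c[keep_t], all_c, n, "z", flip = FALSE))
      add(quads(all_c[!keep_t], all_c[keep_t], n, "z", flip = FALSE))
    } else {
      add(quads(all_c, all_c, n, "z", flip = FALSE))
    }
    # weld band to previous cube
    if (has_bottom) {
      rim <- vid(perim[, 1], perim[, 2], 0L)
      m <- length(rim)
      nxt <- c(2:m, 1L)
      f0 <- nfaces
      add(rbind(cbind(prev_rim, prev_rim[nxt], rim[nxt]),
                cbind(prev_rim, rim[nxt], rim)))
      contact_faces <- c(contact_faces, (f0 + 1L):nfaces)
    }
    if (has_top) prev_rim <- vid(perim[, 1], perim[, 2], n)
    lobe_info[[k]] <- list(z_bottom = z0, z_top = z0 + s, z_mid = z0 + s / 2,
                           has_bottom_contact = has_bottom,
                           has_top_contact = has_top, R_max = s / 2)
  }
  list(vertices = do.call(rbind, verts),
       faces = do.call(rbind, faces),
       labels = unlist(labels),
       contact_faces = contact_faces,
       lobe_info = lobe_info,
       n_theta = NA_integer_,
       near_contact_inset = max(1.5 * res, 2 * eps))
}

# seed layouts: geometric target positions snapped to the clean mesh,
# reported at the (possibly noisy) mesh's vertex coordinates
.suggest_seeds <- function(mesh, raw, spec) {
  v <- mesh$vertices
  lab <- raw$labels
  inset <- raw$near_contact_inset
  rows <- list()
  near_pts <- function(info, az, z_off_sign) {
    zc <- if (z_off_sign > 0) info$z_bottom + inset else info$z_top - inset
    r <- spec$contact_radius + inset
    cbind(r * cos(az), r * sin(az), zc)
  }
  az8 <- 2 * pi * (0:7) / 8
  az4 <- az8[c(1, 3, 5, 7)] # 0, 90, 180, 270 degrees
  snap_to_lobe <- function(pts, k) {
    idx <- which(lab == k)
    vapply(seq_len(nrow(pts)), function(i) {
      d2 <- (v[idx, 1] - pts[i, 1])^2 + (v[idx, 2] - pts[i, 2])^2 +
        (v[idx, 3] - pts[i, 3])^2
      idx[which.min(d2)]
    }, integer(1))
  }
  for (k in seq_len(spec$n_lobes)) {
    info <- raw$lobe_info[[k]]
    centroid <- colMeans(v[lab == k, , drop = FALSE])
    centre_vtx <- snap_to_lobe(matrix(centroid, 1), k)
    # near-contact targets: 4 for the 5-seed layout, 8 for the 12-seed
    # layout; the 12-seed set extends the 5-seed set at every contact
    mk_near <- function(wide) {
      both <- info$has_bottom_contact && info$has_top_contact
      if (both) {
        if (wide) {
          rbind(near_pts(info, az8[c(1, 2, 5, 6)], +1),
                near_pts(info, az8[c(3, 4, 7, 8)], -1))
        } else {
          rbind(near_pts(info, az4[c(1, 3)], +1),
                near_pts(info, az4[c(2, 4)], -1))
        }
      } else if (info$has_bottom_contact) {
        near_pts(info, if (wide) az8 else az4, +1)
      } else if (info$has_top_contact) {
        near_pts(info, if (wide) az8 else az4, -1)
      } else { # free lobe: spread on the equator instead
        az <- if (wide) az8 else az4
        cbind(info$R_max * cos(az), info$R_max * sin(az), info$z_mid)
      }
    }
    body4 <- cbind(info$R_max * cos(az4), info$R_max * sin(az4), info$z_mid)
    v5 <- c(centre_vtx, snap_to_lobe(mk_near(FALSE), k))
    v12 <- c(snap_to_lobe(body4, k), snap_to_lobe(mk_near(TRUE), k))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x = v[v5, 1], y = v[v5, 2], z = v[v5, 3], label = k, layout = "seeds5")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x = v[v12, 1], y = v[v12, 2], z = v[v12, 3], label = k,
      layout = "seeds12")
  }
  dplyr::bind_rows(rows)
}

#' Jitter mesh vertices along their normals
#'
#' Displaces every vertex along its unit normal by zero-mean Gaussian noise
#' (emulating CT image noise on a thresholded surface). Topology is
#' unchanged; normals are recomputed. Seeded and reproducible.
#'
#' @param mesh a [tri_mesh()].
#' @param noise_sd standard deviation in mm (>= 0; 0 is the identity).
#' @param random_seed integer seed.
#' @return the perturbed [tri_mesh()].
#' @export
perturb_mesh <- function(mesh, noise_sd, random_seed = 1) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(mesh)
  g <- withr::with_seed(as.integer(random_seed),
                        stats::rnorm(nrow(mesh$vertices), 0, noise_sd))
  mesh$vertices <- mesh$vertices + mesh$vertex_normals * g
  compute_vertex_normals(mesh)
}

#' Voxelise a fixture into a CT-like phantom volume
#'
#' Rasterises the chain solid at the given spacing: voxels whose centre lies
#' inside any lobe get `bone_hu`, the rest `background_hu`. The interior
#' voxel count is recorded in the `n_interior` attribute (used to verify the
#' thresholding front end).
#'
#' @param spec a [fixture_spec()].
#' @param spacing voxel spacing, mm (length 3).
#' @param bone_hu,background_hu intensities; `bone_hu > background_hu`.
#' @return a [volume3d()] with attribute `n_interior`.
#' @export
generate_phantom_volume <- function(spec, spacing = c(0.5, 0.5, 0.5),
                                    bone_hu = 1000, background_hu = 0) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (bone_hu <= background_hu)
    stop("bone_hu must exceed background_hu", call. = FALSE)
  spacing <- rep(spacing, length.out = 3)
  geo <- .lobe_geometry(spec)
  raw <- if (spec$lobe_shape == "cube") .build_cube_chain(spec)
         else .build_round_chain(spec)
  infos <- raw$lobe_info
  R_m <- geo$R_max
  half_xy <- if (spec$lobe_shape == "cube") spec$lobe_height / 2 else R_m
  z_lo <- infos[[1]]$z_bottom
  z_hi <- infos[[length(infos)]]$z_top
  margin <- 2 * spacing
  origin <- c(-half_xy - margin[1], -half_xy - margin[2], z_lo - margin[3])
  dims <- ceiling((c(half_xy, half_xy, z_hi) - origin + margin) / spacing) + 1L

  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]

  lobe_inside_counts <- integer(spec$n_lobes)
  vol <- array(background_hu, dim = dims)
  r2grid <- outer(xs^2, ys^2, "+") # squared radius in the xy plane
  for (k in seq_len(spec$n_lobes)) {
    info <- infos[[k]]
    zsel <- which(zs >= info$z_bottom & zs <= info$z_top)
    if (!length(zsel)) {
      stop("spacing too coarse: a lobe contains no voxel centres",
           call. = FALSE)
    }
    cnt <- 0L
    for (iz in zsel) {
      rmax <- .lobe_radius_at(zs[iz], info, spec, geo)
      if (rmax <= 0) next
      ins <- if (spec$lobe_shape == "cube") {
        outer(abs(xs) <= rmax, abs(ys) <= rmax, "&")
      } else {
        r2grid <= rmax^2
      }
      newly <- ins & vol[, , iz] == background_hu
      vol[, , iz][newly] <- bone_hu
      cnt <- cnt + sum(ins)
    }
    lobe_inside_counts[k] <- cnt
    if (cnt == 0L)
      stop("spacing too coarse: a lobe contains no voxel centres",
           call. = FALSE)
  }
  out <- volume3d(vol, spacing = spacing, origin = origin)
  attr(out, "n_interior") <- sum(vol == bone_hu)
  out
}

# radius of the lobe cross-section at world height z (half-width for cubes)
.lobe_radius_at <- function(z, info, spec, geo) {
  if (spec$lobe_shape == "cube") return(spec$lobe_height / 2)
  cr <- spec$contact_radius
  A <- geo$A
  R_m <- geo$R_max
  b <- geo$b
  h <- spec$lobe_height
  h_b <- h / 2
  fshape <- function(u) u / ((1 - b) + b * u)
  zl <- z - info$z_bottom
  ht <- info$z_top - info$z_bottom
  bot_closed <- !info$has_bottom_contact
  top_closed <- !info$has_top_contact
  if (bot_closed && top_closed) { # sphere
    d <- zl - R_m
    v <- R_m^2 - d^2
    return(if (v > 0) sqrt(v) else 0)
  }
  if (bot_closed) { # cap then half barrel down to the top rim
    if (zl <= R_m) {
      v <- R_m^2 - (zl - R_m)^2
      return(if (v > 0) sqrt(v) else 0)
    }
    t <- 1 - (zl - R_m) / h_b
    return(cr + A * fshape(sin(pi * t / 2)))
  }
  if (top_closed) {
    if (zl >= h_b) {
      v <- R_m^2 - (zl - h_b)^2
      return(if (v > 0) sqrt(v) else 0)
    }
    t <- zl / h_b
    return(cr + A * fshape(sin(pi * t / 2)))
  }
  cr + A * fshape(sin(pi * zl / ht))
}
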