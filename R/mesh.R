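#' Triangle surface mesh
#'
#' Constructs the package's mesh container: an indexed triangle mesh in world
#' millimetres with per-face and per-vertex unit normals. On construction the
#' mesh is cleaned: duplicate vertices are welded (spatial hash at the
#' `weld_tolerance` grid, so exact duplicates -- e.g. the per-facet vertices
#' STL stores -- always merge) and zero-area faces are dropped. Vertices left
#' without any incident face keep a zero normal and are flagged
#' unsegmentable; they are retained so external per-vertex data stays aligned.
#'
#' @param vertices numeric matrix, n x 3, world coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param labels optional integer vector of per-vertex labels carried through
#'   cleanup (e.g. read from a PLY `label` property).
#' @param clean logical; weld duplicates and drop degenerate faces.
#' @param weld_tolerance vertex welding tolerance in mm.
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `vertex_normals`, `face_normals`, `face_areas`, `labels` (or `NULL`).
#' @export
tri_mesh <- function(vertices, faces, labels = NULL, clean = TRUE,
                     weld_tolerance = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (nrow(vertices) == 0L) stop("empty mesh: no vertices", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) && ncol(faces) != 3L)
    stop("`faces` must have 3 columns", call. = FALSE)
  if (length(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(vertices))
      stop("`labels` must have one entry per vertex", call. = FALSE)
  }

  if (clean) {
    key <- paste(round(vertices[, 1] / weld_tolerance),
                 round(vertices[, 2] / weld_tolerance),
                 round(vertices[, 3] / weld_tolerance))
    first <- !duplicated(key)
    remap <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[first]
    if (length(faces)) {
      faces <- matrix(remap[faces], ncol = 3L)
      # degenerate after welding: repeated indices or zero area
      distinct <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
        faces[, 1] != faces[, 3]
      faces <- faces[distinct, , drop = FALSE]
      if (nrow(faces)) {
        ar <- .face_areas(vertices, faces)
        faces <- faces[ar > 1e-12, , drop = FALSE]
      }
    }
  }

  mesh <- structure(
    list(vertices = vertices, faces = faces, labels = labels),
    class = "tri_mesh"
  )
  compute_vertex_normals(mesh)
}

.face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

.face_areas <- function(vertices, faces) {
  cr <- .face_cross(vertices, faces)
  0.5 * sqrt(rowSums(cr^2))
}

.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Recompute face and vertex normals
#'
#' Face normals follow the winding order (counter-clockwise seen from
#' outside); each vertex normal is the area-weighted mean of its incident
#' face normals, renormalised to unit length. Isolated vertices (no incident
#' face) get a zero normal and are reported by [unsegmentable_vertices()].
#'
#' @param mesh a [tri_mesh()].
#' @return the mesh with `face_normals`, `face_areas` and `vertex_normals`
#'   filled in.
#' @export
compute_vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (!length(f)) {
    mesh$face_normals <- matrix(numeric(0), 0, 3)
    mesh$face_areas <- numeric(0)
    mesh$vertex_normals <- matrix(0, n, 3)
    return(mesh)
  }
  cr <- .face_cross(v, f) # |cross| = 2 * area, direction = face normal
  area <- 0.5 * sqrt(rowSums(cr^2))
  fn <- .unit_rows(cr)
  vn <- matrix(0, n, 3)
  for (d in 1:3) {
    # area-weighted accumulation; cr is already area-weighted (x2)
    acc <- rowsum(c(cr[, d], cr[, d], cr[, d]),
                  group = c(f[, 1], f[, 2], f[, 3]))
    vn[as.integer(rownames(acc)), d] <- acc
  }
  mesh$face_normals <- fn
  mesh$face_areas <- area
  mesh$vertex_normals <- .unit_rows(vn)
  mesh
}

#' Vertices that cannot take part in region growing
#'
#' A vertex with no incident face has no defined normal (stored as the zero
#' vector) and is permanently unsegmentable.
#'
#' @param mesh a [tri_mesh()].
#' @return integer vector of vertex indices.
#' @export
unsegmentable_vertices <- function(mesh) {
  which(rowSums(mesh$vertex_normals^2) == 0)
}

#' Edge adjacency of a mesh
#'
#' `neighbors(u)` holds every vertex sharing an edge with `u`, sorted in
#' ascending index order (the determinism contract all traversals rely on).
#' Non-manifold edges are tolerated: all incident faces' vertices count as
#' neighbours.
#'
#' @param mesh a [tri_mesh()].
#' @return a list of length `n_vertices` of sorted integer vectors.
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  if (!length(f)) return(rep(list(integer(0)), n))
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  adj <- split(j, factor(i, levels = seq_len(n)))
  unname(lapply(adj, function(x) sort(unique(x))))
}

#' Angle between the vertex normals of two vertices
#'
#' The connectivity test of the region-growing algorithm: the arccosine of
#' the clamped dot product of the two unit vertex normals, in degrees within
#' [0, 180]. Vectorised over pairs.
#'
#' @param mesh a [tri_mesh()].
#' @param u,v vertex indices (recycled to a common length).
#' @return numeric vector of angles in degrees.
#' @export
normal_angle <- function(mesh, u, v) {
  vn <- mesh$vertex_normals
  nu <- vn[u, , drop = FALSE]
  nv <- vn[v, , drop = FALSE]
  if (any(rowSums(nu^2) == 0) || any(rowSums(nv^2) == 0))
    stop("unsegmentable vertex: zero normal", call. = FALSE)
  d <- pmin(1, pmax(-1, rowSums(nu * nv)))
  acos(d) * 180 / pi
}

# directed edge table (each undirected edge once, u < v) with face counts
.edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  first <- !duplicated(key)
  data.frame(u = e[first, 1], v = e[first, 2],
             count = as.integer(cnt[key[first]]))
}

#' Find boundary loops (holes) of a mesh
#'
#' A boundary edge is incident to exactly one face. Boundary edges are
#' chained into closed cycles; a watertight mesh returns an empty list.
#' Non-manifold edges (more than two incident faces) are reported via the
#' `non_manifold_edges` attribute and a warning, never an error.
#'
#' @param mesh a [tri_mesh()].
#' @return a list of integer vectors, each an ordered closed cycle of vertex
#'   indices, with attribute `non_manifold_edges` (two-column matrix).
#' @export
find_boundary_loops <- function(mesh) {
  et <- .edge_table(mesh)
  nm <- et[et$count > 2, c("u", "v"), drop = FALSE]
  if (nrow(nm))
    warning(sprintf("%d non-manifold edge(s) found", nrow(nm)), call. = FALSE)
  be <- et[et$count == 1, , drop = FALSE]
  loops <- list()
  if (nrow(be)) {
    # adjacency restricted to boundary edges
    nbr <- split(c(be$v, be$u), c(be$u, be$v))
    used <- new.env(parent = emptyenv())
    ekey <- function(a, b) paste(min(a, b), max(a, b))
    verts <- sort(unique(c(be$u, be$v)))
    for (start in verts) {
      nb <- nbr[[as.character(start)]]
      nb <- nb[!vapply(nb, function(x) isTRUE(used[[ekey(start, x)]]), TRUE)]
      while (length(nb)) {
        loop <- start
        prev <- start
        cur <- min(nb)
        used[[ekey(prev, cur)]] <- TRUE
        closed <- FALSE
        repeat {
          loop <- c(loop, cur)
          nxt <- nbr[[as.character(cur)]]
          nxt <- nxt[!vapply(nxt, function(x) isTRUE(used[[ekey(cur, x)]]), TRUE)]
          if (!length(nxt)) break
          prev <- cur
          cur <- min(nxt)
          used[[ekey(prev, cur)]] <- TRUE
          if (cur == start) {
            closed <- TRUE
            break
          }
        }
        if (closed) loops[[length(loops) + 1L]] <- loop
        nb <- nbr[[as.character(start)]]
        nb <- nb[!vapply(nb, function(x) isTRUE(used[[ekey(start, x)]]), TRUE)]
      }
    }
  }
  attr(loops, "non_manifold_edges") <- as.matrix(nm)
  loops
}

#' Edge-connected components of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return integer vector of component ids, one per vertex (isolated vertices
#'   get their own component).
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  if (!length(mesh$faces)) return(seq_len(n))
  g <- igraph::graph_from_edgelist(
    rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)]),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum over faces; positive when normals (winding) point
#' outward. Meaningful for closed surfaces only.
#'
#' @param mesh a [tri_mesh()].
#' @return scalar volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$labels)) sprintf(", %d labels",
                                              length(unique(x$labels)))
              else ""))
  invisible(x)
}
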