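#' Fresh label state for a mesh
#'
#' Per-vertex segment assignment (0 = unassigned) plus the pass history that
#' makes [undo_last_pass()] possible. Every region-growing pass appends one
#' entry to `pass_log` recording the threshold used, the vertices newly
#' labelled in that pass, and any seeds added just before it; replaying the
#' log reproduces the current labels exactly.
#'
#' @param mesh a [tri_mesh()].
#' @return an object of class `label_state`.
#' @export
new_label_state <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  structure(
    list(labels = integer(nrow(mesh$vertices)), pass_log = list()),
    class = "label_state"
  )
}

#' Snap raw seed points to mesh vertices
#'
#' Each seed (a world-coordinate point with a positive segment label) is
#' snapped to its nearest mesh vertex; exact distance ties break to the
#' lowest vertex index. Two seeds may not snap to the same vertex with
#' different labels.
#'
#' @param mesh a [tri_mesh()].
#' @param seeds data frame with columns `x`, `y`, `z`, `label`.
#' @return a tibble with columns `x`, `y`, `z`, `label`, `vertex`.
#' @export
snap_seeds <- function(mesh, seeds) {
  stopifnot(inherits(mesh, "tri_mesh"))
  seeds <- tibble::as_tibble(seeds)
  req <- c("x", "y", "z", "label")
  if (!all(req %in% names(seeds)))
    stop("seeds need columns x, y, z, label", call. = FALSE)
  if (nrow(seeds) == 0L)
    stop("at least one seed point is required", call. = FALSE)
  if (any(seeds$label < 1))
    stop("segment labels must be >= 1", call. = FALSE)
  v <- mesh$vertices
  snapped <- vapply(seq_len(nrow(seeds)), function(i) {
    d2 <- (v[, 1] - seeds$x[i])^2 + (v[, 2] - seeds$y[i])^2 +
      (v[, 3] - seeds$z[i])^2
    which.min(d2) # first minimum = lowest index on ties
  }, integer(1))
  seeds$vertex <- snapped
  seeds$label <- as.integer(seeds$label)
  conflicts <- stats::aggregate(label ~ vertex, data = seeds,
                                FUN = function(x) length(unique(x)))
  bad <- conflicts$vertex[conflicts$label > 1]
  if (length(bad)) {
    culprits <- which(seeds$vertex == bad[1])
    stop(sprintf(
      "seeds %s snap to the same vertex %d with different labels",
      paste(culprits, collapse = " and "), bad[1]), call. = FALSE)
  }
  seeds
}

# adjacency + per-edge normal angles, computed once per mesh
.grow_context <- function(mesh, adjacency = NULL) {
  adj <- if (is.null(adjacency)) vertex_adjacency(mesh) else adjacency
  n <- nrow(mesh$vertices)
  us <- rep(seq_len(n), lengths(adj))
  vs <- unlist(adj, use.names = FALSE)
  vn <- mesh$vertex_normals
  ang <- rep(NA_real_, length(us))
  if (length(us)) {
    nu <- vn[us, , drop = FALSE]
    nv <- vn[vs, , drop = FALSE]
    ok <- rowSums(nu^2) > 0 & rowSums(nv^2) > 0
    d <- pmin(1, pmax(-1, rowSums(nu * nv)))
    ang[ok] <- acos(d[ok]) * 180 / pi
  }
  list(adj = adj,
       ang = unname(split(ang, factor(us, levels = seq_len(n)))))
}

#' One region-growing pass at a fixed connectivity threshold
#'
#' Breadth-first traversal in strict FIFO order. The frontier is enqueued
#' sorted by vertex index; a dequeued vertex's unlabelled neighbours are
#' visited in ascending index order and each is labelled with the current
#' vertex's region and enqueued iff the angle between the two vertex normals
#' is at most `theta` degrees. A pass never overwrites an existing label;
#' when two regions race for the same vertex within a pass, FIFO order
#' decides. The newly labelled set is appended to the pass log.
#'
#' @param mesh a [tri_mesh()].
#' @param state a [new_label_state()] (frontier vertices must be labelled).
#' @param frontier integer vertex indices to grow from.
#' @param theta connectivity threshold angle in degrees, in [0, 180].
#' @param context optional precomputed adjacency/angle context (internal
#'   reuse across passes).
#' @param seeds_added optional snapped-seed tibble recorded in the log entry.
#' @return the extended `label_state`.
#' @export
region_grow_pass <- function(mesh, state, frontier, theta, context = NULL,
                             seeds_added = NULL) {
  stopifnot(inherits(state, "label_state"))
  if (theta < 0 || theta > 180) stop("theta must be in [0, 180]", call. = FALSE)
  labels <- state$labels
  frontier <- sort(unique(as.integer(frontier)))
  if (length(frontier) && any(labels[frontier] == 0L))
    stop("all frontier vertices must be labelled", call. = FALSE)
  ctx <- if (is.null(context)) .grow_context(mesh) else context
  adj <- ctx$adj
  ang <- ctx$ang

  n <- length(labels)
  queue <- integer(n)
  nq <- length(frontier)
  queue[seq_len(nq)] <- frontier
  head <- 1L
  newly <- integer(0)
  while (head <= nq) {
    u <- queue[head]
    head <- head + 1L
    nb <- adj[[u]]
    if (!length(nb)) next
    a <- ang[[u]]
    take <- labels[nb] == 0L & !is.na(a) & a <= theta
    if (any(take)) {
      vs <- nb[take] # ascending by construction
      labels[vs] <- labels[u]
      newly <- c(newly, vs)
      if (nq + length(vs) > length(queue))
        queue <- c(queue, integer(n))
      queue[nq + seq_along(vs)] <- vs
      nq <- nq + length(vs)
    }
  }
  state$labels <- labels
  state$pass_log[[length(state$pass_log) + 1L]] <- list(
    theta = theta,
    labeled = newly,
    labels_assigned = labels[newly],
    seed_vertices = if (is.null(seeds_added)) integer(0) else seeds_added$vertex,
    seed_labels = if (is.null(seeds_added)) integer(0) else seeds_added$label
  )
  state
}

#' Undo the last region-growing pass
#'
#' All vertices labelled in the last pass (including seeds added immediately
#' before it) revert to unassigned and the log entry is removed. On an empty
#' log this is a no-op with a warning.
#'
#' @param state a `label_state`.
#' @return the reverted `label_state`.
#' @export
undo_last_pass <- function(state) {
  stopifnot(inherits(state, "label_state"))
  np <- length(state$pass_log)
  if (np == 0L) {
    warning("nothing to undo: pass log is empty", call. = FALSE)
    return(state)
  }
  entry <- state$pass_log[[np]]
  state$labels[entry$labeled] <- 0L
  state$labels[entry$seed_vertices] <- 0L
  state$pass_log[[np]] <- NULL
  state
}

#' Replay a pass log from scratch
#'
#' Rebuilds the per-vertex labels implied by the recorded pass history;
#' `replay_log(state)` always equals `state$labels` (the undo-stack
#' invariant).
#'
#' @param state a `label_state`.
#' @return integer vector of per-vertex labels.
#' @export
replay_log <- function(state) {
  labels <- integer(length(state$labels))
  for (entry in state$pass_log) {
    labels[entry$seed_vertices] <- entry$seed_labels
    labels[entry$labeled] <- entry$labels_assigned
  }
  labels
}

.apply_seeds <- function(state, seeds) {
  cur <- state$labels[seeds$vertex]
  bad <- cur != 0L & cur != seeds$label
  if (any(bad))
    stop(sprintf("seed on vertex %d conflicts with existing label %d",
                 seeds$vertex[bad][1], cur[bad][1]), call. = FALSE)
  state$labels[seeds$vertex] <- seeds$label
  state
}

#' Iterative seed-point surface segmentation
#'
#' The full semi-automatic procedure: seeds are snapped to the mesh and grown
#' at the initial connectivity threshold; the threshold is then raised by
#' `theta_step` degrees and growth resumes from the current region
#' boundaries, repeating until every segmentable vertex is labelled or the
#' ceiling `theta_max` would be exceeded. The default schedule (5, 5, 60)
#' starts at 5 degrees and raises by 5 degrees per pass. Between passes an
#' optional `hook` (called as `hook(state, theta)`) may request an undo of
#' the last pass and/or add seed points, mirroring interactive use; the
#' non-interactive default just runs the schedule.
#'
#' @param mesh a [tri_mesh()].
#' @param seeds data frame with columns `x`, `y`, `z`, `label` (snapped via
#'   [snap_seeds()] if it lacks a `vertex` column).
#' @param theta_init,theta_step,theta_max threshold schedule in degrees;
#'   `0 <= theta_init <= theta_max <= 180`, `theta_step > 0`.
#' @param hook optional callback; may return a list with elements `undo`
#'   (logical) and/or `seeds` (data frame of raw seeds). After an undo the
#'   same threshold is retried.
#' @param verbose emit one log line per pass (theta, newly labelled count,
#'   remaining count).
#' @return a `label_state`; if unlabelled segmentable vertices remain at the
#'   ceiling, a warning reports their count.
#' @export
iterative_segment <- function(mesh, seeds, theta_init = 5, theta_step = 5,
                              theta_max = 60, hook = NULL, verbose = FALSE) {
  if (!(theta_init >= 0 && theta_init <= theta_max && theta_max <= 180))
    stop("need 0 <= theta_init <= theta_max <= 180", call. = FALSE)
  if (theta_step <= 0) stop("theta_step must be > 0", call. = FALSE)
  if (!"vertex" %in% names(as.data.frame(seeds))) {
    seeds <- snap_seeds(mesh, seeds)
  } else {
    seeds <- tibble::as_tibble(seeds)
  }
  ctx <- .grow_context(mesh)
  segmentable <- rowSums(mesh$vertex_normals^2) > 0
  state <- new_label_state(mesh)
  state <- .apply_seeds(state, seeds)
  pending_seeds <- seeds
  theta <- theta_init
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10000L) stop("iterative_segment: too many passes", call. = FALSE)
    frontier <- .frontier_vertices(state$labels, ctx$adj)
    state <- region_grow_pass(mesh, state, frontier, theta, context = ctx,
                              seeds_added = pending_seeds)
    pending_seeds <- NULL
    remaining <- sum(segmentable & state$labels == 0L)
    if (verbose) {
      last <- state$pass_log[[length(state$pass_log)]]
      message(sprintf("pass %d: theta=%g newly_labeled=%d remaining=%d",
                      length(state$pass_log), theta, length(last$labeled),
                      remaining))
    }
    if (remaining == 0L) break
    advance <- TRUE
    if (!is.null(hook)) {
      req <- hook(state, theta)
      if (!is.null(req)) {
        if (isTRUE(req$undo)) {
          state <- undo_last_pass(state)
          advance <- FALSE # retry the same threshold after user intervention
        }
        if (!is.null(req$seeds)) {
          s <- req$seeds
          if (!"vertex" %in% names(as.data.frame(s))) s <- snap_seeds(mesh, s)
          state <- .apply_seeds(state, s)
          pending_seeds <- s
        }
      }
    }
    if (advance) {
      theta <- theta + theta_step
      if (theta > theta_max) {
        warning(sprintf(
          "%d segmentable vertices remain unlabelled at theta_max = %g",
          remaining, theta_max), call. = FALSE)
        break
      }
    }
  }
  state
}

# labelled vertices with at least one unlabelled neighbour
.frontier_vertices <- function(labels, adj) {
  lab <- which(labels != 0L)
  lab[vapply(adj[lab], function(nb) any(labels[nb] == 0L), logical(1))]
}

#' Extract the submesh of one segment label
#'
#' Keeps the faces whose three vertices all carry `label` and reindexes the
#' vertices; faces spanning labels or touching unlabelled vertices are
#' dropped.
#'
#' @param mesh a [tri_mesh()].
#' @param labels per-vertex integer labels (or a `label_state`).
#' @param label the segment to extract.
#' @return a [tri_mesh()], or `NULL` if the label has no whole face.
#' @export
label_submesh <- function(mesh, labels, label) {
  if (inherits(labels, "label_state")) labels <- labels$labels
  f <- mesh$faces
  keep <- labels[f[, 1]] == label & labels[f[, 2]] == label &
    labels[f[, 3]] == label
  if (!any(keep)) return(NULL)
  fk <- f[keep, , drop = FALSE]
  used <- sort(unique(as.vector(fk)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[fk], ncol = 3), clean = FALSE)
}

#' Export one mesh file per segment label
#'
#' Segments are written exactly as the algorithm produced them (holes
#' included, no repair). Faces spanning two labels or touching unlabelled
#' vertices belong to no segment; their count is reported.
#'
#' @param mesh a [tri_mesh()].
#' @param state a `label_state` (or a per-vertex label vector).
#' @param out_dir output directory (created if missing).
#' @param format `"ply"` (default; carries the label) or `"stl"`/`"obj"`.
#' @param prefix file name prefix.
#' @return a tibble with columns `label`, `n_vertices`, `n_faces`, `path`,
#'   with attribute `n_spanning_faces`.
#' @export
export_segments <- function(mesh, state, out_dir, format = "ply",
                            prefix = "segment") {
  labels <- if (inherits(state, "label_state")) state$labels else state
  if (all(labels == 0L))
    stop("no labelled vertices to export", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- mesh$faces
  whole <- labels[f[, 1]] != 0L & labels[f[, 1]] == labels[f[, 2]] &
    labels[f[, 2]] == labels[f[, 3]]
  n_spanning <- sum(!whole)
  out <- list()
  for (lab in sort(unique(labels[labels > 0L]))) {
    sub <- label_submesh(mesh, labels, lab)
    if (is.null(sub)) {
      warning(sprintf("label %d has no whole face; skipped", lab),
              call. = FALSE)
      next
    }
    path <- file.path(out_dir, sprintf("%s_%03d.%s", prefix, lab, format))
    write_mesh(sub, path,
               labels = if (format == "ply")
                 rep(lab, nrow(sub$vertices)) else NULL)
    out[[length(out) + 1L]] <- tibble::tibble(
      label = lab, n_vertices = nrow(sub$vertices),
      n_faces = nrow(sub$faces), path = path
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_spanning_faces") <- n_spanning
  res
}

#' @export
print.label_state <- function(x, ...) {
  cat(sprintf(
    "<label_state> %d vertices, %d labelled (%d labels), %d passes\n",
    length(x$labels), sum(x$labels != 0L),
    length(unique(x$labels[x$labels > 0L])), length(x$pass_log)))
  invisible(x)
}

#' Tidy a label state into a per-vertex tibble
#'
#' @param x a `label_state`.
#' @param ... unused.
#' @return a tibble with columns `vertex` and `label` (0 = unassigned).
#' @export
tidy.label_state <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$labels), label = x$labels)
}

#' One-row summary of a label state
#'
#' @param x a `label_state`.
#' @param ... unused.
#' @return a tibble with vertex/label/pass counts and the last threshold.
#' @export
glance.label_state <- function(x, ...) {
  tibble::tibble(
    n_vertices = length(x$labels),
    n_labeled = sum(x$labels != 0L),
    n_unlabeled = sum(x$labels == 0L),
    n_labels = length(unique(x$labels[x$labels > 0L])),
    n_passes = length(x$pass_log),
    theta_final = if (length(x$pass_log))
      x$pass_log[[length(x$pass_log)]]$theta else NA_real_
  )
}
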