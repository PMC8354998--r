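# Independent oracles, deliberately written as plain scalar R so they share
# no code path with the package implementation.

# exact point-to-triangle distance by enumerating the seven candidate
# minimisers: the plane projection, the three clamped edge projections and
# the three vertices
oracle_point_tri <- function(p, a, b, c) {
  cand <- list(a, b, c)
  edge_pt <- function(q0, q1) {
    e <- q1 - q0
    t <- sum((p - q0) * e) / sum(e * e)
    q0 + min(1, max(0, t)) * e
  }
  cand <- c(cand, list(edge_pt(a, b), edge_pt(b, c), edge_pt(c, a)))
  n <- pracma_cross(b - a, c - a)
  nn <- sum(n * n)
  if (nn > 0) {
    # barycentric coordinates of the in-plane projection
    q <- p - n * sum((p - a) * n) / nn
    w <- bary_coords(q, a, b, c)
    if (all(w >= 0)) cand <- c(cand, list(q))
  }
  d <- vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1))
  min(d)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

bary_coords <- function(q, a, b, c) {
  m <- cbind(b - a, c - a)
  ab <- crossprod(m)
  rhs <- crossprod(m, q - a)
  uv <- solve(ab, rhs)
  c(1 - sum(uv), uv)
}

# exhaustive scan over all triangles, scalar loop
oracle_closest_mesh <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1, function(p) {
    best <- Inf
    for (t in seq_len(nrow(f))) {
      d <- oracle_point_tri(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
      if (d < best) best <- d
    }
    best
  })
}

# order-independent reachability closure: vertices connected to the seed by a
# path whose consecutive vertex-normal angles all stay within theta
oracle_reachable <- function(mesh, seed_vertex, theta) {
  adj <- vertex_adjacency(mesh)
  vn <- mesh$vertex_normals
  ang <- function(u, v) {
    if (sum(vn[u, ]^2) == 0 || sum(vn[v, ]^2) == 0) return(Inf)
    acos(min(1, max(-1, sum(vn[u, ] * vn[v, ])))) * 180 / pi
  }
  inset <- rep(FALSE, nrow(mesh$vertices))
  inset[seed_vertex] <- TRUE
  repeat {
    changed <- FALSE
    for (u in which(inset)) {
      for (v in adj[[u]]) {
        if (!inset[v] && ang(u, v) <= theta) {
          inset[v] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  which(inset)
}

# naive FIFO transcription of the growing pass, list-based queue
oracle_grow_fifo <- function(mesh, labels, frontier, theta) {
  adj <- vertex_adjacency(mesh)
  vn <- mesh$vertex_normals
  queue <- as.list(sort(unique(frontier)))
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    for (v in adj[[u]]) { # ascending order
      if (labels[v] != 0L) next
      if (sum(vn[u, ]^2) == 0 || sum(vn[v, ]^2) == 0) next
      a <- acos(min(1, max(-1, sum(vn[u, ] * vn[v, ])))) * 180 / pi
      if (a <= theta) {
        labels[v] <- labels[u]
        queue[[length(queue) + 1L]] <- v
      }
    }
  }
  labels
}

# ICC(2,1) through stats::aov sums of squares
oracle_icc_aov <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  rn <- trimws(rownames(av))
  msr <- av[rn == "subj", "Mean Sq"]
  msc <- av[rn == "rater", "Mean Sq"]
  mse <- av[rn == "Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

shrout_fleiss_ratings <- function() {
  matrix(c(9, 2, 5, 8,
           6, 1, 3, 2,
           8, 4, 6, 8,
           7, 1, 2, 6,
           10, 5, 6, 9,
           6, 2, 4, 7), ncol = 4, byrow = TRUE)
}
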