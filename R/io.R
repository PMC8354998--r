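#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supported formats: STL (ASCII and binary little-endian), PLY (ASCII 1.0,
#' with an optional per-vertex integer `label` property which is preserved on
#' the returned mesh), and Wavefront OBJ (polygonal faces are fan
#' triangulated). The mesh is cleaned on ingestion: duplicate vertices welded
#' within 1e-6 mm (STL stores per-facet vertices, so welding is what makes
#' adjacency meaningful) and degenerate faces dropped.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"stl"`, `"ply"`, `"obj"`; `"auto"` picks by
#'   file extension.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      stl = "stl", ply = "ply", obj = "obj",
      stop("cannot infer mesh format from extension of ", path, call. = FALSE)
    )
  }
  switch(format,
    stl = .read_stl(path),
    ply = .read_ply(path),
    obj = .read_obj(path)
  )
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' PLY output carries per-vertex integer labels (either `labels` or the
#' mesh's own `labels` field) as a `label` property; STL and OBJ cannot store
#' labels. Binary STL is little-endian.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"stl"`, `"ply"` or `"obj"`.
#' @param labels optional per-vertex integer labels (PLY only).
#' @param binary logical, write binary STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       labels = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      stl = "stl", ply = "ply", obj = "obj",
      stop("cannot infer mesh format from extension of ", path, call. = FALSE)
    )
  }
  if (is.null(labels)) labels <- mesh$labels
  switch(format,
    stl = if (binary) .write_stl_binary(mesh, path) else .write_stl_ascii(mesh, path),
    ply = .write_ply(mesh, path, labels),
    obj = .write_obj(mesh, path)
  )
  invisible(path)
}

# ---- STL ----

.read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 5L)
  close(con)
  if (identical(rawToChar(head), "solid")) {
    m <- tryCatch(.read_stl_ascii(path), error = function(e) NULL)
    if (!is.null(m)) return(m)
    # some binary files also start with "solid"
  }
  .read_stl_binary(path)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices in ASCII STL ", path, call. = FALSE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  if (anyNA(v) || nrow(v) %% 3L != 0L)
    stop("malformed ASCII STL ", path, call. = FALSE)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  tri_mesh(v, f)
}

.read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", size = 4L, endian = "little")
  if (is.na(ntri) || ntri < 0L || 84 + 50 * as.numeric(ntri) > sz)
    stop("malformed binary STL ", path, call. = FALSE)
  if (ntri == 0L) stop("empty mesh in ", path, call. = FALSE)
  recs <- readBin(con, "raw", n = 50L * ntri)
  recs <- matrix(recs, nrow = 50L)
  vbytes <- recs[13:48, , drop = FALSE] # 9 floats per facet, normals skipped
  v <- matrix(readBin(as.raw(vbytes), "numeric", size = 4L, n = 9L * ntri,
                      endian = "little"),
              ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  tri_mesh(v, f)
}

.write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- mesh$face_normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vertseg", con)
  if (nrow(f)) {
    tri <- function(i) {
      c(sprintf("facet normal %.17g %.17g %.17g", fn[i, 1], fn[i, 2], fn[i, 3]),
        "  outer loop",
        sprintf("    vertex %.17g %.17g %.17g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "  endloop", "endfacet")
    }
    writeLines(unlist(lapply(seq_len(nrow(f)), tri)), con)
  }
  writeLines("endsolid vertseg", con)
}

.write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- mesh$face_normals
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(c(fn[i, ], t(v[f[i, ], , drop = FALSE])), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

# ---- PLY (ASCII) ----

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("PLY header not terminated in ", path, call. = FALSE)
  header <- trimws(lines[seq_len(hend)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)

  nv <- nf <- 0L
  vprops <- character(0)
  elem <- ""
  for (ln in header) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      elem <- tok[2]
      if (elem == "vertex") nv <- as.integer(tok[3])
      if (elem == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && elem == "vertex" && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  if (nv == 0L) stop("empty mesh in ", path, call. = FALSE)
  body <- lines[(hend + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  v <- vdat[, c("x", "y", "z"), drop = FALSE]
  labels <- if ("label" %in% colnames(vdat)) as.integer(vdat[, "label"]) else NULL
  f <- NULL
  if (nf > 0L) {
    flines <- body[nv + seq_len(nf)]
    fl <- strsplit(trimws(flines), "\\s+")
    f <- do.call(rbind, lapply(fl, function(x) {
      n <- as.integer(x[1])
      idx <- as.integer(x[2:(1 + n)]) + 1L # PLY is 0-based
      if (n == 3L) idx else t(vapply(2:(n - 1L),
                                     function(k) idx[c(1L, k, k + 1L)],
                                     integer(3)))
    }))
  }
  if (is.null(f)) f <- matrix(integer(0), 0, 3)
  tri_mesh(v, f, labels = labels)
}

.write_ply <- function(mesh, path, labels = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z")
  if (!is.null(labels)) hdr <- c(hdr, "property int label")
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(labels)) {
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g %d", v[, 1], v[, 2], v[, 3],
                       as.integer(labels)), con)
  }
  if (nrow(f))
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
}

# ---- OBJ ----

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl)) stop("no vertices in OBJ ", path, call. = FALSE)
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- NULL
  if (length(fl)) {
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
      idx <- as.integer(vapply(strsplit(x[-1], "/"), `[`, "", 1L))
      idx[idx < 0] <- nrow(v) + 1L + idx[idx < 0]
      n <- length(idx)
      if (n == 3L) idx else t(vapply(2:(n - 1L),
                                     function(k) idx[c(1L, k, k + 1L)],
                                     integer(3)))
    }))
  }
  if (is.null(f)) f <- matrix(integer(0), 0, 3)
  tri_mesh(v, f)
}

.write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f)) writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
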