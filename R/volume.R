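#' CT-like scalar volume
#'
#' A 3D scalar array of Hounsfield-unit-like intensities together with an
#' invertible affine mapping 0-based voxel indices to world millimetres.
#'
#' @param data numeric 3D array.
#' @param spacing voxel spacing in mm (length 3, strictly positive); ignored
#'   when `affine` is given.
#' @param origin world position of voxel (0,0,0); ignored when `affine` is
#'   given.
#' @param affine optional full 4x4 voxel-to-world matrix.
#' @return an object of class `volume3d` with elements `data` and `affine`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     affine = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (is.null(affine)) {
    if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  if (any(sqrt(colSums(affine[1:3, 1:3]^2)) <= 0))
    stop("spacing must be strictly positive on all axes", call. = FALSE)
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  sp <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<volume3d> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(sp, 4), collapse = " x ")))
  invisible(x)
}

.vox_to_world <- function(vox0, affine) {
  # vox0: n x 3 matrix of 0-based voxel coordinates
  sweep(vox0 %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

#' Read a volume from NIfTI or NRRD
#'
#' NIfTI (`.nii`, `.nii.gz`) goes through RNifti; NRRD (`.nrrd`) through a
#' minimal built-in reader (attached data, `raw`/`gzip`/`ascii`/`text`
#' encodings, 3D only).
#'
#' @param path file path.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    volume3d(array(as.numeric(img), dim = dim(img)),
             affine = unclass(RNifti::xform(img)))
  } else if (grepl("\\.nrrd$", lower)) {
    .read_nrrd(path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
}

#' Write a volume to NIfTI
#'
#' @param volume a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not a NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("NRRD header not terminated", call. = FALSE)
    if (!nzchar(ln)) break
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) stop("only 3D NRRD supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(sizes)
  rtype <- switch(type,
    "signed char" = , "int8" = , "int8_t" = list("integer", 1L, TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = list("integer", 1L, FALSE),
    "short" = , "signed short" = , "int16" = , "int16_t" = list("integer", 2L, TRUE),
    "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" = list("integer", 2L, FALSE),
    "int" = , "signed int" = , "int32" = , "int32_t" = list("integer", 4L, TRUE),
    "float" = list("numeric", 4L, TRUE),
    "double" = list("numeric", 8L, TRUE),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
  endian <- if (!is.null(fields[["endian"]]) &&
                fields[["endian"]] == "big") "big" else "little"
  vals <- switch(enc,
    raw = readBin(con, rtype[[1]], n = n, size = rtype[[2]],
                  signed = rtype[[3]], endian = endian),
    gzip = , gz = {
      comp <- readBin(con, "raw", n = file.info(path)$size)
      readBin(memDecompress(comp, type = "gzip"), rtype[[1]], n = n,
              size = rtype[[2]], signed = rtype[[3]], endian = endian)
    },
    ascii = , text = , txt = as.numeric(scan(con, what = double(), n = n,
                                             quiet = TRUE)),
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  )
  aff <- diag(4)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- vapply(vecs, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    }, numeric(3))
    aff[1:3, 1:3] <- dirs # columns = per-axis direction vectors
  } else if (!is.null(fields[["spacings"]])) {
    diag(aff)[1:3] <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]])) {
    aff[1:3, 4] <- as.numeric(strsplit(gsub("[()]", "",
                                            fields[["space origin"]]),
                                       ",")[[1]])
  }
  volume3d(array(as.numeric(vals), dim = sizes), affine = aff)
}

#' Global intensity thresholding
#'
#' The standard bone-preset front end: a binary mask of voxels whose
#' intensity is at or above the Hounsfield threshold.
#'
#' @param volume a [volume3d()].
#' @param hu_threshold finite scalar threshold (default 226, a common CT bone
#'   preset).
#' @return a [volume3d()] of 0/1 values with the same shape and affine.
#' @export
threshold_volume <- function(volume, hu_threshold = 226) {
  stopifnot(inherits(volume, "volume3d"))
  if (!is.finite(hu_threshold)) stop("threshold must be finite", call. = FALSE)
  mask <- array(as.integer(volume$data >= hu_threshold), dim = dim(volume$data))
  volume3d(mask, affine = volume$affine)
}

# Tetrahedral decomposition of the unit cube around its main diagonal.
# Corner order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1)
.mt_corners <- matrix(c(
  0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
  0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1
), ncol = 3, byrow = TRUE)

.mt_tets <- matrix(c(
  1, 2, 3, 7,
  1, 3, 4, 7,
  1, 4, 8, 7,
  1, 8, 5, 7,
  1, 5, 6, 7,
  1, 6, 2, 7
), ncol = 4, byrow = TRUE)

.mt_edges <- matrix(c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4), ncol = 2,
                    byrow = TRUE)

# triangles (as triples of tet-edge ids 1..6) per inside-bitmask case 1..14
.mt_cases <- list(
  `1` = list(c(1, 2, 3)),
  `2` = list(c(1, 4, 5)),
  `3` = list(c(2, 4, 5), c(2, 5, 3)),
  `4` = list(c(2, 4, 6)),
  `5` = list(c(1, 4, 6), c(1, 6, 3)),
  `6` = list(c(1, 2, 6), c(1, 6, 5)),
  `7` = list(c(3, 5, 6)),
  `8` = list(c(3, 5, 6)),
  `9` = list(c(1, 2, 6), c(1, 6, 5)),
  `10` = list(c(1, 4, 6), c(1, 6, 3)),
  `11` = list(c(2, 4, 6)),
  `12` = list(c(2, 4, 5), c(2, 5, 3)),
  `13` = list(c(1, 4, 5)),
  `14` = list(c(1, 2, 3))
)

#' Extract an iso-surface as a triangle mesh
#'
#' Triangulates the iso-surface of a scalar volume at the given threshold
#' (marching tetrahedra: every cell is split into six tetrahedra around its
#' main diagonal, with linear interpolation along crossing edges). The
#' decomposition is conforming across cells, so a supra-threshold region that
#' does not touch the array border yields a watertight surface. Vertices are
#' mapped to world mm through the volume affine and all face normals are
#' oriented outward, away from the supra-threshold region.
#'
#' @param volume a [volume3d()].
#' @param hu_threshold iso value, strictly between the volume minimum and
#'   maximum.
#' @return a [tri_mesh()].
#' @export
extract_surface <- function(volume, hu_threshold = 226) {
  stopifnot(inherits(volume, "volume3d"))
  dat <- volume$data
  rng <- range(dat)
  if (!(hu_threshold > rng[1] && hu_threshold <= rng[2]))
    stop(sprintf("empty iso-surface: threshold %g outside data range [%g, %g]",
                 hu_threshold, rng[1], rng[2]), call. = FALSE)
  dm <- dim(dat)
  inside <- dat >= hu_threshold

  # active cells: corner insides disagree
  cs <- function(di, dj, dk) {
    inside[(1 + di):(dm[1] - 1 + di), (1 + dj):(dm[2] - 1 + dj),
           (1 + dk):(dm[3] - 1 + dk), drop = FALSE]
  }
  s <- cs(0, 0, 0) + cs(1, 0, 0) + cs(1, 1, 0) + cs(0, 1, 0) +
    cs(0, 0, 1) + cs(1, 0, 1) + cs(1, 1, 1) + cs(0, 1, 1)
  act <- which(s > 0L & s < 8L)
  if (!length(act))
    stop(sprintf("empty iso-surface at threshold %g", hu_threshold),
         call. = FALSE)
  cdm <- dm - 1L
  A <- arrayInd(act, cdm) # 1-based cell origin voxel coords

  n1 <- dm[1]
  n12 <- dm[1] * dm[2]
  lin <- function(coord) coord[, 1] + (coord[, 2] - 1L) * n1 +
    (coord[, 3] - 1L) * n12

  tris <- vector("list", 6 * 14)
  ti <- 0L
  for (tt in seq_len(6)) {
    cids <- .mt_tets[tt, ]
    # per active cell: values and world coords of the 4 tet corners
    li <- lapply(1:4, function(q) {
      lin(sweep(A, 2, .mt_corners[cids[q], ], "+"))
    })
    vals <- vapply(li, function(ix) dat[ix], numeric(nrow(A)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    ins <- vals >= hu_threshold
    case <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    wc <- lapply(1:4, function(q) {
      vox0 <- sweep(A - 1L, 2, .mt_corners[cids[q], ], "+")
      .vox_to_world(vox0, volume$affine)
    })
    for (cs_id in 1:14) {
      rows <- which(case == cs_id)
      if (!length(rows)) next
      # inside-corner centroid, for orientation
      insR <- ins[rows, , drop = FALSE]
      ctr <- matrix(0, length(rows), 3)
      for (q in 1:4) ctr <- ctr + wc[[q]][rows, , drop = FALSE] * insR[, q]
      ctr <- ctr / rowSums(insR)
      edge_pt <- function(eid) {
        a <- .mt_edges[eid, 1]
        b <- .mt_edges[eid, 2]
        va <- vals[rows, a]
        vb <- vals[rows, b]
        t <- (hu_threshold - va) / (vb - va)
        wc[[a]][rows, , drop = FALSE] +
          (wc[[b]][rows, , drop = FALSE] - wc[[a]][rows, , drop = FALSE]) * t
      }
      for (tr in .mt_cases[[as.character(cs_id)]]) {
        p1 <- edge_pt(tr[1])
        p2 <- edge_pt(tr[2])
        p3 <- edge_pt(tr[3])
        e1 <- p2 - p1
        e2 <- p3 - p1
        nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                     e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                     e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
        toward_inside <- rowSums(nrm * (ctr - (p1 + p2 + p3) / 3)) > 0
        if (any(toward_inside)) { # flip so normals point away from inside
          tmp <- p2[toward_inside, , drop = FALSE]
          p2[toward_inside, ] <- p3[toward_inside, , drop = FALSE]
          p3[toward_inside, ] <- tmp
        }
        ti <- ti + 1L
        tris[[ti]] <- cbind(p1, p2, p3)
      }
    }
  }
  tris <- tris[seq_len(ti)]
  soup <- do.call(rbind, tris) # n x 9: p1 p2 p3 per row
  nv <- nrow(soup)
  verts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE],
                 soup[, 7:9, drop = FALSE])
  faces <- cbind(seq_len(nv), seq_len(nv) + nv, seq_len(nv) + 2L * nv)
  tri_mesh(verts, faces)
}
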