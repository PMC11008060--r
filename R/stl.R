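# STL (stereolithography / Surface Tessellation Language) input and output,
# binary and ASCII. STL carries no connectivity, so reading welds coincident
# vertices (1e-6 mm grid) and drops degenerate and duplicate facets.

#' Read an STL file
#'
#' Detects binary vs ASCII automatically. Duplicate vertices within 1e-6 mm
#' are merged, degenerate (area < 1e-12 mm^2) and duplicate faces dropped;
#' the counts are reported via [message()].
#'
#' @param path path to a `.stl` file.
#' @param quiet suppress the cleanup message.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) stop("format error in '", path, "': file too short (",
                      size, " bytes) to be STL")
  head_raw <- readBin(path, "raw", n = min(size, 512))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)][1:min(80, size)])
  is_ascii <- grepl("^\\s*solid", head_txt) &&
    grepl("facet", rawToChar(head_raw[head_raw <= as.raw(127) & head_raw != as.raw(0)]))
  mesh <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  merged <- merge_vertices(mesh, tol = 1e-6)
  if (!quiet) {
    mv <- attr(merged, "merged_vertices") %||% 0L
    df <- attr(merged, "dropped_faces") %||% 0L
    if (mv > 0L || df > 0L)
      message(sprintf("read_stl('%s'): merged %d duplicate vertices, dropped %d faces",
                      basename(path), mv, df))
  }
  merged$name <- sub("\\.stl$", "", basename(path), ignore.case = TRUE)
  merged
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(n) || n <= 0)
    stop("format error in '", path, "': invalid facet count at byte 80")
  expected <- 84 + 50 * as.numeric(n)
  if (size < expected)
    stop("format error in '", path, "': truncated binary STL (",
         size, " bytes, expected ", expected, ")")
  r <- readBin(con, "raw", 50 * n)
  # facet record: 12 float32 (normal + 3 vertices) + uint16 attribute
  idx <- as.vector(outer(1:48, (seq_len(n) - 1) * 50, "+"))
  fl <- readBin(r[idx], "numeric", size = 4, n = 12 * n, endian = "little")
  fm <- matrix(fl, nrow = 12)      # columns are facets
  verts <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  if (!all(is.finite(verts)))
    stop("format error in '", path, "': non-finite vertex coordinates")
  surface_mesh(verts, matrix(seq_len(3 * n), ncol = 3, byrow = TRUE),
               drop_degenerate = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L) stop("empty geometry: no vertices in ASCII STL '", path, "'")
  if (length(vl) %% 3 != 0)
    stop("format error in '", path, "': vertex count ", length(vl),
         " not a multiple of 3 (near line ", vl[length(vl)], ")")
  coords <- t(vapply(strsplit(trimws(lines[vl]), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[2:4]))
    x
  }, numeric(3)))
  if (!all(is.finite(coords))) {
    bad <- vl[which(!stats::complete.cases(coords))[1]]
    stop("format error in '", path, "': unparseable vertex at line ", bad)
  }
  n <- length(vl) / 3
  surface_mesh(coords, matrix(seq_len(3 * n), ncol = 3, byrow = TRUE),
               drop_degenerate = FALSE)
}

#' Write an STL file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @note STL stores float32: coordinates are rounded to single precision on
#'   write; internal computation remains double.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path)
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  nrm <- face_normals(mesh)
  # 12 float32 per facet: normal, v1, v2, v3 (rows of fm)
  fm <- rbind(t(nrm), t(v[f[, 1], , drop = FALSE]),
              t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
  fr <- writeBin(as.vector(fm), raw(), size = 4, endian = "little")
  recs <- rbind(matrix(fr, nrow = 48), matrix(as.raw(0), 2, n))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", paste0("airwaymorph binary STL: ", mesh$name)))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeBin(as.vector(recs), con)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals(mesh)
  vtx <- function(p) sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines <- c(sprintf("solid %s", mesh$name),
             as.vector(rbind(
               sprintf("  facet normal %.9g %.9g %.9g", nrm[, 1], nrm[, 2], nrm[, 3]),
               "    outer loop",
               vtx(v[f[, 1], , drop = FALSE]),
               vtx(v[f[, 2], , drop = FALSE]),
               vtx(v[f[, 3], , drop = FALSE]),
               "    endloop",
               "  endfacet")),
             sprintf("endsolid %s", mesh$name))
  writeLines(lines, path)
}
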