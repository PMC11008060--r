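# shared fixtures built in code

# axis-aligned rectangular solid, watertight, outward orientation
box_mesh <- function(min_xyz, max_xyz) {
  lo <- as.numeric(min_xyz); hi <- as.numeric(max_xyz)
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # vertex order: (x,y,z) bits with x fastest
  f <- rbind(c(1, 5, 7), c(1, 7, 3),   # x = lo, normal -x
             c(2, 4, 8), c(2, 8, 6),   # x = hi, normal +x
             c(1, 2, 6), c(1, 6, 5),   # y = lo
             c(3, 8, 4), c(3, 7, 8),   # y = hi
             c(1, 4, 2), c(1, 3, 4),   # z = lo
             c(5, 6, 8), c(5, 8, 7))   # z = hi
  m <- surface_mesh(v, f, name = "box")
  stopifnot(mesh_volume(m) > 0)
  m
}

reverse_faces <- function(m) {
  m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

# contour object built by hand (for area/centroid unit tests)
manual_contour <- function(loops, plane) {
  structure(list(loops = lapply(loops, function(L) matrix(L, ncol = 3)),
                 plane = plane), class = "section_contour")
}

square_loop <- function(center = c(0, 0, 0), side = 1, z = NULL) {
  h <- side / 2
  cz <- if (is.null(z)) center[3] else z
  rbind(c(center[1] - h, center[2] - h, cz),
        c(center[1] + h, center[2] - h, cz),
        c(center[1] + h, center[2] + h, cz),
        c(center[1] - h, center[2] + h, cz))
}

circle_loop <- function(radius, center = c(0, 0, 0), n = 256) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(t), center[2] + radius * sin(t), center[3])
}

random_rotation <- function() {
  rotation_from_euler(stats::runif(1, -180, 180), stats::runif(1, -89, 89),
                      stats::runif(1, -180, 180))
}

ascii_cube_stl <- function(path) {
  m <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  write_stl(m, path, binary = FALSE)
  path
}
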