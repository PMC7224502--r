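# Triangulated surface I/O: STL (ASCII and binary) and OFF.

#' Read / write triangulated surfaces
#'
#' Formats are chosen by extension: `.stl` (ASCII by default, binary with
#' `binary = TRUE`; both variants are detected automatically on read) and
#' `.off`. STL stores no shared vertices, so vertices are merged on read;
#' OFF round-trips preserve the vertex count and triangle topology exactly.
#'
#' @param surface a [tri_surface()].
#' @param path file path.
#' @param binary write binary STL (ignored for OFF).
#' @return `read_surface()` returns a [tri_surface()];
#'   `write_surface()` returns `path` invisibly.
#' @export
write_surface <- function(surface, path, binary = FALSE) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    if (binary) write_stl_binary(surface, path) else write_stl_ascii(surface, path)
  } else if (grepl("\\.off$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(surface$vertices), nrow(surface$triangles)), con)
    writeLines(sprintf("%.17g %.17g %.17g", surface$vertices[, 1],
                       surface$vertices[, 2], surface$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", surface$triangles[, 1] - 1L,
                       surface$triangles[, 2] - 1L, surface$triangles[, 3] - 1L), con)
  } else stop("unknown surface format: ", path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  } else if (grepl("\\.off$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (toupper(lines[1]) != "OFF") stop("parse error line 1: missing OFF magic")
    counts <- scan(text = lines[2], quiet = TRUE)
    nv <- counts[1]; nf <- counts[2]
    verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                         quiet = TRUE), ncol = 3L, byrow = TRUE)
    fdat <- scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                 quiet = TRUE)
    fm <- matrix(fdat, ncol = 4L, byrow = TRUE)
    if (any(fm[, 1] != 3)) stop("only triangular OFF faces are supported")
    tri_surface(verts, fm[, 2:4] + 1L,
                sub("\\.off$", "", basename(path), ignore.case = TRUE))
  } else stop("unknown surface format: ", path)
}

write_stl_ascii <- function(surface, path) {
  v1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  n <- cross3(v2 - v1, v3 - v1)
  n <- n / pmax(rownorm(n), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", surface$name), con)
  body <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                         "  vertex %.17g %.17g %.17g\n",
                         "  vertex %.17g %.17g %.17g\n",
                         "  vertex %.17g %.17g %.17g\n endloop\nendfacet"),
                  n[, 1], n[, 2], n[, 3],
                  v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
                  v3[, 1], v3[, 2], v3[, 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", surface$name), con)
}

write_stl_binary <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC(surface$name, width = -80))
  writeBin(c(header, raw(80 - length(header)))[1:80], con)
  nt <- nrow(surface$triangles)
  writeBin(as.integer(nt), con, size = 4L, endian = "little")
  v1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  n <- cross3(v2 - v1, v3 - v1)
  n <- n / pmax(rownorm(n), 1e-300)
  dat <- t(cbind(n, v1, v2, v3))          # 12 floats per facet
  for (i in seq_len(nt)) {
    writeBin(as.numeric(dat[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nt <- readBin(con, "integer", 1, size = 4L, endian = "little")
  sz == 84 + 50 * nt
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nt <- readBin(con, "integer", 1, size = 4L, endian = "little")
  tri_v <- matrix(0, 3L * nt, 3L)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", 2L))
    tri_v[3L * i - 2:0, ] <- matrix(vals[4:12], 3L, byrow = TRUE)
  }
  soup_to_surface(tri_v, sub("\\.stl$", "", basename(path), ignore.case = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("parse error: no 'vertex' lines found in ASCII STL")
  vals <- scan(text = gsub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
  tri_v <- matrix(vals, ncol = 3L, byrow = TRUE)
  if (nrow(tri_v) %% 3L != 0L) stop("parse error: vertex count not divisible by 3")
  soup_to_surface(tri_v, sub("\\.stl$", "", basename(path), ignore.case = TRUE))
}

# merge a triangle soup (3 rows per facet) into an indexed surface
soup_to_surface <- function(tri_v, name) {
  key <- paste(tri_v[, 1], tri_v[, 2], tri_v[, 3])
  uid <- match(key, key)
  used <- sort(unique(uid))
  remap <- integer(nrow(tri_v)); remap[used] <- seq_along(used)
  tri_surface(tri_v[used, , drop = FALSE],
              matrix(remap[uid], ncol = 3L, byrow = TRUE), name)
}
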