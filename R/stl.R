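#' Write a mesh to STL
#'
#' Binary (default) or ASCII stereolithography export, units mm. Facet
#' normals are recomputed from the triangle winding.
#'
#' @param mesh a `grid_mesh`.
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  u <- p2 - p1; w <- p3 - p1
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  nt <- nrow(tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    ## 12 floats per facet: normal, v1, v2, v3; then a 2-byte attribute
    block <- t(cbind(n, p1, p2, p3))
    for (i in seq_len(nt)) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid gridcollim", con)
    for (i in seq_len(nt)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid gridcollim", con)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects binary vs ASCII. Vertices shared between facets are
#' welded (coordinates rounded to 1e-4 mm, the single-precision limit for
#' these dimensions).
#'
#' @param path STL file path.
#' @return A `grid_mesh`.
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  nt <- tryCatch(readBin(con, "integer", 1L, size = 4, endian = "little"),
                 error = function(e) NA_integer_)
  close(con)
  is_binary <- !is.na(nt) && size == 84 + 50 * as.numeric(nt)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    coords <- matrix(NA_real_, nt * 3L, 3L)
    for (i in seq_len(nt)) {
      vals <- readBin(con, "numeric", 12L, size = 4, endian = "little")
      readBin(con, "raw", 2L)
      coords[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L,
                                                 byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0 || length(vlines) %% 3L != 0L)
      stop("read_stl: malformed ASCII STL", call. = FALSE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                    function(p) as.numeric(p[2:4])))
  }
  weld_mesh(coords, digits = 4)
}
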