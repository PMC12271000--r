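#' Read and write dose planes as delimited text
#'
#' Planar doses are stored as tab-separated matrices with a two-line
#' header carrying the grid origin and spacing:
#' \preformatted{# origin: x0 y0
#' # spacing: dx dy}
#'
#' @param plane a [dose_plane()].
#' @param path file path.
#' @return `write_dose_plane()` returns `path` invisibly;
#'   `read_dose_plane()` returns a [dose_plane()].
#' @export
write_dose_plane <- function(plane, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin: %.9g %.9g", plane$origin[1],
                       plane$origin[2]),
               sprintf("# spacing: %.9g %.9g", plane$spacing[1],
                       plane$spacing[2])), con)
  utils::write.table(plane$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  hdr <- readLines(path, n = 2L)
  parse_hdr <- function(line, key) {
    if (!startsWith(line, paste0("# ", key, ":")))
      stop(sprintf("read_dose_plane: missing '%s' header", key),
           call. = FALSE)
    as.numeric(strsplit(trimws(sub(".*:", "", line)), "\\s+")[[1]])
  }
  origin <- parse_hdr(hdr[1], "origin")
  spacing <- parse_hdr(hdr[2], "spacing")
  vals <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t"))
  dimnames(vals) <- NULL
  dose_plane(vals, origin = origin, spacing = spacing)
}

#' Read and write dose grids (MHD-style header + raw)
#'
#' Volumes use a MetaImage-style layout: a small text header (`.mhd`)
#' describing dimensions, spacing and origin, next to a raw
#' little-endian 64-bit float data file.
#'
#' @param grid a [dose_grid()].
#' @param path header file path (`.mhd`); the data file replaces the
#'   extension with `.raw`.
#' @return `write_dose_grid()` returns `path` invisibly;
#'   `read_dose_grid()` returns a [dose_grid()].
#' @export
write_dose_grid <- function(grid, path) {
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", grid$dims[1], grid$dims[2],
                   grid$dims[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g", grid$spacing[1],
                   grid$spacing[2], grid$spacing[3]),
           sprintf("Offset = %.9g %.9g %.9g", grid$origin[1],
                   grid$origin[2], grid$origin[3]),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    line <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(line)) stop(sprintf("read_dose_grid: missing '%s'", key),
                            call. = FALSE)
    trimws(sub(".*=", "", line[1]))
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  dose_grid(array(vals, dim = dims), origin = origin, spacing = spacing)
}

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `collimator`, `beam`,
#' `dose_engine`, `gamma`, `metrics` and top-level `seed`, `output_dir`
#' and `log_level`. Every present section is validated by constructing
#' the corresponding object; missing sections fall back to package
#' defaults.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @return A list of validated components (class `run_config`).
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  spec <- do.call(collimator_spec, raw$collimator %||% list())
  geom <- do.call(beam_geometry, raw$beam %||% list())
  model <- do.call(beam_model, raw$dose_engine %||% list())
  criteria <- do.call(gamma_criteria, raw$gamma %||% list())
  metrics <- raw$metrics %||% list()
  if (is.null(metrics$cylinder_diameters))
    metrics$cylinder_diameters <- c(5, 10, 15)
  if (is.null(metrics$geud_exponent)) metrics$geud_exponent <- -10
  structure(list(
    collimator = spec, beam = geom, dose_engine = model,
    gamma = criteria, metrics = metrics,
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% ".",
    log_level = raw$log_level %||% "info"
  ), class = "run_config")
}

#' Write a layout table as CSV
#'
#' @param spec a [collimator_spec()].
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_layout_csv <- function(spec, path) {
  holes <- layout_holes(spec)
  utils::write.csv(
    holes[, c("row", "col", "x", "y", "tilt_x", "tilt_y")],
    path, row.names = FALSE)
  invisible(path)
}
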