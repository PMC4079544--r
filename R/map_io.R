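#' Write a density map as a CCP4/MRC map file
#'
#' Emits a minimal MRC2014/CCP4-compatible map: 1024-byte header, mode 2
#' (32-bit IEEE floats), column/row/section order x, y, z, orthogonal cell,
#' space group P1, little-endian. The map's absolute-scale densities are
#' written as-is in e-/A^3.
#'
#' @param map A \code{density_map}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  dims <- dim(map$grid)
  vals <- as.numeric(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                        # NC, NR, NS
  wi(2L)                          # MODE 2: float32
  wi(c(0L, 0L, 0L))               # start indices
  wi(dims)                        # sampling grid MX, MY, MZ
  wf(map$cell)                    # cell lengths
  wf(c(90, 90, 90))               # cell angles
  wi(c(1L, 2L, 3L))               # MAPC, MAPR, MAPS
  wf(c(min(vals), max(vals), mean(vals)))
  wi(1L)                          # ISPG = P1
  wi(0L)                          # NSYMBT
  wi(integer(25))                 # extra block
  wf(c(0, 0, 0))                  # origin (MRC2014 words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))             # RMS
  wi(0L)                          # NLABL
  writeBin(raw(800), con)         # label block
  wf(vals)
  invisible(path)
}

#' Read a CCP4/MRC map file
#'
#' Reads mode-2 (float32) maps with x, y, z axis order and an orthogonal
#' cell, as written by [write_ccp4_map()] or standard crystallographic
#' software. The result is marked absolute-scale; leveling utilities can be
#' applied afterwards if the scale is in doubt.
#'
#' @param path Map file path.
#' @return A \code{density_map}.
#' @export
read_ccp4_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2 floats)")
  ri(3)                 # start indices (ignored; maps are whole-cell)
  mxyz <- ri(3)
  cell <- rf(3)
  angles <- rf(3)
  if (any(abs(angles - 90) > 1e-3))
    stop("only orthogonal cells are supported")
  axis_order <- ri(3)
  if (!identical(axis_order, c(1L, 2L, 3L)))
    stop("only x,y,z axis order is supported")
  rf(3)                 # min/max/mean
  ri(1)                 # ISPG
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  if (!identical(dims, mxyz))
    stop("sub-volume maps (NC/NR/NS != MX/MY/MZ) are not supported")
  vals <- rf(prod(dims))
  if (length(vals) != prod(dims)) stop("truncated map data in ", path)
  new_density_map(array(vals, dim = dims), cell)
}

#' Write a reflection set as delimited text
#'
#' Tab-separated columns \code{h k l f_re f_im source} with a short
#' \code{#}-prefixed header recording cell, grid and resolution limit.
#'
#' @param refl A \code{reflection_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reflections <- function(refl, path) {
  stopifnot(inherits(refl, "reflection_set"))
  cell <- attr(refl, "cell"); dims <- attr(refl, "dims")
  d_min <- attr(refl, "d_min")
  hdr <- c(sprintf("# cell %.8g %.8g %.8g", cell[1], cell[2], cell[3]),
           sprintf("# dims %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("# d_min %s", if (is.null(d_min)) "none" else
             format(d_min, digits = 10)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(refl), path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, append = TRUE))
  invisible(path)
}

#' Read a reflection set written by [write_reflections()]
#'
#' @param path Input path.
#' @return A \code{reflection_set}.
#' @export
read_reflections <- function(path) {
  if (!file.exists(path)) stop("reflection file not found: ", path)
  hdr <- readLines(path, n = 3)
  cell <- as.numeric(strsplit(hdr[1], " +")[[1]][3:5])
  dims <- as.integer(strsplit(hdr[2], " +")[[1]][3:5])
  dmin_tok <- strsplit(hdr[3], " +")[[1]][3]
  d_min <- if (dmin_tok == "none") NULL else as.numeric(dmin_tok)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  new_reflection_set(df, cell, dims, d_min)
}
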