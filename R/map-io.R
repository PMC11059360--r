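# MRC/CCP4 map I/O. Mode-2 (32-bit float) maps only, which covers all
# modern cryo-EM depositions; axis order is normalised to (x, y, z) on read
# using the MAPC/MAPR/MAPS header words, and the MRC2014 ORIGIN record is
# honoured (no implicit re-centering). Little-endian on disk.

#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (float32) MRC map and normalises it to the package's
#' [DensityMap-class] convention: value array indexed (x, y, z) with the
#' fastest-varying file axis permuted into place, voxel size from
#' `cell / sampling`, and origin taken from the MRC2014 ORIGIN words (with
#' the classic CCP4 `NXSTART`-style start offsets used as fallback when the
#' ORIGIN record is all zero).
#'
#' @param path path to an `.mrc`/`.map` file.
#' @return A [DensityMap-class] object.
#' @seealso [writeDensityMap()], [renderDensity()]
#' @export
readDensityMap <- function(path) {
    if (!file.exists(path)) stop("map file not found: ", path)
    sz <- file.size(path)
    if (sz < 1024) stop("corrupt MRC file (shorter than header): ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
    mode <- readBin(con, "integer", 1, size = 4, endian = "little")
    nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
    mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
    cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
    readBin(con, "numeric", 3, size = 4, endian = "little")  # cell angles
    mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
    readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin/max/mean
    readBin(con, "integer", 1, size = 4, endian = "little")  # ispg
    nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
    readBin(con, "integer", 25, size = 4, endian = "little") # extra
    origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
    maptag <- readChar(con, 4, useBytes = TRUE)
    if (mode != 2L)
        stop("unsupported MRC mode ", mode, " (only mode 2 float32)")
    if (any(nxyz <= 0L) || any(mxyz <= 0L) || !setequal(mapcrs, 1:3))
        stop("corrupt MRC header in ", path)
    n <- prod(nxyz)
    if (sz < 1024 + nsymbt + 4 * n)
        stop("truncated MRC file: ", path, " (expected ",
             1024 + nsymbt + 4 * n, " bytes, got ", sz, ")")
    seek(con, 1024 + nsymbt)
    vals <- readBin(con, "numeric", n, size = 4, endian = "little")
    # file layout: columns (fastest) x rows x sections; axis k of the file
    # is Cartesian axis mapcrs[k]
    arr <- array(vals, dim = nxyz)
    perm <- match(1:3, mapcrs)       # where each Cartesian axis lives
    arr <- aperm(arr, perm)
    voxel <- cella / mxyz
    if (all(origin == 0) && any(nstart != 0))
        origin <- nstart[perm] * voxel
    DensityMap(arr, voxel = voxel, origin = origin)
}

#' Write an MRC/CCP4 density map
#'
#' Writes a mode-2 (float32) MRC2014 file with canonical axis order
#' (MAPC/MAPR/MAPS = 1/2/3) and the origin stored in the ORIGIN words.
#'
#' @param x a [DensityMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDensityMap <- function(x, path) {
    d <- dim(mapValues(x))
    vox <- voxelSize(x)
    con <- file(path, "wb")
    on.exit(close(con))
    wi <- function(v) writeBin(as.integer(v), con, size = 4,
                               endian = "little")
    wf <- function(v) writeBin(as.numeric(v), con, size = 4,
                               endian = "little")
    vals <- as.vector(mapValues(x))
    wi(d); wi(2L)                       # nx ny nz, mode
    wi(c(0L, 0L, 0L)); wi(d)            # nstart, mx my mz
    wf(d * vox); wf(c(90, 90, 90))      # cell lengths, angles
    wi(1:3)                             # mapc mapr maps
    wf(c(min(vals), max(vals), mean(vals)))
    wi(1L); wi(0L)                      # ispg, nsymbt
    wi(rep(0L, 25))                     # extra
    wf(mapOrigin(x))                    # origin
    writeChar("MAP ", con, nchars = 4, eos = NULL)
    writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # LE machine stamp
    wf(stats::sd(vals))
    wi(0L)                              # nlabl
    writeBin(raw(800), con)             # labels
    wf(vals)
    invisible(path)
}
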