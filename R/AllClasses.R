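#' Atomic structure container
#'
#' Holds a hierarchical atomic model flattened to one row per atom. Author
#' (PDB) residue numbering is preserved throughout: residue 166 in the table
#' is the residue a structural biologist would call G166. Coordinates are in
#' angstrom. Every atom carries a van der Waals radius assigned from a
#' [radiiTable()] at construction, so downstream geometry (pore profiling,
#' SASA, neighbour censuses) never needs to look radii up again.
#'
#' @slot atoms `data.frame` with columns `serial` (integer), `name` (atom
#'   name, e.g. "CA"), `element` (symbol, e.g. "C"), `resname` (3-letter
#'   code), `resno` (author residue number), `chain` (chain id), `x`, `y`,
#'   `z` (angstrom), `vdw` (angstrom) and `hetero` (logical HETATM flag).
#' @slot title free-text description.
#' @slot assembly assembly/accession identifier (may be `""`).
#'
#' @seealso [Structure()], [readStructure()], [selectAtoms()]
#' @export
setClass("Structure",
    representation(atoms = "data.frame", title = "character",
                   assembly = "character"))

setValidity("Structure", function(object) {
    at <- object@atoms
    need <- c("serial", "name", "element", "resname", "resno", "chain",
              "x", "y", "z", "vdw", "hetero")
    miss <- setdiff(need, names(at))
    if (length(miss))
        return(paste("atoms table missing columns:",
                     paste(miss, collapse = ", ")))
    if (nrow(at) < 1L)
        return("structure must contain at least one atom")
    if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
        return("atom coordinates must be finite")
    if (!all(is.finite(at$vdw)) || any(at$vdw <= 0))
        return("all van der Waals radii must be positive")
    if (any(!nzchar(at$element)))
        return("element symbols must be non-empty")
    TRUE
})

#' Construct a Structure from an atom table
#'
#' @param atoms atom `data.frame`; see [Structure-class] for required
#'   columns. A `vdw` column is added from `radii` when absent.
#' @param title free-text title.
#' @param assembly assembly identifier.
#' @param radii a [radiiTable()] used to fill in missing `vdw` values.
#' @return A [Structure-class] object.
#' @examples
#' at <- data.frame(serial = 1L, name = "CA", element = "C",
#'                  resname = "GLY", resno = 1L, chain = "A",
#'                  x = 0, y = 0, z = 0, hetero = FALSE)
#' s <- Structure(at, title = "one carbon")
#' nAtoms(s)
#' @export
Structure <- function(atoms, title = "", assembly = "",
                      radii = radiiTable()) {
    atoms <- as.data.frame(atoms)
    if (is.null(atoms$hetero)) atoms$hetero <- FALSE
    if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
    if (is.null(atoms$vdw))
        atoms$vdw <- lookupRadius(atoms$element, radii)
    rownames(atoms) <- NULL
    new("Structure", atoms = atoms, title = title, assembly = assembly)
}

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname atomRecords
#' @export
setMethod("atomRecords", "Structure", function(x) x@atoms)

#' @rdname coords
#' @export
setMethod("coords", "Structure", function(x) {
    m <- as.matrix(x@atoms[, c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
})

setMethod("show", "Structure", function(object) {
    at <- object@atoms
    cat("Structure:", if (nzchar(object@title)) object@title else "<untitled>",
        "\n")
    cat("  ", nrow(at), " atoms, ",
        length(unique(paste(at$chain, at$resno))), " residues, chains: ",
        paste(sort(unique(at$chain)), collapse = " "), "\n", sep = "")
    cat("  hetero atoms:", sum(at$hetero), "\n")
    invisible(object)
})

#' Cryo-EM density map container
#'
#' A 3D scalar grid with physical voxel size and origin, axis order
#' normalised to (x, y, z) regardless of how the source file permuted its
#' axes. The origin is the Cartesian position of the centre of voxel
#' (1, 1, 1); voxel `(i, j, k)` sits at `origin + (i-1, j-1, k-1) * voxel`.
#'
#' @slot values 3D numeric array indexed (x, y, z).
#' @slot voxel numeric length-3, angstrom per voxel.
#' @slot origin numeric length-3, angstrom.
#'
#' @seealso [DensityMap()], [readDensityMap()], [renderDensity()]
#' @export
setClass("DensityMap",
    representation(values = "array", voxel = "numeric", origin = "numeric"))

setValidity("DensityMap", function(object) {
    if (length(dim(object@values)) != 3L)
        return("values must be a 3D array")
    if (length(object@voxel) != 3L || any(!is.finite(object@voxel)) ||
        any(object@voxel <= 0))
        return("voxel must be 3 positive finite numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("origin must be 3 finite numbers")
    if (any(!is.finite(object@values)))
        return("map values must be finite")
    TRUE
})

#' Construct a DensityMap
#'
#' @param values 3D numeric array indexed (x, y, z).
#' @param voxel voxel size in angstrom; scalar or length-3.
#' @param origin Cartesian position of voxel (1,1,1), angstrom.
#' @return A [DensityMap-class] object.
#' @export
DensityMap <- function(values, voxel, origin = c(0, 0, 0)) {
    if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
    new("DensityMap", values = values, voxel = as.numeric(voxel),
        origin = as.numeric(origin))
}

#' @rdname mapValues
#' @export
setMethod("mapValues", "DensityMap", function(x) x@values)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxel)

#' @rdname mapOrigin
#' @export
setMethod("mapOrigin", "DensityMap", function(x) x@origin)

setMethod("show", "DensityMap", function(object) {
    d <- dim(object@values)
    cat("DensityMap: ", paste(d, collapse = " x "), " grid\n", sep = "")
    cat("  voxel (A): ", paste(signif(object@voxel, 4), collapse = ", "),
        "\n  origin (A): ", paste(signif(object@origin, 4), collapse = ", "),
        "\n  value range: ", paste(signif(range(object@values), 4),
                                   collapse = " .. "), "\n", sep = "")
    invisible(object)
})

#' Per-replicate substrate distance trace
#'
#' One molecular-dynamics replicate reduced to a scalar per frame: the
#' distance (angstrom) from the substrate to a reference atom, conventionally
#' the C-alpha at the N-terminal end of TM3 (G166 in SLC26A2). This scalar is
#' the entire currency of the residency statistic: a frame is "bound" when
#' the distance falls inside a [bindingWindow()].
#'
#' @slot replicate character replicate identifier.
#' @slot distances numeric per-frame distances, angstrom.
#' @slot source one of "synthetic", "file", "coordinates".
#' @slot seed integer seed used to generate the trace (NA when not synthetic).
#'
#' @seealso [TrajectoryTrace()], [simulateBindingTrace()], [boundFraction()]
#' @export
setClass("TrajectoryTrace",
    representation(replicate = "character", distances = "numeric",
                   source = "character", seed = "integer"))

setValidity("TrajectoryTrace", function(object) {
    if (length(object@distances) < 1L)
        return("trace must contain at least one frame")
    if (any(!is.finite(object@distances)) || any(object@distances < 0))
        return("distances must be finite and non-negative")
    if (!object@source %in% c("synthetic", "file", "coordinates"))
        return("source must be synthetic, file or coordinates")
    TRUE
})

#' Construct a TrajectoryTrace
#'
#' @param distances numeric vector of per-frame distances (angstrom).
#' @param replicate replicate identifier.
#' @param source provenance tag: "synthetic", "file" or "coordinates".
#' @param seed generator seed, or `NA` for non-synthetic traces.
#' @return A [TrajectoryTrace-class] object.
#' @export
TrajectoryTrace <- function(distances, replicate = "rep1",
                            source = "coordinates", seed = NA_integer_) {
    new("TrajectoryTrace", replicate = as.character(replicate),
        distances = as.numeric(distances), source = source,
        seed = as.integer(seed))
}

#' @rdname distances
#' @export
setMethod("distances", "TrajectoryTrace", function(x) x@distances)

#' @rdname nFrames
#' @export
setMethod("nFrames", "TrajectoryTrace", function(x) length(x@distances))

#' @rdname replicateId
#' @export
setMethod("replicateId", "TrajectoryTrace", function(x) x@replicate)

setMethod("show", "TrajectoryTrace", function(object) {
    cat("TrajectoryTrace '", object@replicate, "' (", object@source, "): ",
        length(object@distances), " frames, distance range ",
        paste(signif(range(object@distances), 4), collapse = " .. "),
        " A\n", sep = "")
    invisible(object)
})
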