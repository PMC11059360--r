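#' @import methods
NULL

#' Number of atoms in a structural object
#'
#' @param x a [Structure-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Atom-level records of a structure
#'
#' Returns the full atom table of a [Structure-class]: one row per atom with
#' serial, name, element, residue name/number, chain, Cartesian coordinates
#' (angstrom), van der Waals radius and HETATM flag.
#'
#' @param x a [Structure-class] object.
#' @return A `data.frame` with one row per atom.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' Cartesian coordinates of a structural object
#'
#' @param x a [Structure-class] object.
#' @return Numeric matrix with `nAtoms(x)` rows and columns x, y, z (angstrom).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Grid values of a density map
#'
#' @param x a [DensityMap-class] object.
#' @return 3D numeric array indexed (x, y, z).
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Voxel size of a density map
#'
#' @param x a [DensityMap-class] object.
#' @return Numeric length-3 vector, angstrom per voxel along x, y, z.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Origin of a density map
#'
#' @param x a [DensityMap-class] object.
#' @return Numeric length-3 vector: Cartesian position (angstrom) of the
#'   centre of grid voxel (1, 1, 1).
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))

#' Per-frame distances of a trajectory trace
#'
#' @param x a [TrajectoryTrace-class] object.
#' @return Numeric vector, one substrate-to-reference distance (angstrom)
#'   per frame.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' Number of frames in a trajectory trace
#'
#' @param x a [TrajectoryTrace-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Replicate identifier of a trajectory trace
#'
#' @param x a [TrajectoryTrace-class] object.
#' @return Character scalar.
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
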