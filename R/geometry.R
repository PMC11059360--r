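# Shared rigid-body geometry: Kabsch superposition and small vector helpers.

vnorm <- function(v) sqrt(sum(v * v))

# Optimal least-squares rotation + translation mapping `mobile` onto `ref`
# (both n x 3, matched rows). Returns list(R, t) with y = x %*% R + t.
kabsch <- function(mobile, ref) {
    stopifnot(nrow(mobile) == nrow(ref), nrow(mobile) >= 3L)
    cm <- colMeans(mobile)
    cr <- colMeans(ref)
    A <- sweep(mobile, 2, cm)
    B <- sweep(ref, 2, cr)
    H <- crossprod(A, B)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$u %*% D %*% t(sv$v)
    list(R = R, t = cr - drop(cm %*% R))
}

applyTransform <- function(xyz, tr) sweep(xyz %*% tr$R, 2, tr$t, "+")

# Match atoms between two structures by (chain, resno, atom name); returns
# a list of index vectors ia / ib plus the number of unmatched keys.
matchAtoms <- function(a, b, name = "CA", hetero = FALSE) {
    ta <- atomRecords(a); tb <- atomRecords(b)
    keep_a <- ta$name %in% name & ta$hetero == hetero
    keep_b <- tb$name %in% name & tb$hetero == hetero
    ka <- paste(ta$chain, ta$resno, ta$name, sep = "|")[keep_a]
    kb <- paste(tb$chain, tb$resno, tb$name, sep = "|")[keep_b]
    common <- intersect(ka, kb)
    list(ia = which(keep_a)[match(common, ka)],
         ib = which(keep_b)[match(common, kb)],
         n_unmatched = length(ka) + length(kb) - 2L * length(common))
}

#' Select atoms of a structure
#'
#' Index-based atom selection on the flat atom table, addressing atoms the
#' way residues are cited in the structural literature: by chain, author
#' residue number, atom name, residue name and/or HETATM status. `NULL`
#' leaves a field unconstrained.
#'
#' @param x a [Structure-class].
#' @param chain,resno,name,resname,hetero selection filters (vectors allowed).
#' @param serial select by atom serial numbers.
#' @return Integer vector of row indices into `atomRecords(x)`.
#' @examples
#' s <- buildToyBundle(bundleSpec(seed = 1))
#' idx <- selectAtoms(s, chain = "A", resno = 1, name = "CA")
#' atomRecords(s)[idx, ]
#' @export
selectAtoms <- function(x, chain = NULL, resno = NULL, name = NULL,
                        resname = NULL, hetero = NULL, serial = NULL) {
    at <- atomRecords(x)
    keep <- rep(TRUE, nrow(at))
    if (!is.null(chain)) keep <- keep & at$chain %in% chain
    if (!is.null(resno)) keep <- keep & at$resno %in% resno
    if (!is.null(name)) keep <- keep & at$name %in% name
    if (!is.null(resname)) keep <- keep & at$resname %in% resname
    if (!is.null(hetero)) keep <- keep & at$hetero == hetero
    if (!is.null(serial)) keep <- keep & at$serial %in% serial
    which(keep)
}

#' Extract a sub-structure
#'
#' @param x a [Structure-class].
#' @param idx integer atom indices (rows of `atomRecords(x)`), e.g. from
#'   [selectAtoms()].
#' @return A new [Structure-class] containing only those atoms.
#' @export
subsetStructure <- function(x, idx) {
    stopifnot(length(idx) >= 1L)
    new("Structure", atoms = atomRecords(x)[idx, , drop = FALSE],
        title = x@title, assembly = x@assembly)
}

# Centroid (unweighted heavy-atom mean) of an atom index set.
atomCentroid <- function(x, idx) {
    stopifnot(length(idx) >= 1L)
    colMeans(coords(x)[idx, , drop = FALSE])
}
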