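# Geometric hydrogen-bond and cation-pi detection. Deposited cryo-EM models
# carry no hydrogens, so the default H-bond mode is heavy-atom
# donor-acceptor distance with element-based typing; when explicit
# hydrogens exist the donor-H...acceptor angle criterion is applied too.

#' Detect hydrogen bonds geometrically
#'
#' Candidate donors/acceptors are nitrogen and oxygen atoms. Pairs in
#' different residues with heavy-atom distance in `[d_min, d_max]` are
#' reported. When the putative donor carries an explicit hydrogen (an H
#' within 1.25 A), the donor-H...acceptor angle at the hydrogen must be at
#' least `angle_min` degrees; hydrogen-free pairs are scored on distance
#' only and flagged `mode = "distance"`.
#'
#' @param x a [Structure-class].
#' @param d_max maximum heavy-atom distance (angstrom, default 3.5).
#' @param d_min minimum distance excluding covalent contacts (default 2.0).
#' @param angle_min minimum angle at the hydrogen (degrees, default 120).
#' @return `data.frame` with donor/acceptor descriptors, `distance_A`,
#'   `angle_deg` (NA in distance-only mode) and `mode`.
#' @export
findHBonds <- function(x, d_max = 3.5, d_min = 2.0, angle_min = 120) {
    at <- atomRecords(x)
    xyz <- coords(x)
    cand <- which(at$element %in% c("N", "O"))
    hyd <- which(at$element == "H")
    out <- list()
    if (length(cand) >= 2L) {
        for (k in seq_along(cand)[-length(cand)]) {
            i <- cand[k]
            js <- cand[(k + 1L):length(cand)]
            js <- js[!(at$chain[js] == at$chain[i] &
                       at$resno[js] == at$resno[i])]
            if (!length(js)) next
            d <- sqrt((xyz[js, 1] - xyz[i, 1])^2 +
                      (xyz[js, 2] - xyz[i, 2])^2 +
                      (xyz[js, 3] - xyz[i, 3])^2)
            sel <- d >= d_min & d <= d_max
            for (m in which(sel)) {
                j <- js[m]
                # treat the nitrogen (or the first atom) as donor
                don <- if (at$element[j] == "N" && at$element[i] != "N") j
                       else i
                acc <- if (don == i) j else i
                ang <- NA_real_
                mode <- "distance"
                if (length(hyd)) {
                    dh <- sqrt((xyz[hyd, 1] - xyz[don, 1])^2 +
                               (xyz[hyd, 2] - xyz[don, 2])^2 +
                               (xyz[hyd, 3] - xyz[don, 3])^2)
                    hh <- hyd[dh <= 1.25]
                    if (length(hh)) {
                        mode <- "distance+angle"
                        angs <- vapply(hh, function(h) {
                            v1 <- xyz[don, ] - xyz[h, ]
                            v2 <- xyz[acc, ] - xyz[h, ]
                            acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                (vnorm(v1) * vnorm(v2))))) * 180 / pi
                        }, numeric(1))
                        ang <- max(angs)
                        if (ang < angle_min) next
                    }
                }
                out[[length(out) + 1L]] <- data.frame(
                    donor_chain = at$chain[don], donor_resno = at$resno[don],
                    donor_resname = at$resname[don],
                    donor_atom = at$name[don],
                    acceptor_chain = at$chain[acc],
                    acceptor_resno = at$resno[acc],
                    acceptor_resname = at$resname[acc],
                    acceptor_atom = at$name[acc],
                    distance_A = d[m], angle_deg = ang, mode = mode,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(donor_chain = character(),
                          donor_resno = integer(),
                          donor_resname = character(),
                          donor_atom = character(),
                          acceptor_chain = character(),
                          acceptor_resno = integer(),
                          acceptor_resname = character(),
                          acceptor_atom = character(),
                          distance_A = numeric(), angle_deg = numeric(),
                          mode = character()))
    do.call(rbind, out)
}

RING_ATOMS <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

CATION_ATOMS <- list(LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))

#' Detect cation-pi pairs
#'
#' Aromatic ring centroids (PHE/TYR six-ring, TRP six-ring) paired with
#' cationic centres (LYS NZ; ARG guanidinium centroid; HIS imidazole
#' centroid) within `d_max`.
#'
#' @param x a [Structure-class].
#' @param d_max centroid-to-centre cutoff (angstrom, default 6).
#' @return `data.frame` with aromatic and cation residue descriptors and
#'   `distance_A`.
#' @export
findCationPi <- function(x, d_max = 6.0) {
    at <- atomRecords(x)
    xyz <- coords(x)
    centreOf <- function(defs) {
        keys <- unique(at[at$resname %in% names(defs),
                          c("chain", "resno", "resname")])
        if (!nrow(keys)) return(NULL)
        cen <- t(apply(keys, 1, function(kk) {
            idx <- which(at$chain == kk[["chain"]] &
                         at$resno == as.integer(kk[["resno"]]) &
                         at$name %in% defs[[kk[["resname"]]]])
            if (length(idx) < 1L) rep(NA_real_, 3)
            else colMeans(xyz[idx, , drop = FALSE])
        }))
        ok <- stats::complete.cases(cen)
        list(keys = keys[ok, , drop = FALSE], cen = cen[ok, , drop = FALSE])
    }
    rings <- centreOf(RING_ATOMS)
    cats <- centreOf(CATION_ATOMS)
    empty <- data.frame(ring_chain = character(), ring_resno = integer(),
                        ring_resname = character(),
                        cation_chain = character(),
                        cation_resno = integer(),
                        cation_resname = character(),
                        distance_A = numeric())
    if (is.null(rings) || is.null(cats) || !nrow(rings$keys) ||
        !nrow(cats$keys))
        return(empty)
    out <- list()
    for (i in seq_len(nrow(rings$keys)))
        for (j in seq_len(nrow(cats$keys))) {
            d <- vnorm(rings$cen[i, ] - cats$cen[j, ])
            if (d <= d_max)
                out[[length(out) + 1L]] <- data.frame(
                    ring_chain = rings$keys$chain[i],
                    ring_resno = as.integer(rings$keys$resno[i]),
                    ring_resname = rings$keys$resname[i],
                    cation_chain = cats$keys$chain[j],
                    cation_resno = as.integer(cats$keys$resno[j]),
                    cation_resname = cats$keys$resname[j],
                    distance_A = d, stringsAsFactors = FALSE)
        }
    if (!length(out)) return(empty)
    do.call(rbind, out)
}
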