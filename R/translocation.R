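#' Substrate-cleft widths from C-alpha residue pairs
#'
#' Measures the width of the substrate cleft as C-alpha to C-alpha
#' distances across the two pocket-forming helices. The default pairs are
#' the three used to track the TM3/TM10 cleft in SLC26A2: 165/442, 166/441
#' and 167/440.
#'
#' @param x a [Structure-class].
#' @param pairs 2-column matrix or data.frame of author residue numbers,
#'   one row per pair (first column on TM3, second on TM10).
#' @param chain chain id the residue numbers refer to.
#' @return `data.frame` with `res_a`, `res_b`, `distance_A`.
#' @export
cleftWidths <- function(x, pairs = cbind(c(165, 166, 167),
                                         c(442, 441, 440)),
                        chain = "A") {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    d <- apply(pairs, 1, function(pr) {
        ia <- selectAtoms(x, chain = chain, resno = pr[1], name = "CA")
        ib <- selectAtoms(x, chain = chain, resno = pr[2], name = "CA")
        if (length(ia) != 1L || length(ib) != 1L)
            stop("cleft pair ", pr[1], "/", pr[2], " (chain ", chain,
                 ") does not resolve to single C-alpha atoms")
        vnorm(coords(x)[ia, ] - coords(x)[ib, ])
    })
    data.frame(res_a = pairs[, 1], res_b = pairs[, 2], distance_A = d)
}

#' Core-domain elevator displacement after gate alignment
#'
#' Quantifies the elevator motion of an alternating-access transporter:
#' superposes the mobile structure onto the reference using gate-domain
#' C-alpha atoms only (least squares), then reports the displacement of the
#' probe selection's C-alpha centroid (canonically TM3/TM10, the helices
#' carrying the substrate pocket) along the membrane normal. Positive
#' values mean displacement towards the +normal (extracellular) side.
#'
#' @param mobile,reference [Structure-class] objects sharing gate residues.
#' @param gate named list of [selectAtoms()] arguments selecting the gate
#'   domain (e.g. `list(chain = "A", resno = gate_residues)`); C-alpha
#'   atoms are taken from this selection and matched by (chain, resno).
#' @param probe named list selecting the probe residues (TM3/TM10 ranges).
#' @param axis membrane normal (defaults to z); overridden e.g. by
#'   `placeMembraneSlab(reference)$normal`.
#' @param min_common minimum number of shared gate C-alpha atoms.
#' @return Signed displacement in angstrom.
#' @export
elevatorShift <- function(mobile, reference, gate, probe,
                          axis = c(0, 0, 1), min_common = 20L) {
    axis <- axis / vnorm(axis)
    caSel <- function(s, sel) {
        idx <- do.call(selectAtoms, c(list(s), sel))
        idx[atomRecords(s)$name[idx] == "CA"]
    }
    gm <- caSel(mobile, gate); gr <- caSel(reference, gate)
    km <- with(atomRecords(mobile)[gm, ], paste(chain, resno))
    kr <- with(atomRecords(reference)[gr, ], paste(chain, resno))
    common <- intersect(km, kr)
    if (length(common) < min_common)
        stop("gate selections share only ", length(common),
             " C-alpha atoms (need >= ", min_common, ")")
    tr <- kabsch(coords(mobile)[gm[match(common, km)], , drop = FALSE],
                 coords(reference)[gr[match(common, kr)], , drop = FALSE])
    pm <- caSel(mobile, probe); pr <- caSel(reference, probe)
    if (!length(pm) || !length(pr))
        stop("probe selection resolves to no C-alpha atoms")
    cm <- colMeans(applyTransform(coords(mobile)[pm, , drop = FALSE], tr))
    cr <- colMeans(coords(reference)[pr, , drop = FALSE])
    sum((cm - cr) * axis)
}

#' Residues with heavy atoms near a ligand
#'
#' Census of residues having any heavy atom within `cutoff` of any ligand
#' atom, with the per-residue minimum distance -- the "within 5 A of the
#' substrate" neighbourhood used to describe binding-site chemistry.
#'
#' @param x a [Structure-class].
#' @param ligand named list of [selectAtoms()] arguments for the ligand.
#' @param cutoff distance cutoff in angstrom (default 5).
#' @return `data.frame` with `chain`, `resno`, `resname`, `min_distance_A`,
#'   sorted by distance. Ligand atoms themselves are excluded.
#' @export
neighborCensus <- function(x, ligand, cutoff = 5.0) {
    li <- do.call(selectAtoms, c(list(x), ligand))
    if (!length(li)) stop("ligand selection matches no atoms")
    at <- atomRecords(x)
    xyz <- coords(x)
    others <- setdiff(seq_len(nrow(at)), li)
    if (!length(others) || cutoff <= 0)
        return(data.frame(chain = character(), resno = integer(),
                          resname = character(),
                          min_distance_A = numeric()))
    dmin <- rep(Inf, length(others))
    for (l in li) {
        d <- sqrt((xyz[others, 1] - xyz[l, 1])^2 +
                  (xyz[others, 2] - xyz[l, 2])^2 +
                  (xyz[others, 3] - xyz[l, 3])^2)
        dmin <- pmin(dmin, d)
    }
    keep <- dmin <= cutoff
    if (!any(keep))
        return(data.frame(chain = character(), resno = integer(),
                          resname = character(),
                          min_distance_A = numeric()))
    hits <- data.frame(chain = at$chain[others][keep],
                       resno = at$resno[others][keep],
                       resname = at$resname[others][keep],
                       d = dmin[keep], stringsAsFactors = FALSE)
    agg <- stats::aggregate(d ~ chain + resno + resname, data = hits, min)
    agg <- agg[order(agg$d), , drop = FALSE]
    names(agg)[4] <- "min_distance_A"
    rownames(agg) <- NULL
    agg
}

#' Ligand-site displacement between two structures
#'
#' Superposes structure `b` onto structure `a` over a shared alignment
#' selection (default: all shared C-alpha atoms) and reports the distance
#' between the two ligand centroids -- e.g. how far the sulfate site sits
#' from the chloride site after aligning the transporters.
#'
#' @param a,b [Structure-class] objects.
#' @param ligand_a,ligand_b named [selectAtoms()] argument lists for the
#'   ligand in each structure.
#' @param alignment named argument list for the alignment selection applied
#'   to both structures; C-alpha atoms matched by (chain, resno, name).
#' @return Distance in angstrom.
#' @export
ligandSiteDisplacement <- function(a, ligand_a, b, ligand_b,
                                   alignment = list(name = "CA")) {
    ia <- do.call(selectAtoms, c(list(a), alignment))
    ib <- do.call(selectAtoms, c(list(b), alignment))
    ta <- atomRecords(a)[ia, ]; tb <- atomRecords(b)[ib, ]
    ka <- paste(ta$chain, ta$resno, ta$name)
    kb <- paste(tb$chain, tb$resno, tb$name)
    common <- intersect(ka, kb)
    if (length(common) < 3L)
        stop("alignment selection shares fewer than 3 atoms")
    tr <- kabsch(coords(b)[ib[match(common, kb)], , drop = FALSE],
                 coords(a)[ia[match(common, ka)], , drop = FALSE])
    la <- do.call(selectAtoms, c(list(a), ligand_a))
    lb <- do.call(selectAtoms, c(list(b), ligand_b))
    if (!length(la) || !length(lb)) stop("ligand selection matches no atoms")
    cb <- colMeans(applyTransform(coords(b)[lb, , drop = FALSE], tr))
    vnorm(atomCentroid(a, la) - cb)
}

#' C-alpha RMSD after optimal superposition
#'
#' Pairs atoms by (chain, residue number, atom name) over the chosen atom
#' names, superposes with the Kabsch algorithm and reports the
#' root-mean-square deviation. Unmatched residues are dropped and counted
#' in the `n_unmatched` attribute.
#'
#' @param mobile,reference [Structure-class] objects.
#' @param names atom names to pair (default `"CA"`).
#' @return RMSD in angstrom with attributes `n_atoms`, `n_unmatched`.
#' @export
structureRmsd <- function(mobile, reference, names = "CA") {
    m <- matchAtoms(mobile, reference, name = names)
    if (length(m$ia) < 3L)
        stop("fewer than 3 shared atoms for superposition")
    A <- coords(mobile)[m$ia, , drop = FALSE]
    B <- coords(reference)[m$ib, , drop = FALSE]
    tr <- kabsch(A, B)
    A2 <- applyTransform(A, tr)
    rmsd <- sqrt(mean(rowSums((A2 - B)^2)))
    attr(rmsd, "n_atoms") <- length(m$ia)
    attr(rmsd, "n_unmatched") <- m$n_unmatched
    rmsd
}
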