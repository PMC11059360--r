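# Hydrophobic membrane-slab placement: a deterministic, PPM-like stand-in.
# The slab normal is fixed to the first principal axis of the C-alpha cloud
# (transmembrane helices run along the membrane normal, so that axis
# dominates the covariance); only the slab centre and half-thickness are
# optimised, by exhaustive grid search on a hydropathy objective.

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
hydropathyScale <- function() {
    c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Place a hydrophobic membrane slab on a structure
#'
#' Grid search over slab centre offset (0.5 A steps along the normal) and
#' half-thickness (10-25 A, 0.5 A steps) maximising the hydropathy
#' objective: sum of Kyte-Doolittle values of solvent-exposed residues
#' inside the slab minus the sum for exposed residues outside it. Exposure
#' is relative accessibility above `exposure_cutoff` (residue SASA over the
#' free-residue reference). A maximised objective at or below 0 is flagged
#' `low_confidence` (e.g. an all-polar bundle has no hydrophobic belt to
#' find).
#'
#' @param x a [Structure-class] with >= 50 residues.
#' @param normal optional user override of the membrane normal.
#' @param hydropathy named per-residue scale (one-letter codes).
#' @param exposure_cutoff relative-accessibility threshold defining
#'   "solvent exposed".
#' @param sasa_params a [sasaParams()] for the exposure computation.
#' @return A list of class `"membraneSlab"`: unit `normal`,
#'   `center_offset` (angstrom along the normal, relative to the C-alpha
#'   centroid), `half_thickness`, `center_point` (3-vector),
#'   `fit_score`, `low_confidence`.
#' @export
placeMembraneSlab <- function(x, normal = NULL,
                              hydropathy = hydropathyScale(),
                              exposure_cutoff = 0.2,
                              sasa_params = sasaParams(n_sphere_points = 240L)) {
    at <- atomRecords(x)
    ca <- which(at$name == "CA" & !at$hetero)
    reskey <- paste(at$chain, at$resno)
    if (length(unique(reskey[ca])) < 50L)
        stop("membrane placement needs at least 50 residues")
    xyz_ca <- coords(x)[ca, , drop = FALSE]
    centroid <- colMeans(xyz_ca)
    if (is.null(normal)) {
        cv <- stats::cov(xyz_ca)
        ev <- eigen(cv, symmetric = TRUE)
        if (ev$values[1] <= 1e-8 || ev$values[2] <= 1e-6 * ev$values[1])
            stop("degenerate (linear) coordinate cloud: cannot place a slab")
        normal <- ev$vectors[, 1]
    }
    normal <- normal / vnorm(normal)
    # deterministic sign: largest-magnitude component positive
    imax <- which.max(abs(normal))
    if (normal[imax] < 0) normal <- -normal
    # residue exposure and hydropathy
    areas <- sasa(x, sasa_params)
    res_area <- tapply(areas, reskey, sum)
    res_name <- tapply(at$resname, reskey, function(v) v[1])
    ref <- maxAccessibleArea()[res_name]
    ref[is.na(ref)] <- mean(maxAccessibleArea())
    rel <- pmin(1.2, as.numeric(res_area) / as.numeric(ref))
    hyd <- hydropathy[AA1[res_name]]
    hyd[is.na(hyd)] <- 0
    depth_res <- tapply(drop(sweep(coords(x), 2, centroid) %*% normal),
                        reskey, mean)
    keep <- rel > exposure_cutoff
    d <- as.numeric(depth_res)[keep]
    w <- as.numeric(hyd)[keep]
    total <- sum(w)
    offsets <- seq(floor(min(d)), ceiling(max(d)), by = 0.5)
    halves <- seq(10, 25, by = 0.5)
    best <- list(score = -Inf)
    for (off in offsets) {
        ad <- abs(d - off)
        for (hh in halves) {
            sin_ <- sum(w[ad <= hh])
            score <- 2 * sin_ - total    # = sum(inside) - sum(outside)
            if (score > best$score)
                best <- list(score = score, off = off, half = hh,
                             inside = sin_)
        }
    }
    # confidence floor: the slab must actually contain net hydrophobic
    # mass; an all-polar structure maximises the objective by covering as
    # little hydropathy as possible and is flagged
    structure(list(normal = normal, center_offset = best$off,
                   half_thickness = best$half,
                   center_point = centroid + best$off * normal,
                   fit_score = best$score,
                   inside_hydropathy = best$inside,
                   low_confidence = best$inside <= 0),
              class = "membraneSlab")
}

#' @export
print.membraneSlab <- function(x, ...) {
    cat(sprintf(
        "Membrane slab: half-thickness %.1f A, centre offset %.1f A,\n  normal (%s), fit score %.1f%s\n",
        x$half_thickness, x$center_offset,
        paste(sprintf("%.2f", x$normal), collapse = ", "), x$fit_score,
        if (x$low_confidence) " [low confidence]" else ""))
    invisible(x)
}

#' Structural environment of one residue
#'
#' Collects the features that drive variant categorisation: signed depth in
#' the membrane (angstrom from the slab centre along the normal), distance
#' to the nearer slab face, relative solvent accessibility (residue SASA
#' over the free-residue reference, capped at 1.2), distance from the
#' residue centroid to the substrate pocket centre, and whether the side
#' chain points away from the bundle axis into the lipid (`lipid_facing`:
#' positive radial component of the C-alpha to side-chain-centroid vector
#' and relative accessibility above `burial_cutoff`). Glycine has no side
#' chain; its centroid falls back to the C-alpha and the result is flagged.
#'
#' @param x a [Structure-class].
#' @param chain,resno residue address (author numbering).
#' @param slab a [placeMembraneSlab()] result.
#' @param pocket_center 3-vector: substrate pocket centre (ligand centroid
#'   or cleft midpoint).
#' @param burial_cutoff relative-accessibility threshold used in the
#'   lipid-facing test.
#' @param helix_context is the residue in regular secondary structure
#'   (helix or strand), where glycine substitutions destabilise?
#' @param sasa_areas optional precomputed per-atom [sasa()] vector for `x`
#'   (recomputed when missing).
#' @return A list of class `"residueEnvironment"` with fields `depth`,
#'   `boundary_distance`, `relative_burial`, `pocket_distance`,
#'   `lipid_facing`, `helix_context`, `glycine_fallback`.
#' @export
residueEnvironment <- function(x, chain, resno, slab, pocket_center,
                               burial_cutoff = 0.2, helix_context = TRUE,
                               sasa_areas = NULL) {
    at <- atomRecords(x)
    idx <- which(at$chain == chain & at$resno == resno & !at$hetero)
    if (!length(idx)) stop("residue ", chain, ":", resno, " not found")
    ica <- idx[at$name[idx] == "CA"]
    if (length(ica) != 1L) stop("residue ", chain, ":", resno,
                                " lacks a unique C-alpha")
    xyz <- coords(x)
    sc <- idx[!at$name[idx] %in% c("N", "CA", "C", "O")]
    gly <- !length(sc)
    sc_centroid <- if (gly) xyz[ica, ]
                   else colMeans(xyz[sc, , drop = FALSE])
    res_centroid <- colMeans(xyz[idx, , drop = FALSE])
    depth <- sum((res_centroid - slab$center_point) * slab$normal)
    boundary <- abs(slab$half_thickness - abs(depth))
    if (is.null(sasa_areas)) sasa_areas <- sasa(x)
    res_area <- sum(sasa_areas[idx])
    ref <- maxAccessibleArea()[at$resname[ica]]
    if (is.na(ref)) ref <- mean(maxAccessibleArea())
    rel <- min(1.2, res_area / ref)
    # radial direction: component of (CA - axis point) orthogonal to normal
    ca_rel <- xyz[ica, ] - slab$center_point
    radial <- ca_rel - sum(ca_rel * slab$normal) * slab$normal
    rn <- vnorm(radial)
    facing <- if (gly || rn == 0) FALSE
              else sum((sc_centroid - xyz[ica, ]) * radial / rn) > 0
    structure(list(chain = chain, resno = resno,
                   resname = at$resname[ica],
                   depth = depth, boundary_distance = boundary,
                   relative_burial = rel,
                   pocket_distance = vnorm(res_centroid - pocket_center),
                   lipid_facing = facing && rel > burial_cutoff,
                   helix_context = helix_context,
                   glycine_fallback = gly,
                   half_thickness = slab$half_thickness),
              class = "residueEnvironment")
}

#' Reference maximum accessible surface areas per residue
#'
#' Theoretical maximum accessible areas (square angstrom) of residue X in
#' an extended Gly-X-Gly context, used to normalise residue SASA into
#' relative accessibility.
#'
#' @return Named numeric vector over 3-letter residue codes.
#' @export
maxAccessibleArea <- function() {
    c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
      GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
      MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
      TYR = 263, VAL = 174)
}
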