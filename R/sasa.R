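# Shrake-Rupley solvent-accessible surface area with deterministic
# generalized-spiral sphere points (no RNG, exactly reproducible).

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic generalized-spiral (golden-angle) point set used for both
#' SASA sampling and Q-score shell sampling.
#'
#' @param n number of points (>= 1).
#' @return `n` x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
    stopifnot(n >= 1L)
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- pi * (1 + sqrt(5)) * i
    cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' SASA parameter record
#'
#' @param probe_radius solvent probe radius (angstrom; 1.4 = water).
#' @param n_sphere_points points per atomic sphere (>= 92).
#' @param radii a [radiiTable()].
#' @return A list of class `"sasaParams"`.
#' @export
sasaParams <- function(probe_radius = 1.4, n_sphere_points = 960L,
                       radii = radiiTable()) {
    stopifnot(probe_radius >= 0, n_sphere_points >= 92L)
    structure(list(probe_radius = probe_radius,
                   n_sphere_points = as.integer(n_sphere_points),
                   radii = radii),
              class = "sasaParams")
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of `n_sphere_points` quasi-uniform points on
#' its probe-expanded sphere (radius vdw + probe) that fall inside no
#' neighbouring atom's expanded sphere, times the expanded-sphere area
#' `4 * pi * (vdw + probe)^2`.
#'
#' @param x a [Structure-class].
#' @param params a [sasaParams()].
#' @return Numeric vector of per-atom areas (square angstrom), one per atom
#'   of `x`, with attribute `total`.
#' @examples
#' at <- data.frame(serial = 1L, name = "C", element = "C", resname = "LIG",
#'                  resno = 1L, chain = "A", x = 0, y = 0, z = 0,
#'                  hetero = TRUE)
#' sasa(Structure(at))        # ~ 4 * pi * 3.1^2
#' @export
sasa <- function(x, params = sasaParams()) {
    stopifnot(inherits(params, "sasaParams"))
    xyz <- coords(x)
    n <- nrow(xyz)
    R <- atomRecords(x)$vdw + params$probe_radius
    pts <- spherePoints(params$n_sphere_points)
    maxR <- max(R)
    areas <- numeric(n)
    for (i in seq_len(n)) {
        # neighbours whose expanded sphere can occlude points of sphere i
        d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
              (xyz[, 3] - xyz[i, 3])^2
        nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
        if (!length(nb)) {
            areas[i] <- 4 * pi * R[i]^2
            next
        }
        sp <- sweep(pts * R[i], 2, xyz[i, ], "+")
        free <- rep(TRUE, nrow(sp))
        for (j in nb) {
            if (!any(free)) break
            dj2 <- (sp[free, 1] - xyz[j, 1])^2 +
                   (sp[free, 2] - xyz[j, 2])^2 +
                   (sp[free, 3] - xyz[j, 3])^2
            free[free] <- dj2 >= R[j]^2
        }
        areas[i] <- 4 * pi * R[i]^2 * mean(free)
    }
    attr(areas, "total") <- sum(areas)
    areas
}

#' Buried interface area between two atom groups
#'
#' The standard buried-area definition:
#' `(SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2`, computed with
#' only the union's atoms present -- atoms outside both groups are excluded
#' from the calculation entirely, which matters and is therefore stated:
#' a group's "isolated" SASA is its SASA extracted from the assembly, not
#' its SASA in the context of the remaining chains.
#'
#' @param x a [Structure-class].
#' @param group_a,group_b named [selectAtoms()] argument lists; must be
#'   non-empty and disjoint.
#' @param params a [sasaParams()].
#' @return A list of class `"interfaceReport"`: `buried_area` (square
#'   angstrom), `per_residue` (named contributions summing to
#'   `buried_area`), plus the group sizes.
#' @export
buriedArea <- function(x, group_a, group_b, params = sasaParams()) {
    ia <- do.call(selectAtoms, c(list(x), group_a))
    ib <- do.call(selectAtoms, c(list(x), group_b))
    if (!length(ia) || !length(ib))
        stop("both groups must select at least one atom")
    if (length(intersect(ia, ib)))
        stop("groups overlap: buried area between a group and itself is ",
             "not defined")
    sa <- sasa(subsetStructure(x, ia), params)
    sb <- sasa(subsetStructure(x, ib), params)
    u <- subsetStructure(x, c(ia, ib))
    su <- sasa(u, params)
    lost <- c(sa, sb) - su              # per-atom area lost on binding
    buried <- sum(lost) / 2
    at <- atomRecords(u)
    res <- paste0(at$chain, ":", at$resname, at$resno)
    per_res <- tapply(lost / 2, res, sum)
    structure(list(buried_area = buried,
                   per_residue = per_res[per_res != 0],
                   n_atoms_a = length(ia), n_atoms_b = length(ib),
                   params = list(probe_radius = params$probe_radius,
                                 n_sphere_points = params$n_sphere_points,
                                 radii = params$radii$name)),
              class = "interfaceReport")
}

#' @export
print.interfaceReport <- function(x, ...) {
    cat(sprintf("Buried interface: %.1f A^2 (%d + %d atoms, %d sphere points)\n",
                x$buried_area, x$n_atoms_a, x$n_atoms_b,
                x$params$n_sphere_points))
    invisible(x)
}
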