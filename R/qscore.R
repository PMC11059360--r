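# Map-model Q-score: per-atom correlation between density sampled around
# the atom and a reference Gaussian of fixed width. 1 means the local
# density is exactly a Gaussian of the reference width centred on the atom;
# ~0.6 is typical of a correct model at 3-3.5 A resolution.

#' Trilinear interpolation of a density map
#'
#' @param map a [DensityMap-class].
#' @param points n x 3 matrix of Cartesian positions (angstrom).
#' @return Numeric vector of interpolated values; `NA` for points outside
#'   the grid.
#' @export
interpolateMap <- function(map, points) {
    v <- mapValues(map)
    d <- dim(v)
    g <- sweep(sweep(points, 2, mapOrigin(map)), 2, voxelSize(map), "/") + 1
    i0 <- floor(g)
    f <- g - i0
    ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
          i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
          i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
    out <- rep(NA_real_, nrow(points))
    if (!any(ok)) return(out)
    i0 <- i0[ok, , drop = FALSE]; f <- f[ok, , drop = FALSE]
    idx <- function(dx, dy, dz)
        cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
    out[ok] <-
        v[idx(0, 0, 0)] * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
        v[idx(1, 0, 0)] * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
        v[idx(0, 1, 0)] * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
        v[idx(0, 0, 1)] * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
        v[idx(1, 1, 0)] * f[, 1] * f[, 2] * (1 - f[, 3]) +
        v[idx(1, 0, 1)] * f[, 1] * (1 - f[, 2]) * f[, 3] +
        v[idx(0, 1, 1)] * (1 - f[, 1]) * f[, 2] * f[, 3] +
        v[idx(1, 1, 1)] * f[, 1] * f[, 2] * f[, 3]
    out
}

#' Q-score parameter record
#'
#' @param shell_radii radii of the concentric sampling shells (angstrom),
#'   strictly increasing; default 0.1 to 2.0 in 0.1 steps.
#' @param min_points,max_points points per shell (deterministic spiral),
#'   scaled with shell radius between these bounds.
#' @param reference_sigma width (angstrom) of the reference Gaussian; 0.6
#'   is the published convention for maps in the ~1.5-3 A range.
#' @return A list of class `"qscoreParams"`.
#' @export
qscoreParams <- function(shell_radii = seq(0.1, 2.0, by = 0.1),
                         min_points = 8L, max_points = 32L,
                         reference_sigma = 0.6) {
    stopifnot(all(diff(shell_radii) > 0), min_points >= 1L,
              max_points >= min_points, reference_sigma > 0)
    structure(list(shell_radii = shell_radii,
                   min_points = as.integer(min_points),
                   max_points = as.integer(max_points),
                   reference_sigma = reference_sigma),
              class = "qscoreParams")
}

#' Map-model Q-score
#'
#' For each selected atom, samples the map (trilinear interpolation) at the
#' atom centre and on concentric spherical shells around it, discards
#' sample points that lie closer to any other model atom than to the probe
#' atom (so neighbouring density does not inflate the score), and computes
#' the Pearson correlation between the sampled values and a reference
#' Gaussian `exp(-d^2 / (2 sigma^2))` of the shell distances. Correlation
#' is scale-free, so the reference needs no amplitude fitting. Atoms whose
#' samples have zero variance (flat map) score 0 and are flagged; atoms
#' outside the map are excluded with a warning.
#'
#' @param map a [DensityMap-class].
#' @param x a [Structure-class] whose atoms define both the probe set and
#'   the occlusion set.
#' @param selection named [selectAtoms()] argument list for the scored
#'   atoms (default: all atoms).
#' @param params a [qscoreParams()].
#' @return A list of class `"qscoreReport"`: `per_atom` (data.frame with
#'   atom descriptors, `q` and `flag`), `per_residue` (mean q per residue)
#'   and `selection_q` (mean over scored atoms).
#' @seealso [ligandQ()], [renderDensity()]
#' @export
qScore <- function(map, x, selection = list(), params = qscoreParams()) {
    stopifnot(inherits(params, "qscoreParams"))
    sel <- do.call(selectAtoms, c(list(x), selection))
    if (!length(sel)) stop("empty selection")
    at <- atomRecords(x)
    xyz <- coords(x)
    qs <- rep(NA_real_, length(sel))
    flags <- character(length(sel))
    for (k in seq_along(sel)) {
        i <- sel[k]
        pos <- rbind(xyz[i, ])
        dists <- 0
        for (r in params$shell_radii) {
            npt <- max(params$min_points,
                       min(params$max_points,
                           ceiling(params$max_points * r /
                                   max(params$shell_radii))))
            sp <- sweep(spherePoints(npt) * r, 2, xyz[i, ], "+")
            pos <- rbind(pos, sp)
            dists <- c(dists, rep(r, npt))
        }
        # occlusion: keep points nearer to atom i than to any other atom
        keep <- rep(TRUE, nrow(pos))
        d2i <- dists^2
        near <- which((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
                      (xyz[, 3] - xyz[i, 3])^2 <=
                      (2 * max(params$shell_radii))^2)
        for (j in setdiff(near, i)) {
            d2j <- (pos[, 1] - xyz[j, 1])^2 + (pos[, 2] - xyz[j, 2])^2 +
                   (pos[, 3] - xyz[j, 3])^2
            keep <- keep & d2j >= d2i
        }
        vals <- interpolateMap(map, pos[keep, , drop = FALSE])
        ref <- exp(-dists[keep]^2 / (2 * params$reference_sigma^2))
        if (anyNA(vals)) {
            flags[k] <- "outside_map"
            next
        }
        spread <- diff(range(vals))
        if (spread <= 1e-9 * max(1, abs(mean(vals))) ||
            stats::sd(ref) == 0) {
            qs[k] <- 0
            flags[k] <- "zero_variance"
            next
        }
        qs[k] <- stats::cor(vals, ref)
        flags[k] <- "ok"
    }
    if (any(flags == "outside_map"))
        warning(sum(flags == "outside_map"),
                " atom(s) outside the map excluded from Q-score",
                call. = FALSE)
    per_atom <- data.frame(chain = at$chain[sel], resno = at$resno[sel],
                           resname = at$resname[sel], name = at$name[sel],
                           q = qs, flag = flags, stringsAsFactors = FALSE)
    scored <- !is.na(qs)
    res_key <- paste0(per_atom$chain, ":", per_atom$resname,
                      per_atom$resno)
    per_res <- tapply(qs[scored], res_key[scored], mean)
    structure(list(per_atom = per_atom,
                   per_residue = per_res,
                   selection_q = mean(qs[scored]),
                   reference_sigma = params$reference_sigma),
              class = "qscoreReport")
}

#' @export
print.qscoreReport <- function(x, ...) {
    cat(sprintf("Q-score: %.3f over %d atom(s) (reference sigma %.2f A)\n",
                x$selection_q, sum(!is.na(x$per_atom$q)),
                x$reference_sigma))
    invisible(x)
}

#' Q-score of a ligand
#'
#' [qScore()] restricted to a ligand selection; the whole model still
#' provides the occlusion set.
#'
#' @inheritParams qScore
#' @param ligand named [selectAtoms()] argument list for the ligand.
#' @return Numeric scalar: the ligand's mean Q.
#' @export
ligandQ <- function(map, x, ligand, params = qscoreParams()) {
    qScore(map, x, selection = ligand, params = params)$selection_q
}
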