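#' Sample points along a translocation-pore path
#'
#' Default path construction: a straight line between two anchor points
#' (e.g. a terminus point on the cytosolic side and one on the
#' extracellular side, passing through the substrate pocket), sampled every
#' `spacing` angstrom. Arbitrary waypoint paths may be supplied instead; in
#' both cases consecutive samples are at most 1 A apart. Points are ordered
#' from the first anchor to the last, and the open/closed classification
#' interprets the first point as the cytosolic terminus.
#'
#' @param from,to 3-vectors (angstrom): path anchors (axis definition).
#' @param spacing sample spacing (angstrom, <= 1).
#' @param waypoints optional n x 3 matrix of user waypoints overriding the
#'   straight axis; resampled at `spacing` along each segment.
#' @return A list of class `"porePath"` with `points` (n x 3), `s`
#'   (arc-length coordinate) and `spacing`.
#' @export
porePath <- function(from, to, spacing = 0.5, waypoints = NULL) {
    stopifnot(spacing > 0, spacing <= 1)
    anchors <- if (is.null(waypoints)) rbind(from, to)
               else as.matrix(waypoints)
    stopifnot(ncol(anchors) == 3L, nrow(anchors) >= 2L)
    pts <- list(anchors[1, , drop = FALSE])
    s <- 0
    for (i in seq_len(nrow(anchors) - 1L)) {
        a <- anchors[i, ]; b <- anchors[i + 1L, ]
        len <- vnorm(b - a)
        if (len == 0) next
        nseg <- ceiling(len / spacing)
        frac <- seq_len(nseg) / nseg
        seg <- outer(1 - frac, a) + outer(frac, b)
        pts <- c(pts, list(seg))
        s <- c(s, s[length(s)] + frac * len)
    }
    points <- do.call(rbind, pts)
    dimnames(points) <- list(NULL, c("x", "y", "z"))
    structure(list(points = points, s = s, spacing = spacing),
              class = "porePath")
}

#' Pore-radius profile along a path
#'
#' At every path point the radius of the largest sphere centred there that
#' does not penetrate any atom's van der Waals sphere:
#' `max(0, min_a(|p - pos(a)| - vdw(a)))`. Points inside an atom clamp to
#' zero. The reference implementation scans all atoms per point; the
#' `"grid"` method uses a cell-list with an expanding-shell search and a
#' provable pruning bound, and returns exactly the same radii.
#'
#' @param x a [Structure-class].
#' @param path a [porePath()].
#' @param method `"brute"` (reference) or `"grid"` (accelerated, exact).
#' @param warn_outside warn when path points fall outside the structure's
#'   bounding box.
#' @return A list of class `"poreProfile"`: `profile` (data.frame with
#'   `s`, `x`, `y`, `z`, `radius_A`), `min_radius`, `min_location`.
#' @examples
#' s <- buildToyBundle(bundleSpec(seed = 1))
#' pp <- poreProfile(s, porePath(c(0, 0, -25), c(0, 0, 25)))
#' pp$min_radius
#' @export
poreProfile <- function(x, path, method = c("brute", "grid"),
                        warn_outside = TRUE) {
    method <- match.arg(method)
    stopifnot(inherits(path, "porePath"))
    if (nAtoms(x) < 1L) stop("empty structure")
    xyz <- coords(x)
    vdw <- atomRecords(x)$vdw
    p <- path$points
    if (warn_outside) {
        lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
        outside <- p[, 1] < lo[1] | p[, 1] > hi[1] |
                   p[, 2] < lo[2] | p[, 2] > hi[2] |
                   p[, 3] < lo[3] | p[, 3] > hi[3]
        if (any(outside))
            warning(sum(outside), " path point(s) outside the structure's ",
                    "bounding box", call. = FALSE)
    }
    radius <- if (method == "brute") poreRadiiBrute(p, xyz, vdw)
              else poreRadiiGrid(p, xyz, vdw)
    imin <- which.min(radius)
    prof <- data.frame(s = path$s, x = p[, 1], y = p[, 2], z = p[, 3],
                       radius_A = radius)
    structure(list(profile = prof, min_radius = radius[imin],
                   min_location = p[imin, ], method = method),
              class = "poreProfile")
}

poreRadiiBrute <- function(p, xyz, vdw) {
    vapply(seq_len(nrow(p)), function(i) {
        d <- sqrt((xyz[, 1] - p[i, 1])^2 + (xyz[, 2] - p[i, 2])^2 +
                  (xyz[, 3] - p[i, 3])^2) - vdw
        max(0, min(d))
    }, numeric(1))
}

# Cell-list accelerated exact search: expanding Chebyshev shells of cells;
# a shell at index s can only contain atoms at Euclidean distance
# >= (s - 1) * h from the query, so once (s - 1) * h - max(vdw) exceeds the
# best clearance found the scan stops without changing the result.
poreRadiiGrid <- function(p, xyz, vdw, h = 4) {
    lo <- apply(xyz, 2, min)
    ci <- floor(sweep(xyz, 2, lo) / h) + 1L
    ncell <- apply(ci, 2, max)
    key <- (ci[, 1] - 1L) + ncell[1] * ((ci[, 2] - 1L) +
            ncell[2] * (ci[, 3] - 1L))
    cells <- split(seq_len(nrow(xyz)), key)
    maxv <- max(vdw)
    vapply(seq_len(nrow(p)), function(i) {
        pc <- floor((p[i, ] - lo) / h) + 1L
        maxshell <- max(abs(pc - 1L), abs(pc - ncell)) + 1L
        best <- Inf
        for (s in 0:maxshell) {
            if ((s - 1) * h - maxv >= best) break
            idx <- shellCells(pc, s, ncell)
            for (k in idx) {
                atoms <- cells[[as.character(k)]]
                if (is.null(atoms)) next
                d <- sqrt((xyz[atoms, 1] - p[i, 1])^2 +
                          (xyz[atoms, 2] - p[i, 2])^2 +
                          (xyz[atoms, 3] - p[i, 3])^2) - vdw[atoms]
                best <- min(best, d)
            }
        }
        max(0, best)
    }, numeric(1))
}

# linear keys of grid cells at Chebyshev distance exactly s from centre pc
shellCells <- function(pc, s, ncell) {
    rng <- lapply(1:3, function(d) {
        lo <- max(1L, pc[d] - s); hi <- min(ncell[d], pc[d] + s)
        if (lo > hi) integer(0) else lo:hi
    })
    if (any(!lengths(rng))) return(integer(0))
    g <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    cheb <- pmax(abs(g[, 1] - pc[1]), abs(g[, 2] - pc[2]),
                 abs(g[, 3] - pc[3]))
    g <- g[cheb == s, , drop = FALSE]
    (g[, 1] - 1L) + ncell[1] * ((g[, 2] - 1L) + ncell[2] * (g[, 3] - 1L))
}

#' @export
print.poreProfile <- function(x, ...) {
    cat(sprintf("Pore profile (%s): %d points, min radius %.2f A at (%s)\n",
                x$method, nrow(x$profile), x$min_radius,
                paste(sprintf("%.1f", x$min_location), collapse = ", ")))
    invisible(x)
}

#' Open/closed classification of a pore profile
#'
#' A membrane side is "open" when every radius on the contiguous path
#' segment from the substrate pocket to that terminus is strictly larger
#' than the threshold -- by default 1.8 A, the theoretical radius of an
#' unhydrated chloride ion. A radius exactly at the threshold counts as
#' closed. The path's first point is taken as the cytosolic terminus.
#'
#' @param profile a [poreProfile()] result.
#' @param pocket_index index of the pocket sample point along the path.
#' @param threshold open-pore radius threshold (angstrom, > 0).
#' @return Named character vector
#'   `c(cytosolic = "open"|"closed", extracellular = "open"|"closed")`.
#' @export
classifyPore <- function(profile, pocket_index, threshold = 1.8) {
    stopifnot(inherits(profile, "poreProfile"), threshold > 0)
    r <- profile$profile$radius_A
    stopifnot(pocket_index >= 1L, pocket_index <= length(r))
    openside <- function(seg) if (all(seg > threshold)) "open" else "closed"
    c(cytosolic = openside(r[seq_len(pocket_index)]),
      extracellular = openside(r[pocket_index:length(r)]))
}

#' Write a pore profile TSV
#'
#' @param profile a [poreProfile()] result.
#' @param path output path; columns `s_along_path_A, x, y, z, radius_A`.
#' @return `path`, invisibly.
#' @export
writePoreProfile <- function(profile, path) {
    tab <- profile$profile
    names(tab)[1] <- "s_along_path_A"
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
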