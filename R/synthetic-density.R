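#' Render a synthetic Gaussian density map from a structure
#'
#' Sums an isotropic Gaussian of standard deviation `sigma` at every atom
#' position onto a regular grid covering the structure plus `padding`. This
#' is the oracle generator for map-model quality scoring: a structure scored
#' against its own rendered map (with matching reference sigma) must give a
#' Q-score of ~1.
#'
#' @param x a [Structure-class].
#' @param sigma Gaussian standard deviation (angstrom, > 0).
#' @param voxel grid spacing (angstrom, > 0). A warning is issued when
#'   `voxel > 2 * sigma` (the Gaussian is then undersampled).
#' @param padding margin (angstrom) added around the structure's bounding
#'   box.
#' @param weight per-atom amplitude (scalar or one value per atom).
#' @return A [DensityMap-class].
#' @examples
#' s <- buildToyBundle(bundleSpec(n_helices = 3, helix_length = 6, seed = 1))
#' m <- renderDensity(s, sigma = 0.6, voxel = 0.5)
#' m
#' @export
renderDensity <- function(x, sigma = 0.6, voxel = 0.5, padding = 4,
                          weight = 1) {
    stopifnot(sigma > 0, voxel > 0, padding >= 0)
    if (voxel > 2 * sigma)
        warning("voxel (", voxel, " A) exceeds 2*sigma (", 2 * sigma,
                " A): rendered density is undersampled", call. = FALSE)
    xyz <- coords(x)
    weight <- rep_len(weight, nrow(xyz))
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    gx <- lo[1] + (seq_len(dims[1]) - 1) * voxel
    gy <- lo[2] + (seq_len(dims[2]) - 1) * voxel
    gz <- lo[3] + (seq_len(dims[3]) - 1) * voxel
    vals <- array(0, dim = dims)
    cutoff <- 4 * sigma
    inv2s2 <- 1 / (2 * sigma^2)
    for (a in seq_len(nrow(xyz))) {
        ix <- which(abs(gx - xyz[a, 1]) <= cutoff)
        iy <- which(abs(gy - xyz[a, 2]) <= cutoff)
        iz <- which(abs(gz - xyz[a, 3]) <= cutoff)
        if (!length(ix) || !length(iy) || !length(iz)) next
        ex <- exp(-(gx[ix] - xyz[a, 1])^2 * inv2s2)
        ey <- exp(-(gy[iy] - xyz[a, 2])^2 * inv2s2)
        ez <- exp(-(gz[iz] - xyz[a, 3])^2 * inv2s2)
        vals[ix, iy, iz] <- vals[ix, iy, iz] +
            weight[a] * (ex %o% ey %o% ez)
    }
    DensityMap(vals, voxel = voxel, origin = lo)
}
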