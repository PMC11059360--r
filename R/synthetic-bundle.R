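#' Specification for a synthetic transmembrane helical bundle
#'
#' Parameter record for [buildToyBundle()]. The bundle emulates the features
#' of a transporter TMD that the geometry stages rely on: an axial substrate
#' cleft of controllable radius, a hydrophobic membrane belt, and
#' lipid-facing vs cleft-facing side chains. Defaults give a 6-helix bundle
#' whose axial pore has a minimum radius of `cleft_radius`.
#'
#' @param n_helices number of helices (>= 3).
#' @param helix_length residues per helix.
#' @param ring_radius clearance (angstrom) between the helix-axis ring and
#'   the pore surface; the helix axes sit at `ring_radius + cleft_radius`
#'   from the bundle (z) axis. The default 5.5 A equals the helix radius
#'   (2.3) plus the side-chain offset (1.5) plus a carbon vdW radius (1.7),
#'   so the innermost atom surfaces graze a cylinder of radius
#'   `cleft_radius`.
#' @param cleft_radius target open radius (angstrom) of the axial pore.
#' @param belt_half_thickness hydrophobic belt half-thickness (angstrom);
#'   residues with |z(CA)| inside it get hydrophobic identities.
#' @param seed integer seed driving the (deterministic) residue identities.
#' @return A validated list of class `"bundleSpec"`.
#' @export
bundleSpec <- function(n_helices = 6L, helix_length = 30L,
                       ring_radius = 5.5, cleft_radius = 2.5,
                       belt_half_thickness = 15, seed = 1L) {
    stopifnot(n_helices >= 3L, helix_length >= 4L, cleft_radius >= 0,
              belt_half_thickness > 0, ring_radius > 0)
    structure(list(n_helices = as.integer(n_helices),
                   helix_length = as.integer(helix_length),
                   ring_radius = ring_radius, cleft_radius = cleft_radius,
                   belt_half_thickness = belt_half_thickness,
                   seed = as.integer(seed)),
              class = "bundleSpec")
}

# one-letter -> three-letter code maps used across the package
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

#' Build a synthetic alpha-helical bundle with an axial cleft
#'
#' Constructs ideal alpha-helices (1.5 A rise and 100 degrees twist per
#' residue, C-alpha helix radius 2.3 A) whose axes stand on a ring of radius
#' `ring_radius + cleft_radius` around the z-axis, leaving an axial pore of
#' minimum radius ~`cleft_radius`. Each residue gets a C-alpha and a
#' pseudo side-chain CB placed 1.5 A further out from the helix axis, so
#' side chains on the outer face point away from the bundle axis
#' (lipid-facing) and those on the inner face line the cleft. Residues
#' inside the membrane belt (|z| <= `belt_half_thickness`) receive
#' hydrophobic identities (LEU/ILE/VAL/PHE), all others polar ones
#' (SER/ASN/GLU/LYS), sampled deterministically from `spec$seed`. Helix
#' phases are staggered so inward-pointing side chains sample the pore wall
#' densely along z.
#'
#' @param spec a [bundleSpec()].
#' @return A [Structure-class]; chains "A", "B", ... are one helix each,
#'   residues numbered 1..`helix_length` per chain.
#' @examples
#' s <- buildToyBundle(bundleSpec(seed = 7))
#' s
#' @export
buildToyBundle <- function(spec) {
    stopifnot(inherits(spec, "bundleSpec"))
    r_axis <- spec$ring_radius + spec$cleft_radius
    if (r_axis <= 3.8)
        stop("bundleSpec places helices overlapping the bundle axis ",
             "(ring_radius + cleft_radius must exceed 3.8 A)")
    nres <- spec$helix_length
    zs <- (seq_len(nres) - (nres + 1) / 2) * 1.5
    hydro <- c("LEU", "ILE", "VAL", "PHE")
    polar <- c("SER", "ASN", "GLU", "LYS")
    rows <- withr::with_seed(spec$seed, {
        lapply(seq_len(spec$n_helices), function(h) {
            theta <- 2 * pi * (h - 1) / spec$n_helices
            u <- c(cos(theta), sin(theta), 0)       # radial unit
            v <- c(-sin(theta), cos(theta), 0)      # tangential unit
            axis_pt <- r_axis * u
            # stagger phases so the inward direction is swept along z
            phi0 <- pi + (h - 1) * (100 * pi / 180) / spec$n_helices
            phi <- phi0 + (seq_len(nres) - 1) * 100 * pi / 180
            ca <- t(vapply(seq_len(nres), function(j)
                axis_pt + 2.3 * (cos(phi[j]) * u + sin(phi[j]) * v) +
                    c(0, 0, zs[j]), numeric(3)))
            cb <- t(vapply(seq_len(nres), function(j)
                axis_pt + 3.8 * (cos(phi[j]) * u + sin(phi[j]) * v) +
                    c(0, 0, zs[j]), numeric(3)))
            in_belt <- abs(zs) <= spec$belt_half_thickness
            resn <- ifelse(in_belt,
                           sample(hydro, nres, replace = TRUE),
                           sample(polar, nres, replace = TRUE))
            data.frame(
                name = rep(c("CA", "CB"), each = nres),
                element = "C",
                resname = rep(resn, 2),
                resno = rep(seq_len(nres), 2),
                chain = LETTERS[h],
                x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
                z = c(ca[, 3], cb[, 3]),
                hetero = FALSE, stringsAsFactors = FALSE)
        })
    })
    at <- do.call(rbind, rows)
    ord <- order(at$chain, at$resno, match(at$name, c("CA", "CB")))
    at <- at[ord, , drop = FALSE]
    at$serial <- seq_len(nrow(at))
    Structure(at, title = sprintf("toy %d-helix bundle, cleft %.2f A",
                                  spec$n_helices, spec$cleft_radius))
}

#' Generate a synthetic missense variant table on a structure
#'
#' Draws `n` residues of chain A spanning the three structural contexts the
#' classifier distinguishes -- lipid-facing belt residues, cleft-lining
#' residues and the remaining (buried/other) residues -- and emits missense
#' records whose substitutions are chosen to exercise the corresponding
#' category rules (hydrophobic-to-charged at the belt, to-arginine at the
#' cleft, to-proline/bulky elsewhere). Deterministic given `seed`.
#'
#' @param x a [Structure-class] from [buildToyBundle()].
#' @param n number of records (>= 1, at most the chain-A residue count).
#' @param seed integer seed.
#' @param belt_half_thickness belt used to label contexts (angstrom).
#' @return `data.frame` with columns `gene`, `protein_change`,
#'   `clinical_significance`, `chain` and `context`.
#' @export
makeVariantFixture <- function(x, n, seed = 1L, belt_half_thickness = 15) {
    at <- atomRecords(x)
    ca <- at[at$name == "CA" & at$chain == "A", , drop = FALSE]
    if (n < 1L || n > nrow(ca))
        stop("n must be between 1 and the chain-A residue count (",
             nrow(ca), ")")
    cb <- at[at$name == "CB" & at$chain == "A", , drop = FALSE]
    cb <- cb[match(ca$resno, cb$resno), , drop = FALSE]
    radial <- cbind(ca$x, ca$y, 0)
    sc_vec <- cbind(cb$x - ca$x, cb$y - ca$y, cb$z - ca$z)
    outward <- rowSums(radial * sc_vec) > 0
    in_belt <- abs(ca$z) <= belt_half_thickness
    r_cb <- sqrt(cb$x^2 + cb$y^2)
    # belt = side chain on the outer bundle surface (not wedged between
    # helices), so downstream environments see it as solvent/lipid exposed
    outer <- r_cb >= stats::quantile(r_cb, 0.7)
    context <- ifelse(in_belt & outward & outer, "belt",
                      ifelse(!outward & r_cb < stats::median(r_cb), "cleft",
                             "core"))
    withr::with_seed(seed, {
        idx <- unlist(lapply(split(seq_len(nrow(ca)), context), function(i)
            sample(i, min(length(i), ceiling(n / 3)))))
        idx <- sample(idx, min(n, length(idx)))
        if (length(idx) < n)
            idx <- c(idx, sample(setdiff(seq_len(nrow(ca)), idx),
                                 n - length(idx)))
        ref1 <- AA1[ca$resname[idx]]
        alt1 <- vapply(seq_along(idx), function(k) {
            pool <- switch(context[idx[k]],
                           belt = c("K", "D", "E", "R"),
                           cleft = "R",
                           core = c("P", "W", "F"))
            pool <- setdiff(pool, ref1[k])
            sample(pool, 1L)
        }, character(1))
        out <- data.frame(
            gene = "TOY",
            protein_change = paste0(ref1, ca$resno[idx], alt1),
            clinical_significance = "Pathogenic",
            chain = "A", context = context[idx],
            stringsAsFactors = FALSE)
        out[order(as.integer(ca$resno[idx])), , drop = FALSE]
    })
}
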