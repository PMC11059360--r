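# Structure-based categorisation of pathogenic missense variants into the
# mechanistic classes used for SLC26A2: substrate-site, lipid-interface,
# fold-destabilising, or unexplained.

#' Standard residue side-chain volumes
#'
#' @return Named numeric vector (cubic angstrom) over one-letter codes.
#' @export
residueVolumes <- function() {
    c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
      E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
      M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
      Y = 193.6, V = 140.0)
}

#' Formal side-chain charges at pH 7
#'
#' @return Named numeric vector over one-letter codes (D/E = -1, K/R = +1,
#'   all others including histidine 0).
#' @export
formalCharges <- function() {
    ch <- stats::setNames(rep(0, 20), names(residueVolumes()))
    ch[c("D", "E")] <- -1
    ch[c("K", "R")] <- 1
    ch
}

#' Physicochemical deltas of an amino-acid substitution
#'
#' Differences (alt minus ref) of Kyte-Doolittle hydropathy, formal charge
#' at pH 7 and residue volume, plus special flags: substitution to proline,
#' to glycine, and loss of a hydrogen-bonding side chain (optional input,
#' from an H-bond census on the reference structure).
#'
#' @param ref_aa,alt_aa one-letter codes (must differ; standard residues).
#' @param hydropathy hydropathy scale (named, one-letter codes).
#' @param hbond_loss does the substitution remove a side chain that
#'   participates in >= 2 hydrogen bonds in the reference structure?
#' @return A list of class `"substitutionDeltas"`: `hydropathy_delta`,
#'   `charge_delta`, `volume_delta`, `to_pro`, `to_gly`, `hbond_loss`.
#' @examples
#' substitutionDeltas("I", "T")$hydropathy_delta   # -5.2
#' @export
substitutionDeltas <- function(ref_aa, alt_aa,
                               hydropathy = hydropathyScale(),
                               hbond_loss = FALSE) {
    aa <- names(residueVolumes())
    if (!ref_aa %in% aa || !alt_aa %in% aa)
        stop("non-standard amino acid code: ", ref_aa, "/", alt_aa)
    if (ref_aa == alt_aa) stop("ref and alt amino acids must differ")
    structure(list(
        ref_aa = ref_aa, alt_aa = alt_aa,
        hydropathy_delta = unname(hydropathy[alt_aa] - hydropathy[ref_aa]),
        charge_delta = unname(formalCharges()[alt_aa] -
                              formalCharges()[ref_aa]),
        volume_delta = unname(residueVolumes()[alt_aa] -
                              residueVolumes()[ref_aa]),
        to_pro = alt_aa == "P",
        to_gly = alt_aa == "G",
        hbond_loss = isTRUE(hbond_loss)),
        class = "substitutionDeltas")
}

#' Variant-category rule set
#'
#' Ordered decision rules mapping a variant's structural environment and
#' substitution deltas to one of four categories. The thresholds are
#' calibration parameters of this package (they are part of the config
#' contract, recorded in every report), not measured quantities:
#' `pocket_cutoff` 8 A, `boundary_cutoff` 5 A, `burial_cutoff` 0.2
#' relative accessibility, `hydropathy_cutoff` -3, `volume_cutoff` 25
#' cubic angstrom. Rule order (substrate site, then lipid interface, then
#' fold) resolves residues with multiple features deterministically.
#'
#' @param pocket_cutoff,boundary_cutoff,burial_cutoff,hydropathy_cutoff,volume_cutoff
#'   rule thresholds (see description).
#' @return A list of class `"categoryRules"`.
#' @seealso [classifyVariant()]
#' @export
categoryRules <- function(pocket_cutoff = 8, boundary_cutoff = 5,
                          burial_cutoff = 0.2, hydropathy_cutoff = -3,
                          volume_cutoff = 25) {
    structure(list(pocket_cutoff = pocket_cutoff,
                   boundary_cutoff = boundary_cutoff,
                   burial_cutoff = burial_cutoff,
                   hydropathy_cutoff = hydropathy_cutoff,
                   volume_cutoff = volume_cutoff),
              class = "categoryRules")
}

#' Classify a missense variant from its structural context
#'
#' Applies the ordered rules:
#' 1. *substrate_site* -- the residue sits at the substrate pocket
#'    (`pocket_distance <= pocket_cutoff`) or is in the configured
#'    cleft-lining set.
#' 2. *lipid_interface* -- the side chain faces the lipid, the residue is
#'    in or near the membrane (inside the slab, or within
#'    `boundary_cutoff` of a slab face), and the substitution disturbs the
#'    lipid contact (hydropathy drop below `hydropathy_cutoff`, any charge
#'    change, or substitution to helix-breaking proline at the boundary).
#' 3. *fold_destabilizing* -- the residue is buried
#'    (`relative_burial < burial_cutoff`) and the substitution is
#'    disruptive: volume increase above `volume_cutoff`, proline, glycine
#'    in regular secondary structure, hydropathy drop below
#'    `hydropathy_cutoff`, or loss of a multi-H-bond side chain.
#' 4. *unexplained* otherwise.
#'
#' @param env a [residueEnvironment()] (or compatible list).
#' @param deltas a [substitutionDeltas()].
#' @param rules a [categoryRules()].
#' @param cleft_residues optional integer vector of residue numbers that
#'   line the substrate cleft regardless of centroid distance.
#' @return A list with `category` and human-readable `rationale`.
#' @export
classifyVariant <- function(env, deltas, rules = categoryRules(),
                            cleft_residues = integer()) {
    stopifnot(inherits(deltas, "substitutionDeltas"),
              inherits(rules, "categoryRules"))
    lab <- paste0(deltas$ref_aa, env$resno, deltas$alt_aa)
    if (env$pocket_distance <= rules$pocket_cutoff ||
        env$resno %in% cleft_residues) {
        return(list(category = "substrate_site", rationale = sprintf(
            "%s: residue at the substrate pocket (centroid %.1f A from pocket centre, cutoff %.1f A); the substitution alters the binding-site chemistry",
            lab, env$pocket_distance, rules$pocket_cutoff)))
    }
    in_membrane <- abs(env$depth) <= env$half_thickness
    near_boundary <- env$boundary_distance <= rules$boundary_cutoff
    lipid_change <- deltas$hydropathy_delta < rules$hydropathy_cutoff ||
        deltas$charge_delta != 0 || deltas$to_pro
    if (env$lipid_facing && (near_boundary || in_membrane) &&
        lipid_change) {
        return(list(category = "lipid_interface", rationale = sprintf(
            "%s: lipid-facing at depth %.1f A (%.1f A from the slab face); hydropathy delta %.1f, charge delta %+d%s disturb the lipid contact",
            lab, env$depth, env$boundary_distance,
            deltas$hydropathy_delta, as.integer(deltas$charge_delta),
            if (deltas$to_pro) ", proline introduction" else "")))
    }
    buried <- env$relative_burial < rules$burial_cutoff
    disruptive <- deltas$volume_delta > rules$volume_cutoff ||
        deltas$to_pro || (deltas$to_gly && isTRUE(env$helix_context)) ||
        deltas$hydropathy_delta < rules$hydropathy_cutoff ||
        deltas$hbond_loss
    if (buried && disruptive) {
        why <- c(
            if (deltas$volume_delta > rules$volume_cutoff)
                sprintf("volume +%.0f A^3", deltas$volume_delta),
            if (deltas$to_pro) "proline introduction",
            if (deltas$to_gly && isTRUE(env$helix_context))
                "glycine in regular secondary structure",
            if (deltas$hydropathy_delta < rules$hydropathy_cutoff)
                sprintf("hydropathy %.1f", deltas$hydropathy_delta),
            if (deltas$hbond_loss) "loss of H-bonded side chain")
        return(list(category = "fold_destabilizing", rationale = sprintf(
            "%s: buried (relative accessibility %.2f < %.2f) and disruptive (%s)",
            lab, env$relative_burial, rules$burial_cutoff,
            paste(why, collapse = "; "))))
    }
    list(category = "unexplained", rationale = sprintf(
        "%s: no rule fired (pocket %.1f A, depth %.1f A, accessibility %.2f, lipid-facing %s)",
        lab, env$pocket_distance, env$depth, env$relative_burial,
        env$lipid_facing))
}

#' Census of charged residues around a point
#'
#' Counts positively charged (ARG/LYS/HIS) and negatively charged
#' (ASP/GLU) residues whose side-chain centroid lies within `radius` of a
#' region centre -- e.g. the electrostatic character of the cytosolic
#' substrate entry.
#'
#' @param x a [Structure-class].
#' @param center 3-vector (angstrom).
#' @param radius census radius (angstrom, default 12).
#' @return A list with `positive`, `negative` counts and a `residues`
#'   data.frame (`chain`, `resno`, `resname`, `charge`, `distance_A`).
#' @export
entryChargeCensus <- function(x, center, radius = 12) {
    at <- atomRecords(x)
    pos_res <- c("ARG", "LYS", "HIS")
    neg_res <- c("ASP", "GLU")
    keys <- unique(at[at$resname %in% c(pos_res, neg_res) & !at$hetero,
                      c("chain", "resno", "resname")])
    rows <- list()
    xyz <- coords(x)
    for (i in seq_len(nrow(keys))) {
        idx <- which(at$chain == keys$chain[i] &
                     at$resno == keys$resno[i] & !at$hetero)
        sc <- idx[!at$name[idx] %in% c("N", "CA", "C", "O")]
        if (!length(sc)) sc <- idx
        d <- vnorm(colMeans(xyz[sc, , drop = FALSE]) - center)
        if (d <= radius)
            rows[[length(rows) + 1L]] <- data.frame(
                chain = keys$chain[i], resno = keys$resno[i],
                resname = keys$resname[i],
                charge = if (keys$resname[i] %in% pos_res) 1L else -1L,
                distance_A = d, stringsAsFactors = FALSE)
    }
    res <- if (length(rows)) do.call(rbind, rows)
           else data.frame(chain = character(), resno = integer(),
                           resname = character(), charge = integer(),
                           distance_A = numeric())
    list(positive = sum(res$charge == 1L),
         negative = sum(res$charge == -1L),
         residues = res[order(res$distance_A), , drop = FALSE])
}

#' Curated SLC26A2 missense variant fixture
#'
#' The 25 pathogenic/likely-pathogenic ClinVar missense variants (21
#' residues) mapped onto the SLC26A2 structures, with hand-curated
#' structural environments (pocket distance, membrane depth, accessibility,
#' lipid facing, secondary-structure context, H-bond involvement) encoding
#' each residue's published structural context, and the mechanistic
#' category stated for it. The environment numbers are curated annotations,
#' not measurements from deposited coordinates; they exist so the
#' classifier's rule logic can be exercised and audited without any
#' download.
#'
#' @return The fixture as parsed by [readVariantTable()] (25 records; the
#'   curated columns are carried through).
#' @export
curatedVariantTable <- function() {
    path <- system.file("extdata", "slc26a2_missense_curated.tsv",
                        package = "elevatorStruct", mustWork = TRUE)
    readVariantTable(path)
}

#' Classify a curated or measured variant table
#'
#' Convenience wrapper: builds [substitutionDeltas()] per record from the
#' table's `ref_aa`/`alt_aa` and a [residueEnvironment()]-compatible list
#' from its curated feature columns, then applies [classifyVariant()].
#'
#' @param tab a data.frame from [readVariantTable()] carrying the feature
#'   columns `pocket_distance`, `depth`, `boundary_distance`,
#'   `relative_burial`, `lipid_facing`, `helix_context`, `hbond_loss` and
#'   `half_thickness`.
#' @param rules a [categoryRules()].
#' @return `tab` with appended `category` and `rationale` columns.
#' @export
annotateVariants <- function(tab, rules = categoryRules()) {
    need <- c("pocket_distance", "depth", "boundary_distance",
              "relative_burial", "lipid_facing", "helix_context",
              "hbond_loss", "half_thickness")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("variant table lacks feature column(s): ",
             paste(miss, collapse = ", "))
    res <- lapply(seq_len(nrow(tab)), function(i) {
        env <- c(as.list(tab[i, need]), list(resno = tab$position[i]))
        deltas <- substitutionDeltas(tab$ref_aa[i], tab$alt_aa[i],
                                     hbond_loss = tab$hbond_loss[i])
        classifyVariant(env, deltas, rules)
    })
    tab$category <- vapply(res, `[[`, character(1), "category")
    tab$rationale <- vapply(res, `[[`, character(1), "rationale")
    tab
}
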