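#' Read an atomic structure from PDB or mmCIF
#'
#' Parses coordinate files into the package's uniform [Structure-class]
#' model. Author residue numbering is preserved (residue labels in reports
#' match the literature, e.g. G166). Alternate locations are resolved to a
#' single conformer per atom: highest occupancy wins, ties broken
#' alphabetically by altloc id. Only the first model of multi-model files is
#' read. Every atom is assigned a van der Waals radius from `radii`.
#'
#' @param path path to a `.pdb`, `.cif` or `.mmcif` file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param radii a [radiiTable()].
#' @return A [Structure-class] object.
#' @seealso [writeStructure()]
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          radii = radiiTable()) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("structure file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, pdb = "pdb", ent = "pdb",
                         cif = "mmcif", mmcif = "mmcif",
                         stop("cannot infer format from extension '.", ext,
                              "'; pass format explicitly"))
    }
    parsed <- tryCatch(
        if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                             verbose = FALSE)
        else bio3d::read.cif(path, verbose = FALSE),
        error = function(e) stop("failed to parse ", format, " file '",
                                 path, "': ", conditionMessage(e),
                                 call. = FALSE))
    at <- parsed$atom
    if (is.null(at) || nrow(at) == 0L)
        stop("empty structure: no ATOM/HETATM records in ", path)
    at <- resolveAltloc(at)
    element <- at$elesy
    if (is.null(element)) element <- rep("", nrow(at))
    blank <- is.na(element) | !nzchar(trimws(element))
    if (any(blank)) element[blank] <- guessElement(at$elety[blank])
    tab <- data.frame(
        serial = as.integer(at$eleno),
        name = trimws(at$elety),
        element = toupper(trimws(element)),
        resname = trimws(at$resid),
        resno = as.integer(at$resno),
        chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
        x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
        hetero = at$type == "HETATM",
        stringsAsFactors = FALSE)
    Structure(tab, title = basename(path), radii = radii)
}

# Keep the highest-occupancy conformer per (chain, resno, insert, name);
# ties broken alphabetically by altloc id.
resolveAltloc <- function(at) {
    alt <- at$alt
    if (is.null(alt)) return(at)
    alt[is.na(alt)] <- ""
    if (all(!nzchar(alt))) return(at)
    occ <- at$o
    if (is.null(occ)) occ <- rep(1, nrow(at))
    occ[is.na(occ)] <- 1
    ins <- at$insert
    if (is.null(ins)) ins <- ""
    ins[is.na(ins)] <- ""
    key <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at[!duplicated(key[ord]), , drop = FALSE]
}

# Infer an element symbol from an atom name (fallback when the element
# column is absent): strip digits/primes, honour two-letter ions.
guessElement <- function(name) {
    nm <- toupper(gsub("[0-9'\"]", "", trimws(name)))
    two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA")
    vapply(nm, function(n) {
        if (n %in% two) n else substr(n, 1L, 1L)
    }, character(1), USE.NAMES = FALSE)
}

#' Write an atomic structure to PDB or mmCIF
#'
#' @param x a [Structure-class].
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @seealso [readStructure()]
#' @export
writeStructure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, pdb = "pdb", cif = "mmcif", mmcif = "mmcif",
                         stop("cannot infer format from extension '.", ext,
                              "'"))
    }
    at <- atomRecords(x)
    if (format == "pdb") {
        bio3d::write.pdb(file = path,
                         xyz = as.vector(t(coords(x))),
                         type = ifelse(at$hetero, "HETATM", "ATOM"),
                         resno = at$resno, resid = at$resname,
                         eleno = at$serial, elety = at$name,
                         chain = at$chain, o = rep(1, nrow(at)),
                         b = rep(0, nrow(at)), elesy = at$element)
    } else {
        writeMmcif(x, path)
    }
    invisible(path)
}

# Minimal mmCIF atom_site writer (auth_* mirrors label_* fields).
writeMmcif <- function(x, path) {
    at <- atomRecords(x)
    hdr <- c("data_structure", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
    rows <- sprintf(
        "%-6s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
        ifelse(at$hetero, "HETATM", "ATOM"), at$serial, at$element,
        at$name, at$resname, at$chain, at$resno, at$x, at$y, at$z,
        at$resno, at$resname, at$chain, at$name)
    writeLines(c(hdr, rows, "#"), path)
    invisible(path)
}
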