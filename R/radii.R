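#' Van der Waals radii tables
#'
#' Element-to-radius maps used for pore profiling, SASA and clash geometry.
#' The default is the Bondi compilation for the elements that occur in
#' protein/ligand models; any element absent from the table falls back to
#' `default` (1.7 A, carbon-like) with a warning so no atom is ever left
#' without a radius.
#'
#' @param name table name; currently only `"bondi"`.
#' @param default fallback radius (angstrom) for unknown elements.
#' @return A list with `name`, `radii` (named numeric vector) and `default`.
#' @examples
#' rt <- radiiTable()
#' rt$radii[["C"]]
#' @export
radiiTable <- function(name = "bondi", default = 1.7) {
    name <- match.arg(name)
    radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90, FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31,
               "NA" = 2.27, K = 2.75, MN = 2.00, CU = 1.40)
    stopifnot(default > 0.5, default < 3.0)
    list(name = name, radii = radii, default = default)
}

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param table a [radiiTable()].
#' @param warn warn once when unknown elements fall back to the default.
#' @return Numeric vector of radii (angstrom), same length as `element`.
#' @export
lookupRadius <- function(element, table = radiiTable(), warn = TRUE) {
    key <- toupper(trimws(element))
    r <- unname(table$radii[key])
    unknown <- is.na(r)
    if (any(unknown)) {
        if (warn)
            warning("unknown element(s) ",
                    paste(unique(key[unknown]), collapse = ", "),
                    "; using default radius ", table$default, " A",
                    call. = FALSE)
        r[unknown] <- table$default
    }
    r
}
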