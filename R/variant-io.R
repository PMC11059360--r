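#' Read a ClinVar-style missense variant table
#'
#' Expects a TSV with header columns `gene`, `protein_change` and
#' `clinical_significance`. Protein changes must use one-letter
#' `<ref><pos><alt>` notation ("R279W"); rows whose change does not parse
#' (e.g. nucleotide-level "c.532C>T", frameshifts, synonymous changes) are
#' skipped with a single summary warning and counted in the `skipped`
#' attribute. Clinical significance is folded to `pathogenic`,
#' `likely_pathogenic` or `other`.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `gene`, `ref_aa`, `position`, `alt_aa`,
#'   `significance` and attribute `skipped` (number of unparseable rows).
#'   Extra columns of the input (e.g. curated structural annotations) are
#'   carried through.
#' @export
readVariantTable <- function(path) {
    if (!file.exists(path)) stop("variant table not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("gene", "protein_change", "clinical_significance")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("variant table missing required column(s): ",
             paste(miss, collapse = ", "))
    m <- regmatches(tab$protein_change,
                    regexec("^([ACDEFGHIKLMNPQRSTVWY])([0-9]+)([ACDEFGHIKLMNPQRSTVWY])$",
                            tab$protein_change))
    ok <- lengths(m) == 4L
    ok[ok] <- vapply(m[ok], function(g) g[2] != g[4], logical(1))
    skipped <- sum(!ok)
    if (skipped > 0L)
        warning(skipped, " row(s) with unparseable protein change skipped",
                call. = FALSE)
    mm <- do.call(rbind, m[ok])
    sig <- tolower(gsub("[ /]", "_", tab$clinical_significance[ok]))
    sig <- ifelse(sig == "pathogenic", "pathogenic",
                  ifelse(sig == "likely_pathogenic", "likely_pathogenic",
                         "other"))
    out <- data.frame(gene = tab$gene[ok],
                      protein_change = tab$protein_change[ok],
                      ref_aa = mm[, 2], position = as.integer(mm[, 3]),
                      alt_aa = mm[, 4], significance = sig,
                      stringsAsFactors = FALSE)
    extra <- setdiff(names(tab), c(need, "protein_change"))
    if (length(extra))
        out <- cbind(out, tab[ok, extra, drop = FALSE])
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

#' Write a two-column trace TSV
#'
#' Serialises a [TrajectoryTrace-class] as `frame`/`distance_A` columns with
#' a `# replicate:` header comment.
#'
#' @param trace a [TrajectoryTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# replicate: ", replicateId(trace)), con)
    writeLines("frame\tdistance_A", con)
    d <- distances(trace)
    writeLines(sprintf("%d\t%.6g", seq_along(d), d), con)
    invisible(path)
}

#' Read a trace TSV written by [writeTrace()]
#'
#' @param path input path.
#' @return A [TrajectoryTrace-class] with `source = "file"`.
#' @export
readTrace <- function(path) {
    if (!file.exists(path)) stop("trace file not found: ", path)
    lines <- readLines(path)
    rep_id <- sub("^# replicate: *", "", lines[startsWith(lines, "#")][1])
    if (is.na(rep_id)) rep_id <- basename(path)
    body <- lines[!startsWith(lines, "#")]
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
    if (!all(c("frame", "distance_A") %in% names(tab)))
        stop("trace file must have columns frame, distance_A: ", path)
    TrajectoryTrace(tab$distance_A, replicate = rep_id, source = "file")
}
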