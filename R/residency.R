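#' Distance window defining the bound state
#'
#' A frame counts as "bound" when the substrate-to-reference distance lies
#' inside this window. The default 3.5-8 A window (closed interval, both
#' edges bound) is the criterion for substrate residency in the TM3/TM10
#' cleft; the 6-8 A sub-window marks frames in which a chloride ion
#' intersects the sulfate site.
#'
#' @param lower,upper window edges in angstrom, `0 <= lower < upper`.
#' @param inclusive `"closed"` (default; both edges count as bound) or
#'   `"open"` (strict inequalities).
#' @return A validated list of class `"bindingWindow"`.
#' @export
bindingWindow <- function(lower = 3.5, upper = 8.0,
                          inclusive = c("closed", "open")) {
    inclusive <- match.arg(inclusive)
    stopifnot(lower >= 0, lower < upper)
    structure(list(lower = lower, upper = upper, inclusive = inclusive),
              class = "bindingWindow")
}

#' Per-frame bound mask under a window criterion
#'
#' @param trace a [TrajectoryTrace-class].
#' @param window a [bindingWindow()].
#' @return Logical vector, one value per frame: is the frame bound?
#' @examples
#' tr <- TrajectoryTrace(c(4, 6, 9))
#' boundMask(tr)          # TRUE TRUE FALSE
#' @export
boundMask <- function(trace, window = bindingWindow()) {
    stopifnot(is(trace, "TrajectoryTrace"), inherits(window, "bindingWindow"))
    d <- distances(trace)
    if (window$inclusive == "closed")
        d >= window$lower & d <= window$upper
    else
        d > window$lower & d < window$upper
}

#' Fraction of frames bound
#'
#' The residency statistic for a single replicate: the fraction of frames
#' whose distance satisfies the window criterion.
#'
#' @inheritParams boundMask
#' @return Numeric scalar in \[0, 1\].
#' @export
boundFraction <- function(trace, window = bindingWindow()) {
    mean(boundMask(trace, window))
}

#' Aggregate residency over replicates
#'
#' Combines per-replicate bound fractions the way replicate MD runs are
#' reported: arithmetic mean plus sample standard deviation (n-1 in the
#' denominator). With a single replicate the sd is reported as 0 and
#' flagged.
#'
#' @param traces list of [TrajectoryTrace-class] objects (>= 1).
#' @param window a [bindingWindow()].
#' @return A list of class `"bindingStatistic"` with `per_replicate`
#'   (named fractions), `mean`, `sd`, `n_replicates` and
#'   `single_replicate` flag.
#' @examples
#' trs <- lapply(1:3, function(s)
#'     simulateBindingTrace(kineticPresets("cl"), 2000, seed = s))
#' aggregateReplicates(trs)
#' @export
aggregateReplicates <- function(traces, window = bindingWindow()) {
    stopifnot(is.list(traces), length(traces) >= 1L)
    fr <- vapply(traces, boundFraction, numeric(1), window = window)
    names(fr) <- vapply(traces, replicateId, character(1))
    single <- length(fr) == 1L
    structure(list(per_replicate = fr,
                   mean = mean(fr),
                   sd = if (single) 0 else stats::sd(fr),
                   n_replicates = length(fr),
                   single_replicate = single,
                   window = window),
              class = "bindingStatistic")
}

#' @export
print.bindingStatistic <- function(x, ...) {
    cat(sprintf("Residency over %d replicate(s): %.0f%% +/- %.0f%%\n",
                x$n_replicates, 100 * x$mean, 100 * x$sd))
    cat("  per replicate:",
        paste(sprintf("%s=%.3f", names(x$per_replicate), x$per_replicate),
              collapse = ", "), "\n")
    if (x$single_replicate)
        cat("  (single replicate: sd not estimable, reported as 0)\n")
    invisible(x)
}

#' Fraction of frames intersecting the sulfate site
#'
#' Frames whose distance to the reference lies in the 6-8 A band, where a
#' chloride ion overlaps the sulfate binding site. A sub-window of the
#' default binding window, so this fraction never exceeds [boundFraction()].
#'
#' @param trace a [TrajectoryTrace-class].
#' @param window intersection band; default 6-8 A closed.
#' @return Numeric scalar in \[0, 1\].
#' @export
siteIntersectionFraction <- function(trace,
                                     window = bindingWindow(6.0, 8.0)) {
    boundFraction(trace, window)
}

#' Reduce coordinate frames to a distance trace
#'
#' Computes, per frame, the Euclidean distance between the ligand (single
#' atom, or the unweighted centroid of a multi-atom selection) and a
#' reference atom -- conventionally the C-alpha of the residue at the
#' N-terminal end of TM3. This is the adapter that turns coordinate
#' trajectories into the scalar currency of the residency statistic; any
#' periodic-boundary unwrapping must happen upstream.
#'
#' @param frames list of [Structure-class] snapshots.
#' @param ligand named list of [selectAtoms()] arguments resolving the
#'   ligand in every frame (e.g. `list(resname = "CL", hetero = TRUE)`).
#' @param reference named list resolving exactly one reference atom
#'   (e.g. `list(chain = "A", resno = 166, name = "CA")`).
#' @param replicate replicate identifier.
#' @return A [TrajectoryTrace-class] with `source = "coordinates"`.
#' @export
extractDistanceTrace <- function(frames, ligand, reference,
                                 replicate = "rep1") {
    stopifnot(is.list(frames), length(frames) >= 1L)
    d <- vapply(seq_along(frames), function(i) {
        s <- frames[[i]]
        li <- do.call(selectAtoms, c(list(s), ligand))
        if (!length(li))
            stop("ligand selection matches no atom in frame ", i)
        ri <- do.call(selectAtoms, c(list(s), reference))
        if (length(ri) != 1L)
            stop("reference selection must match exactly one atom in ",
                 "frame ", i, " (matched ", length(ri), ")")
        vnorm(atomCentroid(s, li) - coords(s)[ri, ])
    }, numeric(1))
    TrajectoryTrace(d, replicate = replicate, source = "coordinates")
}

#' Residency report as a JSON-ready list
#'
#' Formats a [aggregateReplicates()] result the way residencies are quoted
#' (integer percent with spread) while retaining full precision.
#'
#' @param stat a `"bindingStatistic"`.
#' @param substrate substrate label for the report.
#' @return A list with `substrate`, `window`, `per_replicate`, `mean`,
#'   `sd`, `percent_label`.
#' @export
residencyReport <- function(stat, substrate = "substrate") {
    stopifnot(inherits(stat, "bindingStatistic"))
    list(substrate = substrate,
         window = c(lower = stat$window$lower, upper = stat$window$upper),
         per_replicate = as.list(stat$per_replicate),
         mean = stat$mean, sd = stat$sd,
         n_replicates = stat$n_replicates,
         percent_label = sprintf("%.0f +/- %.0f %%", 100 * stat$mean,
                                 100 * stat$sd))
}
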