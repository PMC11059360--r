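#' Two-state kinetic preset for synthetic binding traces
#'
#' Defines a per-frame two-state (bound/unbound) Markov chain plus the
#' distance emissions of each state. Emission supports are kept strictly
#' inside (bound: 4.0-7.5 A) and strictly outside (unbound: 9.0-30.0 A) the
#' default 3.5-8 A binding window, so the window criterion recovers the
#' hidden state sequence exactly and edge-inclusivity conventions cannot
#' change synthetic results. The stationary bound probability is
#' `p_on / (p_on + p_off)`.
#'
#' @param name preset label.
#' @param p_on per-frame unbound-to-bound transition probability.
#' @param p_off per-frame bound-to-unbound transition probability.
#' @param bound_emission length-2 range (angstrom) of the bound-state
#'   uniform distance emission.
#' @param unbound_emission length-2 range of the unbound-state emission.
#' @param start_state `"stationary"` (draw the initial state from the
#'   stationary distribution), `"bound"` or `"unbound"`.
#' @return A validated list of class `"kineticPreset"`.
#' @seealso [kineticPresets()], [simulateBindingTrace()]
#' @export
kineticPreset <- function(name, p_on, p_off,
                          bound_emission = c(4.0, 7.5),
                          unbound_emission = c(9.0, 30.0),
                          start_state = c("stationary", "bound",
                                          "unbound")) {
    start_state <- match.arg(start_state)
    stopifnot(p_on >= 0, p_on <= 1, p_off >= 0, p_off <= 1,
              length(bound_emission) == 2L, length(unbound_emission) == 2L,
              bound_emission[1] < bound_emission[2],
              unbound_emission[1] < unbound_emission[2])
    if (p_on + p_off == 0 && start_state == "stationary")
        stop("stationary start undefined when p_on + p_off = 0")
    structure(list(name = name, p_on = p_on, p_off = p_off,
                   bound_emission = bound_emission,
                   unbound_emission = unbound_emission,
                   start_state = start_state),
              class = "kineticPreset")
}

#' Built-in kinetic presets for the three substrates
#'
#' Presets whose stationary bound probabilities encode the residency levels
#' of the three substrates: chloride (stationary 0.82, from p_on 0.0041 /
#' p_off 0.0009), sulfate (absorbing bound state, stationary 1) and oxalate
#' (stationary 0.65, from p_on 0.00325 / p_off 0.00175).
#'
#' @param name `"cl"`, `"so4"` or `"ox"`.
#' @return A [kineticPreset()].
#' @examples
#' p <- kineticPresets("cl")
#' p$p_on / (p$p_on + p$p_off)   # 0.82
#' @export
kineticPresets <- function(name = c("cl", "so4", "ox")) {
    switch(match.arg(name),
           cl = kineticPreset("preset_cl", p_on = 0.0041, p_off = 0.0009),
           so4 = kineticPreset("preset_so4", p_on = 0, p_off = 0,
                               start_state = "bound"),
           ox = kineticPreset("preset_ox", p_on = 0.00325,
                              p_off = 0.00175))
}

#' Stationary bound probability of a kinetic preset
#'
#' `p_on / (p_on + p_off)`; for an absorbing preset (both rates 0) the
#' start state's occupancy (1 for bound, 0 for unbound).
#'
#' @param preset a [kineticPreset()].
#' @return Numeric scalar in \[0, 1\].
#' @export
stationaryBoundProbability <- function(preset) {
    stopifnot(inherits(preset, "kineticPreset"))
    if (preset$p_on + preset$p_off == 0)
        return(if (preset$start_state == "bound") 1 else 0)
    preset$p_on / (preset$p_on + preset$p_off)
}

#' Simulate a synthetic substrate-distance trace
#'
#' Samples the preset's two-state Markov chain for `n_frames` frames and
#' draws a per-frame distance from the active state's uniform emission.
#' Only the distances are retained -- exactly the information a real
#' trajectory reduction provides -- together with the replicate id and seed.
#' Same seed, same preset: byte-identical trace.
#'
#' @param preset a [kineticPreset()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @param replicate replicate identifier (default derived from the seed).
#' @return A [TrajectoryTrace-class] with `source = "synthetic"`.
#' @examples
#' tr <- simulateBindingTrace(kineticPresets("so4"), 100, seed = 1)
#' boundFraction(tr)   # 1: absorbing bound state
#' @export
simulateBindingTrace <- function(preset, n_frames, seed,
                                 replicate = paste0("seed", seed)) {
    stopifnot(inherits(preset, "kineticPreset"), n_frames >= 1L)
    n_frames <- as.integer(n_frames)
    withr::with_seed(as.integer(seed), {
        state <- switch(preset$start_state,
                        bound = TRUE, unbound = FALSE,
                        stationary = stats::runif(1) <
                            stationaryBoundProbability(preset))
        u <- stats::runif(n_frames)
        states <- logical(n_frames)
        for (i in seq_len(n_frames)) {
            states[i] <- state
            state <- if (state) u[i] >= preset$p_off
                     else u[i] < preset$p_on
        }
        d <- numeric(n_frames)
        nb <- sum(states)
        d[states] <- stats::runif(nb, preset$bound_emission[1],
                                  preset$bound_emission[2])
        d[!states] <- stats::runif(n_frames - nb,
                                   preset$unbound_emission[1],
                                   preset$unbound_emission[2])
        TrajectoryTrace(d, replicate = replicate, source = "synthetic",
                        seed = seed)
    })
}
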