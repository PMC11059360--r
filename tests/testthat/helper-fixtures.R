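# Fixtures built in code at test time: tiny structures, PDB text, rigid
# transforms. No binary files anywhere.

# atom-table shortcut
mkAtoms <- function(x, y, z, name = "CA", element = "C", resname = "ALA",
                    resno = seq_along(x), chain = "A", hetero = FALSE) {
    data.frame(serial = seq_along(x), name = name, element = element,
               resname = resname, resno = resno, chain = chain,
               x = x, y = y, z = z, hetero = hetero,
               stringsAsFactors = FALSE)
}

# three-atom glycine PDB with known coordinates
glyPdbFile <- function() {
    path <- tempfile(fileext = ".pdb")
    writeLines(c(
"ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
"ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
"ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
"END"), path)
    path
}

# one atom with two altlocs: A (occ 0.60) at x=1, B (occ 0.40) at x=2
altlocPdbFile <- function() {
    path <- tempfile(fileext = ".pdb")
    writeLines(c(
"ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
"ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
"END"), path)
    path
}

# random rigid-body transform (fixed seed supplied by caller)
randomRigid <- function() {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    list(R = R, t = stats::rnorm(3, sd = 8))
}

transformStructure <- function(s, tr) {
    at <- atomRecords(s)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(tr$R)
    at$x <- xyz[, 1] + tr$t[1]
    at$y <- xyz[, 2] + tr$t[2]
    at$z <- xyz[, 3] + tr$t[3]
    Structure(at, title = s@title)
}

# independent brute-force pore radii: plain double loop, no vectorised
# shortcuts shared with the implementation
bruteClearance <- function(points, xyz, vdw) {
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(points))) {
        best <- Inf
        for (a in seq_len(nrow(xyz))) {
            d <- sqrt(sum((points[i, ] - xyz[a, ])^2)) - vdw[a]
            if (d < best) best <- d
        }
        out[i] <- max(0, best)
    }
    out
}

# one-letter lookup independent of package internals
AA1char <- function(res3) {
    map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
    map[res3]
}

# toy bundle cached per session (deterministic)
toyBundle <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- buildToyBundle(bundleSpec(seed = 11))
        cache
    }
})
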