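test_that("toy bundle helices have ideal alpha-helix geometry", {
    s <- buildToyBundle(bundleSpec(n_helices = 3, helix_length = 20,
                                   seed = 2))
    at <- atomRecords(s)
    ca <- at[at$name == "CA" & at$chain == "A", ]
    ca <- ca[order(ca$resno), ]
    dd <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    # closed form for rise 1.5, twist 100 deg, radius 2.3:
    # sqrt((2 * 2.3 * sin(50 deg))^2 + 1.5^2) = 3.83 A
    expect_true(all(abs(dd - 3.8) <= 0.1))
})

test_that("membrane-belt residues are hydrophobic, the rest polar", {
    s <- buildToyBundle(bundleSpec(belt_half_thickness = 15, seed = 5))
    at <- atomRecords(s)
    ca <- at[at$name == "CA", ]
    in_belt <- abs(ca$z) <= 15
    expect_true(all(ca$resname[in_belt] %in%
                        c("LEU", "ILE", "VAL", "PHE")))
    expect_true(all(ca$resname[!in_belt] %in%
                        c("SER", "ASN", "GLU", "LYS")))
})

test_that("bundle pore radius matches the requested cleft radius", {
    for (cr in c(1.0, 2.5)) {
        s <- buildToyBundle(bundleSpec(cleft_radius = cr, seed = 3))
        zr <- range(coords(s)[, 3]) + c(3, -3)
        path <- porePath(c(0, 0, zr[1]), c(0, 0, zr[2]))
        # independent brute-force sphere-growth oracle
        r_oracle <- bruteClearance(path$points, coords(s),
                                   atomRecords(s)$vdw)
        expect_lt(abs(min(r_oracle) - cr), 0.3)
        prof <- poreProfile(s, path, warn_outside = FALSE)
        expect_equal(prof$profile$radius_A, r_oracle, tolerance = 1e-12)
    }
})

test_that("impossible bundle specs are rejected", {
    expect_error(buildToyBundle(bundleSpec(ring_radius = 1,
                                           cleft_radius = 0)),
                 "overlapping")
    expect_error(bundleSpec(n_helices = 2), "n_helices")
})

test_that("absorbing bound preset emits only in-window distances", {
    tr <- simulateBindingTrace(kineticPresets("so4"), 5000, seed = 9)
    expect_true(all(distances(tr) >= 4.0 & distances(tr) <= 7.5))
    expect_equal(boundFraction(tr), 1.0)
})

test_that("a never-binding preset gives zero bound fraction", {
    p <- kineticPreset("dead", p_on = 0, p_off = 0.5,
                       start_state = "unbound")
    tr <- simulateBindingTrace(p, 2000, seed = 1)
    expect_equal(boundFraction(tr), 0.0)
})

test_that("long-run bound fractions recover the Markov stationary value", {
    # stationary p_on / (p_on + p_off); tolerance 3 Monte-Carlo SEs with
    # autocorrelation factor (1 + 2 * (1 - lambda) / lambda), lambda = p_on + p_off
    for (nm in c("cl", "ox")) {
        p <- kineticPresets(nm)
        pstat <- stationaryBoundProbability(p)
        lam <- p$p_on + p$p_off
        n <- 50000L
        se <- sqrt(pstat * (1 - pstat) * (1 + 2 * (1 - lam) / lam) / n)
        fr <- vapply(1:3, function(sd)
            boundFraction(simulateBindingTrace(p, n, seed = sd)),
            numeric(1))
        expect_lt(abs(mean(fr) - pstat), 3 * se / sqrt(3))
    }
})

test_that("emissions never touch the window edges, so the mask is the state", {
    tr <- simulateBindingTrace(kineticPresets("cl"), 20000, seed = 4)
    inner <- boundMask(tr, bindingWindow(4.0, 7.5))
    outer <- boundMask(tr, bindingWindow(3.5, 8.0))
    expect_identical(inner, outer)
    d <- distances(tr)
    expect_false(any(d > 7.5 & d < 9.0))
    expect_false(any(d > 3.0 & d < 4.0))
})

test_that("generators are deterministic given the seed", {
    t1 <- simulateBindingTrace(kineticPresets("cl"), 1000, seed = 42)
    t2 <- simulateBindingTrace(kineticPresets("cl"), 1000, seed = 42)
    expect_identical(distances(t1), distances(t2))
    b1 <- buildToyBundle(bundleSpec(seed = 42))
    b2 <- buildToyBundle(bundleSpec(seed = 42))
    expect_identical(atomRecords(b1), atomRecords(b2))
    v1 <- makeVariantFixture(b1, 8, seed = 7)
    v2 <- makeVariantFixture(b2, 8, seed = 7)
    expect_identical(v1, v2)
})

test_that("rendered density peaks at atom positions", {
    at <- mkAtoms(x = c(0, 12), y = c(0, 0), z = c(0, 0), name = "C",
                  resname = "LIG", hetero = TRUE)
    s <- Structure(at)
    m <- renderDensity(s, sigma = 0.8, voxel = 0.5, padding = 3)
    v <- mapValues(m)
    top <- which(v == max(v), arr.ind = TRUE)
    pos <- sweep(sweep(top - 1, 2, voxelSize(m), "*"), 2, mapOrigin(m),
                 "+")
    # two equal maxima, each at a voxel nearest an atom centre
    expect_equal(nrow(top), 2L)
    d_to_atoms <- apply(pos, 1, function(p)
        min(sqrt(colSums((t(coords(s)) - p)^2))))
    expect_true(all(d_to_atoms <= sqrt(3) * 0.5 / 2 + 1e-9))
    expect_warning(renderDensity(s, sigma = 0.2, voxel = 0.5),
                   "undersampled")
})

test_that("variant fixtures address existing residues and span contexts", {
    s <- toyBundle()
    tab <- makeVariantFixture(s, 9, seed = 3)
    expect_equal(nrow(tab), 9L)
    pos <- as.integer(gsub("[A-Z]", "", tab$protein_change))
    ca <- atomRecords(s)
    ca <- ca[ca$name == "CA" & ca$chain == "A", ]
    expect_true(all(pos %in% ca$resno))
    ref <- substr(tab$protein_change, 1, 1)
    expect_equal(unname(ref),
                 unname(AA1char(ca$resname[match(pos, ca$resno)])))
    expect_true(all(c("belt", "cleft") %in% tab$context))
    expect_error(makeVariantFixture(s, 10000, seed = 1), "between 1 and")
})
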