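test_that("the slab recovers the constructed hydrophobic belt", {
    s <- toyBundle()
    slab <- placeMembraneSlab(s)
    expect_lt(abs(slab$center_offset), 1)
    expect_lt(abs(slab$half_thickness - 15), 1)
    expect_false(slab$low_confidence)
    expect_equal(abs(slab$normal[3]), 1, tolerance = 1e-4)
})

test_that("slab placement is equivariant under rigid rotation", {
    s <- toyBundle()
    slab <- placeMembraneSlab(s)
    set.seed(19)
    tr <- randomRigid()
    rot <- transformStructure(s, tr)
    slab2 <- placeMembraneSlab(rot)
    # the normal rotates with the structure (sign is conventional)
    n_expected <- drop(tr$R %*% slab$normal)
    expect_lt(min(sum((slab2$normal - n_expected)^2),
                  sum((slab2$normal + n_expected)^2)), 1e-6)
    expect_lt(abs(slab2$half_thickness - slab$half_thickness), 0.51)
    expect_lt(abs(abs(slab2$center_offset) - abs(slab$center_offset)),
              0.51)
})

test_that("an all-polar bundle is flagged low confidence", {
    # belt thinner than any admissible slab: essentially no hydrophobics
    s <- buildToyBundle(bundleSpec(belt_half_thickness = 0.6, seed = 4))
    slab <- placeMembraneSlab(s)
    expect_true(slab$low_confidence)
    expect_lte(slab$inside_hydropathy, 0)
})

test_that("residue environments expose depth, burial and facing", {
    s <- toyBundle()
    slab <- placeMembraneSlab(s)
    areas <- sasa(s, sasaParams(n_sphere_points = 240L))
    at <- atomRecords(s)
    ca <- at[at$name == "CA", ]
    cb <- at[at$name == "CB", ]
    cb <- cb[match(paste(ca$chain, ca$resno), paste(cb$chain, cb$resno)), ]
    # a mid-membrane residue on the outer bundle surface, side chain out
    r_cb <- sqrt(cb$x^2 + cb$y^2)
    cand <- which(abs(ca$z) < 5 & r_cb > 10.5)
    expect_gt(length(cand), 0)
    i <- cand[1]
    env <- residueEnvironment(s, ca$chain[i], ca$resno[i], slab,
                              pocket_center = c(0, 0, 0),
                              sasa_areas = areas)
    expect_lt(abs(env$depth), 6)
    expect_true(env$lipid_facing)
    # an inward-facing cleft residue near the pocket centre
    j <- which(abs(ca$z) < 4 & r_cb < 6)[1]
    env2 <- residueEnvironment(s, ca$chain[j], ca$resno[j], slab,
                               pocket_center = c(0, 0, 0),
                               sasa_areas = areas)
    expect_lt(env2$pocket_distance, 8)
    expect_false(env2$lipid_facing)
})

test_that("a residue outside the slab reports its boundary distance", {
    set.seed(20)
    # synthetic 60-residue line cloud is degenerate; use the bundle and a
    # hand-built slab to test the geometry arithmetic in isolation
    s <- toyBundle()
    slab <- list(normal = c(0, 0, 1), center_offset = 0,
                 half_thickness = 15, center_point = c(0, 0, 0),
                 fit_score = 1, low_confidence = FALSE)
    at <- atomRecords(s)
    top <- at$resno[at$chain == "A"][which.max(at$z[at$chain == "A"])]
    env <- residueEnvironment(s, "A", top, slab,
                              pocket_center = c(0, 0, 0),
                              sasa_areas = sasa(s, sasaParams(
                                  n_sphere_points = 240L)))
    expect_equal(env$boundary_distance, abs(abs(env$depth) - 15),
                 tolerance = 1e-9)
})

test_that("substitution deltas come from the published scales", {
    d <- substitutionDeltas("I", "T")
    expect_equal(d$hydropathy_delta, -5.2)
    expect_equal(substitutionDeltas("D", "V")$charge_delta, 1)
    expect_true(substitutionDeltas("L", "P")$to_pro)
    expect_true(substitutionDeltas("A", "G")$to_gly)
    expect_equal(substitutionDeltas("A", "V")$volume_delta, 51.4,
                 tolerance = 1e-9)
    expect_error(substitutionDeltas("X", "T"), "non-standard")
    expect_error(substitutionDeltas("A", "A"), "must differ")
})

test_that("the rule set is total and deterministic", {
    set.seed(22)
    aa <- names(residueVolumes())
    cats <- c("substrate_site", "lipid_interface", "fold_destabilizing",
              "unexplained")
    for (i in 1:60) {
        env <- list(resno = sample(1:700, 1),
                    pocket_distance = runif(1, 0, 50),
                    depth = runif(1, -40, 40),
                    boundary_distance = runif(1, 0, 25),
                    relative_burial = runif(1, 0, 1.2),
                    lipid_facing = runif(1) < 0.5,
                    helix_context = runif(1) < 0.5,
                    half_thickness = 15)
        pair <- sample(aa, 2)
        deltas <- substitutionDeltas(pair[1], pair[2],
                                     hbond_loss = runif(1) < 0.2)
        res <- classifyVariant(env, deltas)
        expect_true(res$category %in% cats)
        expect_identical(classifyVariant(env, deltas)$category,
                         res$category)
    }
})

test_that("classifier reproduces the reported category of each curated variant", {
    ann <- annotateVariants(curatedVariantTable())
    expect_equal(ann$category, ann$reported_category)
    # the three flagship examples
    expect_equal(ann$category[ann$protein_change == "G166R"],
                 "substrate_site")
    expect_equal(ann$category[ann$protein_change == "R279W"],
                 "lipid_interface")
    expect_equal(ann$category[ann$protein_change == "D250V"],
                 "unexplained")
})

test_that("belt variants from the fixture generator classify as lipid interface", {
    s <- toyBundle()
    slab <- placeMembraneSlab(s)
    areas <- sasa(s, sasaParams(n_sphere_points = 240L))
    tab <- makeVariantFixture(s, 9, seed = 3)
    belt <- tab[tab$context == "belt", ][1, ]
    pos <- as.integer(gsub("[A-Z]", "", belt$protein_change))
    env <- residueEnvironment(s, "A", pos, slab,
                              pocket_center = c(0, 0, 0),
                              sasa_areas = areas)
    deltas <- substitutionDeltas(substr(belt$protein_change, 1, 1),
                                 substr(belt$protein_change,
                                        nchar(belt$protein_change),
                                        nchar(belt$protein_change)))
    res <- classifyVariant(env, deltas)
    expect_equal(res$category, "lipid_interface")
})

test_that("the charged-entry census counts side-chain centroids in range", {
    ring <- seq(0, 2 * pi, length.out = 7)[1:6]
    at <- do.call(rbind, lapply(1:6, function(i) {
        resn <- c("LYS", "ARG", "LYS", "ARG", "LYS", "ASP")[i]
        a <- mkAtoms(c(6 * cos(ring[i]), 7 * cos(ring[i])),
                     c(6 * sin(ring[i]), 7 * sin(ring[i])), c(0, 0),
                     name = c("CA", "CB"), resname = resn, resno = i)
        a
    }))
    at$serial <- seq_len(nrow(at))
    s <- Structure(at)
    cen <- entryChargeCensus(s, center = c(0, 0, 0), radius = 12)
    expect_equal(cen$positive, 5L)
    expect_equal(cen$negative, 1L)
    empty <- entryChargeCensus(s, center = c(500, 0, 0), radius = 12)
    expect_equal(c(empty$positive, empty$negative), c(0L, 0L))
})
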