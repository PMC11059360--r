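test_that("pore radius is clearance to the nearest vdW surface", {
    # carbon (vdw 1.7) at distance 5 from the first path point
    s <- Structure(mkAtoms(5, 0, 0, name = "C", resname = "LIG",
                           hetero = TRUE))
    path <- porePath(c(0, 0, 0), c(0, 0, 1))
    prof <- poreProfile(s, path, warn_outside = FALSE)
    expect_equal(prof$profile$radius_A[1], 5 - 1.7)
    # a point inside the vdW sphere clamps to zero
    s2 <- Structure(mkAtoms(0.5, 0, 0, name = "C", resname = "LIG",
                            hetero = TRUE))
    prof2 <- poreProfile(s2, path, warn_outside = FALSE)
    expect_equal(prof2$profile$radius_A[1], 0)
    expect_error(suppressWarnings(
        poreProfile(s, structure(list(), class = "porePath"))))
})

test_that("grid-accelerated pore search equals brute force exactly", {
    s <- toyBundle()
    set.seed(12)
    paths <- list(
        porePath(c(0, 0, -24), c(0, 0, 24)),
        porePath(c(-30, -5, -40), c(25, 10, 40)),   # partly outside
        porePath(c(3, 2, -10), c(-3, -2, 10), spacing = 0.33))
    for (path in paths) {
        b <- suppressWarnings(poreProfile(s, path, method = "brute",
                                          warn_outside = FALSE))
        g <- suppressWarnings(poreProfile(s, path, method = "grid",
                                          warn_outside = FALSE))
        expect_identical(b$profile$radius_A, g$profile$radius_A)
    }
})

test_that("adding atoms never increases any pore radius", {
    set.seed(13)
    at <- mkAtoms(runif(30, -8, 8), runif(30, -8, 8), runif(30, -8, 8),
                  name = "C", resname = "LIG", hetero = TRUE)
    path <- porePath(c(0, 0, -8), c(0, 0, 8))
    r_prev <- NULL
    for (n in c(10, 20, 30)) {
        s <- Structure(at[1:n, ])
        r <- poreProfile(s, path, warn_outside = FALSE)$profile$radius_A
        if (!is.null(r_prev)) expect_true(all(r <= r_prev + 1e-12))
        r_prev <- r
    }
})

test_that("open/closed classification follows the strict 1.8 A rule", {
    mkProf <- function(r) structure(
        list(profile = data.frame(s = seq_along(r), x = 0, y = 0,
                                  z = seq_along(r), radius_A = r),
             min_radius = min(r), min_location = c(0, 0, 1),
             method = "brute"),
        class = "poreProfile")
    # cytosolic half all 2.0; one extracellular radius 1.5
    prof <- mkProf(c(2, 2, 2, 2, 2, 1.5, 2))
    cls <- classifyPore(prof, pocket_index = 4)
    expect_equal(cls[["cytosolic"]], "open")
    expect_equal(cls[["extracellular"]], "closed")
    # exact threshold equality counts as closed
    expect_equal(classifyPore(mkProf(c(2, 1.8, 2)), 1)[["extracellular"]],
                 "closed")
    expect_equal(unname(classifyPore(mkProf(rep(2, 5)), 3)),
                 c("open", "open"))
    # raising the threshold can only flip open -> closed
    set.seed(14)
    for (i in 1:10) {
        prof <- mkProf(runif(20, 0.5, 3))
        lo <- classifyPore(prof, 10, threshold = 1.2)
        hi <- classifyPore(prof, 10, threshold = 2.0)
        expect_true(all(!(lo == "closed" & hi == "open")))
    }
})

test_that("cleft widths measure C-alpha pair distances by author number", {
    at <- rbind(mkAtoms(0, 0, 0, resno = 165),
                mkAtoms(7.25, 0, 0, resno = 442))
    at$serial <- 1:2
    s <- Structure(at)
    w <- cleftWidths(s, pairs = cbind(165, 442))
    expect_equal(w$distance_A, 7.25)
    s2 <- toyBundle()
    pairs <- cbind(c(3, 5), c(10, 12))
    w1 <- cleftWidths(s2, pairs)
    expect_equal(w1$distance_A, cleftWidths(s2, pairs)$distance_A)
    expect_error(cleftWidths(s2, cbind(3, 999)), "999")
})

test_that("elevator shift recovers a constructed core displacement", {
    s <- toyBundle()
    gate <- list(chain = c("A", "B", "C"))
    probe <- list(chain = "E")
    expect_equal(elevatorShift(s, s, gate, probe), 0, tolerance = 1e-9)
    # translate the core chains (D-F) by +5 A along z, gate untouched
    at <- atomRecords(s)
    shift <- at$chain %in% c("D", "E", "F")
    at$z[shift] <- at$z[shift] + 5
    mob <- Structure(at)
    expect_equal(elevatorShift(mob, s, gate, probe), 5, tolerance = 1e-6)
    # a whole-body rotation+translation vanishes after gate alignment
    set.seed(15)
    rot <- transformStructure(s, randomRigid())
    expect_lt(abs(elevatorShift(rot, s, gate, probe)), 1e-6)
    expect_error(elevatorShift(s, s, list(chain = "A", resno = 1:3),
                               probe), "share only")
})

test_that("neighbour census applies the heavy-atom cutoff per residue", {
    at <- rbind(
        mkAtoms(0, 0, 0, name = "CL", element = "CL", resname = "CL",
                resno = 500, chain = "L", hetero = TRUE),
        mkAtoms(4.9, 0, 0, resno = 10),
        mkAtoms(0, 5.1, 0, resno = 20))
    at$serial <- 1:3
    s <- Structure(at)
    cen <- neighborCensus(s, ligand = list(resname = "CL"), cutoff = 5)
    expect_equal(cen$resno, 10)
    expect_equal(cen$min_distance_A, 4.9)
    expect_equal(nrow(neighborCensus(s, list(resname = "CL"),
                                     cutoff = 0)), 0L)
    expect_error(neighborCensus(s, list(resname = "SO4")), "no atoms")
})

test_that("ligand site displacement is measured after superposition", {
    s <- toyBundle()
    at <- atomRecords(s)
    lig <- at[1, ]
    lig$serial <- 9999L; lig$name <- "CL"; lig$element <- "CL"
    lig$resname <- "CL"; lig$resno <- 500L; lig$chain <- "L"
    lig$hetero <- TRUE; lig$x <- 0; lig$y <- 0; lig$z <- 0
    a <- Structure(rbind(at, lig))
    expect_equal(ligandSiteDisplacement(a, list(resname = "CL"), a,
                                        list(resname = "CL")), 0)
    # displace the ligand by 2.5 A and rigidly move the whole copy
    lig2 <- lig; lig2$x <- 1.5; lig2$y <- 2.0
    b <- Structure(rbind(at, lig2))
    set.seed(16)
    b <- transformStructure(b, randomRigid())
    expect_equal(ligandSiteDisplacement(a, list(resname = "CL"), b,
                                        list(resname = "CL")), 2.5,
                 tolerance = 1e-6)
})

test_that("superposed RMSD agrees with an independent reference implementation", {
    s <- toyBundle()
    set.seed(23)
    at <- atomRecords(s)
    at$x <- at$x + rnorm(nrow(at), 0, 0.3)
    at$y <- at$y + rnorm(nrow(at), 0, 0.3)
    at$z <- at$z + rnorm(nrow(at), 0, 0.3)
    noisy <- transformStructure(Structure(at), randomRigid())
    ours <- as.numeric(structureRmsd(noisy, s))
    # bio3d's fitted RMSD over the same C-alpha pairing as the oracle
    ca_a <- selectAtoms(noisy, name = "CA")
    ca_b <- selectAtoms(s, name = "CA")
    ref <- bio3d::rmsd(as.vector(t(coords(s)[ca_b, ])),
                       as.vector(t(coords(noisy)[ca_a, ])), fit = TRUE)
    expect_equal(ours, ref, tolerance = 5e-3)  # bio3d rounds to 3 decimals
})

test_that("RMSD vanishes under rigid motion and tracks coordinate noise", {
    s <- toyBundle()
    expect_equal(as.numeric(structureRmsd(s, s)), 0, tolerance = 1e-9)
    set.seed(17)
    moved <- transformStructure(s, randomRigid())
    expect_lt(as.numeric(structureRmsd(moved, s)), 1e-6)
    # isotropic gaussian noise of sd sigma per coordinate: rmsd ~ sigma*sqrt(3)
    sigma <- 0.2
    at <- atomRecords(s)
    at$x <- at$x + rnorm(nrow(at), 0, sigma)
    at$y <- at$y + rnorm(nrow(at), 0, sigma)
    at$z <- at$z + rnorm(nrow(at), 0, sigma)
    noisy <- Structure(at)
    r <- as.numeric(structureRmsd(noisy, s))
    expect_lt(abs(r - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
    expect_equal(attr(structureRmsd(noisy, s), "n_atoms"), 180L)
})
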