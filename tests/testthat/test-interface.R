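test_that("isolated-atom SASA matches the closed-form sphere area", {
    s <- Structure(mkAtoms(0, 0, 0, name = "C", resname = "LIG",
                           hetero = TRUE))
    a <- sasa(s)
    expect_equal(as.numeric(a), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
    # two identical atoms far apart: no occlusion
    s2 <- Structure(mkAtoms(c(0, 100), c(0, 0), c(0, 0), name = "C",
                            resname = "LIG", hetero = TRUE))
    a2 <- sasa(s2)
    expect_equal(as.numeric(a2), rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("a caged atom has zero accessible area", {
    g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
    at <- mkAtoms(c(0, g$x * 2), c(0, g$y * 2), c(0, g$z * 2),
                  name = "C", resname = "LIG", hetero = TRUE)
    s <- Structure(at)
    expect_equal(sasa(s)[1], 0)
})

test_that("two-sphere buried area matches the analytic spherical cap", {
    # equal radii R = vdw + probe; centre distance d < 2R:
    # buried = (A + B - AB)/2 = 2 * pi * R * (R - d/2)
    d <- 3.0
    s <- Structure(mkAtoms(c(0, d), c(0, 0), c(0, 0), name = "C",
                           resname = "LIG", resno = c(1, 2),
                           hetero = TRUE))
    rep <- buriedArea(s, list(resno = 1), list(resno = 2))
    R <- 1.7 + 1.4
    expect_equal(rep$buried_area, 2 * pi * R * (R - d / 2),
                 tolerance = 0.02)
    # per-residue contributions sum to the buried area
    expect_equal(sum(rep$per_residue), rep$buried_area,
                 tolerance = 1e-6)
})

test_that("buried area is symmetric, vanishes at distance, and rejects overlap", {
    s <- toyBundle()
    ga <- list(chain = "A"); gb <- list(chain = "B")
    ab <- buriedArea(s, ga, gb, sasaParams(n_sphere_points = 240L))
    ba <- buriedArea(s, gb, ga, sasaParams(n_sphere_points = 240L))
    expect_equal(ab$buried_area, ba$buried_area, tolerance = 1e-9)
    expect_gt(ab$buried_area, 0)
    # translate chain B 100 A away: interface disappears
    at <- atomRecords(s)
    at$x[at$chain == "B"] <- at$x[at$chain == "B"] + 100
    far <- Structure(at)
    expect_equal(buriedArea(far, ga, gb,
                            sasaParams(n_sphere_points = 240L))$buried_area,
                 0)
    expect_error(buriedArea(s, ga, ga), "overlap")
    expect_error(buriedArea(s, list(chain = "Z"), gb), "at least one")
})

test_that("SASA converges in the sphere point count", {
    # doubling the point count moves each atom's area by less than 2% of
    # its expanded-sphere area (the natural discretisation scale)
    s <- subsetStructure(toyBundle(), 1:30)
    a1 <- sasa(s, sasaParams(n_sphere_points = 960L))
    a2 <- sasa(s, sasaParams(n_sphere_points = 1920L))
    sphere <- 4 * pi * (atomRecords(s)$vdw + 1.4)^2
    expect_true(all(abs(a1 - a2) < 0.02 * sphere))
})

test_that("SASA and buried area are stable under rigid motion", {
    # the spiral point set is fixed in the global frame, so per-atom areas
    # fluctuate by the point-discretisation scale under rotation while the
    # buried area (a sum over many atoms) is far tighter
    s <- subsetStructure(toyBundle(), selectAtoms(toyBundle(),
                                                  chain = c("A", "B")))
    set.seed(18)
    moved <- transformStructure(s, randomRigid())
    p <- sasaParams(n_sphere_points = 960L)
    expect_lt(max(abs(sasa(moved, p) - sasa(s, p))), 2.5)
    b1 <- buriedArea(moved, list(chain = "A"), list(chain = "B"),
                     p)$buried_area
    b2 <- buriedArea(s, list(chain = "A"), list(chain = "B"),
                     p)$buried_area
    expect_lt(abs(b1 - b2) / b2, 0.01)
})

test_that("hydrogen bonds are detected by distance and vetoed by geometry", {
    # O...O pair at 2.8 A, no hydrogens: distance-only mode
    at <- rbind(mkAtoms(0, 0, 0, name = "OG", element = "O",
                        resname = "SER", resno = 1),
                mkAtoms(2.8, 0, 0, name = "OG", element = "O",
                        resname = "SER", resno = 5))
    at$serial <- 1:2
    hb <- findHBonds(Structure(at))
    expect_equal(nrow(hb), 1L)
    expect_equal(hb$distance_A, 2.8)
    expect_equal(hb$mode, "distance")
    # at 4.0 A: nothing
    at2 <- at; at2$x[2] <- 4.0
    expect_equal(nrow(findHBonds(Structure(at2))), 0L)
    # explicit H at a 90-degree donor angle: rejected
    at3 <- rbind(at, mkAtoms(0, 1.0, 0, name = "HG", element = "H",
                             resname = "SER", resno = 1))
    at3$serial <- 1:3
    expect_equal(nrow(findHBonds(Structure(at3))), 0L)
    # H pointing at the acceptor: accepted with angle reported
    at4 <- at3; at4$x[3] <- 1.0; at4$y[3] <- 0
    hb4 <- findHBonds(Structure(at4))
    expect_equal(nrow(hb4), 1L)
    expect_equal(hb4$mode, "distance+angle")
    expect_gt(hb4$angle_deg, 179)
})

test_that("cation-pi pairs use ring and guanidinium centroids", {
    ring <- function(cx) {
        ang <- seq(0, 2 * pi, length.out = 7)[1:6]
        mkAtoms(cx + 1.39 * cos(ang), 1.39 * sin(ang), rep(0, 6),
                name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                element = "C", resname = "PHE", resno = 10)
    }
    arg <- function(d) {
        at <- mkAtoms(c(d, d + 0.7, d + 0.7, d + 1.4),
                      c(0, 0.6, -0.6, 0), rep(0, 4),
                      name = c("NE", "CZ", "NH1", "NH2"),
                      element = c("N", "C", "N", "N"), resname = "ARG",
                      resno = 20)
        at
    }
    near <- rbind(ring(0), arg(3.8))        # centroid separation ~4.5 A
    near$serial <- seq_len(nrow(near))
    hits <- findCationPi(Structure(near))
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$ring_resno, 10L)
    expect_equal(hits$cation_resno, 20L)
    far <- rbind(ring(0), arg(6.3))         # centroid separation ~7 A
    far$serial <- seq_len(nrow(far))
    expect_equal(nrow(findCationPi(Structure(far))), 0L)
    # no aromatics at all
    expect_equal(nrow(findCationPi(toyBundle())), 0L)
})
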