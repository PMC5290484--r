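test_that("phosphate contact rule is inclusive at 1 nm", {
  topo <- contactTopology(360, nPIP = 1)
  place <- function(dist) frame(0, c(10, 10, 10),
                                rbind(c(5, 5, 5), c(5, 5, 5 + dist)))
  expect_equal(pipContacts(place(0.99), topo), 1L)
  expect_equal(pipContacts(place(1.00), topo), 1L)   # inclusive cutoff
  expect_length(pipContacts(place(1.01), topo), 0)
  expect_warning(out <- pipContacts(place(0.5), topo, role = "PIP2"),
                 "absent")
  expect_length(out, 0)
})

test_that("cell-list contacts equal brute force and an independent oracle", {
  set.seed(6)
  cfg <- analysisConfig()
  for (rep in 1:25) {
    nL <- sample(20:60, 1)
    topo <- contactTopology(360:365, nPIP = nL)
    box <- c(runif(1, 4, 8), runif(1, 4, 8), runif(1, 4, 8))
    co <- rbind(matrix(runif(18, 0, box[1]), 6, 3),
                matrix(runif(nL * 3, -2, 12), nL, 3))
    f <- frame(0, box, co)
    a <- pipContacts(f, topo, cfg, method = "cell")
    b <- pipContacts(f, topo, cfg, method = "brute")
    expect_identical(a, b)
    expect_identical(a, oracleContacts(f, topo, cfg$contactCutoff))
  }
})

test_that("bound-only contact series keeps exactly the bound frames", {
  # protein 4 beads around z; bilayer proxied by 2 lipids at z = 3
  rows <- rbind(pRow(0:3, paste0("BB", 1:4), 360:363, "PHD", 0L, "protein",
                     bb = TRUE),
                pRow(4:5, "P1", 1001:1002, "PIP3", 1:2, "lipid:PIP3",
                     phos = TRUE))
  topo <- topology(rows)
  mk <- function(zProt) {
    co <- rbind(sweep(refGeom4(), 2, c(5, 5, zProt), "+"),
                c(5, 5, 3), c(8, 8, 3))
    frame(zProt, c(10, 10, 20), co)
  }
  tr <- trajectory(topo, lapply(c(6.5, 7.0, 9.5), mk))  # d_z 3.5, 4, 6.5
  ref <- referenceOrientation(tr)
  s <- orientationSeries(tr, ref)
  expect_equal(s$bound, c(TRUE, TRUE, FALSE))
  cs <- contactCountSeries(tr, s, boundOnly = TRUE)
  expect_equal(nrow(cs$frames), 2)
  csAll <- contactCountSeries(tr, s, boundOnly = FALSE)
  expect_gte(sum(csAll$frames$n_contacts), sum(cs$frames$n_contacts))
  expect_error(contactCountSeries(tr, s[1:2, ]), "aligned")
  # no bound frames at all -> empty series, not an error
  trU <- trajectory(topo, lapply(c(9.5, 9.8), mk))
  sU <- orientationSeries(trU, ref)
  expect_equal(nrow(contactCountSeries(trU, sU, boundOnly = TRUE)$frames), 0)
})

test_that("residue contact ranking counts per frame per lipid", {
  rows <- rbind(pRow(0:2, paste0("BB", 1:3), c(360, 362, 370), "PHD", 0L,
                     "protein", bb = TRUE),
                pRow(3L, "P1", 1001L, "PIP3", 1L, "lipid:PIP3", phos = TRUE))
  topo <- topology(rows)
  co <- rbind(c(5, 5, 5), c(5, 5, 6), c(5, 5, 7), c(5, 5, 6.2))
  tr <- trajectory(topo, list(frame(0, c(10, 10, 10), co),
                              frame(1, c(10, 10, 10), co)))
  rk <- residueContactRanking(tr)
  expect_equal(rk$residue_id[1], 362)       # held nearest the only PIP
  expect_equal(rk$count[1], 2)              # once per frame
  # a lipid can touch several residues: sum >= per-lipid contact events
  expect_gte(sum(rk$count), 2)
  # no contacts anywhere: zero counts, residue-id order
  far <- co; far[4, 3] <- 1.0
  tr0 <- trajectory(topo, list(frame(0, c(10, 10, 10), far)))
  rk0 <- residueContactRanking(tr0)
  expect_equal(rk0$count, rep(0L, 3))
  expect_equal(rk0$residue_id, c(360, 362, 370))
})

test_that("leaflet assignment splits at the lipid-COM midplane, ties to upper", {
  rows <- rbind(pRow(0L, "BB1", 360L, "PHD", 0L, "protein", bb = TRUE),
                pRow(1:3, "P1", 1001:1003, "PIP3", 1:3, "lipid:PIP3",
                     phos = TRUE))
  topo <- topology(rows)
  co <- rbind(c(5, 5, 9), c(5, 5, 3), c(5, 5, 7), c(5, 5, 5))  # midplane 5
  la <- leafletAssign(frame(0, c(10, 10, 20), co), topo)
  expect_equal(unname(la[c("1", "2", "3")]), c("lower", "upper", "upper"))
  expect_equal(attr(la, "midplane"), 5)
  expect_equal(attr(la, "proximal"), "upper")  # protein at z = 9
})

test_that("leaflet assignment reproduces the generator's labels exactly", {
  r <- generateEncounterTrajectory(syntheticConfig(seed = 13, nFrames = 5,
                                                   nEquil = 5))
  topo <- r$trajectory@topology
  mols <- unique(particles(topo)$molecule_id[grepl("^lipid:",
                                                   particles(topo)$role)])
  for (f in frames(r$trajectory)) {
    la <- leafletAssign(f, topo)
    expect_identical(unname(la[as.character(mols)]), r$truth$lipidLeaflet)
  }
})

test_that("annulus occupancy counts by leaflet and adds up", {
  rows <- rbind(pRow(0L, "BB1", 360L, "PHD", 0L, "protein", bb = TRUE),
                pRow(1:7, "P1", 1001:1007, "PIP3", 1:7, "lipid:PIP3",
                     phos = TRUE))
  topo <- topology(rows)
  # 4 phosphates at 0.5 nm from the protein, 3 at 2.5 nm, two leaflets
  co <- rbind(c(5, 5, 7),
              c(5, 5.5, 7), c(5.5, 5, 7), c(4.5, 5, 7), c(5, 4.5, 7),
              c(5, 7.5, 7), c(7.5, 5, 7), c(2.5, 5, 3))
  f <- frame(0, c(10, 10, 10), co)
  cfg <- analysisConfig()
  expect_equal(annulusCount(f, topo, cfg, leaflet = "both"), 4L)
  expect_equal(annulusCount(f, topo, cfg, leaflet = "proximal") +
                 annulusCount(f, topo, cfg, leaflet = "distal"),
               annulusCount(f, topo, cfg, leaflet = "both"))
  expect_equal(annulusCount(f, topo, cfg, role = "PIP2"), 0L)
})

test_that("binding-site calls follow the loop-fraction rules", {
  loops <- list(beta12 = c(360, 372), beta34 = c(380, 390),
                beta56 = c(400, 410))
  mk <- function(ids, n) data.frame(residue_id = ids, count = n)
  expect_equal(classifyBindingSite(mk(c(362, 365, 385), c(5, 4, 6)),
                                   loops)$label, "canonical")
  expect_equal(classifyBindingSite(mk(c(362, 365, 405), c(5, 4, 6)),
                                   loops)$label, "non-canonical")
  expect_equal(classifyBindingSite(mk(362, 0), loops)$label, "none")
  # mostly non-loop contacts -> none
  expect_equal(classifyBindingSite(mk(c(362, 420), c(1, 99)), loops)$label,
               "none")
  fr <- classifyBindingSite(mk(c(362, 385, 420), c(3, 2, 5)), loops)$fractions
  expect_lte(sum(fr), 1)
  expect_error(classifyBindingSite(mk(362, 1),
                                   list(beta12 = c(360, 372),
                                        beta34 = c(370, 380),
                                        beta56 = c(400, 410))), "overlap")
  expect_error(classifyBindingSite(mk(362, 1),
                                   list(beta12 = c(360, 372), beta34 = NULL,
                                        beta56 = NULL)), "configured")
})

test_that("interaction persistence reports fraction and break events", {
  rows <- rbind(pRow(0L, "NH1", 360L, "ARG", 0L, "protein"),
                pRow(1L, "OE1", 396L, "GLN", 0L, "protein"))
  topo <- topology(rows)
  mk <- function(d, t) frame(t, c(10, 10, 10),
                             rbind(c(5, 5, 5), c(5, 5, 5 + d)))
  alternating <- trajectory(topo, lapply(0:9, function(t)
    mk(if (t %% 2 == 0) 0.3 else 0.6, t)))
  ip <- interactionPersistence(alternating, 0, 1, cutoff = 0.35)
  expect_equal(ip$fraction, 0.5)
  expect_equal(ip$breaks, 5)
  always <- trajectory(topo, lapply(0:9, function(t) mk(0.3, t)))
  ipA <- interactionPersistence(always, 0, 1, cutoff = 0.35)
  expect_equal(ipA$fraction, 1.0)
  expect_equal(ipA$breaks, 0)
  never <- trajectory(topo, lapply(0:9, function(t) mk(0.6, t)))
  ipN <- interactionPersistence(never, 0, 1, cutoff = 0.35)
  expect_equal(ipN$fraction, 0.0)
  expect_equal(ipN$breaks, 1)
  expect_error(interactionPersistence(always, 0, 0), "identical")
  # residue-level addressing and permutation invariance of the fraction
  ipR <- interactionPersistence(alternating, 360, 396, cutoff = 0.35,
                                type = "residue")
  expect_equal(ipR$fraction, 0.5)
  # same contact multiset in a different order: fraction unchanged, break
  # count not (documented)
  perm <- trajectory(topo, lapply(0:9, function(t)
    mk(if (t < 5) 0.6 else 0.3, t)))
  ipP <- interactionPersistence(perm, 0, 1, cutoff = 0.35)
  expect_equal(ipP$fraction, ip$fraction)
  expect_equal(ipP$breaks, 1)
})
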