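mkFrame <- function(coords, box = c(10, 10, 10)) frame(0, box, coords)

test_that("protein-bilayer separation uses mass-weighted, image-corrected COMs", {
  topo <- topology(rbind(pRow(0:1, c("BB1", "BB2"), 360:361, "PHD", 0L,
                              "protein", bb = TRUE),
                         pRow(2:3, c("PO4", "PO4"), 1:2, "POPC", 1:2,
                              "lipid:POPC")))
  f <- mkFrame(rbind(c(5, 5, 7), c(5, 5, 7), c(5, 5, 3), c(5, 5, 3)))
  expect_equal(dzProteinBilayer(f, topo), 4.0)
  # symmetry: equal-mass protein straddling the bilayer COM
  f2 <- mkFrame(rbind(c(5, 5, 2), c(5, 5, 4), c(5, 5, 3), c(5, 5, 3)))
  expect_equal(dzProteinBilayer(f2, topo), 0.0)
  # protein split across the periodic z boundary: COM wraps to 10.0, and the
  # COM difference to the bilayer at z = 3 is the 3.0 nm minimum image
  f3 <- mkFrame(rbind(c(5, 5, 9.9), c(5, 5, 0.1), c(5, 5, 3), c(5, 5, 3)))
  expect_equal(dzProteinBilayer(f3, topo), 3.0)
  expect_error(dzProteinBilayer(f, contactTopology(nPIP = 0)), "lipid")
})

test_that("Rzz equals the closed-form value for single-axis rotations", {
  g <- refGeom4()
  topo <- contactTopology(360:363, nPIP = 0)
  ref <- structure(list(ids = 0:3, coords = g), class = "ReferenceOrientation")
  expect_equal(rzz(mkFrame(g + 5), ref), 1.0, tolerance = 1e-9)
  expect_equal(rzz(mkFrame(g %*% t(rotX(pi)) + 5), ref), -1.0,
               tolerance = 1e-9)
  expect_equal(rzz(mkFrame(g %*% t(rotY(pi / 3)) + 5), ref), 0.5,
               tolerance = 1e-9)
  expect_equal(rzz(mkFrame(g %*% t(rotX(pi / 4)) + 5), ref), cos(pi / 4),
               tolerance = 1e-9)
})

test_that("Rzz is invariant to rigid translations of the frame", {
  g <- refGeom4()
  ref <- structure(list(ids = 0:3, coords = g), class = "ReferenceOrientation")
  set.seed(11)
  for (i in 1:20) {
    th <- runif(1, 0, pi)
    rot <- rotY(th) %*% rotX(runif(1, 0, pi))
    shift <- runif(3, 0, 3)
    v0 <- rzz(mkFrame(g %*% t(rot) + 2), ref)
    v1 <- rzz(mkFrame(sweep(g %*% t(rot), 2, shift, "+")), ref)
    expect_equal(v0, v1, tolerance = 1e-9)
    expect_lte(abs(v1), 1 + 1e-9)
  }
})

test_that("bound classification is strict at the threshold and monotone", {
  expect_true(classifyBound(4.0))
  expect_false(classifyBound(4.75))   # strict "smaller than"
  expect_true(classifyBound(0))
  d <- sort(runif(50, 0, 8))
  b <- classifyBound(d)
  # monotone: once unbound, never bound again at larger separation
  expect_true(all(diff(as.integer(b)) <= 0))
})

test_that("landscape histograms conserve counts and resolve the mode", {
  s1 <- data.frame(time = 0, d_z = 4.0, r_zz = 0.8, bound = TRUE)
  l1 <- orientationLandscape(s1)
  expect_equal(sum(l1@counts), 1)
  expect_equal(sum(l1@density), 1)
  mb <- modeBin(l1)
  expect_true(mb$dz[1] <= 4.0 && 4.0 <= mb$dz[2])
  # conservation on a random series, nothing dropped at range edges
  set.seed(2)
  s <- data.frame(time = seq_len(500), d_z = runif(500, 3, 6),
                  r_zz = runif(500, -1, 1), bound = TRUE)
  l <- orientationLandscape(s)
  expect_equal(sum(l@counts), 500)
  # mode ties break toward smaller separation
  s2 <- data.frame(time = 1:2, d_z = c(5.05, 3.05), r_zz = c(0.52, 0.52),
                   bound = TRUE)
  l2 <- orientationLandscape(s2)
  expect_equal(modeBin(l2)$dz, c(3.0, 3.1), tolerance = 1e-9)
  # filtering away every frame is an explicit error
  s3 <- data.frame(time = 1, d_z = 6.0, r_zz = 0, bound = FALSE)
  expect_error(orientationLandscape(s3, boundOnly = TRUE), "empty")
})

test_that("RMSF vanishes for static and rigidly moving structures", {
  g <- refGeom4() + 5
  topo <- contactTopology(360:363, nPIP = 0)
  static <- trajectory(topo, lapply(0:4, function(t)
    frame(t, c(10, 10, 10), g)))
  r0 <- rmsf(static)
  expect_equal(r0$rmsf, rep(0, 4), tolerance = 1e-9)
  set.seed(3)
  rigid <- trajectory(topo, lapply(0:9, function(t)
    frame(t, c(10, 10, 10),
          sweep(refGeom4() %*% t(rotY(runif(1, 0, pi)) %*%
                                   rotX(runif(1, 0, pi))),
                2, runif(3, 2, 8), "+"))))
  rr <- rmsf(rigid)
  expect_equal(rr$rmsf, rep(0, 4), tolerance = 1e-9)
})

test_that("RMSF recovers the amplitude of an isolated oscillation", {
  d <- 0.3
  base <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1), c(2, 2, 2)) + 4
  topo <- contactTopology(360:364, nPIP = 0)
  frs <- lapply(0:9, function(t) {
    co <- base
    co[5, 1] <- co[5, 1] + d * (-1)^t   # +/- d about its mean, no net rotation
    frame(t, c(10, 10, 10), co)
  })
  tr <- trajectory(topo, frs)
  ref <- referenceOrientation(tr, ids = 0:3)
  out <- rmsf(tr, reference = ref, alignIds = 0:3, ids = 0:4)
  expect_equal(out$rmsf[out$residue_id == 364], d, tolerance = 1e-9)
  expect_equal(out$rmsf[out$residue_id != 364], rep(0, 4), tolerance = 1e-9)
  expect_error(rmsf(trajectory(topo, frs[1])), ">= 2 frames")
})

test_that("RMSF is invariant under a global rigid transform of all frames", {
  set.seed(4)
  base <- refGeom4() + 5
  topo <- contactTopology(360:363, nPIP = 0)
  frs <- lapply(0:7, function(t)
    frame(t, c(20, 20, 20), base + matrix(rnorm(12, 0, 0.05), 4, 3)))
  tr <- trajectory(topo, frs)
  rot <- rotY(0.7) %*% rotX(1.1)
  frs2 <- lapply(frs, function(f)
    frame(f$time, f$box, sweep(f$coords %*% t(rot), 2, c(3, 2, 1), "+")))
  tr2 <- trajectory(topo, frs2)
  ref <- referenceOrientation(tr)
  expect_equal(rmsf(tr, ref)$rmsf, rmsf(tr2, ref)$rmsf, tolerance = 1e-8)
})

test_that("Kabsch superposition agrees with the bio3d oracle", {
  set.seed(5)
  g <- matrix(rnorm(30), 10, 3)
  rot <- rotY(0.9) %*% rotX(0.4)
  cur <- sweep(g %*% t(rot), 2, c(1, 2, 3), "+")
  R <- kabschRotation(g, cur)
  expect_equal(R, rot, tolerance = 1e-9)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(g)),
                                            mobile = as.numeric(t(cur))))
  aligned <- sweep(cur, 2, colMeans(cur)) %*% R
  aligned <- sweep(aligned, 2, colMeans(g), "+")
  expect_equal(as.numeric(t(aligned)), as.numeric(fitted), tolerance = 1e-6)
})
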