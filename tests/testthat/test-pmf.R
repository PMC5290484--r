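flatWin <- function(z0s, n = 1500, k = 1000, seed = 1)
  generateUmbrellaSamples(list(form = "flat"), data.frame(z0 = z0s, k = k),
                          nSamples = n, seed = seed)

test_that("window planning follows the fine/coarse spacing protocol", {
  ctr <- planUmbrellaCenters(umbrellaPlan(start = 1.0))
  expect_length(ctr, 24)                       # 21 fine + 3 coarse
  expect_equal(ctr[1:3], c(1.0, 1.1, 1.2))
  expect_equal(tail(ctr, 4), c(3.0, 3.2, 3.4, 3.6))
  expect_true(all(diff(ctr) > 0))
  expect_length(planUmbrellaCenters(umbrellaPlan(0, total = 2.0)), 21)
  expect_length(planUmbrellaCenters(umbrellaPlan(0, total = 2.05)), 21)
  expect_error(umbrellaPlan(0, total = 1.5), "fine range")
})

test_that("window extraction picks nearest frames from a constant-rate pull", {
  rows <- rbind(pRow(0:3, paste0("BB", 1:4), 360:363, "PHD", 0L, "protein",
                     bb = TRUE),
                pRow(4L, "P1", 1001L, "PIP3", 1L, "lipid:PIP3", phos = TRUE))
  topo <- topology(rows)
  # pull at 0.001 nm/ps, frames every 20 ps: separations 0.5 + 0.02 i
  mk <- function(i) {
    co <- rbind(sweep(refGeom4(), 2, c(5, 5, 5 + 0.5 + 0.02 * i), "+"),
                c(5, 5, 5))
    frame(20 * i, c(10, 10, 20), co)
  }
  tr <- trajectory(topo, lapply(0:135, mk))   # spans 0.5 .. 3.2 nm
  plan <- umbrellaPlan(start = 0.5)
  w <- extractWindows(tr, plan, anchor = 4L)
  expect_equal(nrow(w), 24)
  expect_true(all(abs(w$rc - w$center) <= 0.01 + 1e-9))
  # ties resolve to the earliest frame
  trTie <- trajectory(topo, lapply(c(0:135, 135), mk))
  wT <- extractWindows(trTie, plan, anchor = 4L)
  expect_equal(wT$frame, w$frame)
  # a pull that stops short lists the unreachable centres
  trShort <- trajectory(topo, lapply(0:60, mk))
  expect_error(extractWindows(trShort, plan, anchor = 4L), "unreachable")
})

test_that("a single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(7)
  s <- rnorm(5000, 2, 0.25)
  p <- wham(list(umbrellaWindow(2, 0, s)), binWidth = 0.05, temperature = 323)
  h <- sampleCounts(p)
  ok <- h > 0
  direct <- -kT(323) * log(h[ok] / sum(h))
  direct <- direct - min(direct)
  expect_lt(max(abs(freeEnergy(p)[ok] - direct)), 1e-10)
  expect_true(all(is.na(freeEnergy(p)[!ok])))   # missing marker, never 0
})

test_that("WHAM is invariant to window relabeling and k units", {
  wins <- flatWin(seq(1, 2, 0.1), n = 800, seed = 12)
  p1 <- wham(wins)
  p2 <- wham(rev(wins))
  expect_lt(max(abs(freeEnergy(p1) - freeEnergy(p2)), na.rm = TRUE), 1e-8)
  winsKcal <- lapply(wins, function(w)
    umbrellaWindow(w$z0, kJToKcal(w$k), w$samples, units = "kcal"))
  p3 <- wham(winsKcal)
  expect_lt(max(abs(freeEnergy(p1) - freeEnergy(p3)), na.rm = TRUE), 1e-10)
})

test_that("disconnected windows raise a connectivity error naming the gap", {
  wins <- flatWin(c(1.0, 5.0), n = 500, seed = 3)
  expect_error(wham(wins), "overlap")
})

test_that("bulk shifting zeroes the bulk, is idempotent and gauge-invariant", {
  wins <- flatWin(seq(1, 2, 0.1), n = 800, seed = 14)
  p <- wham(wins)
  s1 <- shiftToBulk(p)
  idx <- sampleCounts(s1) > 0 & binCenters(s1) >= max(binCenters(s1)[sampleCounts(s1) > 0]) -
    0.1 * diff(range(binCenters(s1)[sampleCounts(s1) > 0]))
  wmean <- sum(freeEnergy(s1)[idx] * sampleCounts(s1)[idx]) /
    sum(sampleCounts(s1)[idx])
  expect_lt(abs(wmean), 1e-9)
  s2 <- shiftToBulk(s1)
  expect_equal(freeEnergy(s1), freeEnergy(s2), tolerance = 1e-12)
  # uniform gauge offsets do not change well depths (min - bulk)
  off <- new("PMFProfile", z = p@z, G = p@G + 5, errors = p@errors,
             counts = p@counts, temperature = p@temperature,
             bulkShifted = FALSE, iterations = p@iterations)
  expect_equal(min(freeEnergy(shiftToBulk(off)), na.rm = TRUE),
               min(freeEnergy(s1), na.rm = TRUE), tolerance = 1e-9)
  # constant profile shifts to all zeros
  const <- new("PMFProfile", z = seq(0.025, 0.975, 0.05), G = rep(5, 20),
               errors = rep(NA_real_, 20), counts = rep(10, 20),
               temperature = 323, bulkShifted = FALSE, iterations = 0)
  expect_equal(freeEnergy(shiftToBulk(const)), rep(0, 20))
})

test_that("bootstrap errors are reproducible, vanish for constant data and scale ~ 1/sqrt(n)", {
  # deterministic samples in one window: zero spread
  wDet <- list(umbrellaWindow(2, 1000, rep(2, 200)))
  eDet <- bootstrapErrors(wDet, nBoot = 10, seed = 2)
  expect_true(all(eDet[sampleCounts(attr(eDet, "profile")) > 0] == 0))
  # seeded reproducibility, bit-exact
  wins <- flatWin(seq(1.6, 2.4, 0.2), n = 400, seed = 4)
  e1 <- bootstrapErrors(wins, nBoot = 15, seed = 9)
  e2 <- bootstrapErrors(wins, nBoot = 15, seed = 9)
  expect_identical(as.numeric(e1), as.numeric(e2))
  # quadrupling the per-window sample count roughly halves the mean error
  winsBig <- flatWin(seq(1.8, 2.2, 0.1), n = 1600, seed = 5)
  eBig <- bootstrapErrors(winsBig, nBoot = 40, seed = 10)
  eSmall <- bootstrapErrors(flatWin(seq(1.8, 2.2, 0.1), n = 400, seed = 5),
                            nBoot = 40, seed = 10)
  ratio <- mean(eBig, na.rm = TRUE) / mean(eSmall, na.rm = TRUE)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("sequential-block convergence flags a drifted first half", {
  set.seed(15)
  z0s <- seq(1.4, 2.6, 0.1)
  kk <- kJToKcal(1000)
  sdW <- sqrt(kT(323) / kk)
  stationary <- lapply(z0s, function(z0)
    umbrellaWindow(z0, 1000, rnorm(1200, z0, sdW)))
  cv <- convergenceProfiles(stationary, blockLength = 600)
  expect_equal(cv$equilibrationBlock, 2)
  expect_true(all(cv$metric[-1] < 0.3))
  # deliberate drift in the first half: first block differs, later ones agree
  drifted <- lapply(z0s, function(z0)
    umbrellaWindow(z0, 1000, c(rnorm(600, z0 + 0.35, sdW),
                               rnorm(600, z0, sdW))))
  cvD <- convergenceProfiles(drifted, blockLength = 600,
                             range = c(1.4, 3.0))
  expect_equal(cvD$equilibrationBlock, 2)
  # bookkeeping: pooled post-equilibration samples = final-profile input
  for (i in seq_along(z0s))
    expect_identical(cvD$finalWindows[[i]]$samples,
                     drifted[[i]]$samples[601:1200])
  expect_error(convergenceProfiles(stationary, blockLength = 1000),
               ">= 2")
})

test_that("well extraction finds parabolic minima and ignores flat profiles", {
  z <- seq(0.025, 1.975, 0.05)
  para <- new("PMFProfile", z = z, G = 3 * (z - 1)^2 - 1 + 0,
              errors = rep(0.01, length(z)), counts = rep(100, length(z)),
              temperature = 323, bulkShifted = TRUE, iterations = 0)
  wp <- findWells(para)
  expect_equal(nrow(wp), 1)
  expect_lt(abs(wp$z - 1.0), 0.05 + 1e-9)
  flat <- new("PMFProfile", z = z, G = rep(0, length(z)),
              errors = rep(0.01, length(z)), counts = rep(100, length(z)),
              temperature = 323, bulkShifted = TRUE, iterations = 0)
  expect_equal(nrow(findWells(flat)), 0)
  mono <- new("PMFProfile", z = z, G = z * 2,
              errors = rep(0.01, length(z)), counts = rep(100, length(z)),
              temperature = 323, bulkShifted = TRUE, iterations = 0)
  expect_equal(nrow(findWells(mono)), 0)
  expect_error(findWells(new("PMFProfile", z = z, G = z, errors = z * 0,
                             counts = rep(1, length(z)), temperature = 323,
                             bulkShifted = FALSE, iterations = 0)),
               "bulk-shifted")
})
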