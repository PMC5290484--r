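## Umbrella-sampling bookkeeping and free-energy estimation: window planning,
## a from-scratch WHAM solver, bulk-zero shifting, bootstrap errors,
## sequential-block convergence diagnostics, and well extraction.

#' Umbrella window container
#'
#' @param z0 window centre (nm).
#' @param k harmonic force constant on the reaction coordinate; `units`
#'   `"kJ"` means kJ/mol/nm^2 (GROMACS convention), `"kcal"` kcal/mol/nm^2.
#'   `k = 0` is admitted as the unbiased special case.
#' @param samples reaction-coordinate values (nm).
#' @param kxy lateral restraint constant (bookkeeping only; a 1-D estimator
#'   never uses it).
#' @param interval sampling interval (ps), provenance only.
#' @param units unit of `k` (and `kxy`).
#' @return list of class `UmbrellaWindow`.
#' @export
umbrellaWindow <- function(z0, k, samples, kxy = NULL, interval = NULL,
                           units = c("kJ", "kcal")) {
  units <- match.arg(units)
  stopifnot(is.numeric(z0), length(z0) == 1, is.numeric(k), k >= 0)
  if (length(samples) && any(!is.finite(samples)))
    stop("umbrella window samples must all be finite")
  structure(list(z0 = z0, k = k, samples = as.numeric(samples), kxy = kxy,
                 interval = interval, units = units),
            class = "UmbrellaWindow")
}

kKcal <- function(w) if (w$units == "kJ") kJToKcal(w$k) else w$k

#' Umbrella window placement plan
#'
#' The pulling protocol this mirrors: the protein is pulled along the
#' membrane normal at `pullRate` for `total` nm, and snapshots are taken at
#' `fineSpacing` intervals over the first `fineRange` nm of separation and at
#' `coarseSpacing` intervals thereafter.
#'
#' @param start initial separation (nm).
#' @param total total pull distance (nm); must be >= `fineRange`.
#' @param fineSpacing,fineRange,coarseSpacing nm.
#' @param pullRate nm/ps (provenance only).
#' @return list of class `UmbrellaPlan`.
#' @export
umbrellaPlan <- function(start, total = 2.6, fineSpacing = 0.1,
                         fineRange = 2.0, coarseSpacing = 0.2,
                         pullRate = 0.001) {
  stopifnot(fineSpacing > 0, coarseSpacing > 0, fineRange > 0)
  if (total < fineRange)
    stop("total pull distance (", total, ") is smaller than the fine range (",
         fineRange, ")")
  structure(list(start = start, total = total, fineSpacing = fineSpacing,
                 fineRange = fineRange, coarseSpacing = coarseSpacing,
                 pullRate = pullRate),
            class = "UmbrellaPlan")
}

#' Planned umbrella window centres
#'
#' `start + {0, fine, ..., fineRange}` followed by coarse steps up to (and
#' including, within 1e-9) `start + total`; strictly increasing, rounded to
#' 1e-6 nm.
#'
#' @param plan an [umbrellaPlan()].
#' @return numeric vector of centres (nm).
#' @examples
#' length(planUmbrellaCenters(umbrellaPlan(0.5)))  # 24: 21 fine + 3 coarse
#' @export
planUmbrellaCenters <- function(plan) {
  stopifnot(inherits(plan, "UmbrellaPlan"))
  fine <- seq(0, plan$fineRange, by = plan$fineSpacing)
  coarse <- numeric(0)
  x <- plan$fineRange + plan$coarseSpacing
  while (x <= plan$total + 1e-9) {
    coarse <- c(coarse, x)
    x <- x + plan$coarseSpacing
  }
  round(plan$start + c(fine, coarse), 6)
}

#' Extract umbrella starting frames from a pull trajectory
#'
#' The reaction coordinate is the z component of (protein COM - anchor); for
#' each planned centre the frame whose coordinate is nearest is selected
#' (earliest frame on ties).  A centre with no frame within half the local
#' spacing is unreachable and triggers an error listing all missing centres.
#'
#' @param pullTraj a [Trajectory-class].
#' @param plan an [umbrellaPlan()].
#' @param anchor either a 0-based particle id (its z is the anchor) or a
#'   fixed z position (nm) when given as `list(z = ...)`.
#' @return data.frame `center`, `frame`, `rc`, `time`.
#' @export
extractWindows <- function(pullTraj, plan, anchor) {
  p <- particles(pullTraj@topology)
  ip <- which(p$role == "protein")
  rcOf <- function(f) {
    comP <- massCOM(makeWhole(f$coords[ip, , drop = FALSE], f$box),
                    p$mass[ip])
    az <- if (is.list(anchor)) anchor$z else f$coords[match(anchor, p$id), 3]
    comP[3] - az
  }
  rc <- vapply(frames(pullTraj), rcOf, numeric(1))
  centers <- planUmbrellaCenters(plan)
  spacing <- ifelse(centers - plan$start <= plan$fineRange + 1e-9,
                    plan$fineSpacing, plan$coarseSpacing)
  pick <- integer(length(centers))
  miss <- character(0)
  for (i in seq_along(centers)) {
    dev <- abs(rc - centers[i])
    j <- which.min(dev)            # which.min returns the earliest tie
    if (dev[j] > 0.5 * spacing[i]) miss <- c(miss, format(centers[i]))
    pick[i] <- j
  }
  if (length(miss))
    stop("unreachable umbrella centre(s): ", paste(miss, collapse = ", "),
         " (pull trajectory does not span the plan)")
  data.frame(center = centers, frame = pick, rc = rc[pick],
             time = frameTimes(pullTraj)[pick])
}

#' Weighted histogram analysis method (WHAM)
#'
#' Self-consistent estimation of the unbiased profile from harmonically
#' biased windows: iterate the window free energies `f_i` and the unbiased
#' bin probabilities
#' `P(b) = sum_i H_i(b) / sum_i n_i exp((f_i - w_i(b))/kT)`,
#' `exp(-f_i/kT) = sum_b P(b) exp(-w_i(b)/kT)`,
#' until `max |delta f| < tol`; then `G(z) = -kT ln P(z)`, reported with
#' `min G = 0` over sampled bins.  A single window with `k = 0` degenerates
#' to Boltzmann inversion of its histogram.  Bins never sampled carry `NA`.
#'
#' @param windows list of [umbrellaWindow()].
#' @param binWidth nm (default 0.05).
#' @param temperature kelvin.
#' @param tol convergence tolerance on `max |delta f|` (kcal/mol).
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param range optional `c(lo, hi)` histogram range (nm); default: the span
#'   of the window centres (of the samples for a single unbiased window).
#'   Samples outside the range are not histogrammed.
#' @return a [PMFProfile-class] (unshifted; see [shiftToBulk()]).
#' @export
wham <- function(windows, binWidth = 0.05, temperature = 323, tol = 1e-7,
                 maxIter = 1e5, range = NULL) {
  stopifnot(length(windows) >= 1, binWidth > 0)
  for (w in windows)
    if (!length(w$samples)) stop("every window needs samples")
  kt <- kT(temperature)
  ord <- order(vapply(windows, `[[`, numeric(1), "z0"))
  windows <- windows[ord]
  z0 <- vapply(windows, `[[`, numeric(1), "z0")
  if (is.null(range)) {
    range <- if (length(windows) == 1 && windows[[1]]$k == 0)
      base::range(windows[[1]]$samples) else base::range(z0)
  }
  lo <- floor(range[1] / binWidth - 1e-9) * binWidth
  hi <- ceiling(range[2] / binWidth + 1e-9) * binWidth
  edges <- seq(lo, hi, by = binWidth)
  if (length(edges) < 2) edges <- c(lo, lo + binWidth)
  nb <- length(edges) - 1
  centers <- edges[-1] - binWidth / 2
  nw <- length(windows)
  H <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    b <- binIndex(s, edges)
    b <- b[!is.na(b)]
    H[i, ] <- tabulate(b, nb)
  }
  # connectivity: neighbouring windows must share a sampled bin
  if (nw > 1) for (i in seq_len(nw - 1)) {
    if (!any(H[i, ] > 0 & H[i + 1, ] > 0))
      stop("umbrella windows do not overlap between z0 = ", z0[i], " and ",
           z0[i + 1], " nm: WHAM support is disconnected")
  }
  n <- rowSums(H)
  Nb <- colSums(H)
  sampled <- Nb > 0
  # bias energies in kT units: B[i, b] = w_i(z_b)/kT
  B <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    kk <- kKcal(windows[[i]])
    B[i, ] <- 0.5 * kk * (centers - z0[i])^2 / kt
  }
  logn <- log(n)
  logNb <- ifelse(sampled, log(Nb), -Inf)
  fr <- rep(0, nw)                       # f_i / kT
  iter <- 0
  repeat {
    iter <- iter + 1
    M <- (logn + fr) - B                 # nw x nb
    cmax <- apply(M, 2, max)
    logDen <- cmax + log(colSums(exp(sweep(M, 2, cmax))))
    logP <- logNb - logDen               # -Inf on unsampled bins
    A <- sweep(-B, 2, logP, "+")         # log(P_b) - B[i,b]
    A[, !sampled] <- -Inf
    rmax <- apply(A, 1, max)
    frNew <- -(rmax + log(rowSums(exp(A - rmax))))
    frNew <- frNew - frNew[1]
    delta <- max(abs(frNew - fr)) * kt
    fr <- frNew
    if (delta < tol) break
    if (iter >= maxIter)
      stop("WHAM did not converge in ", maxIter,
           " iterations (residual ", format(delta), " kcal/mol)")
  }
  M <- (logn + fr) - B
  cmax <- apply(M, 2, max)
  logP <- logNb - (cmax + log(colSums(exp(sweep(M, 2, cmax)))))
  G <- -kt * logP
  G[!sampled] <- NA_real_
  G <- G - min(G, na.rm = TRUE)
  new("PMFProfile", z = centers, G = G, errors = rep(NA_real_, nb),
      counts = Nb, temperature = temperature, bulkShifted = FALSE,
      iterations = iter)
}

# indices of the bulk bins: outermost fraction (largest z) of the sampled
# range, or an explicit z interval
bulkBins <- function(profile, bulk) {
  sampled <- which(sampleCounts(profile) > 0)
  if (!length(sampled)) stop("profile has no sampled bins")
  z <- binCenters(profile)
  idx <- if (length(bulk) == 2) {
    intersect(sampled, which(z >= bulk[1] & z <= bulk[2]))
  } else {
    zs <- z[sampled]
    cutoffZ <- max(zs) - bulk * (max(zs) - min(zs))
    intersect(sampled, which(z >= cutoffZ))
  }
  if (!length(idx)) stop("bulk region contains no sampled bins")
  idx
}

#' Shift a PMF so the bulk level is zero
#'
#' Uniform shift making the sample-count-weighted mean of G over the bulk
#' region exactly zero; bootstrap errors are unchanged.  The default bulk
#' region is the outermost 10% (largest z) of the sampled range; an explicit
#' `c(lo, hi)` interval overrides it.
#'
#' @param profile a [PMFProfile-class].
#' @param bulk fraction (scalar in (0, 1)) or explicit z interval.
#' @return the shifted [PMFProfile-class] (`bulkShifted = TRUE`); idempotent.
#' @export
shiftToBulk <- function(profile, bulk = 0.1) {
  idx <- bulkBins(profile, bulk)
  w <- sampleCounts(profile)[idx]
  off <- sum(freeEnergy(profile)[idx] * w) / sum(w)
  new("PMFProfile", z = profile@z, G = profile@G - off,
      errors = profile@errors, counts = profile@counts,
      temperature = profile@temperature, bulkShifted = TRUE,
      iterations = profile@iterations)
}

#' Align an analytic truth to a profile's bulk gauge
#'
#' Evaluates a known potential on the profile's bin centres and applies the
#' same count-weighted bulk-zero shift as [shiftToBulk()], so estimate and
#' truth share one gauge and can be compared bin by bin.
#'
#' @param profile a [PMFProfile-class].
#' @param U vectorised potential function (kcal/mol).
#' @param bulk bulk definition as in [shiftToBulk()].
#' @return numeric vector of gauge-matched truth values on the bin centres.
#' @export
alignTruthToBulk <- function(profile, U, bulk = 0.1) {
  idx <- bulkBins(profile, bulk)
  u <- U(binCenters(profile))
  w <- sampleCounts(profile)[idx]
  u - sum(u[idx] * w) / sum(w)
}

#' Bootstrap standard errors for a WHAM profile
#'
#' Complete-histogram bootstrap: within every window the samples are resampled
#' with replacement, WHAM is re-run, each replicate profile is bulk-shifted,
#' and the per-bin standard deviation across replicates is reported.
#' Replicates that fail to converge are dropped (and counted); more than 20%
#' dropped is an error.
#'
#' @param windows list of [umbrellaWindow()].
#' @param nBoot number of replicates (>= 2).
#' @param seed RNG seed (bit-reproducible).
#' @param equilFraction leading fraction of each window discarded before
#'   resampling (equilibration discard).
#' @param bulk bulk definition passed to [shiftToBulk()].
#' @param ... passed to [wham()] (`binWidth`, `temperature`, `range`, ...).
#' @return numeric per-bin standard errors (NA where < 2 replicates sampled
#'   the bin), with attributes `nDropped` and `profile` (the full-data
#'   bulk-shifted [PMFProfile-class] with errors filled in).
#' @export
bootstrapErrors <- function(windows, nBoot = 200, seed = 1L,
                            equilFraction = 0, bulk = 0.1, ...) {
  stopifnot(nBoot >= 2, equilFraction >= 0, equilFraction < 1)
  trimmed <- lapply(windows, function(w) {
    s <- w$samples
    keep <- s[seq.int(floor(equilFraction * length(s)) + 1, length(s))]
    umbrellaWindow(w$z0, w$k, keep, w$kxy, w$interval, w$units)
  })
  full <- shiftToBulk(wham(trimmed, ...), bulk)
  nb <- length(binCenters(full))
  reps <- matrix(NA_real_, nBoot, nb)
  dropped <- 0
  withSeed(seed, {
    for (r in seq_len(nBoot)) {
      bw <- lapply(trimmed, function(w)
        umbrellaWindow(w$z0, w$k,
                       w$samples[sample.int(length(w$samples),
                                            replace = TRUE)],
                       w$kxy, w$interval, w$units))
      prof <- tryCatch(shiftToBulk(wham(bw, ...), bulk),
                       error = function(e) NULL)
      if (is.null(prof)) dropped <- dropped + 1
      else reps[r, ] <- freeEnergy(prof)
    }
  })
  if (dropped > 0.2 * nBoot)
    stop(dropped, " of ", nBoot, " bootstrap replicates failed to converge")
  err <- apply(reps, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) sd(v) else NA_real_
  })
  out <- new("PMFProfile", z = full@z, G = full@G, errors = err,
             counts = full@counts, temperature = full@temperature,
             bulkShifted = TRUE, iterations = full@iterations)
  structure(err, nDropped = dropped, profile = out)
}

#' Sequential-block convergence diagnostics
#'
#' Splits every window's sample series into sequential blocks of
#' `blockLength` samples, runs WHAM per block, and reports the metric
#' `max_b |G_j(b) - G_(j-1)(b)|` between consecutive block profiles.  The
#' equilibration end is the first block whose metric falls under `threshold`;
#' the final profile pools all blocks from that one onward.
#'
#' @param windows list of [umbrellaWindow()].
#' @param blockLength samples per block (>= 2 complete blocks required).
#' @param threshold kcal/mol on the block-to-block metric.
#' @param bulk bulk definition for shifting.
#' @param ... passed to [wham()].
#' @return list: `profiles` (per block, shifted), `metric` (NA, then one
#'   value per block from the 2nd), `equilibrationBlock`, `finalProfile`,
#'   `finalWindows` (the pooled post-equilibration input set).
#' @export
convergenceProfiles <- function(windows, blockLength, threshold = 0.3,
                                bulk = 0.1, ...) {
  nmin <- min(vapply(windows, function(w) length(w$samples), numeric(1)))
  nBlocks <- floor(nmin / blockLength)
  if (nBlocks < 2) stop("need >= 2 complete blocks (have ", nBlocks, ")")
  blockWin <- function(j, upto = FALSE) {
    lapply(windows, function(w) {
      idx <- if (upto) seq.int((j - 1) * blockLength + 1,
                               nBlocks * blockLength)
             else seq.int((j - 1) * blockLength + 1, j * blockLength)
      umbrellaWindow(w$z0, w$k, w$samples[idx], w$kxy, w$interval, w$units)
    })
  }
  profiles <- lapply(seq_len(nBlocks), function(j)
    shiftToBulk(wham(blockWin(j), ...), bulk))
  metric <- rep(NA_real_, nBlocks)
  for (j in 2:nBlocks) {
    g1 <- freeEnergy(profiles[[j - 1]]); g2 <- freeEnergy(profiles[[j]])
    ok <- is.finite(g1) & is.finite(g2)
    metric[j] <- max(abs(g2[ok] - g1[ok]))
  }
  eq <- which(metric < threshold)[1]
  if (is.na(eq)) eq <- nBlocks
  finalWindows <- blockWin(eq, upto = TRUE)
  list(profiles = profiles, metric = metric, equilibrationBlock = eq,
       finalProfile = shiftToBulk(wham(finalWindows, ...), bulk),
       finalWindows = finalWindows)
}

#' Locate free-energy wells
#'
#' Strict local minima of the binned, bulk-shifted profile whose surrounding
#' barrier (prominence: the lower of the maximal rises to the left and right
#' before a deeper point or the profile edge) exceeds the local bootstrap
#' error.  Wells are returned in order of increasing z; a monotone or flat
#' profile yields an empty report.
#'
#' @param profile a bulk-shifted [PMFProfile-class].
#' @param minProminence floor on the required prominence (kcal/mol), used
#'   where bootstrap errors are unavailable.
#' @return data.frame of class `WellReport`: `z`, `depth` (kcal/mol),
#'   `prominence`, `barrier_to_next` (max G between consecutive wells; NA for
#'   the last well).
#' @export
findWells <- function(profile, minProminence = 0.05) {
  if (!profile@bulkShifted)
    stop("profile must be bulk-shifted before well extraction")
  G <- freeEnergy(profile)
  z <- binCenters(profile)
  err <- profileErrors(profile)
  ok <- which(is.finite(G))
  g <- G[ok]; n <- length(g)
  # local minima with plateau support: a run of equal values bounded by
  # strictly larger neighbours counts once, at its first bin
  cand <- integer(0)
  if (n >= 3) {
    i <- 2
    while (i <= n - 1) {
      if (g[i] < g[i - 1]) {
        j <- i
        while (j < n && g[j + 1] == g[i]) j <- j + 1
        if (j < n && g[j + 1] > g[i]) cand <- c(cand, i)
        i <- j + 1
      } else i <- i + 1
    }
  }
  rows <- list()
  for (i in cand) {
    # prominence: walk out until a strictly deeper point or the edge
    left <- g[seq_len(i - 1)]
    deeperL <- which(left < g[i])
    lMax <- if (length(deeperL)) max(left[(max(deeperL) + 1):(i - 1)])
            else max(left)
    right <- g[(i + 1):n]
    deeperR <- which(right < g[i])
    rMax <- if (length(deeperR)) max(right[seq_len(min(deeperR) - 1)])
            else max(right)
    prom <- min(lMax, rMax) - g[i]
    need <- max(minProminence, if (is.finite(err[ok[i]])) err[ok[i]] else 0)
    if (prom > need)
      rows[[length(rows) + 1]] <- data.frame(z = z[ok[i]], depth = g[i],
                                             prominence = prom)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(z = numeric(0), depth = numeric(0), prominence = numeric(0))
  out <- out[order(out$z), ]
  out$barrier_to_next <- rep(NA_real_, nrow(out))
  if (nrow(out) > 1) for (i in seq_len(nrow(out) - 1)) {
    seg <- G[z >= out$z[i] & z <= out$z[i + 1]]
    out$barrier_to_next[i] <- max(seg, na.rm = TRUE)
  }
  class(out) <- c("WellReport", "data.frame")
  out
}
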