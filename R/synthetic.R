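## Synthetic ground-truth generators.
##
## The encounter generator evolves a rigid pseudo-protein over a planar
## bilayer with a *known* 1-D binding potential U(z) and a known preferred
## orientation, plus laterally mobile point lipids with optional
## protein-induced clustering.  All moves are symmetric-proposal Metropolis
## updates of the joint energy U(z) + 1[bound] * V(Rzz) (+ clustering term for
## lipids), so the stationary distribution is the exact Boltzmann law and
## every downstream estimator can be checked against closed forms.

#' Analytic 1-D potentials
#'
#' Build `U(z)` (kcal/mol) from a form tag + parameters:
#' * `flat`: 0 everywhere;
#' * `harmonic`: `0.5 * k * (z - z0)^2` with `k` in kcal/mol/nm^2;
#' * `double_well`: `d1*exp(-((z-z1)/width)^2) + d2*exp(-((z-z2)/width)^2)`
#'   (depths `d1`, `d2` are signed, typically negative; `d2 = 0` gives a
#'   single Gaussian well).
#'
#' @param pot list with `form` and the parameters above.
#' @return vectorised function of z (nm) returning kcal/mol.
#' @examples
#' U <- makePotential(list(form = "double_well", d1 = -3, z1 = 1,
#'                         d2 = -1, z2 = 2.5, width = 0.25))
#' U(c(1, 2.5))
#' @export
makePotential <- function(pot) {
  stopifnot(is.list(pot), !is.null(pot$form))
  switch(pot$form,
    flat = function(z) rep(0, length(z)),
    harmonic = {
      z0 <- pot$z0; k <- pot$k
      stopifnot(is.numeric(z0), is.numeric(k), k > 0)
      function(z) 0.5 * k * (z - z0)^2
    },
    double_well = {
      d1 <- pot$d1; z1 <- pot$z1; d2 <- pot$d2; z2 <- pot$z2; w <- pot$width
      stopifnot(is.numeric(d1), is.numeric(z1), is.numeric(d2),
                is.numeric(z2), is.numeric(w), w > 0)
      function(z) d1 * exp(-((z - z1) / w)^2) + d2 * exp(-((z - z2) / w)^2)
    },
    stop("unknown potential form: ", pot$form))
}

# orientation potential V(Rzz) in kcal/mol, minimum 0 at the target
makeOrientationPotential <- function(op) {
  target <- op$target; a <- op$strength
  stopifnot(is.numeric(target), target >= -1, target <= 1,
            is.numeric(a), a >= 0)
  function(rzz) 0.5 * a * (rzz - target)^2
}

#' Synthetic encounter-simulation configuration
#'
#' Defaults encode the emulated study conditions: 323 K, a bilayer of
#' thickness 4 nm centred at half the box height, 4 PIP3 point lipids per
#' leaflet, a single binding well of depth -3 kcal/mol at a protein-bilayer
#' separation of 4.0 nm, a preferred orientation Rzz = 0.8, and ensembles of
#' 2000 saved frames per run.  See the methods vignette for the reasoning
#' behind each default.
#'
#' @param seed RNG seed (fixed seed implies bit-identical output).
#' @param temperature kelvin.
#' @param timestep ps per Monte-Carlo substep (time bookkeeping only).
#' @param nFrames saved frames per run.
#' @param nEquil equilibration frames discarded before recording.
#' @param substeps protein-z Metropolis substeps per saved frame.
#' @param zStep proposal s.d. (nm) for protein-z moves.
#' @param rotSubsteps rigid-rotation Metropolis proposals per saved frame.
#' @param rotStep proposal rotation-angle s.d. (rad).
#' @param box orthorhombic box (nm, length 3).
#' @param bilayerThickness nm; leaflet planes sit at `box[3]/2 +/- thickness/2`.
#' @param truePmf ground-truth binding potential, see [makePotential()];
#'   the z argument is the protein-bilayer COM separation d_z.
#' @param orientationPotential list(target, strength): harmonic restraint
#'   `0.5*strength*(Rzz - target)^2` (kcal/mol), active only while bound.
#' @param zRange allowed d_z interval (nm); proposals outside are rejected.
#' @param zInit starting d_z (default: displaced into bulk, `max(zRange) - 0.5`).
#' @param proteinDiffusion lateral COM diffusion coefficient (nm^2/ps).
#' @param nLipidsPerLeaflet named integer vector, e.g. `c(PIP3 = 4)`; names are
#'   lipid species (`POPC`, `POPS`, `PIP2`, `PIP3`, ...).
#' @param lipidDiffusion lateral lipid diffusion coefficient (nm^2/ps).
#' @param clusteringStrength kcal/mol depth of the lateral attraction pulling
#'   proximal-leaflet PIP phosphates toward the bound protein (0 = uniform).
#' @param clusteringSigma nm range of that attraction.
#' @param boundThreshold nm; same 4.75 nm bound rule as the analysis side.
#' @param proteinGeometry optional n x 3 matrix of rigid pseudo-particle
#'   coordinates (nm, will be centred); needs >= 4 non-coplanar rows.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L, temperature = 323, timestep = 2,
                            nFrames = 2000, nEquil = 200, substeps = 50,
                            zStep = 0.15, rotSubsteps = 10, rotStep = 0.35,
                            box = c(10, 10, 20), bilayerThickness = 4,
                            truePmf = list(form = "double_well", d1 = -3,
                                           z1 = 4.0, d2 = 0, z2 = 6,
                                           width = 0.35),
                            orientationPotential = list(target = 0.8,
                                                        strength = 40),
                            zRange = c(3.2, 9.0), zInit = NULL,
                            proteinDiffusion = 0.01,
                            nLipidsPerLeaflet = c(PIP3 = 4),
                            lipidDiffusion = 0.1,
                            clusteringStrength = 0, clusteringSigma = 1.5,
                            boundThreshold = 4.75,
                            proteinGeometry = NULL) {
  stopifnot(timestep > 0, nFrames >= 1, nEquil >= 0, substeps >= 1,
            length(box) == 3, all(box > 0), bilayerThickness > 0,
            all(nLipidsPerLeaflet >= 0), lipidDiffusion >= 0,
            clusteringStrength >= 0, boundThreshold > 0,
            zRange[1] < zRange[2])
  kT(temperature)  # validates temperature > 0
  cfg <- list(seed = seed, temperature = temperature, timestep = timestep,
              nFrames = nFrames, nEquil = nEquil, substeps = substeps,
              zStep = zStep, rotSubsteps = rotSubsteps, rotStep = rotStep,
              box = box, bilayerThickness = bilayerThickness,
              truePmf = truePmf, orientationPotential = orientationPotential,
              zRange = zRange,
              zInit = if (is.null(zInit)) max(zRange) - 0.5 else zInit,
              proteinDiffusion = proteinDiffusion,
              nLipidsPerLeaflet = nLipidsPerLeaflet,
              lipidDiffusion = lipidDiffusion,
              clusteringStrength = clusteringStrength,
              clusteringSigma = clusteringSigma,
              boundThreshold = boundThreshold,
              proteinGeometry = proteinGeometry)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# default rigid pseudo-protein: 6 beads, centred, non-coplanar, ~3 nm tall
defaultProteinGeometry <- function() {
  rbind(c(0, 0, 1.5), c(0, 0, -1.5), c(0, 0, 0),
        c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
}

proteinGeometry <- function(config) {
  g <- if (is.null(config$proteinGeometry)) defaultProteinGeometry()
       else as.matrix(config$proteinGeometry)
  if (nrow(g) < 4)
    stop("protein needs >= 4 pseudo-particles (Rzz undefined otherwise)")
  g <- sweep(g, 2, colMeans(g))
  if (qr(g)$rank < 3)
    stop("protein pseudo-particles must be non-coplanar")
  g
}

#' Build the synthetic topology
#'
#' Protein: >= 4 rigid pseudo-particles (backbone-flagged, residue ids from
#' 360 so the default beta1/beta2 loop range applies).  Lipids: one point
#' particle per molecule; PIP species carry the `is_phosphate` flag.  Leaflet
#' membership is encoded by initial z (upper leaflet first).
#'
#' @param config a [syntheticConfig()].
#' @return a [Topology-class].
#' @examples
#' topo <- makeTopology(syntheticConfig())
#' sum(particles(topo)$is_phosphate) # 8: 4 PIP3 per leaflet
#' @export
makeTopology <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  g <- proteinGeometry(config)
  np <- nrow(g)
  prot <- data.frame(id = seq_len(np) - 1L, name = paste0("BB", seq_len(np)),
                     residue_id = 359L + seq_len(np), residue_name = "PHD",
                     molecule_id = 0L, role = "protein", mass = 72,
                     is_phosphate = FALSE, is_backbone = TRUE,
                     stringsAsFactors = FALSE)
  counts <- config$nLipidsPerLeaflet
  lip <- NULL
  if (sum(counts) > 0) {
    species <- rep(rep(names(counts), counts), 2)        # upper then lower
    nl <- length(species)
    isPIP <- species %in% c("PIP2", "PIP3")
    lip <- data.frame(id = 0L, name = ifelse(isPIP, "P1", "PO4"),
                      residue_id = 1000L + seq_len(nl), residue_name = species,
                      molecule_id = seq_len(nl),
                      role = paste0("lipid:", species), mass = 72,
                      is_phosphate = isPIP, is_backbone = FALSE,
                      stringsAsFactors = FALSE)
  }
  p <- rbind(prot, lip)
  p$id <- seq_len(nrow(p)) - 1L
  rownames(p) <- NULL
  topology(p)
}

# lipid bookkeeping for the generator: leaflet label and fixed z per lipid
lipidLayout <- function(config) {
  counts <- config$nLipidsPerLeaflet
  if (sum(counts) == 0)
    return(data.frame(leaflet = character(0), z = numeric(0)))
  zMid <- config$box[3] / 2
  half <- config$bilayerThickness / 2
  nl <- sum(counts)
  data.frame(leaflet = rep(c("upper", "lower"), each = nl),
             z = rep(c(zMid + half, zMid - half), each = nl),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic encounter trajectory with known ground truth
#'
#' Rigid-body Metropolis dynamics of the pseudo-protein in the ground-truth
#' potential `U(d_z)`, harmonic orientation bias toward the target Rzz while
#' bound (`d_z < boundThreshold`), free lateral diffusion with periodic
#' wrapping, and in-leaflet lipid moves with an optional clustering
#' attraction toward the bound protein's lateral position.  The sampled
#' stationary law is exactly `exp(-[U(z) + 1(bound) V(Rzz)] / kT)` (times the
#' uniform Haar measure in orientation and uniform lateral measure).
#'
#' @param config a [syntheticConfig()].
#' @return list with `trajectory` ([Trajectory-class]) and `truth`: a list
#'   with `pmfGrid` (data.frame z, U), `preferredRzz`, `boundFraction`
#'   (analytic occupancy of the bound region, orientation entropy included),
#'   `lipidLeaflet` (generator leaflet labels, in lipid molecule order), and
#'   `proximalLeaflet` (`"upper"`; the protein approaches from above).
#' @export
generateEncounterTrajectory <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, {
    topo <- makeTopology(config)
    geom <- proteinGeometry(config)
    np <- nrow(geom)
    U <- makePotential(config$truePmf)
    V <- makeOrientationPotential(config$orientationPotential)
    kt <- kT(config$temperature)
    bt <- config$boundThreshold
    box <- config$box
    zMid <- box[3] / 2
    lay <- lipidLayout(config)
    nl <- nrow(lay)
    dtFrame <- config$timestep * config$substeps

    # state
    z <- config$zInit
    Ucur <- U(z)
    R <- diag(3)
    rzzCur <- 1
    Vcur <- V(rzzCur)
    xy <- box[1:2] / 2
    lipXY <- cbind(runif(nl, 0, box[1]), runif(nl, 0, box[2]))
    sdXY <- sqrt(2 * config$proteinDiffusion * dtFrame)
    sdLip <- sqrt(2 * config$lipidDiffusion * dtFrame)
    cs <- config$clusteringStrength
    csig <- config$clusteringSigma
    Wclu <- function(r) -cs * exp(-r^2 / (2 * csig^2))
    prox <- lay$leaflet == "upper"

    nTot <- config$nEquil + config$nFrames
    frs <- vector("list", config$nFrames)
    for (i in seq_len(nTot)) {
      bound <- z < bt
      # --- protein z: random-walk Metropolis on U(z) + 1(bound) V(Rzz)
      dz <- rnorm(config$substeps, 0, config$zStep)
      lu <- log(runif(config$substeps))
      for (s in seq_len(config$substeps)) {
        zp <- z + dz[s]
        if (zp < config$zRange[1] || zp > config$zRange[2]) next
        Up <- U(zp)
        dE <- (Up - Ucur) + ((zp < bt) - bound) * Vcur
        if (lu[s] < -dE / kt) {
          z <- zp; Ucur <- Up; bound <- zp < bt
        }
      }
      # --- rigid rotation: uniform axis, Gaussian angle, Metropolis on V
      for (s in seq_len(config$rotSubsteps)) {
        ax <- rnorm(3)
        Rp <- axisAngleRotation(ax, rnorm(1, 0, config$rotStep)) %*% R
        rzzP <- Rp[3, 3]
        dE <- if (bound) V(rzzP) - Vcur else 0
        if (log(runif(1)) < -dE / kt) {
          R <- Rp; rzzCur <- rzzP; Vcur <- V(rzzCur)
        }
      }
      # --- lateral COM diffusion (free, wrapped)
      xy <- (xy + rnorm(2, 0, sdXY)) %% box[1:2]
      # --- lipids: in-leaflet Metropolis with optional clustering attraction
      if (nl > 0) {
        propXY <- lipXY + matrix(rnorm(2 * nl, 0, sdLip), nl, 2)
        propXY[, 1] <- propXY[, 1] %% box[1]
        propXY[, 2] <- propXY[, 2] %% box[2]
        if (bound && cs > 0) {
          rOld <- sqrt(rowSums(minImage(sweep(lipXY, 2, xy), box[1:2])^2))
          rNew <- sqrt(rowSums(minImage(sweep(propXY, 2, xy), box[1:2])^2))
          dW <- ifelse(prox, Wclu(rNew) - Wclu(rOld), 0)
          acc <- log(runif(nl)) < -dW / kt
        } else acc <- rep(TRUE, nl)
        lipXY[acc, ] <- propXY[acc, ]
      }
      # --- record
      if (i > config$nEquil) {
        pc <- geom %*% t(R)
        coords <- rbind(cbind(pc[, 1] + xy[1], pc[, 2] + xy[2],
                              pc[, 3] + zMid + z),
                        if (nl > 0) cbind(lipXY[, 1], lipXY[, 2], lay$z))
        coords[, 1] <- coords[, 1] %% box[1]
        coords[, 2] <- coords[, 2] %% box[2]
        frs[[i - config$nEquil]] <- frame((i - config$nEquil - 1) * dtFrame,
                                          box, coords)
      }
    }
    grid <- seq(config$zRange[1], config$zRange[2], length.out = 501)
    truth <- list(pmfGrid = data.frame(z = grid, U = U(grid)),
                  preferredRzz = config$orientationPotential$target,
                  boundFraction = boundFractionAnalytic(config),
                  lipidLeaflet = lay$leaflet,
                  proximalLeaflet = "upper",
                  # body-frame reference: Rzz is imposed relative to the
                  # untransformed rigid geometry, not to the first saved frame
                  reference = structure(list(ids = seq_len(np) - 1L,
                                             coords = geom),
                                        class = "ReferenceOrientation"))
    list(trajectory = trajectory(topo, frs), truth = truth)
  })
}

#' Analytic bound-state occupancy of the generator's stationary law
#'
#' Probability that `d_z < boundThreshold` under
#' `p(z, Rzz) ~ exp(-[U(z) + 1(bound) V(Rzz)]/kT)` on `zRange` x `[-1, 1]`:
#' the bound region is weighted by the orientational partition factor
#' `c_b = (1/2) * integral exp(-V(c)/kT) dc`.
#'
#' @param config a [syntheticConfig()].
#' @return probability in (0, 1).
#' @export
boundFractionAnalytic <- function(config) {
  U <- makePotential(config$truePmf)
  V <- makeOrientationPotential(config$orientationPotential)
  kt <- kT(config$temperature)
  bt <- min(config$boundThreshold, config$zRange[2])
  cb <- integrate(function(c) exp(-V(c) / kt), -1, 1,
                  rel.tol = 1e-10)$value / 2
  zb <- if (bt > config$zRange[1])
    integrate(function(z) exp(-U(z) / kt), config$zRange[1], bt,
              rel.tol = 1e-10)$value else 0
  zu <- if (bt < config$zRange[2])
    integrate(function(z) exp(-U(z) / kt), bt, config$zRange[2],
              rel.tol = 1e-10)$value else 0
  zb * cb / (zb * cb + zu)
}

#' Boltzmann umbrella-window samples from a known potential
#'
#' Draws, for each window `(z0, k)`, independent samples from the density
#' proportional to `exp(-[U(z) + (k/2)(z - z0)^2]/kT)` by rejection sampling
#' against the analytic Gaussian envelope of the bias alone.
#'
#' @param truePmf potential description for [makePotential()] (kcal/mol).
#' @param windows data.frame with columns `z0` (nm) and `k` (kJ/mol/nm^2,
#'   GROMACS convention) -- or a vector of centres with a single `k` passed
#'   via the `k` argument.
#' @param nSamples samples per window.
#' @param temperature kelvin.
#' @param seed RNG seed; same seed, identical samples.
#' @param k force constant (kJ/mol/nm^2) when `windows` is a plain vector.
#' @return list of [umbrellaWindow()] objects, with an `"overlap"` attribute:
#'   a data.frame of adjacent-window histogram overlap (shared 0.05 nm bins
#'   with samples in both).
#' @export
generateUmbrellaSamples <- function(truePmf, windows, nSamples,
                                    temperature = 323, seed = 1L, k = 1000) {
  if (!is.data.frame(windows)) windows <- data.frame(z0 = windows, k = k)
  stopifnot(nrow(windows) >= 1, all(windows$k > 0), nSamples >= 1)
  U <- makePotential(truePmf)
  kt <- kT(temperature)
  withSeed(seed, {
    out <- lapply(seq_len(nrow(windows)), function(i) {
      z0 <- windows$z0[i]
      kk <- kJToKcal(windows$k[i])          # kcal/mol/nm^2
      s <- sqrt(kt / kk)
      gz <- seq(z0 - 8 * s, z0 + 8 * s, length.out = 2001)
      uMin <- min(U(gz))
      acc <- numeric(0)
      tried <- 0
      while (length(acc) < nSamples) {
        m <- max(2 * (nSamples - length(acc)), 1000)
        zp <- rnorm(m, z0, s)
        keep <- runif(m) < exp(-(U(zp) - uMin) / kt)
        tried <- tried + m
        acc <- c(acc, zp[keep])
        if (tried > 1e4 && length(acc) / tried < 1e-4)
          stop("rejection acceptance rate < 1e-4 in window ", i,
               ": rescale the envelope (potential far below its biased range)")
      }
      umbrellaWindow(z0 = z0, k = windows$k[i], samples = acc[seq_len(nSamples)])
    })
    if (length(out) > 1) {
      bw <- 0.05
      ov <- vapply(seq_len(length(out) - 1), function(i) {
        b1 <- unique(floor(out[[i]]$samples / bw))
        b2 <- unique(floor(out[[i + 1]]$samples / bw))
        length(intersect(b1, b2))
      }, numeric(1))
      attr(out, "overlap") <- data.frame(window = seq_along(ov),
                                         sharedBins = ov)
    }
    out
  })
}

#' Simulate an SPR saturation binding curve
#'
#' `B_i = Bmax * C_i / (KD + C_i) + N(0, noiseSd)`.
#'
#' @param KD dissociation constant (uM).
#' @param Bmax maximal response (response units).
#' @param concentrations analyte concentrations (uM), all > 0.
#' @param noiseSd Gaussian response noise s.d. (response units).
#' @param seed RNG seed.
#' @return data.frame of class `BindingCurve` with columns `conc`, `response`.
#' @examples
#' simulateSaturation(300, 100, serialDilution(2400, 8), noiseSd = 0)
#' @export
simulateSaturation <- function(KD, Bmax, concentrations, noiseSd = 0,
                               seed = NULL) {
  stopifnot(KD > 0, Bmax > 0, all(concentrations > 0), noiseSd >= 0)
  b <- Bmax * concentrations / (KD + concentrations)
  if (noiseSd > 0) b <- withSeed(seed, b + rnorm(length(b), 0, noiseSd))
  out <- data.frame(conc = concentrations, response = b)
  class(out) <- c("BindingCurve", "data.frame")
  out
}
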