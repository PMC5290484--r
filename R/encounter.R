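## Per-frame geometric descriptors of membrane association: protein-bilayer
## z separation, Kabsch Rzz orientation, bound-state rule, 2-D landscapes,
## per-residue RMSF.

#' Analysis configuration
#'
#' Thresholds and bin widths shared across the encounter and contact
#' analyses.  Defaults follow the coarse-grained encounter protocol: a frame
#' is *bound* when the protein-bilayer centre-of-mass z separation is smaller
#' than 4.75 nm; a PIP lipid is *in contact* when its headgroup phosphate is
#' within 1 nm of any protein particle; the clustering annulus extends 1 nm
#' from the protein surface; landscape bins are 0.1 nm x 0.05 Rzz units.
#'
#' @param boundThreshold nm, strict upper bound for the bound state.
#' @param contactCutoff nm, inclusive phosphate-protein contact cutoff.
#' @param annulusWidth nm, annulus extent from the protein surface.
#' @param dzBinWidth,rzzBinWidth landscape bin widths.
#' @param loops named list of inclusive residue-id ranges `c(lo, hi)` for the
#'   inter-strand loops; `beta12` defaults to residues 360-372 (the positively
#'   charged beta1/beta2 loop), `beta34` and `beta56` are system-specific and
#'   must be set for binding-site classification.
#' @param persistenceCutoff nm, default pairwise-contact cutoff for
#'   [interactionPersistence()] (0.35 nm suits atomistic donor-acceptor
#'   pairs; use ~0.55 nm for CG beads).
#' @return list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(boundThreshold = 4.75, contactCutoff = 1.0,
                           annulusWidth = 1.0, dzBinWidth = 0.1,
                           rzzBinWidth = 0.05,
                           loops = list(beta12 = c(360, 372), beta34 = NULL,
                                        beta56 = NULL),
                           persistenceCutoff = 0.35) {
  stopifnot(boundThreshold > 0, contactCutoff > 0, annulusWidth > 0,
            dzBinWidth > 0, rzzBinWidth > 0, persistenceCutoff > 0)
  structure(list(boundThreshold = boundThreshold,
                 contactCutoff = contactCutoff, annulusWidth = annulusWidth,
                 dzBinWidth = dzBinWidth, rzzBinWidth = rzzBinWidth,
                 loops = loops, persistenceCutoff = persistenceCutoff),
            class = "AnalysisConfig")
}

# role-filtered particle indices (1-based rows into the particle table)
roleIdx <- function(topology, role) which(particles(topology)$role == role)

lipidIdx <- function(topology) grep("^lipid:", particles(topology)$role)

#' Protein-bilayer centre-of-mass z separation
#'
#' Each group (protein; all lipid particles) is made whole by minimum-image
#' wrapping about its own first particle, mass-weighted COMs are taken, and
#' the z difference is reduced to its minimum image.  Returns the magnitude
#' by default (the landscape axis is a distance); `signed = TRUE` keeps the
#' sign (positive when the protein sits above the bilayer COM).
#'
#' @param frame a frame (see [frame()]).
#' @param topology the matching [Topology-class].
#' @param signed return signed separation instead of `|dz|`.
#' @return separation in nm.
#' @export
dzProteinBilayer <- function(frame, topology, signed = FALSE) {
  p <- particles(topology)
  ip <- which(p$role == "protein")
  il <- lipidIdx(topology)
  if (!length(ip)) stop("no particles with role 'protein' in topology")
  if (!length(il)) stop("no lipid particles in topology")
  comP <- massCOM(makeWhole(frame$coords[ip, , drop = FALSE], frame$box),
                  p$mass[ip])
  comL <- massCOM(makeWhole(frame$coords[il, , drop = FALSE], frame$box),
                  p$mass[il])
  d <- minImage(comP[3] - comL[3], frame$box[3])
  if (signed) d else abs(d)
}

#' Reference orientation for Rzz and RMSF
#'
#' Centred backbone coordinates defining the body frame against which
#' rotations are measured.  Defaults to the first frame of a trajectory; an
#' explicit structure can be supplied instead so landscapes are reported
#' against a fixed, logged reference.
#'
#' @param x a [Trajectory-class] (first frame used) or a list as returned by
#'   [readStructure()].
#' @param ids optional particle ids (0-based) to use; default: backbone
#'   particles.
#' @return list of class `ReferenceOrientation` with `ids` and centred
#'   `coords`.
#' @export
referenceOrientation <- function(x, ids = NULL) {
  if (is(x, "Trajectory")) {
    topo <- x@topology; fr <- frames(x)[[1]]
  } else {
    topo <- x$topology; fr <- x$frame
  }
  p <- particles(topo)
  if (is.null(ids)) ids <- p$id[p$is_backbone]
  if (length(ids) < 4)
    stop("reference orientation needs >= 4 particles (got ", length(ids), ")")
  coords <- makeWhole(fr$coords[match(ids, p$id), , drop = FALSE], fr$box)
  coords <- sweep(coords, 2, colMeans(coords))
  if (qr(coords)$rank < 2)
    stop("reference particles are collinear; orientation undefined")
  structure(list(ids = as.integer(ids), coords = coords),
            class = "ReferenceOrientation")
}

#' Rzz orientation descriptor
#'
#' Element `[3,3]` of the least-squares (Kabsch) proper rotation superposing
#' the centred reference onto the current backbone coordinates: 1 when the
#' body z axis points as in the reference, -1 when flipped, `cos(theta)` for
#' a rotation by `theta` about any in-plane axis.
#'
#' @param frame a frame.
#' @param reference a [referenceOrientation()].
#' @return dimensionless value in `[-1, 1]`.
#' @export
rzz <- function(frame, reference) {
  stopifnot(inherits(reference, "ReferenceOrientation"))
  cur <- makeWhole(frame$coords[reference$ids + 1L, , drop = FALSE], frame$box)
  R <- kabschRotation(reference$coords, cur)
  R[3, 3]
}

#' Bound-state rule
#'
#' Bound iff the protein-bilayer COM z separation is strictly smaller than
#' the threshold (default 4.75 nm).
#'
#' @param d_z separation (nm), >= 0.
#' @param config an [analysisConfig()].
#' @return logical.
#' @examples
#' classifyBound(4.0)   # TRUE
#' classifyBound(4.75)  # FALSE (strict)
#' @export
classifyBound <- function(d_z, config = analysisConfig()) {
  stopifnot(all(d_z >= 0))
  d_z < config$boundThreshold
}

#' Per-frame orientation series
#'
#' Computes, for every frame, the separation `d_z`, the orientation `r_zz`
#' and the bound flag -- the record feeding [orientationLandscape()] and
#' bound-only contact counting.
#'
#' @param traj a [Trajectory-class].
#' @param reference a [referenceOrientation()]; default: first frame.
#' @param config an [analysisConfig()].
#' @return data.frame with columns `time`, `d_z`, `r_zz`, `bound`.
#' @export
orientationSeries <- function(traj, reference = referenceOrientation(traj),
                              config = analysisConfig()) {
  topo <- traj@topology
  rows <- lapply(frames(traj), function(f) {
    d <- dzProteinBilayer(f, topo)
    data.frame(time = f$time, d_z = d, r_zz = rzz(f, reference),
               bound = classifyBound(d, config))
  })
  do.call(rbind, rows)
}

# half-open [lo, hi) bin index with the final bin closed above
binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  i
}

# bin edges as multiples of width covering the data (so round thresholds such
# as d_z = 4.0 or Rzz = 0.8 fall on edges)
alignedEdges <- function(x, width) {
  lo <- floor(min(x) / width - 1e-9) * width
  hi <- ceiling(max(x) / width + 1e-9) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

#' Two-dimensional (d_z, Rzz) binding landscape
#'
#' Histogram of the orientation series on aligned bins (half-open `[lo, hi)`,
#' the final bin closed so no frame is dropped at the range boundary), with a
#' normalised density and the mode bin reported as the preferred binding
#' mode.  Mode ties are broken toward smaller separation (the
#' membrane-proximal mode).
#'
#' @param series data.frame from [orientationSeries()].
#' @param config an [analysisConfig()] (bin widths).
#' @param boundOnly restrict to bound frames.
#' @return an [OrientationLandscape-class].
#' @export
orientationLandscape <- function(series, config = analysisConfig(),
                                 boundOnly = FALSE) {
  stopifnot(nrow(series) > 0)
  if (boundOnly) series <- series[series$bound, , drop = FALSE]
  if (!nrow(series))
    stop("empty landscape: every frame was filtered out (no bound frames)")
  dzE <- alignedEdges(series$d_z, config$dzBinWidth)
  rzE <- alignedEdges(series$r_zz, config$rzzBinWidth)
  i <- binIndex(series$d_z, dzE)
  j <- binIndex(series$r_zz, rzE)
  counts <- matrix(0L, length(dzE) - 1, length(rzE) - 1)
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  dens <- counts / sum(counts)
  best <- which(counts == max(counts), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]  # smaller d_z
  new("OrientationLandscape", dzEdges = dzE, rzzEdges = rzE,
      counts = counts, density = dens,
      mode = as.integer(best))
}

#' Per-residue root mean square fluctuation
#'
#' Every frame is least-squares aligned (rotation + translation) to the
#' reference using the alignment particle set; the RMSF of each analysed
#' particle is the root of the time-averaged squared displacement from its
#' own time-mean aligned position; residues average their particles, and
#' multiple trajectories (e.g. repeats with different force fields) are
#' averaged per residue with equal weight.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param reference a [referenceOrientation()]; default: first frame of the
#'   first trajectory.
#' @param alignIds particle ids used for the superposition (default: the
#'   reference's ids).
#' @param ids particle ids analysed (default: backbone particles).
#' @return data.frame `residue_id`, `rmsf` (nm), `n_frames`, `n_traj`.
#' @export
rmsf <- function(trajs, reference = NULL, alignIds = NULL, ids = NULL) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (is.null(reference)) reference <- referenceOrientation(trajs[[1]])
  if (is.null(alignIds)) alignIds <- reference$ids
  p <- particles(trajs[[1]]@topology)
  if (is.null(ids)) ids <- p$id[p$is_backbone]
  perTraj <- lapply(trajs, function(tr) {
    if (nFrames(tr) < 2) stop("RMSF needs >= 2 frames")
    ai <- match(alignIds, p$id)
    xi <- match(ids, p$id)
    refA <- makeWhole(frames(tr)[[1]]$coords, frames(tr)[[1]]$box)
    refAlign <- reference$coords[match(alignIds, reference$ids), , drop = FALSE]
    aligned <- lapply(frames(tr), function(f) {
      w <- makeWhole(f$coords, f$box)
      cur <- w[ai, , drop = FALSE]
      R <- kabschRotation(refAlign, sweep(cur, 2, colMeans(cur)))
      # map current coords into the reference body frame
      sweep(w, 2, colMeans(cur)) %*% R
    })
    arr <- simplify2array(lapply(aligned, function(a) a[xi, , drop = FALSE]))
    mean3 <- apply(arr, c(1, 2), mean)
    disp2 <- apply((arr - array(mean3, dim(arr)))^2, c(1, 3), sum)
    partRmsf <- sqrt(rowMeans(disp2))
    data.frame(residue_id = p$residue_id[xi], rmsf = partRmsf)
  })
  agg <- lapply(perTraj, function(d)
    stats::aggregate(rmsf ~ residue_id, d, mean))
  merged <- Reduce(function(a, b) merge(a, b, by = "residue_id"), agg)
  out <- data.frame(residue_id = merged$residue_id,
                    rmsf = rowMeans(as.matrix(merged[, -1, drop = FALSE])),
                    n_frames = sum(vapply(trajs, nFrames, numeric(1))),
                    n_traj = length(trajs))
  out[order(out$residue_id), ]
}
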