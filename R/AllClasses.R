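## Central S4 containers.  Topology/Trajectory carry the particle system,
## PMFProfile the WHAM output, OrientationLandscape the 2-D binding histogram,
## LangmuirFit the 1:1 saturation fit.

.particleRoles <- c("protein", "lipid:POPC", "lipid:POPE", "lipid:POPS",
                    "lipid:PIP2", "lipid:PIP3", "solvent", "other")

.particleCols <- c("id", "name", "residue_id", "residue_name", "molecule_id",
                   "role", "mass", "is_phosphate", "is_backbone")

#' Particle topology of a protein/membrane system
#'
#' Particle metadata for every analysis in the package: identity, residue and
#' molecule membership, a coarse role (protein, lipid species, solvent, other),
#' mass, and flags marking phosphoinositide headgroup phosphates and backbone
#' particles.  Particle ids are dense `0..N-1` in file order.
#'
#' @slot particles data.frame with columns `id`, `name`, `residue_id`,
#'   `residue_name`, `molecule_id`, `role`, `mass`, `is_phosphate`,
#'   `is_backbone`.
#' @seealso [readStructure()], [makeTopology()]
#' @export
setClass("Topology", representation(particles = "data.frame"))

setValidity("Topology", function(object) {
  p <- object@particles
  if (!all(.particleCols %in% names(p)))
    return(paste("particles must have columns:", paste(.particleCols, collapse = ", ")))
  if (nrow(p) == 0) return("topology has no particles")
  if (!identical(as.integer(p$id), seq_len(nrow(p)) - 1L))
    return("particle ids must be dense 0..N-1 in row order")
  if (!all(p$role %in% .particleRoles))
    return(paste("unknown role(s):", paste(setdiff(p$role, .particleRoles), collapse = ", ")))
  if (!all(is.finite(p$mass)) || any(p$mass <= 0))
    return("all masses must be finite and > 0")
  pip <- p[p$role %in% c("lipid:PIP2", "lipid:PIP3"), ]
  if (nrow(pip)) {
    byMol <- tapply(pip$is_phosphate, pip$molecule_id, any)
    if (!all(byMol))
      return("every PIP2/PIP3 molecule needs >= 1 particle flagged is_phosphate")
  }
  TRUE
})

#' Construct a Topology
#'
#' @param particles data.frame as documented for [Topology-class].
#' @return a validated `Topology`.
#' @export
topology <- function(particles) {
  particles$id <- as.integer(particles$id)
  new("Topology", particles = as.data.frame(particles, stringsAsFactors = FALSE))
}

#' @describeIn Topology-class particle table accessor
#' @param object,x a `Topology`.
#' @export
setGeneric("particles", function(object) standardGeneric("particles"))

#' @rdname Topology-class
#' @export
setMethod("particles", "Topology", function(object) object@particles)

#' @describeIn Topology-class number of particles
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))

#' @rdname Topology-class
#' @export
setMethod("nParticles", "Topology", function(object) nrow(object@particles))

setMethod("show", "Topology", function(object) {
  p <- object@particles
  cat("Topology with", nrow(p), "particles,",
      length(unique(p$molecule_id)), "molecules\n")
  print(table(role = p$role))
  invisible(object)
})

## A Frame is deliberately light-weight: a plain list with fields time (ps),
## box (nm, length 3) and coords (N x 3 nm), checked by frame().

#' Construct and validate a single coordinate frame
#'
#' @param time time in ps.
#' @param box orthorhombic box edge lengths (nm), length 3, all > 0.
#' @param coords N x 3 matrix of positions (nm), finite.
#' @return list with class `"Frame"`.
#' @export
frame <- function(time, box, coords) {
  coords <- as.matrix(coords)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive finite edge lengths (orthorhombic)")
  if (ncol(coords) != 3 || any(!is.finite(coords)))
    stop("coords must be an N x 3 matrix of finite positions")
  structure(list(time = as.numeric(time), box = as.numeric(box), coords = coords),
            class = "Frame")
}

#' Trajectory: a Topology plus time-ordered frames
#'
#' @slot topology the shared [Topology-class].
#' @slot frames list of frames (see [frame()]); times non-decreasing, each
#'   coordinate block matching the topology's particle count.
#' @export
setClass("Trajectory", representation(topology = "Topology", frames = "list"))

setValidity("Trajectory", function(object) {
  n <- nParticles(object@topology)
  if (!length(object@frames)) return("trajectory has no frames")
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!inherits(f, "Frame")) return(sprintf("frame %d is not a Frame", i))
    if (nrow(f$coords) != n)
      return(sprintf("frame %d has %d coordinate rows; topology has %d particles",
                     i, nrow(f$coords), n))
  }
  tms <- vapply(object@frames, `[[`, numeric(1), "time")
  if (is.unsorted(tms)) return("frame times must be non-decreasing")
  TRUE
})

#' Construct a Trajectory
#'
#' @param topology a [Topology-class].
#' @param frames list of frames built with [frame()].
#' @return a validated `Trajectory`.
#' @export
trajectory <- function(topology, frames) new("Trajectory", topology = topology, frames = frames)

#' @describeIn Trajectory-class list of frames
#' @param object a `Trajectory`.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname Trajectory-class
#' @export
setMethod("frames", "Trajectory", function(object) object@frames)

#' @describeIn Trajectory-class number of frames
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setMethod("nFrames", "Trajectory", function(object) length(object@frames))

#' @describeIn Trajectory-class frame times (ps)
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname Trajectory-class
#' @export
setMethod("frameTimes", "Trajectory",
          function(object) vapply(object@frames, `[[`, numeric(1), "time"))

#' @rdname Trajectory-class
#' @export
setMethod("nParticles", "Trajectory", function(object) nParticles(object@topology))

setMethod("show", "Trajectory", function(object) {
  tms <- frameTimes(object)
  cat("Trajectory:", length(object@frames), "frames,",
      nParticles(object@topology), "particles, t =",
      format(tms[1]), "...", format(tms[length(tms)]), "ps\n")
  invisible(object)
})

#' Potential of mean force profile
#'
#' WHAM-estimated free-energy profile G(z) on a regular grid of bin centres.
#' Bins never visited by any window carry `NA` (an explicit missing marker,
#' never 0).  After [shiftToBulk()] the count-weighted mean of G over the bulk
#' region is exactly zero and `bulkShifted` is `TRUE`.
#'
#' @slot z bin centres (nm).
#' @slot G free energy (kcal/mol); `NA` on unsampled bins.
#' @slot errors bootstrap standard errors (kcal/mol); `NA` when not computed.
#' @slot counts per-bin total sample counts.
#' @slot temperature kelvin.
#' @slot bulkShifted logical.
#' @slot iterations WHAM iterations used.
#' @export
setClass("PMFProfile", representation(z = "numeric", G = "numeric",
                                      errors = "numeric", counts = "numeric",
                                      temperature = "numeric",
                                      bulkShifted = "logical",
                                      iterations = "numeric"))

setValidity("PMFProfile", function(object) {
  if (length(object@z) != length(object@G)) return("z and G lengths differ")
  if (length(object@errors) != length(object@G)) return("errors length differs from G")
  if (length(object@counts) != length(object@G)) return("counts length differs from G")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (any(!is.na(object@errors) & object@errors < 0)) return("errors must be >= 0")
  if (any(object@counts > 0 & !is.finite(object@G)))
    return("G must be finite on every bin with >= 1 sample")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    return("temperature must be a single positive value")
  TRUE
})

#' @describeIn PMFProfile-class bin centres (nm)
#' @param object a `PMFProfile`.
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname PMFProfile-class
#' @export
setMethod("binCenters", "PMFProfile", function(object) object@z)

#' @describeIn PMFProfile-class free energies (kcal/mol)
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))

#' @rdname PMFProfile-class
#' @export
setMethod("freeEnergy", "PMFProfile", function(object) object@G)

#' @describeIn PMFProfile-class bootstrap standard errors (kcal/mol)
#' @export
setGeneric("profileErrors", function(object) standardGeneric("profileErrors"))

#' @rdname PMFProfile-class
#' @export
setMethod("profileErrors", "PMFProfile", function(object) object@errors)

#' @describeIn PMFProfile-class per-bin sample counts
#' @export
setGeneric("sampleCounts", function(object) standardGeneric("sampleCounts"))

#' @rdname PMFProfile-class
#' @export
setMethod("sampleCounts", "PMFProfile", function(object) object@counts)

setMethod("show", "PMFProfile", function(object) {
  ok <- !is.na(object@G)
  cat("PMFProfile:", length(object@z), "bins on [",
      format(min(object@z)), ",", format(max(object@z)), "] nm; T =",
      object@temperature, "K;", if (object@bulkShifted) "bulk-shifted" else "unshifted",
      "\n  min G =", format(min(object@G[ok])), "kcal/mol at z =",
      format(object@z[ok][which.min(object@G[ok])]), "nm\n")
  invisible(object)
})

#' @describeIn PMFProfile-class data.frame view (z, G, error, count)
#' @param x a `PMFProfile`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "PMFProfile", function(x, ...) {
  data.frame(z = x@z, G = x@G, error = x@errors, count = x@counts)
})

#' Two-dimensional (separation, Rzz) binding landscape
#'
#' @slot dzEdges bin edges for the protein-bilayer z separation (nm).
#' @slot rzzEdges bin edges for the Rzz orientation descriptor.
#' @slot counts integer count matrix (dz bins x rzz bins).
#' @slot density counts normalised to sum 1 over contributing frames.
#' @slot mode length-2 integer index (dz bin, rzz bin) of the mode bin; ties
#'   broken toward smaller separation.
#' @export
setClass("OrientationLandscape", representation(dzEdges = "numeric",
                                                rzzEdges = "numeric",
                                                counts = "matrix",
                                                density = "matrix",
                                                mode = "integer"))

setValidity("OrientationLandscape", function(object) {
  if (nrow(object@counts) != length(object@dzEdges) - 1) return("counts rows != dz bins")
  if (ncol(object@counts) != length(object@rzzEdges) - 1) return("counts cols != rzz bins")
  if (any(object@counts < 0)) return("negative counts")
  if (sum(object@counts) > 0 && abs(sum(object@density) - 1) > 1e-9)
    return("density must sum to 1 when any frame contributes")
  TRUE
})

#' @describeIn OrientationLandscape-class mode-bin intervals as a list with
#'   elements `dz` and `rzz`, each `c(lo, hi)`.
#' @param object an `OrientationLandscape`.
#' @export
setGeneric("modeBin", function(object) standardGeneric("modeBin"))

#' @rdname OrientationLandscape-class
#' @export
setMethod("modeBin", "OrientationLandscape", function(object) {
  i <- object@mode
  list(dz = object@dzEdges[c(i[1], i[1] + 1L)],
       rzz = object@rzzEdges[c(i[2], i[2] + 1L)])
})

setMethod("show", "OrientationLandscape", function(object) {
  mb <- modeBin(object)
  cat("OrientationLandscape:", sum(object@counts), "frames in",
      nrow(object@counts), "x", ncol(object@counts), "bins\n",
      " mode bin: d_z in [", mb$dz[1], ",", mb$dz[2], ") nm, Rzz in [",
      mb$rzz[1], ",", mb$rzz[2], ")\n")
  invisible(object)
})

#' 1:1 Langmuir saturation fit
#'
#' Result of fitting `B = Bmax * C / (KD + C)` to equilibrium responses.
#'
#' @slot KD dissociation constant (same concentration units as the input).
#' @slot Bmax maximal response.
#' @slot se standard errors `c(KD, Bmax)` from the curvature at the optimum.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot data the fitted curve (data.frame `conc`, `response`).
#' @export
setClass("LangmuirFit", representation(KD = "numeric", Bmax = "numeric",
                                       se = "numeric", rss = "numeric",
                                       converged = "logical", data = "data.frame"))

setValidity("LangmuirFit", function(object) {
  if (object@converged && (object@KD <= 0 || object@Bmax <= 0))
    return("KD and Bmax must be > 0 on a converged fit")
  TRUE
})

#' @describeIn LangmuirFit-class dissociation constant
#' @param object a `LangmuirFit`.
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))

#' @rdname LangmuirFit-class
#' @export
setMethod("kd", "LangmuirFit", function(object) object@KD)

#' @describeIn LangmuirFit-class maximal response
#' @export
setGeneric("bmax", function(object) standardGeneric("bmax"))

#' @rdname LangmuirFit-class
#' @export
setMethod("bmax", "LangmuirFit", function(object) object@Bmax)

#' @rdname LangmuirFit-class
#' @export
setMethod("coef", "LangmuirFit", function(object) c(KD = object@KD, Bmax = object@Bmax))

setMethod("show", "LangmuirFit", function(object) {
  cat("LangmuirFit: KD =", format(object@KD), "+/-", format(object@se[1]),
      " Bmax =", format(object@Bmax), "+/-", format(object@se[2]),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  invisible(object)
})
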