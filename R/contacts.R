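## PIP contact detection (cell list + brute-force oracle), residue contact
## ranking, leaflet assignment, annulus clustering occupancy, binding-site
## classification, and pairwise interaction persistence.

normalizeRole <- function(role) {
  if (!grepl("^lipid:", role)) role <- paste0("lipid:", role)
  if (!role %in% .particleRoles) stop("unknown lipid role: ", role)
  role
}

# phosphate coordinates + owning molecule ids for one lipid role; for lipids
# without a flagged phosphate (point-lipid species) the molecule itself is
# used
rolePhosphates <- function(frame, topology, role) {
  p <- particles(topology)
  sel <- p$role == role
  if (!any(sel)) return(NULL)
  use <- sel & (p$is_phosphate | !ave(p$is_phosphate, p$molecule_id,
                                      FUN = any))
  list(coords = frame$coords[use, , drop = FALSE],
       mol = p$molecule_id[use])
}

#' PIP molecules in contact with the protein
#'
#' A lipid counts as in contact when any of its headgroup phosphate particles
#' lies within the cutoff (inclusive, default 1 nm) of *any* protein
#' particle, under minimum-image distances.  The default cell-list search is
#' required (and tested) to agree bit-for-bit with the brute-force all-pairs
#' oracle (`method = "brute"`).
#'
#' @param frame a frame.
#' @param topology the matching [Topology-class].
#' @param config an [analysisConfig()].
#' @param role lipid role (`"PIP3"`, `"lipid:PIP3"`, ...).
#' @param method `"cell"` (cell list, cell edge = cutoff) or `"brute"`.
#' @return sorted integer vector of lipid molecule ids in contact.
#' @export
pipContacts <- function(frame, topology, config = analysisConfig(),
                        role = "PIP3", method = c("cell", "brute")) {
  method <- match.arg(method)
  role <- normalizeRole(role)
  p <- particles(topology)
  ip <- which(p$role == "protein")
  if (!length(ip)) stop("no particles with role 'protein' in topology")
  ph <- rolePhosphates(frame, topology, role)
  if (is.null(ph)) {
    warning("role ", role, " absent from topology; empty contact set")
    return(integer(0))
  }
  prot <- frame$coords[ip, , drop = FALSE]
  hit <- if (method == "brute")
    bruteWithin(ph$coords, prot, frame$box, config$contactCutoff)
  else
    cellWithin(ph$coords, prot, frame$box, config$contactCutoff)
  sort(unique(ph$mol[hit]))
}

# brute force: which rows of q have any row of p within cutoff (<=, PBC)
bruteWithin <- function(q, p, box, cutoff) {
  if (!nrow(q) || !nrow(p)) return(logical(nrow(q)))
  dm <- miDistMatrix(q, p, box)
  apply(dm <= cutoff, 1, any)
}

# cell list over the periodic orthorhombic box; cell edge >= cutoff, 27
# neighbour cells searched; distances via the same miDistMatrix as the oracle
cellWithin <- function(q, p, box, cutoff) {
  if (!nrow(q) || !nrow(p)) return(logical(nrow(q)))
  nc <- pmax(1L, floor(box / cutoff))
  edge <- box / nc
  cellOf <- function(x) {
    ix <- floor((x %% box[col(x)]) / edge[col(x)])
    ix <- pmin(pmax(ix, 0), matrix(nc - 1, nrow(x), 3, byrow = TRUE))
    ix[, 1] + nc[1] * (ix[, 2] + nc[2] * ix[, 3])
  }
  pc <- cellOf(p)
  pMap <- split(seq_len(nrow(p)), pc)
  qi <- floor((q %% matrix(box, nrow(q), 3, byrow = TRUE)) /
                matrix(edge, nrow(q), 3, byrow = TRUE))
  qi <- pmin(pmax(qi, 0), matrix(nc - 1, nrow(q), 3, byrow = TRUE))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- logical(nrow(q))
  for (r in seq_len(nrow(q))) {
    neigh <- sweep(off, 2, qi[r, ], "+")
    neigh <- sweep(neigh, 2, nc, "%%")
    key <- unique(neigh[, 1] + nc[1] * (neigh[, 2] + nc[2] * neigh[, 3]))
    cand <- unlist(pMap[as.character(key)], use.names = FALSE)
    if (length(cand))
      out[r] <- any(miDistMatrix(q[r, , drop = FALSE],
                                 p[cand, , drop = FALSE], box) <= cutoff)
  }
  out
}

#' Leaflet assignment of lipids
#'
#' Each lipid is assigned `upper` or `lower` by the sign of its phosphate z
#' (molecule COM z for species without a phosphate flag) relative to the
#' bilayer midplane, taken as the lipid-COM z; a phosphate exactly at the
#' midplane goes to `upper` (documented tie rule).  The protein's *proximal*
#' leaflet is the one whose mean `|z - protein COM z|` is smaller.
#'
#' @param frame a frame.
#' @param topology the matching [Topology-class].
#' @return named character vector (names = lipid molecule ids) with
#'   attributes `midplane` (nm) and `proximal` (`"upper"` or `"lower"`).
#' @export
leafletAssign <- function(frame, topology) {
  p <- particles(topology)
  il <- lipidIdx(topology)
  if (!length(il)) stop("no lipid particles in topology")
  lw <- makeWhole(frame$coords[il, , drop = FALSE], frame$box)
  mid <- massCOM(lw, p$mass[il])[3]
  mols <- p$molecule_id[il]
  zPer <- tapply(seq_along(il), mols, function(k) {
    ph <- p$is_phosphate[il[k]]
    mean(lw[if (any(ph)) k[ph] else k, 3])
  })
  zPer <- setNames(as.vector(zPer), names(zPer))
  leaf <- ifelse(zPer >= mid, "upper", "lower")
  ip <- which(p$role == "protein")
  if (length(ip)) {
    comP <- massCOM(makeWhole(frame$coords[ip, , drop = FALSE], frame$box),
                    p$mass[ip])[3]
    dUp <- mean(abs(zPer[leaf == "upper"] - comP))
    dLo <- mean(abs(zPer[leaf == "lower"] - comP))
    proximal <- if (!is.finite(dLo) || (is.finite(dUp) && dUp <= dLo))
      "upper" else "lower"
  } else proximal <- NA_character_
  structure(leaf, midplane = unname(mid), proximal = proximal)
}

#' Annulus occupancy around the protein
#'
#' Number of role-lipids whose phosphate lies within `annulusWidth` of the
#' protein surface -- operationalised as the minimum phosphate-to-any-protein
#' particle 3-D minimum-image distance being `<=` the width -- restricted to
#' the requested leaflet.
#'
#' @param frame a frame.
#' @param topology the matching [Topology-class].
#' @param config an [analysisConfig()].
#' @param role lipid role.
#' @param leaflet `"proximal"`, `"distal"` or `"both"`.
#' @return integer count.
#' @export
annulusCount <- function(frame, topology, config = analysisConfig(),
                         role = "PIP3",
                         leaflet = c("proximal", "distal", "both")) {
  leaflet <- match.arg(leaflet)
  role <- normalizeRole(role)
  ph <- rolePhosphates(frame, topology, role)
  if (is.null(ph)) return(0L)
  p <- particles(topology)
  prot <- frame$coords[p$role == "protein", , drop = FALSE]
  inAnn <- bruteWithin(ph$coords, prot, frame$box, config$annulusWidth)
  if (leaflet != "both") {
    la <- leafletAssign(frame, topology)
    want <- if (leaflet == "proximal") attr(la, "proximal") else
      setdiff(c("upper", "lower"), attr(la, "proximal"))
    inAnn <- inAnn & la[as.character(ph$mol)] %in% want
  }
  sum(inAnn)
}

#' Per-frame PIP contact series
#'
#' Applies [pipContacts()] and [annulusCount()] frame by frame, optionally
#' restricted to the frames classified bound in the aligned orientation
#' series (the convention for reporting contact numbers).
#'
#' @param traj a [Trajectory-class].
#' @param series data.frame from [orientationSeries()], aligned
#'   frame-for-frame with `traj`.
#' @param config an [analysisConfig()].
#' @param role lipid role.
#' @param boundOnly drop frames that fail the bound rule.
#' @return list of class `ContactSeries`: `frames` (data.frame `time`,
#'   `n_contacts`, `annulus_proximal`, `annulus_distal`, `bound`),
#'   `contacts` (list of molecule-id sets), `role`.
#' @export
contactCountSeries <- function(traj, series, config = analysisConfig(),
                               role = "PIP3", boundOnly = TRUE) {
  if (nrow(series) != nFrames(traj))
    stop("series (", nrow(series), " rows) is not aligned with trajectory (",
         nFrames(traj), " frames)")
  role <- normalizeRole(role)
  keep <- if (boundOnly) which(series$bound) else seq_len(nFrames(traj))
  sets <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    f <- frames(traj)[[keep[k]]]
    sets[[k]] <- suppressWarnings(pipContacts(f, traj@topology, config, role))
    rows[[k]] <- data.frame(
      time = f$time, n_contacts = length(sets[[k]]),
      annulus_proximal = annulusCount(f, traj@topology, config, role, "proximal"),
      annulus_distal = annulusCount(f, traj@topology, config, role, "distal"),
      bound = series$bound[keep[k]])
  }
  structure(list(frames = if (length(rows)) do.call(rbind, rows) else
                   data.frame(time = numeric(0), n_contacts = integer(0),
                              annulus_proximal = integer(0),
                              annulus_distal = integer(0), bound = logical(0)),
                 contacts = sets, role = role),
            class = "ContactSeries")
}

#' Residue contact ranking
#'
#' For every frame and every contacting lipid, a residue's count increments
#' once per lipid whose phosphate is within the cutoff of any particle of
#' that residue.  Residues are returned in descending count order, ties
#' broken by ascending residue id.
#'
#' @param traj a [Trajectory-class].
#' @param config an [analysisConfig()].
#' @param role lipid role.
#' @return data.frame `residue_id`, `count`, ordered as above.
#' @export
residueContactRanking <- function(traj, config = analysisConfig(),
                                  role = "PIP3") {
  role <- normalizeRole(role)
  p <- particles(traj@topology)
  ip <- which(p$role == "protein")
  resOf <- p$residue_id[ip]
  resIds <- sort(unique(resOf))
  counts <- setNames(rep(0L, length(resIds)), resIds)
  for (f in frames(traj)) {
    ph <- rolePhosphates(f, traj@topology, role)
    if (is.null(ph) || !nrow(ph$coords)) next
    dm <- miDistMatrix(ph$coords, f$coords[ip, , drop = FALSE], f$box)
    for (r in resIds) {
      hit <- dm[, resOf == r, drop = FALSE] <= config$contactCutoff
      counts[as.character(r)] <- counts[as.character(r)] +
        sum(apply(hit, 1, any))
    }
  }
  out <- data.frame(residue_id = resIds, count = as.integer(counts))
  out[order(-out$count, out$residue_id), ]
}

#' Canonical vs non-canonical binding-site call
#'
#' Computes the fraction of residue contacts falling in each configured
#' inter-strand loop.  `canonical` when the beta1/beta2 and beta3/beta4 loops
#' carry the two largest fractions, `non-canonical` when beta1/beta2 and
#' beta5/beta6 do, `mixed` otherwise, and `none` when under 10% of contacts
#' are in any loop (or there are no contacts at all).
#'
#' @param ranking data.frame `residue_id`, `count` from
#'   [residueContactRanking()].
#' @param loops named list of inclusive residue ranges; needs `beta12`,
#'   `beta34`, `beta56` (see [analysisConfig()]).
#' @return list of class `SiteCall`: `label`, `fractions` (per loop).
#' @export
classifyBindingSite <- function(ranking, loops = analysisConfig()$loops) {
  need <- c("beta12", "beta34", "beta56")
  if (!all(need %in% names(loops)) ||
      any(vapply(loops[need], is.null, logical(1))))
    stop("loops beta12, beta34 and beta56 must all be configured")
  rng <- lapply(loops[need], function(r) seq(r[1], r[2]))
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(rng[[i]], rng[[j]])))
      stop("loop ranges overlap: ", need[i], " and ", need[j])
  total <- sum(ranking$count)
  frac <- vapply(rng, function(rr)
    if (total > 0) sum(ranking$count[ranking$residue_id %in% rr]) / total
    else 0, numeric(1))
  names(frac) <- need
  label <- if (total == 0 || sum(frac) < 0.1) "none" else {
    top2 <- names(sort(frac, decreasing = TRUE))[1:2]
    if (setequal(top2, c("beta12", "beta34"))) "canonical"
    else if (setequal(top2, c("beta12", "beta56"))) "non-canonical"
    else "mixed"
  }
  structure(list(label = label, fractions = frac), class = "SiteCall")
}

#' Pairwise interaction persistence
#'
#' Fraction of frames in which the minimum distance between two particle (or
#' residue) groups is within the cutoff, plus the number of break events
#' (maximal runs of consecutive non-contact frames).  The fraction is
#' invariant to frame-order permutation; the break-event count is not.
#'
#' @param traj a [Trajectory-class].
#' @param a,b the two members: particle ids (0-based) when
#'   `type = "particle"`, residue ids when `type = "residue"`.
#' @param cutoff nm; default from [analysisConfig()].
#' @param type how `a` and `b` are interpreted.
#' @return list `fraction`, `breaks`, `contact` (per-frame logical).
#' @export
interactionPersistence <- function(traj, a, b,
                                   cutoff = analysisConfig()$persistenceCutoff,
                                   type = c("particle", "residue")) {
  type <- match.arg(type)
  p <- particles(traj@topology)
  pick <- function(m) {
    i <- if (type == "particle") which(p$id %in% m)
         else which(p$residue_id %in% m)
    if (!length(i)) stop("pair member matches no particles: ",
                         paste(m, collapse = ","))
    i
  }
  ia <- pick(a); ib <- pick(b)
  if (identical(sort(ia), sort(ib)))
    stop("the two pair members are identical")
  contact <- vapply(frames(traj), function(f)
    min(miDistMatrix(f$coords[ia, , drop = FALSE],
                     f$coords[ib, , drop = FALSE], f$box)) <= cutoff,
    logical(1))
  r <- rle(contact)
  list(fraction = mean(contact), breaks = sum(!r$values),
       contact = contact)
}

#' Expected annulus occupancy under lateral uniformity
#'
#' Closed-form check value for clustering statistics: for each (subsampled)
#' frame the lateral region where a phosphate at the leaflet plane would be
#' within `annulusWidth` of some protein particle is a union of disks (disk
#' radius `sqrt(w^2 - dz^2)` per protein particle); its area is integrated on
#' a fine midpoint grid, and the expected count is leaflet lipid density
#' times the mean area.
#'
#' @param traj a [Trajectory-class].
#' @param config an [analysisConfig()].
#' @param role lipid role whose per-leaflet density is used.
#' @param leaflet `"proximal"` or `"distal"`.
#' @param every subsample stride over frames.
#' @param gridStep integration grid step (nm).
#' @return list `expected` (mean count/frame), `area` (mean nm^2),
#'   `density` (lipids/nm^2), `nFramesUsed`.
#' @export
uniformAnnulusExpectation <- function(traj, config = analysisConfig(),
                                      role = "PIP3", leaflet = "proximal",
                                      every = 20, gridStep = 0.02) {
  role <- normalizeRole(role)
  p <- particles(traj@topology)
  ip <- which(p$role == "protein")
  idx <- seq(1, nFrames(traj), by = every)
  areas <- vapply(idx, function(i) {
    f <- frames(traj)[[i]]
    la <- leafletAssign(f, traj@topology)
    want <- if (leaflet == "proximal") attr(la, "proximal") else
      setdiff(c("upper", "lower"), attr(la, "proximal"))
    il <- lipidIdx(traj@topology)
    zLeaf <- mean(f$coords[il, 3][la[as.character(p$molecule_id[il])] == want])
    prot <- makeWhole(f$coords[ip, , drop = FALSE], f$box)
    dz <- abs(prot[, 3] - zLeaf)
    ok <- dz < config$annulusWidth
    if (!any(ok)) return(0)
    rad <- sqrt(config$annulusWidth^2 - dz[ok]^2)
    cx <- prot[ok, 1]; cy <- prot[ok, 2]
    xs <- seq(min(cx - rad), max(cx + rad), by = gridStep) + gridStep / 2
    ys <- seq(min(cy - rad), max(cy + rad), by = gridStep) + gridStep / 2
    inside <- matrix(FALSE, length(xs), length(ys))
    for (j in seq_along(rad))
      inside <- inside | (outer((xs - cx[j])^2, (ys - cy[j])^2, "+") <=
                            rad[j]^2)
    sum(inside) * gridStep^2
  }, numeric(1))
  # per-leaflet density of the role (half the role's lipids per leaflet by
  # construction of the synthetic membrane; counted from the first frame)
  la1 <- leafletAssign(frames(traj)[[1]], traj@topology)
  mols <- unique(p$molecule_id[p$role == role])
  want <- if (leaflet == "proximal") attr(la1, "proximal") else
    setdiff(c("upper", "lower"), attr(la1, "proximal"))
  nRole <- sum(la1[as.character(mols)] == want)
  bx <- frames(traj)[[1]]$box
  dens <- nRole / (bx[1] * bx[2])
  list(expected = dens * mean(areas), area = mean(areas), density = dens,
       nFramesUsed = length(idx))
}
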