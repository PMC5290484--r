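# Hand-built fixtures and independent oracle helpers.  Everything here is
# generated in code; no binary data.

# minimal particle table row builder
pRow <- function(id, name, resid, resname, mol, role, mass = 72,
                 phos = FALSE, bb = FALSE) {
  data.frame(id = id, name = name, residue_id = resid, residue_name = resname,
             molecule_id = mol, role = role, mass = mass,
             is_phosphate = phos, is_backbone = bb, stringsAsFactors = FALSE)
}

# topology: protein with one particle per residue at given residue ids, plus
# nPIP single-bead PIP3 lipids (each its own phosphate)
contactTopology <- function(proteinResidues = 360:363, nPIP = 1,
                            pipRole = "lipid:PIP3") {
  np <- length(proteinResidues)
  rows <- pRow(seq_len(np) - 1L, paste0("BB", seq_len(np)), proteinResidues,
               "PHD", 0L, "protein", bb = TRUE)
  if (nPIP > 0)
    rows <- rbind(rows, pRow(np + seq_len(nPIP) - 1L, "P1",
                             1000L + seq_len(nPIP), sub("lipid:", "", pipRole),
                             seq_len(nPIP), pipRole, phos = TRUE))
  topology(rows)
}

# non-coplanar 4-point reference geometry (nm, centred on construction)
refGeom4 <- function() {
  g <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  sweep(g, 2, colMeans(g))
}

rotX <- function(th) rbind(c(1, 0, 0), c(0, cos(th), -sin(th)),
                           c(0, sin(th), cos(th)))
rotY <- function(th) rbind(c(cos(th), 0, sin(th)), c(0, 1, 0),
                           c(-sin(th), 0, cos(th)))

# independent brute-force periodic contact oracle, coded separately from the
# package (its own distance arithmetic)
oracleContacts <- function(frame, topo, cutoff, role = "lipid:PIP3") {
  p <- particles(topo)
  prot <- frame$coords[p$role == "protein", , drop = FALSE]
  sel <- which(p$role == role & p$is_phosphate)
  hit <- integer(0)
  for (i in sel) {
    q <- frame$coords[i, ]
    for (j in seq_len(nrow(prot))) {
      d <- q - prot[j, ]
      d <- d - frame$box * round(d / frame$box)
      if (sqrt(sum(d * d)) <= cutoff) { hit <- c(hit, p$molecule_id[i]); break }
    }
  }
  sort(unique(hit))
}

# GRO fixture with residues POPC, PIP3, ALA (fixed-width records)
writeTinyGRO <- function(path) {
  lines <- c(
    "tiny three-particle system",
    "    3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "POPC", "PO4", 1, 1.0, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2, "PIP3", "P1", 2, 2.0, 2.0, 2.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 3, "ALA", "CA", 3, 3.0, 3.0, 3.0),
    "   5.0 5.0 10.0")
  writeLines(lines, path)
  path
}

# small deterministic trajectory over a given topology
linearTrajectory <- function(topo, zs, box = c(10, 10, 10), dt = 20) {
  n <- nParticles(topo)
  frs <- lapply(seq_along(zs), function(i) {
    coords <- matrix(rep(c(5, 5, 0), each = n), n, 3)
    coords[, 3] <- zs[[i]]
    frame((i - 1) * dt, box, coords)
  })
  trajectory(topo, frs)
}
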