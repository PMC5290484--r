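## Structure / trajectory readers and tabular writers.
##
## GRO is parsed by hand (fixed-width records, line-numbered errors); PDB goes
## through bio3d::read.pdb and is converted from angstrom to nm on read.
## Trajectories travel as a plain columnar TSV dialect: a "#box Lx Ly Lz"
## comment, a header, then one row per particle per frame block with columns
## time_ps, x, y, z (nm).  Only orthorhombic boxes are accepted.

#' Default residue-name to role map
#'
#' Editable mapping used by [readStructure()] to assign particle roles.  Keys
#' are residue names, values one of the roles in a [Topology-class].  Standard
#' amino acids map to `protein`; POPC/POPE/POPS and the common PIP residue
#' names (POP2/PIP2, POP3/PIP3) map to their lipid roles; water/ions map to
#' `solvent`.  Override or extend with a YAML file via `mapFile`:
#' a top-level `roles:` mapping plus an optional `phosphate_names:` list of
#' particle names flagged as PIP headgroup phosphates and `backbone_names:`.
#'
#' @param mapFile optional YAML file overriding/extending the defaults.
#' @return list with elements `roles` (named character), `phosphate_names`,
#'   `backbone_names`.
#' @export
defaultRoleMap <- function(mapFile = NULL) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP")
  roles <- c(setNames(rep("protein", length(aa)), aa),
             POPC = "lipid:POPC", POPE = "lipid:POPE", POPS = "lipid:POPS",
             POP2 = "lipid:PIP2", PIP2 = "lipid:PIP2",
             POP3 = "lipid:PIP3", PIP3 = "lipid:PIP3",
             W = "solvent", WF = "solvent", SOL = "solvent", HOH = "solvent",
             TIP3 = "solvent", NA. = "solvent", CL = "solvent", ION = "solvent",
             NAp = "solvent", CLm = "solvent", K = "solvent")
  map <- list(roles = roles,
              # PIP headgroup phosphates: Martini-style bead names and
              # atomistic P atoms other than the glycerol-backbone phosphate
              phosphate_names = c("P1", "P2", "P3", "P4", "P5", "PO4",
                                  "PO1", "PO2", "PO3", "P"),
              backbone_names = c("BB", "CA", "N", "C", "O"))
  if (!is.null(mapFile)) {
    y <- yaml::read_yaml(mapFile)
    if (!is.null(y$roles)) {
      ov <- unlist(y$roles)
      bad <- setdiff(ov, .particleRoles)
      if (length(bad)) stop("role map file assigns unknown role(s): ",
                            paste(bad, collapse = ", "))
      map$roles[names(ov)] <- ov
    }
    if (!is.null(y$phosphate_names)) map$phosphate_names <- unlist(y$phosphate_names)
    if (!is.null(y$backbone_names)) map$backbone_names <- unlist(y$backbone_names)
  }
  map
}

# crude particle masses: CG bead names get the Martini 72 Da, otherwise the
# element implied by the first alphabetic character of the particle name
.cgBeads <- c("BB", "SC1", "SC2", "SC3", "SC4", "PO4", "GL1", "GL2",
              "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B",
              "D2A", "D2B", "NC3", "NH3", "CNO", "P1", "P2", "P3", "P4", "P5")
.elementMass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)

particleMass <- function(name) {
  m <- rep(72, length(name))
  atom <- !(name %in% .cgBeads)
  el <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name[atom])
  m[atom] <- ifelse(el %in% names(.elementMass), .elementMass[el], 12.011)
  m
}

# assemble the particle table shared by both structure readers
buildParticles <- function(name, residue_id, residue_name, map) {
  n <- length(name)
  role <- unname(map$roles[residue_name])
  unknown <- is.na(role)
  if (any(unknown)) {
    warning("unknown residue name(s) assigned role 'other': ",
            paste(unique(residue_name[unknown]), collapse = ", "))
    role[unknown] <- "other"
  }
  # molecule boundaries: contiguous protein particles form one molecule,
  # every other residue instance is its own molecule
  newRes <- c(TRUE, residue_id[-1] != residue_id[-n] |
                residue_name[-1] != residue_name[-n])
  isProt <- role == "protein"
  breaks <- newRes & !(isProt & c(FALSE, isProt[-n]))
  molecule_id <- cumsum(breaks) - 1L
  isPIP <- role %in% c("lipid:PIP2", "lipid:PIP3")
  data.frame(id = seq_len(n) - 1L, name = name,
             residue_id = as.integer(residue_id),
             residue_name = residue_name, molecule_id = molecule_id,
             role = role, mass = particleMass(name),
             is_phosphate = isPIP & name %in% map$phosphate_names,
             is_backbone = name %in% map$backbone_names,
             stringsAsFactors = FALSE)
}

#' Read a structure file (GRO or PDB)
#'
#' Parses particle metadata and one coordinate frame.  Roles are assigned from
#' residue names via the role map ([defaultRoleMap()]); unknown residues get
#' role `other` with a warning.  PDB coordinates (angstrom) are converted to
#' nm; triclinic boxes are rejected.
#'
#' @param path file path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @param map role map, see [defaultRoleMap()].
#' @param box fallback box (nm) for PDB files without a CRYST1 record.
#' @return list with elements `topology` ([Topology-class]) and `frame`.
#' @export
readStructure <- function(path, format = c("gro", "pdb"), map = defaultRoleMap(),
                          box = NULL) {
  if (missing(format))
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "gro") readGRO(path, map) else readPDBnm(path, map, box)
}

readGRO <- function(path, map) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3)
    stop("parse error in ", path, ": need title, atom count, atoms and box ",
         "(got ", length(lines), " line(s))")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0)
    stop("parse error at line 2: invalid atom count '", trimws(lines[2]), "'")
  if (length(lines) < 2 + n + 1)
    stop("structural error: header declares ", n, " atoms but file has only ",
         length(lines) - 3, " atom line(s)")
  atomLines <- lines[3:(2 + n)]
  num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) stop("parse error at line ", ln[which(is.na(v))[1]],
                            ": bad ", what)
    v
  }
  ln <- 3:(2 + n)
  resid <- num(substr(atomLines, 1, 5), ln, "residue number")
  resname <- trimws(substr(atomLines, 6, 10))
  name <- trimws(substr(atomLines, 11, 15))
  x <- num(substr(atomLines, 21, 28), ln, "x coordinate")
  y <- num(substr(atomLines, 29, 36), ln, "y coordinate")
  z <- num(substr(atomLines, 37, 44), ln, "z coordinate")
  boxFields <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                                    "\\s+")[[1]]))
  if (any(is.na(boxFields)) || !length(boxFields))
    stop("parse error at line ", 3 + n, ": bad box line")
  if (length(boxFields) > 3 && any(boxFields[4:length(boxFields)] != 0))
    stop("triclinic box rejected: only orthorhombic boxes are supported")
  boxv <- boxFields[1:3]
  topo <- topology(buildParticles(name, resid, resname, map))
  list(topology = topo, frame = frame(0, boxv, cbind(x, y, z)))
}

readPDBnm <- function(path, map, box) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("parse error reading PDB ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  if (!nrow(a)) stop("parse error: no ATOM/HETATM records in ", path)
  coords <- cbind(a$x, a$y, a$z) / 10  # angstrom -> nm
  if (is.null(box)) {
    cr <- tryCatch(pdb$cryst1, error = function(e) NULL)
    if (!is.null(cr) && length(cr$abc) == 3 && all(is.finite(cr$abc)) &&
        all(cr$abc > 0)) {
      if (!is.null(cr$abg) && any(abs(cr$abg - 90) > 1e-6))
        stop("triclinic box rejected: only orthorhombic boxes are supported")
      box <- cr$abc / 10
    } else {
      warning("no CRYST1 box in ", path, "; using a 100 nm cube")
      box <- c(100, 100, 100)
    }
  }
  topo <- topology(buildParticles(a$elety, a$resno, a$resid, map))
  list(topology = topo, frame = frame(0, box, coords))
}

#' Read a columnar-TSV trajectory
#'
#' Dialect: optional leading `#box Lx Ly Lz` comment, a header line
#' `time_ps\tx\ty\tz`, then one row per particle per frame block.  The
#' per-frame particle count must equal the topology size.
#'
#' @param path file path.
#' @param topology the matching [Topology-class].
#' @param format only `"tsv"` is supported; requesting `"xtc"` errors (no XTC
#'   support; convert externally to the TSV dialect).
#' @param box box edge lengths (nm) if the file lacks a `#box` comment.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, format = c("tsv", "xtc"), box = NULL) {
  format <- match.arg(format)
  if (format == "xtc")
    stop("XTC input is not supported; convert to the columnar TSV dialect ",
         "(see writeTrajectory)")
  if (!file.exists(path)) stop("file does not exist: ", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "#box")) {
    box <- as.numeric(strsplit(trimws(sub("^#box", "", first)), "\\s+")[[1]])
  }
  if (is.null(box) || length(box) != 3)
    stop("no box available: file lacks a '#box Lx Ly Lz' line and no box= given")
  dt <- data.table::fread(path, sep = "\t", skip = if (startsWith(first, "#box")) 1 else 0)
  need <- c("time_ps", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("trajectory TSV must have columns: ", paste(need, collapse = ", "))
  n <- nParticles(topology)
  if (nrow(dt) %% n != 0)
    stop("truncated final frame: frame index ", nrow(dt) %/% n + 1,
         " has ", nrow(dt) %% n, " of ", n, " particle rows")
  nf <- nrow(dt) %/% n
  frs <- vector("list", nf)
  tm <- dt$time_ps; xs <- dt$x; ys <- dt$y; zs <- dt$z
  for (i in seq_len(nf)) {
    idx <- ((i - 1) * n + 1):(i * n)
    ti <- tm[idx]
    if (length(unique(ti)) != 1)
      stop("inconsistent times inside frame block ", i)
    frs[[i]] <- frame(ti[1], box, cbind(x = xs[idx], y = ys[idx], z = zs[idx]))
  }
  trajectory(topology, frs)
}

#' Write a trajectory in the columnar TSV dialect
#'
#' @param traj a [Trajectory-class]; the box must be constant across frames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTrajectory <- function(traj, path) {
  bx <- frames(traj)[[1]]$box
  for (f in frames(traj))
    if (any(abs(f$box - bx) > 0)) stop("TSV dialect requires a constant box")
  # %.17g round-trips IEEE doubles exactly, keeping the dialect bit-faithful
  g17 <- function(v) sprintf("%.17g", v)
  rows <- data.table::rbindlist(lapply(frames(traj), function(f)
    data.table::data.table(time_ps = g17(f$time), x = g17(f$coords[, 1]),
                           y = g17(f$coords[, 2]), z = g17(f$coords[, 3]))))
  writeLines(c(sprintf("#box %.17g %.17g %.17g", bx[1], bx[2], bx[3]),
               "time_ps\tx\ty\tz"), path)
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE, append = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Write an analysis table as TSV
#'
#' Header row; doubles rendered with 6 significant digits; row order preserved
#' (deterministic).  Empty input is an error, not an empty file.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records)
  if (!nrow(records) || !ncol(records))
    stop("refusing to write an empty table")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
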