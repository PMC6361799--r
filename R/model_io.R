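# Domain types for two-chain molecular systems and the on-disk formats the
# pipeline touches: PDB structures, multi-model PDB trajectories, a JSON
# parameter sidecar (charges / Lennard-Jones / hydrogen-bond roles), and CSV
# energy series.

#' Construct a two-partner topology
#'
#' A topology holds an ordered atom table plus a bipartition of the atoms into
#' two binding partners (e.g. a peptide ligand and its receptor). All energy
#' routines in bindscope act on the inter-partner interaction only.
#'
#' @param atoms A data.frame with one row per atom and columns `atom_name`,
#'   `element`, `residue_number`, `residue_name`, `chain_id`, `charge` (e),
#'   `rmin_half` (A, AMBER R_min/2 convention), `epsilon` (kcal/mol),
#'   `donor_heavy`, `acceptor`, `polar_hydrogen` (logicals), and
#'   `bonded_heavy` (integer atom index of the heavy atom a polar hydrogen is
#'   bonded to; `NA` otherwise).
#' @param partner1_chains,partner2_chains Character vectors of chain ids
#'   forming each partner. Must be disjoint and together cover every chain.
#' @param temperature Default temperature in K carried by the system.
#' @return An object of class `"topology"`: a list with elements `atoms`,
#'   `partner1`, `partner2` (1-based atom index vectors) and `temperature`.
#' @seealso [read_topology()], [build_toy_dimer()]
#' @export
topology <- function(atoms, partner1_chains, partner2_chains,
                     temperature = 300) {
  required <- c("atom_name", "element", "residue_number", "residue_name",
                "chain_id", "charge", "rmin_half", "epsilon",
                "donor_heavy", "acceptor", "polar_hydrogen", "bonded_heavy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  n <- nrow(atoms)
  if (n < 1L) stop("topology needs at least one atom")
  if (any(atoms$rmin_half < 0)) stop("rmin_half must be >= 0")
  if (any(atoms$epsilon < 0)) stop("epsilon must be >= 0")
  hyd <- which(atoms$polar_hydrogen)
  bad <- hyd[is.na(atoms$bonded_heavy[hyd]) |
               atoms$bonded_heavy[hyd] < 1 | atoms$bonded_heavy[hyd] > n]
  if (length(bad))
    stop("polar hydrogen(s) without a recorded bonded heavy atom: ",
         paste(.atom_label(atoms, bad), collapse = ", "))

  partner1_chains <- as.character(partner1_chains)
  partner2_chains <- as.character(partner2_chains)
  if (length(intersect(partner1_chains, partner2_chains)))
    stop("partner chain lists overlap: ",
         paste(intersect(partner1_chains, partner2_chains), collapse = ", "))
  p1 <- which(atoms$chain_id %in% partner1_chains)
  p2 <- which(atoms$chain_id %in% partner2_chains)
  if (length(p1) + length(p2) != n)
    stop("partner chain lists do not cover all chains; uncovered: ",
         paste(setdiff(unique(atoms$chain_id),
                       c(partner1_chains, partner2_chains)), collapse = ", "))
  if (length(p1) == 0L || length(p2) == 0L)
    stop("each partner must contain at least one atom")

  obj <- structure(
    list(atoms = atoms, partner1 = p1, partner2 = p2,
         partner1_chains = partner1_chains,
         partner2_chains = partner2_chains,
         temperature = temperature),
    class = "topology")
  obj
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(.residue_key(x$atoms))), "residues\n")
  cat("  partner1 (chains ", paste(x$partner1_chains, collapse = ","), "): ",
      length(x$partner1), " atoms\n", sep = "")
  cat("  partner2 (chains ", paste(x$partner2_chains, collapse = ","), "): ",
      length(x$partner2), " atoms\n", sep = "")
  cat("  temperature:", x$temperature, "K\n")
  invisible(x)
}

# residue identity key "chain:resnum:resname", one per atom row
.residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$residue_name, sep = ":")
}

.atom_label <- function(atoms, idx) {
  paste0(atoms$chain_id[idx], ":", atoms$residue_number[idx], ":",
         atoms$atom_name[idx])
}

#' Construct a trajectory
#'
#' @param topology A [topology()].
#' @param coords A numeric array of dimension `c(n_atoms, 3, n_frames)` in
#'   Angstrom, or a single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param frame_interval Time between stored frames in femtoseconds.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, frame_interval = 10) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  n <- nrow(topology$atoms)
  if (length(dim(coords)) != 3L || dim(coords)[1] != n || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array matching the topology")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 fs")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, frame interval", x$frame_interval, "fs\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(trj) {
  stopifnot(inherits(trj, "trajectory"))
  dim(trj$coords)[3]
}

#' Extract one frame of a trajectory
#' @param trj A [trajectory()].
#' @param i Frame index (1-based).
#' @return An `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_coords <- function(trj, i) {
  stopifnot(inherits(trj, "trajectory"))
  if (i < 1 || i > dim(trj$coords)[3]) stop("frame index out of range: ", i)
  trj$coords[, , i, drop = TRUE]
}

#' Construct a per-frame energy series
#'
#' @param values Numeric vector of per-frame energies in kcal/mol; must be
#'   finite and non-empty.
#' @param component Component label, e.g. `"ele"`, `"vdw"`, `"total"`,
#'   `"polar"`, `"nonpolar"`, or a residue-scoped label such as
#'   `"A:3:ARG:total"`.
#' @param frame_interval Time between frames, fs.
#' @param temperature Temperature in K the series was sampled at.
#' @return An object of class `"energy_series"`.
#' @export
energy_series <- function(values, component = "total", frame_interval = 10,
                          temperature = 300) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("energy series must contain at least one value")
  if (!all(is.finite(values))) stop("energy series contains non-finite values")
  if (!is.character(component) || length(component) != 1L || !nzchar(component))
    stop("component must be a single non-empty string")
  if (frame_interval <= 0) stop("frame_interval must be > 0 fs")
  structure(list(values = values, component = component,
                 frame_interval = frame_interval, temperature = temperature),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat("energy_series [", x$component, "]: ", length(x$values),
      " frames, mean ", sprintf("%.4f", mean(x$values)), " kcal/mol\n",
      sep = "")
  invisible(x)
}

#' @export
length.energy_series <- function(x) length(x$values)

#' @export
mean.energy_series <- function(x, ...) mean(x$values, ...)

## ---------------------------------------------------------------------------
## PDB structure + parameter sidecar
## ---------------------------------------------------------------------------

#' Read a topology from a PDB structure and a JSON parameter sidecar
#'
#' The PDB file supplies atom identities and ordering; the sidecar supplies
#' per-atom partial charges, Lennard-Jones parameters (R_min/2 + epsilon) and
#' hydrogen-bond role annotations, plus the two partner chain lists. The
#' sidecar is keyed by chain, then residue number, then atom name, so the same
#' structure can be paired with alternative charge sets (for example a
#' polarized protein-specific charge set) by swapping sidecars.
#'
#' @param structure_path Path to a PDB file with unique
#'   (chain, residue number, atom name) triples, no insertion codes, no altlocs.
#' @param params_path Path to the JSON sidecar. Top-level fields:
#'   `partner1_chains`, `partner2_chains`, optional `temperature`, and `atoms`
#'   keyed chain -> residue number -> atom name with fields `charge`,
#'   `rmin_half`, `epsilon`, optional `roles` (subset of `"donor_heavy"`,
#'   `"acceptor"`, `"polar_hydrogen"`) and, for polar hydrogens,
#'   `bonded_heavy` (atom name of the bonded donor heavy atom in the same
#'   residue).
#' @return A [topology()], atom ordering following file order.
#' @export
read_topology <- function(structure_path, params_path) {
  pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(trimws(at$insert))))
    stop("PDB insertion codes are not supported: ", structure_path)
  if (any(!is.na(at$alt) & nzchar(trimws(at$alt))))
    stop("PDB altloc records are not supported: ", structure_path)
  key <- paste(at$chain, at$resno, at$elety, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name) in ", structure_path,
         ": ", key[duplicated(key)][1])

  side <- jsonlite::fromJSON(params_path, simplifyVector = FALSE)
  for (f in c("partner1_chains", "partner2_chains", "atoms"))
    if (is.null(side[[f]])) stop("parameter sidecar lacks field '", f, "'")

  n <- nrow(at)
  element <- at$elesy
  element[is.na(element) | !nzchar(trimws(element))] <-
    substr(trimws(at$elety[is.na(element) | !nzchar(trimws(element))]), 1, 1)
  element <- toupper(trimws(element))

  charge <- rmin_half <- epsilon <- numeric(n)
  donor <- acceptor <- polarh <- logical(n)
  bonded_name <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    entry <- side$atoms[[as.character(at$chain[i])]][[
      as.character(at$resno[i])]][[at$elety[i]]]
    if (is.null(entry) || is.null(entry$charge) || is.null(entry$rmin_half) ||
        is.null(entry$epsilon))
      stop("missing parameters for atom (", at$chain[i], ", ", at$resno[i],
           ", ", at$elety[i], ") in ", params_path)
    charge[i] <- entry$charge
    rmin_half[i] <- entry$rmin_half
    epsilon[i] <- entry$epsilon
    roles <- unlist(entry$roles)
    donor[i] <- "donor_heavy" %in% roles
    acceptor[i] <- "acceptor" %in% roles
    polarh[i] <- "polar_hydrogen" %in% roles
    if (!is.null(entry$bonded_heavy)) bonded_name[i] <- entry$bonded_heavy
  }

  bonded_heavy <- rep(NA_integer_, n)
  for (i in which(polarh)) {
    if (is.na(bonded_name[i]))
      stop("polar hydrogen (", at$chain[i], ", ", at$resno[i], ", ",
           at$elety[i], ") lacks a bonded_heavy entry in the sidecar")
    j <- which(at$chain == at$chain[i] & at$resno == at$resno[i] &
                 at$elety == bonded_name[i])
    if (length(j) != 1L)
      stop("bonded_heavy '", bonded_name[i], "' not found for hydrogen (",
           at$chain[i], ", ", at$resno[i], ", ", at$elety[i], ")")
    bonded_heavy[i] <- j
  }

  atoms <- data.frame(
    atom_name = at$elety, element = element,
    residue_number = at$resno, residue_name = at$resid,
    chain_id = at$chain, charge = charge, rmin_half = rmin_half,
    epsilon = epsilon, donor_heavy = donor, acceptor = acceptor,
    polar_hydrogen = polarh, bonded_heavy = bonded_heavy,
    stringsAsFactors = FALSE)

  temperature <- if (!is.null(side$temperature)) side$temperature else 300
  topology(atoms,
           partner1_chains = unlist(side$partner1_chains),
           partner2_chains = unlist(side$partner2_chains),
           temperature = temperature)
}

#' Write a topology (and a reference frame) to PDB + JSON sidecar
#'
#' Inverse of [read_topology()]: emits the structure as a PDB file (coordinates
#' to 3 decimals) and the per-atom parameters as a JSON sidecar.
#'
#' @param top A [topology()].
#' @param reference An `n_atoms x 3` coordinate matrix (Angstrom).
#' @param structure_path,params_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_topology <- function(top, reference, structure_path, params_path) {
  stopifnot(inherits(top, "topology"))
  a <- top$atoms
  n <- nrow(a)
  reference <- as.matrix(reference)
  if (!all(dim(reference) == c(n, 3)))
    stop("reference frame does not match topology atom count")
  bio3d::write.pdb(file = structure_path,
                   xyz = as.vector(t(reference)),
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = seq_len(n), elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)

  atoms <- list()
  for (i in seq_len(n)) {
    roles <- c(if (a$donor_heavy[i]) "donor_heavy",
               if (a$acceptor[i]) "acceptor",
               if (a$polar_hydrogen[i]) "polar_hydrogen")
    entry <- list(charge = a$charge[i], rmin_half = a$rmin_half[i],
                  epsilon = a$epsilon[i])
    if (length(roles)) entry$roles <- as.list(roles)
    if (!is.na(a$bonded_heavy[i]))
      entry$bonded_heavy <- a$atom_name[a$bonded_heavy[i]]
    ch <- a$chain_id[i]; rn <- as.character(a$residue_number[i])
    atoms[[ch]][[rn]][[a$atom_name[i]]] <- entry
  }
  side <- list(partner1_chains = as.list(top$partner1_chains),
               partner2_chains = as.list(top$partner2_chains),
               temperature = top$temperature,
               atoms = atoms)
  jsonlite::write_json(side, params_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(structure_path, params_path))
}

## ---------------------------------------------------------------------------
## Multi-model PDB trajectories
## ---------------------------------------------------------------------------

# Count ATOM/HETATM records per MODEL block so atom-count errors can name the
# offending model before handing the file to the full parser.
.scan_model_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!length(model_starts)) return(sum(is_atom))
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  vapply(seq_along(model_starts), function(k)
    sum(is_atom[model_starts[k]:model_ends[k]]), integer(1))
}

.frame_interval_from_header <- function(path) {
  head_lines <- readLines(path, n = 50, warn = FALSE)
  m <- grep("^REMARK +FRAME_INTERVAL_FS ", head_lines, value = TRUE)
  if (!length(m)) return(NULL)
  as.numeric(sub("^REMARK +FRAME_INTERVAL_FS +", "", m[1]))
}

#' Read a multi-model PDB trajectory against a known topology
#'
#' @param trajectory_path Path to a (multi-model) PDB file whose atom order
#'   matches `top` in every model.
#' @param top The [topology()] the frames belong to.
#' @param frame_interval Time between frames in fs; if `NULL`, taken from a
#'   `REMARK FRAME_INTERVAL_FS` header line when present, else 10 fs.
#' @return A [trajectory()], frames in model order.
#' @export
read_trajectory <- function(trajectory_path, top, frame_interval = NULL) {
  stopifnot(inherits(top, "topology"))
  n <- nrow(top$atoms)
  counts <- .scan_model_counts(trajectory_path)
  bad <- which(counts != n)
  if (length(bad))
    stop("model ", bad[1], " of ", trajectory_path, " has ", counts[bad[1]],
         " atoms; topology has ", n)

  pdb <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  mism <- which(at$elety != top$atoms$atom_name |
                  at$resno != top$atoms$residue_number |
                  at$chain != top$atoms$chain_id)
  if (length(mism))
    stop("atom order mismatch with topology at atom ", mism[1], " (",
         .atom_label(top$atoms, mism[1]), " expected)")

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n, 3, nf))
  for (k in seq_len(nf))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  if (is.null(frame_interval))
    frame_interval <- .frame_interval_from_header(trajectory_path)
  if (is.null(frame_interval)) frame_interval <- 10
  trajectory(top, coords, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written to 3 decimals (PDB fixed columns); the frame
#' interval is recorded in a `REMARK FRAME_INTERVAL_FS` header line so
#' [read_trajectory()] can recover it.
#'
#' @param trj A [trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trj, path) {
  stopifnot(inherits(trj, "trajectory"))
  a <- trj$topology$atoms
  n <- nrow(a)
  nf <- dim(trj$coords)[3]
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * n)
  for (k in seq_len(nf)) xyz[k, ] <- as.vector(t(trj$coords[, , k]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_number, resid = a$residue_name,
                   eleno = seq_len(n), elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  body <- readLines(path, warn = FALSE)
  writeLines(c(sprintf("REMARK FRAME_INTERVAL_FS %s",
                       format(trj$frame_interval, digits = 17)), body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Energy series CSV
## ---------------------------------------------------------------------------

#' Write an energy series to CSV
#'
#' Values are written as decimal text at 17 significant digits, so the
#' write/read round trip is bit-exact for doubles. Temperature and frame
#' interval are stored as leading comment lines.
#'
#' @param series An [energy_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_energy_series <- function(series, path) {
  stopifnot(inherits(series, "energy_series"))
  n <- length(series$values)
  rows <- sprintf("%d,%s,%s,%s",
                  seq_len(n),
                  sprintf("%.17g", (seq_len(n) - 1) * series$frame_interval),
                  sprintf("%.17g", series$values),
                  series$component)
  writeLines(c(sprintf("# temperature_k %.17g", series$temperature),
               sprintf("# frame_interval_fs %.17g", series$frame_interval),
               "frame,time_fs,value,component",
               rows), path)
  invisible(path)
}

#' Read an energy series written by [write_energy_series()]
#'
#' @param path Path to the CSV file.
#' @return An [energy_series()].
#' @export
read_energy_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty energy-series file: ", path)
  temperature <- 300
  frame_interval <- 10
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    if (grepl("^# temperature_k ", lines[i]))
      temperature <- as.numeric(sub("^# temperature_k ", "", lines[i]))
    if (grepl("^# frame_interval_fs ", lines[i]))
      frame_interval <- as.numeric(sub("^# frame_interval_fs ", "", lines[i]))
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "frame,time_fs,value,component")
    stop("line ", i, ": expected header 'frame,time_fs,value,component' in ",
         path)
  data_lines <- lines[-seq_len(i)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (!length(data_lines)) stop("no data rows in ", path)
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  component <- NULL
  values <- numeric(length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    lineno <- i + k
    if (length(p) != 4L)
      stop("line ", lineno, ": expected 4 comma-separated fields in ", path)
    v <- suppressWarnings(as.numeric(p[3]))
    if (is.na(v))
      stop("line ", lineno, ": non-numeric value '", p[3], "' in ", path)
    values[k] <- v
    if (is.null(component)) component <- p[4]
    else if (!identical(component, p[4]))
      stop("line ", lineno, ": inconsistent component label in ", path)
  }
  energy_series(values, component = component,
                frame_interval = frame_interval, temperature = temperature)
}
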