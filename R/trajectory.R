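#' @importFrom stats sd var coef lm setNames aggregate
#' @importFrom utils read.delim write.table head tail str modifyList
NULL

# classed error helper so callers can distinguish failure modes
smd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "switchmd_error")))
}

#' Construct a trajectory object
#'
#' An `md_trajectory` stores an ordered set of frames sharing one atom table:
#' coordinates live in a `frames x 3N` matrix (the layout used by MD analysis
#' tools), atom metadata in a data frame with one row per atom.
#'
#' @param xyz numeric matrix, one row per frame, columns `x1,y1,z1,x2,...` (A).
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `resno` (residue id as in the source file),
#'   `chain`, `elesy` (element), `water` (logical).
#' @param times frame times in ns, strictly increasing; defaults to
#'   `0:(nframes-1)`.
#' @param source free-text provenance label.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(xyz, atoms, times = NULL, source = "memory") {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) smd_stop("trajectory needs at least one frame", "switchmd_structure_error")
  if (ncol(xyz) != 3L * nrow(atoms))
    smd_stop(sprintf("xyz has %d columns but atom table implies %d", ncol(xyz), 3L * nrow(atoms)),
             "switchmd_structure_error")
  if (any(!is.finite(xyz))) smd_stop("non-finite coordinates", "switchmd_structure_error")
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz) || (nrow(xyz) > 1L && any(diff(times) <= 0)))
    smd_stop("times must match frame count and be strictly increasing", "switchmd_structure_error")
  atoms$water <- atoms$resid %in% c("HOH", "TIP3", "SOL", "WAT")
  rownames(atoms) <- NULL
  structure(list(xyz = xyz, atoms = atoms, times = as.numeric(times), source = source),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frame(s), %d atoms, chains {%s}, %d water(s)\n",
              n_frames(x), n_atoms(x),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              sum(x$atoms$water)))
  cat(sprintf("  time: %.3f .. %.3f ns   source: %s\n",
              x$times[1], x$times[length(x$times)], x$source))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix, one row per atom, columns x,y,z (A).
#' @export
frame_coords <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) smd_stop("frame index out of range", "switchmd_range_error")
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Select atom indices by metadata
#'
#' All supplied filters are combined with AND. Selections are resolved against
#' the shared atom table, so an index set computed once addresses the same
#' atoms in every frame.
#'
#' @param traj an `md_trajectory`.
#' @param chain,resno,elety,resid optional filters (vectors allowed).
#' @param water `NA` (no filter), `TRUE` (waters only) or `FALSE`.
#' @return integer vector of atom indices (possibly empty).
#' @export
atom_select <- function(traj, chain = NULL, resno = NULL, elety = NULL,
                        resid = NULL, water = NA) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.na(water))   keep <- keep & a$water == water
  which(keep)
}

# columns of the xyz matrix covered by a set of atom indices
xyz_cols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

#' One-letter sequence of a chain
#'
#' Residues are taken in order of first appearance; unknown residue names map
#' to `X`. Used to feed [detect_motifs()].
#'
#' @param traj an `md_trajectory`.
#' @param chain chain identifier.
#' @return named character scalar (names give residue ids, collapsed).
#' @export
chain_sequence <- function(traj, chain) {
  a <- traj$atoms[traj$atoms$chain == chain & !traj$atoms$water, , drop = FALSE]
  if (nrow(a) == 0L) smd_stop(sprintf("no atoms in chain '%s'", chain), "switchmd_selection_error")
  first <- !duplicated(a$resno)
  aa <- aa_three_to_one(a$resid[first])
  structure(paste(aa, collapse = ""), resno = a$resno[first])
}

aa_three_to_one <- function(x) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- tab[x]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' One frame per `MODEL` record; a file without `MODEL` records yields a
#' single frame. Waters (residue name HOH/TIP3/SOL/WAT) are retained and
#' flagged. Files with insertion codes are rejected; models with differing
#' atom counts raise a structure error; malformed coordinate fields raise a
#' parse error naming the offending line. For alternate locations the
#' highest-occupancy conformer is kept (ties: first encountered).
#'
#' @param path PDB file path.
#' @param dt frame spacing in ns used to assign times (default 1 ns/frame).
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, dt = 1) {
  if (!file.exists(path)) smd_stop(sprintf("file not found: %s", path), "switchmd_io_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_coord)) smd_stop("no ATOM/HETATM records", "switchmd_parse_error")

  # line-level validation: coordinates numeric, no insertion codes
  ci <- which(is_coord)
  for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
    v <- suppressWarnings(as.numeric(substr(lines[ci], fld[1], fld[2])))
    if (any(is.na(v)))
      smd_stop(sprintf("malformed coordinate field at line %d", ci[which(is.na(v))[1]]),
               "switchmd_parse_error")
  }
  ins <- substr(lines[ci], 27L, 27L)
  if (any(ins != " " & ins != ""))
    smd_stop(sprintf("insertion code at line %d: renumber the structure first",
                     ci[which(ins != " " & ins != "")[1]]),
             "switchmd_parse_error")

  # per-model record counts must agree
  model_of <- cumsum(rec == "MODEL ")
  nmodel <- max(model_of)
  if (nmodel > 1L) {
    counts <- table(model_of[is_coord])
    if (length(unique(as.integer(counts))) != 1L)
      smd_stop(sprintf("inconsistent atom counts across models: %s",
                       paste(as.integer(counts), collapse = "/")),
               "switchmd_structure_error")
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  xyz <- matrix(pdb$xyz, nrow = nrow(pdb$xyz))

  # altloc: keep highest occupancy per (chain, resno, resid, atom name)
  if (any(!is.na(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "\r")
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[duplicated(key)])) {
      grp <- which(key == k)
      keep[grp] <- FALSE
      keep[grp[which.max(occ[grp])]] <- TRUE
    }
    atoms <- atoms[keep, , drop = FALSE]
    xyz <- xyz[, xyz_cols(which(keep)), drop = FALSE]
  }

  at <- data.frame(elety = atoms$elety, resid = atoms$resid, resno = atoms$resno,
                   chain = ifelse(is.na(atoms$chain), " ", atoms$chain),
                   elesy = ifelse(is.na(atoms$elesy), "", atoms$elesy),
                   stringsAsFactors = FALSE)
  at$water <- at$resid %in% c("HOH", "TIP3", "SOL", "WAT")
  md_trajectory(xyz, at, times = (seq_len(nrow(xyz)) - 1) * dt, source = path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the PDB precision (3 decimals, A); reading the
#' file back reproduces them to that precision.
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   type = ifelse(a$water, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, elesy = a$elesy)
  invisible(path)
}

#' Extract a frame window as a new trajectory
#' @param traj an `md_trajectory`.
#' @param frames integer vector of frame indices (1-based, increasing).
#' @return an `md_trajectory` restricted to those frames.
#' @export
trajectory_window <- function(traj, frames) {
  frames <- as.integer(frames)
  if (length(frames) == 0L || any(frames < 1L | frames > n_frames(traj)))
    smd_stop("window outside trajectory bounds", "switchmd_range_error")
  md_trajectory(traj$xyz[frames, , drop = FALSE], traj$atoms,
                times = traj$times[frames], source = traj$source)
}
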