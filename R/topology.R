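# Core containers: topology, structure3d, trajectory.
#
# Conventions (fixed across the package):
#   * atom indices are 0-based and contiguous;
#   * residue sequence numbers are 1-based PDB numbers; the residue identity
#     key is (chain, resseq, inscode, resname);
#   * all coordinates are in Angstrom;
#   * a trajectory stores frames as an F x 3N matrix (x1,y1,z1,x2,...), the
#     layout bio3d uses, so frame slicing and distance evaluation vectorize.

#' Build a topology
#'
#' A topology is the static atom table of a protein-ligand complex: names,
#' elements, residue identities and the protein/ligand partition. Solvent and
#' ions are expected to have been removed at load time.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resseq`, `inscode`, `chain`, `is_ligand`, `is_hydrogen`. Row order
#'   defines the 0-based atom index.
#' @return Object of class `"topology"`.
#' @export
topology <- function(atoms) {
  req <- c("name", "element", "resname", "resseq", "inscode", "chain",
           "is_ligand", "is_hydrogen")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_schema(paste0("topology atom table missing column(s): ",
                       paste(miss, collapse = ", ")))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$index <- seq_len(nrow(atoms)) - 1L
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$is_ligand <- as.logical(atoms$is_ligand)
  atoms$is_hydrogen <- as.logical(atoms$is_hydrogen)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, natoms = nrow(atoms)), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<topology> %d atoms (%d protein / %d ligand; %d hydrogen), %d residues\n",
              x$natoms, sum(!a$is_ligand), sum(a$is_ligand),
              sum(a$is_hydrogen),
              nrow(unique(a[, c("chain", "resseq", "inscode", "resname")]))))
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$inscode, atoms$resname, sep = "|")
}

#' Build a single-snapshot structure
#'
#' @param top A [topology()].
#' @param xyz Numeric natoms x 3 matrix of coordinates in Angstrom.
#' @return Object of class `"structure3d"`.
#' @export
structure3d <- function(top, xyz) {
  stopifnot(inherits(top, "topology"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != top$natoms || ncol(xyz) != 3L)
    stop_topology(sprintf("coordinate matrix is %d x %d; expected %d x 3",
                          nrow(xyz), ncol(xyz), top$natoms))
  if (!all(is.finite(xyz)))
    stop_domain("structure coordinates must all be finite")
  dimnames(xyz) <- NULL
  structure(list(topology = top, xyz = xyz), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms\n", x$topology$natoms))
  invisible(x)
}

#' Build a trajectory
#'
#' @param top A [topology()].
#' @param xyz Numeric F x 3N matrix, one frame per row, columns ordered
#'   (x1, y1, z1, x2, ...), Angstrom.
#' @param frames data.frame with columns `replica_id` (0-based, int),
#'   `time` (ns) and `frame_index_in_replica` (0-based, int); one row per
#'   frame. Defaults to a single replica sampled at 1 ns.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(top, xyz, frames = NULL) {
  stopifnot(inherits(top, "topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * top$natoms)
    stop_topology(sprintf("trajectory has %d coordinate columns; expected %d",
                          ncol(xyz), 3L * top$natoms))
  if (is.null(frames)) {
    frames <- data.frame(replica_id = 0L,
                         time = as.numeric(seq_len(nrow(xyz)) - 1L),
                         frame_index_in_replica = seq_len(nrow(xyz)) - 1L)
  }
  if (nrow(frames) != nrow(xyz))
    stop_topology("frame metadata rows do not match coordinate rows")
  # frames within a replica must be time-ordered
  for (r in unique(frames$replica_id)) {
    tt <- frames$time[frames$replica_id == r]
    if (is.unsorted(tt)) stop_topology(sprintf("frames of replica %s are not time-ordered", r))
  }
  dimnames(xyz) <- NULL
  rownames(frames) <- NULL
  structure(list(topology = top, xyz = xyz, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %d replica(s)\n",
              nrow(x$xyz), x$topology$natoms,
              length(unique(x$frames$replica_id))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj A [trajectory()].
#' @param i Frame number, 1-based (position in the pooled frame order).
#' @return A [structure3d()].
#' @export
frame_structure <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    stop_domain(sprintf("frame %d out of range 1..%d", i, n_frames(traj)))
  structure3d(traj$topology, matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE))
}

# flat 3N row -> n x 3, and back
xyz_unflatten <- function(row) matrix(row, ncol = 3L, byrow = TRUE)
xyz_flatten <- function(mat) as.numeric(t(mat))

#' Convert a structure to a one-frame trajectory
#' @param s A [structure3d()].
#' @return A [trajectory()] with a single frame.
#' @export
as_trajectory <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  trajectory(s$topology, matrix(xyz_flatten(s$xyz), nrow = 1L))
}
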