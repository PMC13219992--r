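# Native-contact identification, analysis window, distance series,
# ensemble-averaged contact matrix and representative-frame selection.
#
# A "native contact" is a protein heavy-atom / ligand heavy-atom pair whose
# distance in the chosen reference structure is strictly below the native
# cutoff (default 4.5 A). The representative frame of a trajectory is the
# frame whose retained-pair distance vector lies closest (Euclidean norm) to
# the ensemble-averaged distance vector, with pairs retained when their mean
# distance over the analysis window is <= 6.75 A.

#' Analysis window
#'
#' Defines the equilibration fraction discarded from the start of each
#' replica before pooling. The default 0.6 keeps the last 40% of every
#' replica (the convention for 100-ns runs analyzed over their final 40 ns).
#'
#' @param discard_fraction Fraction in `[0, 1)` of each replica's frames
#'   dropped from the front.
#' @return Object of class `"analysis_window"`.
#' @export
analysis_window <- function(discard_fraction = 0.6) {
  if (!is.numeric(discard_fraction) || length(discard_fraction) != 1L ||
      is.na(discard_fraction) || discard_fraction < 0 || discard_fraction >= 1)
    stop_domain("discard_fraction must lie in [0, 1)")
  structure(list(discard_fraction = discard_fraction),
            class = "analysis_window")
}

#' Apply the analysis window to a trajectory
#'
#' Per replica, drops the first `floor(discard_fraction * n)` frames, then
#' concatenates the surviving frames in replica order (pooled).
#'
#' @param traj A [trajectory()].
#' @param window An [analysis_window()] (or a bare fraction).
#' @return The windowed, pooled [trajectory()].
#' @export
apply_window <- function(traj, window = analysis_window()) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.numeric(window)) window <- analysis_window(window)
  df <- window$discard_fraction
  keep <- logical(n_frames(traj))
  for (r in unique(traj$frames$replica_id)) {
    rows <- which(traj$frames$replica_id == r)
    nkeep <- length(rows) - floor(df * length(rows))
    if (nkeep < 1L)
      stop_window(sprintf("replica %s has no frames left after windowing", r))
    keep[rows[seq.int(length(rows) - nkeep + 1L, length(rows))]] <- TRUE
  }
  trajectory(traj$topology, traj$xyz[keep, , drop = FALSE],
             traj$frames[keep, , drop = FALSE])
}

#' Identify native contacts in a reference structure
#'
#' All protein heavy-atom / ligand heavy-atom pairs with Euclidean distance
#' strictly below `cutoff` in the reference structure. Each pair stores its
#' reference distance r0.
#'
#' @param reference A [structure3d()].
#' @param protein_sel,ligand_sel Selections (expression strings or
#'   [select_atoms()] results) for the two sides. Hydrogens are always
#'   excluded.
#' @param cutoff Native-contact cutoff in Angstrom (strict `<`).
#' @return Object of class `"contact_set"`: list with `pairs` (data.frame
#'   `protein_atom`, `ligand_atom`, `r0`, sorted by protein then ligand
#'   index), `reference_mode`, `cutoff` and `reference` structure.
#' @param reference_mode Which reference convention this set encodes:
#'   `"dock"` (initial docking pose), `"exp"` (experimental pose) or
#'   `"repr"` (trajectory representative).
#' @export
identify_native_contacts <- function(reference,
                                     protein_sel = "protein and heavy",
                                     ligand_sel = "ligand and heavy",
                                     cutoff = 4.5,
                                     reference_mode = c("repr", "dock", "exp")) {
  stopifnot(inherits(reference, "structure3d"))
  reference_mode <- match.arg(reference_mode)
  top <- reference$topology
  p_idx <- resolve_selection(top, protein_sel)
  l_idx <- resolve_selection(top, ligand_sel)
  hyd <- top$atoms$index[top$atoms$is_hydrogen]
  p_idx <- setdiff(p_idx, hyd)
  l_idx <- setdiff(l_idx, hyd)
  if (length(intersect(p_idx, l_idx)))
    stop_selection("protein and ligand selections overlap")
  if (!length(p_idx) || !length(l_idx))
    stop_no_contacts("empty protein or ligand selection")
  P <- reference$xyz[p_idx + 1L, , drop = FALSE]
  L <- reference$xyz[l_idx + 1L, , drop = FALSE]
  # all-pairs distances (np x nl)
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * (P %*% t(L))
  d <- sqrt(pmax(d2, 0))
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    stop_no_contacts(sprintf("no native contacts below %.3g A", cutoff))
  pairs <- data.frame(protein_atom = p_idx[hit[, 1]],
                      ligand_atom = l_idx[hit[, 2]],
                      r0 = d[hit])
  pairs <- pairs[order(pairs$protein_atom, pairs$ligand_atom), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, reference_mode = reference_mode,
                 cutoff = cutoff, reference = reference),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d native contacts (< %.3g A, reference '%s')\n",
              nrow(x$pairs), x$cutoff, x$reference_mode))
  invisible(x)
}

#' Per-frame distances for a set of atom pairs
#'
#' Evaluates the Euclidean distance of every pair in every frame of the
#' trajectory, vectorized over frames.
#'
#' @param traj A [trajectory()] (typically windowed and pooled).
#' @param pairs data.frame with `protein_atom` and `ligand_atom` 0-based
#'   index columns (e.g. `contact_set$pairs`), or a `contact_set`.
#' @return Object of class `"distance_series"`: list with `pairs`, `values`
#'   (frames x pairs matrix, Angstrom) and `frames` metadata.
#' @export
compute_distance_series <- function(traj, pairs) {
  stopifnot(inherits(traj, "trajectory"))
  if (inherits(pairs, "contact_set")) pairs <- pairs$pairs
  n <- traj$topology$natoms
  pi <- as.integer(pairs$protein_atom)
  li <- as.integer(pairs$ligand_atom)
  if (any(pi < 0L | pi >= n) || any(li < 0L | li >= n))
    stop_domain("pair atom index out of range for this topology")
  dx <- traj$xyz[, 3L * pi + 1L, drop = FALSE] - traj$xyz[, 3L * li + 1L, drop = FALSE]
  dy <- traj$xyz[, 3L * pi + 2L, drop = FALSE] - traj$xyz[, 3L * li + 2L, drop = FALSE]
  dz <- traj$xyz[, 3L * pi + 3L, drop = FALSE] - traj$xyz[, 3L * li + 3L, drop = FALSE]
  values <- sqrt(dx * dx + dy * dy + dz * dz)
  dimnames(values) <- NULL
  structure(list(pairs = pairs, values = values, frames = traj$frames),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d frames x %d pairs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Ensemble-averaged contact matrix
#'
#' Considers every protein heavy-atom / ligand heavy-atom pair, averages its
#' distance over the (windowed, pooled) trajectory, and retains the pairs
#' whose mean distance is `<= retention_cutoff` (inclusive). The retained
#' mean-distance vector is the ensemble average that representative-frame
#' selection scores against.
#'
#' @param traj_windowed A windowed, pooled [trajectory()].
#' @param protein_sel,ligand_sel Heavy-atom selections for the two sides.
#' @param retention_cutoff Retention threshold on the mean distance, in
#'   Angstrom (inclusive `<=`).
#' @return Object of class `"ensemble_contact_matrix"`: list with
#'   `candidate_pairs` (all pairs with their mean distances), `retained`
#'   (subset with mean `<=` cutoff), `mean_vector` and `retention_cutoff`.
#' @export
ensemble_contact_matrix <- function(traj_windowed,
                                    protein_sel = "protein and heavy",
                                    ligand_sel = "ligand and heavy",
                                    retention_cutoff = 6.75) {
  stopifnot(inherits(traj_windowed, "trajectory"))
  top <- traj_windowed$topology
  hyd <- top$atoms$index[top$atoms$is_hydrogen]
  p_idx <- setdiff(resolve_selection(top, protein_sel), hyd)
  l_idx <- setdiff(resolve_selection(top, ligand_sel), hyd)
  if (!length(p_idx) || !length(l_idx))
    stop_no_contacts("empty protein or ligand selection")
  cand <- expand.grid(protein_atom = p_idx, ligand_atom = l_idx,
                      KEEP.OUT.ATTRS = FALSE)
  cand <- cand[order(cand$protein_atom, cand$ligand_atom), , drop = FALSE]
  rownames(cand) <- NULL
  series <- compute_distance_series(traj_windowed, cand)
  cand$mean_distance <- colMeans(series$values)
  keep <- cand$mean_distance <= retention_cutoff
  if (!any(keep))
    stop_no_contacts(sprintf("no pairs with mean distance <= %.3g A",
                             retention_cutoff))
  retained <- cand[keep, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(candidate_pairs = cand, retained = retained,
                 mean_vector = retained$mean_distance,
                 retention_cutoff = retention_cutoff),
            class = "ensemble_contact_matrix")
}

#' @export
print.ensemble_contact_matrix <- function(x, ...) {
  cat(sprintf("<ensemble_contact_matrix> %d/%d pairs retained (mean <= %.3g A)\n",
              nrow(x$retained), nrow(x$candidate_pairs), x$retention_cutoff))
  invisible(x)
}

#' Select the representative frame of a trajectory
#'
#' Assembles, for each frame, the distances of the retained pairs into a
#' vector and returns the frame minimizing the Euclidean distance to the
#' ensemble-averaged vector. Ties are broken by the lowest pooled frame
#' index.
#'
#' @param traj_windowed The same windowed, pooled [trajectory()] the matrix
#'   was built from.
#' @param matrix An [ensemble_contact_matrix()].
#' @return Object of class `"representative_result"`: list with
#'   `frame_global_index` (1-based position in the pooled trajectory),
#'   `replica_id`, `frame_index_in_replica`, `structure` and
#'   `euclidean_distance`.
#' @export
select_representative <- function(traj_windowed, matrix) {
  stopifnot(inherits(traj_windowed, "trajectory"),
            inherits(matrix, "ensemble_contact_matrix"))
  series <- compute_distance_series(traj_windowed, matrix$retained)
  dev <- sweep(series$values, 2L, matrix$mean_vector)
  norms <- sqrt(rowSums(dev * dev))
  best <- which.min(norms)    # which.min returns the first (lowest) index on ties
  structure(list(frame_global_index = as.integer(best),
                 replica_id = traj_windowed$frames$replica_id[best],
                 frame_index_in_replica =
                   traj_windowed$frames$frame_index_in_replica[best],
                 structure = frame_structure(traj_windowed, best),
                 euclidean_distance = norms[best]),
            class = "representative_result")
}

#' @export
print.representative_result <- function(x, ...) {
  cat(sprintf("<representative_result> pooled frame %d (replica %d, frame %d), ||d - dbar|| = %.4g A\n",
              x$frame_global_index, x$replica_id, x$frame_index_in_replica,
              x$euclidean_distance))
  invisible(x)
}
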