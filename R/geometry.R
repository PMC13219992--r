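# Rigid-body superposition (Kabsch), ligand heavy-atom RMSD and C-alpha
# RMSF.
#
# RMSD convention: the mobile structure is least-squares fitted onto the
# reference using the fit selection (default: protein C-alpha), the
# transform is applied to the whole complex, and the RMSD is then taken
# over the ligand heavy atoms in absolute coordinates -- the ligand is
# never re-fitted, so genuine ligand displacement survives the
# superposition.

#' Rigid transform
#' @param rotation 3x3 proper rotation matrix (applied to row vectors on the
#'   right).
#' @param translation Length-3 translation, Angstrom.
#' @return Object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop_domain("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop_domain("rotation must be proper orthogonal (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

# Kabsch fit of row-vector clouds: finds R (proper) and t minimizing
# || P %*% R + t - Q ||.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - as.numeric(cp %*% R)
  rigid_transform(R, t)
}

#' Optimal superposition of two structures
#'
#' Least-squares (Kabsch) rotation + translation minimizing the RMSD over
#' the fit selection; reflections are excluded.
#'
#' @param mobile,target [structure3d()] objects sharing atom correspondence
#'   over the fit selection.
#' @param fit_selection Selection resolving to the same >= 3, non-collinear
#'   atoms in both structures.
#' @return A [rigid_transform()] mapping `mobile` onto `target`.
#' @export
superpose <- function(mobile, target, fit_selection = "protein and name CA") {
  stopifnot(inherits(mobile, "structure3d"), inherits(target, "structure3d"))
  mi <- resolve_selection(mobile$topology, fit_selection)
  ti <- resolve_selection(target$topology, fit_selection)
  if (length(mi) != length(ti))
    stop_superposition("fit selection resolves to different atom counts")
  if (length(mi) < 3L)
    stop_superposition("fit selection needs at least 3 atoms")
  P <- mobile$xyz[mi + 1L, , drop = FALSE]
  Q <- target$xyz[ti + 1L, , drop = FALSE]
  sv <- svd(sweep(P, 2L, colMeans(P)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop_superposition("fit selection is (near-)collinear; superposition is degenerate")
  kabsch(P, Q)
}

#' Apply a rigid transform
#' @param x A [structure3d()] or an n x 3 coordinate matrix.
#' @param tf A [rigid_transform()].
#' @return Transformed object of the same type.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "structure3d"))
    return(structure3d(x$topology, apply_transform(x$xyz, tf)))
  sweep(as.matrix(x) %*% tf$rotation, 2L, tf$translation, "+")
}

#' Ligand heavy-atom RMSD after protein superposition
#'
#' Fits `structure` onto `reference` over `fit_selection`, applies the
#' transform to the whole complex, then evaluates
#' `sqrt(mean(|x_i - x_i_ref|^2))` over the ligand heavy atoms without
#' re-fitting the ligand.
#'
#' @param structure,reference [structure3d()] objects; ligand atoms must
#'   correspond 1:1 by name/residue identity.
#' @param ligand_sel Ligand selection (hydrogens are excluded).
#' @param fit_selection Protein fit selection (default C-alpha).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(structure, reference,
                        ligand_sel = "ligand and heavy",
                        fit_selection = "protein and name CA") {
  stopifnot(inherits(structure, "structure3d"), inherits(reference, "structure3d"))
  si <- setdiff(resolve_selection(structure$topology, ligand_sel),
                structure$topology$atoms$index[structure$topology$atoms$is_hydrogen])
  ri <- setdiff(resolve_selection(reference$topology, ligand_sel),
                reference$topology$atoms$index[reference$topology$atoms$is_hydrogen])
  if (length(si) != length(ri) || length(si) == 0L)
    stop_correspondence("ligand selections do not correspond 1:1")
  sid <- paste(structure$topology$atoms$name[si + 1L],
               residue_key(structure$topology$atoms[si + 1L, ]))
  rid <- paste(reference$topology$atoms$name[ri + 1L],
               residue_key(reference$topology$atoms[ri + 1L, ]))
  if (!identical(sid, rid))
    stop_correspondence("ligand atom identities differ between structure and reference")
  tf <- superpose(structure, reference, fit_selection)
  xs <- apply_transform(structure$xyz, tf)[si + 1L, , drop = FALSE]
  xr <- reference$xyz[ri + 1L, , drop = FALSE]
  sqrt(mean(rowSums((xs - xr)^2)))
}

#' Per-residue C-alpha RMSF
#'
#' Least-squares aligns every frame to the representative structure over
#' `fit_selection`, then computes, per C-alpha atom, the root-mean-square
#' fluctuation about its time-averaged position, reported per residue.
#' Protein residues lacking a C-alpha atom are omitted with a warning.
#'
#' @param traj_windowed A windowed, pooled [trajectory()] (>= 2 frames).
#' @param representative The [structure3d()] all frames are aligned to.
#' @param fit_selection Alignment selection (default protein C-alpha).
#' @return data.frame: `chain`, `resseq`, `inscode`, `resname`, `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(traj_windowed, representative,
                 fit_selection = "protein and name CA") {
  stopifnot(inherits(traj_windowed, "trajectory"),
            inherits(representative, "structure3d"))
  if (n_frames(traj_windowed) < 2L)
    stop_domain("RMSF needs at least 2 frames")
  top <- traj_windowed$topology
  ca_idx <- resolve_selection(top, "protein and name CA")
  prot <- top$atoms[!top$atoms$is_ligand, , drop = FALSE]
  n_res <- nrow(unique(prot[, c("chain", "resseq", "inscode")]))
  if (length(ca_idx) < n_res)
    warning(sprintf("%d protein residue(s) lack a CA atom and are omitted from RMSF",
                    n_res - length(ca_idx)), call. = FALSE)
  Fn <- n_frames(traj_windowed)
  acc <- array(NA_real_, dim = c(Fn, length(ca_idx), 3L))
  for (f in seq_len(Fn)) {
    fs <- frame_structure(traj_windowed, f)
    tf <- superpose(fs, representative, fit_selection)
    acc[f, , ] <- apply_transform(fs$xyz, tf)[ca_idx + 1L, , drop = FALSE]
  }
  mean_pos <- apply(acc, c(2L, 3L), mean)
  sq <- sweep(acc, c(2L, 3L), mean_pos)^2
  rmsf_vals <- sqrt(colMeans(sq[, , 1L, drop = FALSE] + sq[, , 2L, drop = FALSE] +
                               sq[, , 3L, drop = FALSE])[, 1L])
  at <- top$atoms[ca_idx + 1L, , drop = FALSE]
  out <- data.frame(chain = at$chain, resseq = at$resseq, inscode = at$inscode,
                    resname = at$resname, rmsf = as.numeric(rmsf_vals),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
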