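# The R-value: a sigmoid-smoothed fraction-of-native-contacts score.
#
# For native contact (i, j) with reference distance r0_ij and instantaneous
# distance rX_ij, the per-contact term is
#
#     1 / (1 + exp(beta * (rX_ij - Lambda * r0_ij)))
#
# and the per-frame R-value is the mean over the N native contacts. The
# trajectory R-value is the unweighted mean of the per-frame values over the
# pooled analysis window (identical, because N is fixed, to the mean over
# the full frames x pairs term matrix). beta is the smoothing steepness in
# 1/Angstrom, Lambda the tolerated relative contact fluctuation.

#' Contact-model parameters
#'
#' @param beta Sigmoid smoothing parameter in 1/Angstrom (default 5.0).
#' @param lam Contact fluctuation parameter Lambda, dimensionless
#'   (default 1.8): a contact counts as about half-formed once the distance
#'   reaches `lam * r0`.
#' @param native_cutoff Native-contact cutoff in Angstrom (default 4.5,
#'   strict `<`).
#' @return Object of class `"contact_params"`.
#' @export
contact_params <- function(beta = 5.0, lam = 1.8, native_cutoff = 4.5) {
  if (!is.numeric(beta) || beta <= 0) stop_domain("beta must be > 0")
  if (!is.numeric(lam) || lam < 1) stop_domain("lam must be >= 1")
  if (!is.numeric(native_cutoff) || native_cutoff <= 0)
    stop_domain("native_cutoff must be > 0")
  structure(list(beta = beta, lam = lam, native_cutoff = native_cutoff),
            class = "contact_params")
}

params_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

#' Per-contact sigmoid term
#'
#' `1 / (1 + exp(beta * (rX - lam * r0)))`, evaluated through the logistic
#' CDF so that extreme separations underflow cleanly to 0 (and deep contacts
#' saturate to 1) without overflow.
#'
#' @param rX Instantaneous distance(s), Angstrom (> 0).
#' @param r0 Reference distance(s), Angstrom (> 0).
#' @param params [contact_params()].
#' @return Value(s) in (0, 1) (0/1 only by double-precision underflow).
#' @export
contact_term <- function(rX, r0, params = contact_params()) {
  if (any(!is.finite(rX)) || any(rX <= 0))
    stop_domain("rX must be finite and > 0")
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop_domain("r0 must be finite and > 0")
  stats::plogis(-params$beta * (rX - params$lam * r0))
}

# term matrix for a frames x pairs distance matrix (columns follow pairs)
contact_term_matrix <- function(values, r0, params) {
  arg <- -params$beta * sweep(values, 2L, params$lam * r0)
  stats::plogis(arg)
}

#' Single-frame R-value
#'
#' Arithmetic mean of the per-contact sigmoid terms over the N native
#' contacts of one frame.
#'
#' @param frame_distances Numeric vector of pair distances, aligned with
#'   `contacts$pairs`.
#' @param contacts A [identify_native_contacts()] result.
#' @param params [contact_params()].
#' @return R-value in (0, 1).
#' @export
r_value_frame <- function(frame_distances, contacts, params = contact_params()) {
  pairs <- if (inherits(contacts, "contact_set")) contacts$pairs else contacts
  if (nrow(pairs) == 0L)
    stop_no_contacts("R-value undefined: zero native contacts")
  if (length(frame_distances) != nrow(pairs))
    stop_domain("distance vector not aligned with contact pairs")
  mean(contact_term(frame_distances, pairs$r0, params))
}

#' Trajectory R-value
#'
#' Computes the per-frame R-values over a distance series and averages them
#' (unweighted) into the global R-value.
#'
#' @param series A [compute_distance_series()] result whose columns follow
#'   `contacts$pairs`.
#' @param contacts A `contact_set`.
#' @param params [contact_params()].
#' @return Object of class `"rvalue_result"`: list with `r_global`,
#'   `per_frame_r`, `n_contacts`, `n_frames`, `reference_mode`, `params`.
#' @export
r_value_trajectory <- function(series, contacts, params = contact_params()) {
  stopifnot(inherits(series, "distance_series"), inherits(contacts, "contact_set"))
  if (nrow(contacts$pairs) == 0L)
    stop_no_contacts("R-value undefined: zero native contacts")
  if (ncol(series$values) != nrow(contacts$pairs))
    stop_domain("distance series does not cover the contact pairs")
  terms <- contact_term_matrix(series$values, contacts$pairs$r0, params)
  per_frame <- rowMeans(terms)
  structure(list(r_global = mean(per_frame),
                 per_frame_r = per_frame,
                 n_contacts = nrow(contacts$pairs),
                 n_frames = nrow(series$values),
                 reference_mode = contacts$reference_mode,
                 params = params),
            class = "rvalue_result")
}

#' @export
print.rvalue_result <- function(x, ...) {
  cat(sprintf("<rvalue_result> R = %.4f over %d frames, %d native contacts (reference '%s')\n",
              x$r_global, x$n_frames, x$n_contacts, x$reference_mode))
  invisible(x)
}

#' Per-residue stability decomposition
#'
#' Groups native contacts by the protein residue owning the protein-side
#' atom. Per residue, `r_residue` is the mean sigmoid term over that
#' residue's (frames x pairs) terms, `contribution = r_residue *
#' contact_count` (the unnormalized per-residue R-value) and
#' `pct_contribution` its percentage share of the total. By construction the
#' contributions sum to `n_contacts * r_global`.
#'
#' @inheritParams r_value_trajectory
#' @param top The [topology()] (for residue identities).
#' @return data.frame with one row per contacting residue: `chain`,
#'   `resseq`, `inscode`, `resname`, `contact_count`, `r_residue`,
#'   `contribution`, `pct_contribution`, ordered by chain then resseq.
#' @export
residue_stability_map <- function(series, contacts, params = contact_params(),
                                  top = contacts$reference$topology) {
  stopifnot(inherits(series, "distance_series"), inherits(contacts, "contact_set"))
  pairs <- contacts$pairs
  if (nrow(pairs) == 0L) stop_no_contacts("zero native contacts")
  terms <- contact_term_matrix(series$values, pairs$r0, params)
  pair_mean <- colMeans(terms)
  atoms <- top$atoms[pairs$protein_atom + 1L, , drop = FALSE]
  key <- residue_key(atoms)
  split_idx <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(split_idx, function(ix) {
    first <- atoms[ix[1], ]
    data.frame(chain = first$chain, resseq = first$resseq,
               inscode = first$inscode, resname = first$resname,
               contact_count = length(ix),
               r_residue = mean(pair_mean[ix]),
               contribution = sum(pair_mean[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_contribution <- 100 * out$contribution / sum(out$contribution)
  out <- out[order(out$chain, out$resseq, out$inscode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-ligand-atom stability map
#'
#' Groups native contacts by ligand heavy atom and categorizes each atom by
#' the mean sigmoid term over its (frames x pairs) terms: `stable` above
#' `thresholds$stable`, `less_stable` above `thresholds$less_stable`,
#' `unstable` below that, and `no_contact` (with `r_atom = NA`) for ligand
#' heavy atoms owning no native contact. The numeric thresholds are package
#' defaults for the conventional three-color stability rendering and are
#' configurable.
#'
#' @inheritParams residue_stability_map
#' @param ligand_sel Ligand selection used to enumerate heavy atoms (so that
#'   contact-free atoms are reported too).
#' @param thresholds Named list with `stable` and `less_stable` cutoffs on
#'   `r_atom`.
#' @return data.frame with one row per ligand heavy atom: `atom_index`,
#'   `name`, `element`, `contact_count`, `r_atom`, `category`.
#' @export
atom_stability_map <- function(series, contacts, params = contact_params(),
                               top = contacts$reference$topology,
                               ligand_sel = "ligand and heavy",
                               thresholds = list(stable = 0.85, less_stable = 0.70)) {
  stopifnot(inherits(series, "distance_series"), inherits(contacts, "contact_set"))
  pairs <- contacts$pairs
  if (nrow(pairs) == 0L) stop_no_contacts("zero native contacts")
  terms <- contact_term_matrix(series$values, pairs$r0, params)
  pair_mean <- colMeans(terms)
  lig_idx <- setdiff(resolve_selection(top, ligand_sel),
                     top$atoms$index[top$atoms$is_hydrogen])
  rows <- lapply(lig_idx, function(ai) {
    ix <- which(pairs$ligand_atom == ai)
    at <- top$atoms[ai + 1L, ]
    r_atom <- if (length(ix)) mean(pair_mean[ix]) else NA_real_
    category <- if (!length(ix)) "no_contact"
      else if (r_atom > thresholds$stable) "stable"
      else if (r_atom > thresholds$less_stable) "less_stable"
      else "unstable"
    data.frame(atom_index = ai, name = at$name, element = at$element,
               contact_count = length(ix), r_atom = r_atom,
               category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' R-value difference between two results
#'
#' @param analog,reference_compound [r_value_trajectory()] results computed
#'   with identical contact-model parameters.
#' @return `analog$r_global - reference_compound$r_global`.
#' @export
delta_r <- function(analog, reference_compound) {
  stopifnot(inherits(analog, "rvalue_result"),
            inherits(reference_compound, "rvalue_result"))
  if (!params_equal(analog$params, reference_compound$params))
    stop_comparability("R-values computed with different contact-model parameters are not comparable")
  analog$r_global - reference_compound$r_global
}
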