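# Four-way pose classification (SS/SD/US/UD), R-value ranking of docking
# ensembles, threshold-sensitivity grids and ensemble-level metrics.
#
# Boundary semantics are strict on both axes: a pose is Stable only if
# r_value > r_min and Similar only if rmsd < rmsd_max; values equal to a
# threshold fall in the unfavorable class.

#' Pose-classification thresholds
#' @param r_min Stability threshold on the R-value (strict `>`, default
#'   0.70).
#' @param rmsd_max Similarity threshold on the ligand RMSD in Angstrom
#'   (strict `<`, default 3.0).
#' @return Object of class `"pose_thresholds"`.
#' @export
pose_thresholds <- function(r_min = 0.70, rmsd_max = 3.0) {
  if (!is.numeric(r_min) || r_min <= 0 || r_min >= 1)
    stop_domain("r_min must lie in (0, 1)")
  if (!is.numeric(rmsd_max) || rmsd_max <= 0)
    stop_domain("rmsd_max must be > 0")
  structure(list(r_min = r_min, rmsd_max = rmsd_max),
            class = "pose_thresholds")
}

#' Classify poses by stability and similarity
#'
#' SS = stable and similar, SD = stable but dissimilar, US = unstable but
#' similar, UD = unstable and dissimilar.
#'
#' @param r_value,rmsd Numeric vectors (recycled to common length).
#' @param thresholds A [pose_thresholds()].
#' @return Character vector of labels in `{"SS","SD","US","UD"}`.
#' @export
classify_pose <- function(r_value, rmsd, thresholds = pose_thresholds()) {
  n <- max(length(r_value), length(rmsd))
  r_value <- rep_len(r_value, n); rmsd <- rep_len(rmsd, n)
  if (any(!is.finite(r_value)) || any(!is.finite(rmsd)))
    stop_classification("r_value and rmsd must be finite")
  stable <- r_value > thresholds$r_min
  similar <- rmsd < thresholds$rmsd_max
  ifelse(stable, ifelse(similar, "SS", "SD"), ifelse(similar, "US", "UD"))
}

#' Rank docking poses by R-value
#'
#' Within each ligand, rank 1 goes to the highest R-value; ties are broken
#' by lower RMSD, then by pose_id lexicographically.
#'
#' @param records data.frame with columns `ligand`, `pose_id`, `r_value`,
#'   `rmsd` (additional columns pass through).
#' @return `records` with a `rank` column, original row order preserved.
#' @export
rank_poses <- function(records) {
  need <- c("ligand", "pose_id", "r_value", "rmsd")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_schema(paste0("rank_poses input missing column(s): ",
                       paste(miss, collapse = ", ")))
  records$rank <- NA_integer_
  for (lig in unique(records$ligand)) {
    rows <- which(records$ligand == lig)
    ord <- order(-records$r_value[rows], records$rmsd[rows],
                 as.character(records$pose_id[rows]))
    records$rank[rows[ord]] <- seq_along(rows)
  }
  records
}

#' Ensemble-level docking / refinement metrics
#'
#' Per ligand: `top1_hit` is TRUE when the docking-score top pose
#' (`dock_rank == 1`) already has initial docking RMSD below `rmsd_max`;
#' `dock_success` when any ensemble pose does; `rescued` when the top-1 pose
#' failed but the R-value-ranked top pose is SS after MD. Rates are
#' aggregated per system and globally (percent of ligands).
#'
#' @param records data.frame with columns `system`, `ligand`, `pose_id`,
#'   `r_value`, `rmsd` (post-MD), `dock_rank`, `dock_rmsd` (initial docking
#'   RMSD).
#' @param thresholds A [pose_thresholds()].
#' @return List with `per_ligand`, `per_system` and `global` data.frames.
#'   `per_system`/`global` report label counts, label percentages (summing
#'   to 100), `top1_hit_rate`, `dock_success_rate` and rescue counts
#'   (`rescued` / `rescue_opportunities`).
#' @export
ensemble_metrics <- function(records, thresholds = pose_thresholds()) {
  need <- c("system", "ligand", "pose_id", "r_value", "rmsd",
            "dock_rank", "dock_rmsd")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_schema(paste0("ensemble_metrics input missing column(s): ",
                       paste(miss, collapse = ", ")))
  records$label <- classify_pose(records$r_value, records$rmsd, thresholds)
  records <- rank_poses(records)
  lig_rows <- split(seq_len(nrow(records)),
                    paste(records$system, records$ligand, sep = "\r"))
  per_ligand <- do.call(rbind, lapply(lig_rows, function(rows) {
    rec <- records[rows, , drop = FALSE]
    topdock <- which(rec$dock_rank == 1L)
    if (length(topdock) != 1L)
      stop_schema(sprintf("ligand '%s' needs exactly one pose with dock_rank == 1",
                          rec$ligand[1]))
    rtop <- which(rec$rank == 1L)
    top1 <- rec$dock_rmsd[topdock] < thresholds$rmsd_max
    data.frame(system = rec$system[1], ligand = rec$ligand[1],
               n_poses = nrow(rec),
               top1_hit = top1,
               dock_success = any(rec$dock_rmsd < thresholds$rmsd_max),
               rescued = if (top1) NA else rec$label[rtop] == "SS",
               stringsAsFactors = FALSE)
  }))
  rownames(per_ligand) <- NULL
  summarize <- function(recs, ligs, system) {
    counts <- vapply(c("SS", "SD", "US", "UD"),
                     function(l) sum(recs$label == l), integer(1))
    pct <- 100 * counts / nrow(recs)
    data.frame(system = system, n_ligands = nrow(ligs), n_poses = nrow(recs),
               n_ss = counts[["SS"]], n_sd = counts[["SD"]],
               n_us = counts[["US"]], n_ud = counts[["UD"]],
               pct_ss = pct[["SS"]], pct_sd = pct[["SD"]],
               pct_us = pct[["US"]], pct_ud = pct[["UD"]],
               top1_hit_rate = 100 * mean(ligs$top1_hit),
               dock_success_rate = 100 * mean(ligs$dock_success),
               rescued = sum(ligs$rescued, na.rm = TRUE),
               rescue_opportunities = sum(!ligs$top1_hit),
               stringsAsFactors = FALSE)
  }
  per_system <- do.call(rbind, lapply(unique(records$system), function(s) {
    summarize(records[records$system == s, , drop = FALSE],
              per_ligand[per_ligand$system == s, , drop = FALSE], s)
  }))
  rownames(per_system) <- NULL
  global <- summarize(records, per_ligand, "ALL")
  list(per_ligand = per_ligand, per_system = per_system, global = global,
       labeled = records)
}

#' Threshold-sensitivity grid
#'
#' For every combination of candidate thresholds, reports the global %SS
#' over all poses, the per-system %SS and `delta_pct_ss` = per-system %SS
#' minus global %SS (a measure of inter-system dispersion; its absolute
#' value is reported alongside).
#'
#' @param records data.frame with `system`, `r_value`, `rmsd`.
#' @param r_grid,rmsd_grid Numeric vectors of candidate thresholds.
#' @return data.frame with columns `r_min`, `rmsd_max`, `system` (`"ALL"`
#'   rows carry the global value), `pct_ss`, `delta_pct_ss`,
#'   `abs_delta_pct_ss`.
#' @export
threshold_grid <- function(records, r_grid = c(0.60, 0.70, 0.80),
                           rmsd_grid = c(2.0, 2.5, 3.0)) {
  need <- c("system", "r_value", "rmsd")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_schema(paste0("threshold_grid input missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (!length(r_grid) || !length(rmsd_grid))
    stop_domain("threshold grids must be non-empty")
  out <- list()
  for (rmin in r_grid) for (rmax in rmsd_grid) {
    th <- pose_thresholds(rmin, rmax)
    lab <- classify_pose(records$r_value, records$rmsd, th)
    global_ss <- 100 * mean(lab == "SS")
    rows <- data.frame(r_min = rmin, rmsd_max = rmax, system = "ALL",
                       pct_ss = global_ss, delta_pct_ss = 0,
                       stringsAsFactors = FALSE)
    for (s in unique(records$system)) {
      sel <- records$system == s
      ss <- 100 * mean(lab[sel] == "SS")
      rows <- rbind(rows, data.frame(r_min = rmin, rmsd_max = rmax,
                                     system = s, pct_ss = ss,
                                     delta_pct_ss = ss - global_ss,
                                     stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- rows
  }
  out <- do.call(rbind, out)
  out$abs_delta_pct_ss <- abs(out$delta_pct_ss)
  rownames(out) <- NULL
  out
}
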