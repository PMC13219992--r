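# Kd -> pKd conversion, native-like filtering and Pearson correlation of
# stability metrics against affinity.
#
# Kd values are normalized to molar internally; pKd = -log10(Kd [M]).
# Complexes whose R-value falls below the native-like threshold (default
# 0.70, strict <) are excluded from affinity correlation: a low R-value
# means the simulated complex no longer represents the native binding mode,
# so its affinity is not informative about the scored pose.

KD_UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Convert a dissociation constant to molar
#' @param value Numeric Kd value(s).
#' @param unit Unit string(s): one of `"M"`, `"mM"`, `"uM"` (also accepted:
#'   `"µM"`), `"nM"`, `"pM"`.
#' @return Kd in molar.
#' @export
kd_to_molar <- function(value, unit = "M") {
  unit <- gsub("µ", "u", unit)
  if (any(!unit %in% names(KD_UNIT_FACTORS)))
    stop_domain(paste0("unknown Kd unit(s): ",
                       paste(setdiff(unit, names(KD_UNIT_FACTORS)), collapse = ", ")))
  value * unname(KD_UNIT_FACTORS[unit])
}

#' pKd from Kd
#' @param kd Dissociation constant(s) in molar (> 0).
#' @return `-log10(kd)`.
#' @export
pkd_from_kd <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop_domain("kd must be finite and > 0")
  -log10(kd)
}

#' Partition complexes into native-like and non-native-like
#'
#' @param r_values Named numeric vector, ligand id -> R-value.
#' @param r_min Native-like threshold (exclusion is strict `<`; an R-value
#'   exactly at the threshold is retained).
#' @return List with `used` (named vector) and `excluded` (data.frame
#'   `ligand`, `r_value`, `reason`).
#' @export
filter_native_like <- function(r_values, r_min = 0.70) {
  if (is.null(names(r_values)) || any(!nzchar(names(r_values))))
    stop_schema("r_values must be a named vector (ligand ids)")
  drop <- r_values < r_min
  list(used = r_values[!drop],
       excluded = data.frame(ligand = names(r_values)[drop],
                             r_value = unname(r_values[drop]),
                             reason = if (any(drop)) "non-native-like" else character(0),
                             stringsAsFactors = FALSE))
}

#' Pearson correlation with missing-value accounting
#'
#' Sample Pearson correlation of paired series; pairs with missing values
#' are dropped and listed. Requires at least 3 complete pairs and non-zero
#' variance in both series.
#'
#' @param x,y Numeric vectors of equal length (names, if present, identify
#'   dropped pairs).
#' @return Object of class `"correlation_result"`: list with `pearson_r`,
#'   `n_used`, `excluded` (data.frame `id`, `reason`).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y))
    stop_domain("x and y must have equal length")
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  ok <- is.finite(x) & is.finite(y)
  excluded <- data.frame(id = ids[!ok],
                         reason = if (any(!ok)) "missing value" else character(0),
                         stringsAsFactors = FALSE)
  if (sum(ok) < 3L)
    stop_correlation(sprintf("need >= 3 complete pairs, have %d", sum(ok)))
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop_correlation("correlation undefined: zero variance in a series")
  structure(list(pearson_r = stats::cor(xs, ys), n_used = sum(ok),
                 excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Pearson r = %.4f (n = %d, %d excluded)\n",
              x$pearson_r, x$n_used, nrow(x$excluded)))
  invisible(x)
}

#' Per-residue correlation of stability metrics with pKd
#'
#' For every protein residue appearing in the per-ligand residue stability
#' maps, correlates both the per-residue R-value and the per-residue
#' contribution against pKd across ligands. Residues present in fewer than
#' 3 ligands, or with zero variance, are flagged rather than scored.
#'
#' @param maps Named list, ligand id -> [residue_stability_map()]
#'   data.frame.
#' @param pkd Named numeric vector, ligand id -> pKd. Only ligands present
#'   in both inputs enter the analysis.
#' @return data.frame with one row per residue: `chain`, `resseq`,
#'   `inscode`, `resname`, `n_ligands`, `r_rvalue_pkd`,
#'   `r_contribution_pkd`, `status` (`"ok"`, `"insufficient_n"` or
#'   `"zero_variance"`).
#' @export
per_residue_correlation <- function(maps, pkd) {
  if (is.null(names(maps)) || is.null(names(pkd)))
    stop_schema("maps and pkd must be named by ligand id")
  ligs <- intersect(names(maps), names(pkd))
  if (length(ligs) < 3L)
    stop_correlation("need >= 3 ligands with both a stability map and a pKd")
  tall <- do.call(rbind, lapply(ligs, function(lg) {
    m <- maps[[lg]]
    m$ligand <- lg
    m
  }))
  tall$reskey <- paste(tall$chain, tall$resseq, tall$inscode, tall$resname,
                       sep = "|")
  out <- lapply(split(tall, tall$reskey), function(d) {
    base <- d[1, c("chain", "resseq", "inscode", "resname")]
    base$n_ligands <- nrow(d)
    y <- pkd[d$ligand]
    corr_or_na <- function(v) {
      res <- tryCatch(correlate(stats::setNames(v, d$ligand), y),
                      ligstab_correlation_error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$pearson_r
    }
    if (nrow(d) < 3L) {
      base$r_rvalue_pkd <- NA_real_
      base$r_contribution_pkd <- NA_real_
      base$status <- "insufficient_n"
    } else {
      base$r_rvalue_pkd <- corr_or_na(d$r_residue)
      base$r_contribution_pkd <- corr_or_na(d$contribution)
      base$status <- if (is.na(base$r_rvalue_pkd) && is.na(base$r_contribution_pkd))
        "zero_variance" else "ok"
    }
    base
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chain, out$resseq, out$inscode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an affinity table
#'
#' Expected TSV columns: `ligand`, `value`, `unit`, `metric` (one of `Kd`,
#' `IC50`, `Ki`), optional `source`. Only `Kd` rows enter pKd correlation by
#' default; IC50/Ki rows require `include_surrogates = TRUE` because those
#' assays are not directly comparable to equilibrium Kd.
#'
#' @param path TSV path.
#' @param include_surrogates Keep IC50/Ki rows (flagged in the output).
#' @return data.frame with `ligand`, `metric`, `kd_molar`, `pkd`,
#'   `surrogate`, `source`.
#' @export
read_affinity_table <- function(path, include_surrogates = FALSE) {
  d <- read_table(path, "tsv")
  need <- c("ligand", "value", "unit", "metric")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_schema(paste0("affinity table missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (!all(d$metric %in% c("Kd", "IC50", "Ki")))
    stop_schema("metric must be one of Kd, IC50, Ki")
  d$surrogate <- d$metric != "Kd"
  if (!include_surrogates) d <- d[!d$surrogate, , drop = FALSE]
  d$kd_molar <- kd_to_molar(d$value, d$unit)
  d$pkd <- pkd_from_kd(d$kd_molar)
  d$source <- if ("source" %in% names(d)) d$source else NA_character_
  d[, c("ligand", "metric", "kd_molar", "pkd", "surrogate", "source")]
}
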