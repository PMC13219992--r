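# Reading structures and trajectories, writing PDB and tabular reports.
#
# PDB and DCD parsing is delegated to bio3d; this layer normalizes the atom
# table into the package's topology (solvent/ion removal, altloc
# deduplication, element inference, protein/ligand partition) and enforces
# the unit convention: everything downstream is in Angstrom (PDB and DCD are
# natively Angstrom; no other conversion is needed for the supported
# formats).

# Residue names dropped at load time (solvent / common crystallization ions
# and additives). Overridable per call.
DEFAULT_SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL",
                              "NA", "CL", "K", "MG", "ZN", "SO4", "GOL",
                              "PO4", "EDO", "ACT")

TWO_LETTER_ELEMENTS <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CU",
                         "SE", "NI", "CO", "CD", "HG", "AS", "SI", "LI",
                         "AL", "PT", "AU", "PD", "AG", "MO", "RU")

infer_element <- function(name, type) {
  nm <- gsub("[^A-Za-z]", "", name)
  if (!nzchar(nm)) return("X")
  first_char <- function(x) toupper(substr(x, 1, 1))
  # hydrogens named like 1HB / HB1 / H
  if (first_char(nm) == "H" || grepl("^[0-9]*H", name)) return("H")
  if (type == "HETATM" && nchar(nm) >= 2 &&
      toupper(substr(nm, 1, 2)) %in% TWO_LETTER_ELEMENTS)
    return(toupper(substr(nm, 1, 2)))
  first_char(nm)
}

normalize_atom_table <- function(atom, path, solvent_resnames) {
  # altloc deduplication: keep highest occupancy; ties prefer altloc 'A'
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$chain[is.na(atom$chain)] <- ""
  atom$o[is.na(atom$o)] <- 1.0
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    occ <- atom$o[rows]
    best <- rows[occ == max(occ)]
    if (length(best) > 1L) {
      pref <- best[atom$alt[best] == "A"]
      best <- if (length(pref)) pref[1] else best[1]
    }
    keep[setdiff(rows, best)] <- FALSE
  }
  atom <- atom[keep, , drop = FALSE]
  drop_solv <- toupper(atom$resid) %in% toupper(solvent_resnames)
  atom <- atom[!drop_solv, , drop = FALSE]
  if (nrow(atom) == 0L)
    stop_io(sprintf("no atoms left in '%s' after solvent/ion filtering", path))
  elem <- atom$elesy
  elem[is.na(elem)] <- ""
  elem <- trimws(elem)
  need <- !nzchar(elem)
  if (any(need))
    elem[need] <- mapply(infer_element, atom$elety[need], atom$type[need],
                         USE.NAMES = FALSE)
  atoms <- data.frame(
    name = trimws(atom$elety),
    element = toupper(elem),
    resname = trimws(atom$resid),
    resseq = as.integer(atom$resno),
    inscode = trimws(atom$insert),
    chain = trimws(atom$chain),
    is_ligand = atom$type == "HETATM",
    is_hydrogen = toupper(elem) %in% c("H", "D"),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, kept = which(keep)[!drop_solv])
}

#' Read a protein-ligand structure from a PDB file
#'
#' Parses ATOM/HETATM records (PDB v3.3). If the file contains MODEL blocks,
#' only the first model is used. Waters, ions and common crystallization
#' additives are dropped; remaining HETATM records are flagged as ligand
#' atoms. Alternate locations are reduced to a single conformer (highest
#' occupancy, ties resolved to altloc A). Elements come from the element
#' column when present, otherwise from atom-name heuristics.
#'
#' @param path Path to a PDB file.
#' @param solvent_resnames Residue names removed at load time.
#' @return A [structure3d()].
#' @export
read_structure <- function(path, solvent_resnames = DEFAULT_SOLVENT_RESNAMES) {
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_io(sprintf("failed to parse PDB '%s': %s",
                                        path, conditionMessage(e))))
  norm <- normalize_atom_table(pdb$atom, path, solvent_resnames)
  top <- topology(norm$atoms)
  xyz <- pdb$xyz
  if (is.matrix(xyz)) xyz <- xyz[1L, ]           # first MODEL only
  coords <- xyz_unflatten(as.numeric(xyz))[norm$kept, , drop = FALSE]
  bad <- which(!stats::complete.cases(coords))
  if (length(bad))
    stop_io(sprintf("missing coordinates in '%s' (atom record %d)",
                    path, bad[1]))
  structure3d(top, coords)
}

#' Read one or more trajectory files
#'
#' Supported formats: DCD and multi-model PDB (chosen by file extension).
#' Files are concatenated in the order given; each file becomes one replica
#' with `replica_id` equal to its 0-based position in `paths`. Trajectory
#' files must contain exactly the atoms of `top`, in order.
#'
#' @param paths Character vector of trajectory file paths.
#' @param top The [topology()] the frames belong to.
#' @param dt Time between consecutive frames, in ns (metadata only).
#' @return A [trajectory()] with pooled frames and per-frame replica
#'   metadata.
#' @export
read_trajectory <- function(paths, top, dt = 1.0) {
  stopifnot(inherits(top, "topology"))
  if (length(paths) == 0L) stop_io("no trajectory files given")
  mats <- vector("list", length(paths))
  metas <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop_io(sprintf("file not found: '%s'", p))
    ext <- tolower(tools::file_ext(p))
    m <- switch(ext,
      pdb = {
        pdb <- tryCatch(
          suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)),
          error = function(e) stop_io(sprintf("failed to parse PDB '%s': %s",
                                              p, conditionMessage(e))))
        x <- pdb$xyz
        if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
        x
      },
      dcd = tryCatch(
        bio3d::read.dcd(p, verbose = FALSE),
        error = function(e) stop_io(sprintf("failed to read DCD '%s': %s",
                                            p, conditionMessage(e)))),
      xtc = stop_io(paste0("XTC input is not supported ('", p, "'); ",
                           "convert to DCD or multi-model PDB first")),
      stop_io(sprintf("unrecognized trajectory extension '.%s' ('%s')",
                      ext, p))
    )
    if (ncol(m) != 3L * top$natoms)
      stop_topology(sprintf(
        "'%s' has %d atoms per frame but the topology has %d",
        p, ncol(m) %/% 3L, top$natoms))
    bad <- which(rowSums(is.na(m)) > 0L)
    if (length(bad))
      stop_io(sprintf("unreadable/truncated frame %d in '%s'", bad[1], p))
    mats[[i]] <- m
    nf <- nrow(m)
    metas[[i]] <- data.frame(replica_id = i - 1L,
                             time = (seq_len(nf) - 1L) * dt,
                             frame_index_in_replica = seq_len(nf) - 1L)
  }
  trajectory(top, do.call(rbind, mats), do.call(rbind, metas))
}

# ---- PDB writing (single formatter shared by structure and trajectory) ----

pdb_atom_lines <- function(top, xyz) {
  a <- top$atoms
  name_fmt <- ifelse(nchar(a$name) < 4L & nchar(a$element) == 1L,
                     sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  sprintf("%-6s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$is_ligand, "HETATM", "ATOM"),
          (a$index %% 99999L) + 1L, name_fmt, "",
          substr(a$resname, 1, 4), substr(paste0(a$chain, " "), 1, 1),
          a$resseq %% 10000L, substr(paste0(a$inscode, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0, a$element)
}

#' Write a structure to a PDB file
#' @param s A [structure3d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  lines <- c(pdb_atom_lines(s$topology, s$xyz), "TER", "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  blocks <- lapply(seq_len(n_frames(traj)), function(f) {
    c(sprintf("MODEL %8d", f),
      pdb_atom_lines(traj$topology, xyz_unflatten(traj$xyz[f, ])),
      "TER", "ENDMDL")
  })
  ok <- tryCatch({ writeLines(c(unlist(blocks), "END"), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write '%s'", path))
  invisible(path)
}

# ---- tabular reports ----

#' Write a report table as TSV or JSON
#'
#' TSV files are tab-delimited with a header row, `.` decimal separator and
#' fixed column order; JSON files hold an array of row objects. Numeric
#' values survive a write/read round trip to better than 1e-12 relative.
#'
#' @param records A data.frame (rows share one schema).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  ok <- tryCatch({
    if (format == "tsv") {
      out <- records
      for (j in seq_along(out))
        if (is.numeric(out[[j]]))
          out[[j]] <- sprintf("%.17g", out[[j]])
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, na = "NA")
    } else {
      jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = FALSE)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Read a report table written by [write_table()]
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(sprintf("file not found: '%s'", path))
  if (format == "tsv") {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
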