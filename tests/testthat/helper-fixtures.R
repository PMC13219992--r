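# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored binary fixtures.

# Minimal hand-built topology: two protein residues (with one hydrogen) and
# a two-heavy-atom ligand carrying one hydrogen.
manual_topology <- function() {
  topology(data.frame(
    name = c("CA", "CB", "HB", "CA", "C1", "C2", "H1"),
    element = c("C", "C", "H", "C", "C", "C", "H"),
    resname = c("ALA", "ALA", "ALA", "GLY", "LIG", "LIG", "LIG"),
    resseq = c(60L, 60L, 60L, 61L, 1L, 1L, 1L),
    inscode = "",
    chain = c("A", "A", "A", "A", "L", "L", "L"),
    is_ligand = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    is_hydrogen = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

# A topology of np protein atoms (one residue each, atom CA) and nl ligand
# atoms; convenient when tests want full control over coordinates.
grid_topology <- function(np, nl) {
  topology(data.frame(
    name = c(rep("CA", np), paste0("C", seq_len(nl))),
    element = "C",
    resname = c(rep("POC", np), rep("LIG", nl)),
    resseq = c(seq_len(np), rep(1L, nl)),
    inscode = "",
    chain = c(rep("A", np), rep("L", nl)),
    is_ligand = c(rep(FALSE, np), rep(TRUE, nl)),
    is_hydrogen = FALSE,
    stringsAsFactors = FALSE))
}

# Trajectory from an explicit list of n x 3 coordinate matrices.
traj_from_coords <- function(top, coord_list, replica_id = NULL) {
  xyz <- do.call(rbind, lapply(coord_list, function(m) as.numeric(t(m))))
  frames <- NULL
  if (!is.null(replica_id)) {
    frames <- do.call(rbind, lapply(split(seq_along(replica_id), replica_id),
      function(ix) data.frame(replica_id = replica_id[ix[1]],
                              time = as.numeric(seq_along(ix) - 1L),
                              frame_index_in_replica = seq_along(ix) - 1L)))
    rownames(frames) <- NULL
  }
  trajectory(top, xyz, frames)
}

# Independent naive oracle for the trajectory R-value: plain double loop
# over frames and pairs with the textbook sigmoid. Deliberately shares no
# code with the package implementation.
naive_r_trajectory <- function(values, r0, beta = 5.0, lam = 1.8) {
  per_frame <- numeric(nrow(values))
  for (f in seq_len(nrow(values))) {
    acc <- 0
    for (k in seq_len(ncol(values))) {
      acc <- acc + 1 / (1 + exp(beta * (values[f, k] - lam * r0[k])))
    }
    per_frame[f] <- acc / ncol(values)
  }
  mean(per_frame)
}

# Random small distance-series instance for oracle-equivalence tests.
random_distance_instance <- function(seed) {
  set.seed(seed)
  K <- sample(2:12, 1)
  Fn <- sample(2:20, 1)
  r0 <- runif(K, 2.0, 4.4)
  values <- matrix(runif(Fn * K, 0.5, 15), Fn, K)
  np <- K  # one protein atom per pair keeps indexing trivial
  pairs <- data.frame(protein_atom = seq_len(K) - 1L,
                      ligand_atom = np + 0L, r0 = r0)
  list(values = values, r0 = r0, pairs = pairs, K = K, Fn = Fn)
}

# Wrap a raw distance matrix as a distance_series aligned with a contact
# set built on a matching synthetic reference geometry.
series_from_values <- function(values, contacts) {
  structure(list(pairs = contacts$pairs, values = values,
                 frames = data.frame(
                   replica_id = 0L,
                   time = as.numeric(seq_len(nrow(values)) - 1L),
                   frame_index_in_replica = seq_len(nrow(values)) - 1L)),
            class = "distance_series")
}

# Contact set at given reference distances without a real geometry: one
# protein atom per contact, all on a line, ligand atom placed to match r0
# is impossible for several pairs at once, so build the object directly.
contacts_from_r0 <- function(r0, top = NULL) {
  K <- length(r0)
  if (is.null(top)) top <- grid_topology(K, 1L)
  ref <- structure3d(top, matrix(0, top$natoms, 3L))
  pairs <- data.frame(protein_atom = seq_len(K) - 1L,
                      ligand_atom = rep(K + 0L, K), r0 = r0)
  structure(list(pairs = pairs, reference_mode = "repr", cutoff = 4.5,
                 reference = ref),
            class = "contact_set")
}

# Tiny PDB texts used by the io tests.
toy_pdb_lines <- function() {
  c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C1  LIG L   1       3.000   0.000   0.000  1.00  0.00           C",
    "END")
}
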