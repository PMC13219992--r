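# Synthetic fixtures with planted ground truth.
#
# Two generator tiers:
#   * distance-level (simulate_distance_series): each native contact is
#     independently "intact" per frame with probability p; intact distances
#     scatter around r0, broken ones sit beyond Lambda * r0. The expected
#     R-value under this emission model has a closed form obtained by
#     pushing the emission densities through the sigmoid (numerical
#     quadrature), which is the planted truth tests recover.
#   * coordinate-level (simulate_trajectory): a toy pocket/ligand complex
#     whose ligand undergoes rigid-body jitter with stochastic excursion
#     events that carry it out of the pocket; realizes the same persistence
#     statistics in 3D so the full pipeline (superposition, representative
#     selection) can run end to end.
#
# All randomness flows from one user seed through named substreams, so
# adding a generator never perturbs existing fixtures.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Synthetic-generator configuration
#'
#' Defaults emulate, at toy scale, the statistics of a multi-replica
#' high-temperature MD study: 12 replicas of 100 frames (1 frame per ns for
#' a 100-ns run), a mostly-bound pose (persistence 0.8), small in-pocket
#' jitter and excursions that carry broken contacts well past the sigmoid
#' midpoint.
#'
#' @param n_residues Pocket pseudo-residues.
#' @param atoms_per_residue Heavy atoms per pseudo-residue (first is CA).
#' @param n_ligand_atoms Ligand heavy atoms.
#' @param n_frames Frames per replica.
#' @param n_replicas Number of replicas.
#' @param persistence Per-contact probability of being intact in a frame
#'   (scalar or per-contact vector), in `[0, 1]`.
#' @param bound_noise_sigma Gaussian distance/position noise, Angstrom.
#' @param broken_offset Distance added beyond `lam * r0` when a contact is
#'   broken, Angstrom.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(n_residues = 8L, atoms_per_residue = 3L,
                             n_ligand_atoms = 6L, n_frames = 100L,
                             n_replicas = 12L, persistence = 0.8,
                             bound_noise_sigma = 0.05, broken_offset = 5.0,
                             seed = 1L) {
  if (any(persistence < 0 | persistence > 1))
    stop_domain("persistence must lie in [0, 1]")
  if (bound_noise_sigma < 0) stop_domain("bound_noise_sigma must be >= 0")
  if (n_residues < 1L || atoms_per_residue < 1L || n_ligand_atoms < 1L ||
      n_frames < 1L || n_replicas < 1L)
    stop_generation("all counts must be >= 1")
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 n_ligand_atoms = as.integer(n_ligand_atoms),
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas),
                 persistence = persistence,
                 bound_noise_sigma = bound_noise_sigma,
                 broken_offset = broken_offset,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic Fibonacci-sphere points (unit radius).
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a toy pocket/ligand complex
#'
#' Places the ligand heavy atoms on a small sphere around the origin and
#' the pocket pseudo-residues (chain A, resname POC, atoms CA/CB/CG/...)
#' radially around it, with a small seeded jitter, so that at least one
#' protein-ligand heavy-atom pair sits below the native-contact cutoff.
#' Geometry is bit-identical for a fixed config + seed.
#'
#' @param config A [generator_config()].
#' @return A [structure3d()] (ligand residue LIG, chain L).
#' @export
make_toy_complex <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_substream(config$seed, "complex", {
    lig <- fib_sphere(config$n_ligand_atoms) * 1.2
    lig <- lig + matrix(rnorm(length(lig), sd = 0.1), ncol = 3L)
    dirs <- fib_sphere(config$n_residues)
    prot <- do.call(rbind, lapply(seq_len(config$n_residues), function(i) {
      base <- dirs[i, ] * 4.0
      do.call(rbind, lapply(seq_len(config$atoms_per_residue), function(k) {
        base + dirs[i, ] * 1.4 * (k - 1L) + rnorm(3L, sd = 0.1)
      }))
    }))
    atom_names <- c("CA", "CB", "CG", "CD", "CE", "CZ", "CH", "CI")
    prot_atoms <- data.frame(
      name = rep(atom_names[seq_len(config$atoms_per_residue)],
                 config$n_residues),
      element = "C",
      resname = "POC",
      resseq = rep(seq_len(config$n_residues), each = config$atoms_per_residue),
      inscode = "", chain = "A", is_ligand = FALSE, is_hydrogen = FALSE,
      stringsAsFactors = FALSE)
    lig_atoms <- data.frame(
      name = paste0("C", seq_len(config$n_ligand_atoms)),
      element = "C", resname = "LIG", resseq = 1L, inscode = "",
      chain = "L", is_ligand = TRUE, is_hydrogen = FALSE,
      stringsAsFactors = FALSE)
    s <- structure3d(topology(rbind(prot_atoms, lig_atoms)),
                     rbind(prot, lig))
    cs <- tryCatch(identify_native_contacts(s),
                   ligstab_no_contacts_error = function(e) NULL)
    if (is.null(cs))
      stop_generation("infeasible geometry: toy complex has no native contact")
    s
  })
}

# E[sigmoid term] under the intact / broken emission densities, by
# quadrature. sigma = 0 collapses to a point evaluation.
expected_term_intact <- function(r0, sigma, params) {
  if (sigma == 0) return(contact_term(r0, r0, params))
  f <- function(r) stats::plogis(-params$beta * (r - params$lam * r0)) *
    stats::dnorm(r, mean = r0, sd = sigma)
  lo <- max(1e-9, r0 - 10 * sigma)
  z <- stats::integrate(f, lower = lo, upper = r0 + 10 * sigma,
                        rel.tol = 1e-10)$value
  # renormalize for the (negligible unless r0 ~ 0) truncation at r > 0
  z / (1 - stats::pnorm(lo, mean = r0, sd = sigma))
}

expected_term_broken <- function(r0, sigma, offset, params) {
  if (sigma == 0) return(stats::plogis(-params$beta * offset))
  f <- function(u) stats::plogis(-params$beta * (u + offset)) *
    2 * stats::dnorm(u, sd = sigma)
  stats::integrate(f, lower = 0, upper = 10 * sigma, rel.tol = 1e-10)$value
}

#' Closed-form expected R-value of the planted emission model
#'
#' @param contacts A `contact_set`.
#' @param config A [generator_config()] (persistence, noise, offset).
#' @param params [contact_params()].
#' @return Expected trajectory R-value (mean over contacts of
#'   `p * E[term | intact] + (1 - p) * E[term | broken]`).
#' @export
expected_r_value <- function(contacts, config, params = contact_params()) {
  pairs <- if (inherits(contacts, "contact_set")) contacts$pairs else contacts
  p <- rep_len(config$persistence, nrow(pairs))
  ei <- vapply(pairs$r0, expected_term_intact, numeric(1),
               sigma = config$bound_noise_sigma, params = params)
  eb <- vapply(pairs$r0, expected_term_broken, numeric(1),
               sigma = config$bound_noise_sigma,
               offset = config$broken_offset, params = params)
  mean(p * ei + (1 - p) * eb)
}

#' Simulate a distance series with planted contact persistence
#'
#' Per frame, each contact is independently intact with probability `p`
#' (distance `r0 + N(0, sigma)`, truncated positive) or broken (distance
#' `lam * r0 + broken_offset + |N(0, sigma)|`).
#'
#' @param config A [generator_config()].
#' @param contacts A `contact_set` (its pairs define the columns).
#' @param params [contact_params()] (supplies `lam` for broken distances).
#' @return List with `series` (a `distance_series` over
#'   `n_frames * n_replicas` pooled frames) and `truth` (list:
#'   `persistence`, `expected_r`, `intact` logical matrix).
#' @export
simulate_distance_series <- function(config, contacts,
                                     params = contact_params()) {
  stopifnot(inherits(config, "generator_config"))
  pairs <- if (inherits(contacts, "contact_set")) contacts$pairs else contacts
  K <- nrow(pairs)
  Fn <- config$n_frames * config$n_replicas
  p <- rep_len(config$persistence, K)
  with_substream(config$seed, "distance_series", {
    intact <- matrix(runif(Fn * K), Fn, K) < matrix(p, Fn, K, byrow = TRUE)
    noise <- matrix(rnorm(Fn * K, sd = max(config$bound_noise_sigma, 0)),
                    Fn, K)
    r0m <- matrix(pairs$r0, Fn, K, byrow = TRUE)
    vals <- ifelse(intact,
                   pmax(r0m + noise, 1e-3),
                   params$lam * r0m + config$broken_offset + abs(noise))
    frames <- data.frame(
      replica_id = rep(seq_len(config$n_replicas) - 1L,
                       each = config$n_frames),
      time = as.numeric(rep(seq_len(config$n_frames) - 1L,
                            config$n_replicas)),
      frame_index_in_replica = rep(seq_len(config$n_frames) - 1L,
                                   config$n_replicas))
    series <- structure(list(pairs = pairs, values = vals, frames = frames),
                        class = "distance_series")
    truth <- list(persistence = p,
                  expected_r = expected_r_value(pairs, config, params),
                  intact = intact)
    list(series = series, truth = truth)
  })
}

#' Simulate a coordinate-level trajectory with planted persistence
#'
#' Builds the toy complex, then generates `n_replicas` x `n_frames` frames
#' in which the ligand undergoes rigid-body Gaussian jitter and, with
#' probability `1 - persistence` per frame, an excursion that translates it
#' out of the pocket far enough that every native contact is broken (beyond
#' `lam * native_cutoff` for all pairs). The protein stays fixed.
#'
#' @param config A [generator_config()] (scalar persistence).
#' @param params [contact_params()] (cutoff geometry for the excursion
#'   displacement).
#' @return List with `trajectory`, `complex` (the reference
#'   [structure3d()]), `contacts` (native contacts of the reference) and
#'   `truth` (list: `persistence`, `bound` logical per pooled frame,
#'   `fraction_bound`, `excursion_displacement`).
#' @export
simulate_trajectory <- function(config = generator_config(),
                                params = contact_params()) {
  stopifnot(inherits(config, "generator_config"))
  if (length(config$persistence) != 1L)
    stop_generation("coordinate-level simulation uses a scalar persistence")
  ref <- make_toy_complex(config)
  contacts <- identify_native_contacts(ref, cutoff = params$native_cutoff)
  lig_rows <- which(ref$topology$atoms$is_ligand)
  # excursion displacement mirroring the distance-tier emission: every
  # native contact (r0 < cutoff) ends up beyond lam * r0 + broken_offset,
  # since the post-excursion distance is at least disp - r0
  disp <- params$lam * params$native_cutoff + config$broken_offset +
    params$native_cutoff
  Fn <- config$n_frames * config$n_replicas
  with_substream(config$seed, "trajectory", {
    bound <- runif(Fn) < config$persistence
    xyz <- matrix(NA_real_, Fn, 3L * ref$topology$natoms)
    for (f in seq_len(Fn)) {
      coords <- ref$xyz
      shift <- rnorm(3L, sd = config$bound_noise_sigma)
      if (!bound[f]) shift <- shift + c(disp, 0, 0)
      coords[lig_rows, ] <- sweep(coords[lig_rows, , drop = FALSE], 2L,
                                  shift, "+")
      xyz[f, ] <- xyz_flatten(coords)
    }
    frames <- data.frame(
      replica_id = rep(seq_len(config$n_replicas) - 1L,
                       each = config$n_frames),
      time = as.numeric(rep(seq_len(config$n_frames) - 1L,
                            config$n_replicas)),
      frame_index_in_replica = rep(seq_len(config$n_frames) - 1L,
                                   config$n_replicas))
    list(trajectory = trajectory(ref$topology, xyz, frames),
         complex = ref, contacts = contacts,
         truth = list(persistence = config$persistence, bound = bound,
                      fraction_bound = mean(bound),
                      excursion_displacement = disp))
  })
}

#' Decoy poses with planted ligand RMSD
#'
#' Pose k is the reference with its ligand rigidly translated by
#' `offsets[k]` Angstrom along +x (protein fixed), so the planted ligand
#' heavy-atom RMSD equals the offset exactly.
#'
#' @param reference A [structure3d()].
#' @param offsets Non-negative offsets in Angstrom.
#' @return List of [structure3d()] poses; the planted RMSD is attached as
#'   attribute `"planted_rmsd"` on each.
#' @export
make_decoy_poses <- function(reference, offsets) {
  stopifnot(inherits(reference, "structure3d"))
  if (any(offsets < 0)) stop_domain("offsets must be >= 0")
  lig_rows <- which(reference$topology$atoms$is_ligand)
  lapply(offsets, function(off) {
    xyz <- reference$xyz
    xyz[lig_rows, 1] <- xyz[lig_rows, 1] + off
    pose <- structure3d(reference$topology, xyz)
    attr(pose, "planted_rmsd") <- off
    pose
  })
}
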