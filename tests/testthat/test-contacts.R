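test_that("native contacts use a strict distance cutoff and store r0", {
  top <- grid_topology(2L, 1L)
  # protein atom 0 at 3.0 A from the ligand atom, protein atom 1 at exactly
  # 4.5 A (excluded by the strict inequality)
  coords <- rbind(c(3, 0, 0), c(0, 4.5, 0), c(0, 0, 0))
  cs <- identify_native_contacts(structure3d(top, coords))
  expect_equal(nrow(cs$pairs), 1L)
  expect_equal(cs$pairs$protein_atom, 0L)
  expect_equal(cs$pairs$r0, 3.0)
  # shrinking the cutoff below 3.0 leaves nothing
  expect_error(identify_native_contacts(structure3d(top, coords), cutoff = 2.9),
               class = "ligstab_no_contacts_error")
})

test_that("all close pairs are found and sorted canonically", {
  top <- grid_topology(3L, 2L)
  set.seed(42)
  coords <- matrix(runif(15, 0, 2.5), 5L, 3L)  # everything within ~4 A
  s <- structure3d(top, coords)
  cs <- identify_native_contacts(s, cutoff = 6.0)
  # brute-force oracle over all protein x ligand pairs
  expected <- list()
  for (p in 1:3) for (l in 4:5) {
    d <- sqrt(sum((coords[p, ] - coords[l, ])^2))
    if (d < 6.0) expected[[length(expected) + 1L]] <-
      c(p - 1L, l - 1L, d)
  }
  em <- do.call(rbind, expected)
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  expect_equal(nrow(cs$pairs), nrow(em))
  expect_equal(cs$pairs$protein_atom, as.integer(em[, 1]))
  expect_equal(cs$pairs$ligand_atom, as.integer(em[, 2]))
  expect_equal(cs$pairs$r0, em[, 3], tolerance = 1e-12)
  # atom-order relabeling leaves the sorted output invariant
  expect_false(is.unsorted(cs$pairs$protein_atom))
})

test_that("apply_window drops the equilibration fraction per replica", {
  top <- grid_topology(1L, 1L)
  mk <- function(n) lapply(seq_len(n), function(i) rbind(c(i, 0, 0), c(0, 0, 0)))
  t100 <- traj_from_coords(top, mk(100))
  w <- apply_window(t100, analysis_window(0.6))
  expect_equal(n_frames(w), 40L)
  expect_equal(w$frames$frame_index_in_replica, 60:99)
  # discard 0 is the identity
  w0 <- apply_window(t100, analysis_window(0))
  expect_equal(w0$xyz, t100$xyz)
  # two replicas pool in replica order
  t2 <- traj_from_coords(top, c(mk(10), mk(10)),
                         replica_id = rep(c(0L, 1L), each = 10L))
  w2 <- apply_window(t2, analysis_window(0.5))
  expect_equal(n_frames(w2), 10L)
  expect_equal(w2$frames$replica_id, rep(c(0L, 1L), each = 5L))
  expect_equal(w2$frames$frame_index_in_replica, rep(5:9, 2L))
})

test_that("apply_window preserves order and is idempotent at discard 0", {
  sim <- simulate_trajectory(generator_config(seed = 9, n_frames = 20,
                                              n_replicas = 3))
  w <- apply_window(sim$trajectory, analysis_window(0.6))
  for (r in 0:2) {
    fi <- w$frames$frame_index_in_replica[w$frames$replica_id == r]
    expect_false(is.unsorted(fi, strictly = TRUE))
  }
  expect_equal(apply_window(w, analysis_window(0))$xyz, w$xyz)
  # a full discard is rejected outright (at least one frame must survive)
  expect_error(analysis_window(1.0), class = "ligstab_domain_error")
})

test_that("distance series match per-frame geometry and the naive loop", {
  top <- grid_topology(2L, 1L)
  ref_coords <- rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 0))
  ref <- structure3d(top, ref_coords)
  cs <- identify_native_contacts(ref, cutoff = 5)
  # static trajectory: every column constant at r0
  static <- traj_from_coords(top, replicate(4, ref_coords, simplify = FALSE))
  ds <- compute_distance_series(static, cs)
  expect_equal(ds$values, matrix(cs$pairs$r0, 4, 2, byrow = TRUE))
  # ligand translated 1 A along the axis of pair 1
  moved <- ref_coords; moved[3, 1] <- -1
  ds2 <- compute_distance_series(traj_from_coords(top, list(moved)), cs)
  expect_equal(ds2$values[1, 1], 4.0)
  # random 5-frame toy vs naive per-frame loop
  set.seed(7)
  frames <- replicate(5, matrix(rnorm(9, sd = 3), 3, 3), simplify = FALSE)
  dsr <- compute_distance_series(traj_from_coords(top, frames), cs)
  for (f in 1:5) for (k in 1:2) {
    p <- cs$pairs$protein_atom[k] + 1L; l <- cs$pairs$ligand_atom[k] + 1L
    expect_equal(dsr$values[f, k],
                 sqrt(sum((frames[[f]][p, ] - frames[[f]][l, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("ensemble matrix retains pairs by inclusive mean-distance cutoff", {
  top <- grid_topology(2L, 1L)
  # pair 1 constant at 6.75 (retained, inclusive); pair 2 alternates 5 / 9
  # (mean 7.0, dropped)
  f1 <- rbind(c(6.75, 0, 0), c(0, 5, 0), c(0, 0, 0))
  f2 <- rbind(c(6.75, 0, 0), c(0, 9, 0), c(0, 0, 0))
  traj <- traj_from_coords(top, list(f1, f2))
  ecm <- ensemble_contact_matrix(traj)
  expect_equal(nrow(ecm$retained), 1L)
  expect_equal(ecm$retained$protein_atom, 0L)
  expect_equal(ecm$retained$mean_distance, 6.75)
  # hand-computed means on a 4-pair toy
  top2 <- grid_topology(2L, 2L)
  g1 <- rbind(c(0, 0, 0), c(0, 3, 0), c(1, 0, 0), c(0, 5, 0))
  g2 <- rbind(c(0, 0, 0), c(0, 3, 0), c(2, 0, 0), c(0, 7, 0))
  ecm2 <- ensemble_contact_matrix(traj_from_coords(top2, list(g1, g2)),
                                  retention_cutoff = 100)
  hand <- sapply(1:2, function(p) sapply(3:4, function(l) {
    mean(c(sqrt(sum((g1[p, ] - g1[l, ])^2)), sqrt(sum((g2[p, ] - g2[l, ])^2))))
  }))
  expect_equal(sort(ecm2$candidate_pairs$mean_distance), sort(as.numeric(hand)),
               tolerance = 1e-12)
})

test_that("the retained set shrinks monotonically as the cutoff tightens", {
  sim <- simulate_trajectory(generator_config(seed = 13, n_frames = 30,
                                              n_replicas = 2))
  w <- apply_window(sim$trajectory)
  sizes <- vapply(c(10, 8, 6.75, 5, 4), function(cut) {
    e <- tryCatch(ensemble_contact_matrix(w, retention_cutoff = cut),
                  ligstab_no_contacts_error = function(e) NULL)
    if (is.null(e)) 0L else nrow(e$retained)
  }, integer(1))
  expect_false(is.unsorted(rev(sizes)))
})

test_that("representative selection equals the exhaustive scan", {
  top <- grid_topology(1L, 1L)
  # all frames identical: tie broken to the first pooled frame
  same <- traj_from_coords(top, replicate(5, rbind(c(3, 0, 0), c(0, 0, 0)),
                                          simplify = FALSE))
  ecm <- ensemble_contact_matrix(same)
  rep <- select_representative(same, ecm)
  expect_equal(rep$frame_global_index, 1L)
  expect_equal(rep$frame_index_in_replica, 0L)
  expect_equal(rep$euclidean_distance, 0)
  # one pair at {3.0, 5.0, 4.1}: mean 4.033..., frame 3 is closest
  three <- traj_from_coords(top, lapply(c(3, 5, 4.1), function(d)
    rbind(c(d, 0, 0), c(0, 0, 0))))
  ecm3 <- ensemble_contact_matrix(three, retention_cutoff = 100)
  rep3 <- select_representative(three, ecm3)
  expect_equal(rep3$frame_global_index, 3L)
  # random instances vs brute-force O(F*K) scan
  for (seed in 1:8) {
    set.seed(seed)
    np <- 3L; nl <- 2L; Fn <- 20L
    topr <- grid_topology(np, nl)
    frames <- replicate(Fn, matrix(runif((np + nl) * 3, 0, 6), np + nl, 3),
                        simplify = FALSE)
    traj <- traj_from_coords(topr, frames)
    ecmr <- ensemble_contact_matrix(traj, retention_cutoff = 100)
    got <- select_representative(traj, ecmr)
    dm <- compute_distance_series(traj, ecmr$retained)$values
    norms <- apply(dm, 1L, function(v) sqrt(sum((v - colMeans(dm))^2)))
    expect_equal(got$frame_global_index, which.min(norms))
    expect_equal(got$euclidean_distance, min(norms), tolerance = 1e-12)
  }
})
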