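test_that("contact_term hits its anchors and is overflow-safe", {
  p <- contact_params()
  # exponent zero at rX = lam * r0, for any r0
  for (r0 in c(2, 3, 4.4)) expect_identical(contact_term(p$lam * r0, r0, p), 0.5)
  # huge separation underflows cleanly to 0
  expect_identical(contact_term(1e6, 3.0, p), 0)
  # hand evaluation of the sigmoid at rX = r0 = 3.0
  expect_equal(contact_term(3.0, 3.0, p), 1 / (1 + exp(-12)), tolerance = 1e-12)
  expect_error(contact_term(-1, 3, p), class = "ligstab_domain_error")
  expect_error(contact_term(3, 0, p), class = "ligstab_domain_error")
})

test_that("frame R-value is the mean sigmoid term over native contacts", {
  p <- contact_params()
  cs <- contacts_from_r0(c(3.0, 3.5))
  # both contacts at the sigmoid midpoint
  expect_equal(r_value_frame(p$lam * cs$pairs$r0, cs, p), 0.5)
  # single contact
  cs1 <- contacts_from_r0(2.5)
  expect_equal(r_value_frame(p$lam * 2.5, cs1, p), 0.5)
  # self-reference frame with r0 >= 2.0 stays essentially fully formed
  cs2 <- contacts_from_r0(c(2.0, 3.0, 4.4))
  expect_gte(r_value_frame(cs2$pairs$r0, cs2, p), 0.999)
  expect_error(r_value_frame(numeric(0), contacts_from_r0(numeric(0))),
               class = "ligstab_no_contacts_error")
})

test_that("trajectory R-value averages per-frame values", {
  p <- contact_params()
  cs <- contacts_from_r0(c(2.0, 3.0, 4.0))
  r0 <- cs$pairs$r0
  # all frames identical to the reference
  vals <- matrix(r0, 5, 3, byrow = TRUE)
  rv <- r_value_trajectory(series_from_values(vals, cs), cs, p)
  expect_gte(rv$r_global, 0.999)
  expect_equal(rv$r_global, mean(rv$per_frame_r))
  # alternating reference / far-displaced frames: R ~ 0.5
  far <- matrix(3 * p$lam * r0, 1, 3)
  alt <- do.call(rbind, rep(list(matrix(r0, 1, 3), far), 5))
  rva <- r_value_trajectory(series_from_values(alt, cs), cs, p)
  oracle <- naive_r_trajectory(alt, r0)
  expect_equal(rva$r_global, oracle, tolerance = 1e-12)
  expect_equal(rva$r_global, 0.5, tolerance = 0.01)
})

test_that("vectorized R-value matches the naive double loop on random toys", {
  for (seed in 1:20) {
    inst <- random_distance_instance(seed)
    cs <- contacts_from_r0(inst$r0)
    rv <- r_value_trajectory(series_from_values(inst$values, cs), cs)
    expect_equal(rv$r_global, naive_r_trajectory(inst$values, inst$r0),
                 tolerance = 1e-12)
  }
})

test_that("R-value decreases strictly when all distances are inflated", {
  inst <- random_distance_instance(99)
  cs <- contacts_from_r0(inst$r0)
  base <- r_value_trajectory(series_from_values(inst$values, cs), cs)$r_global
  for (s in c(1.1, 1.5, 3)) {
    inflated <- r_value_trajectory(series_from_values(inst$values * s, cs),
                                   cs)$r_global
    expect_lt(inflated, base)
  }
  expect_gt(base, 0); expect_lt(base, 1)
})

test_that("per-residue decomposition reproduces planted contributions", {
  p <- contact_params()
  # residue 1 owns 1 contact, residues 2-4 one each: regroup so residue A
  # has 1 contact and residue B has 3, all at the sigmoid midpoint
  top <- topology(data.frame(
    name = c("CA", "CA", "CB", "CG", "C1"),
    element = "C",
    resname = c("POC", "POC", "POC", "POC", "LIG"),
    resseq = c(1L, 2L, 2L, 2L, 1L),
    inscode = "", chain = c("A", "A", "A", "A", "L"),
    is_ligand = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    is_hydrogen = FALSE, stringsAsFactors = FALSE))
  r0 <- c(3, 3, 3, 3)
  pairs <- data.frame(protein_atom = 0:3, ligand_atom = 4L, r0 = r0)
  cs <- structure(list(pairs = pairs, reference_mode = "repr", cutoff = 4.5,
                       reference = structure3d(top, matrix(0, 5, 3))),
                  class = "contact_set")
  vals <- matrix(p$lam * 3, 6, 4)   # every term exactly 0.5
  m <- residue_stability_map(series_from_values(vals, cs), cs, p, top)
  expect_equal(m$contact_count, c(1L, 3L))
  expect_equal(m$r_residue, c(0.5, 0.5))
  expect_equal(m$contribution, c(0.5, 1.5))
  expect_equal(m$pct_contribution, c(25, 75))
  rv <- r_value_trajectory(series_from_values(vals, cs), cs, p)
  expect_equal(sum(m$contribution), rv$n_contacts * rv$r_global,
               tolerance = 1e-12)
})

test_that("decomposition identities hold on random fixtures", {
  for (seed in c(2, 17, 31)) {
    cfg <- generator_config(seed = seed, n_frames = 40, n_replicas = 2,
                            persistence = runif(1, 0.3, 0.9))
    sim <- simulate_trajectory(generator_config(seed = seed, n_frames = 10,
                                                n_replicas = 1))
    cs <- sim$contacts
    ds <- simulate_distance_series(cfg, cs)
    rv <- r_value_trajectory(ds$series, cs)
    m <- residue_stability_map(ds$series, cs, top = sim$complex$topology)
    expect_equal(sum(m$contribution), rv$n_contacts * rv$r_global,
                 tolerance = 1e-9)
    expect_equal(sum(m$pct_contribution), 100, tolerance = 1e-9)
  }
})

test_that("ligand-atom stability map brackets categories and flags no_contact", {
  p <- contact_params()
  top <- grid_topology(1L, 2L)   # ligand atom C2 will own no contact
  pairs <- data.frame(protein_atom = 0L, ligand_atom = 1L, r0 = 3.0)
  cs <- structure(list(pairs = pairs, reference_mode = "repr", cutoff = 4.5,
                       reference = structure3d(top, matrix(0, 3, 3))),
                  class = "contact_set")
  # constant term 0.75: rX = lam*r0 - log(3)/beta
  rx <- p$lam * 3.0 - log(3) / p$beta
  m <- atom_stability_map(series_from_values(matrix(rx, 4, 1), cs), cs, p, top)
  expect_equal(m$category[m$atom_index == 1L], "less_stable")
  expect_equal(m$r_atom[m$atom_index == 1L], 0.75, tolerance = 1e-12)
  expect_equal(m$category[m$atom_index == 2L], "no_contact")
  expect_true(is.na(m$r_atom[m$atom_index == 2L]))
  # near-reference distances -> stable
  ms <- atom_stability_map(series_from_values(matrix(3.0, 4, 1), cs), cs, p, top)
  expect_equal(ms$category[ms$atom_index == 1L], "stable")
  # far distances -> unstable
  mu <- atom_stability_map(series_from_values(matrix(20, 4, 1), cs), cs, p, top)
  expect_equal(mu$category[mu$atom_index == 1L], "unstable")
})

test_that("delta_r subtracts and refuses mismatched parameters", {
  cs <- contacts_from_r0(c(3, 3.5))
  v1 <- series_from_values(matrix(cs$pairs$r0, 4, 2, byrow = TRUE), cs)
  v2 <- series_from_values(matrix(cs$pairs$r0 * 1.6, 4, 2, byrow = TRUE), cs)
  a <- r_value_trajectory(v1, cs)
  b <- r_value_trajectory(v2, cs)
  expect_equal(delta_r(a, a), 0)
  expect_equal(delta_r(a, b), -delta_r(b, a))
  b2 <- r_value_trajectory(v2, cs, contact_params(beta = 4))
  expect_error(delta_r(a, b2), class = "ligstab_comparability_error")
})

test_that("averaging over frames commutes with the full-matrix mean", {
  inst <- random_distance_instance(5)
  cs <- contacts_from_r0(inst$r0)
  rv <- r_value_trajectory(series_from_values(inst$values, cs), cs)
  p <- contact_params()
  full <- mean(contact_term(as.numeric(inst$values),
                            rep(inst$r0, each = nrow(inst$values)), p))
  expect_equal(rv$r_global, full, tolerance = 1e-12)
})
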