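test_that("pKd conversion is exact and strictly decreasing in Kd", {
  expect_equal(pkd_from_kd(1e-9), 9.0)
  expect_equal(pkd_from_kd(1.0), 0.0)
  expect_equal(pkd_from_kd(26.9e-9), -log10(26.9e-9), tolerance = 1e-12)
  expect_equal(pkd_from_kd(26.9e-9), 7.5702, tolerance = 1e-4)
  kds <- sort(10^runif(20, -12, 0))
  expect_false(is.unsorted(rev(pkd_from_kd(kds))))
  expect_error(pkd_from_kd(0), class = "ligstab_domain_error")
  expect_error(pkd_from_kd(-1e-9), class = "ligstab_domain_error")
})

test_that("Kd unit normalization covers the common assay units", {
  expect_equal(kd_to_molar(26.9, "nM"), 26.9e-9)
  expect_equal(kd_to_molar(0.2, "pM"), 0.2e-12)
  expect_equal(kd_to_molar(4.8, "uM"), 4.8e-6)
  expect_equal(kd_to_molar(4.8, "µM"), 4.8e-6)
  expect_equal(kd_to_molar(1, "M"), 1)
  expect_error(kd_to_molar(1, "kg"), class = "ligstab_domain_error")
})

test_that("native-like filtering excludes strictly below the threshold", {
  rv <- c(cmpd7 = 0.64, borderline = 0.70, strong = 0.95)
  part <- filter_native_like(rv)
  expect_equal(part$excluded$ligand, "cmpd7")
  expect_equal(part$excluded$reason, "non-native-like")
  expect_setequal(names(part$used), c("borderline", "strong"))
  # nothing excluded when everything is stable
  all_high <- filter_native_like(c(a = 0.9, b = 0.92))
  expect_equal(nrow(all_high$excluded), 0L)
  expect_length(all_high$used, 2L)
})

test_that("correlate reproduces hand-computed Pearson values", {
  x <- 1:5
  expect_equal(correlate(x, 2 * x + 1)$pearson_r, 1.0)
  expect_equal(correlate(x, -x)$pearson_r, -1.0)
  expect_equal(correlate(c(1, 2, 3), c(2, 1, 3))$pearson_r, 0.5,
               tolerance = 1e-12)
  expect_error(correlate(c(1, 2), c(3, 4)), class = "ligstab_correlation_error")
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)),
               class = "ligstab_correlation_error")
})

test_that("correlate matches the textbook formula on random data", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    r <- correlate(x, y)$pearson_r
    textbook <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r, textbook, tolerance = 1e-12)
  }
})

test_that("correlate drops and lists incomplete pairs", {
  x <- c(a = 1, b = 2, c = 3, d = NA, e = 5)
  y <- c(a = 2, b = 4, c = 6, d = 8, e = 10)
  res <- correlate(x, y)
  expect_equal(res$n_used, 4L)
  expect_equal(res$excluded$id, "d")
  expect_equal(res$pearson_r, 1.0)
})

test_that("filtering order does not affect the surviving-set correlation", {
  set.seed(6)
  rv <- stats::setNames(runif(10, 0.4, 1), paste0("L", 1:10))
  pkd <- stats::setNames(5 + 3 * rv + rnorm(10, sd = 0.2), names(rv))
  part <- filter_native_like(rv)
  a <- correlate(part$used, pkd[names(part$used)])$pearson_r
  # filter applied after subsetting in a different order
  shuffled <- sample(names(rv))
  part2 <- filter_native_like(rv[shuffled])
  b <- correlate(part2$used, pkd[names(part2$used)])$pearson_r
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("per-residue correlation flags and scores residues correctly", {
  mkmap <- function(rA, cA, rB) data.frame(
    chain = c("A", "A"), resseq = c(1L, 2L), inscode = "",
    resname = c("POC", "POC"),
    contact_count = c(cA, 2L),
    r_residue = c(rA, rB),
    contribution = c(rA * cA, rB * 2),
    pct_contribution = NA_real_, stringsAsFactors = FALSE)
  pkd <- c(l1 = 6, l2 = 7, l3 = 8, l4 = 9)
  # residue 1 contribution is linear in pkd; residue 2 is constant
  maps <- list(l1 = mkmap(0.60, 2L, 0.5), l2 = mkmap(0.70, 2L, 0.5),
               l3 = mkmap(0.80, 2L, 0.5), l4 = mkmap(0.90, 2L, 0.5))
  res <- per_residue_correlation(maps, pkd)
  r1 <- res[res$resseq == 1L, ]
  expect_equal(r1$r_rvalue_pkd, 1.0, tolerance = 1e-12)
  expect_equal(r1$r_contribution_pkd, 1.0, tolerance = 1e-12)
  expect_equal(r1$status, "ok")
  r2 <- res[res$resseq == 2L, ]
  expect_equal(r2$status, "zero_variance")
  expect_true(is.na(r2$r_rvalue_pkd))
  # hand-computed Pearson on a non-degenerate 4-ligand toy
  maps2 <- list(l1 = mkmap(0.60, 2L, 0.9), l2 = mkmap(0.75, 2L, 0.4),
                l3 = mkmap(0.65, 2L, 0.7), l4 = mkmap(0.90, 2L, 0.5))
  res2 <- per_residue_correlation(maps2, pkd)
  hand <- function(v) sum((v - mean(v)) * (pkd - mean(pkd))) /
    sqrt(sum((v - mean(v))^2) * sum((pkd - mean(pkd))^2))
  expect_equal(res2$r_rvalue_pkd[res2$resseq == 2L],
               hand(c(0.9, 0.4, 0.7, 0.5)), tolerance = 1e-12)
  # a residue present in < 3 ligands is flagged insufficient
  maps3 <- maps2
  maps3$l1 <- maps3$l1[1, ]; maps3$l2 <- maps3$l2[1, ]; maps3$l3 <- maps3$l3[1, ]
  res3 <- per_residue_correlation(maps3, pkd)
  expect_equal(res3$status[res3$resseq == 2L], "insufficient_n")
})

test_that("affinity tables exclude IC50/Ki surrogates by default", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand\tvalue\tunit\tmetric",
               "a\t26.9\tnM\tKd",
               "b\t4.8\tuM\tIC50",
               "c\t0.2\tpM\tKd"), f)
  d <- read_affinity_table(f)
  expect_setequal(d$ligand, c("a", "c"))
  expect_equal(d$pkd[d$ligand == "a"], -log10(26.9e-9))
  with_sur <- read_affinity_table(f, include_surrogates = TRUE)
  expect_equal(nrow(with_sur), 3L)
  expect_true(with_sur$surrogate[with_sur$ligand == "b"])
})
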