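code5 <- genetic_code(5L)

test_that("table 5 has the expected structure", {
  expect_equal(length(code5$sense), 62)
  expect_setequal(code5$stops, c("TAA", "TAG"))
  expect_equal(length(code5$families), 20)
  # AGA/AGG are serine under the invertebrate mitochondrial code
  expect_true(all(c("AGA", "AGG") %in% code5$families[["S"]]))
  expect_equal(length(code5$families[["S"]]), 8)
})

test_that("codon counting drops terminal stops and partial codons", {
  ct <- count_codons(list("ATGTTAAAATAA"), code5)
  expect_equal(unname(ct$counts[c("ATG", "TTA", "AAA")]), c(1L, 1L, 1L))
  expect_equal(ct$n_codons, 3)
  ct2 <- count_codons(list("ATGTT"), code5)
  expect_equal(ct2$n_codons, 1)
  expect_equal(unname(ct2$counts[["ATG"]]), 1L)
  expect_error(count_codons(list("ATGXX"), code5), "non-DNA")
  expect_error(count_codons(list(), code5), "empty")
  # internal stops flagged, not counted
  ct3 <- count_codons(list("ATGTAAATG"), code5)
  expect_equal(ct3$internal_stops, 1)
  expect_equal(ct3$n_codons, 2)
})

test_that("codon counts equal an independent recount on random CDS sets", {
  set.seed(31)
  for (r in 1:10) {
    cds <- replicate(sample(2:5, 1), random_dna(3 * sample(20:60, 1)))
    ct <- count_codons(as.list(cds), code5)
    expect_identical(ct$counts, oracle_codon_counts(cds, code5))
  }
})

test_that("RSCU behaves on two-codon families and satisfies the sum rule", {
  # Lys family AAA/AAG used 5/5 -> both 1; Phe TTT/TTC used 10/0 -> 2 and 0
  counts <- c(AAA = 5, AAG = 5, TTT = 10)
  r <- rscu(counts, code5)
  expect_equal(unname(r[c("AAA", "AAG")]), c(1, 1))
  expect_equal(unname(r[c("TTT", "TTC")]), c(2, 0))
  # empty families flagged (by amino acid) and zero
  expect_true("G" %in% attr(r, "empty_families"))
  expect_true(all(r[code5$families[["G"]]] == 0))
  # family sums equal family sizes on dense random counts
  set.seed(32)
  dense <- stats::setNames(sample(1:50, 62, TRUE), code5$sense)
  rd <- rscu(dense, code5)
  for (fam in code5$families) {
    expect_equal(sum(rd[fam]), length(fam), tolerance = 1e-9)
    expect_equal(mean(rd[fam]), 1, tolerance = 1e-9)
  }
})

test_that("ENC hits its uniform and degenerate limits", {
  uniform <- stats::setNames(rep(1e11, 62), code5$sense)
  expect_equal(enc(uniform, code5), 62, tolerance = 1e-9)
  one_per_family <- stats::setNames(
    rep(1e6, 20), vapply(code5$families, `[[`, character(1), 1))
  expect_equal(enc(one_per_family, code5), 20, tolerance = 1e-6)
})

test_that("ENC matches a direct re-evaluation of the homozygosity formula", {
  set.seed(33)
  for (r in 1:5) {
    counts <- stats::setNames(stats::rpois(62, 1000 / 62) + 1L, code5$sense)
    # independent implementation: per-family F, size classes, Wright sum
    Fk <- list()
    for (fam in code5$families) {
      n <- sum(counts[fam]); k <- length(fam)
      p <- counts[fam] / n
      Fk[[length(Fk) + 1]] <- c(k = k, F = (n * sum(p^2) - 1) / (n - 1))
    }
    fk <- do.call(rbind, Fk)
    expected <- sum(vapply(unique(fk[, "k"]), function(k) {
      sum(fk[, "k"] == k) / mean(fk[fk[, "k"] == k, "F"])
    }, numeric(1)))
    expect_equal(enc(counts, code5), min(expected, 62), tolerance = 1e-9)
  }
})

test_that("ENC is stable under count rescaling at large n", {
  set.seed(34)
  # biased usage so ENC sits well inside (20, 62); the bias-corrected
  # homozygosity gives ENC an O(1/n) dependence on total counts, so scale
  # invariance is a large-n property
  lam <- rep(c(60, 600), length.out = 62)
  counts <- stats::setNames(stats::rpois(62, lam) + 1L, code5$sense)
  e1 <- enc(counts, code5)
  expect_true(e1 > 20 && e1 < 62)
  expect_true(abs(enc(counts * 2, code5) - e1) < 0.1)
})

test_that("positional GC matches definitions and a brute-force tally", {
  g <- positional_gc(list("GGGGGG"), code5)
  expect_equal(unlist(g), c(gc1 = 100, gc2 = 100, gc3 = 100, gc12 = 100))
  g2 <- positional_gc(list("ATGATG"), code5)
  expect_equal(unlist(g2), c(gc1 = 0, gc2 = 0, gc3 = 100, gc12 = 0))
  set.seed(35)
  for (r in 1:5) {
    cds <- replicate(3, random_dna(3 * sample(30:60, 1)))
    pg <- positional_gc(as.list(cds), code5)
    # oracle: expand the counted codons and tally per position
    counts <- oracle_codon_counts(cds, code5)
    cods <- rep(names(counts), counts)
    for (k in 1:3) {
      b <- substr(cods, k, k)
      expect_equal(pg[[paste0("gc", k)]], 100 * mean(b %in% c("G", "C")),
                   tolerance = 1e-9)
    }
    expect_identical(pg$gc12, (pg$gc1 + pg$gc2) / 2)
    expect_true(all(unlist(pg) >= 0 & unlist(pg) <= 100))
  }
})

test_that("the null ENC curve evaluates and obeys its reflection identity", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  s <- seq(0, 1, by = 0.05)
  expect_equal(enc_expected(s), enc_expected(1 - s) + (2 * s - 1), tolerance = 1e-12)
  expect_error(enc_expected(1.2))
})

test_that("neutrality regression recovers exact lines and the OLS solution", {
  x <- c(10, 20, 30, 40)
  # an exact line triggers base R's perfect-fit note in summary.lm
  fit <- suppressWarnings(neutrality_regression(x, 0.5 * x + 10))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$interpretation, "mutation-bias dominant")
  # closed-form normal equations on noisy data
  set.seed(36)
  gx <- runif(30, 5, 40); gy <- 0.3 * gx + 25 + rnorm(30)
  f2 <- neutrality_regression(gx, gy)
  slope_cf <- sum((gx - mean(gx)) * (gy - mean(gy))) / sum((gx - mean(gx))^2)
  expect_equal(f2$slope, slope_cf, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(gy) - slope_cf * mean(gx), tolerance = 1e-10)
  # the 95% band contains the fitted line everywhere
  grid <- seq(min(gx), max(gx), length.out = 25)
  band <- f2$ci95_band(grid)
  line <- f2$intercept + f2$slope * grid
  expect_true(all(band$lwr <= line + 1e-12 & line <= band$upr + 1e-12))
  expect_error(neutrality_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(neutrality_regression(1:2, 1:2), "at least 3")
})

test_that("RSCU clustering keeps identical taxa adjacent and splits bias poles", {
  set.seed(37)
  base <- matrix(runif(5 * 20), 5, 20,
                 dimnames = list(paste0("t", 1:5), paste0("c", 1:20)))
  base[2, ] <- base[5, ]  # two identical rows
  cl <- cluster_rscu_matrix(base)
  ord <- cl$row_order
  expect_equal(abs(which(ord == 2) - which(ord == 5)), 1)
  # columns polarized into unfavoured (<1) and favoured (>1) codons split
  # into the two top-level clusters
  pol <- cbind(matrix(runif(6 * 10, 0, 0.8), 6, 10),
               matrix(runif(6 * 10, 1.2, 2), 6, 10))
  colnames(pol) <- c(paste0("lo", 1:10), paste0("hi", 1:10))
  rownames(pol) <- paste0("t", 1:6)
  cc <- cluster_rscu_matrix(pol)
  grp <- stats::cutree(cc$col_hclust, k = 2)
  expect_equal(length(unique(grp[1:10])), 1)
  expect_equal(length(unique(grp[11:20])), 1)
  expect_false(grp[1] == grp[11])
  # NA reported by cell
  bad <- base; bad[3, 4] <- NA
  expect_error(cluster_rscu_matrix(bad), "t3")
})

test_that("clustering topology is invariant to input row order", {
  set.seed(38)
  m <- matrix(rnorm(8 * 15), 8, 15, dimnames = list(paste0("t", 1:8), paste0("c", 1:15)))
  cl1 <- cluster_rscu_matrix(m)
  perm <- sample(8)
  cl2 <- cluster_rscu_matrix(m[perm, ])
  coph1 <- as.matrix(stats::cophenetic(cl1$row_hclust))
  coph2 <- as.matrix(stats::cophenetic(cl2$row_hclust))
  expect_equal(coph2[rownames(coph1), colnames(coph1)], coph1, tolerance = 1e-12)
})

test_that("AT-rich third positions make every family favour A/U-ending codons", {
  sim <- simulate_mitogenome(sim_params(seed = 6, gc3_target = 12))
  summ <- codon_usage_summary(sim$truth$cds, code5, taxon = sim$record$id)
  for (fam in code5$families) {
    if (sum(summ$counts$counts[fam]) == 0) next
    top <- fam[which.max(summ$rscu[fam])]
    expect_true(substr(top, 3, 3) %in% c("A", "T"),
                label = paste("family top codon", top, "ends A/U"))
  }
})
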