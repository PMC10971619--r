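test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_mitogenome(sim_params(seed = 123))
  b <- simulate_mitogenome(sim_params(seed = 123))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$features, b$record$features)
  expect_identical(a$truth$cds, b$truth$cds)
  c <- simulate_mitogenome(sim_params(seed = 124))
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("default simulations emulate the study-system genome architecture", {
  for (s in c(1, 17)) {
    sim <- simulate_mitogenome(sim_params(seed = s))
    rec <- sim$record
    gc <- gene_content(rec)
    expect_equal(unname(gc[["genes"]]), 37)
    expect_equal(unname(gc[["PCG"]]), 13)
    expect_equal(unname(gc[["tRNA"]]), 22)
    expect_equal(unname(gc[["rRNA"]]), 2)
    cr <- rec$features[rec$features$kind == "noncoding", ]
    expect_gte(cr$end - cr$start, 200)
    # strand partitioning: 9 PCGs and 14 tRNAs on the major strand
    f <- rec$features
    expect_equal(sum(f$kind == "PCG" & f$strand == "+"), 9)
    expect_equal(sum(f$kind == "tRNA" & f$strand == "+"), 14)
    expect_true(all(f$strand[f$kind == "rRNA"] == "-"))
    # composition: AT-rich, A modal, G rarest
    comp <- base_composition(rec)
    expect_gt(comp$at_pct, 70)
    expect_identical(names(which.max(comp$counts)), "A")
    expect_identical(names(which.min(comp$counts)), "G")
    expect_true(validate_record(rec))
  }
})

test_that("realized composition tracks the programmed targets", {
  sim <- simulate_mitogenome(sim_params(seed = 30, gc3_target = 20))
  pg <- positional_gc(count_codons(sim$truth$cds))
  expect_lt(abs(pg$gc3 - 20), 0.5)
  expect_lt(abs(pg$gc12 - sim$truth$gc12_target), 0.5)
  # genome-scale AT within a point of what the base probabilities imply
  p <- sim$truth$params$base_probs
  expect_lt(abs(base_composition(sim$record)$at_pct -
                  100 * (p[["A"]] + p[["T"]])), 2.5)
})

test_that("infeasible composition targets are rejected before emission", {
  expect_error(sim_params(gc3_target = 120), "infeasible")
  expect_error(sim_params(gc3_target = 50, gc12_slope = 3, gc12_intercept = 80),
               "infeasible")
  tpl <- default_gene_template()
  tpl$length[tpl$name == "cox1"] <- 1537L
  expect_error(sim_params(gene_template = tpl), "divisible by 3")
})

test_that("implant truth is sufficient to score recovery downstream", {
  implant <- list(upstream = "trnS2", downstream = "nad1",
                  anticodon = "AAT", length = 74L)
  sim <- simulate_mitogenome(sim_params(seed = 31, implant_trna = implant))
  tr <- sim$truth$implant
  expect_identical(
    substr(sim$record$sequence, tr$offset_genome + 1, tr$offset_genome + tr$length),
    tr$sequence)
  cands <- predict_trna(circular_substr(sim$record$sequence, tr$gap_start,
                                        tr$gap_start + tr$gap_length))
  expect_equal(cands$offset[1], tr$offset_in_gap)
  expect_identical(cands$anticodon[1], tr$anticodon)
})

test_that("simulated records round-trip through GenBank I/O", {
  sims <- simulate_taxa(sim_params(seed = 32, n_taxa = 3))
  f <- tempfile(fileext = ".gb")
  write_genbank(lapply(sims, `[[`, "record"), f)
  back <- read_genbank(f)
  for (i in 1:3) {
    expect_identical(back[[i]]$sequence, sims[[i]]$record$sequence)
    expect_identical(back[[i]]$features, sims[[i]]$record$features)
  }
})

test_that("neutrality simulations realize their programmed line", {
  # zero noise: recovered slope within 0.02 of the programmed 0.23
  taxa <- simulate_taxa_for_neutrality(
    sim_params(seed = 33, n_taxa = 10, gc12_slope = 0.23, gc12_intercept = 27.73),
    noise_sd = 0)
  pts <- t(vapply(taxa, function(tx) {
    pg <- positional_gc(list(tx$cds))
    c(gc3 = pg$gc3, gc12 = pg$gc12)
  }, numeric(2)))
  fit <- neutrality_regression(pts[, "gc3"], pts[, "gc12"])
  expect_lt(abs(fit$slope - 0.23), 0.02)
  expect_lt(abs(fit$intercept - 27.73), 0.5)
  # pure drift limit: slope 1, intercept 0
  taxa1 <- simulate_taxa_for_neutrality(
    sim_params(seed = 34, n_taxa = 10, gc12_slope = 1, gc12_intercept = 0),
    noise_sd = 0)
  pts1 <- t(vapply(taxa1, function(tx) {
    pg <- positional_gc(list(tx$cds)); c(pg$gc3, pg$gc12)
  }, numeric(2)))
  fit1 <- suppressWarnings(neutrality_regression(pts1[, 1], pts1[, 2]))
  expect_lt(abs(fit1$slope - 1), 0.02)
  expect_lt(abs(fit1$intercept), 0.5)
  # realized targets within the 0.5-point emission tolerance
  for (tx in taxa) {
    pg <- positional_gc(list(tx$cds))
    expect_lt(abs(pg$gc3 - tx$gc3_target), 0.5)
    expect_lt(abs(pg$gc12 - tx$gc12_target), 0.5)
  }
  expect_error(simulate_taxa_for_neutrality(sim_params(), noise_sd = -1), ">= 0")
})

test_that("the programmed slope sits inside the fitted 95% CI in most replicates", {
  params <- sim_params(seed = 35, n_taxa = 40, gc12_slope = 0.4,
                       gc12_intercept = 25)
  inside <- 0L
  nrep <- 30L
  for (r in seq_len(nrep)) {
    p <- params; p$seed <- params$seed + r
    taxa <- simulate_taxa_for_neutrality(p, noise_sd = 2, n_codons = 600L)
    pts <- t(vapply(taxa, function(tx) {
      pg <- positional_gc(list(tx$cds)); c(pg$gc3, pg$gc12)
    }, numeric(2)))
    fit <- neutrality_regression(pts[, 1], pts[, 2])
    ci <- stats::confint(fit$model)["gc3", ]
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) inside <- inside + 1L
  }
  expect_gte(inside / nrep, 0.9)
})

test_that("tree simulation obeys its limits and saturation expectation", {
  tree <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  a0 <- simulate_alignment_on_tree(tree, 200, seed = 1)
  expect_equal(length(unique(a0)), 1)
  expect_error(simulate_alignment_on_tree(tree, 0), "zero-length")
  # two leaves at large total distance: p-distance near its analytic value
  t2 <- ape::read.tree(text = "(X:1.5,Y:1.5);")
  kappa <- 4
  aln <- simulate_alignment_on_tree(t2, 20000, kappa = kappa, seed = 2)
  d <- 3  # total path length
  e2 <- exp(-4 * d / (kappa + 2)); e1 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  expected_p <- (1 / 4 + e2 / 4 - e1 / 2) + 2 * (1 / 4 - e2 / 4)
  got_p <- pairwise_distance(aln[["X"]], aln[["Y"]], "p")
  expect_lt(abs(got_p - expected_p), 3 * sqrt(expected_p * (1 - expected_p) / 20000))
})
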