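make_gene_set <- function(lens = c(g1 = 300L, g2 = 450L), taxa = c("A", "B")) {
  set.seed(61)
  genes <- lapply(lens, function(L)
    stats::setNames(vapply(taxa, function(t) random_dna(L), character(1)), taxa))
  as_aligned_gene_set(genes)
}

test_that("the 13 canonical PCGs are extracted per taxon in coding orientation", {
  sims <- simulate_taxa(sim_params(seed = 70, n_taxa = 4))
  recs <- lapply(sims, `[[`, "record")
  gs <- extract_pcg_set(recs)
  expect_equal(length(gs$genes), 13)
  expect_true(all(vapply(gs$genes, length, integer(1)) == 4))
  expect_equal(nrow(gs$missing), 0)
  # extracted minor-strand gene equals the emitted coding sequence
  expect_identical(gs$genes[["nad1"]][[recs[[1]]$id]], sims[[1]]$truth$cds[["nad1"]])
  # a record lacking atp8 is flagged
  r2 <- recs[[1]]
  r2$features <- r2$features[r2$features$name != "atp8", ]
  expect_warning(gs2 <- extract_pcg_set(list(r2, recs[[2]])), "atp8")
  expect_equal(gs2$missing$gene, "atp8")
  # a record with no recognizable PCGs errors by name
  r3 <- recs[[1]]
  r3$features <- r3$features[r3$features$kind != "PCG", ]
  expect_error(extract_pcg_set(list(r3)), r3$id)
})

test_that("synonymous gene labels unify through the GenBank reader", {
  rec <- simulate_mitogenome(sim_params(seed = 71), id = "SYN1")$record
  f <- tempfile(fileext = ".gb")
  write_genbank(rec, f)
  txt <- readLines(f)
  txt <- sub('/gene="nad2"', '/gene="ND2"', txt)
  txt <- sub('/gene="cox1"', '/gene="COI"', txt)
  txt <- sub('/gene="cob"', '/gene="CYTB"', txt)
  writeLines(txt, f)
  back <- read_genbank(f)[[1]]
  expect_true(all(c("nad2", "cox1", "cob") %in% back$features$name))
  gs <- extract_pcg_set(list(back))
  expect_equal(length(gs$genes[["nad2"]]), 1)
})

test_that("concatenation produces tiling partitions in gene order", {
  gs <- make_gene_set()
  sm <- concatenate(gs)
  expect_equal(sm$total_length, 750)
  expect_equal(sm$partitions$start, c(1, 301))
  expect_equal(sm$partitions$end, c(300, 750))
  expect_true(all(nchar(sm$matrix) == 750))
  rev_sm <- concatenate(gs, gene_order = c("g2", "g1"))
  expect_equal(rev_sm$partitions$gene, c("g2", "g1"))
  expect_identical(slice_partition(rev_sm, "g1"), slice_partition(sm, "g1"))
  # 13 simulated genes: total length equals the sum of per-gene lengths
  sims <- simulate_taxa(sim_params(seed = 72, n_taxa = 3))
  gs13 <- as_aligned_gene_set(extract_pcg_set(lapply(sims, `[[`, "record")))
  sm13 <- concatenate(gs13)
  expect_equal(sm13$total_length,
               sum(vapply(gs13$genes, function(g) nchar(g[[1]]), integer(1))))
  # slicing at partition bounds reproduces each input alignment exactly
  for (g in names(gs13$genes))
    expect_identical(slice_partition(sm13, g), gs13$genes[[g]][sm13$taxa])
})

test_that("missing taxa are gap-filled or rejected per policy", {
  gs <- make_gene_set()
  gs$genes$g2 <- gs$genes$g2["A"]
  expect_error(concatenate(gs), "missing")
  sm <- concatenate(gs, missing_policy = "gapfill")
  expect_identical(substr(sm$matrix[["B"]], 301, 750), strrep("-", 450))
  # ragged alignments are named
  gr <- make_gene_set()
  gr$genes$g1[["B"]] <- paste0(gr$genes$g1[["B"]], "AC")
  expect_error(as_aligned_gene_set(unclass(gr)$genes), "g1")
})

test_that("pairwise distances follow their closed forms", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_distance("AAAA", "AAAG", "p"), 0.25)
  # construct P = 0.1 transitions, Q = 0.05 transversions over 100 sites
  a <- strrep("A", 100)
  bv <- rep("A", 100); bv[1:10] <- "G"; bv[11:15] <- "C"
  b <- paste(bv, collapse = "")
  got <- pairwise_distance(a, b, "K2P")
  expect_equal(got, -0.5 * log((1 - 2 * 0.1 - 0.05) * sqrt(1 - 2 * 0.05)),
               tolerance = 1e-12)
  # gap/N sites excluded from the denominator
  expect_equal(pairwise_distance("AC-TN", "ACGTA", "p"), 0)
  expect_error(pairwise_distance("NN", "AC"), "zero valid")
  expect_error(pairwise_distance(strrep("A", 10), strrep("G", 10), "K2P"),
               "saturated")
})

test_that("NJ recovers additive trees exactly", {
  # quartet ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tree <- nj_tree(d)
  # topology: AB|CD split present
  expect_true(ape::is.monophyletic(ape::root(tree, "C"), c("A", "B")))
  # path distances on the tree reproduce the input matrix
  path <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, d, tolerance = 1e-9)
  # 3 taxa: the single star resolution with fitted branch lengths
  d3 <- d[1:3, 1:3]
  t3 <- nj_tree(d3)
  expect_equal(length(t3$tip.label), 3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-9)
  # non-symmetric input rejected
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ agrees with UPGMA on ultrametric distances", {
  d <- matrix(8, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  d[1:3, 1:3] <- 4; d[4:6, 4:6] <- 4
  d[1, 2] <- d[2, 1] <- 2; d[4, 5] <- d[5, 4] <- 2
  diag(d) <- 0
  nj <- nj_tree(d)
  up <- ape::as.phylo(stats::hclust(stats::as.dist(d), "average"))
  expect_equal(ape::dist.topo(ape::unroot(up), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
})

test_that("two-clade simulated sequences give monophyletic NJ clades", {
  tree <- ape::read.tree(
    text = "(((A:0.02,B:0.02):0.08,(C:0.02,D:0.02):0.08):0.0);")
  aln <- simulate_alignment_on_tree(tree, 3000, kappa = 4, seed = 9)
  nt <- nj_tree(distance_matrix(aln, "K2P"))
  expect_true(ape::is.monophyletic(ape::root(nt, "C"), c("A", "B")))
  expect_true(ape::is.monophyletic(ape::root(nt, "A"), c("C", "D")))
})

test_that("matrix writers round-trip and agree on partitions", {
  gs <- make_gene_set()
  sm <- concatenate(gs)
  prefix <- file.path(tempdir(), "toy_sm")
  out <- write_matrix(sm, prefix)
  phy <- readLines(out$files[["phylip"]])
  expect_identical(phy[1], "2 750")
  expect_identical(read_phylip(out$files[["phylip"]]),
                   stats::setNames(unname(sm$matrix), c("A", "B")))
  expect_identical(read_fasta(out$files[["fasta"]]),
                   stats::setNames(unname(sm$matrix), c("A", "B")))
  np <- read_nexus_partitions(out$files[["nexus"]])
  expect_equal(np$gene, sm$partitions$gene)
  expect_equal(np$start, sm$partitions$start)
  expect_equal(np$end, sm$partitions$end)
  parts <- readLines(out$files[["partitions"]])
  expect_identical(parts, c("DNA, g1 = 1-300", "DNA, g2 = 301-750"))
  # taxon sanitisation emits a mapping
  sm2 <- sm; sm2$taxa <- c("A sp.", "B/2"); names(sm2$matrix) <- sm2$taxa
  out2 <- write_matrix(sm2, file.path(tempdir(), "toy_sm2"), "fasta")
  expect_identical(unname(out2$name_map), c("A_sp.", "B_2"))
})
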