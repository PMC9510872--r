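test_that("the simulator is fully deterministic under a seed", {
  cfg <- sim_config(seed = 99, n_gaps = 2, copies_per_cluster = 15,
                    satellite_clusters = 2)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(as.character(b1$draft), as.character(b2$draft))
  expect_identical(as.character(b1$donors), as.character(b2$donors))
  expect_identical(b1$monomer_truth, b2$monomer_truth)
  expect_identical(b1$gap_truth, b2$gap_truth)
  # a different seed changes the genome
  b3 <- simulate_bundle(sim_config(seed = 100, n_gaps = 2,
                                   copies_per_cluster = 15,
                                   satellite_clusters = 2))
  expect_false(identical(as.character(b1$genome), as.character(b3$genome)))
})

test_that("truth annotations are internally consistent with the emitted sequences", {
  cfg <- sim_config(seed = 51, n_gaps = 2, copies_per_cluster = 20,
                    satellite_clusters = 4)
  b <- simulate_bundle(cfg)
  g <- as.character(b$genome[["chr1"]])
  mt <- b$monomer_truth
  expect_equal(nrow(mt), 80L)
  expect_equal(sort(unique(mt$cluster)), 1:4)
  # every truth monomer re-extracts from the genome
  for (i in seq_len(nrow(mt)))
    expect_identical(substr(g, mt$start[i] + 1, mt$end[i]), mt$sequence[i])
  # gaps are N-runs in the draft and absent from the truth
  d <- as.character(b$draft[["chr1"]])
  found <- find_gaps(b$draft)
  expect_equal(found$start, b$gap_truth$start)
  expect_equal(found$end, b$gap_truth$end)
  expect_false(grepl("N", g))
  # telomere truth matches the detector
  tel <- find_telomeres(b$genome)
  expect_equal(nrow(tel), 2L)
  expect_equal(sort(tel$start), sort(b$telomere_truth$start))
})

test_that("degrade plants gaps and substitutions as specified", {
  set.seed(1)
  g <- Biostrings::DNAStringSet(c(chr = rand_dna(5000)))
  spec <- data.frame(scaffold_id = "chr", start = 1000L, end = 1500L)
  # no errors: draft equals truth outside the gap
  d0 <- degrade(g, spec, error_rate = 0)
  s0 <- as.character(d0[["chr"]])
  expect_equal(substr(s0, 1001, 1500), strrep("N", 500))
  expect_equal(substr(s0, 1, 1000), substr(as.character(g[[1]]), 1, 1000))
  fg <- find_gaps(d0)
  expect_equal(fg$start, 1000L)
  expect_equal(fg$end, 1500L)
  # with errors: substitution count near the planted rate
  d1 <- degrade(g, spec, error_rate = 0.01, seed = 3)
  diffs <- sum(strsplit(as.character(d1[["chr"]]), "")[[1]] !=
                 strsplit(as.character(g[[1]]), "")[[1]])
  expect_gt(diffs, 500 + 10)   # 500 N bases plus ~45 substitutions
  expect_lt(diffs, 500 + 100)
  # overlapping gaps are rejected
  bad <- rbind(spec, data.frame(scaffold_id = "chr", start = 1400L,
                                end = 1600L))
  expect_error(degrade(g, bad), "overlapping")
})

test_that("a written bundle round-trips through the standard formats", {
  cfg <- sim_config(seed = 77, n_gaps = 1, copies_per_cluster = 10,
                    satellite_clusters = 2)
  b <- simulate_bundle(cfg)
  dir <- file.path(tempdir(), "bundle_test")
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "truth_genome.fa", "draft.fa", "donors.fa", "anchors.fa",
    "monomer_truth.bed", "gap_truth.bed", "telomere_truth.tsv",
    "manifest.json")))))
  g <- read_fasta(file.path(dir, "truth_genome.fa"))
  expect_identical(as.character(g[["chr1"]]),
                   as.character(b$genome[["chr1"]]))
  mb <- read_bed(file.path(dir, "monomer_truth.bed"))
  expect_equal(nrow(mb), nrow(b$monomer_truth))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 77L)
  unlink(dir, recursive = TRUE)
})

test_that("infeasible configurations are rejected with a named constraint", {
  expect_error(simulate_bundle(sim_config(seed = 1, n_gaps = 50,
                                          copies_per_cluster = 5,
                                          satellite_clusters = 2)),
               "infeasible|too many gaps")
})
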