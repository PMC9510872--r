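test_that("the bundled centromeric satellite consensus is 178 bp with standard gates", {
  cons <- cen180_consensus()
  expect_equal(nchar(cons$seq), 178L)
  expect_equal(cons$length_range, c(165, 185))
  expect_equal(cons$min_query_coverage, 0.90)
})

test_that("a single embedded consensus copy is found as one full-length monomer", {
  set.seed(2)
  cons <- cen180_consensus()
  genome <- c(chr = paste0(rand_dna(500), cons$seq, rand_dna(500)))
  mon <- find_monomers(genome, cons)
  expect_equal(nrow(mon), 1L)
  expect_equal(mon$length, 178L)
  expect_equal(mon$start, 500L)
  expect_equal(mon$identity, 1.0)
  expect_equal(mon$sequence, cons$seq)
})

test_that("tandem arrays decompose into tiling monomers matching the planted copy number", {
  set.seed(4)
  cons <- cen180_consensus()
  copies <- vapply(1:60, function(i) mutate_seq(cons$seq, n_subs = 3), "")
  genome <- c(chr = paste0(rand_dna(300), paste(copies, collapse = ""),
                           rand_dna(300)))
  mon <- find_monomers(genome, cons)
  expect_equal(nrow(mon), 60L)
  expect_true(all(mon$length >= 165 & mon$length <= 185))
  # tiling: consecutive monomers adjacent within 2 bp
  gaps <- mon$start[-1] - mon$end[-nrow(mon)]
  expect_true(all(abs(gaps) <= 2))
  # strand invariance: the reverse complement yields the mirrored set
  mon_rc <- find_monomers(c(chr = revcomp(genome[[1]])), cons)
  expect_equal(nrow(mon_rc), 60L)
  L <- nchar(genome[[1]])
  expect_equal(sort(L - mon_rc$end), sort(mon$start))
  expect_setequal(mon_rc$strand, "-")
})

test_that("truncated copies below the coverage gate are excluded", {
  set.seed(6)
  cons <- cen180_consensus()
  trunc <- substr(cons$seq, 1, floor(0.8 * 178))  # 80% of the consensus
  genome <- c(chr = paste0(rand_dna(400), trunc, rand_dna(400)))
  expect_equal(nrow(find_monomers(genome, cons)), 0L)
})

test_that("consensus-anchored alignment projects monomers onto consensus columns", {
  cons <- cen180_consensus()
  m1 <- cons$seq
  m2 <- mutate_seq(cons$seq, positions = c(10, 50))
  # 2 bp deletion at consensus columns 100-101
  m3 <- paste0(substr(cons$seq, 1, 99), substr(cons$seq, 102, 178))
  aln <- build_monomer_alignment(c(m1, m2, m3), cons)
  expect_equal(dim(aln$matrix), c(3L, 178L))
  expect_equal(paste(aln$matrix[1, ], collapse = ""), cons$seq)
  expect_equal(aln$matrix[3, 100:101], c("-", "-"))
  # row-degap invariant: gaps removed reproduce each monomer
  for (i in 1:3) {
    row <- aln$matrix[i, ]
    expect_equal(paste(row[row != "-"], collapse = ""), c(m1, m2, m3)[i])
  }
  # planted variant alleles appear at the planted columns
  expect_true(aln$matrix[2, 10] != substr(cons$seq, 10, 10))
  expect_equal(paste(aln$matrix[2, -c(10, 50)], collapse = ""),
               paste(strsplit(cons$seq, "")[[1]][-c(10, 50)], collapse = ""))
})

test_that("divergent sequences are excluded from the alignment with a warning", {
  set.seed(8)
  cons <- cen180_consensus()
  expect_warning(
    aln <- build_monomer_alignment(c(cons$seq, cons$seq, rand_dna(178)),
                                   cons),
    "excluded")
  expect_equal(nrow(aln$matrix), 2L)
  expect_equal(aln$excluded, 3L)
})

test_that("two planted monomer families are recovered with K_star = 2", {
  set.seed(10)
  cons <- cen180_consensus()
  fam <- vapply(1:2, function(k) mutate_seq(cons$seq, n_subs = 10), "")
  seqs <- c(vapply(1:100, function(i) mutate_seq(fam[1], rate = 0.005), ""),
            vapply(1:100, function(i) mutate_seq(fam[2], rate = 0.005), ""))
  truth <- rep(1:2, each = 100)
  aln <- build_monomer_alignment(seqs, cons)
  cl <- cluster_monomers(aln, K_range = 2:10, seed = 3)
  expect_equal(cl$K_star, 2L)
  expect_gte(label_agreement(cl$labels, truth), 0.99)
})

test_that("clustering is deterministic under a seed and stable to row permutation", {
  set.seed(12)
  cons <- cen180_consensus()
  fam <- vapply(1:3, function(k) mutate_seq(cons$seq, n_subs = 8), "")
  seqs <- unlist(lapply(1:3, function(k)
    vapply(1:40, function(i) mutate_seq(fam[k], rate = 0.004), "")))
  aln <- build_monomer_alignment(seqs, cons)
  cl1 <- cluster_monomers(aln, seed = 9)
  cl2 <- cluster_monomers(aln, seed = 9)
  expect_identical(cl1$labels, cl2$labels)
  expect_identical(cl1$bic, cl2$bic)
  # permuting rows changes labels only up to relabeling
  perm <- sample(length(seqs))
  aln_p <- build_monomer_alignment(seqs[perm], cons)
  cl_p <- cluster_monomers(aln_p, seed = 9)
  expect_equal(label_agreement(cl_p$labels, cl1$labels[perm]), 1)
  # log-likelihood is non-decreasing in K on the same data
  expect_true(all(diff(cl1$log_likelihood) > -1e-6))
})

test_that("identical rows short-circuit to the degenerate single-cluster result", {
  cons <- cen180_consensus()
  aln <- build_monomer_alignment(rep(cons$seq, 5), cons)
  cl <- cluster_monomers(aln, K_range = 2:5, seed = 1)
  expect_true(cl$degenerate)
  expect_equal(cl$K_star, 2L)
  expect_equal(length(unique(cl$labels)), 1L)
})

test_that("windowed identity heatmaps separate homogeneous and divergent arrays", {
  set.seed(14)
  cons <- cen180_consensus()$seq
  # homogeneous perfect tandem array: all entries 1
  arr <- strrep(cons, 12)
  M <- identity_heatmap(arr, window = 500)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= 0.99))
  # two arrays at ~5% divergence: within-array high, cross-array ~0.95
  consB <- mutate_seq(cons, n_subs = 9)          # ~5% of 178
  region <- paste0(strrep(cons, 8), strrep(consB, 8))
  M2 <- identity_heatmap(region, window = 700)
  nw <- nrow(M2)
  half <- nw %/% 2
  within <- c(M2[1:half, 1:half][upper.tri(M2[1:half, 1:half])],
              M2[(half + 1):nw, (half + 1):nw][
                upper.tri(M2[(half + 1):nw, (half + 1):nw])])
  cross <- M2[1:half, (half + 1):nw]
  expect_true(all(within > 0.99))
  expect_lt(abs(mean(cross) - 0.95), 0.011)
  # random non-repetitive sequence: off-diagonal entries are 0
  M3 <- identity_heatmap(rand_dna(2000), window = 500)
  expect_true(all(M3[upper.tri(M3)] == 0))
})
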