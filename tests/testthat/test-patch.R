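test_that("find_gaps reports maximal N-runs at or above the minimum length", {
  expect_equal(nrow(find_gaps(c(s = "ACGT"))), 0L)
  g <- find_gaps(c(s = paste0("AC", strrep("N", 50), "GT")), min_n_run = 10)
  expect_equal(g$start, 2L)
  expect_equal(g$end, 52L)
  expect_equal(g$n_run_length, 50L)
  g2 <- find_gaps(c(s = paste0("A", strrep("N", 10), "C",
                               strrep("N", 10), "G")), min_n_run = 10)
  expect_equal(nrow(g2), 2L)
  expect_equal(g2$start, c(1L, 12L))
  # short runs below the minimum are not gaps
  expect_equal(nrow(find_gaps(c(s = "ACGNNNNACGT"), min_n_run = 10)), 0L)
})

test_that("anchor pairs are selected when concordant and rejected below the identity gate", {
  cfg <- sim_config(seed = 13, n_gaps = 1, copies_per_cluster = 20,
                    satellite_clusters = 2)
  b <- simulate_bundle(cfg)
  gap <- find_gaps(b$draft)[1, ]
  pair <- select_anchor_pair(gap, b$anchors, b$draft, b$donors)
  expect_false(is.null(pair))
  expect_equal(pair$orientation, "same")
  expect_equal(pair$left_anchor_id, "gap1_L")
  expect_equal(pair$right_anchor_id, "gap1_R")
  expect_gte(pair$draft_hits$left$identity, 0.999)

  # anchors mutated to ~99.8% identity fail the > 99.9% gate
  set.seed(5)
  bad <- as.character(b$anchors)
  bad <- vapply(bad, function(a) mutate_seq(a, n_subs = 2), "")
  names(bad) <- names(b$anchors)
  pair_bad <- select_anchor_pair(gap, bad, b$draft, b$donors)
  expect_null(pair_bad)
})

test_that("inverted donors are detected and patched back to the truth", {
  cfg <- sim_config(seed = 17, n_gaps = 2, copies_per_cluster = 20,
                    satellite_clusters = 2, invert_donors = TRUE)
  b <- simulate_bundle(cfg)
  res <- patch_all(b$draft, b$donors, b$anchors)
  expect_true(all(res$report$orientation == "inverted"))
  expect_identical(as.character(res$assembly[["chr1"]]),
                   as.character(b$genome[["chr1"]]))
})

test_that("apply_patch splices exactly and builds a consistent liftover", {
  set.seed(29)
  s <- rand_dna(400)
  draft <- c(chr = paste0(substr(s, 1, 100), strrep("N", 100),
                          substr(s, 201, 400)))
  donor <- c(d = paste0(substr(s, 51, 250), "ACGTACGTAC",
                        substr(s, 251, 350)))
  # replace draft [100,200) with donor [50,260): 100 bp -> 210 bp (+110)
  plan <- structure(list(
    scaffold_id = "chr", replaced_span = c(start = 100L, end = 200L),
    donor_id = "d", donor_span = c(start = 50L, end = 260L),
    donor_orientation = "same", mode = "span",
    provenance = list(),
    flank_check = list(left = unname(substr(draft, 81, 100)),
                       right = unname(substr(draft, 201, 220)))),
    class = "patch_plan")
  res <- apply_patch(draft, donor, plan)
  out <- as.character(res$assembly[["chr"]])
  expect_equal(nchar(out), 400 + 110)
  # conservation outside the replaced span
  expect_equal(substr(out, 1, 100), substr(s, 1, 100))
  expect_equal(substr(out, 311, 510), substr(s, 201, 400))
  # liftover: downstream offset equals the length change
  lift <- res$liftover
  expect_equal(lift$new_start[3] - lift$old_start[3], 110L)
  expect_equal(lift_position(lift, "chr", c(0, 99, 250)),
               c(0L, 99L, 360L))
  expect_true(is.na(lift_position(lift, "chr", 150)))
  # identity patch: donor span identical to replaced span
  plan2 <- plan
  plan2$donor_span <- c(start = 50L, end = 150L)
  donor2 <- c(d = paste0(substr(s, 51, 100), strrep("N", 0),
                         substr(draft, 101, 200), substr(s, 201, 250)))
  # stale plan: draft edited since planning
  draft2 <- draft
  substr(draft2, 90, 90) <- if (substr(draft2, 90, 90) == "A") "C" else "A"
  expect_error(apply_patch(draft2, donor, plan), "stale")
})

test_that("patch_all reconstructs a gapped simulated genome byte-exactly", {
  cfg <- sim_config(seed = 7, n_gaps = 3, copies_per_cluster = 20,
                    satellite_clusters = 2)
  b <- simulate_bundle(cfg)
  res <- patch_all(b$draft, b$donors, b$anchors)
  expect_equal(nrow(res$remaining_gaps), 0L)
  expect_equal(sum(res$report$status == "filled"), 3L)
  expect_identical(as.character(res$assembly[["chr1"]]),
                   as.character(b$genome[["chr1"]]))
  # idempotence: re-running on the patched, gap-free assembly is a no-op
  res2 <- patch_all(res$assembly, b$donors, b$anchors)
  expect_identical(as.character(res2$assembly[["chr1"]]),
                   as.character(res$assembly[["chr1"]]))
  expect_equal(nrow(res2$report), 0L)
})

test_that("gaps without donor coverage remain unfilled; empty anchors change nothing", {
  cfg <- sim_config(seed = 19, n_gaps = 3, copies_per_cluster = 20,
                    satellite_clusters = 2)
  b <- simulate_bundle(cfg)
  donors_partial <- b$donors["donor1"]
  res <- patch_all(b$draft, donors_partial, b$anchors)
  expect_equal(sum(res$report$status == "filled"), 1L)
  expect_equal(nrow(res$remaining_gaps), 2L)
  expect_equal(res$remaining_gaps$start, b$gap_truth$start[2:3])

  res0 <- patch_all(b$draft, b$donors, Biostrings::DNAStringSet())
  expect_identical(as.character(res0$assembly[["chr1"]]),
                   as.character(b$draft[["chr1"]]))
  expect_true(all(res0$report$status == "unfilled"))
})

test_that("whole-contig mode replaces the scaffold with the donor contig", {
  cfg <- sim_config(seed = 23, n_gaps = 1, copies_per_cluster = 15,
                    satellite_clusters = 2)
  b <- simulate_bundle(cfg)
  res <- patch_all(b$draft, b$donors, b$anchors, mode = "whole_contig")
  expect_identical(as.character(res$assembly[["chr1"]]),
                   as.character(b$donors[["donor1"]]))
  expect_equal(nrow(res$remaining_gaps), 0L)
})
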