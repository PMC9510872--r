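test_that("methylation calls aggregate per site with duplicate handling", {
  calls <- data.frame(
    seq_id = "chr1",
    pos = rep(c(100L, 200L), c(10L, 4L)),
    read_id = c(paste0("r", 1:10), paste0("s", 1:4)),
    methylated = c(rep(c(TRUE, FALSE), 5), TRUE, TRUE, TRUE, FALSE))
  sites <- methylation_frequency(calls)
  expect_equal(sites$pos, c(100L, 200L))
  expect_equal(sites$frequency, c(0.5, 0.75))
  expect_equal(sites$total_reads, c(10L, 4L))
  dup <- rbind(calls, calls[1, ])
  expect_warning(sites2 <- methylation_frequency(dup), "duplicate")
  expect_equal(sites2$total_reads, c(10L, 4L))
})

test_that("region summaries use the strict >0.8 high-methylation rule", {
  sites <- data.frame(seq_id = "chr1", pos = c(10L, 20L, 30L, 40L),
                      methylated_reads = c(9L, 7L, 8L, 8L),
                      total_reads = 10L,
                      frequency = c(0.9, 0.7, 0.8, 0.8))
  s1 <- summarize_regions(sites, data.frame(seq_id = "chr1", start = 0L,
                                            end = 25L, name = "r1"))
  expect_equal(s1$mean_frequency, 0.8)
  expect_equal(s1$fraction_sites_above_threshold, 0.5)
  # sites exactly at the threshold do not count (strict inequality)
  s2 <- summarize_regions(sites, data.frame(seq_id = "chr1", start = 25L,
                                            end = 50L, name = "r2"))
  expect_equal(s2$fraction_sites_above_threshold, 0)
  # empty region flagged with NA means
  s3 <- summarize_regions(sites, data.frame(seq_id = "chr1", start = 500L,
                                            end = 600L, name = "r3"))
  expect_true(s3$flagged)
  expect_equal(s3$site_count, 0L)
  expect_true(is.na(s3$mean_frequency))
})

test_that("a planted hypomethylated block is recovered within 0.05", {
  sim <- sim_methylation(20000, blocks = data.frame(start = 5000,
                                                    end = 10000),
                         background_freq = 0.9, block_freq = 0.2,
                         coverage = 30, seed = 21)
  sites <- methylation_frequency(sim$calls)
  regs <- data.frame(seq_id = "chr1",
                     start = c(0L, 5000L, 10000L),
                     end = c(5000L, 10000L, 20000L),
                     name = c("bg1", "block", "bg2"))
  summ <- summarize_regions(sites, regs)
  expect_lt(abs(summ$mean_frequency[summ$region == "block"] - 0.2), 0.05)
  expect_gt(summ$mean_frequency[summ$region == "bg1"],
            summ$mean_frequency[summ$region == "block"])
  expect_gt(summ$mean_frequency[summ$region == "bg2"],
            summ$mean_frequency[summ$region == "block"])
})

test_that("uniform ChIP samples give enrichment ~1 and scaling cancels", {
  cr <- data.frame(seq_id = "chr1", start = c(0L, 2000L),
                   end = c(1000L, 3000L), name = c("c1", "c2"))
  set.seed(5)
  mk_reads <- function(n) {
    mid <- sample(0:2999, n, replace = TRUE)
    data.frame(seq_id = "chr1", start = pmax(0L, mid - 50L),
               end = pmax(0L, mid - 50L) + 100L)
  }
  tr <- mk_reads(20000); ct <- mk_reads(20000)
  enr <- chip_cluster_enrichment(tr, ct, cr)
  expect_true(all(abs(enr$enrichment_ratio - 1) < 0.1))
  # conservation: per-cluster counts sum to reads with midpoints in regions
  mid <- (tr$start + tr$end) / 2
  in_any <- (mid >= 0 & mid < 1000) | (mid >= 2000 & mid < 3000)
  expect_equal(sum(enr$treatment_count), sum(in_any))
  # scale invariance: tripling both samples leaves ratios unchanged (< 1%)
  enr3 <- chip_cluster_enrichment(tr[rep(1:nrow(tr), 3), ],
                                  ct[rep(1:nrow(ct), 3), ], cr)
  expect_true(all(abs(enr3$enrichment_ratio / enr$enrichment_ratio - 1)
                  < 0.01))
  expect_error(chip_cluster_enrichment(tr[0, ], ct, cr), "zero total")
})

test_that("a 3x binding preference on cluster 3 is recovered near 3 and in rank order", {
  cr <- data.frame(seq_id = "chr1",
                   start = c(10000L, 30000L, 50000L, 70000L),
                   end = c(15000L, 35000L, 55000L, 75000L),
                   name = paste0("cluster", 1:4))
  reads <- sim_chip_reads(200000, cr, weights = c(1, 1, 3, 1),
                          n_reads = 50000, seed = 11)
  enr <- chip_cluster_enrichment(reads$treatment, reads$control, cr)
  r3 <- enr$enrichment_ratio[enr$region == "cluster3"]
  expect_lt(abs(r3 - 3) / 3, 0.15)
  expect_true(all(enr$enrichment_ratio[enr$region != "cluster3"] < r3))
})

test_that("an empty cluster region falls back to the pseudocount ratio and is flagged", {
  cr <- data.frame(seq_id = "chr1", start = c(0L, 5000L),
                   end = c(1000L, 6000L), name = c("c1", "empty"))
  tr <- data.frame(seq_id = "chr1", start = c(100L, 200L), end = c(200L, 300L))
  ct <- data.frame(seq_id = "chr1", start = c(150L, 250L), end = c(250L, 350L))
  enr <- chip_cluster_enrichment(tr, ct, cr)
  e <- enr[enr$region == "empty", ]
  expect_true(e$flagged)
  expect_equal(e$enrichment_ratio, 1)   # 0.5 / 0.5
})
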