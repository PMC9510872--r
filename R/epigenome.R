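#' Aggregate per-read methylation calls into site frequencies
#'
#' Calls are rows of (position, read id, methylated flag), optionally with
#' a `seq_id`. Plus- and minus-strand calls at a CpG are expected to be
#' pooled upstream (symmetric CpG aggregation). Duplicate
#' (position, read_id) rows keep the first occurrence with a warning.
#'
#' @param calls data.frame with columns `pos` (0-based), `read_id`,
#'   `methylated` (logical/0-1), and optionally `seq_id`
#' @return data.frame with `seq_id`, `pos`, `methylated_reads`,
#'   `total_reads`, `frequency`, ordered by sequence then position; sites
#'   with zero reads are absent by construction
#' @export
methylation_frequency <- function(calls) {
  stopifnot(all(c("pos", "read_id", "methylated") %in% names(calls)))
  df <- as.data.frame(calls)
  if (!"seq_id" %in% names(df)) df$seq_id <- "seq"
  dup <- duplicated(df[, c("seq_id", "pos", "read_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (position, read) call(s); keeping first")
    df <- df[!dup, ]
  }
  key <- interaction(df$seq_id, df$pos, drop = TRUE, lex.order = TRUE)
  meth <- tapply(as.logical(df$methylated), key, sum)
  tot <- tapply(df$methylated, key, length)
  first <- !duplicated(key)
  out <- data.frame(seq_id = df$seq_id[first], pos = df$pos[first],
                    stringsAsFactors = FALSE)
  k1 <- key[first]
  out$methylated_reads <- as.integer(meth[as.character(k1)])
  out$total_reads <- as.integer(tot[as.character(k1)])
  out$frequency <- out$methylated_reads / out$total_reads
  out <- out[order(out$seq_id, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Summarize methylation over regions or clusters
#'
#' Per region: the mean site frequency and the fraction of sites with
#' frequency strictly above `threshold` (the "> 0.8" convention used for
#' centromeric CpG tracks).
#'
#' @param sites data.frame from [methylation_frequency()]
#' @param regions data.frame with `seq_id`, `start`, `end` (0-based
#'   half-open) and optionally `name` (region/cluster label)
#' @param threshold strict lower bound for the high-methylation fraction
#'   (default 0.8)
#' @return data.frame with `region`, `seq_id`, `start`, `end`,
#'   `site_count`, `mean_frequency`, `fraction_sites_above_threshold`;
#'   regions with no sites get `NA` means and a `flagged` mark
#' @export
summarize_regions <- function(sites, regions, threshold = 0.8) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(regions)))
  nm <- if ("name" %in% names(regions)) as.character(regions$name)
  else paste0("region", seq_len(nrow(regions)))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sel <- sites$seq_id == r$seq_id & sites$pos >= r$start & sites$pos < r$end
    f <- sites$frequency[sel]
    data.frame(region = nm[i], seq_id = r$seq_id, start = r$start,
               end = r$end, site_count = length(f),
               mean_frequency = if (length(f)) mean(f) else NA_real_,
               fraction_sites_above_threshold =
                 if (length(f)) mean(f > threshold) else NA_real_,
               flagged = length(f) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' ChIP enrichment per satellite cluster
#'
#' Counts treatment and control reads per cluster region (a read belongs
#' to a region iff its midpoint falls inside it), converts counts to CPM
#' using each sample's total supplied read count as the denominator, and
#' reports the pseudocount-stabilised enrichment ratio
#' `(treatment CPM + pseudocount) / (control CPM + pseudocount)`.
#'
#' @param treatment_reads,control_reads data.frames of read intervals
#'   (`seq_id`, `start`, `end`, 0-based half-open)
#' @param cluster_regions data.frame with `seq_id`, `start`, `end` and
#'   optionally `name` (cluster label)
#' @param pseudocount CPM pseudocount (default 0.5)
#' @return data.frame with `region`, `treatment_count`, `control_count`,
#'   `chip_treatment_cpm`, `chip_control_cpm`, `enrichment_ratio`,
#'   `flagged` (TRUE when a region has zero reads in either sample)
#' @export
chip_cluster_enrichment <- function(treatment_reads, control_reads,
                                    cluster_regions, pseudocount = 0.5) {
  n_t <- nrow(treatment_reads); n_c <- nrow(control_reads)
  if (n_t == 0L || n_c == 0L) stop("zero total reads in a sample")
  nm <- if ("name" %in% names(cluster_regions))
    as.character(cluster_regions$name)
  else paste0("cluster", seq_len(nrow(cluster_regions)))
  count_in <- function(reads, r) {
    mid <- (reads$start + reads$end) / 2
    sum(reads$seq_id == r$seq_id & mid >= r$start & mid < r$end)
  }
  out <- lapply(seq_len(nrow(cluster_regions)), function(i) {
    r <- cluster_regions[i, ]
    tc <- count_in(treatment_reads, r)
    cc <- count_in(control_reads, r)
    t_cpm <- tc / n_t * 1e6
    c_cpm <- cc / n_c * 1e6
    data.frame(region = nm[i], treatment_count = tc, control_count = cc,
               chip_treatment_cpm = t_cpm, chip_control_cpm = c_cpm,
               enrichment_ratio = (t_cpm + pseudocount) / (c_cpm + pseudocount),
               flagged = tc == 0L || cc == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
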