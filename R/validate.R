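#' Clone-based structural validation
#'
#' A clone (BAC-like sequence with independently determined sequence) is
#' "resolved" by an assembly when at least `resolve_threshold` of its
#' length aligns to a single contig. Aligned bases are counted on the
#' clone axis after merging overlapping hit intervals per contig, so
#' tandem-repeat multi-hits cannot inflate coverage.
#'
#' @param clone a single sequence (character, DNAString or length-1
#'   DNAStringSet)
#' @param assembly named [Biostrings::DNAStringSet] of contigs
#' @param resolve_threshold minimum aligned fraction (default 0.995,
#'   compared inclusively)
#' @param min_hit_identity,min_hit_length filters on individual alignment
#'   hits before coverage is accumulated
#' @param hits optional precomputed hit data.frame (as from
#'   [align_local()], with a `target_id` column naming the contig); when
#'   supplied the aligner is not run
#' @return list of class `clone_verdict`: `clone_id`, `clone_length`,
#'   `best_contig`, `best_single_contig_aligned`, `aligned_fraction`,
#'   `resolved`, `primary_identity`
#' @export
clone_resolve <- function(clone, assembly, resolve_threshold = 0.995,
                          min_hit_identity = 0.9, min_hit_length = 50L,
                          hits = NULL) {
  cl <- as_seq_chr(clone, "clone")
  clone_len <- unname(nchar(cl))
  stopifnot(clone_len > 0L)
  if (is.null(hits)) {
    assembly <- as_seq_set(assembly, "contig")
    hits <- do.call(rbind, lapply(names(assembly), function(cid)
      align_local(stats::setNames(unname(cl), names(cl)), assembly[cid],
                  min_identity = min_hit_identity,
                  min_length = min_hit_length)))
  }
  if (is.null(hits) || nrow(hits) == 0L)
    return(clone_verdict(names(cl), clone_len, NA_character_, 0L, 0,
                         resolve_threshold, NA_real_))
  per_contig <- vapply(split(hits, hits$target_id), function(h) {
    ir <- IRanges::reduce(IRanges::IRanges(start = h$q_start + 1L,
                                           end = h$q_end))
    sum(IRanges::width(ir))
  }, integer(1))
  best <- names(per_contig)[which.max(per_contig)]
  aligned <- max(per_contig)
  primary <- hits[order(-hits$score), ][1L, ]
  clone_verdict(names(cl), clone_len, best, aligned, aligned / clone_len,
                resolve_threshold, primary$identity)
}

clone_verdict <- function(clone_id, clone_length, best_contig, aligned,
                          fraction, threshold, primary_identity) {
  structure(list(
    clone_id = clone_id, clone_length = clone_length,
    best_contig = best_contig,
    best_single_contig_aligned = as.integer(aligned),
    aligned_fraction = fraction,
    resolved = fraction >= threshold,
    resolve_threshold = threshold,
    primary_identity = primary_identity), class = "clone_verdict")
}

#' Clone resolution rate
#'
#' Percentage of clones resolved by the assembly, rounded half-up to two
#' decimals (e.g. 1427 of 1465 gives 97.41).
#'
#' @param verdicts list of `clone_verdict` objects, or a logical vector of
#'   resolved flags
#' @return percentage with two decimals
#' @export
resolution_rate <- function(verdicts) {
  resolved <- if (is.logical(verdicts)) verdicts
  else vapply(verdicts, function(v) isTRUE(v$resolved), TRUE)
  if (length(resolved) == 0L) stop("no verdicts supplied")
  round_half_up(100 * sum(resolved) / length(resolved), 2)
}

#' Mean identity of primary clone alignments
#'
#' For each clone the primary (highest-score) hit is taken; identities are
#' averaged across clones, weighted by clone length by default (set
#' `weighted = FALSE` for the unweighted mean; both are legitimate
#' summaries and they coincide for equal-length clones).
#'
#' @param identities numeric vector of primary-hit identities, one per clone
#' @param lengths clone lengths (same order); required when `weighted`
#' @param weighted length-weight the mean (default TRUE)
#' @return identity fraction
#' @export
mean_identity <- function(identities, lengths = NULL, weighted = TRUE) {
  stopifnot(is.numeric(identities), length(identities) > 0L)
  if (!weighted) return(mean(identities))
  stopifnot(!is.null(lengths), length(lengths) == length(identities))
  sum(identities * lengths) / sum(lengths)
}

#' Validate a set of clones against an assembly
#'
#' @param clones named DNAStringSet of clone sequences
#' @param assembly named DNAStringSet of contigs
#' @param ... passed to [clone_resolve()]
#' @return list with `table` (one row per clone), `rate` (resolution
#'   percentage), `mean_identity_weighted`, `mean_identity_unweighted`
#' @export
validate_clones <- function(clones, assembly, ...) {
  clones <- as_seq_set(clones, "clone")
  verdicts <- lapply(names(clones), function(id)
    clone_resolve(clones[id], assembly, ...))
  tab <- do.call(rbind, lapply(verdicts, function(v)
    data.frame(clone_id = v$clone_id, clone_length = v$clone_length,
               best_contig = v$best_contig,
               aligned = v$best_single_contig_aligned,
               aligned_fraction = v$aligned_fraction,
               resolved = v$resolved,
               primary_identity = v$primary_identity,
               stringsAsFactors = FALSE)))
  ok <- !is.na(tab$primary_identity)
  list(table = tab,
       rate = resolution_rate(tab$resolved),
       mean_identity_weighted = if (any(ok))
         mean_identity(tab$primary_identity[ok], tab$clone_length[ok])
       else NA_real_,
       mean_identity_unweighted = if (any(ok))
         mean_identity(tab$primary_identity[ok], weighted = FALSE)
       else NA_real_)
}
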