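#' Pairwise local alignment
#'
#' Seed-and-extend local aligner shared by anchoring, clone validation and
#' satellite monomer detection. Exact k-mer seeds locate candidate loci on
#' both strands; each locus is then aligned with a full affine-gap
#' Smith-Waterman (Gotoh) restricted to a window around the seeds, yielding
#' base-level CIGARs. Identity is column-inclusive ("BLAST identity"):
#' matched columns divided by all alignment columns including inserted and
#' deleted bases, so the value is always recomputable from the CIGAR.
#'
#' Hits are sorted by score (descending), ties broken by leftmost target
#' start, then `+` strand first. For a `-` strand hit, query coordinates
#' refer to the forward query; the CIGAR describes the reverse-complemented
#' query walked along the forward target.
#'
#' @param query,target sequences (character scalar, [Biostrings::DNAString],
#'   or length-1 [Biostrings::DNAStringSet]); names become hit ids
#' @param min_identity minimum hit identity in `[0,1]`
#' @param min_length minimum alignment columns per hit (default 30, twice
#'   the seed length, which suppresses chance micro-alignments)
#' @param k_seed exact seed length (default 15)
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`;
#'   a gap of length L costs `gap_open + L * gap_ext`
#' @param both_strands search the reverse strand too (default TRUE)
#' @param max_hits keep at most this many hits (default unlimited)
#' @param extend_full_query extend each hit outward so the whole query is
#'   covered where the target allows, scoring the extension columns as
#'   match/mismatch (no indels). Used for satellite monomer decomposition,
#'   where local alignment would otherwise clip copies whose terminal
#'   bases are substituted
#' @return data.frame of hits with columns `query_id`, `target_id`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open),
#'   `q_core_start`, `q_core_end` (the query span before any full-query
#'   extension), `strand`, `identity`, `aligned_columns`, `matches`,
#'   `mismatches`, `cigar`, `score`; zero rows when nothing qualifies
#' @export
align_local <- function(query, target, min_identity = 0, min_length = 30L,
                        k_seed = 15L, scoring = default_scoring(),
                        both_strands = TRUE, max_hits = Inf,
                        extend_full_query = FALSE) {
  q <- as_seq_chr(query, "query")
  t <- as_seq_chr(target, "target")
  stopifnot(nchar(q) > 0L, nchar(t) > 0L)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- list()
  for (st in strands) {
    qs <- if (st == "+") q else revcomp(q)
    hits[[st]] <- strand_hits(unname(qs), unname(t), st, k_seed, scoring,
                              extend_full_query)
  }
  df <- do.call(rbind, hits)
  if (is.null(df) || nrow(df) == 0L) return(empty_hits(names(q), names(t)))
  # map minus-strand query coords back to forward query
  qlen <- nchar(q)
  minus <- df$strand == "-"
  if (any(minus)) {
    qs2 <- qlen - df$q_end[minus]
    qe2 <- qlen - df$q_start[minus]
    df$q_start[minus] <- qs2
    df$q_end[minus] <- qe2
    cs2 <- qlen - df$q_core_end[minus]
    ce2 <- qlen - df$q_core_start[minus]
    df$q_core_start[minus] <- cs2
    df$q_core_end[minus] <- ce2
  }
  df$query_id <- names(q)
  df$target_id <- names(t)
  df <- dedupe_hits(df)
  df <- df[df$identity >= min_identity & df$aligned_columns >= min_length, ,
           drop = FALSE]
  df <- df[order(-df$score, df$t_start, df$strand), , drop = FALSE]
  if (nrow(df) > max_hits) df <- df[seq_len(max_hits), , drop = FALSE]
  rownames(df) <- NULL
  df[, hit_cols()]
}

#' @rdname align_local
#' @export
default_scoring <- function() {
  list(match = 1L, mismatch = -2L, gap_open = 3L, gap_ext = 1L)
}

hit_cols <- function() {
  c("query_id", "target_id", "q_start", "q_end", "t_start", "t_end",
    "q_core_start", "q_core_end", "strand", "identity", "aligned_columns",
    "matches", "mismatches", "cigar", "score")
}

empty_hits <- function(qid = character(), tid = character()) {
  data.frame(query_id = character(), target_id = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             q_core_start = integer(), q_core_end = integer(),
             strand = character(), identity = numeric(),
             aligned_columns = integer(), matches = integer(),
             mismatches = integer(), cigar = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

# hits for one query orientation against the forward target
strand_hits <- function(qs, ts, strand, k_seed, scoring,
                        extend_full_query = FALSE) {
  qlen <- nchar(qs); tlen <- nchar(ts)
  seeds <- .find_seeds_cpp(qs, ts, as.integer(min(k_seed, max(4L, qlen))))
  loci <- if (nrow(seeds) > 0L) cluster_seeds(seeds, qlen, k_seed) else NULL
  if (is.null(loci)) {
    # no seeds: fall back to one full DP only on small problems, so short
    # or highly divergent pairs still get their best local alignment
    # without paying quadratic time on long seedless (i.e. unrelated)
    # sequence pairs
    if (as.numeric(qlen + 1) * (tlen + 1) > 4.5e6) return(NULL)
    loci <- data.frame(w_start = 0L, w_end = tlen)
  }
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    ws <- loci$w_start[i]; we <- loci$w_end[i]
    al <- .sw_align_cpp(qs, substr(ts, ws + 1L, we),
                        scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_ext)
    if (!isTRUE(al$found)) next
    al$t_start <- al$t_start + ws
    al$t_end <- al$t_end + ws
    core <- c(al$q_start, al$q_end)
    if (extend_full_query) al <- extend_alignment(al, qs, ts, scoring)
    cols <- al$matches + al$mismatches + al$insertions + al$deletions
    out[[i]] <- data.frame(
      q_start = al$q_start, q_end = al$q_end,
      t_start = al$t_start, t_end = al$t_end,
      q_core_start = core[1], q_core_end = core[2],
      strand = strand,
      identity = al$matches / cols,
      aligned_columns = cols,
      matches = al$matches, mismatches = al$mismatches,
      cigar = al$cigar, score = al$score,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

# stretch a local alignment outward (indel-free) until the full query is
# covered or the target ends; extension columns score as match/mismatch
extend_alignment <- function(al, qs, ts, scoring) {
  ops_pre <- ""; ops_post <- ""
  n1 <- min(al$q_start, al$t_start)
  if (n1 > 0L) {
    qseg <- strsplit(substr(qs, al$q_start - n1 + 1L, al$q_start), "")[[1]]
    tseg <- strsplit(substr(ts, al$t_start - n1 + 1L, al$t_start), "")[[1]]
    eq <- qseg == tseg & qseg != "N"
    al$matches <- al$matches + sum(eq)
    al$mismatches <- al$mismatches + sum(!eq)
    al$score <- al$score + sum(eq) * scoring$match + sum(!eq) * scoring$mismatch
    al$q_start <- al$q_start - n1
    al$t_start <- al$t_start - n1
    ops_pre <- rle_cigar(ifelse(eq, "=", "X"))
  }
  qlen <- nchar(qs); tlen <- nchar(ts)
  n2 <- min(qlen - al$q_end, tlen - al$t_end)
  if (n2 > 0L) {
    qseg <- strsplit(substr(qs, al$q_end + 1L, al$q_end + n2), "")[[1]]
    tseg <- strsplit(substr(ts, al$t_end + 1L, al$t_end + n2), "")[[1]]
    eq <- qseg == tseg & qseg != "N"
    al$matches <- al$matches + sum(eq)
    al$mismatches <- al$mismatches + sum(!eq)
    al$score <- al$score + sum(eq) * scoring$match + sum(!eq) * scoring$mismatch
    al$q_end <- al$q_end + n2
    al$t_end <- al$t_end + n2
    ops_post <- rle_cigar(ifelse(eq, "=", "X"))
  }
  al$cigar <- paste0(ops_pre, al$cigar, ops_post)
  al
}

rle_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

# group seed matches into candidate target windows: seeds sharing a
# diagonal band and lying close along the target belong to one locus
cluster_seeds <- function(seeds, qlen, k_seed) {
  diag <- seeds[, "t_pos"] - seeds[, "q_pos"]
  ord <- order(diag, seeds[, "t_pos"])
  diag <- diag[ord]
  tpos <- seeds[ord, "t_pos"]
  qpos <- seeds[ord, "q_pos"]
  band <- max(50L, as.integer(0.15 * qlen))
  grp <- cumsum(c(TRUE, diff(diag) > band))
  loci <- lapply(split(seq_along(grp), grp), function(ix) {
    # split a diagonal group where seeds are far apart along the target
    tp <- tpos[ix]; o <- order(tp); ix <- ix[o]; tp <- tp[o]
    sub <- cumsum(c(TRUE, diff(tp) > qlen))
    lapply(split(ix, sub), function(jx) {
      t_lo <- min(tpos[jx]) - min(qpos[jx])
      t_hi <- max(tpos[jx]) + k_seed + (qlen - max(qpos[jx]))
      c(w_start = max(0L, t_lo - band), w_end = t_hi + band)
    })
  })
  loci <- do.call(rbind, unlist(loci, recursive = FALSE))
  df <- data.frame(w_start = as.integer(loci[, "w_start"]),
                   w_end = as.integer(loci[, "w_end"]))
  # merge near-identical windows to avoid redundant DP calls
  df <- unique(df)
  df <- df[order(df$w_start, df$w_end), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1L) {
    for (i in 2L:nrow(df)) {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (df$w_start[i] >= df$w_start[j] && df$w_end[i] <= df$w_end[j])
        keep[i] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# drop hits nearly identical to a better-scoring hit (same strand,
# reciprocal target overlap > 90%); artifacts of overlapping DP windows
dedupe_hits <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(-df$score, df$t_start, df$strand), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in 2L:nrow(df)) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || df$strand[i] != df$strand[j]) next
      ov <- min(df$t_end[i], df$t_end[j]) - max(df$t_start[i], df$t_start[j])
      if (ov <= 0) next
      wi <- df$t_end[i] - df$t_start[i]
      wj <- df$t_end[j] - df$t_start[j]
      if (ov > 0.9 * wi && ov > 0.9 * wj) { keep[i] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}

#' Alignment identity from a CIGAR string
#'
#' Column-inclusive identity: matched columns over all alignment columns
#' (matches + mismatches + inserted + deleted bases). With `M` ops the
#' match/mismatch split is not encoded, so `mismatch_count` is required.
#'
#' @param cigar CIGAR string (ops M, =, X, I, D; S/H clips are ignored)
#' @param mismatch_count number of mismatching columns inside M ops
#' @return identity fraction in `[0, 1]`
#' @export
identity_from_cigar <- function(cigar, mismatch_count = NULL) {
  p <- parse_cigar(cigar)
  n <- function(op) sum(p$count[p$op == op])
  m_cols <- n("M")
  if (m_cols > 0L && is.null(mismatch_count))
    stop("CIGAR contains M ops; mismatch_count is required")
  mm <- n("X") + (if (m_cols > 0L) mismatch_count else 0L)
  matched <- n("=") + (if (m_cols > 0L) m_cols - mismatch_count else 0L)
  cols <- matched + mm + n("I") + n("D")
  if (cols == 0L) stop("CIGAR has no alignment columns")
  matched / cols
}

#' Write alignment hits as a PAF-like TSV
#'
#' @param hits hit data.frame from [align_local()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hits <- function(hits, path) {
  write_tsv_table(hits[, hit_cols()], path)
}
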