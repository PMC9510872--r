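#' Detect telomeric repeat arrays at sequence ends
#'
#' Scans each sequence end for an array of the telomeric repeat unit
#' (default the plant-type `CCCTAAA`, whose reverse complement `TTTAGGG`
#' is searched at 3' ends). The array is grown copy by copy with a
#' two-state scan that tolerates interrupted (degenerate) copies as long
#' as the purity — the fraction of array bases inside exact unit copies —
#' stays at or above `min_purity`.
#'
#' @param assembly named DNAStringSet (or named character)
#' @param unit telomeric repeat unit, length >= 3 (default "CCCTAAA")
#' @param max_offset maximum distance (bp) between the sequence end and
#'   the array (default 1000); more distant arrays are taken to be
#'   unplaced interstitial fragments and ignored
#' @param min_units minimum number of exact unit copies (default 10)
#' @param min_purity minimum array purity (default 0.8)
#' @return data.frame with `seq_id`, `end` ("5p"/"3p"), `start`, `end_pos`
#'   (0-based half-open), `repeat_unit_count`, `length`, `purity`
#' @export
find_telomeres <- function(assembly, unit = "CCCTAAA", max_offset = 1000L,
                           min_units = 10L, min_purity = 0.8) {
  stopifnot(nchar(unit) >= 3L)
  assembly <- as_seq_set(assembly)
  unit <- toupper(unit)
  out <- list()
  for (id in names(assembly)) {
    s <- as.character(assembly[[id]])
    for (side in c("5p", "3p")) {
      u <- if (side == "5p") unit else revcomp(unit)
      rec <- telomere_scan(s, u, side, max_offset, min_units, min_purity)
      if (!is.null(rec)) {
        rec$seq_id <- id
        rec$end <- side
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), end = character(),
                      start = integer(), end_pos = integer(),
                      repeat_unit_count = integer(), length = integer(),
                      purity = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(out, function(r)
    data.frame(seq_id = r$seq_id, end = r$end, start = r$start,
               end_pos = r$end_pos, repeat_unit_count = r$units,
               length = r$length, purity = r$purity,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

# grow a telomere array from one end of s; returns NULL when no array
telomere_scan <- function(s, u, side, max_offset, min_units, min_purity) {
  ulen <- nchar(u)
  L <- nchar(s)
  m <- stringi::stri_locate_all_fixed(s, u)[[1]]
  if (is.na(m[1, 1])) return(NULL)
  starts <- m[, 1] - 1L # 0-based
  # greedy non-overlapping tiling of exact copies, oriented from the end
  if (side == "5p") {
    starts <- sort(starts)
    tiled <- integer()
    last_end <- -1L
    for (p in starts) if (p >= last_end) { tiled <- c(tiled, p); last_end <- p + ulen }
  } else {
    starts <- sort(starts, decreasing = TRUE)
    tiled <- integer()
    last_start <- L + 1L
    for (p in starts) if (p + ulen <= last_start) { tiled <- c(tiled, p); last_start <- p }
  }
  if (length(tiled) == 0L) return(NULL)
  # seed copy must sit within max_offset of the end
  first <- tiled[1L]
  edge_dist <- if (side == "5p") first else L - (first + ulen)
  if (edge_dist > max_offset) return(NULL)
  # extend copy by copy while purity holds
  lo <- first; hi <- first + ulen; units <- 1L
  for (p in tiled[-1L]) {
    new_lo <- min(lo, p); new_hi <- max(hi, p + ulen)
    purity <- ((units + 1L) * ulen) / (new_hi - new_lo)
    if (purity < min_purity) break
    lo <- new_lo; hi <- new_hi; units <- units + 1L
  }
  purity <- (units * ulen) / (hi - lo)
  if (units < min_units || purity < min_purity) return(NULL)
  list(start = lo, end_pos = hi, units = units, length = hi - lo,
       purity = purity)
}

#' Extract novel regions by alignment complement
#'
#' Given alignment intervals on the target assembly (typically filtered
#' upstream to a minimum identity and length, e.g. 95% identity over
#' 10 kb), the novel regions are the complement of the merged covered
#' intervals over each target sequence. Covered and novel regions
#' partition every sequence.
#'
#' @param seq_lengths named integer vector of target sequence lengths
#' @param covered data.frame of intervals on the target (`seq_id`,
#'   `start`, `end`, 0-based half-open); may be empty
#' @return data.frame of novel intervals (`seq_id`, `start`, `end`)
#' @export
novel_regions <- function(seq_lengths, covered) {
  stopifnot(!is.null(names(seq_lengths)))
  if (nrow(covered) > 0) {
    stopifnot(all(covered$seq_id %in% names(seq_lengths)))
    gr <- intervals_to_granges(
      data.frame(seq_id = covered$seq_id, start = covered$start,
                 end = covered$end, strand = "."),
      seqlengths = seq_lengths)
    GenomicRanges::strand(gr) <- "*"
    novel <- GenomicRanges::gaps(GenomicRanges::reduce(gr))
    novel <- novel[GenomicRanges::strand(novel) == "*"]
  } else {
    novel <- GenomicRanges::GRanges(
      seqnames = factor(names(seq_lengths), levels = names(seq_lengths)),
      ranges = IRanges::IRanges(start = 1L, end = unname(seq_lengths)),
      seqlengths = seq_lengths)
  }
  df <- granges_to_intervals(novel)[, c("seq_id", "start", "end")]
  df <- df[order(match(df$seq_id, names(seq_lengths)), df$start), ]
  rownames(df) <- NULL
  df
}
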