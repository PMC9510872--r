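#' Count canonical k-mers
#'
#' Every k-mer is recorded in canonical form: the lexicographic minimum of
#' the k-mer and its reverse complement, which makes counts strand
#' independent. k must be odd so no k-mer equals its own reverse
#' complement's canonical ambiguity. k-mers containing `N` are skipped.
#'
#' @param sequences DNAStringSet or character vector
#' @param k odd k-mer size, 1 < k <= 31 (default 21)
#' @return named integer vector: canonical k-mer -> multiplicity
#' @export
count_kmers <- function(sequences, k = 21L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (canonicalization ambiguity)")
  stopifnot(k > 1L, k <= 31L)
  seqs <- toupper(as.character(as_seq_set(sequences)))
  kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    stringi::stri_sub(s, seq_len(L - k + 1L), length = k)
  }), use.names = FALSE)
  if (length(kmers) == 0L) return(stats::setNames(integer(), character()))
  kmers <- kmers[!stringi::stri_detect_fixed(kmers, "N")]
  if (length(kmers) == 0L) return(stats::setNames(integer(), character()))
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", kmers))
  canon <- pmin(kmers, rc)
  tab <- table(canon)
  stats::setNames(as.integer(tab), names(tab))
}

#' k-mer based consensus quality (QV) estimate
#'
#' Merqury-style model: with T total assembly k-mer instances of which B
#' are absent from the read k-mer set, the per-base error probability is
#' `E = 1 - (1 - B/T)^(1/k)` (a base error corrupts up to k overlapping
#' k-mers), and `QV = -10 log10(E)`. When B = 0 the QV is reported at a
#' configurable cap with `qv_capped = TRUE`.
#'
#' @param assembly_kmers,read_kmers named integer vectors from
#'   [count_kmers()]
#' @param k the k-mer size the sets were built with
#' @param cap QV reported when no assembly-only k-mers exist (default 99)
#' @return list of class `qv_report`: `k`, `T`, `B`, `E`, `qv`,
#'   `accuracy_pct`, `qv_capped`
#' @export
estimate_qv <- function(assembly_kmers, read_kmers, k = 21L, cap = 99) {
  if (length(read_kmers) == 0L) stop("empty read k-mer set is uninformative")
  total <- sum(assembly_kmers)
  if (total == 0L) stop("assembly has no k-mers")
  absent <- !(names(assembly_kmers) %in% names(read_kmers))
  B <- sum(assembly_kmers[absent])
  if (B == 0L) {
    qv <- cap
    E <- 10^(-qv / 10)
    capped <- TRUE
  } else {
    E <- 1 - (1 - B / total)^(1 / k)
    qv <- -10 * log10(E)
    capped <- FALSE
  }
  structure(list(k = k, T = total, B = B, E = E, qv = qv,
                 accuracy_pct = qv_to_accuracy(qv), qv_capped = capped),
            class = "qv_report")
}

#' @export
print.qv_report <- function(x, ...) {
  cat(sprintf("QV report (k=%d): T=%d, B=%d, E=%.3g, QV=%.2f%s, accuracy=%.6f%%\n",
              x$k, x$T, x$B, x$E, x$qv, if (x$qv_capped) " (capped)" else "",
              x$accuracy_pct))
  invisible(x)
}

#' Convert QV to a base-accuracy percentage
#'
#' `accuracy = 100 - 10^(QV/-10) * 100`, i.e. the Phred error probability
#' expressed as a percentage of correct bases, reported at six decimals
#' (rounded half-up). A QV of 20 is 99.0% accuracy; 67.78 is 99.999983%.
#'
#' @param qv non-negative quality value(s)
#' @return accuracy percentage(s), six-decimal precision
#' @export
qv_to_accuracy <- function(qv) {
  stopifnot(all(qv >= 0))
  round_half_up(100 - 10^(qv / -10) * 100, 6)
}

#' k-mer completeness of an assembly
#'
#' Share of reliable read k-mers (multiplicity at least
#' `reliability_floor`; rarer k-mers are treated as sequencing errors)
#' that are present in the assembly k-mer set, as a percentage over
#' distinct k-mers.
#'
#' @param read_kmers,assembly_kmers named integer vectors from
#'   [count_kmers()]
#' @param reliability_floor minimum read multiplicity (default 2)
#' @return completeness percentage
#' @export
kmer_completeness <- function(read_kmers, assembly_kmers,
                              reliability_floor = 2L) {
  stopifnot(reliability_floor >= 1L)
  reliable <- names(read_kmers)[read_kmers >= reliability_floor]
  if (length(reliable) == 0L) stop("no reliable read k-mers")
  100 * sum(reliable %in% names(assembly_kmers)) / length(reliable)
}
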