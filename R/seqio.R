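#' Read a FASTA file into a DNAStringSet
#'
#' Records are uppercased on read. IUPAC ambiguity codes outside
#' A, C, G, T, N are converted to `N` with a warning, so that every
#' downstream alphabet (k-mer counting, alignment scoring) stays closed.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path path to a FASTA (or FASTA.gz) file
#' @return a named [Biostrings::DNAStringSet]; record order preserved
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    stop("empty record in ", path, ": ", ids[Biostrings::width(set) == 0L][1L])
  chars <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    warning(sum(bad), " record(s) contained non-ACGTN IUPAC codes; ",
            "converted to N")
    chars[bad] <- gsub("[^ACGTN]", "N", chars[bad])
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  out
}

#' Write a DNAStringSet to FASTA
#'
#' Lines are wrapped at 80 columns for deterministic output.
#'
#' @param seqs named [Biostrings::DNAStringSet] (or named character vector)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_set(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read and write 6-column BED
#'
#' Intervals are a `data.frame` with columns `seq_id`, `start`, `end`,
#' `name`, `score`, `strand`; coordinates are 0-based half-open and the
#' strand is one of `+`, `-`, `.`. `read_bed(write_bed(x))` is the
#' identity. Missing name/score fields read back as `"."`.
#'
#' @param intervals data.frame with at least `seq_id`, `start`, `end`
#' @param path file path (`.gz` accepted on read)
#' @return `read_bed`: a data.frame as above; `write_bed`: `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  df <- as_bed_df(intervals)
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$seq_id, df$start, df$end, df$name, df$score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(empty_bed())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path)
  get <- function(i, default = ".")
    vapply(parts, function(p) if (length(p) >= i) p[i] else default, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1L],
         " in ", path, ": non-integer coordinates")
  df <- data.frame(seq_id = get(1), start = start, end = end,
                   name = get(4), score = get(5), strand = get(6),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

empty_bed <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             name = character(), score = character(), strand = character(),
             stringsAsFactors = FALSE)
}

as_bed_df <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  df <- as.data.frame(intervals)
  stopifnot(all(c("seq_id", "start", "end") %in% names(df)))
  if (is.null(df$name)) df$name <- rep(".", nrow(df))
  if (is.null(df$score)) df$score <- rep(".", nrow(df))
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  df <- df[, c("seq_id", "start", "end", "name", "score", "strand")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- as.character(df$name)
  df$score <- as.character(df$score)
  df$strand <- as.character(df$strand)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("invalid interval: require 0 <= start < end")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

# intervals data.frame -> GRanges (coordinates shift to 1-based closed)
intervals_to_granges <- function(df, seqlengths = NULL) {
  strand <- if (is.null(df$strand)) "*" else ifelse(df$strand == ".", "*", df$strand)
  sn <- if (is.null(seqlengths)) df$seq_id else
    factor(df$seq_id, levels = names(seqlengths))
  GenomicRanges::GRanges(
    seqnames = sn,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand,
    seqlengths = seqlengths)
}

granges_to_intervals <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = rep(".", length(gr)), score = rep(".", length(gr)),
    strand = ifelse(s == "*", ".", s),
    stringsAsFactors = FALSE)
}

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string over ops M, =, X, I, D, S, H
#' @return data.frame with columns `op` (character) and `count` (integer),
#'   in input order; concatenating `count` and `op` reproduces the input
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, nzchar(cigar))
  toks <- stringi::stri_match_all_regex(cigar, "(\\d+)([A-Za-z=])")[[1]]
  if (anyNA(toks) || paste(toks[, 1], collapse = "") != cigar)
    stop("unparseable CIGAR: ", cigar)
  ops <- toks[, 3]
  bad <- setdiff(unique(ops), c("M", "=", "X", "I", "D", "S", "H"))
  if (length(bad))
    stop("unknown CIGAR op: ", paste(bad, collapse = ", "))
  counts <- as.integer(toks[, 2])
  if (any(counts <= 0L)) stop("CIGAR counts must be positive")
  data.frame(op = ops, count = counts, stringsAsFactors = FALSE)
}

#' Read/write simple TSV tables
#'
#' Convenience wrappers around [data.table::fread()]/[data.table::fwrite()]
#' used for all tabular reports (gzip accepted on read).
#'
#' @param x data.frame to write
#' @param path file path
#' @return `read_tsv_table`: a data.frame; `write_tsv_table`: `path`,
#'   invisibly
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
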