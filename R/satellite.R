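#' Satellite consensus presets
#'
#' `cen180_consensus()` returns the 178-bp *Arabidopsis thaliana*
#' centromeric satellite consensus used for monomer detection, with the
#' standard length filter 165-185 bp and a 90% query-coverage gate.
#' `satellite_consensus()` builds a custom preset.
#'
#' @param name preset label
#' @param seq consensus DNA string
#' @param length_range two-element numeric: retained monomer length range
#' @param min_query_coverage minimum consensus coverage per hit
#' @return list of class `satellite_consensus`
#' @export
satellite_consensus <- function(seq, name = "custom",
                                length_range = c(0.9, 1.1) * nchar(seq),
                                min_query_coverage = 0.9) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) > 0L, grepl("^[ACGTN]+$", seq),
            length(length_range) == 2L, length_range[1] <= length_range[2])
  structure(list(name = name, seq = seq,
                 length_range = as.numeric(length_range),
                 min_query_coverage = min_query_coverage),
            class = "satellite_consensus")
}

#' @rdname satellite_consensus
#' @export
cen180_consensus <- function() {
  satellite_consensus(
    paste0("AAAAGCCTAAGTATTGTTTCCTTGTTAGAAGATACAAAGACAAAGACTCATATGGACTT",
           "CGGCTACACCATCAAAGCTTTGAGAAGCAAGAAGAAGCTTGGTTAGTGTTTTGGAGTCA",
           "AATATGACTTGATGTCATGTGTATGATTGAGTATAACAACTTAAACCGCAACCGGATCTT"),
    name = "CEN180", length_range = c(165, 185), min_query_coverage = 0.90)
}

#' @rdname satellite_consensus
#' @param unit_length nominal 5S rDNA unit length used for the custom
#'   consensus argument
#' @export
rdna5s_preset <- function(seq, unit_length = 500) {
  satellite_consensus(seq, name = "5S", length_range = c(490, 510),
                      min_query_coverage = 0.90)
}

#' Decompose a genome into satellite monomers
#'
#' Aligns the consensus against the genome on both strands, keeps hits
#' covering at least the preset's consensus fraction, resolves overlaps
#' greedily by score (a retained hit suppresses hits overlapping it by
#' more than 10% of their own length), and retains monomers whose length
#' falls inside the preset's range. Monomer sequences are reported in
#' consensus orientation.
#'
#' @param genome named DNAStringSet (or named character)
#' @param consensus a `satellite_consensus` (e.g. [cen180_consensus()])
#' @param min_identity minimum hit identity (default 0.5)
#' @return data.frame with `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `length`, `identity`, `sequence`, sorted by coordinate
#' @export
find_monomers <- function(genome, consensus, min_identity = 0.5) {
  stopifnot(inherits(consensus, "satellite_consensus"))
  genome <- as_seq_set(genome)
  clen <- nchar(consensus$seq)
  out <- list()
  for (id in names(genome)) {
    tseq <- as.character(genome[[id]])
    hits <- align_local(stats::setNames(consensus$seq, consensus$name),
                        stats::setNames(tseq, id),
                        min_identity = min_identity,
                        min_length = floor(consensus$min_query_coverage * clen),
                        extend_full_query = TRUE)
    if (nrow(hits) == 0L) next
    # coverage gate uses the core (pre-extension) aligned span
    cov <- (hits$q_core_end - hits$q_core_start) / clen
    hits <- hits[cov >= consensus$min_query_coverage, , drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- resolve_overlaps(hits, max_overlap_frac = 0.10)
    len <- hits$t_end - hits$t_start
    keep <- len >= consensus$length_range[1] & len <= consensus$length_range[2]
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) == 0L) next
    seqs <- substr(rep(tseq, nrow(hits)), hits$t_start + 1L, hits$t_end)
    minus <- hits$strand == "-"
    if (any(minus)) seqs[minus] <- vapply(seqs[minus], revcomp, "")
    out[[id]] <- data.frame(
      seq_id = id, start = hits$t_start, end = hits$t_end,
      strand = hits$strand, length = hits$t_end - hits$t_start,
      identity = hits$identity, sequence = unname(seqs),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), identity = numeric(),
                      sequence = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(match(df$seq_id, names(genome)), df$start), ]
  rownames(df) <- NULL
  df
}

# greedy overlap resolution: keep hits in score order, drop a hit when it
# overlaps an already retained hit by more than max_overlap_frac of its
# own length (same target axis)
resolve_overlaps <- function(hits, max_overlap_frac = 0.10) {
  hits <- hits[order(-hits$score, hits$t_start), , drop = FALSE]
  keep <- logical(nrow(hits))
  kept_s <- integer(0); kept_e <- integer(0)
  for (i in seq_len(nrow(hits))) {
    s <- hits$t_start[i]; e <- hits$t_end[i]
    ov <- pmin(e, kept_e) - pmax(s, kept_s)
    if (length(ov) == 0L || all(ov <= max_overlap_frac * (e - s))) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Consensus-anchored monomer alignment matrix
#'
#' Aligns each monomer to the consensus and projects it onto the
#' consensus columns: every row has one symbol from \{A,C,G,T,-\} per
#' consensus position. Deletions relative to the consensus appear as `-`;
#' insertions are collapsed out of the matrix and kept in a per-row
#' `insertions` annotation (position, inserted bases), so each monomer is
#' recoverable from its row plus annotations. For near-fixed-length
#' satellite monomers this consensus-anchored strategy is an accurate,
#' linear-time stand-in for a full progressive multiple alignment; an
#' externally computed multiple alignment in aligned-FASTA can be imported
#' with [read_alignment_fasta()] instead.
#'
#' @param monomers data.frame from [find_monomers()] (needs a `sequence`
#'   column), or a character vector of monomer sequences
#' @param consensus a `satellite_consensus`
#' @param min_identity monomers aligning below this identity to the
#'   consensus are excluded with a warning (default 0.5)
#' @return list of class `monomer_alignment`: `matrix` (character matrix,
#'   rows = monomers, cols = consensus positions), `insertions` (per-row
#'   list), `excluded` (row indices dropped), `consensus`
#' @export
build_monomer_alignment <- function(monomers, consensus, min_identity = 0.5) {
  stopifnot(inherits(consensus, "satellite_consensus"))
  seqs <- if (is.data.frame(monomers)) monomers$sequence else as.character(monomers)
  stopifnot(length(seqs) >= 2L)
  clen <- nchar(consensus$seq)
  sc <- default_scoring()
  rows <- vector("list", length(seqs))
  inserts <- vector("list", length(seqs))
  excluded <- integer()
  for (i in seq_along(seqs)) {
    al <- .sw_align_cpp(seqs[i], consensus$seq,
                        sc$match, sc$mismatch, sc$gap_open, sc$gap_ext)
    # global-scale identity: matched columns over the longer of monomer
    # and consensus, so a short high-identity local island in an
    # unrelated sequence does not pass the gate
    ident <- if (isTRUE(al$found))
      al$matches / max(nchar(seqs[i]), clen)
    else 0
    if (!isTRUE(al$found) || ident < min_identity) {
      excluded <- c(excluded, i)
      next
    }
    row <- rep("-", clen)
    ins <- list()
    qpos <- al$q_start; tpos <- al$t_start # 0-based cursors
    p <- parse_cigar(al$cigar)
    for (j in seq_len(nrow(p))) {
      op <- p$op[j]; cnt <- p$count[j]
      if (op %in% c("=", "X")) {
        row[(tpos + 1L):(tpos + cnt)] <-
          strsplit(substr(seqs[i], qpos + 1L, qpos + cnt), "")[[1]]
        qpos <- qpos + cnt; tpos <- tpos + cnt
      } else if (op == "D") {          # consensus bases absent from monomer
        tpos <- tpos + cnt
      } else if (op == "I") {          # monomer bases absent from consensus
        ins[[length(ins) + 1L]] <- list(
          after_col = tpos, bases = substr(seqs[i], qpos + 1L, qpos + cnt))
        qpos <- qpos + cnt
      }
    }
    # unaligned monomer prefix/suffix recorded as insertions at the edges
    if (al$q_start > 0L)
      ins <- c(list(list(after_col = 0L,
                         bases = substr(seqs[i], 1L, al$q_start))), ins)
    if (al$q_end < nchar(seqs[i]))
      ins[[length(ins) + 1L]] <- list(
        after_col = clen, bases = substr(seqs[i], al$q_end + 1L, nchar(seqs[i])))
    rows[[i]] <- row
    inserts[[i]] <- ins
  }
  if (length(excluded)) {
    warning(length(excluded), " monomer(s) below identity ", min_identity,
            " to the consensus were excluded")
    rows <- rows[-excluded]
    inserts <- inserts[-excluded]
  }
  if (length(rows) < 2L) stop("fewer than 2 alignable monomers")
  mat <- do.call(rbind, rows)
  colnames(mat) <- NULL
  structure(list(matrix = mat, insertions = inserts, excluded = excluded,
                 consensus = consensus), class = "monomer_alignment")
}

#' Read an aligned FASTA (external multiple alignment) as a monomer matrix
#'
#' @param path aligned-FASTA path (all records equal width, gaps as `-`)
#' @return a `monomer_alignment` with empty insertion annotations
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  chars <- toupper(as.character(set))
  w <- unique(nchar(chars))
  if (length(w) != 1L) stop("aligned FASTA rows differ in width")
  mat <- do.call(rbind, strsplit(chars, ""))
  rownames(mat) <- NULL
  structure(list(matrix = mat,
                 insertions = rep(list(list()), nrow(mat)),
                 excluded = integer(), consensus = NULL),
            class = "monomer_alignment")
}

#' Cluster satellite monomers with a multinomial mixture
#'
#' Fits, for each K in `K_range`, a mixture of per-column independent
#' multinomials over \{A,C,G,T,-\} by EM (multiple seeded restarts, best
#' log-likelihood kept) and records `BIC(K) = -2 logL + p log(n)` with
#' `p = (K-1) + 4 K m` free parameters (m alignment columns). The
#' selected K* is the BIC inflection: the K maximising the discrete
#' second difference `BIC(K-1) - 2 BIC(K) + BIC(K+1)`. A single-component
#' fit (K = 1) is added below the range so the lower edge of `K_range` is
#' eligible as an inflection.
#'
#' @param alignment a `monomer_alignment` (or a character matrix over
#'   \{A,C,G,T,-,N\})
#' @param K_range candidate cluster counts (default 2:10)
#' @param seed RNG seed for the EM restarts (mandatory for reproducibility)
#' @param n_init random restarts per K (default 10)
#' @param max_iter EM iterations cap (default 200)
#' @param tol relative log-likelihood convergence tolerance (default 1e-6)
#' @return list of class `cluster_result`: `K_range`, `bic` (named), `K_star`,
#'   `labels`, `log_likelihood` (named), `consensus` (per-cluster consensus
#'   strings), `degenerate`
#' @export
cluster_monomers <- function(alignment, K_range = 2:10, seed = 1L,
                             n_init = 10L, max_iter = 200L, tol = 1e-6) {
  mat <- if (inherits(alignment, "monomer_alignment")) alignment$matrix
  else alignment
  stopifnot(is.matrix(mat))
  n <- nrow(mat); m <- ncol(mat)
  K_range <- sort(unique(as.integer(K_range)))
  stopifnot(n >= max(K_range))
  symbols <- c("A", "C", "G", "T", "-")
  x <- matrix(match(mat, symbols), n, m)
  x[is.na(x)] <- 5L # treat N/other as the gap/other category

  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    labels <- rep(1L, n)
    return(structure(list(K_range = K_range,
                          bic = stats::setNames(rep(NA_real_, length(K_range)),
                                                K_range),
                          K_star = min(K_range), labels = labels,
                          log_likelihood = NULL,
                          consensus = consensus_from_labels(mat, labels),
                          degenerate = TRUE), class = "cluster_result"))
  }

  Ks <- c(1L, K_range)
  fits <- vector("list", length(Ks))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  for (ki in seq_along(Ks)) {
    K <- Ks[ki]
    best <- NULL
    for (r in seq_len(if (K == 1L) 1L else n_init)) {
      fit <- em_multinomial(x, K, max_iter, tol)
      if (is.null(best) || fit$logL > best$logL) best <- fit
    }
    fits[[ki]] <- best
  }
  logL <- vapply(fits, function(f) f$logL, 0)
  p <- (Ks - 1) + 4 * Ks * m
  bic <- -2 * logL + p * log(n)
  names(bic) <- names(logL) <- Ks

  # inflection: discrete second difference over the augmented K grid
  idx <- which(Ks %in% K_range)
  d2 <- vapply(idx, function(i) {
    if (i == 1L || i == length(Ks)) return(NA_real_)
    bic[i - 1L] - 2 * bic[i] + bic[i + 1L]
  }, 0)
  if (all(is.na(d2))) {
    K_star <- K_range[which.min(bic[idx])]
  } else {
    K_star <- K_range[which.max(d2)]
  }
  fit_star <- fits[[which(Ks == K_star)]]
  labels <- max.col(fit_star$resp)
  structure(list(K_range = K_range, bic = bic[as.character(K_range)],
                 K_star = K_star, labels = labels,
                 log_likelihood = logL[as.character(K_range)],
                 consensus = consensus_from_labels(mat, labels),
                 degenerate = FALSE), class = "cluster_result")
}

# EM for a mixture of per-column multinomials over 5 categories.
# x: n x m integer matrix with values 1..5. Components are initialised
# from K random prototype rows (random-uniform soft assignments leave all
# components at the column mean profile, a saddle point EM cannot leave).
em_multinomial <- function(x, K, max_iter, tol, pseudo = 0.5) {
  n <- nrow(x); m <- ncol(x)
  # one-hot indicator matrices per category (n x m), fixed across EM
  ind <- lapply(1:5, function(c) (x == c) * 1)
  # k-means++-style prototype selection: after a random first prototype,
  # each next one is drawn with probability proportional to its squared
  # Hamming distance from the chosen set, so well-separated variant
  # families are all represented at initialisation
  proto <- sample(n, 1L)
  if (K > 1L) {
    d <- rowSums(x != matrix(x[proto, ], n, m, byrow = TRUE))
    for (k in 2L:K) {
      w <- d^2
      nxt <- if (sum(w) == 0) sample(n, 1L)
      else sample(n, 1L, prob = w)
      proto <- c(proto, nxt)
      d <- pmin(d, rowSums(x != matrix(x[nxt, ], n, m, byrow = TRUE)))
    }
  }
  # prototype-based theta: probability 0.85 on the prototype's symbol
  ltheta <- lapply(1:5, function(c) {
    p <- matrix(0.15 / 4, K, m)
    p[ind[[c]][proto, , drop = FALSE] == 1] <- 0.85
    log(p)
  })
  pi_k <- rep(1 / K, K)
  logL_old <- -Inf
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E step: loglik_ik = log pi_k + sum_j ltheta[k, j, x_ij]
    ll <- matrix(rep(log(pi_k), each = n), n, K)
    for (c in 1:5) ll <- ll + ind[[c]] %*% t(ltheta[[c]])
    mx <- apply(ll, 1, max)
    w <- exp(ll - mx)
    sw <- rowSums(w)
    resp <- w / sw
    logL <- sum(mx + log(sw))
    if (is.finite(logL_old) &&
        abs(logL - logL_old) < tol * (abs(logL_old) + 1)) break
    logL_old <- logL
    # M step
    nk <- colSums(resp)
    pi_k <- nk / n
    theta <- lapply(ind, function(I) crossprod(resp, I) + pseudo) # K x m
    denom <- Reduce(`+`, theta)
    ltheta <- lapply(theta, function(tc) log(tc / denom))
  }
  list(logL = logL, resp = resp, pi = pi_k)
}

# majority-vote consensus string per cluster (gaps dropped)
consensus_from_labels <- function(mat, labels) {
  vapply(sort(unique(labels)), function(k) {
    sub <- mat[labels == k, , drop = FALSE]
    cons <- apply(sub, 2, function(col) {
      tb <- sort(table(col), decreasing = TRUE)
      names(tb)[1L]
    })
    paste(cons[cons != "-"], collapse = "")
  }, "")
}

#' Windowed pairwise identity matrix of a region
#'
#' Splits the region into consecutive non-overlapping windows and computes
#' the best local-alignment identity between every window pair; entries
#' without a qualifying alignment are 0, the diagonal is 1. This is the
#' matrix behind pairwise-identity heatmaps of centromere arrays.
#'
#' @param region_sequence character / DNAString region (length >= 2 windows)
#' @param window window size in bp (default 5000)
#' @param min_length minimum alignment columns for a pair to score
#'   (default `window %/% 5`)
#' @return symmetric numeric matrix, one row/column per window; row names
#'   give the window start offsets
#' @export
identity_heatmap <- function(region_sequence, window = 5000L,
                             min_length = window %/% 5L) {
  s <- as_seq_chr(region_sequence, "region")
  L <- nchar(s)
  stopifnot(L >= 2L * window)
  nw <- L %/% window
  starts <- (seq_len(nw) - 1L) * window
  wins <- substring(s, starts + 1L, starts + window)
  M <- diag(1, nw)
  for (i in seq_len(nw - 1L)) for (j in (i + 1L):nw) {
    h <- align_local(wins[i], wins[j], min_length = min_length)
    v <- if (nrow(h) > 0L) h$identity[1L] else 0
    M[i, j] <- M[j, i] <- v
  }
  rownames(M) <- colnames(M) <- starts
  M
}
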