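# shared fixture builders; everything is generated in code under fixed seeds

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at given positions (1-based) or at a rate
mutate_seq <- function(s, rate = NULL, n_subs = NULL, positions = NULL) {
  ch <- strsplit(s, "")[[1]]
  idx <- if (!is.null(positions)) positions
  else if (!is.null(n_subs)) sample(length(ch), n_subs)
  else which(runif(length(ch)) < rate)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# map detected monomers to truth monomers by midpoint containment
truth_labels_for <- function(monomers, truth) {
  mid <- (monomers$start + monomers$end) / 2
  vapply(mid, function(m) {
    i <- which(truth$start <= m & truth$end > m)
    if (length(i)) truth$cluster[i[1L]] else NA_integer_
  }, integer(1))
}

# agreement between two labelings up to relabeling (adjusted Rand index)
label_agreement <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
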