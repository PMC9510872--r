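#' Simulation configuration
#'
#' Defines a ground-truthed synthetic genome in the data regime of a
#' repeat-rich plant chromosome: telomeric arrays at both ends, unique
#' arms, a centromeric satellite region of clustered monomer arrays
#' interrupted by LTR-like insertions, a degraded draft with planted
#' scaffolding gaps, donor contigs covering the gaps, and anchor sequences
#' flanking each gap drawn from unique sequence.
#'
#' @param seed mandatory integer seed; every emitted artefact is a
#'   deterministic function of (config, seed)
#' @param arm_length length of each unique arm (bp)
#' @param telomere_units exact telomere unit copies per end
#' @param telomere_unit telomeric repeat unit
#' @param satellite_clusters number of satellite monomer clusters
#' @param copies_per_cluster monomer copies per cluster
#' @param diagnostic_subs diagnostic substitutions distinguishing each
#'   cluster consensus from the base consensus
#' @param per_copy_sub_rate per-base random substitution rate within each
#'   monomer copy
#' @param satellite_consensus base consensus (default [cen180_consensus()])
#' @param ltr_count,ltr_length LTR-like random insertions interrupting the
#'   satellite region
#' @param n_gaps planted scaffolding gaps in the draft
#' @param gap_length_range gap length range (bp)
#' @param anchor_length anchor (BAC-like) sequence length
#' @param anchor_offset distance from gap edge to its anchor
#' @param donor_flank donor contig extent beyond each anchor
#' @param draft_error_rate substitution rate applied to the draft outside
#'   gaps (QV-style degradation)
#' @param invert_donors logical vector (recycled over gaps): emit the
#'   donor contig reverse-complemented
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed,
                       arm_length = 6000L,
                       telomere_units = 50L,
                       telomere_unit = "CCCTAAA",
                       satellite_clusters = 4L,
                       copies_per_cluster = 100L,
                       diagnostic_subs = 8L,
                       per_copy_sub_rate = 0.005,
                       satellite_consensus = cen180_consensus(),
                       ltr_count = 2L,
                       ltr_length = 800L,
                       n_gaps = 3L,
                       gap_length_range = c(2000L, 5000L),
                       anchor_length = 1000L,
                       anchor_offset = 200L,
                       donor_flank = 2500L,
                       draft_error_rate = 0,
                       invert_donors = FALSE) {
  stopifnot(!missing(seed), is.numeric(seed))
  cfg <- list(seed = as.integer(seed), arm_length = as.integer(arm_length),
              telomere_units = as.integer(telomere_units),
              telomere_unit = toupper(telomere_unit),
              satellite_clusters = as.integer(satellite_clusters),
              copies_per_cluster = as.integer(copies_per_cluster),
              diagnostic_subs = as.integer(diagnostic_subs),
              per_copy_sub_rate = per_copy_sub_rate,
              satellite_consensus = satellite_consensus,
              ltr_count = as.integer(ltr_count),
              ltr_length = as.integer(ltr_length),
              n_gaps = as.integer(n_gaps),
              gap_length_range = as.integer(gap_length_range),
              anchor_length = as.integer(anchor_length),
              anchor_offset = as.integer(anchor_offset),
              donor_flank = as.integer(donor_flank),
              draft_error_rate = draft_error_rate,
              invert_donors = invert_donors)
  stopifnot(all(c(cfg$per_copy_sub_rate, cfg$draft_error_rate) >= 0),
            all(c(cfg$per_copy_sub_rate, cfg$draft_error_rate) <= 1))
  structure(cfg, class = "sim_config")
}

# deterministic substream seed from a root seed and a component name;
# adding a component never perturbs another component's draws
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (31^(seq_len(nchar(name)) %% 7)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate = NULL, n_subs = NULL, positions = NULL) {
  chars <- strsplit(s, "")[[1]]
  if (!is.null(positions)) {
    idx <- positions
  } else if (!is.null(n_subs)) {
    idx <- sample(length(chars), min(n_subs, length(chars)))
  } else {
    idx <- which(stats::runif(length(chars)) < rate)
  }
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a ground-truthed genome bundle
#'
#' Builds the truth genome, a degraded draft with planted gaps, donor
#' contigs and anchors that let [patch_all()] reconstruct the truth, plus
#' truth annotations (monomers with cluster labels, gaps, telomeres). An
#' internal consistency audit (monomer sequences re-extracted from the
#' genome match their records; gap intervals are N-runs in the draft) runs
#' before the bundle is returned.
#'
#' @param config a [sim_config()]
#' @return list of class `truth_bundle` with elements `genome`, `draft`,
#'   `donors`, `anchors` (DNAStringSets), `monomer_truth`, `gap_truth`,
#'   `telomere_truth`, `cluster_regions` (data.frames), `config`
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  tel5 <- strrep(cfg$telomere_unit, cfg$telomere_units)
  tel3 <- strrep(revcomp(cfg$telomere_unit), cfg$telomere_units)
  arm1 <- with_substream(cfg$seed, "arm1", random_dna(cfg$arm_length))
  arm2 <- with_substream(cfg$seed, "arm2", random_dna(cfg$arm_length))

  # gaps are planted in unique spacer segments interleaved between the
  # satellite blocks: at this scale a 1-kb anchor inside a tandem array
  # could never place uniquely, whereas real BAC anchors are long enough
  # to reach out of the array into unique flanking sequence
  sat <- with_substream(cfg$seed, "satellite",
                        simulate_satellite_region(cfg))
  prefix_len <- nchar(tel5) + nchar(arm1)
  genome_chr <- paste0(tel5, arm1, sat$region, arm2, tel3)
  monomer_truth <- sat$monomers
  monomer_truth$start <- monomer_truth$start + prefix_len
  monomer_truth$end <- monomer_truth$end + prefix_len
  monomer_truth$seq_id <- "chr1"
  cluster_regions <- sat$cluster_regions
  cluster_regions$start <- cluster_regions$start + prefix_len
  cluster_regions$end <- cluster_regions$end + prefix_len
  cluster_regions$seq_id <- "chr1"

  genome <- Biostrings::DNAStringSet(stats::setNames(genome_chr, "chr1"))
  L <- nchar(genome_chr)

  gap_truth <- sat$gaps
  if (nrow(gap_truth)) {
    gap_truth$start <- gap_truth$start + prefix_len
    gap_truth$end <- gap_truth$end + prefix_len
    gap_truth$scaffold_id <- "chr1"
    gap_truth <- gap_truth[, c("scaffold_id", "start", "end")]
  } else {
    gap_truth <- data.frame(scaffold_id = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)
  }

  draft <- with_substream(cfg$seed, "draft_errors",
                          degrade(genome, gap_truth, cfg$draft_error_rate,
                                  seed = NULL))

  anchors <- list(); donors <- list()
  for (i in seq_len(nrow(gap_truth))) {
    gs <- gap_truth$start[i]; ge <- gap_truth$end[i]
    la_end <- gs - cfg$anchor_offset
    la_start <- la_end - cfg$anchor_length
    ra_start <- ge + cfg$anchor_offset
    ra_end <- ra_start + cfg$anchor_length
    if (la_start < 0L || ra_end > L)
      stop("infeasible config: anchors extend beyond the genome")
    anchors[[paste0("gap", i, "_L")]] <- substr(genome_chr, la_start + 1L, la_end)
    anchors[[paste0("gap", i, "_R")]] <- substr(genome_chr, ra_start + 1L, ra_end)
    ds <- max(0L, la_start - cfg$donor_flank)
    de <- min(L, ra_end + cfg$donor_flank)
    donor_seq <- substr(genome_chr, ds + 1L, de)
    inv <- rep_len(cfg$invert_donors, nrow(gap_truth))[i]
    if (inv) donor_seq <- revcomp(donor_seq)
    donors[[paste0("donor", i)]] <- donor_seq
  }

  bundle <- structure(list(
    genome = genome,
    draft = draft,
    donors = as_seq_set(unlist(anchors_or_empty(donors))),
    anchors = as_seq_set(unlist(anchors_or_empty(anchors))),
    monomer_truth = monomer_truth,
    gap_truth = gap_truth,
    telomere_truth = data.frame(
      seq_id = "chr1", end = c("5p", "3p"),
      start = c(0L, L - nchar(tel3)),
      end_pos = c(nchar(tel5), L),
      units = cfg$telomere_units, stringsAsFactors = FALSE),
    cluster_regions = cluster_regions,
    config = cfg), class = "truth_bundle")
  audit_bundle(bundle)
  bundle
}

anchors_or_empty <- function(x) {
  if (length(x) == 0L) return(character())
  x
}

# pre-write consistency audit: truth records must match emitted sequences
audit_bundle <- function(bundle) {
  g <- as.character(bundle$genome[["chr1"]])
  mt <- bundle$monomer_truth
  for (i in seq_len(min(nrow(mt), 25L))) {
    s <- substr(g, mt$start[i] + 1L, mt$end[i])
    if (!identical(s, mt$sequence[i]))
      stop("bundle audit failed: monomer ", i, " mismatches the genome")
  }
  d <- as.character(bundle$draft[["chr1"]])
  for (i in seq_len(nrow(bundle$gap_truth))) {
    run <- substr(d, bundle$gap_truth$start[i] + 1L, bundle$gap_truth$end[i])
    if (!grepl("^N+$", run))
      stop("bundle audit failed: gap ", i, " is not an N-run in the draft")
  }
  invisible(TRUE)
}

# satellite region with clustered monomer arrays, LTR interruptions, and
# unique gap-spacer segments; returns region string, monomer truth
# (region-local coords), cluster blocks, and planted gap intervals
simulate_satellite_region <- function(cfg) {
  cons <- cfg$satellite_consensus$seq
  clen <- nchar(cons)
  K <- cfg$satellite_clusters
  cluster_cons <- character(K)
  for (k in seq_len(K)) {
    pos <- sample(clen, cfg$diagnostic_subs)
    cluster_cons[k] <- mutate_dna(cons, positions = pos)
  }
  n_mono <- K * cfg$copies_per_cluster
  # monomer indices after which a gap spacer is inserted (evenly spread)
  gap_after <- if (cfg$n_gaps > 0L)
    round(seq_len(cfg$n_gaps) * n_mono / (cfg$n_gaps + 1L))
  else integer()
  if (anyDuplicated(gap_after) || any(gap_after == 0L) ||
      any(gap_after >= n_mono))
    stop("infeasible config: too many gaps for the satellite region")
  gap_lens <- if (cfg$n_gaps > 0L)
    sample(seq(cfg$gap_length_range[1], cfg$gap_length_range[2]),
           cfg$n_gaps, replace = TRUE)
  else integer()
  margin <- cfg$anchor_offset + cfg$anchor_length + 100L

  pieces <- character(); mono <- list(); gaps <- list()
  block_start <- 0L; block_cluster <- 1L; blocks <- list()
  offset <- 0L; mono_i <- 0L
  close_block <- function(upto) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      seq_id = "region", start = block_start, end = upto,
      name = paste0("cluster", block_cluster), stringsAsFactors = FALSE)
  }
  for (k in seq_len(K)) {
    if (k > 1L) {
      # LTR-like interruption between clusters (no gap here)
      if (cfg$ltr_count >= k - 1L && cfg$ltr_length > 0L) {
        ltr <- random_dna(cfg$ltr_length)
        pieces <- c(pieces, ltr)
        offset <- offset + nchar(ltr)
      }
      block_start <- offset; block_cluster <- k
    }
    for (cp in seq_len(cfg$copies_per_cluster)) {
      m <- mutate_dna(cluster_cons[k], rate = cfg$per_copy_sub_rate)
      pieces <- c(pieces, m)
      mono[[length(mono) + 1L]] <- data.frame(
        seq_id = "region", start = offset, end = offset + nchar(m),
        strand = "+", cluster = k, sequence = m, stringsAsFactors = FALSE)
      offset <- offset + nchar(m)
      mono_i <- mono_i + 1L
      gi <- match(mono_i, gap_after)
      if (!is.na(gi) && mono_i < n_mono) {
        close_block(offset)
        glen <- gap_lens[gi]
        spacer <- random_dna(glen + 2L * margin)
        gaps[[gi]] <- data.frame(
          start = offset + margin, end = offset + margin + glen,
          stringsAsFactors = FALSE)
        pieces <- c(pieces, spacer)
        offset <- offset + nchar(spacer)
        block_start <- offset
      }
    }
  }
  close_block(offset)
  blocks <- do.call(rbind, blocks)
  blocks <- blocks[blocks$end > blocks$start, , drop = FALSE]
  list(region = paste(pieces, collapse = ""),
       monomers = do.call(rbind, mono),
       cluster_regions = blocks,
       gaps = if (length(gaps)) do.call(rbind, gaps)
       else data.frame(start = integer(), end = integer()))
}

#' Degrade a truth genome into a draft
#'
#' Plants N-run gaps at the given loci and substitutes bases elsewhere at
#' `error_rate`.
#'
#' @param truth_genome named DNAStringSet
#' @param gap_spec data.frame with `scaffold_id`, `start`, `end`
#'   (0-based half-open); gaps must not overlap
#' @param error_rate substitution probability per base outside gaps
#' @param seed optional seed (NULL inherits the caller's RNG state)
#' @return draft DNAStringSet
#' @export
degrade <- function(truth_genome, gap_spec, error_rate = 0, seed = NULL) {
  truth_genome <- as_seq_set(truth_genome)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
  }
  out <- truth_genome
  for (id in names(truth_genome)) {
    s <- as.character(truth_genome[[id]])
    gs <- gap_spec[gap_spec$scaffold_id == id, , drop = FALSE]
    if (nrow(gs) > 1L) {
      gs <- gs[order(gs$start), ]
      if (any(gs$start[-1L] < gs$end[-nrow(gs)]))
        stop("overlapping planted gaps on ", id)
    }
    in_gap <- rep(FALSE, nchar(s))
    for (i in seq_len(nrow(gs)))
      in_gap[(gs$start[i] + 1L):gs$end[i]] <- TRUE
    if (error_rate > 0) {
      chars <- strsplit(s, "")[[1]]
      idx <- which(stats::runif(length(chars)) < error_rate & !in_gap)
      for (i in idx)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      s <- paste(chars, collapse = "")
    }
    if (any(in_gap)) {
      chars <- strsplit(s, "")[[1]]
      chars[in_gap] <- "N"
      s <- paste(chars, collapse = "")
    }
    out[[id]] <- Biostrings::DNAString(s)
  }
  out
}

#' Simulate per-read methylation calls
#'
#' CpG-like sites at regular spacing receive binomially sampled
#' methylation calls at `coverage` reads per site; sites inside `blocks`
#' use `block_freq`, others `background_freq`.
#'
#' @param genome_length sequence length (bp)
#' @param blocks data.frame of hypo/hyper blocks (`start`, `end`) or NULL
#' @param background_freq,block_freq true methylation frequencies
#' @param site_spacing distance between sites (default 50 bp)
#' @param coverage reads per site (default 30)
#' @param seed RNG seed
#' @param seq_id sequence name (default "chr1")
#' @return list with `calls` (per-read rows: `seq_id`, `pos`, `read_id`,
#'   `methylated`) and `truth` (`pos`, `true_frequency`)
#' @export
sim_methylation <- function(genome_length, blocks = NULL,
                            background_freq = 0.9, block_freq = 0.2,
                            site_spacing = 50L, coverage = 30L, seed = 1L,
                            seq_id = "chr1") {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(substream_seed(seed, "methylation"))
  pos <- seq(0L, genome_length - 1L, by = site_spacing)
  truef <- rep(background_freq, length(pos))
  if (!is.null(blocks)) {
    for (i in seq_len(nrow(blocks)))
      truef[pos >= blocks$start[i] & pos < blocks$end[i]] <- block_freq
  }
  calls <- do.call(rbind, lapply(seq_along(pos), function(i) {
    meth <- stats::rbinom(coverage, 1L, truef[i])
    data.frame(seq_id = seq_id, pos = pos[i],
               read_id = paste0("r", i, "_", seq_len(coverage)),
               methylated = meth == 1L, stringsAsFactors = FALSE)
  }))
  list(calls = calls,
       truth = data.frame(pos = pos, true_frequency = truef))
}

#' Simulate ChIP read intervals with cluster preference
#'
#' Reads are placed uniformly per base over the genome, except that bases
#' inside each cluster region carry that cluster's weight (so a weight of
#' 3 triples a region's read density relative to background weight 1).
#' The control sample uses all-1 weights.
#'
#' @param genome_length sequence length (bp)
#' @param cluster_regions data.frame (`seq_id`, `start`, `end`, `name`)
#' @param weights per-cluster treatment weights (recycled)
#' @param n_reads reads per sample (default 50000)
#' @param read_length read length (default 100)
#' @param seed RNG seed
#' @param seq_id sequence name
#' @return list with `treatment` and `control` read-interval data.frames
#' @export
sim_chip_reads <- function(genome_length, cluster_regions,
                           weights = c(1, 1, 3, 1), n_reads = 50000L,
                           read_length = 100L, seed = 1L, seq_id = "chr1") {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(substream_seed(seed, "chip"))
  w <- rep_len(weights, nrow(cluster_regions))
  draw <- function(weighted) {
    # piecewise-constant density over [0, genome_length)
    segs <- data.frame(start = 0, end = genome_length, w = 1)
    if (weighted) {
      cr <- cluster_regions[order(cluster_regions$start), ]
      segs <- list(); last <- 0
      for (i in seq_len(nrow(cr))) {
        if (cr$start[i] > last)
          segs[[length(segs) + 1L]] <- c(last, cr$start[i], 1)
        segs[[length(segs) + 1L]] <- c(cr$start[i], cr$end[i], w[i])
        last <- cr$end[i]
      }
      if (last < genome_length)
        segs[[length(segs) + 1L]] <- c(last, genome_length, 1)
      segs <- as.data.frame(do.call(rbind, segs))
      names(segs) <- c("start", "end", "w")
    }
    mass <- (segs$end - segs$start) * segs$w
    seg_idx <- sample.int(nrow(segs), n_reads, replace = TRUE,
                          prob = mass / sum(mass))
    mid <- floor(segs$start[seg_idx] +
                   stats::runif(n_reads) * (segs$end[seg_idx] - segs$start[seg_idx]))
    start <- pmax(0L, as.integer(mid) - read_length %/% 2L)
    data.frame(seq_id = seq_id, start = start,
               end = pmin(as.integer(genome_length), start + read_length),
               stringsAsFactors = FALSE)
  }
  treatment <- draw(TRUE)
  control <- draw(FALSE)
  list(treatment = treatment, control = control)
}

#' Write a truth bundle to a directory
#'
#' Emits truth genome, draft, donors and anchors as FASTA, monomer and
#' gap truth as BED, telomere truth as TSV, and a manifest (JSON) with the
#' seed and a config digest.
#'
#' @param bundle a `truth_bundle`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "truth_genome.fa"))
  write_fasta(bundle$draft, file.path(dir, "draft.fa"))
  if (length(bundle$donors))
    write_fasta(bundle$donors, file.path(dir, "donors.fa"))
  if (length(bundle$anchors))
    write_fasta(bundle$anchors, file.path(dir, "anchors.fa"))
  mt <- bundle$monomer_truth
  write_bed(data.frame(seq_id = mt$seq_id, start = mt$start, end = mt$end,
                       name = paste0("cluster", mt$cluster), score = ".",
                       strand = mt$strand),
            file.path(dir, "monomer_truth.bed"))
  gt <- bundle$gap_truth
  if (nrow(gt))
    write_bed(data.frame(seq_id = gt$scaffold_id, start = gt$start,
                         end = gt$end), file.path(dir, "gap_truth.bed"))
  write_tsv_table(bundle$telomere_truth, file.path(dir, "telomere_truth.tsv"))
  cfg <- unclass(bundle$config)
  cfg$satellite_consensus <- unclass(cfg$satellite_consensus)
  manifest <- list(seed = cfg$seed,
                   config_digest = digest_config(cfg),
                   package_version = as.character(utils::packageVersion("anchorfill")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  # small stable rolling hash; avoids a digest-package dependency
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 131 + v[i]) %% 2147483647
  sprintf("%010d", h)
}
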