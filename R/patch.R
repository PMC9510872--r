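#' Find assembly gaps (N-runs)
#'
#' Scaffolding gaps are maximal runs of `N` of at least `min_n_run` bases.
#'
#' @param assembly named [Biostrings::DNAStringSet] (or named character)
#' @param min_n_run minimum run length to report (default 10 bp, which
#'   separates scaffolding gaps from incidental ambiguity characters)
#' @return data.frame with `scaffold_id`, `start`, `end` (0-based
#'   half-open), `n_run_length`, sorted by scaffold then coordinate
#' @export
find_gaps <- function(assembly, min_n_run = 10L) {
  assembly <- as_seq_set(assembly)
  out <- lapply(names(assembly), function(id) {
    s <- as.character(assembly[[id]])
    loc <- stringi::stri_locate_all_regex(
      s, sprintf("N{%d,}", as.integer(min_n_run)))[[1]]
    if (is.na(loc[1, 1])) return(NULL)
    data.frame(scaffold_id = id, start = loc[, 1] - 1L, end = loc[, 2],
               n_run_length = loc[, 2] - loc[, 1] + 1L,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), n_run_length = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(match(df$scaffold_id, names(assembly)), df$start), ]
  rownames(df) <- NULL
  df
}

#' Select a concordant anchor pair for a gap
#'
#' Implements the anchor strategy for gap filling: find two anchor
#' sequences (BAC-like clones) flanking the gap that align uniquely and at
#' high identity to both the draft scaffold and a single donor contig, in
#' the same relative order and orientation on both ("concordantly").
#' Among qualifying pairs the one with the smallest summed gap-to-anchor
#' distance wins.
#'
#' An anchor is usable only if its best placement reaches `min_identity`
#' with at least `min_coverage` of the anchor aligned, and no second
#' placement reaches identity 0.98 over half the anchor (repeat-induced
#' multi-mapping guard).
#'
#' @param gap one row of [find_gaps()] output
#' @param anchors named [Biostrings::DNAStringSet] of anchor sequences
#' @param draft the draft assembly (DNAStringSet)
#' @param donors donor contigs (DNAStringSet)
#' @param min_identity anchor identity gate (default 0.999)
#' @param min_coverage minimum aligned fraction of each anchor (default 0.9)
#' @param max_anchor_distance furthest allowed distance (bp) between the
#'   gap edge and an anchor's draft hit (default `Inf`)
#' @return a list of class `anchor_pair` (fields `left_anchor_id`,
#'   `right_anchor_id`, `donor_id`, `orientation`, `draft_hits`,
#'   `donor_hits`) or `NULL` when no pair qualifies
#' @export
select_anchor_pair <- function(gap, anchors, draft, donors,
                               min_identity = 0.999, min_coverage = 0.9,
                               max_anchor_distance = Inf) {
  anchors <- as_seq_set(anchors, "anchor")
  draft <- as_seq_set(draft, "scaffold")
  donors <- as_seq_set(donors, "donor")
  scaf <- draft[gap$scaffold_id]
  # per anchor: its unique placement on the draft scaffold, and its unique
  # placement within each donor contig separately. An anchor may hit
  # several (overlapping) donors; only multiple placements within one
  # target make it ambiguous (repeat-induced).
  usable <- lapply(names(anchors), function(aid) {
    alen <- Biostrings::width(anchors[aid])
    d <- best_unique_hit(align_local(anchors[aid], scaf, min_identity = 0),
                         alen, min_identity, min_coverage)
    if (is.null(d)) return(NULL)
    per_donor <- list()
    for (did in names(donors)) {
      h <- best_unique_hit(
        align_local(anchors[aid], donors[did], min_identity = 0),
        alen, min_identity, min_coverage)
      if (!is.null(h)) per_donor[[did]] <- h
    }
    if (length(per_donor) == 0L) return(NULL)
    list(id = aid, draft = d, donor = per_donor)
  })
  usable <- usable[!vapply(usable, is.null, TRUE)]
  if (length(usable) < 2L) return(NULL)

  lefts <- Filter(function(u) u$draft$t_end <= gap$start &&
                    gap$start - u$draft$t_end <= max_anchor_distance, usable)
  rights <- Filter(function(u) u$draft$t_start >= gap$end &&
                     u$draft$t_start - gap$end <= max_anchor_distance, usable)
  best <- NULL; best_dist <- Inf
  for (L in lefts) for (R in rights) {
    if (L$id == R$id) next
    for (did in intersect(names(L$donor), names(R$donor))) {
      Ld <- L$donor[[did]]; Rd <- R$donor[[did]]
      # relative orientation of each anchor between draft and donor
      sL <- L$draft$strand == Ld$strand
      sR <- R$draft$strand == Rd$strand
      if (sL != sR) next
      orientation <- if (sL) "same" else "inverted"
      # order along donor must match order along draft after orientation
      donor_order_ok <- if (orientation == "same")
        Ld$t_end <= Rd$t_start else Rd$t_end <= Ld$t_start
      if (!donor_order_ok) next
      dist <- (gap$start - L$draft$t_end) + (R$draft$t_start - gap$end)
      if (dist < best_dist) {
        best_dist <- dist
        best <- structure(list(
          left_anchor_id = L$id, right_anchor_id = R$id,
          donor_id = did, orientation = orientation,
          draft_hits = list(left = L$draft, right = R$draft),
          donor_hits = list(left = Ld, right = Rd)),
          class = "anchor_pair")
      }
    }
  }
  best
}

# best placement if it passes identity/coverage gates and is unique;
# hits: data.frame possibly spanning several targets (donor_id column)
best_unique_hit <- function(hits, anchor_len, min_identity, min_coverage) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$score), , drop = FALSE]
  h <- hits[1L, ]
  if (h$identity < min_identity) return(NULL)
  if ((h$q_end - h$q_start) / anchor_len < min_coverage) return(NULL)
  if (nrow(hits) > 1L) {
    rest <- hits[-1L, , drop = FALSE]
    ambiguous <- rest$identity >= 0.98 &
      (rest$q_end - rest$q_start) / anchor_len >= 0.5
    if (any(ambiguous)) return(NULL)
  }
  as.list(h)
}

#' Build a patch plan from a gap and its anchor pair
#'
#' In `span` mode the replaced draft span runs between the inner anchor
#' boundaries (left hit end to right hit start), and the donor span between
#' the corresponding inner boundaries on the donor. In `whole_contig` mode
#' the whole scaffold is replaced by the whole donor contig.
#'
#' @param gap one row of [find_gaps()] output
#' @param pair an `anchor_pair` from [select_anchor_pair()]
#' @param draft,donors sequence sets (used to record stale-detection flanks)
#' @param mode `"span"` (default) or `"whole_contig"`
#' @return list of class `patch_plan`
#' @export
build_patch_plan <- function(gap, pair, draft, donors, mode = c("span", "whole_contig")) {
  mode <- match.arg(mode)
  draft <- as_seq_set(draft)
  donors <- as_seq_set(donors)
  scaffold_id <- gap$scaffold_id
  donor_id <- pair$donor_id
  if (mode == "span") {
    rs <- pair$draft_hits$left$t_end
    re <- pair$draft_hits$right$t_start
    if (pair$orientation == "same") {
      ds <- pair$donor_hits$left$t_end
      de <- pair$donor_hits$right$t_start
    } else {
      ds <- pair$donor_hits$right$t_end
      de <- pair$donor_hits$left$t_start
    }
  } else {
    rs <- 0L; re <- Biostrings::width(draft[scaffold_id])
    ds <- 0L; de <- Biostrings::width(donors[donor_id])
  }
  if (!(rs <= gap$start && re >= gap$end))
    stop("patch plan does not cover the gap")
  if (de <= ds) stop("empty donor span; anchors too close on donor")
  scaf_chr <- as.character(draft[[scaffold_id]])
  structure(list(
    scaffold_id = scaffold_id,
    replaced_span = c(start = as.integer(rs), end = as.integer(re)),
    donor_id = donor_id,
    donor_span = c(start = as.integer(ds), end = as.integer(de)),
    donor_orientation = pair$orientation,
    mode = mode,
    provenance = list(
      left_anchor = pair$left_anchor_id,
      right_anchor = pair$right_anchor_id,
      left_identity = pair$draft_hits$left$identity,
      right_identity = pair$draft_hits$right$identity),
    # draft context recorded at planning time; apply_patch refuses to run
    # if the sequence has changed under the plan
    flank_check = list(
      left = substr(scaf_chr, max(1L, rs - 19L), rs),
      right = substr(scaf_chr, re + 1L, min(nchar(scaf_chr), re + 20L)))),
    class = "patch_plan")
}

#' Apply a patch plan to a draft assembly
#'
#' Splices the donor span (reverse-complemented when the plan's orientation
#' is `inverted`) in place of the replaced draft span. Every base outside
#' the replaced span is untouched. Refuses to run when the draft no longer
#' matches the flanking context recorded in the plan (stale coordinates).
#'
#' @param draft named DNAStringSet
#' @param donor the donor contig collection (DNAStringSet)
#' @param plan a `patch_plan` from [build_patch_plan()]
#' @return list with `assembly` (patched DNAStringSet) and `liftover`
#'   (data.frame: `scaffold_id`, `old_start`, `old_end`, `new_start`,
#'   `new_end`; replaced segments have `NA` new coordinates)
#' @export
apply_patch <- function(draft, donor, plan) {
  draft <- as_seq_set(draft)
  donor <- as_seq_set(donor)
  sid <- plan$scaffold_id
  s <- as.character(draft[[sid]])
  rs <- plan$replaced_span["start"]; re <- plan$replaced_span["end"]
  if (re > nchar(s)) stop("patch plan coordinates exceed scaffold length")
  left_now <- substr(s, max(1L, rs - 19L), rs)
  right_now <- substr(s, re + 1L, min(nchar(s), re + 20L))
  if (!identical(left_now, plan$flank_check$left) ||
      !identical(right_now, plan$flank_check$right))
    stop("stale patch plan: draft sequence changed since planning")
  d <- as.character(donor[[plan$donor_id]])
  ins <- substr(d, plan$donor_span["start"] + 1L, plan$donor_span["end"])
  if (plan$donor_orientation == "inverted") ins <- revcomp(ins)
  patched <- paste0(substr(s, 1L, rs), ins,
                    substr(s, re + 1L, nchar(s)))
  out <- draft
  out[[sid]] <- Biostrings::DNAString(patched)
  shift <- nchar(ins) - (re - rs)
  lift <- data.frame(
    scaffold_id = sid,
    old_start = c(0L, rs, re),
    old_end = c(rs, re, nchar(s)),
    new_start = c(0L, NA_integer_, re + shift),
    new_end = c(rs, NA_integer_, nchar(s) + shift),
    stringsAsFactors = FALSE)
  lift <- lift[lift$old_end > lift$old_start | is.na(lift$new_start), ]
  rownames(lift) <- NULL
  list(assembly = out, liftover = lift)
}

#' Map coordinates through a liftover table
#'
#' @param liftover table from [apply_patch()] or [patch_all()]
#' @param scaffold_id scaffold name
#' @param pos vector of 0-based positions on the old assembly
#' @return new positions; `NA` for positions inside replaced segments
#' @export
lift_position <- function(liftover, scaffold_id, pos) {
  lt <- liftover[liftover$scaffold_id == scaffold_id, , drop = FALSE]
  vapply(pos, function(p) {
    seg <- lt[lt$old_start <= p & p < lt$old_end, , drop = FALSE]
    if (nrow(seg) == 0L || is.na(seg$new_start[1L])) return(NA_integer_)
    as.integer(p - seg$old_start[1L] + seg$new_start[1L])
  }, integer(1))
}

#' Fill all gaps of a draft assembly with donor contigs
#'
#' Iterates gaps in coordinate order, selects a concordant anchor pair for
#' each, and applies non-overlapping patch plans. When two candidate plans
#' overlap, the one with the higher combined anchor identity is kept and
#' the conflict is reported. Patches on a scaffold are applied from right
#' to left so earlier plan coordinates stay valid.
#'
#' @inheritParams select_anchor_pair
#' @param mode `"span"` or `"whole_contig"` (see [build_patch_plan()])
#' @param min_n_run gap definition passed to [find_gaps()]
#' @return list with `assembly` (patched), `report` (one row per gap:
#'   status `filled`/`unfilled`, donor, anchors, identities, reason),
#'   `liftover` (combined liftover table), and `remaining_gaps`
#' @export
patch_all <- function(draft, donors, anchors, min_identity = 0.999,
                      min_coverage = 0.9, mode = c("span", "whole_contig"),
                      min_n_run = 10L, max_anchor_distance = Inf) {
  mode <- match.arg(mode)
  draft <- as_seq_set(draft, "scaffold")
  donors <- as_seq_set(donors, "donor")
  anchors <- as_seq_set(anchors, "anchor")
  gaps <- find_gaps(draft, min_n_run = min_n_run)
  report <- list()
  plans <- list()
  for (i in seq_len(nrow(gaps))) {
    gap <- gaps[i, ]
    rec <- list(scaffold_id = gap$scaffold_id, gap_start = gap$start,
                gap_end = gap$end, status = "unfilled", donor_id = NA,
                left_anchor = NA, right_anchor = NA,
                left_identity = NA_real_, right_identity = NA_real_,
                orientation = NA, reason = "")
    pair <- if (length(anchors) >= 2L)
      select_anchor_pair(gap, anchors, draft, donors,
                         min_identity = min_identity,
                         min_coverage = min_coverage,
                         max_anchor_distance = max_anchor_distance)
    else NULL
    if (is.null(pair)) {
      rec$reason <- "no concordant anchor pair"
      report[[i]] <- rec
      next
    }
    plan <- build_patch_plan(gap, pair, draft, donors, mode = mode)
    rec$status <- "planned"
    rec$donor_id <- plan$donor_id
    rec$left_anchor <- pair$left_anchor_id
    rec$right_anchor <- pair$right_anchor_id
    rec$left_identity <- pair$draft_hits$left$identity
    rec$right_identity <- pair$draft_hits$right$identity
    rec$orientation <- plan$donor_orientation
    plans[[length(plans) + 1L]] <- plan
    report[[i]] <- rec
  }
  report <- do.call(rbind, lapply(report, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(report))
    report <- data.frame(scaffold_id = character(), gap_start = integer(),
                         gap_end = integer(), status = character(),
                         reason = character(), stringsAsFactors = FALSE)

  # resolve overlapping plans: keep higher combined anchor identity
  if (length(plans) > 1L) {
    drop <- rep(FALSE, length(plans))
    comb <- vapply(plans, function(p)
      p$provenance$left_identity + p$provenance$right_identity, 0)
    for (a in seq_along(plans)) for (b in seq_along(plans)) {
      if (a >= b || drop[a] || drop[b]) next
      pa <- plans[[a]]; pb <- plans[[b]]
      if (pa$scaffold_id != pb$scaffold_id) next
      ov <- min(pa$replaced_span["end"], pb$replaced_span["end"]) -
        max(pa$replaced_span["start"], pb$replaced_span["start"])
      if (ov > 0) {
        loser <- if (comb[a] >= comb[b]) b else a
        drop[loser] <- TRUE
        k <- which(report$status == "planned")[loser]
        report$status[k] <- "unfilled"
        report$reason[k] <- "overlapping plan dropped (lower anchor identity)"
      }
    }
    plans <- plans[!drop]
  }

  # apply per scaffold from right to left
  assembly <- draft
  lifts <- list()
  ord <- order(vapply(plans, function(p) p$scaffold_id, ""),
               -vapply(plans, function(p) p$replaced_span[["start"]], 0))
  for (p in plans[ord]) {
    res <- apply_patch(assembly, donors, p)
    assembly <- res$assembly
    lifts[[length(lifts) + 1L]] <- res$liftover
  }
  report$status[report$status == "planned"] <- "filled"
  remaining <- find_gaps(assembly, min_n_run = min_n_run)
  list(assembly = assembly, report = report,
       liftover = if (length(lifts)) do.call(rbind, lifts) else NULL,
       remaining_gaps = remaining)
}
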