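# Classification of excess draft genes: when a family has more members in
# the draft than in the reference, the extra gene is either a cleaved gene
# (two models matching complementary, non-overlapping parts of the
# full-length reference) or a split allele (two near-identical full-length
# copies of the reference).

#' Classify one excess-gene family as cleaved or split
#'
#' Aligns draft members to each other and to the family's full-length
#' reference model. SPLIT: two draft models align to each other with
#' identity > `min_identity` over at least `min_overlap_frac` of their
#' length (both coverages) and each covers most of its own span against
#' the reference. CLEAVED: two draft models occupy near-disjoint footprints
#' on the reference (mutual footprint overlap at most
#' `max_complement_overlap` of the shorter footprint), have no split-grade
#' hit to each other, and jointly cover at least `complement_cover` of the
#' reference. Anything else is UNCLASSIFIED. Evidence is always returned.
#'
#' @param draft_seqs Named character vector of draft member sequences
#'   (>= 2).
#' @param ref_seq Full-length reference sequence (single string).
#' @param min_identity Percent identity threshold for the split rule (95).
#' @param min_overlap_frac Mutual coverage fraction for the split rule
#'   (0.80).
#' @param max_complement_overlap Tolerated footprint overlap for the
#'   cleaved rule, as a fraction of the shorter footprint (0.10; exact-zero
#'   overlap is brittle under alignment fuzz).
#' @param complement_cover Fraction of the reference the joint footprints
#'   must cover for the cleaved rule (0.80).
#' @return List: `verdict` in cleaved/split/unclassified, `evidence`
#'   (data frame of the triggering alignments).
#' @export
classify_family <- function(draft_seqs, ref_seq, min_identity = 95,
                            min_overlap_frac = 0.80,
                            max_complement_overlap = 0.10,
                            complement_cover = 0.80) {
  if (length(draft_seqs) < 2) stop("need >= 2 draft members")
  if (is.null(ref_seq) || !nzchar(ref_seq)) stop("missing reference sequence")
  ids <- names(draft_seqs)
  ref_len <- nchar(ref_seq)
  # footprint of each draft model on the reference
  fp <- lapply(draft_seqs, function(s) align_pair(s, ref_seq))
  ev <- list(); ne <- 0L
  note <- function(type, a, b, h) {
    ne <<- ne + 1L
    ev[[ne]] <<- data.frame(type = type, query = a, subject = b,
                            identity = h$identity, qcov = h$qcov,
                            scov = h$scov, score = h$score,
                            stringsAsFactors = FALSE)
  }
  for (i in seq_along(ids)) note("vs_reference", ids[i], "reference", fp[[i]])
  verdict <- "unclassified"
  pair_ev <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    h <- align_pair(draft_seqs[[i]], draft_seqs[[j]])
    note("draft_vs_draft", ids[i], ids[j], h)
    pair_ev[[paste(i, j)]] <- h
  }
  for (key in names(pair_ev)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    i <- ij[1]; j <- ij[2]
    h <- pair_ev[[key]]
    mutual_split <- h$identity > min_identity &&
      h$qcov >= min_overlap_frac && h$scov >= min_overlap_frac
    if (mutual_split &&
        fp[[i]]$qcov >= min_overlap_frac && fp[[j]]$qcov >= min_overlap_frac) {
      verdict <- "split"
      break
    }
    # cleaved: near-disjoint reference footprints, complementary coverage
    ri <- fp[[i]]$s_range; rj <- fp[[j]]$s_range
    ov <- overlap_len(ri[1], ri[2], rj[1], rj[2])
    shorter <- min(ri[2] - ri[1] + 1, rj[2] - rj[1] + 1)
    joint <- (ri[2] - ri[1] + 1) + (rj[2] - rj[1] + 1) - ov
    if (!mutual_split && ov <= max_complement_overlap * shorter &&
        joint >= complement_cover * ref_len) {
      verdict <- "cleaved"
      break
    }
  }
  list(verdict = verdict, evidence = do.call(rbind, ev))
}

#' Classify every positive-delta family in a clustering
#'
#' Applies [classify_family()] to each family whose draft count exceeds its
#' reference count. The reference model used is the family's longest
#' reference member.
#'
#' @param families Family table with `assembly` column (or parseable
#'   `"label|model"` ids), as fed to [compare_family_sizes()].
#' @param sequences Named character vector covering all member ids.
#' @param draft,reference Assembly labels.
#' @param ... Thresholds passed to [classify_family()].
#' @return List: `table` (family, verdict, n_draft, n_reference) and
#'   `summary` (named counts cleaved/split/unclassified).
#' @export
classify_all <- function(families, sequences, draft = "draft",
                         reference = "reference", ...) {
  cmp <- compare_family_sizes(families, draft, reference)
  if (is.null(families$assembly))
    families$assembly <- sub("\\|.*$", "", families$model_id)
  pos <- cmp$deltas[cmp$deltas$delta > 0, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pos))) {
    fam <- pos$family[i]
    mem <- families[families$family == fam, , drop = FALSE]
    d_ids <- mem$model_id[mem$assembly == draft]
    r_ids <- mem$model_id[mem$assembly == reference]
    verdict <- "unclassified"
    if (length(d_ids) >= 2 && length(r_ids) >= 1) {
      r_seq <- sequences[r_ids]
      ref <- r_seq[[which.max(nchar(r_seq))]]
      verdict <- classify_family(sequences[d_ids], ref, ...)$verdict
    }
    rows[[i]] <- data.frame(family = fam, verdict = verdict,
                            n_draft = pos$n_draft[i],
                            n_reference = pos$n_reference[i],
                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(family = character(), verdict = character(),
                  n_draft = integer(), n_reference = integer(),
                  stringsAsFactors = FALSE)
  smry <- vapply(c("cleaved", "split", "unclassified"),
                 function(v) sum(tab$verdict == v), integer(1))
  list(table = tab, summary = smry)
}
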