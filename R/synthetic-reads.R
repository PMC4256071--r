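# Paired-end cDNA read-pair placement: fragments are sampled from spliced
# transcripts (so inserts behave as if introns were absent, which is what
# lets mRNA evidence jump assembly gaps that coincide with introns) and
# both mates are projected through the fragmentation plan into contig
# coordinates, with gene-of-origin provenance retained.

# transcription-order exon blocks with transcript offsets
tx_blocks <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  te <- cumsum(w)
  data.frame(g_start = ex$start, g_end = ex$end, strand = ex$strand,
             t_start = te - w + 1L, t_end = te, stringsAsFactors = FALSE)
}

# Project mate transcript intervals [a, b] (vectors) into contig
# coordinates under `pieces` (the plan's pieces for this scaffold, in
# genomic order). A mate crossing an exon junction or a contig boundary is
# represented by its longest gap-free, single-contig segment. Returns
# contig/start/end vectors (NA where nothing projects, which cannot happen
# for within-transcript mates).
project_mates <- function(blocks, pieces, a, b) {
  n <- length(a)
  best_len <- integer(n)
  out_ctg <- rep(NA_character_, n)
  out_s <- rep(NA_integer_, n); out_e <- rep(NA_integer_, n)
  ps <- pieces$start; pe <- pieces$end
  for (bi in seq_len(nrow(blocks))) {
    oa <- pmax(a, blocks$t_start[bi]); ob <- pmin(b, blocks$t_end[bi])
    val <- which(oa <= ob)
    if (!length(val)) next
    if (blocks$strand[bi] == "+") {
      gs <- blocks$g_start[bi] + (oa[val] - blocks$t_start[bi])
      ge <- blocks$g_start[bi] + (ob[val] - blocks$t_start[bi])
    } else {
      ge <- blocks$g_end[bi] - (oa[val] - blocks$t_start[bi])
      gs <- blocks$g_end[bi] - (ob[val] - blocks$t_start[bi])
    }
    p1 <- findInterval(gs, ps); p2 <- findInterval(ge, ps)
    for (d in 0:max(p2 - p1)) {
      pc <- p1 + d
      ok <- which(pc <= p2)
      if (!length(ok)) break
      cs <- pmax(gs[ok], ps[pc[ok]]); ce <- pmin(ge[ok], pe[pc[ok]])
      len <- ce - cs + 1L
      # longest segment wins; ties broken by smallest contig id
      cand <- pieces$contig[pc[ok]]
      cur <- out_ctg[val[ok]]
      better <- len > best_len[val[ok]] |
        (len == best_len[val[ok]] & (is.na(cur) | cand < cur))
      upd <- ok[better]
      if (length(upd)) {
        li <- match(upd, ok)
        best_len[val[upd]] <- len[li]
        out_ctg[val[upd]] <- pieces$contig[pc[upd]]
        out_s[val[upd]] <- cs[li] - ps[pc[upd]] + 1L
        out_e[val[upd]] <- ce[li] - ps[pc[upd]] + 1L
      }
    }
  }
  list(contig = out_ctg, start = out_s, end = out_e)
}

#' Simulate paired-end cDNA read pairs with known gene of origin
#'
#' cDNA fragments are drawn from each gene's spliced transcript —
#' uniformly positioned, gene chosen in proportion to `expression` — and
#' the two mates (the fragment's first and last `read_len` bases) are
#' projected through the fragmentation plan into contig coordinates. A
#' fragment whose mates land on different contigs is exactly the evidence
#' that reconnects a cleaved gene. Reads are emitted as placed alignments
#' (no sequencing-error or mapper model): MAPQ 60 and unique placement by
#' default, with `n_multimap` pairs downgraded (MAPQ 0, non-unique) to
#' exercise alignment filters.
#'
#' With `exhaustive = TRUE`, one pair is emitted for every valid fragment
#' start position of every expressed gene (fragment length fixed at
#' `frag_mean`): deterministic saturating coverage, the limit the sampling
#' mode approaches at high depth.
#'
#' @param genome A `sim_genome`.
#' @param plan A `frag_plan` for that genome.
#' @param n_pairs Number of pairs to sample (ignored when `exhaustive`).
#' @param read_len Read length in bp.
#' @param frag_mean,frag_sd Fragment-length law (normal, truncated below at
#'   `2 * read_len` and above at the transcript length).
#' @param exhaustive Emit all placements instead of sampling.
#' @param n_multimap Number of sampled pairs flagged as multi-mappers.
#' @param seed Integer seed.
#' @return `read_pairs` data frame: pair_id, gene, contig1/start1/end1/
#'   mapq1/unique1 and the mate2 equivalents.
#' @export
make_read_pairs <- function(genome, plan, n_pairs, read_len = 75L,
                            frag_mean = 250, frag_sd = 30,
                            exhaustive = FALSE, n_multimap = 0L, seed = 1) {
  if (frag_mean < 2 * read_len)
    stop("fragment size shorter than 2 read lengths")
  expr <- genome$genes$expression
  if (all(expr == 0)) stop("genome has no expressed gene")
  validate_plan(genome, plan)
  pieces_by_scaf <- split(plan$pieces, plan$pieces$scaffold)
  genes <- genome$genes
  blocks <- lapply(genes$gene_id, function(g) tx_blocks(genome, g))
  names(blocks) <- genes$gene_id
  tlen <- vapply(blocks, function(b) b$t_end[nrow(b)], integer(1))
  with_seed(seed, {
    if (exhaustive) {
      F <- as.integer(frag_mean)
      gsel <- character(0); pos <- integer(0); flen <- integer(0)
      for (g in genes$gene_id[expr > 0]) {
        np <- tlen[[g]] - F + 1L
        if (np < 1L) next
        gsel <- c(gsel, rep(g, np))
        pos <- c(pos, seq_len(np))
        flen <- c(flen, rep(F, np))
      }
    } else {
      if (n_pairs == 0L)
        return(read_sam(textConnection_empty_sam()))
      eligible <- expr > 0 & tlen[genes$gene_id] >= 2 * read_len
      if (!any(eligible)) stop("no gene long enough for a fragment")
      gsel <- sample(genes$gene_id[eligible], n_pairs, replace = TRUE,
                     prob = expr[eligible])
      flen <- pmax(2L * read_len,
                   as.integer(round(stats::rnorm(n_pairs, frag_mean, frag_sd))))
      flen <- pmin(flen, tlen[gsel])
      pos <- 1L + as.integer(floor(stats::runif(n_pairs) * (tlen[gsel] - flen + 1L)))
    }
    n <- length(gsel)
    if (n == 0L) return(read_sam(textConnection_empty_sam()))
    m1c <- character(n); m1s <- integer(n); m1e <- integer(n)
    m2c <- character(n); m2s <- integer(n); m2e <- integer(n)
    for (g in unique(gsel)) {
      idx <- which(gsel == g)
      scaf <- genes$scaffold[genes$gene_id == g]
      pp <- pieces_by_scaf[[scaf]]
      b <- blocks[[g]]
      pr1 <- project_mates(b, pp, pos[idx], pos[idx] + read_len - 1L)
      pr2 <- project_mates(b, pp, pos[idx] + flen[idx] - read_len,
                           pos[idx] + flen[idx] - 1L)
      m1c[idx] <- pr1$contig; m1s[idx] <- pr1$start; m1e[idx] <- pr1$end
      m2c[idx] <- pr2$contig; m2s[idx] <- pr2$start; m2e[idx] <- pr2$end
    }
    pairs <- data.frame(
      pair_id = sprintf("rp%07d", seq_len(n)), gene = gsel,
      contig1 = m1c, start1 = m1s, end1 = m1e,
      mapq1 = 60L, unique1 = TRUE,
      contig2 = m2c, start2 = m2s, end2 = m2e,
      mapq2 = 60L, unique2 = TRUE,
      stringsAsFactors = FALSE, row.names = NULL)
    if (n_multimap > 0L) {
      mm <- sample.int(n, min(n_multimap, n))
      pairs$unique1[mm] <- FALSE
      pairs$mapq1[mm] <- 0L
    }
    pairs
  })
}

# an empty read_pairs frame via the SAM reader's empty branch
textConnection_empty_sam <- function() {
  tf <- tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6\tSO:unsorted", tf)
  tf
}
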