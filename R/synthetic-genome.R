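#' Length and count distribution helpers
#'
#' Small constructors returning sampling functions `n -> integer vector`,
#' used to parameterize the genome simulator. `len_lognormal` floors the
#' draw at `min` (lognormal body, hard minimum); `len_constant` is the
#' degenerate law; `count_pois1` is 1 + Poisson(lambda), the simulator's
#' exons-per-gene law (guarantees at least one exon).
#'
#' @param meanlog,sdlog Log-scale parameters of the lognormal.
#' @param min Hard minimum length in bp.
#' @param value Constant value.
#' @param lambda Poisson mean of the (count - 1) part.
#' @return A function taking `n` and returning `n` positive integers.
#' @export
len_lognormal <- function(meanlog, sdlog, min = 1L) {
  force(meanlog); force(sdlog); force(min)
  function(n) pmax(as.integer(min), as.integer(ceiling(stats::rlnorm(n, meanlog, sdlog))))
}

#' @rdname len_lognormal
#' @export
len_constant <- function(value) {
  force(value)
  function(n) rep(as.integer(value), n)
}

#' @rdname len_lognormal
#' @export
count_pois1 <- function(lambda) {
  force(lambda)
  function(n) 1L + stats::rpois(n, lambda)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, STOP_CODONS)
}

# A valid ORF of `len` bases (len %% 3 == 0, len >= 6): ATG, sense codons,
# one stop.
random_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 6)
  n_mid <- len / 3 - 2
  mid <- if (n_mid > 0) paste(sample(sense_codons(), n_mid, replace = TRUE),
                              collapse = "") else ""
  paste0("ATG", mid, sample(STOP_CODONS, 1))
}

#' Simulate a multi-chromosome genome with multi-exon protein-coding genes
#'
#' Builds `n_scaffolds` gap-free scaffolds populated with `n_genes` genes.
#' Each gene's spliced CDS is a valid ORF (starts with ATG, ends with a stop
#' codon, no internal in-frame stop, length divisible by 3); exons are
#' separated by introns and genes by intergenic spacers, all with lengths
#' drawn from the supplied distributions. Strand is random per gene. The
#' returned object carries the full truth annotation, which downstream
#' modules use as provenance.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_scaffolds Number of scaffolds; genes are dealt round-robin.
#' @param exon_len,intron_len,intergenic_len Length laws (`n -> lengths`),
#'   e.g. from [len_lognormal()]. Defaults give compact invertebrate-like
#'   genes (exons ~200 bp, introns ~400 bp, intergenic ~1.5 kb).
#' @param n_exons Exons-per-gene law; default 1 + Poisson(4), i.e. mean 5.
#' @param gc GC fraction of non-coding sequence.
#' @param expression Expression weight given to every gene (relative read
#'   sampling weight); a vector of length `n_genes` is recycled as given.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return A `sim_genome`: list with `seqs` (named DNAStringSet), `genes`
#'   (gene_id, scaffold, strand, expression) and `exons` (gene_id, scaffold,
#'   strand, exon, start, end; 1-based inclusive, genomic order).
#' @export
make_genome <- function(n_genes, n_scaffolds = 3L,
                        exon_len = len_lognormal(log(200), 0.6, min = 30),
                        intron_len = len_lognormal(log(400), 0.7, min = 60),
                        intergenic_len = len_lognormal(log(1500), 0.8, min = 200),
                        n_exons = count_pois1(4),
                        gc = 0.42, expression = 1, seed = 1) {
  stopifnot(n_genes >= 1, n_scaffolds >= 1, n_scaffolds <= n_genes,
            gc > 0, gc < 1)
  for (f in list(exon_len, intron_len, intergenic_len, n_exons)) {
    probe <- with_seed(seed, f(5L))
    if (any(probe <= 0)) stop("length/count distributions must yield positive values")
  }
  expression <- rep_len(expression, n_genes)
  if (any(expression < 0)) stop("expression levels must be non-negative")

  with_seed(seed, {
    scaf_of_gene <- rep_len(seq_len(n_scaffolds), n_genes)
    seqs <- character(n_scaffolds)
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    pos <- rep(0L, n_scaffolds)  # bases written so far per scaffold
    scaf_chunks <- vector("list", n_scaffolds)
    for (s in seq_len(n_scaffolds)) {
      lead <- random_bases(intergenic_len(1L), gc)
      scaf_chunks[[s]] <- list(lead)
      pos[s] <- nchar(lead)
    }
    for (g in seq_len(n_genes)) {
      s <- scaf_of_gene[g]
      k <- n_exons(1L)
      elens <- exon_len(k)
      # force CDS length to a codon multiple (>= 6) by padding the last exon
      pad <- (3L - sum(elens) %% 3L) %% 3L
      elens[k] <- elens[k] + pad
      if (sum(elens) < 6L) elens[k] <- elens[k] + 6L
      cds <- random_orf(sum(elens))
      pieces <- character(2L * k - 1L)
      piece_lens <- integer(2L * k - 1L)
      off <- 0L
      for (j in seq_len(k)) {
        pieces[2L * j - 1L] <- substr(cds, off + 1L, off + elens[j])
        piece_lens[2L * j - 1L] <- elens[j]
        off <- off + elens[j]
        if (j < k) {
          il <- intron_len(1L)
          pieces[2L * j] <- random_bases(il, gc)
          piece_lens[2L * j] <- il
        }
      }
      strand <- sample(c("+", "-"), 1L)
      block <- paste(pieces, collapse = "")
      L <- nchar(block)
      # exon intervals within the block, transcription orientation
      ends <- cumsum(piece_lens)
      starts <- ends - piece_lens + 1L
      ex_idx <- seq(1L, 2L * k - 1L, by = 2L)
      es <- starts[ex_idx]; ee <- ends[ex_idx]
      if (strand == "-") {
        block <- revcomp_chr(block)
        tmp <- L - ee + 1L
        ee <- L - es + 1L
        es <- tmp
        ord <- order(es)
        es <- es[ord]; ee <- ee[ord]
      }
      gstart <- pos[s]
      scaf_chunks[[s]] <- c(scaf_chunks[[s]],
                            list(block, random_bases(intergenic_len(1L), gc)))
      pos[s] <- pos[s] + L + nchar(scaf_chunks[[s]][[length(scaf_chunks[[s]])]])
      gid <- sprintf("g%04d", g)
      genes[[g]] <- data.frame(gene_id = gid, scaffold = sprintf("scf%02d", s),
                               strand = strand, expression = expression[g],
                               stringsAsFactors = FALSE)
      exons[[g]] <- data.frame(gene_id = gid, scaffold = sprintf("scf%02d", s),
                               strand = strand, exon = seq_len(k),
                               start = gstart + es, end = gstart + ee,
                               stringsAsFactors = FALSE)
    }
    seqs <- vapply(scaf_chunks, function(ch) paste(unlist(ch), collapse = ""),
                   character(1))
    names(seqs) <- sprintf("scf%02d", seq_len(n_scaffolds))
    structure(list(
      seqs = Biostrings::DNAStringSet(seqs),
      genes = do.call(rbind, genes),
      exons = do.call(rbind, exons)
    ), class = "sim_genome")
  })
}

#' Spliced CDS of a truth gene
#'
#' Concatenates exon sequence in genomic order and reverse-complements for
#' minus-strand genes, yielding the mRNA/CDS in transcription orientation.
#'
#' @param genome A `sim_genome`.
#' @param gene_id Gene identifier.
#' @return Character scalar (DNA).
#' @export
gene_cds <- function(genome, gene_id) {
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown gene: ", gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  seq <- genome$seqs[[ex$scaffold[1]]]
  s <- paste(vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(seq, ex$start[i], ex$end[i])), character(1)),
    collapse = "")
  if (ex$strand[1] == "-") revcomp_chr(s) else s
}

#' Draw a template contig-length distribution
#'
#' Emulates the heavy-tailed contig-length profile of a highly fragmented
#' crustacean-scale draft assembly (thousands of contigs, strongly skewed
#' lengths): a lognormal body with a hard minimum, or the degenerate
#' all-equal law for tests.
#'
#' @param n Number of lengths (>= 1).
#' @param law `"lognormal"` or `"equal"`.
#' @param meanlog,sdlog Lognormal parameters (defaults give a ~9.5 kb mean
#'   with a long right tail).
#' @param value Length used by the `"equal"` law.
#' @param min_len Hard minimum length.
#' @param seed Integer seed.
#' @return Integer vector of `n` lengths, sorted descending.
#' @export
make_template_lengths <- function(n, law = c("lognormal", "equal"),
                                  meanlog = 8.4, sdlog = 1.2, value = NULL,
                                  min_len = 500L, seed = 1) {
  stopifnot(n >= 1)
  law <- match.arg(law)
  v <- with_seed(seed, switch(law,
    lognormal = pmax(as.integer(min_len),
                     as.integer(ceiling(stats::rlnorm(n, meanlog, sdlog)))),
    equal = {
      if (is.null(value)) stop("law 'equal' needs `value`")
      rep(as.integer(value), n)
    }))
  sort(v, decreasing = TRUE)
}
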