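# Engineered annotation artifacts with known ground truth: split alleles
# (one heterozygous locus assembled as two near-identical apparent
# paralogs), collapsed paralogs (two true duplicates assembled as one
# locus) and cleaved genes (one gene emitted as two complementary
# fragments, as fragmentation produces).

# substitute bases at `rate`, never to the same base; seeded by caller's RNG
mutate_seq <- function(s, rate) {
  if (rate == 0) return(s)
  n <- nchar(s)
  pos <- which(stats::runif(n) < rate)
  if (!length(pos)) return(s)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Engineer a draft annotation with known split/collapsed/cleaved artifacts
#'
#' Builds paired draft and reference gene-sequence sets from a simulated
#' genome's truth annotation. Unaffected genes appear once on each side
#' with identical sequence. For each *split* case the draft carries two
#' full-length near-identical copies of one gene (pairwise identity
#' 1 - `divergence`, emulating a heterozygous locus assembled twice). For
#' each *collapsed* case the reference carries two paralogs (~3% diverged)
#' while the draft carries only one model. For each *cleaved* case the
#' draft carries two complementary non-overlapping fragments of the gene —
#' the same artifact the fragmenter produces when a breakpoint lands inside
#' a gene. Truth labels record the engineered class per gene, giving
#' downstream classifiers an exact oracle.
#'
#' @param genome A `sim_genome`.
#' @param n_split,n_collapsed,n_cleaved Number of genes per artifact class;
#'   their sum must not exceed the gene count.
#' @param divergence Split-allele substitution rate in \[0, 0.05\] (split
#'   alleles are near-identical by construction); default 0.01.
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector, ids
#'   `"draft|..."`/`"reference|..."`), `members` (model_id, assembly,
#'   truth_gene, kind), `labels` (truth_gene, kind).
#' @export
make_artifact_annotation <- function(genome, n_split = 0L, n_collapsed = 0L,
                                     n_cleaved = 0L, divergence = 0.01,
                                     seed = 1) {
  if (divergence < 0 || divergence > 0.05)
    stop("divergence must be in [0, 0.05]: split alleles are near-identical")
  gids <- genome$genes$gene_id
  if (n_split + n_collapsed + n_cleaved > length(gids))
    stop("more artifact cases than truth genes")
  with_seed(seed, {
    picked <- sample(gids, n_split + n_collapsed + n_cleaved)
    kind <- stats::setNames(rep("normal", length(gids)), gids)
    kind[picked] <- rep(c("split", "collapsed", "cleaved"),
                        c(n_split, n_collapsed, n_cleaved))
    seqs <- character(0)
    rows <- list(); n <- 0L
    add <- function(id, assembly, gene, k) {
      n <<- n + 1L
      rows[[n]] <<- data.frame(model_id = id, assembly = assembly,
                               truth_gene = gene, kind = k,
                               stringsAsFactors = FALSE)
    }
    for (g in gids) {
      S <- gene_cds(genome, g)
      k <- kind[[g]]
      if (k == "normal") {
        seqs[paste0("reference|", g)] <- S
        seqs[paste0("draft|", g)] <- S
        add(paste0("reference|", g), "reference", g, k)
        add(paste0("draft|", g), "draft", g, k)
      } else if (k == "split") {
        seqs[paste0("reference|", g)] <- S
        seqs[paste0("draft|", g, ".a")] <- S
        seqs[paste0("draft|", g, ".b")] <- mutate_seq(S, divergence)
        add(paste0("reference|", g), "reference", g, k)
        add(paste0("draft|", g, ".a"), "draft", g, k)
        add(paste0("draft|", g, ".b"), "draft", g, k)
      } else if (k == "collapsed") {
        seqs[paste0("reference|", g, ".a")] <- S
        seqs[paste0("reference|", g, ".b")] <- mutate_seq(S, 0.03)
        seqs[paste0("draft|", g)] <- S
        add(paste0("reference|", g, ".a"), "reference", g, k)
        add(paste0("reference|", g, ".b"), "reference", g, k)
        add(paste0("draft|", g), "draft", g, k)
      } else { # cleaved
        L <- nchar(S)
        m <- floor(L * stats::runif(1, 0.3, 0.7))
        seqs[paste0("reference|", g)] <- S
        seqs[paste0("draft|", g, ".1")] <- substr(S, 1L, m)
        seqs[paste0("draft|", g, ".2")] <- substr(S, m + 1L, L)
        add(paste0("reference|", g), "reference", g, k)
        add(paste0("draft|", g, ".1"), "draft", g, k)
        add(paste0("draft|", g, ".2"), "draft", g, k)
      }
    }
    list(sequences = seqs,
         members = do.call(rbind, rows),
         labels = data.frame(truth_gene = gids, kind = unname(kind[gids]),
                             stringsAsFactors = FALSE))
  })
}
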