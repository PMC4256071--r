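# Emulation of ab initio gene prediction on a fragmented assembly: the truth
# annotation is projected onto contigs, genes are cleaved at contig
# boundaries, and predictors' tendency to report fragments as complete genes
# is modeled by a single probability.

new_gene_models <- function(models, exons) {
  structure(list(models = models, exons = exons), class = "gene_models")
}

empty_gene_models <- function() {
  new_gene_models(
    data.frame(model_id = character(), contig = character(),
               strand = character(), has_start = logical(),
               has_stop = logical(), provenance = character(),
               stringsAsFactors = FALSE),
    data.frame(model_id = character(), contig = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE))
}

#' Project a truth annotation onto the contigs of a fragmentation plan
#'
#' Each truth gene yields one gene model per contig that carries at least
#' one of its exonic bases (intron-only overlap yields nothing: predictors
#' detect exons). Exons are clipped at contig edges and re-expressed in
#' contig coordinates. Completeness is evaluated in transcription order:
#' a model has its start codon iff the CDS 5'-terminal base lies on its
#' contig, and its stop iff the 3'-terminal base does — so an unbroken gene
#' yields exactly one complete model, and a cleaved forward-strand gene
#' yields a first fragment lacking the stop and a last fragment lacking the
#' start. Provenance (the truth gene id) is always recorded.
#'
#' @param genome A `sim_genome` carrying the truth annotation.
#' @param plan A `frag_plan` for that genome.
#' @return A `gene_models` object: `models` (model_id, contig, strand,
#'   has_start, has_stop, provenance) and `exons` (model_id, contig, start,
#'   end; contig coordinates, 1-based inclusive).
#' @export
project_annotation <- function(genome, plan) {
  validate_plan(genome, plan)
  pieces <- split(plan$pieces, plan$pieces$scaffold)
  mrows <- list(); erows <- list(); nm <- 0L
  for (gid in genome$genes$gene_id) {
    g <- genome$genes[genome$genes$gene_id == gid, ]
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    p <- pieces[[g$scaffold]]
    if (is.null(p)) stop("plan lacks scaffold ", g$scaffold)
    five_prime <- if (g$strand == "+") min(ex$start) else max(ex$end)
    three_prime <- if (g$strand == "+") max(ex$end) else min(ex$start)
    cand <- p[p$end >= min(ex$start) & p$start <= max(ex$end), , drop = FALSE]
    part <- 0L
    for (i in seq_len(nrow(cand))) {
      cs <- cand$start[i]; ce <- cand$end[i]
      hit <- ex$end >= cs & ex$start <= ce
      if (!any(hit)) next
      part <- part + 1L
      clip <- ex[hit, , drop = FALSE]
      clip$start <- pmax(clip$start, cs) - cs + 1L
      clip$end <- pmin(clip$end, ce) - cs + 1L
      nm <- nm + 1L
      mid <- sprintf("%s.p%d", gid, part)
      mrows[[nm]] <- data.frame(
        model_id = mid, contig = cand$contig[i], strand = g$strand,
        has_start = five_prime >= cs && five_prime <= ce,
        has_stop = three_prime >= cs && three_prime <= ce,
        provenance = gid, stringsAsFactors = FALSE)
      erows[[nm]] <- data.frame(model_id = mid, contig = cand$contig[i],
                                start = clip$start, end = clip$end,
                                stringsAsFactors = FALSE)
    }
  }
  if (nm == 0L) return(empty_gene_models())
  new_gene_models(do.call(rbind, mrows), do.call(rbind, erows))
}

#' Emulate predictors inventing start/stop codons on fragments
#'
#' Real ab initio predictors typically report a gene fragment as a complete
#' gene, which is why complete-model counts rise with fragmentation. Each
#' missing completeness flag is independently set to TRUE with probability
#' `p_invent`. `p_invent = 1` is the aggressive-predictor limit (every
#' fragment reported complete); `p_invent = 0` the conservative limit.
#'
#' @param models A `gene_models` object.
#' @param p_invent Probability in \[0, 1\]; default 1.
#' @param seed Integer seed.
#' @return The `gene_models` with flags updated; provenance untouched.
#' @export
emulate_boundary_invention <- function(models, p_invent = 1, seed = 1) {
  stopifnot(p_invent >= 0, p_invent <= 1)
  mt <- models$models
  with_seed(seed, {
    miss_start <- !mt$has_start
    mt$has_start[miss_start] <- stats::runif(sum(miss_start)) < p_invent
    miss_stop <- !mt$has_stop
    mt$has_stop[miss_stop] <- stats::runif(sum(miss_stop)) < p_invent
  })
  new_gene_models(mt, models$exons)
}

#' Keep only complete gene models
#'
#' A model is complete when its sequence contains both a start and a stop
#' codon (here: both completeness flags are set).
#'
#' @param models A `gene_models` object.
#' @return The filtered `gene_models`.
#' @export
filter_complete <- function(models) {
  keep <- models$models$has_start & models$models$has_stop
  mt <- models$models[keep, , drop = FALSE]
  rownames(mt) <- NULL
  ex <- models$exons[models$exons$model_id %in% mt$model_id, , drop = FALSE]
  rownames(ex) <- NULL
  new_gene_models(mt, ex)
}

#' Exons-per-gene histogram
#'
#' Fragmentation pushes this distribution toward single-exon models; the
#' histogram and its mean are the standard summary of that collapse.
#'
#' @param models A `gene_models` object.
#' @return List: `histogram` (data frame `n_exons`, `count`) and `mean`.
#' @export
exons_per_gene <- function(models) {
  if (!nrow(models$models))
    return(list(histogram = data.frame(n_exons = integer(), count = integer()),
                mean = NaN))
  cnt <- table(factor(models$exons$model_id, levels = models$models$model_id))
  tab <- table(as.integer(cnt))
  list(histogram = data.frame(n_exons = as.integer(names(tab)),
                              count = as.integer(tab)),
       mean = mean(as.integer(cnt)))
}
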