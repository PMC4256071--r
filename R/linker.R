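# Paired-end RNA-seq correction of fragmentation-induced over-prediction:
# qualifying read pairs whose mates hit exons of two gene models on
# different contigs become edges of a connection graph, and set merging
# (union-find / connected components) collapses connected models into one
# locus.

#' Filter read-pair alignments by mapping quality and uniqueness
#'
#' Keeps pairs where both mates reach `min_mapq` and, when
#' `require_unique`, both are uniquely placed. Dropped counts are reported
#' by reason via `message()`.
#'
#' @param pairs `read_pairs` data frame.
#' @param min_mapq Minimum MAPQ per mate (default 30).
#' @param require_unique Require both mates uniquely placed (default TRUE).
#' @return The filtered pairs.
#' @export
filter_alignments <- function(pairs, min_mapq = 30L, require_unique = TRUE) {
  ok_mapq <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  ok_uni <- if (require_unique) pairs$unique1 & pairs$unique2 else TRUE
  log_count("linker", "pairs dropped for mapq", sum(!ok_mapq))
  log_count("linker", "pairs dropped for multi-mapping", sum(ok_mapq & !ok_uni))
  out <- pairs[ok_mapq & ok_uni, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mate interval -> model ids whose exons it overlaps (>= 1 bp), per contig
overlap_models <- function(contig, start, end, exons_by_contig) {
  res <- vector("list", length(contig))
  for (ctg in unique(contig)) {
    if (is.na(ctg)) next
    ex <- exons_by_contig[[ctg]]
    idx <- which(contig == ctg)
    if (is.null(ex)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start[idx], end[idx]),
      IRanges::IRanges(ex$start, ex$end))
    hit_models <- split(ex$model_id[S4Vectors::subjectHits(ov)],
                        S4Vectors::queryHits(ov))
    for (qn in names(hit_models))
      res[[idx[as.integer(qn)]]] <- unique(hit_models[[qn]])
  }
  res
}

#' Build the model connection graph from paired-end evidence
#'
#' A pair contributes to the edge (g1, g2) iff mate 1 overlaps an exon of
#' g1, mate 2 overlaps an exon of g2, the models differ and their contigs
#' differ (cross-contig evidence only: pairs within one contig say nothing
#' about assembly fragmentation). Support accumulates per edge. Pairs whose
#' contigs carry no known models are skipped and counted.
#'
#' @param pairs Filtered `read_pairs`.
#' @param models A `gene_models` object (exons indexed by contig).
#' @param same_contig Allow edges between models on one contig (off by
#'   default; opt-in for predictor-cleaved rather than assembly-cleaved
#'   models).
#' @return A `connection_graph`: `nodes` (all model ids) and `edges`
#'   (model1, model2, support), model1 < model2.
#' @export
build_connection_graph <- function(pairs, models, same_contig = FALSE) {
  exons_by_contig <- split(models$exons, models$exons$contig)
  known <- unique(models$exons$contig)
  skipped <- sum(!(pairs$contig1 %in% known) | !(pairs$contig2 %in% known))
  log_count("linker", "pairs on contigs without models", skipped)
  h1 <- overlap_models(pairs$contig1, pairs$start1, pairs$end1, exons_by_contig)
  h2 <- overlap_models(pairs$contig2, pairs$start2, pairs$end2, exons_by_contig)
  n1 <- vapply(h1, length, integer(1))
  n2 <- vapply(h2, length, integer(1))
  valid <- which(n1 > 0 & n2 > 0 &
                   (same_contig | pairs$contig1 != pairs$contig2))
  if (length(valid)) {
    # expand every (model of mate1) x (model of mate2) combination per pair
    a <- unlist(mapply(function(x, y) rep(x, each = length(y)),
                       h1[valid], h2[valid], SIMPLIFY = FALSE),
                use.names = FALSE)
    b <- unlist(mapply(function(x, y) rep(y, times = length(x)),
                       h1[valid], h2[valid], SIMPLIFY = FALSE),
                use.names = FALSE)
    keep <- a != b
    e_from <- pmin(a[keep], b[keep]); e_to <- pmax(a[keep], b[keep])
  } else {
    e_from <- character(0); e_to <- character(0)
  }
  if (length(e_from)) {
    key <- paste(e_from, e_to, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(model1 = vapply(parts, `[[`, "", 1L),
                        model2 = vapply(parts, `[[`, "", 2L),
                        support = as.integer(tab), stringsAsFactors = FALSE,
                        row.names = NULL)
  } else {
    edges <- data.frame(model1 = character(), model2 = character(),
                        support = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = models$models$model_id, edges = edges),
            class = "connection_graph")
}

#' Merge connected gene models (set merging)
#'
#' Drops edges with support below `k`, then merges models within each
#' connected component of the remaining graph into one locus. The revised
#' gene count is the original count minus one per extra member of each
#' merged group, so `revised + reduction == original` always holds.
#'
#' @param graph A `connection_graph`.
#' @param k Minimum read-pair support per edge (>= 1).
#' @return A `merge_result`: `groups` (list of model-id sets, size >= 2),
#'   `membership` (model_id, group), `original`, `revised`, `reduction`.
#' @export
merge_models <- function(graph, k = 1L) {
  stopifnot(k >= 1)
  ed <- graph$edges[graph$edges$support >= k, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("model1", "model2")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- unname(groups[vapply(groups, length, integer(1)) >= 2])
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, "", 1L))]
  original <- length(graph$nodes)
  reduction <- sum(vapply(groups, length, integer(1)) - 1L)
  membership <- data.frame(
    model_id = unlist(groups) %||% character(0),
    group = rep(sprintf("grp%05d", seq_along(groups)),
                vapply(groups, length, integer(1))),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(groups = groups, membership = membership,
                 original = original, revised = original - reduction,
                 reduction = reduction),
            class = "merge_result")
}

#' Cumulative-dataset and support-threshold correction curves
#'
#' The cumulative table adds datasets in the given order and reports the
#' revised gene count plus the incremental reduction each dataset brings
#' (support only accumulates, so the revised count is non-increasing). The
#' threshold table pools all datasets and sweeps the minimum read support
#' `k`, reporting the revised count and the number of models collapsed at
#' each `k` (collapsed is non-increasing in `k`).
#'
#' @param datasets List of `read_pairs` data frames (already filtered).
#' @param models A `gene_models` object.
#' @param k_range Integer vector of support thresholds (default 1:10).
#' @param same_contig Passed to [build_connection_graph()].
#' @return List of data frames `cumulative` (n_datasets, n_pairs, revised,
#'   reduction, cumulative_reduction) and `threshold` (k, revised,
#'   collapsed).
#' @export
correction_curves <- function(datasets, models, k_range = 1:10,
                              same_contig = FALSE) {
  stopifnot(length(datasets) >= 1)
  pool <- NULL
  cum <- list()
  prev_revised <- length(models$models$model_id)
  total_pairs <- 0L
  for (i in seq_along(datasets)) {
    pool <- rbind(pool, datasets[[i]])
    total_pairs <- total_pairs + nrow(datasets[[i]])
    gr <- build_connection_graph(pool, models, same_contig = same_contig)
    mr <- merge_models(gr, k = 1L)
    cum[[i]] <- data.frame(n_datasets = i, n_pairs = total_pairs,
                           revised = mr$revised,
                           reduction = prev_revised - mr$revised,
                           cumulative_reduction = mr$reduction)
    prev_revised <- mr$revised
  }
  gr <- build_connection_graph(pool, models, same_contig = same_contig)
  thr <- lapply(k_range, function(k) {
    mr <- merge_models(gr, k = k)
    data.frame(k = k, revised = mr$revised, collapsed = mr$reduction)
  })
  list(cumulative = do.call(rbind, cum), threshold = do.call(rbind, thr))
}

#' Score a merge against synthetic provenance
#'
#' Only possible on synthetic runs, where every model records its truth
#' gene. A merged group is correct iff all members share one truth gene;
#' a truth gene is missed iff it was fragmented into several models that
#' do not all end up in one group.
#'
#' @param merge A `merge_result`.
#' @param models The `gene_models` that were merged (with provenance).
#' @return List: `correct`, `incorrect`, `missed`, and `missed_genes`.
#' @export
recovery_report <- function(merge, models) {
  prov <- stats::setNames(models$models$provenance, models$models$model_id)
  if (any(is.na(prov)) || any(prov == "unknown")) {
    message("[linker] provenance unknown; recovery report skipped")
    return(NULL)
  }
  per_group <- vapply(merge$groups,
                      function(g) length(unique(prov[g])) == 1L, logical(1))
  correct <- sum(per_group)
  incorrect <- sum(!per_group)
  frag_genes <- names(which(table(prov) >= 2))
  group_of <- stats::setNames(merge$membership$group, merge$membership$model_id)
  missed_genes <- frag_genes[vapply(frag_genes, function(g) {
    m <- names(prov)[prov == g]
    gr <- unique(group_of[m])
    length(gr) != 1L || anyNA(gr)
  }, logical(1))]
  list(correct = correct, incorrect = incorrect,
       missed = length(missed_genes), missed_genes = missed_genes)
}
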