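# helpers to build tiny models/pairs tables by hand
mini_models <- function(layout) {
  # layout: list(model_id = list(contig, exon starts/ends))
  mrows <- list(); erows <- list()
  for (mid in names(layout)) {
    s <- layout[[mid]]
    mrows[[mid]] <- data.frame(model_id = mid, contig = s$contig, strand = "+",
                               has_start = TRUE, has_stop = TRUE,
                               provenance = s$prov %||% "unknown",
                               stringsAsFactors = FALSE)
    erows[[mid]] <- data.frame(model_id = mid, contig = s$contig,
                               start = s$start, end = s$end,
                               stringsAsFactors = FALSE)
  }
  structure(list(models = do.call(rbind, mrows), exons = do.call(rbind, erows)),
            class = "gene_models")
}

mini_pair <- function(id, c1, s1, e1, c2, s2, e2, mapq = 60L, unique = TRUE) {
  data.frame(pair_id = id, gene = "g", contig1 = c1, start1 = s1, end1 = e1,
             mapq1 = mapq, unique1 = unique, contig2 = c2, start2 = s2,
             end2 = e2, mapq2 = mapq, unique2 = unique,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("filter_alignments drops by mapq and uniqueness", {
  pairs <- rbind(mini_pair("p1", "c1", 1, 50, "c2", 1, 50),
                 mini_pair("p2", "c1", 1, 50, "c2", 1, 50, mapq = 0L),
                 mini_pair("p3", "c1", 1, 50, "c2", 1, 50, unique = FALSE))
  expect_identical(suppressMessages(filter_alignments(pairs))$pair_id, "p1")
  expect_identical(
    suppressMessages(filter_alignments(pairs, require_unique = FALSE))$pair_id,
    c("p1", "p3"))
  expect_identical(
    suppressMessages(filter_alignments(pairs, min_mapq = 0))$pair_id,
    c("p1", "p2"))
})

test_that("connection graph: exon overlap, cross-contig rule, support", {
  m <- mini_models(list(
    A = list(contig = "c1", start = 100L, end = 200L),
    B = list(contig = "c2", start = 100L, end = 200L),
    C = list(contig = "c2", start = 500L, end = 600L)))
  pairs <- rbind(
    mini_pair("p1", "c1", 150, 180, "c2", 120, 160),   # A-B edge
    mini_pair("p2", "c1", 150, 180, "c2", 120, 160),   # A-B again
    mini_pair("p3", "c2", 120, 160, "c2", 520, 560),   # same contig: no edge
    mini_pair("p4", "c1", 150, 180, "c1", 150, 180),   # same model: no edge
    mini_pair("p5", "c1", 300, 340, "c2", 120, 160),   # mate1 not exonic
    mini_pair("p6", "c9", 10, 40, "c2", 120, 160))     # unknown contig
  gr <- suppressMessages(build_connection_graph(pairs, m))
  expect_identical(gr$edges,
                   data.frame(model1 = "A", model2 = "B", support = 2L,
                              stringsAsFactors = FALSE))
  # opt-in same-contig linking recovers B-C
  gr2 <- suppressMessages(build_connection_graph(pairs, m, same_contig = TRUE))
  expect_true(any(gr2$edges$model1 == "B" & gr2$edges$model2 == "C"))
})

test_that("merge_models: thresholding, components, conservation", {
  m <- mini_models(list(A = list(contig = "c1", start = 1L, end = 9L),
                        B = list(contig = "c2", start = 1L, end = 9L),
                        C = list(contig = "c3", start = 1L, end = 9L)))
  gr <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(model1 = c("A", "B"), model2 = c("B", "C"),
                       support = c(3L, 1L), stringsAsFactors = FALSE)),
    class = "connection_graph")
  r2 <- merge_models(gr, k = 2)
  expect_identical(r2$groups, list(c("A", "B")))
  expect_identical(r2$revised, 2L)
  r1 <- merge_models(gr, k = 1)
  expect_identical(r1$groups, list(c("A", "B", "C")))
  expect_identical(r1$reduction, 2L)
  empty <- structure(list(nodes = c("A", "B", "C"),
                          edges = gr$edges[0, ]), class = "connection_graph")
  r0 <- merge_models(empty, k = 1)
  expect_identical(r0$revised, r0$original)
  expect_identical(r0$reduction, 0L)
})

test_that("merge_models agrees with brute-force transitive closure", {
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    nodes <- sprintf("m%03d", 1:n)
    ne <- sample(0:(2 * n), 1)
    e <- unique(data.frame(
      a = sample(nodes, ne, TRUE), b = sample(nodes, ne, TRUE),
      stringsAsFactors = FALSE))
    e <- e[e$a != e$b, , drop = FALSE]
    edges <- data.frame(model1 = pmin(e$a, e$b), model2 = pmax(e$a, e$b),
                        support = sample(1:3, nrow(e), TRUE),
                        stringsAsFactors = FALSE)
    gr <- structure(list(nodes = nodes, edges = edges),
                    class = "connection_graph")
    for (k in 1:2) {
      mr <- merge_models(gr, k = k)
      keep <- edges[edges$support >= k, , drop = FALSE]
      comp <- closure_components(nodes, keep)
      expect_identical(mr$revised, length(unique(comp)))
      expect_identical(mr$revised + mr$reduction, length(nodes))
    }
  }
})

test_that("correction curves are monotone and conserve counts", {
  g <- fix_genome()
  pl <- fix_plan()
  models <- filter_complete(emulate_boundary_invention(
    project_annotation(g, pl), 1, seed = 1))
  datasets <- lapply(1:3, function(i)
    make_read_pairs(g, pl, 1500, seed = 70 + i))
  cc <- suppressMessages(correction_curves(datasets, models, k_range = 1:10))
  expect_true(all(diff(cc$cumulative$revised) <= 0))
  expect_true(all(diff(cc$threshold$collapsed) <= 0))
  expect_true(all(diff(cc$threshold$revised) >= 0))
  n <- nrow(models$models)
  expect_true(all(cc$threshold$revised + cc$threshold$collapsed == n))
  expect_true(all(cc$cumulative$revised + cc$cumulative$cumulative_reduction == n))
  # duplicating a dataset adds support but changes no component
  cc2 <- suppressMessages(correction_curves(
    list(datasets[[1]], datasets[[1]]), models, k_range = 1))
  expect_identical(cc2$cumulative$reduction[2], 0L)
})

test_that("recovery_report scores merges against provenance", {
  m <- mini_models(list(
    A1 = list(contig = "c1", start = 1L, end = 9L, prov = "gA"),
    A2 = list(contig = "c2", start = 1L, end = 9L, prov = "gA"),
    B1 = list(contig = "c3", start = 1L, end = 9L, prov = "gB"),
    B2 = list(contig = "c4", start = 1L, end = 9L, prov = "gB"),
    C  = list(contig = "c5", start = 1L, end = 9L, prov = "gC")))
  gr <- structure(list(
    nodes = m$models$model_id,
    edges = data.frame(model1 = c("A1", "B1"), model2 = c("A2", "C"),
                       support = c(2L, 1L), stringsAsFactors = FALSE)),
    class = "connection_graph")
  rep1 <- recovery_report(merge_models(gr, k = 1), m)
  expect_identical(rep1$correct, 1L)    # {A1,A2}
  expect_identical(rep1$incorrect, 1L)  # {B1,C}
  expect_identical(rep1$missed_genes, "gB")
  # no reads: every fragmented gene is missed
  rep0 <- recovery_report(merge_models(structure(
    list(nodes = m$models$model_id, edges = gr$edges[0, ]),
    class = "connection_graph"), k = 1), m)
  expect_identical(sort(rep0$missed_genes), c("gA", "gB"))
  # unknown provenance: report skipped
  m2 <- m; m2$models$provenance <- "unknown"
  expect_null(suppressMessages(recovery_report(merge_models(gr, 1), m2)))
})

test_that("split-allele model copies acquire no connecting edges", {
  g <- fix_genome()
  pl <- fix_plan()
  models <- project_annotation(g, pl)
  # duplicate a full-length (single-model) gene onto a phantom second contig,
  # as a split allele would appear: both copies full-length
  singles <- names(which(table(models$models$provenance) == 1))
  mid <- models$models$model_id[models$models$provenance == singles[1]]
  dup_m <- models$models[models$models$model_id == mid, ]
  dup_e <- models$exons[models$exons$model_id == mid, ]
  dup_m$model_id <- "splitcopy"; dup_m$contig <- "phantom"
  dup_e$model_id <- "splitcopy"; dup_e$contig <- "phantom"
  models$models <- rbind(models$models, dup_m)
  models$exons <- rbind(models$exons, dup_e)
  rp <- make_read_pairs(g, pl, 4000, seed = 77)
  gr <- suppressMessages(build_connection_graph(rp, models))
  expect_false(any(gr$edges$model1 == "splitcopy" |
                     gr$edges$model2 == "splitcopy"))
  mr <- merge_models(gr, k = 1)
  expect_false("splitcopy" %in% mr$membership$model_id)
})
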