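test_that("make_genome produces valid ORFs, disjoint exons, and is deterministic", {
  g <- fix_genome()
  expect_equal(nrow(g$genes), 40L)
  stops <- c("TAA", "TAG", "TGA")
  for (gid in g$genes$gene_id[1:10]) {
    cds <- gene_cds(g, gid)
    expect_identical(nchar(cds) %% 3, 0)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% stops)
    # no internal in-frame stop
    codons <- substring(cds, seq(1, nchar(cds) - 3, 3), seq(3, nchar(cds) - 1, 3))
    expect_false(any(codons[-length(codons)] %in% stops))
  }
  # exons disjoint, ordered, within scaffold
  for (gid in g$genes$gene_id) {
    ex <- g$exons[g$exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    expect_true(all(ex$start <= ex$end))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    expect_lte(max(ex$end), Biostrings::width(g$seqs[ex$scaffold[1]]))
  }
  g2 <- make_genome(40, n_scaffolds = 2, seed = 7)
  expect_identical(as.character(g$seqs), as.character(g2$seqs))
  expect_identical(g$exons, g2$exons)
  expect_false(identical(as.character(g$seqs),
                         as.character(make_genome(40, n_scaffolds = 2,
                                                  seed = 8)$seqs)))
})

test_that("single-exon 300 bp construction is forced", {
  g <- make_genome(1, n_scaffolds = 1, n_exons = len_constant(1),
                   exon_len = len_constant(300), seed = 2)
  cds <- gene_cds(g, g$genes$gene_id[1])
  expect_identical(nchar(cds), 300L)
  expect_identical(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, 298, 300) %in% c("TAA", "TAG", "TGA"))
})

test_that("exons-per-gene histogram matches the requested law (chi-square)", {
  g <- make_genome(300, n_scaffolds = 3, n_exons = count_pois1(4), seed = 41)
  obs <- table(factor(pmin(table(g$exons$gene_id), 11), levels = 1:11))
  p <- stats::dpois(0:9, 4)
  p <- c(p, 1 - sum(p))  # counts 1..10 and 11+ tail
  chi <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p))
  expect_gt(chi$p.value, 1e-3)
})

test_that("make_genome rejects bad inputs", {
  expect_error(make_genome(0), "n_genes")
  expect_error(make_genome(5, exon_len = function(n) rep(-1L, n)), "positive")
  expect_error(make_genome(5, expression = -1), "non-negative")
})

test_that("make_template_lengths: laws, ordering, floor", {
  expect_identical(make_template_lengths(4, law = "equal", value = 250),
                   rep(250L, 4))
  tl <- make_template_lengths(17941, seed = 1)
  expect_length(tl, 17941)
  expect_identical(tl, sort(tl, decreasing = TRUE))
  expect_true(all(tl >= 500))
  expect_identical(tl, make_template_lengths(17941, seed = 1))
  expect_error(make_template_lengths(0), "n >= 1")
})

test_that("make_artifact_annotation engineers the stated identities", {
  g <- make_genome(12, n_scaffolds = 2, seed = 5)
  art <- make_artifact_annotation(g, n_split = 2, n_collapsed = 1,
                                  n_cleaved = 2, divergence = 0.01, seed = 3)
  expect_setequal(unique(art$labels$kind),
                  c("normal", "split", "collapsed", "cleaved"))
  split_genes <- art$labels$truth_gene[art$labels$kind == "split"]
  for (sg in split_genes) {
    a <- art$sequences[[paste0("draft|", sg, ".a")]]
    b <- art$sequences[[paste0("draft|", sg, ".b")]]
    h <- draftgauge:::align_pair(a, b)
    expect_gt(h$identity, 95)
    expect_gte(h$qcov, 0.8)
    expect_gte(h$scov, 0.8)
  }
  cleaved_genes <- art$labels$truth_gene[art$labels$kind == "cleaved"]
  for (cg in cleaved_genes) {
    f1 <- art$sequences[[paste0("draft|", cg, ".1")]]
    f2 <- art$sequences[[paste0("draft|", cg, ".2")]]
    expect_identical(paste0(f1, f2),
                     art$sequences[[paste0("reference|", cg)]])
  }
  # identity case: no artifacts -> draft mirrors truth exactly
  id <- make_artifact_annotation(g, seed = 1)
  d <- id$sequences[startsWith(names(id$sequences), "draft|")]
  r <- id$sequences[startsWith(names(id$sequences), "reference|")]
  expect_identical(unname(d), unname(r))
  expect_error(make_artifact_annotation(g, n_split = 1, divergence = 0.2),
               "divergence")
  expect_error(make_artifact_annotation(g, n_split = 10, n_cleaved = 10),
               "more artifact cases")
})

test_that("read pairs respect provenance and contig assignment", {
  g <- fix_genome()
  pl <- fix_plan()
  rp <- make_read_pairs(g, pl, 400, seed = 5)
  expect_identical(nrow(rp), 400L)
  expect_identical(rp, make_read_pairs(g, pl, 400, seed = 5))
  expect_true(all(rp$mapq1 >= 0 & rp$mapq1 <= 60))
  # provenance closure: every mate lies within the contig-projected exons
  # of its gene of origin (direct interval check)
  piece <- pl$pieces
  for (i in sample.int(nrow(rp), 60)) {
    for (m in 1:2) {
      ctg <- rp[[paste0("contig", m)]][i]
      s <- rp[[paste0("start", m)]][i]; e <- rp[[paste0("end", m)]][i]
      pc <- piece[piece$contig == ctg, ]
      gs <- pc$start + s - 1L; ge <- pc$start + e - 1L
      ex <- g$exons[g$exons$gene_id == rp$gene[i], ]
      expect_true(any(ex$start <= gs & ex$end >= ge),
                  label = sprintf("mate %d of %s inside an exon", m, rp$pair_id[i]))
    }
  }
  expect_error(make_read_pairs(g, pl, 10, read_len = 200, frag_mean = 250),
               "2 read lengths")
  g0 <- g; g0$genes$expression <- 0
  expect_error(make_read_pairs(g0, pl, 10), "no expressed gene")
  expect_identical(nrow(make_read_pairs(g, pl, 0)), 0L)
})

test_that("genes on one contig give same-contig pairs; cleaved genes cross", {
  genome <- toy_genome()
  # no cuts: everything on one contig
  rp <- make_read_pairs(genome, toy_plan(integer(0)), 100,
                        read_len = 50, frag_mean = 150, seed = 2)
  expect_true(all(rp$contig1 == rp$contig2))
  # cut between exons 5 and 6 (intron at 1301..1400): junction-spanning
  # fragments must connect the two contigs
  rp2 <- make_read_pairs(genome, toy_plan(1350L), 500,
                         read_len = 50, frag_mean = 150, seed = 2)
  expect_true(any(rp2$contig1 != rp2$contig2))
  cross <- rp2[rp2$contig1 != rp2$contig2, ]
  expect_true(all(cross$contig1 == "ctg000001" & cross$contig2 == "ctg000002"))
})

test_that("engineered multi-mappers are flagged", {
  g <- fix_genome()
  rp <- make_read_pairs(g, fix_plan(), 1000, n_multimap = 100, seed = 6)
  expect_identical(sum(!(rp$unique1 & rp$unique2)), 100L)
  kept <- suppressMessages(filter_alignments(rp))
  expect_identical(nrow(kept), 900L)
})
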