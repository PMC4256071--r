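rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

test_that("all_vs_all_similarity: identity, symmetry, random rejection", {
  set.seed(21)
  s <- rand_seq(600)
  seqs <- c(a = s, b = s, r1 = rand_seq(1000), r2 = rand_seq(1000))
  hits <- all_vs_all_similarity(seqs)
  ab <- hits[hits$query == "a" & hits$subject == "b", ]
  expect_identical(nrow(ab), 1L)
  expect_equal(ab$identity, 100)
  expect_equal(ab$qcov, 1)
  expect_equal(ab$scov, 1)
  # no self hits; two seeded random 1 kb sequences produce no hit
  expect_false(any(hits$query == hits$subject))
  expect_identical(nrow(hits[hits$query == "r1" & hits$subject == "r2", ]), 0L)
  # symmetry with swapped coverages
  for (i in seq_len(nrow(hits))) {
    mirror <- hits[hits$query == hits$subject[i] & hits$subject == hits$query[i], ]
    expect_identical(nrow(mirror), 1L)
    expect_equal(mirror$score, hits$score[i])
    expect_equal(mirror$qcov, hits$scov[i])
  }
  expect_error(all_vs_all_similarity(c(a = "ACGT")), "at least 2")
  expect_error(all_vs_all_similarity(c(a = "", b = "ACGT")), "empty")
})

test_that("kmer-jaccard engine agrees with a direct set computation", {
  set.seed(22)
  s1 <- rand_seq(400)
  s2 <- paste0(substr(s1, 1, 250), rand_seq(150))
  hits <- all_vs_all_similarity(c(x = s1, y = s2), method = "kmer-jaccard",
                                min_score = 0.01)
  km <- function(s, k = 11) {
    v <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(v)))
    unique(pmin(v, rc))
  }
  jac <- length(intersect(km(s1), km(s2))) / length(union(km(s1), km(s2)))
  expect_equal(hits$score[hits$query == "x"], jac)
})

test_that("MCL: cliques, single edges, and the partition property", {
  clique <- function(ids) {
    ij <- t(utils::combn(ids, 2))
    data.frame(query = ij[, 1], subject = ij[, 2], score = 1,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(clique(c("a1", "a2", "a3")), clique(c("b1", "b2", "b3")))
  fam <- mcl_cluster(hits)
  expect_identical(length(unique(fam$family)), 2L)
  expect_identical(sort(fam$model_id[fam$family == fam$family[fam$model_id == "a1"]]),
                   c("a1", "a2", "a3"))
  # single edge
  fam2 <- mcl_cluster(data.frame(query = "A", subject = "B", score = 1))
  expect_identical(length(unique(fam2$family)), 1L)
  # isolated nodes become singleton families; partition property
  fam3 <- mcl_cluster(hits, nodes = c("a1", "b1", "lonely"))
  expect_identical(sort(fam3$model_id),
                   sort(c("a1", "a2", "a3", "b1", "b2", "b3", "lonely")))
  expect_identical(anyDuplicated(fam3$model_id), 0L)
  expect_identical(length(unique(fam3$family)), 3L)
  expect_error(mcl_cluster(hits, inflation = 1), "inflation")
})

test_that("MCL splits a barbell graph; naive dense implementation agrees", {
  ids <- c(paste0("L", 1:4), paste0("R", 1:4))
  ij <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  w <- c(rep(1, 12), 0.1)  # weak bridge
  hits <- data.frame(query = ids[ij[, 1]], subject = ids[ij[, 2]], score = w,
                     stringsAsFactors = FALSE)
  fam <- mcl_cluster(hits, inflation = 2.0)
  expect_identical(length(unique(fam$family)), 2L)
  expect_identical(sort(fam$model_id[fam$family == fam$family[fam$model_id == "L1"]]),
                   paste0("L", 1:4))
  # oracle: independent naive dense MCL on the same matrix
  adj <- matrix(0, 8, 8, dimnames = list(ids, ids))
  adj[ij] <- w; adj <- pmax(adj, t(adj))
  oracle <- naive_mcl(adj, inflation = 2.0)
  fam_int <- as.integer(factor(fam$family[match(ids, fam$model_id)]))
  expect_identical(table(fam_int, oracle)["1", ] > 0,
                   !(table(fam_int, oracle)["2", ] > 0))
})

test_that("MCL families refine connected components; inflation controls granularity", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    ids <- sprintf("n%02d", 1:n)
    m <- sample(n:(2 * n), 1)
    e <- cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    hits <- data.frame(query = ids[e[, 1]], subject = ids[e[, 2]],
                       score = 1, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(hits[, 1:2], directed = FALSE,
                                       vertices = ids)
    comp <- igraph::components(g)$membership
    for (infl in c(1.5, 2, 6)) {
      fam <- mcl_cluster(hits, inflation = infl, nodes = ids)
      fx <- stats::setNames(fam$family, fam$model_id)[ids]
      # no family ever spans two components of the input graph
      expect_true(all(tapply(comp, fx, function(x) length(unique(x))) == 1))
      # MCL cannot be coarser than the components
      expect_gte(length(unique(fx)), length(unique(comp)))
    }
  }
})

test_that("compare_family_sizes deltas and histogram", {
  fams <- data.frame(
    family = c(rep("f1", 5), rep("f2", 2), rep("f3", 1), rep("f4", 6)),
    assembly = c("draft", "draft", "draft", "reference", "reference",
                 "draft", "reference",
                 "reference",
                 rep("draft", 5), "reference"),
    model_id = sprintf("m%02d", 1:14), stringsAsFactors = FALSE)
  cmp <- compare_family_sizes(fams, "draft", "reference")
  d <- stats::setNames(cmp$deltas$delta, cmp$deltas$family)
  expect_identical(d, c(f1 = 1L, f2 = 0L, f3 = -1L, f4 = 4L))
  h <- stats::setNames(cmp$histogram$count, cmp$histogram$bin)
  expect_identical(unname(h[c("-1", "0", "1", ">=+3")]), c(1L, 1L, 1L, 1L))
  expect_identical(sum(cmp$histogram$count), nrow(cmp$deltas))
  expect_error(compare_family_sizes(fams, "nope", "reference"), "unknown label")
})

test_that("end-to-end family recovery on artifact-free assemblies", {
  g <- make_genome(40, n_scaffolds = 2, seed = 17)
  art <- make_artifact_annotation(g, seed = 1)
  hits <- all_vs_all_similarity(art$sequences, method = "kmer-jaccard")
  fam <- mcl_cluster(hits, nodes = names(art$sequences))
  # every family should be exactly one truth gene's draft+reference pair
  truth <- sub("^[a-z]+\\|", "", fam$model_id)
  per_family <- tapply(truth, fam$family, function(x) length(unique(x)))
  expect_gte(mean(per_family == 1), 0.99)
  cmp <- compare_family_sizes(fam, "draft", "reference")
  expect_true(all(cmp$deltas$delta == 0))
})
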