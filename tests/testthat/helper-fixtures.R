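# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

fix_genome <- function() fixture("genome40", function()
  make_genome(40, n_scaffolds = 2, seed = 7))

fix_plan <- function() fixture("plan40", function() {
  tl <- make_template_lengths(200, seed = 3)
  plan_fragmentation(fix_genome(), tl, 40, seed = 11)
})

# Hand-built genome: one scaffold, one forward-strand 10-exon gene with
# 100 bp exons at known positions (exon i spans [200i+1, 200i+100]).
toy_genome <- function(strand = "+") {
  scaffold_len <- 2400L
  starts <- 200L * (1:10) + 1L
  exons <- data.frame(gene_id = "gX", scaffold = "s1", strand = strand,
                      exon = 1:10, start = starts, end = starts + 99L,
                      stringsAsFactors = FALSE)
  seq <- paste(sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE),
               collapse = "")
  structure(list(
    seqs = Biostrings::DNAStringSet(c(s1 = seq)),
    genes = data.frame(gene_id = "gX", scaffold = "s1", strand = strand,
                       expression = 1, stringsAsFactors = FALSE),
    exons = exons), class = "sim_genome")
}

# a frag_plan cutting scaffold s1 (length 2400) at the given last-base
# positions of the left pieces
toy_plan <- function(cuts, scaffold_len = 2400L) {
  bounds <- c(0L, sort(as.integer(cuts)), scaffold_len)
  pieces <- data.frame(
    contig = sprintf("ctg%06d", seq_len(length(bounds) - 1L)),
    scaffold = "s1",
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1L], stringsAsFactors = FALSE)
  structure(list(x = nrow(pieces), seed = 0L,
                 scaffolds = data.frame(scaffold = "s1",
                                        length = scaffold_len,
                                        stringsAsFactors = FALSE),
                 pieces = pieces), class = "frag_plan")
}

# independent naive dense MCL used as oracle (plain loops, no pruning)
naive_mcl <- function(adj, inflation = 2, iters = 60) {
  n <- nrow(adj)
  M <- adj
  for (i in seq_len(n)) M[i, i] <- max(adj[i, ])
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s > 0) M[, j] <- M[, j] / s
    }
  }
  # components of the support, by DFS
  sup <- (M > 1e-9) | t(M > 1e-9)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      stack <- c(stack, which(sup[u, ] & is.na(comp)))
    }
  }
  comp
}

# brute-force transitive closure components via boolean matrix powers
closure_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  if (nrow(edges)) {
    A[cbind(edges$model1, edges$model2)] <- TRUE
    A[cbind(edges$model2, edges$model1)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  match(apply(A, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(A, 1, function(r) paste(which(r), collapse = ","))))
}
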