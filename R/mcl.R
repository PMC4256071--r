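#' Markov clustering (MCL) of a similarity graph
#'
#' Implements the MCL process on the weighted undirected graph defined by
#' the hit list: scores become edge weights, each node receives a self-loop
#' equal to its maximum incident edge weight, columns are normalized to a
#' stochastic matrix, and expansion (matrix squaring) alternates with
#' inflation (entrywise power `inflation`, then column renormalization)
#' until the iterate stabilizes. Families are the connected components of
#' the limit matrix's nonzero structure. Inflation controls granularity:
#' 2.0 is the conventional default; as inflation grows the partition
#' approaches the connected components of the input graph restricted to a
#' hard threshold.
#'
#' @param hits Hit data frame from [all_vs_all_similarity()] (columns
#'   query, subject, score), or any symmetric weighted edge list.
#' @param inflation Inflation exponent (> 1).
#' @param max_iter Iteration cap; non-convergence returns the current
#'   partition with a warning.
#' @param tol Convergence tolerance on the max absolute entry change.
#' @param nodes Optional full node universe; nodes absent from `hits`
#'   become singleton families.
#' @return Data frame (family, model_id); each input node appears exactly
#'   once. Family ids are content-addressed as `fam.<lexicographically
#'   smallest member id>` so reruns are comparable.
#' @export
mcl_cluster <- function(hits, inflation = 2.0, max_iter = 100L, tol = 1e-6,
                        nodes = NULL) {
  stopifnot(inflation > 1)
  ids <- sort(unique(c(hits$query, hits$subject, nodes)))
  n <- length(ids)
  if (n == 0L)
    return(data.frame(family = character(), model_id = character(),
                      stringsAsFactors = FALSE))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(hits)) {
    qi <- match(hits$query, ids); si <- match(hits$subject, ids)
    keep <- qi != si
    M[cbind(qi[keep], si[keep])] <- hits$score[keep]
    M <- pmax(M, t(M))  # enforce symmetry
  }
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                 # expansion
    M <- M^inflation             # inflation
    M[M < 1e-12] <- 0            # prune numerical dust
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current partition")
  # families = connected components of the limit matrix's support
  adj <- (M > 1e-9) | (t(M) > 1e-9)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  fam_name <- vapply(split(ids, comp), min, character(1))
  data.frame(family = paste0("fam.", fam_name[as.character(comp)]),
             model_id = ids, stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-family gene counts between a draft and a reference assembly
#'
#' For every family containing members from either assembly, the family
#' size delta is the draft count minus the reference count: positive deltas
#' are excess draft genes (cleaved fragments or split alleles), negative
#' deltas are deficits (collapsed paralogs or missing genes). The histogram
#' bins deltas at integers with both tails at |delta| >= 3 collapsed into
#' `<=-3` / `>=+3` bins (reported, never dropped).
#'
#' @param families Data frame (family, model_id) as from [mcl_cluster()],
#'   with an `assembly` column, or with model ids of the form
#'   `"<assembly>|<model>"` from which labels are parsed.
#' @param draft,reference Assembly labels to compare.
#' @return List: `deltas` (family, n_draft, n_reference, delta) and
#'   `histogram` (bin, count).
#' @export
compare_family_sizes <- function(families, draft, reference) {
  if (is.null(families$assembly)) {
    if (!all(grepl("|", families$model_id, fixed = TRUE)))
      stop("families need an `assembly` column or 'label|model' ids")
    families$assembly <- sub("\\|.*$", "", families$model_id)
  }
  labs <- unique(families$assembly)
  if (!draft %in% labs) stop("unknown label: ", draft)
  if (!reference %in% labs) stop("unknown label: ", reference)
  sub <- families[families$assembly %in% c(draft, reference), , drop = FALSE]
  fams <- sort(unique(sub$family))
  n_d <- vapply(fams, function(f)
    sum(sub$family == f & sub$assembly == draft), integer(1))
  n_r <- vapply(fams, function(f)
    sum(sub$family == f & sub$assembly == reference), integer(1))
  deltas <- data.frame(family = fams, n_draft = n_d, n_reference = n_r,
                       delta = n_d - n_r, stringsAsFactors = FALSE,
                       row.names = NULL)
  bin <- ifelse(deltas$delta <= -3, "<=-3",
                ifelse(deltas$delta >= 3, ">=+3",
                       as.character(deltas$delta)))
  lv <- c("<=-3", "-2", "-1", "0", "1", "2", ">=+3")
  tab <- table(factor(bin, levels = lv))
  list(deltas = deltas,
       histogram = data.frame(bin = lv, count = as.integer(tab),
                              stringsAsFactors = FALSE))
}
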