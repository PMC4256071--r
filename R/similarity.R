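# All-vs-all sequence similarity: the edge weights feeding family clustering
# and the evidence used by the cleaved/split classifier.

canonical_kmers <- function(s, k = 11L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

align_pair <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 5, gapExtension = 2)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln),
       q_range = c(Biostrings::start(pr), Biostrings::end(pr)),
       s_range = c(Biostrings::start(sr), Biostrings::end(sr)),
       qcov = (Biostrings::end(pr) - Biostrings::start(pr) + 1) / nchar(a),
       scov = (Biostrings::end(sr) - Biostrings::start(sr) + 1) / nchar(b))
}

#' All-vs-all sequence similarity
#'
#' Compares every unordered pair of sequences and reports hits above
#' `min_score`, symmetrically (a hit A-B implies the mirrored hit B-A with
#' the same score) and with self-hits excluded. Two engines:
#' `"local-align"` runs a local (Smith-Waterman) alignment
#' (match 2 / mismatch -3, gap open 5 / extend 2) and reports percent
#' identity plus query/subject coverage of the best local alignment;
#' `"kmer-jaccard"` reports the Jaccard index of canonical k-mer sets
#' (k = 11) as the score, with containment fractions as coverages — much
#' faster, adequate for building a clustering graph.
#'
#' @param sequences Named character vector or DNAStringSet (>= 2, non-empty).
#' @param method `"local-align"` (default) or `"kmer-jaccard"`.
#' @param min_score Hit threshold; defaults to 100 (alignment score) or
#'   0.2 (Jaccard) depending on method.
#' @param k K-mer size for the Jaccard engine.
#' @return Data frame: query, subject, identity (0-100), qcov, scov
#'   (fractions), score.
#' @export
all_vs_all_similarity <- function(sequences,
                                  method = c("local-align", "kmer-jaccard"),
                                  min_score = NULL, k = 11L) {
  method <- match.arg(method)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(sequences))) stop("empty sequences rejected")
  if (is.null(names(sequences))) stop("sequences must be named")
  if (is.null(min_score))
    min_score <- if (method == "local-align") 100 else 0.2
  ids <- names(sequences)
  rows <- list(); n <- 0L
  if (method == "kmer-jaccard") {
    km <- lapply(sequences, canonical_kmers, k = k)
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (method == "local-align") {
        h <- align_pair(sequences[[i]], sequences[[j]])
        if (h$score < min_score) next
        n <- n + 1L
        rows[[n]] <- data.frame(query = ids[i], subject = ids[j],
                                identity = h$identity, qcov = h$qcov,
                                scov = h$scov, score = h$score,
                                stringsAsFactors = FALSE)
      } else {
        inter <- length(intersect(km[[i]], km[[j]]))
        if (inter == 0) next
        uni <- length(union(km[[i]], km[[j]]))
        jac <- inter / uni
        if (jac < min_score) next
        n <- n + 1L
        rows[[n]] <- data.frame(query = ids[i], subject = ids[j],
                                identity = 100 * jac,
                                qcov = inter / length(km[[i]]),
                                scov = inter / length(km[[j]]),
                                score = jac, stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L)
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), qcov = numeric(),
                      scov = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  mirror <- data.frame(query = hits$subject, subject = hits$query,
                       identity = hits$identity, qcov = hits$scov,
                       scov = hits$qcov, score = hits$score,
                       stringsAsFactors = FALSE)
  out <- rbind(hits, mirror)
  out <- out[order(out$query, out$subject), ]
  rownames(out) <- NULL
  out
}
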