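# Fragmentation of an intact genome into a simulated draft assembly, and
# splitting of gapped scaffolds into contigs at long N-runs.

scaffold_lengths <- function(genome) {
  if (inherits(genome, "sim_genome")) {
    stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  } else if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.character(genome)) {
    stats::setNames(nchar(genome), names(genome))
  } else stop("unsupported genome representation")
}

genome_seqs <- function(genome) {
  if (inherits(genome, "sim_genome")) genome$seqs
  else if (methods::is(genome, "DNAStringSet")) genome
  else Biostrings::DNAStringSet(genome)
}

new_assembly <- function(seqs, map) {
  structure(list(seqs = seqs, map = map), class = "assembly")
}

#' Split gapped scaffolds into contigs at long N-runs
#'
#' Scaffolds are cut wherever a run of `N` of length >= `min_gap` occurs;
#' shorter N-runs are retained inside contigs. The default cutoff of 50 bp
#' reflects the longest gap an ab initio predictor can span while still
#' calling a single gene, which makes the contig — not the scaffold — the
#' fundamental unit for gene prediction. Flanking Ns are trimmed from each
#' piece and empty pieces are dropped.
#'
#' @param scaffolds Named character vector or DNAStringSet.
#' @param min_gap Minimum N-run length that splits (>= 1).
#' @return An `assembly`: list of `seqs` (DNAStringSet of gap-free contigs)
#'   and `map` (contig, scaffold, start, end; source interval, 1-based).
#' @export
split_on_gaps <- function(scaffolds, min_gap = 50L) {
  stopifnot(min_gap >= 1)
  if (methods::is(scaffolds, "DNAStringSet"))
    scaffolds <- stats::setNames(as.character(scaffolds), names(scaffolds))
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scf%02d", seq_along(scaffolds))
  rows <- list(); seqs <- character(0); n <- 0L
  for (sid in names(scaffolds)) {
    s <- scaffolds[[sid]]
    L <- nchar(s)
    m <- gregexpr(sprintf("N{%d,}", min_gap), s)[[1]]
    if (m[1] == -1) {
      starts <- 1L; ends <- L
    } else {
      gs <- as.integer(m)
      ge <- gs + attr(m, "match.length") - 1L
      starts <- c(1L, ge + 1L)
      ends <- c(gs - 1L, L)
    }
    for (i in seq_along(starts)) {
      if (starts[i] > ends[i]) next
      piece <- substr(s, starts[i], ends[i])
      # trim flanking Ns of any length; interior short runs stay
      lead <- attr(regexpr("^N*", piece), "match.length")
      trail <- attr(regexpr("N*$", piece), "match.length")
      a <- starts[i] + lead
      b <- ends[i] - trail
      if (a > b) next
      n <- n + 1L
      rows[[n]] <- data.frame(contig = NA_character_, scaffold = sid,
                              start = a, end = b, stringsAsFactors = FALSE)
      seqs[n] <- substr(s, a, b)
    }
  }
  if (n == 0L) {
    return(new_assembly(Biostrings::DNAStringSet(),
                        data.frame(contig = character(), scaffold = character(),
                                   start = integer(), end = integer(),
                                   stringsAsFactors = FALSE)))
  }
  map <- do.call(rbind, rows)
  map$contig <- sprintf("ctg%06d", seq_len(n))
  names(seqs) <- map$contig
  new_assembly(Biostrings::DNAStringSet(seqs), map)
}

#' Drop short contigs
#'
#' Keeps sequences of length >= `min_len`, preserving order. The 1 kb
#' default mirrors the standard pre-annotation filter that removes the very
#' small scaffolds responsible for most incomplete gene predictions.
#'
#' @param contigs An `assembly`, DNAStringSet, or numeric length vector.
#' @param min_len Minimum retained length (>= 0).
#' @return Same representation as the input, filtered.
#' @export
filter_short <- function(contigs, min_len = 1000L) {
  stopifnot(min_len >= 0)
  if (inherits(contigs, "assembly")) {
    keep <- Biostrings::width(contigs$seqs) >= min_len
    if (!any(keep)) warning("all contigs shorter than min_len; empty assembly")
    new_assembly(contigs$seqs[keep], contigs$map[keep, , drop = FALSE])
  } else if (methods::is(contigs, "DNAStringSet")) {
    keep <- Biostrings::width(contigs) >= min_len
    if (!any(keep)) warning("all contigs shorter than min_len; empty set")
    contigs[keep]
  } else {
    keep <- contigs >= min_len
    if (!any(keep)) warning("all contigs shorter than min_len; empty set")
    contigs[keep]
  }
}

#' Plan a random fragmentation into exactly x contigs
#'
#' Takes the longest `x` lengths from a template distribution, rescales them
#' by largest-remainder so they sum exactly to the genome length (the
#' template typically comes from a different-sized genome), shuffles them,
#' and lays them end to end along the concatenated genome. Cuts falling
#' across a scaffold boundary are snapped: the boundary itself becomes a
#' cut and the nearest template cut is dropped, merging the smaller
#' leftover into its neighbor. At most a couple of pieces per scaffold
#' boundary deviate from the template multiset; everything else realizes
#' the rescaled template lengths exactly, the pieces tile every scaffold,
#' and nothing is discarded.
#'
#' @param genome `sim_genome`, DNAStringSet, or named character vector.
#' @param template Integer vector of template contig lengths (any order).
#' @param x Target contig count; `n_scaffolds <= x <= length(template)`.
#' @param seed Integer seed for shuffling/dealing.
#' @return A `frag_plan`: list with `x`, `seed`, `scaffolds` (scaffold,
#'   length) and `pieces` (contig, scaffold, start, end) tiling each
#'   scaffold in order.
#' @export
plan_fragmentation <- function(genome, template, x, seed = 1) {
  sl <- scaffold_lengths(genome)
  x <- as.integer(x)
  if (x > length(template)) stop("x exceeds template size")
  if (x < length(sl)) stop("x must be >= number of scaffolds")
  G <- sum(sl)
  sel <- sort(as.integer(template), decreasing = TRUE)[seq_len(x)]
  scaled <- largest_remainder(sel, G, floor_min = 1L)
  with_seed(seed, {
    shuffled <- sample(scaled)
    cuts <- cumsum(as.numeric(shuffled))[-x]     # internal cuts, concat space
    bounds <- cumsum(as.numeric(sl))
    inner_bounds <- bounds[-length(bounds)]
    # snap: each scaffold boundary becomes a cut; drop the nearest template
    # cut so the piece count stays exactly x
    alive <- !(cuts %in% inner_bounds)
    need <- setdiff(inner_bounds, cuts)
    for (b in need) {
      cand <- which(alive)
      if (!length(cand)) stop("cannot place scaffold boundaries: too few cuts")
      drop <- cand[which.min(abs(cuts[cand] - b))]
      alive[drop] <- FALSE
    }
    final <- sort(c(cuts[alive], inner_bounds))
    edges <- c(0, final, G)
    scaf_of <- findInterval(edges[-1] - 0.5, c(0, bounds))
    offset <- c(0, bounds)[scaf_of]
    pieces <- data.frame(
      contig = sprintf("ctg%06d", seq_len(x)),
      scaffold = names(sl)[scaf_of],
      start = as.integer(edges[-(x + 1L)] - offset + 1L),
      end = as.integer(edges[-1] - offset),
      stringsAsFactors = FALSE)
    structure(list(x = x, seed = as.integer(seed),
                   scaffolds = data.frame(scaffold = names(sl),
                                          length = as.integer(sl),
                                          stringsAsFactors = FALSE),
                   pieces = pieces),
              class = "frag_plan")
  })
}

#' Refine a plan to a larger contig count (nested fragmentation)
#'
#' Adds `x_new - x` cuts to an existing plan without moving any existing
#' breakpoint: pieces are chosen with probability proportional to the
#' number of internal cut sites and cut uniformly at random. Every
#' breakpoint of the coarse plan is a breakpoint of the refined plan, which
#' makes fragmentation-sweep curves exactly monotone rather than monotone
#' in expectation. Realized lengths no longer track the template once
#' refined; sweeps trade that for exact nesting.
#'
#' @param plan A `frag_plan`.
#' @param x_new Target contig count (> `plan$x`).
#' @param seed Integer seed.
#' @return A `frag_plan` with `x_new` pieces nesting `plan`.
#' @export
refine_plan <- function(plan, x_new, seed = 1) {
  x_new <- as.integer(x_new)
  stopifnot(inherits(plan, "frag_plan"), x_new >= plan$x)
  if (x_new == plan$x) return(plan)
  p <- plan$pieces
  with_seed(seed, {
    for (i in seq_len(x_new - plan$x)) {
      sites <- (p$end - p$start)  # internal cut sites per piece
      if (all(sites == 0)) stop("cannot refine: all pieces are single bases")
      j <- sample.int(nrow(p), 1L, prob = sites)
      cut <- p$start[j] + sample.int(sites[j], 1L) - 1L  # last base of left piece
      left <- p[j, ]; right <- p[j, ]
      left$end <- cut; right$start <- cut + 1L
      p <- rbind(p[seq_len(j - 1L), , drop = FALSE], left, right,
                 p[-seq_len(j), , drop = FALSE])
    }
    p$contig <- sprintf("ctg%06d", seq_len(nrow(p)))
    rownames(p) <- NULL
    structure(list(x = x_new, seed = as.integer(seed),
                   scaffolds = plan$scaffolds, pieces = p),
              class = "frag_plan")
  })
}

validate_plan <- function(genome, plan) {
  sl <- scaffold_lengths(genome)
  ps <- plan$scaffolds
  if (!identical(sort(names(sl)), sort(ps$scaffold)) ||
      !all(sl[ps$scaffold] == ps$length))
    stop("plan/genome mismatch: scaffold ids or lengths differ")
  p <- plan$pieces
  for (s in ps$scaffold) {
    q <- p[p$scaffold == s, , drop = FALSE]
    if (q$start[1] != 1L || q$end[nrow(q)] != sl[[s]] ||
        (nrow(q) > 1 && any(q$start[-1] != q$end[-nrow(q)] + 1L)))
      stop("plan pieces do not tile scaffold ", s)
  }
  invisible(TRUE)
}

#' Apply a fragmentation plan
#'
#' Extracts the planned pieces from the genome. Concatenating the contigs
#' of each scaffold in source order reproduces the scaffold exactly.
#'
#' @param genome Genome the plan was built for.
#' @param plan A `frag_plan`.
#' @return An `assembly` with exactly `plan$x` contigs.
#' @export
apply_fragmentation <- function(genome, plan) {
  validate_plan(genome, plan)
  seqs <- genome_seqs(genome)
  p <- plan$pieces
  out <- vapply(seq_len(nrow(p)), function(i)
    as.character(Biostrings::subseq(seqs[[p$scaffold[i]]], p$start[i], p$end[i])),
    character(1))
  names(out) <- p$contig
  new_assembly(Biostrings::DNAStringSet(out), p)
}

#' Assembly summary statistics
#'
#' N50 is the length of the contig at which the cumulative sum of the
#' descending-sorted lengths first reaches half the total assembly size.
#'
#' @param contigs An `assembly`, DNAStringSet, or numeric length vector.
#' @return List: `count`, `total`, `n50`, and `lengths` (sorted descending).
#' @export
assembly_stats <- function(contigs) {
  lens <- if (inherits(contigs, "assembly")) Biostrings::width(contigs$seqs)
  else if (methods::is(contigs, "DNAStringSet")) Biostrings::width(contigs)
  else as.integer(contigs)
  if (!length(lens)) return(list(count = 0L, total = 0L, n50 = 0L,
                                 lengths = integer()))
  lens <- sort(lens, decreasing = TRUE)
  n50 <- lens[which(cumsum(as.numeric(lens)) >= sum(as.numeric(lens)) / 2)[1]]
  list(count = length(lens), total = sum(lens), n50 = as.integer(n50),
       lengths = lens)
}
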