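#' Read and write FASTA
#'
#' Thin wrappers around Biostrings, fixed at 80-column wrapping so that
#' write -> read -> write is byte-identical.
#'
#' @param x A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path File path.
#' @return `read_fasta` returns a [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read and write template contig-length lists
#'
#' Plain text, one positive integer length per line, descending.
#'
#' @param lengths Integer vector.
#' @param path File path.
#' @export
write_template_lengths <- function(lengths, path) {
  writeLines(format(lengths, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_template_lengths
#' @export
read_template_lengths <- function(path) {
  v <- as.integer(readLines(path))
  if (anyNA(v) || any(v <= 0)) stop("template lengths must be positive integers")
  sort(v, decreasing = TRUE)
}

# ---- GFF3 (fixed dialect: gene/mRNA/exon/CDS, canonical attribute order) ----

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  gsub(";", "%3B", gsub("=", "%3D", gsub(",", "%2C", x, fixed = TRUE),
                        fixed = TRUE), fixed = TRUE)
}

gff3_line <- function(seqid, source, type, start, end, score, strand, phase, attrs) {
  paste(seqid, source, type, start, end, score, strand, phase, attrs, sep = "\t")
}

#' Write a truth annotation as GFF3
#'
#' One `gene` / `mRNA` pair per gene plus `exon` and `CDS` features (every
#' exonic base is coding in the simulator's gene model). Coordinates are
#' 1-based inclusive, matching both the internal representation and GFF3.
#'
#' @param genome A `sim_genome` (see [make_genome()]), or any list with
#'   `genes` and `exons` data frames in the same layout.
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genome, path) {
  genes <- genome$genes
  exons <- genome$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    gid <- gff3_escape(g$gene_id)
    lines <- c(
      gff3_line(g$scaffold, "draftgauge", "gene", min(ex$start), max(ex$end), ".",
                g$strand, ".",
                sprintf("ID=%s;expression=%s", gid,
                        format(g$expression, trim = TRUE))),
      gff3_line(g$scaffold, "draftgauge", "mRNA", min(ex$start), max(ex$end), ".",
                g$strand, ".", sprintf("ID=%s.t1;Parent=%s", gid, gid)),
      vapply(seq_len(nrow(ex)), function(j)
        gff3_line(g$scaffold, "draftgauge", "exon", ex$start[j], ex$end[j], ".",
                  g$strand, ".", sprintf("ID=%s.e%d;Parent=%s.t1", gid, j, gid)),
        character(1)),
      vapply(seq_len(nrow(ex)), function(j)
        gff3_line(g$scaffold, "draftgauge", "CDS", ex$start[j], ex$end[j], ".",
                  g$strand, "0", sprintf("ID=%s.c%d;Parent=%s.t1", gid, j, gid)),
        character(1))
    )
    writeLines(lines, con)
  }
  invisible(path)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(sprintf("(^|;)%s=[^;]*", key), attrs))
  if (length(m) == 0 || m == "") return(NA_character_)
  sub(sprintf("^;?%s=", key), "", m)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  type <- vapply(f, `[[`, "", 3L)
  gene_rows <- f[type == "gene"]
  exon_rows <- f[type == "exon"]
  genes <- data.frame(
    gene_id = vapply(gene_rows, function(x) gff3_attr(x[9], "ID"), ""),
    scaffold = vapply(gene_rows, `[[`, "", 1L),
    strand = vapply(gene_rows, `[[`, "", 7L),
    expression = as.numeric(vapply(gene_rows, function(x)
      gff3_attr(x[9], "expression"), "")),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = sub("\\.t1$", "", vapply(exon_rows, function(x)
      gff3_attr(x[9], "Parent"), "")),
    scaffold = vapply(exon_rows, `[[`, "", 1L),
    strand = vapply(exon_rows, `[[`, "", 7L),
    start = as.integer(vapply(exon_rows, `[[`, "", 4L)),
    end = as.integer(vapply(exon_rows, `[[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  exons$exon <- stats::ave(seq_len(nrow(exons)), exons$gene_id, FUN = seq_along)
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write predicted gene models as GFF3
#'
#' Models live on contigs; completeness flags and true-gene provenance are
#' carried as attributes (`has_start`, `has_stop`, `provenance`) on the
#' `gene` feature. [read_models_gff3()] inverts the writer exactly.
#'
#' @param models A `gene_models` object (see [project_annotation()]).
#' @param path Output path.
#' @export
write_models_gff3 <- function(models, path) {
  mt <- models$models
  ex <- models$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(mt))) {
    m <- mt[i, ]
    e <- ex[ex$model_id == m$model_id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    mid <- gff3_escape(m$model_id)
    lines <- c(
      gff3_line(m$contig, "draftgauge", "gene", min(e$start), max(e$end), ".",
                m$strand, ".",
                sprintf("ID=%s;has_start=%s;has_stop=%s;provenance=%s%s", mid,
                        tolower(m$has_start), tolower(m$has_stop),
                        gff3_escape(m$provenance),
                        if (!is.null(mt$group) && !is.na(m$group))
                          sprintf(";merge_group=%s", gff3_escape(m$group)) else "")),
      vapply(seq_len(nrow(e)), function(j)
        gff3_line(m$contig, "draftgauge", "exon", e$start[j], e$end[j], ".",
                  m$strand, ".", sprintf("ID=%s.e%d;Parent=%s", mid, j, mid)),
        character(1))
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_models_gff3
#' @export
read_models_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  type <- vapply(f, `[[`, "", 3L)
  gr <- f[type == "gene"]
  er <- f[type == "exon"]
  mt <- data.frame(
    model_id = vapply(gr, function(x) gff3_attr(x[9], "ID"), ""),
    contig = vapply(gr, `[[`, "", 1L),
    strand = vapply(gr, `[[`, "", 7L),
    has_start = vapply(gr, function(x) gff3_attr(x[9], "has_start"), "") == "true",
    has_stop = vapply(gr, function(x) gff3_attr(x[9], "has_stop"), "") == "true",
    provenance = vapply(gr, function(x) gff3_attr(x[9], "provenance"), ""),
    stringsAsFactors = FALSE
  )
  grp <- vapply(gr, function(x) gff3_attr(x[9], "merge_group"), "")
  if (any(!is.na(grp))) mt$group <- grp
  ex <- data.frame(
    model_id = vapply(er, function(x) gff3_attr(x[9], "Parent"), ""),
    contig = vapply(er, `[[`, "", 1L),
    start = as.integer(vapply(er, `[[`, "", 4L)),
    end = as.integer(vapply(er, `[[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(match(ex$model_id, mt$model_id), ex$start), ]
  rownames(ex) <- NULL
  structure(list(models = mt, exons = ex), class = "gene_models")
}

# ---- SAM (text; one line per mate, paired via flags; mapq in col 5) --------

#' Write and read placed read pairs as SAM
#'
#' Pairs are emitted as two alignment records with proper `@SQ` headers.
#' Uniqueness is carried in a bwa-style `XT:A:U`/`XT:A:R` tag and
#' gene-of-origin provenance in `XG:Z:`. Sequences are omitted (`*`): the
#' generator places alignments directly, so only coordinates matter.
#'
#' @param pairs A `read_pairs` data frame from [make_read_pairs()].
#' @param contig_lengths Named integer vector of contig lengths for `@SQ`.
#' @param path Output path.
#' @export
write_sam <- function(pairs, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(pairs)) {
    mate_line <- function(flag, contig, start, end, mapq, unique,
                          ncontig, nstart, gene, id) {
      sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*\tXT:A:%s\tXG:Z:%s",
              id, flag, contig, start, as.integer(mapq), end - start + 1L,
              if (ncontig == contig) "=" else ncontig, nstart,
              if (unique) "U" else "R", gene)
    }
    l1 <- mapply(mate_line, 65L, pairs$contig1, pairs$start1, pairs$end1,
                 pairs$mapq1, pairs$unique1, pairs$contig2, pairs$start2,
                 pairs$gene, pairs$pair_id)
    l2 <- mapply(mate_line, 129L, pairs$contig2, pairs$start2, pairs$end2,
                 pairs$mapq2, pairs$unique2, pairs$contig1, pairs$start1,
                 pairs$gene, pairs$pair_id)
    writeLines(as.vector(rbind(l1, l2)), con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  aln <- ln[!startsWith(ln, "@")]
  if (!length(aln)) {
    return(data.frame(pair_id = character(), gene = character(),
                      contig1 = character(), start1 = integer(), end1 = integer(),
                      mapq1 = integer(), unique1 = logical(),
                      contig2 = character(), start2 = integer(), end2 = integer(),
                      mapq2 = integer(), unique2 = logical(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(aln, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  parse_mate <- function(rows) {
    data.frame(
      pair_id = vapply(rows, `[[`, "", 1L),
      contig = vapply(rows, `[[`, "", 3L),
      start = as.integer(vapply(rows, `[[`, "", 4L)),
      mapq = as.integer(vapply(rows, `[[`, "", 5L)),
      len = as.integer(sub("M$", "", vapply(rows, `[[`, "", 6L))),
      unique = vapply(rows, function(x)
        any(x == "XT:A:U"), logical(1)),
      gene = sub("^XG:Z:", "",
                 vapply(rows, function(x) grep("^XG:Z:", x, value = TRUE), "")),
      stringsAsFactors = FALSE
    )
  }
  m1 <- parse_mate(f[bitwAnd(flag, 64L) > 0])
  m2 <- parse_mate(f[bitwAnd(flag, 128L) > 0])
  m2 <- m2[match(m1$pair_id, m2$pair_id), ]
  data.frame(
    pair_id = m1$pair_id, gene = m1$gene,
    contig1 = m1$contig, start1 = m1$start, end1 = m1$start + m1$len - 1L,
    mapq1 = m1$mapq, unique1 = m1$unique,
    contig2 = m2$contig, start2 = m2$start, end2 = m2$start + m2$len - 1L,
    mapq2 = m2$mapq, unique2 = m2$unique,
    stringsAsFactors = FALSE
  )
}

# ---- Fragmentation plan JSON ----------------------------------------------

#' Serialize a fragmentation plan
#'
#' The JSON records seed, target contig count and every piece interval, so a
#' fragmentation is replayable exactly; [read_plan()] inverts it.
#'
#' @param plan A `frag_plan` from [plan_fragmentation()].
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    x = plan$x, seed = plan$seed,
    scaffolds = plan$scaffolds,
    pieces = plan$pieces
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    x = as.integer(obj$x), seed = as.integer(obj$seed),
    scaffolds = data.frame(scaffold = obj$scaffolds$scaffold,
                           length = as.integer(obj$scaffolds$length),
                           stringsAsFactors = FALSE),
    pieces = data.frame(contig = obj$pieces$contig,
                        scaffold = obj$pieces$scaffold,
                        start = as.integer(obj$pieces$start),
                        end = as.integer(obj$pieces$end),
                        stringsAsFactors = FALSE)
  ), class = "frag_plan")
}

# plain TSV with fixed formatting (used by reports)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
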