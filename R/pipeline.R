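# End-to-end experiment orchestration: simulate -> fragment -> emulate
# prediction -> (cluster/classify) -> RNA-seq-correct, fully replayable
# from a config + seed.

#' Default experiment configuration
#'
#' Returns the config list consumed by [run_fragmentation_sweep()] and
#' [run_correction_experiment()]. Fields: `seed`; `genome` (arguments to
#' [make_genome()]); `template` (arguments to [make_template_lengths()]);
#' `x_values` (fragmentation levels, ascending; plans are nested so sweep
#' curves are exactly monotone); `p_invent`; `reads` (read_len, frag_mean,
#' frag_sd, n_datasets, n_pairs or exhaustive); `linker` (min_mapq,
#' require_unique, k_range); `out_dir` (optional; reports are written there
#' as TSV/JSON when set).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_genes = 200L, n_scaffolds = 3L),
    template = list(law = "lognormal"),
    x_values = c(20L, 100L, 500L),
    p_invent = 1.0,
    reads = list(read_len = 75L, frag_mean = 250, frag_sd = 30,
                 n_datasets = 3L, n_pairs = 20000L, exhaustive = FALSE),
    linker = list(min_mapq = 30L, require_unique = TRUE, k_range = 1:10),
    out_dir = NULL
  )
}

#' Read a JSON experiment config
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path JSON file.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(user$seed %||% 1L)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  cfg$x_values <- as.integer(cfg$x_values)
  cfg
}

sweep_plans <- function(genome, cfg) {
  xs <- sort(as.integer(cfg$x_values))
  template <- do.call(make_template_lengths,
                      c(list(n = max(xs)), cfg$template,
                        list(seed = cfg$seed + 1L)))
  plans <- vector("list", length(xs))
  plans[[1]] <- plan_fragmentation(genome, template, xs[1],
                                   seed = cfg$seed + 2L)
  for (i in seq_along(xs)[-1])
    plans[[i]] <- refine_plan(plans[[i - 1]], xs[i], seed = cfg$seed + 2L + i)
  names(plans) <- as.character(xs)
  plans
}

#' Run a fragmentation sweep
#'
#' Simulates a genome, fragments it at each level in `x_values` with
#' nested plans, emulates prediction, and reports per level the total and
#' complete model counts and the exons-per-model summary — the
#' gene-count-versus-fragmentation curve and the exon-collapse histograms.
#'
#' @param config Config list (see [default_config()]).
#' @return List: `report` (one row per x), `histograms` (exon-count
#'   histograms per x), `genome`, `plans`.
#' @export
run_fragmentation_sweep <- function(config = default_config()) {
  cfg <- config
  genome <- do.call(make_genome, c(cfg$genome, list(seed = cfg$seed)))
  plans <- sweep_plans(genome, cfg)
  rows <- list(); hists <- list()
  for (xc in names(plans)) {
    models <- project_annotation(genome, plans[[xc]])
    models <- emulate_boundary_invention(models, cfg$p_invent,
                                         seed = cfg$seed + 100L + as.integer(xc) %% 1000L)
    complete <- filter_complete(models)
    epg <- exons_per_gene(complete)
    rows[[xc]] <- data.frame(x = as.integer(xc),
                             n_models = nrow(models$models),
                             n_complete = nrow(complete$models),
                             mean_exons = epg$mean)
    hists[[xc]] <- epg$histogram
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report, file.path(cfg$out_dir, "fragmentation_sweep.tsv"))
    for (xc in names(hists))
      write_tsv(hists[[xc]],
                file.path(cfg$out_dir, sprintf("exons_per_gene_x%s.tsv", xc)))
    write_fasta(genome$seqs, file.path(cfg$out_dir, "genome.fa"))
    write_genes_gff3(genome, file.path(cfg$out_dir, "truth.gff3"))
    for (xc in names(plans))
      write_plan(plans[[xc]], file.path(cfg$out_dir, sprintf("plan_x%s.json", xc)))
  }
  list(report = report, histograms = hists, genome = genome, plans = plans)
}

#' Run an RNA-seq correction experiment
#'
#' Fragments a genome at the largest configured level, emulates complete
#' gene models, simulates paired-end cDNA datasets, and produces the
#' cumulative-dataset and support-threshold correction tables plus a
#' provenance-based recovery report.
#'
#' @param config Config list (see [default_config()]).
#' @param sweep Optional result of [run_fragmentation_sweep()] to reuse
#'   (genome and plans); simulated afresh when NULL.
#' @return List: `curves` (cumulative + threshold tables), `recovery`,
#'   `models`, `merge` (k = 1 result on pooled data).
#' @export
run_correction_experiment <- function(config = default_config(), sweep = NULL) {
  cfg <- config
  if (is.null(sweep)) {
    genome <- do.call(make_genome, c(cfg$genome, list(seed = cfg$seed)))
    plans <- sweep_plans(genome, cfg)
  } else {
    genome <- sweep$genome
    plans <- sweep$plans
  }
  plan <- plans[[length(plans)]]
  models <- project_annotation(genome, plan)
  models <- emulate_boundary_invention(models, cfg$p_invent,
                                       seed = cfg$seed + 200L)
  models <- filter_complete(models)
  rd <- cfg$reads
  datasets <- lapply(seq_len(rd$n_datasets), function(i) {
    p <- make_read_pairs(genome, plan,
                         n_pairs = rd$n_pairs, read_len = rd$read_len,
                         frag_mean = rd$frag_mean, frag_sd = rd$frag_sd,
                         exhaustive = isTRUE(rd$exhaustive),
                         seed = cfg$seed + 300L + i)
    filter_alignments(p, min_mapq = cfg$linker$min_mapq,
                      require_unique = cfg$linker$require_unique)
  })
  curves <- correction_curves(datasets, models, k_range = cfg$linker$k_range)
  graph <- build_connection_graph(do.call(rbind, datasets), models)
  merge <- merge_models(graph, k = 1L)
  recovery <- recovery_report(merge, models)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(curves$cumulative, file.path(cfg$out_dir, "correction_cumulative.tsv"))
    write_tsv(curves$threshold, file.path(cfg$out_dir, "correction_threshold.tsv"))
    if (!is.null(recovery))
      jsonlite::write_json(recovery[c("correct", "incorrect", "missed")],
                           file.path(cfg$out_dir, "recovery.json"),
                           auto_unbox = TRUE)
    merged <- models
    merged$models$group <- merge$membership$group[
      match(merged$models$model_id, merge$membership$model_id)]
    write_models_gff3(merged, file.path(cfg$out_dir, "models_merged.gff3"))
  }
  list(curves = curves, recovery = recovery, models = models, merge = merge)
}
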