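# End-to-end orchestration: simulate (or load) -> detect -> annotate ->
# characterize -> compare, with per-stage artifacts and a machine-readable
# summary.

#' Pipeline configuration
#'
#' @param outdir Output directory (created if missing).
#' @param sim A [sim_config] for the synthetic route, or NULL when real
#'   inputs are given.
#' @param inputs For the file route: named list with `pileups`, `fasta`,
#'   `gtf`, `vcf` (optional), `metadata` (TSV with sample/population/
#'   tissue/individual/dna_sample), `expression` (optional TSV),
#'   `gene_lengths` (optional TSV gene_id/length).
#' @param filters A [filter_config]; its `autosome_names` may be left
#'   empty on the synthetic route (filled from the generated reference).
#' @param splice_max_dist Exon-boundary distance threshold for
#'   splice-relevance candidates (default 10 bp).
#' @param alpha Significance threshold for correlation and BH-adjusted
#'   differential tests.
#' @param min_support Sample-support threshold for tSES/pSES calling.
#' @param flank_k Flank size for the base-preference matrices.
#' @param use_vcf_mask Mask candidates with the known-variant set.
#' @param write_artifacts `"all"` writes every stage table; `"summary"`
#'   writes only the summary JSON.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), inputs = NULL,
                            filters = filter_config(),
                            splice_max_dist = 10L, alpha = 0.05,
                            min_support = 3L, flank_k = 10L,
                            use_vcf_mask = TRUE,
                            write_artifacts = c("all", "summary")) {
  stopifnot(splice_max_dist >= 0, alpha > 0, alpha < 1, min_support >= 1)
  structure(list(outdir = outdir, sim = sim, inputs = inputs,
                 filters = filters, splice_max_dist = splice_max_dist,
                 alpha = alpha, min_support = min_support,
                 flank_k = flank_k, use_vcf_mask = isTRUE(use_vcf_mask),
                 write_artifacts = match.arg(write_artifacts)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

load_inputs <- function(cfg) {
  inp <- cfg$inputs
  for (f in c("pileups", "fasta", "metadata"))
    if (!file.exists(inp[[f]]))
      stop("input file missing: ", f, " (", inp[[f]], ")")
  genome <- read_fasta(inp$fasta)
  genes <- if (!is.null(inp$gtf)) read_gtf(inp$gtf)
  list(genome = genome, genes = genes,
       pileups = read_pileup_tsv(inp$pileups),
       metadata = utils::read.delim(inp$metadata),
       variants = if (!is.null(inp$vcf)) read_vcf_positions(inp$vcf),
       expression = if (!is.null(inp$expression))
         as.matrix(utils::read.delim(inp$expression, row.names = 1L)),
       gene_lengths = if (!is.null(inp$gene_lengths)) {
         gl <- utils::read.delim(inp$gene_lengths)
         stats::setNames(gl$length, gl$gene_id)
       },
       truth = NULL, autosomes = cfg$filters$autosome_names)
}

#' Run the full editome pipeline
#'
#' Stages run in dependency order (simulate/load, detect, annotate,
#' characterize, compare, summarize); a stage failure aborts with the
#' stage name while earlier artifacts are retained. The summary JSON
#' reports observation and non-redundant site counts, class fractions,
#' level-distribution fractions, strand tallies, tSES/pSES/pDES counts
#' and nonsynonymous fractions.
#'
#' @param cfg A [pipeline_config].
#' @return (Invisibly) list with all stage results and the summary.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  all_artifacts <- cfg$write_artifacts == "all"
  art <- function(name) file.path(cfg$outdir, name)

  data <- if (is.null(cfg$sim)) {
    stage("load", load_inputs(cfg))
  } else {
    stage("simulate", {
      sim <- simulate_editome(cfg$sim)
      if (all_artifacts) {
        write_fasta(sim$reference$genome, art("reference.fa"))
        write_gtf(sim$reference$genes, art("annotation.gtf"))
        write_vcf(sim$truth$snps, art("known_snps.vcf"))
        write_pileup_tsv(sim$pileups, art("pileups.tsv"))
        data.table::fwrite(sim$samples, art("samples.tsv"), sep = "\t")
        data.table::fwrite(sim$truth$sites, art("truth_sites.tsv"),
                           sep = "\t")
        ex <- data.table::as.data.table(sim$expression,
                                        keep.rownames = "gene_id")
        data.table::fwrite(ex, art("expression.tsv"), sep = "\t")
      }
      list(genome = sim$reference$genome, genes = sim$reference$genes,
           pileups = sim$pileups, metadata = sim$samples,
           variants = variant_set(snps = sim$truth$snps[, c("chrom",
                                                            "pos")]),
           expression = sim$expression, gene_lengths = sim$gene_lengths,
           truth = sim$truth, autosomes = sim$reference$autosomes)
    })
  }

  filters <- cfg$filters
  if (length(filters$autosome_names) == 0L)
    filters$autosome_names <- data$autosomes

  det <- stage("detect", detect_editing(
    data$pileups, data$metadata,
    variants = if (cfg$use_vcf_mask) data$variants,
    cfg = filters))

  ann <- stage("annotate", {
    if (is.null(data$genes)) stop("no gene annotation available")
    annotate_sites(det$sites, data$genes)
  })
  lv_sum <- level_summary(det$observations)
  cls_sum <- class_count_summary(ann, det$observations)
  if (all_artifacts) {
    data.table::fwrite(ann, art("sites.tsv"), sep = "\t")
    data.table::fwrite(det$observations, art("observations.tsv"),
                       sep = "\t")
    write_sites_bed(ann, art("sites.bed"))
  }

  char <- stage("characterize", {
    flanks <- list()
    for (cls in c("A-to-I", "C-to-U")) {
      sel <- ann[ann$canonical_class == cls &
                   ann$resolved_strand %in% c("+", "-")]
      if (nrow(sel) == 0L) next
      fl <- vapply(seq_len(nrow(sel)), function(i)
        extract_flank(data$genome, sel$chrom[i], sel$pos[i],
                      sel$resolved_strand[i], k = cfg$flank_k),
        character(1))
      flanks[[cls]] <- flank_frequency(fl)
      if (all_artifacts) {
        out <- data.table::as.data.table(t(flanks[[cls]]),
                                         keep.rownames = "offset")
        data.table::fwrite(out, art(paste0(
          "flank_", sub("-to-", "", cls), ".tsv")), sep = "\t")
      }
    }
    recoding <- site_recoding(ann, data$genes, data$genome)
    nn <- nearest_site_distances(ann)
    exd <- site_exon_distances(ann, data$genes)
    splice <- exd[exd$is_min &
                    splice_candidate_filter(exd$distance,
                                            cfg$splice_max_dist)]
    if (all_artifacts) {
      data.table::fwrite(recoding, art("recoding.tsv"), sep = "\t")
      data.table::fwrite(exd, art("exon_distances.tsv"), sep = "\t")
    }
    list(flanks = flanks, recoding = recoding,
         recoding_summary = recoding_summary(recoding),
         nearest = nn, exon_distances = exd, splice_candidates = splice)
  })

  comp <- stage("compare", {
    em <- build_matrix(det$observations, data$metadata)
    tses <- call_tses(em, min_support = cfg$min_support)
    tissues <- unique(data$metadata$tissue)
    pses <- data.table::rbindlist(lapply(tissues, function(t)
      call_pses(em, t, min_support = cfg$min_support)))
    pdes <- data.table::rbindlist(lapply(tissues, function(t)
      call_pdes(em, t, alpha = cfg$alpha,
                min_per_group = cfg$min_support)), fill = TRUE)
    cat_ids <- names(Filter(function(gm) !is.na(gm$gene_name) &&
                              gm$gene_name %in% CATALYZER_NAMES,
                            data$genes))
    correlations <- NULL
    if (!is.null(data$expression) && length(cat_ids) > 0L) {
      exm <- expression_matrix(
        data$expression[, data$metadata$sample, drop = FALSE],
        data$gene_lengths)
      correlations <- correlate_with_catalyzers(em, exm, cat_ids,
                                                alpha = cfg$alpha)
    }
    if (all_artifacts) {
      lvdt <- data.table::as.data.table(em$levels,
                                        keep.rownames = "site")
      data.table::fwrite(lvdt, art("editing_matrix.tsv"), sep = "\t")
      data.table::fwrite(tses, art("tses.tsv"), sep = "\t")
      data.table::fwrite(pses, art("pses.tsv"), sep = "\t")
      data.table::fwrite(pdes, art("pdes.tsv"), sep = "\t")
    }
    list(matrix = em, tses = tses, pses = pses, pdes = pdes,
         shared_tissue = shared_site_summary(em, "tissue"),
         shared_population = shared_site_summary(em, "population"),
         correlations = correlations)
  })

  summary <- stage("summarize", {
    nonsyn <- lapply(char$recoding_summary$nonsyn, function(x)
      list(nonsynonymous = x$nonsynonymous, sites = x$sites,
           fraction = round(x$fraction, 4)))
    s <- list(
      n_observations = det$n_observations,
      n_sites = det$n_sites,
      class_fractions = stats::setNames(
        as.list(cls_sum$by_class$percent), cls_sum$by_class$key),
      level_fractions = stats::setNames(
        as.list(lv_sum$levels$percent), lv_sum$levels$threshold),
      strand_tally = stats::setNames(
        as.list(cls_sum$strand_tally$count), cls_sum$strand_tally$key),
      clustered_fraction = round(char$nearest$fraction_below, 4),
      n_tses = nrow(comp$tses), n_pses = nrow(comp$pses),
      n_pdes_tested = nrow(comp$pdes),
      n_pdes = if (nrow(comp$pdes)) sum(comp$pdes$significant) else 0L,
      nonsynonymous = nonsyn)
    jsonlite::write_json(s, art("summary.json"), auto_unbox = TRUE,
                         digits = 8, pretty = TRUE)
    s
  })

  invisible(list(data = data, detection = det, sites = ann,
                 level_summary = lv_sum, class_summary = cls_sum,
                 characterization = char, comparative = comp,
                 summary = summary))
}
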