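# Strand resolution, canonical-class assignment and feature annotation.
#
# The sequencing library is unstranded, so the edited strand is inferred
# from the hosting gene: an A>G change in a plus-strand gene and a T>C
# change in a minus-strand gene are both A-to-I on the transcribed strand;
# likewise C>T (+) and G>A (-) are C-to-U. Sites without a host gene, or
# hosted by genes on both strands whose implied classes disagree, are
# ambiguous.

CANONICAL <- c("A-to-I", "C-to-U", "other", "ambiguous")

class_on_strand <- function(raw, strand) {
  if (strand == "+") {
    if (raw == "AG") return("A-to-I")
    if (raw == "CT") return("C-to-U")
  } else {
    if (raw == "TC") return("A-to-I")
    if (raw == "GA") return("C-to-U")
  }
  "other"
}

#' Resolve canonical editing class and strand from host-gene strands
#'
#' @param ref_base,alt_base Reference and alternative base (forward
#'   reference orientation), distinct, in A/C/G/T.
#' @param host_strands Character vector of strands (`"+"`/`"-"`) of the
#'   hosting genes; may be empty.
#' @return List with `canonical_class` (`A-to-I`, `C-to-U`, `other`,
#'   `ambiguous`) and `resolved_strand` (`+`, `-`, `*`).
#' @export
resolve_class <- function(ref_base, alt_base, host_strands) {
  if (!ref_base %in% BASES || !alt_base %in% BASES)
    stop("invalid base: ", ref_base, "/", alt_base)
  if (ref_base == alt_base) stop("ref and alt base must differ")
  raw <- paste0(ref_base, alt_base)
  strands <- unique(host_strands)
  if (length(strands) == 0L)
    return(list(canonical_class = "ambiguous", resolved_strand = "*"))
  if (length(strands) == 1L)
    return(list(canonical_class = class_on_strand(raw, strands),
                resolved_strand = strands))
  cls_p <- class_on_strand(raw, "+")
  cls_m <- class_on_strand(raw, "-")
  list(canonical_class = if (cls_p == cls_m) cls_p else "ambiguous",
       resolved_strand = "*")
}

FEATURE_LEVELS <- c("CDS", "5'UTR", "3'UTR", "exon_other", "intron",
                    "intergenic")

pos_in <- function(pos, iv) {
  nrow(iv) > 0L && any(iv$start <= pos & iv$end >= pos)
}

#' Assign a genomic feature label to a site
#'
#' Within a hosting transcript the precedence is CDS > 5'UTR > 3'UTR >
#' exon_other > intron; across transcripts the highest-precedence label
#' wins. A site hosted by no gene is intergenic.
#'
#' @param pos 1-based position.
#' @param host_genes List of [gene_model]s whose gene body contains the
#'   site (may be empty).
#' @return List with `feature`, and character vectors `cds_transcripts` /
#'   `exon_transcripts` naming the transcripts hosting the site in their
#'   CDS or exons.
#' @export
assign_feature <- function(pos, host_genes) {
  best <- "intergenic"
  cds_tx <- character(0)
  exon_tx <- character(0)
  for (gm in host_genes) {
    for (tr in gm$transcripts) {
      span <- c(min(tr$exons$start), max(tr$exons$end))
      if (pos < span[1L] || pos > span[2L]) next
      lab <- if (pos_in(pos, tr$cds)) "CDS"
        else if (pos_in(pos, tr$utr5)) "5'UTR"
        else if (pos_in(pos, tr$utr3)) "3'UTR"
        else if (pos_in(pos, tr$exons)) "exon_other"
        else "intron"
      if (lab == "CDS") cds_tx <- c(cds_tx, tr$transcript_id)
      if (lab %in% c("CDS", "5'UTR", "3'UTR", "exon_other"))
        exon_tx <- c(exon_tx, tr$transcript_id)
      if (match(lab, FEATURE_LEVELS) < match(best, FEATURE_LEVELS))
        best <- lab
    }
  }
  list(feature = best, cds_transcripts = cds_tx, exon_transcripts = exon_tx)
}

gene_index <- function(genes) {
  data.table::rbindlist(lapply(genes, function(gm) {
    gb <- gene_body(gm)
    data.table::data.table(gene_id = gm$gene_id, chrom = gm$chrom,
                           start = gb[1L], end = gb[2L],
                           strand = gm$strand, biotype = gm$biotype)
  }))
}

#' Annotate non-redundant sites with class, strand, feature and host genes
#'
#' Host genes are found by intersecting the site position with gene-body
#' intervals (min exon start to max exon end); the canonical class and
#' strand follow [resolve_class], and the feature label follows
#' [assign_feature].
#'
#' @param sites Site table with `chrom`, `pos`, `ref_base`, `alt_base`.
#' @param genes List of [gene_model]s.
#' @return `sites` with added columns `raw_type`, `canonical_class`,
#'   `resolved_strand`, `feature`, `host_genes` (comma-joined ids),
#'   `biotype` (of the first host gene), `cds_transcripts`,
#'   `exon_transcripts` (comma-joined transcript ids).
#' @export
annotate_sites <- function(sites, genes) {
  sites <- data.table::as.data.table(sites)
  idx <- gene_index(genes)
  n <- nrow(sites)
  out <- data.table::data.table(
    raw_type = paste0(sites$ref_base, sites$alt_base),
    canonical_class = character(n), resolved_strand = character(n),
    feature = character(n), host_genes = character(n),
    biotype = NA_character_, cds_transcripts = character(n),
    exon_transcripts = character(n))
  for (i in seq_len(n)) {
    hosts <- idx[idx$chrom == sites$chrom[i] & idx$start <= sites$pos[i] &
                   idx$end >= sites$pos[i]]
    rc <- resolve_class(sites$ref_base[i], sites$alt_base[i], hosts$strand)
    fa <- assign_feature(sites$pos[i], genes[hosts$gene_id])
    data.table::set(out, i, "canonical_class", rc$canonical_class)
    data.table::set(out, i, "resolved_strand", rc$resolved_strand)
    data.table::set(out, i, "feature", fa$feature)
    data.table::set(out, i, "host_genes",
                    paste(hosts$gene_id, collapse = ","))
    data.table::set(out, i, "biotype",
                    if (nrow(hosts)) hosts$biotype[1L] else NA_character_)
    data.table::set(out, i, "cds_transcripts",
                    paste(fa$cds_transcripts, collapse = ","))
    data.table::set(out, i, "exon_transcripts",
                    paste(fa$exon_transcripts, collapse = ","))
  }
  cbind(sites, out)
}

RAW_TYPES <- c("AC", "AG", "AT", "CA", "CG", "CT",
               "GA", "GC", "GT", "TA", "TC", "TG")

#' Class, raw-type and strand summary over non-redundant sites
#'
#' All percentages use the non-redundant site total as denominator.
#' Per-sample median counts per raw type are computed from the observation
#' table (each observation's raw type is its ref>alt pair).
#'
#' @param sites Annotated site table ([annotate_sites]).
#' @param observations Optional observation table for the per-sample
#'   median raw-type counts.
#' @return List with `n_sites`, `by_class`, `by_raw_type`, `strand_tally`
#'   (each with counts and percents), and `median_raw_type` (per-sample
#'   median count and its percent share) when observations are given.
#' @export
class_count_summary <- function(sites, observations = NULL) {
  sites <- data.table::as.data.table(sites)
  n <- nrow(sites)
  tab <- function(x, levels) {
    cnt <- table(factor(x, levels = levels))
    data.frame(key = names(cnt), count = as.integer(cnt),
               percent = percent(as.integer(cnt), n))
  }
  out <- list(n_sites = n,
              by_class = tab(sites$canonical_class, CANONICAL),
              by_raw_type = tab(sites$raw_type, RAW_TYPES),
              strand_tally = tab(sites$resolved_strand, c("+", "-", "*")))
  if (!is.null(observations)) {
    obs <- data.table::as.data.table(observations)
    rt <- paste0(obs$ref_base, obs$alt_base)
    cnt <- table(factor(rt, levels = RAW_TYPES), obs$sample)
    med <- apply(cnt, 1L, stats::median)
    out$median_raw_type <- data.frame(
      key = names(med), median_count = as.numeric(med),
      percent = percent(as.numeric(med), sum(med)))
  }
  out
}
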