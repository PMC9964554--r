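# Readers/writers for the external formats the pipeline touches, plus the
# internal pileup-count TSV dialect. All coordinates are 1-based inclusive
# (GTF/VCF native); conversion to 0-based half-open happens only at the BED
# boundary.

PILEUP_HEADER <- c("chrom", "pos", "sample", "source", "A", "C", "G", "T",
                   "mean_qual")
BASES <- c("A", "C", "G", "T")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and multi-line records joined; the header token
#' before the first whitespace becomes the name.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  keys <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(keys))
    stop("duplicate FASTA record key: ", keys[duplicated(keys)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- keys
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

known_biotypes <- c("protein_coding", "lincRNA", "pseudogene",
                    "processed_pseudogene")

#' Construct a gene model
#'
#' A gene model carries the gene-level metadata and one or more transcripts,
#' each with sorted, non-overlapping exon intervals and optional CDS/UTR
#' intervals contained in exons. A transcript whose total CDS length is not a
#' multiple of 3 is flagged (`cds_incomplete`), not rejected.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param biotype One of `protein_coding`, `lincRNA`, `pseudogene`,
#'   `processed_pseudogene`, `other`.
#' @param transcripts Named list; each element a list with `transcript_id`,
#'   and data.frames `exons`, `cds`, `utr5`, `utr3` of 1-based inclusive
#'   `start`/`end` intervals.
#' @param gene_name Optional display name.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, biotype, transcripts,
                       gene_name = NA_character_) {
  gm <- structure(
    list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
         strand = strand,
         biotype = if (biotype %in% known_biotypes) biotype else "other",
         transcripts = transcripts),
    class = "gene_model")
  validate_gene_model(gm)
}

empty_iv <- function() data.frame(start = integer(), end = integer())

iv_df <- function(start, end) {
  stopifnot(length(start) == length(end))
  data.frame(start = as.integer(start), end = as.integer(end))
}

sort_iv <- function(iv) iv[order(iv$start), , drop = FALSE]

iv_contained <- function(inner, outer) {
  # every inner interval inside some outer interval
  if (nrow(inner) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer$start <= inner$start[i] & outer$end >= inner$end[i])
  }, logical(1)))
}

validate_gene_model <- function(gm) {
  if (!gm$strand %in% c("+", "-"))
    stop("gene ", gm$gene_id, ": unknown strand '", gm$strand, "'")
  for (ti in seq_along(gm$transcripts)) {
    tr <- gm$transcripts[[ti]]
    ex <- sort_iv(tr$exons)
    if (nrow(ex) == 0L)
      stop("gene ", gm$gene_id, ": transcript without exons")
    if (any(ex$end < ex$start))
      stop("gene ", gm$gene_id, ": exon end < start")
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("gene ", gm$gene_id, ": overlapping exons in transcript ",
           tr$transcript_id)
    for (part in c("cds", "utr5", "utr3")) {
      if (is.null(tr[[part]])) tr[[part]] <- empty_iv()
      tr[[part]] <- sort_iv(tr[[part]])
      if (!iv_contained(tr[[part]], ex))
        stop("gene ", gm$gene_id, ": ", part,
             " interval outside exons in transcript ", tr$transcript_id)
    }
    cds_len <- sum(tr$cds$end - tr$cds$start + 1L)
    tr$cds_incomplete <- cds_len > 0L && cds_len %% 3L != 0L
    tr$exons <- ex
    gm$transcripts[[ti]] <- tr
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s, %d transcript(s)\n",
              x$gene_id, x$biotype, x$chrom,
              paste(gene_body(x), collapse = "-"), x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' Gene-body span of a gene model
#'
#' @param gm A `gene_model`.
#' @return Integer vector `c(start, end)`: min exon start to max exon end
#'   over all transcripts.
#' @export
gene_body <- function(gm) {
  ex <- do.call(rbind, lapply(gm$transcripts, `[[`, "exons"))
  c(min(ex$start), max(ex$end))
}

#' Read gene models from an Ensembl-dialect GTF
#'
#' Parses gene/transcript/exon/CDS/five_prime_utr/three_prime_utr features.
#' Intervals stay 1-based inclusive; UTRs are taken as annotated, never
#' inferred.
#'
#' @param path Path to a GTF file.
#' @return List of [gene_model] objects, named by gene id.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  strand <- as.character(BiocGenerics::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  gene_id <- as.character(meta$gene_id)
  tx_id <- if ("transcript_id" %in% names(meta))
    as.character(meta$transcript_id) else rep(NA_character_, length(gr))

  tx_known <- unique(tx_id[type == "transcript"])
  part_types <- c(exon = "exon", cds = "CDS", utr5 = "five_prime_utr",
                  utr3 = "three_prime_utr")
  bad <- type %in% part_types & (is.na(tx_id) | !tx_id %in% tx_known)
  if (any(bad))
    stop("feature without parent transcript at ", chrom[bad][1L], ":",
         start[bad][1L])
  if (any(strand[type %in% c("gene", "transcript", part_types)] == "*"))
    stop("unknown strand character in GTF")

  genes <- list()
  for (g in unique(gene_id[type == "gene"])) {
    gi <- which(type == "gene" & gene_id == g)[1L]
    biotype <- if ("gene_biotype" %in% names(meta))
      as.character(meta$gene_biotype[gi]) else "other"
    if (is.na(biotype)) biotype <- "other"
    gname <- if ("gene_name" %in% names(meta))
      as.character(meta$gene_name[gi]) else NA_character_
    txs <- list()
    for (tid in unique(tx_id[type == "transcript" & gene_id == g])) {
      part <- function(tp) {
        sel <- type == tp & tx_id == tid
        sort_iv(iv_df(start[sel], end[sel]))
      }
      txs[[tid]] <- list(transcript_id = tid, exons = part("exon"),
                         cds = part("CDS"), utr5 = part("five_prime_utr"),
                         utr3 = part("three_prime_utr"))
    }
    genes[[g]] <- gene_model(g, chrom[gi], strand[gi], biotype, txs,
                             gene_name = gname)
  }
  genes
}

gtf_attr <- function(...) {
  kv <- c(...)
  paste0(names(kv), " \"", kv, "\";", collapse = " ")
}

#' Write gene models as an Ensembl-dialect GTF
#'
#' @param genes List of [gene_model] objects.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  row <- function(chrom, type, start, end, strand, frame, attrs) {
    sprintf("%s\teditome\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, start, end, strand, frame, attrs)
  }
  for (gm in genes) {
    gb <- gene_body(gm)
    ga <- gtf_attr(gene_id = gm$gene_id, gene_biotype = gm$biotype)
    lines <- c(lines, row(gm$chrom, "gene", gb[1], gb[2], gm$strand, ".", ga))
    for (tr in gm$transcripts) {
      ta <- gtf_attr(gene_id = gm$gene_id, transcript_id = tr$transcript_id,
                     gene_biotype = gm$biotype)
      lines <- c(lines,
                 row(gm$chrom, "transcript", min(tr$exons$start),
                     max(tr$exons$end), gm$strand, ".", ta))
      for (i in seq_len(nrow(tr$exons)))
        lines <- c(lines, row(gm$chrom, "exon", tr$exons$start[i],
                              tr$exons$end[i], gm$strand, ".", ta))
      if (nrow(tr$cds) > 0L) {
        # phase: bases to skip to reach the next codon start, in transcript
        # orientation
        ord <- if (gm$strand == "+") order(tr$cds$start)
               else order(-tr$cds$start)
        lens <- tr$cds$end - tr$cds$start + 1L
        cum <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
        phase <- (3L - cum %% 3L) %% 3L
        for (k in seq_along(ord)) {
          i <- ord[k]
          lines <- c(lines, row(gm$chrom, "CDS", tr$cds$start[i],
                                tr$cds$end[i], gm$strand,
                                as.character(phase[k]), ta))
        }
      }
      utr_types <- c(utr5 = "five_prime_utr", utr3 = "three_prime_utr")
      for (nm in names(utr_types)) {
        iv <- tr[[nm]]
        for (i in seq_len(nrow(iv)))
          lines <- c(lines, row(gm$chrom, utr_types[[nm]], iv$start[i],
                                iv$end[i], gm$strand, ".", ta))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP and INDEL positions from a VCF
#'
#' Keeps only positional information: SNPs as (chrom, pos) where both REF
#' and ALT have length 1, INDELs as 1-based inclusive intervals
#' `(POS, POS + max(len(REF), len(ALT)) - 1)`. Multiallelic records are
#' split per ALT allele.
#'
#' @param path Path to a VCF v4.x file (plain text).
#' @return A `variant_set`: list with data.frames `snps` (chrom, pos) and
#'   `indels` (chrom, start, end).
#' @export
read_vcf_positions <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  snps <- list(); indels <- list()
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L)
      stop("malformed VCF line ", i, ": fewer than 5 fields")
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L)
      stop("malformed VCF line ", i, ": bad POS '", f[2L], "'")
    ref <- f[4L]
    for (alt in strsplit(f[5L], ",", fixed = TRUE)[[1L]]) {
      if (!grepl("^[ACGTNacgtn]+$", alt) || !grepl("^[ACGTNacgtn]+$", ref))
        stop("malformed VCF line ", i, ": unsupported allele '", alt, "'")
      if (nchar(ref) == 1L && nchar(alt) == 1L) {
        snps[[length(snps) + 1L]] <- data.frame(chrom = f[1L], pos = pos)
      } else {
        indels[[length(indels) + 1L]] <- data.frame(
          chrom = f[1L], start = pos,
          end = pos + max(nchar(ref), nchar(alt)) - 1L)
      }
    }
  }
  variant_set(
    snps = if (length(snps)) unique(do.call(rbind, snps)) else
      data.frame(chrom = character(), pos = integer()),
    indels = if (length(indels)) unique(do.call(rbind, indels)) else
      data.frame(chrom = character(), start = integer(), end = integer()))
}

#' Construct a variant set
#'
#' @param snps data.frame with `chrom`, `pos` (1-based).
#' @param indels data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(snps = data.frame(chrom = character(),
                                          pos = integer()),
                        indels = data.frame(chrom = character(),
                                            start = integer(),
                                            end = integer())) {
  stopifnot(all(snps$pos >= 1L), all(indels$start >= 1L),
            all(indels$end >= indels$start))
  structure(list(snps = snps, indels = indels), class = "variant_set")
}

#' Write planted SNPs as a minimal VCF
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  snps$chrom, as.integer(snps$pos), snps$ref, snps$alt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

validate_pileup <- function(dt) {
  counts <- as.matrix(dt[, BASES, with = FALSE])
  if (any(counts < 0L)) stop("negative base count in pileup")
  if (any(!dt$source %in% c("DNA", "RNA")))
    stop("pileup source must be 'DNA' or 'RNA'")
  if (any(dt$pos < 1L)) stop("pileup pos must be >= 1")
  invisible(dt)
}

#' Read the internal pileup-count TSV dialect
#'
#' Tab-separated with header `chrom pos sample source A C G T mean_qual`;
#' counts are forward-reference oriented (the library is unstranded).
#'
#' @param path Path to a pileup TSV.
#' @return data.table with columns chrom, pos, sample, source, A, C, G, T,
#'   mean_qual.
#' @export
read_pileup_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c(1, 3, 4),
                                            integer = c(2, 5, 6, 7, 8),
                                            numeric = 9))
  if (!identical(names(dt), PILEUP_HEADER))
    stop("pileup TSV header must be: ", paste(PILEUP_HEADER, collapse = " "))
  validate_pileup(dt)
  dt[]
}

#' Write pileup records in the internal TSV dialect
#'
#' @param records data.frame/data.table with the pileup columns.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(records, path) {
  dt <- data.table::as.data.table(records)[, PILEUP_HEADER, with = FALSE]
  validate_pileup(dt)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write sites as BED6
#'
#' Converts 1-based site positions to BED 0-based half-open intervals of
#' width 1. Name column holds the canonical class; strand is `"."` for
#' ambiguous sites.
#'
#' @param sites data.frame with `chrom`, `pos`, `canonical_class`,
#'   `resolved_strand`.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  strand <- ifelse(sites$resolved_strand %in% c("+", "-"),
                   sites$resolved_strand, ".")
  writeLines(sprintf("%s\t%d\t%d\t%s\t.\t%s",
                     sites$chrom, as.integer(sites$pos) - 1L,
                     as.integer(sites$pos), sites$canonical_class, strand),
             path)
  invisible(path)
}
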