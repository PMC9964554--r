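# Sequence-context, codon/recoding, clustering and splice-proximity
# analyses of classified editing sites.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Extract the flanking window around an edited base
#'
#' Returns the `2k + 1` bases centered on the site, oriented along the
#' edited (transcribed) strand: minus-strand sites yield the reverse
#' complement of the plus-strand window. Windows running off the
#' chromosome are N-padded so that all windows stay rectangular.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,pos Site coordinates (1-based).
#' @param resolved_strand `"+"` or `"-"`; ambiguous sites must be excluded
#'   by the caller.
#' @param k Flank size on each side (default 10).
#' @return Character scalar of length `2k + 1`.
#' @export
extract_flank <- function(genome, chrom, pos, resolved_strand, k = 10L) {
  if (!resolved_strand %in% c("+", "-"))
    stop("flank extraction requires a resolved strand")
  seq <- genome[[chrom]]
  len <- nchar(seq)
  if (pos < 1L || pos > len) stop("position outside chromosome")
  lo <- pos - k
  hi <- pos + k
  core <- substr(seq, max(lo, 1L), min(hi, len))
  win <- paste0(strrep("N", max(0L, 1L - lo)), core,
                strrep("N", max(0L, hi - len)))
  if (resolved_strand == "-") revcomp(win) else win
}

#' Per-position base frequencies of centered flank windows
#'
#' @param flanks Character vector of equal-length windows (from
#'   [extract_flank]); `N`s contribute nothing.
#' @return 4 x (2k+1) matrix of frequencies; rows A/C/G/T, columns labelled
#'   by offset -k..k; each column with any non-N base sums to 1.
#' @export
flank_frequency <- function(flanks) {
  if (length(flanks) == 0L) stop("no flank sequences given")
  w <- unique(nchar(flanks))
  if (length(w) != 1L) stop("flank windows differ in length")
  if (w %% 2L != 1L) stop("flank windows must have odd length")
  k <- (w - 1L) / 2L
  m <- do.call(rbind, strsplit(flanks, "", fixed = TRUE))
  freq <- sapply(seq_len(w), function(j) {
    cnt <- table(factor(m[, j], levels = BASES))
    tot <- sum(cnt)
    if (tot == 0L) rep(0, 4L) else as.numeric(cnt) / tot
  })
  dimnames(freq) <- list(BASES, as.character(seq(-k, k)))
  freq
}

#' Offset of a genomic position within the spliced CDS
#'
#' Counts coding bases 5' of the site in transcript orientation: the
#' number of CDS bases preceding it after removing non-coding sequence.
#' Minus-strand transcripts count from the rightmost CDS base.
#'
#' @param pos 1-based genomic position, inside a CDS interval.
#' @param transcript Transcript element of a [gene_model] (needs `cds`).
#' @param strand Transcript strand.
#' @return 0-based integer offset in `0 .. CDS_length - 1`.
#' @export
cds_offset <- function(pos, transcript, strand) {
  cds <- sort_iv(transcript$cds)
  hit <- which(cds$start <= pos & cds$end >= pos)
  if (length(hit) == 0L) stop("position ", pos, " not in CDS")
  lens <- cds$end - cds$start + 1L
  if (strand == "+") {
    sum(lens[seq_len(hit - 1L)]) + (pos - cds$start[hit])
  } else {
    n <- nrow(cds)
    after <- if (hit < n) sum(lens[(hit + 1L):n]) else 0L
    after + (cds$end[hit] - pos)
  }
}

#' Codon number and within-codon position from a CDS offset
#'
#' @param offset 0-based offset within the spliced CDS.
#' @return List with `codon_number` (1-based) and `codon_pos` (1, 2 or 3).
#' @export
codon_index <- function(offset) {
  stopifnot(all(offset >= 0))
  list(codon_number = offset %/% 3L + 1L, codon_pos = offset %% 3L + 1L)
}

# Standard genetic code, sense-strand codons.
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Recode a codon by an editing event
#'
#' Substitutes A>G (A-to-I) or C>T (C-to-U) at the edited codon position
#' (codon given sense-strand oriented) and translates both codons with the
#' standard genetic code.
#'
#' @param ref_codon Three-letter reference codon, sense strand.
#' @param codon_pos Edited position within the codon (1, 2 or 3).
#' @param canonical_class `"A-to-I"` or `"C-to-U"`.
#' @return List with `ref_codon`, `edited_codon`, `ref_aa`, `edited_aa`
#'   (single letter, `*` for stop) and `synonymous`.
#' @export
recode <- function(ref_codon, codon_pos, canonical_class) {
  stopifnot(nchar(ref_codon) == 3L, codon_pos %in% 1:3)
  base <- substr(ref_codon, codon_pos, codon_pos)
  sub <- switch(canonical_class, "A-to-I" = c(from = "A", to = "G"),
                "C-to-U" = c(from = "C", to = "T"),
                stop("class must be A-to-I or C-to-U"))
  if (base != sub[["from"]])
    stop("codon base ", base, " at position ", codon_pos,
         " incompatible with ", canonical_class)
  edited <- ref_codon
  substr(edited, codon_pos, codon_pos) <- sub[["to"]]
  ref_aa <- GENETIC_CODE_TABLE[[toupper(ref_codon)]]
  edited_aa <- GENETIC_CODE_TABLE[[toupper(edited)]]
  list(ref_codon = ref_codon, edited_codon = edited, ref_aa = ref_aa,
       edited_aa = edited_aa, synonymous = ref_aa == edited_aa)
}

spliced_cds_seq <- function(genome, chrom, transcript, strand) {
  cds <- sort_iv(transcript$cds)
  parts <- vapply(seq_len(nrow(cds)), function(i)
    substr(genome[[chrom]], cds$start[i], cds$end[i]), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Recoding consequences of CDS-hosted sites
#'
#' For every site x CDS-hosting transcript pair, locates the codon,
#' applies [recode] and reports the amino-acid consequence. Sites whose
#' canonical class is not A-to-I/C-to-U, or that hit an incomplete codon
#' at the CDS end, are skipped.
#'
#' @param sites Annotated site table with `cds_transcripts` set.
#' @param genes List of [gene_model]s.
#' @param genome Named character vector of chromosome sequences.
#' @return data.table with one row per (site, transcript): chrom, pos,
#'   canonical_class, transcript_id, codon_number, codon_pos, ref_codon,
#'   edited_codon, ref_aa, edited_aa, synonymous.
#' @export
site_recoding <- function(sites, genes, genome) {
  sites <- data.table::as.data.table(sites)
  tx_of <- list()
  for (gm in genes)
    for (tr in gm$transcripts)
      tx_of[[tr$transcript_id]] <- list(tr = tr, strand = gm$strand,
                                        chrom = gm$chrom)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    cls <- sites$canonical_class[i]
    if (!cls %in% c("A-to-I", "C-to-U")) next
    txids <- strsplit(sites$cds_transcripts[i], ",", fixed = TRUE)[[1L]]
    txids <- txids[nzchar(txids)]
    for (tid in txids) {
      tx <- tx_of[[tid]]
      off <- cds_offset(sites$pos[i], tx$tr, tx$strand)
      ci <- codon_index(off)
      cds_seq <- spliced_cds_seq(genome, tx$chrom, tx$tr, tx$strand)
      codon <- substr(cds_seq, (ci$codon_number - 1L) * 3L + 1L,
                      ci$codon_number * 3L)
      if (nchar(codon) < 3L) next  # incomplete trailing codon
      rec <- recode(codon, ci$codon_pos, cls)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = sites$chrom[i], pos = sites$pos[i], canonical_class = cls,
        transcript_id = tid, codon_number = ci$codon_number,
        codon_pos = ci$codon_pos, ref_codon = rec$ref_codon,
        edited_codon = rec$edited_codon, ref_aa = rec$ref_aa,
        edited_aa = rec$edited_aa, synonymous = rec$synonymous)
    }
  }
  if (length(rows) == 0L)
    return(data.table::data.table(
      chrom = character(), pos = integer(), canonical_class = character(),
      transcript_id = character(), codon_number = integer(),
      codon_pos = integer(), ref_codon = character(),
      edited_codon = character(), ref_aa = character(),
      edited_aa = character(), synonymous = logical()))
  data.table::rbindlist(rows)
}

#' Summarise recoding results
#'
#' Builds the reference-by-edited amino-acid count matrix per canonical
#' class and the nonsynonymous fraction. The per-site synonymous flag used
#' for fractions is "nonsynonymous if nonsynonymous in ANY hosting
#' transcript".
#'
#' @param results Table from [site_recoding].
#' @return List with `aa_matrix` (per class), and `nonsyn` (per class:
#'   numerator, denominator, fraction over unique sites).
#' @export
recoding_summary <- function(results) {
  results <- data.table::as.data.table(results)
  out <- list(aa_matrix = list(), nonsyn = list())
  for (cls in c("A-to-I", "C-to-U")) {
    r <- results[results$canonical_class == cls]
    out$aa_matrix[[cls]] <- table(ref = r$ref_aa, edited = r$edited_aa)
    synonymous <- NULL
    per_site <- r[, list(nonsyn = any(!synonymous)),
                  by = c("chrom", "pos")]
    d <- nrow(per_site)
    n <- sum(per_site$nonsyn)
    out$nonsyn[[cls]] <- list(nonsynonymous = n, sites = d,
                              fraction = if (d > 0L) n / d else NA_real_)
  }
  out
}

#' Nearest-neighbour distances between sites
#'
#' For each site, the distance to the nearest other site on the same
#' chromosome; singletons yield NA.
#'
#' @param sites Site table with `chrom`, `pos`.
#' @param threshold Distance threshold for the clustering fraction
#'   (default 20 bp, strict inequality).
#' @return List with `distances` (aligned with the input rows), `n_below`,
#'   and `fraction_below` (denominator: sites with a defined distance).
#' @export
nearest_site_distances <- function(sites, threshold = 20L) {
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0L) stop("no sites given")
  d <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (length(idx) < 2L) next
    o <- idx[order(sites$pos[idx])]
    p <- sites$pos[o]
    gaps <- diff(p)
    nd <- pmin(c(Inf, gaps), c(gaps, Inf))
    d[o] <- nd
  }
  defined <- !is.na(d)
  list(distances = d, n_below = sum(d < threshold, na.rm = TRUE),
       fraction_below = if (any(defined))
         sum(d < threshold, na.rm = TRUE) / sum(defined) else NA_real_)
}

#' Distance from a site to the nearest exon boundary of a transcript
#'
#' Genomic-axis distance to the start or end of the hosting exon; 0 when
#' the site is the first or last exon base.
#'
#' @param pos 1-based genomic position, inside an exon of the transcript.
#' @param transcript Transcript element of a [gene_model].
#' @return Non-negative integer.
#' @export
exon_boundary_distance <- function(pos, transcript) {
  ex <- transcript$exons
  hit <- which(ex$start <= pos & ex$end >= pos)
  if (length(hit) == 0L) stop("position ", pos, " not exonic")
  min(pos - ex$start[hit], ex$end[hit] - pos)
}

#' Exon-boundary distances for exon-hosted sites
#'
#' Computes per-(site, transcript) boundary distances and the per-site
#' minimum over hosting transcripts.
#'
#' @param sites Annotated site table with `exon_transcripts` set.
#' @param genes List of [gene_model]s.
#' @return data.table with chrom, pos, canonical_class, transcript_id,
#'   distance, is_min (flag for the per-site minimum).
#' @export
site_exon_distances <- function(sites, genes) {
  sites <- data.table::as.data.table(sites)
  tx_of <- list()
  for (gm in genes)
    for (tr in gm$transcripts) tx_of[[tr$transcript_id]] <- tr
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    txids <- strsplit(sites$exon_transcripts[i], ",", fixed = TRUE)[[1L]]
    txids <- txids[nzchar(txids)]
    for (tid in txids)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = sites$chrom[i], pos = sites$pos[i],
        canonical_class = sites$canonical_class[i], transcript_id = tid,
        distance = exon_boundary_distance(sites$pos[i], tx_of[[tid]]))
  }
  if (length(rows) == 0L)
    return(data.table::data.table(
      chrom = character(), pos = integer(), canonical_class = character(),
      transcript_id = character(), distance = integer(),
      is_min = logical()))
  dt <- data.table::rbindlist(rows)
  distance <- is_min <- NULL
  dt[, is_min := distance == min(distance), by = c("chrom", "pos")]
  dt[]
}

#' Filter sites by exon-boundary distance
#'
#' Splice-relevance candidates: sites at most `max_dist` bases from an
#' exon start or end.
#'
#' @param distances Numeric vector of boundary distances.
#' @param max_dist Inclusive threshold (e.g. 5 for tissue-specific, 10 for
#'   population-level analyses).
#' @return Logical vector: distance <= max_dist.
#' @export
splice_candidate_filter <- function(distances, max_dist) {
  distances <= max_dist
}
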