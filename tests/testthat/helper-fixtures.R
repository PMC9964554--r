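# Shared fixtures. The "standard" simulation is the stated world of the
# recovery criteria: >= 20x DNA / >= 30x RNA mean depth, error <= 0.5%,
# true levels >= 0.1, 500 planted sites, seed pinned at 1. It is built
# once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

std_config <- function() {
  sim_config(seed = 1L, level_min = 0.1)
}

std_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_editome(std_config())
  .fixture_env$sim
}

std_detection <- function() {
  if (is.null(.fixture_env$det)) {
    sim <- std_sim()
    # no VCF mask: the DNA-purity filters themselves must remove the
    # planted SNPs
    .fixture_env$det <- detect_editing(
      sim$pileups, sim$samples, variants = NULL,
      cfg = filter_config(autosome_names = sim$reference$autosomes))
  }
  .fixture_env$det
}

std_annotated <- function() {
  if (is.null(.fixture_env$ann))
    .fixture_env$ann <- annotate_sites(std_detection()$sites,
                                       std_sim()$reference$genes)
  .fixture_env$ann
}

empty_iv_test <- function() data.frame(start = integer(), end = integer())

# one pileup row
prow <- function(chrom, pos, sample, source, A = 0L, C = 0L, G = 0L,
                 T = 0L, mean_qual = 37) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         sample = sample, source = source,
                         A = as.integer(A), C = as.integer(C),
                         G = as.integer(G), T = as.integer(T),
                         mean_qual = mean_qual)
}

random_pileup <- function(n, sample = "s1", source = "RNA",
                          chroms = c("chr1", "chr2"), max_pos = 1000L) {
  keys <- unique(data.frame(
    chrom = sample.int(length(chroms), n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE)))
  keys <- keys[order(keys$chrom, keys$pos), ]
  data.table::data.table(
    chrom = chroms[keys$chrom], pos = keys$pos, sample = sample,
    source = source,
    A = rpois(nrow(keys), 5), C = rpois(nrow(keys), 5),
    G = rpois(nrow(keys), 5), T = rpois(nrow(keys), 5),
    mean_qual = round(runif(nrow(keys), 20, 40), 1))
}

# DNA/RNA pileups over n_pos positions with realistic structure: DNA is
# reference-dominated with occasional contamination, RNA carries edits,
# errors and dropouts -- so the filter cascade sees passes and every kind
# of failure
make_cohort_pileups <- function(n_pos = 200L, rna_samples = 4L,
                                chroms = c("chr1", "chr2", "chrX")) {
  bases <- c("A", "C", "G", "T")
  key <- data.frame(chrom = sample(chroms, n_pos, replace = TRUE),
                    pos = sample.int(5000L, n_pos),
                    ref = sample(bases, n_pos, replace = TRUE))
  key <- key[!duplicated(key[c("chrom", "pos")]), ]
  key <- key[order(key$chrom, key$pos), ]
  n <- nrow(key)
  metadata <- data.frame(sample = paste0("r", seq_len(rna_samples)),
                         dna_sample = paste0("d", rep(1:2, length.out =
                                                        rna_samples)))
  mk <- function(sample_id, source) {
    cnt <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
    depth <- rpois(n, if (source == "DNA") 8 else 15)
    cnt[cbind(seq_len(n), match(key$ref, bases))] <- depth
    # contamination / edits on a random alternative base
    hit <- runif(n) < if (source == "DNA") 0.15 else 0.5
    altb <- vapply(key$ref, function(b) sample(setdiff(bases, b), 1L),
                   character(1))
    extra <- ifelse(hit, rpois(n, if (source == "DNA") 1.5 else 4), 0L)
    idx <- cbind(seq_len(n), match(altb, bases))
    cnt[idx] <- cnt[idx] + as.integer(extra)
    # occasional second alternative base (multiallelic candidates)
    hit2 <- runif(n) < 0.08 & source == "RNA"
    altb2 <- vapply(seq_len(n), function(i)
      sample(setdiff(bases, c(key$ref[i], altb[i])), 1L), character(1))
    idx2 <- cbind(seq_len(n), match(altb2, bases))
    cnt[idx2] <- cnt[idx2] + as.integer(ifelse(hit2, rpois(n, 3), 0L))
    out <- data.table::data.table(chrom = key$chrom, pos = key$pos,
                                  sample = sample_id, source = source)
    cbind(out, data.table::as.data.table(cnt))[, mean_qual := 35][]
  }
  parts <- c(lapply(unique(metadata$dna_sample), mk, source = "DNA"),
             lapply(metadata$sample, mk, source = "RNA"))
  list(pileups = data.table::rbindlist(parts), metadata = metadata)
}

# a small two-gene annotation used by annotation/characterization tests:
# plus-strand coding gene (two exons) and minus-strand coding gene
tiny_genes <- function() {
  plus <- gene_model(
    "gplus", "chr1", "+", "protein_coding",
    list(tplus = list(
      transcript_id = "tplus",
      exons = data.frame(start = c(101L, 201L), end = c(150L, 280L)),
      cds = data.frame(start = c(111L, 201L), end = c(150L, 238L)),
      utr5 = data.frame(start = 101L, end = 110L),
      utr3 = data.frame(start = 239L, end = 280L))))
  minus <- gene_model(
    "gminus", "chr1", "-", "protein_coding",
    list(tminus = list(
      transcript_id = "tminus",
      exons = data.frame(start = c(401L, 501L), end = c(460L, 580L)),
      cds = data.frame(start = c(421L, 501L), end = c(460L, 556L)),
      utr5 = data.frame(start = 557L, end = 580L),
      utr3 = data.frame(start = 401L, end = 420L))))
  list(gplus = plus, gminus = minus)
}

# Independent single-pass re-implementation of the whole filter cascade,
# used as the oracle for the detection pipeline. Deliberately written as
# plain loops over data.frames.
oracle_survivors <- function(pileups, metadata, cfg) {
  pil <- as.data.frame(pileups)
  bases <- c("A", "C", "G", "T")
  per_sample <- list()
  for (i in seq_len(nrow(metadata))) {
    s <- metadata$sample[i]
    rna <- pil[pil$sample == s & pil$source == "RNA", ]
    dna <- pil[pil$sample == metadata$dna_sample[i] & pil$source == "DNA", ]
    rownames(dna) <- paste(dna$chrom, dna$pos)
    out <- list()
    for (j in seq_len(nrow(rna))) {
      d <- dna[paste(rna$chrom[j], rna$pos[j]), ]
      if (nrow(d) == 0 || is.na(d$A)) next
      dcnt <- as.integer(d[bases])
      if (sum(dcnt) == 0) next
      ref <- bases[which.max(dcnt)]
      rcnt <- as.integer(rna[j, bases])
      rcov <- sum(rcnt)
      alts <- bases[bases != ref & rcnt > 0]
      multi <- sum(rcnt[bases != ref] >= cfg$min_alt_reads) >= 2
      for (ab in alts) {
        ok <- rcov >= cfg$min_rna_cov &&
          sum(dcnt) >= cfg$min_dna_cov &&
          rcnt[match(ab, bases)] >= cfg$min_alt_reads &&
          (sum(dcnt) - dcnt[match(ref, bases)]) <= cfg$max_dna_alt_reads &&
          rcnt[match(ab, bases)] / rcov >= cfg$min_rna_alt_freq &&
          dcnt[match(ref, bases)] / sum(dcnt) >= cfg$min_dna_ref_freq &&
          !(cfg$exclude_multiallelic && multi)
        if (ok)
          out[[length(out) + 1L]] <- data.frame(
            chrom = rna$chrom[j], pos = rna$pos[j], sample = s,
            alt = ab, level = rcnt[match(ab, bases)] / rcov)
      }
    }
    per_sample[[s]] <- if (length(out)) do.call(rbind, out) else NULL
  }
  obs <- do.call(rbind, per_sample)
  if (is.null(obs)) return(list(observations = obs, sites = character(0)))
  keep_sites <- character(0)
  for (k in unique(paste(obs$chrom, obs$pos))) {
    rows <- obs[paste(obs$chrom, obs$pos) == k, ]
    if (length(unique(rows$sample)) < cfg$min_samples) next
    if (cfg$drop_all_ones && all(rows$level == 1)) next
    if (cfg$autosomes_only && !rows$chrom[1] %in% cfg$autosome_names) next
    keep_sites <- c(keep_sites, k)
  }
  obs <- obs[paste(obs$chrom, obs$pos) %in% keep_sites, ]
  list(observations = obs, sites = sort(keep_sites))
}
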