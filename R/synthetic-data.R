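# Seeded synthetic editome: a toy genome and annotation, planted germline
# SNPs and editing sites with controlled per-sample editing levels, and
# matched multi-sample DNA/RNA pileups plus an expression count matrix.
#
# The stated world emulates the study design the analysis assumes: two
# populations x four tissues x five individuals (40 RNA libraries, one
# blood DNA library per individual), A-to-I and C-to-U sites planted on
# the strand-appropriate reference base inside genes, uniform sequencing
# error across the three non-reference bases, and negative-binomial depth
# and expression. All randomness flows from `seed` through fixed per-stage
# substreams (seed, seed+1, seed+2).

CATALYZER_NAMES <- c("ADAR", "ADARB1", "ADARB2",
                     "APOBEC1", "APOBEC2", "APOBEC4")

#' Simulation configuration
#'
#' Defaults describe a desk-scale analog of a two-population, four-tissue,
#' five-individual editome study: a 2 x 30 kb genome with 24 genes, 100
#' germline SNPs, 300 planted A-to-I and 200 C-to-U sites, ~30x DNA and
#' ~50x RNA depth, 0.2% per-base sequencing error, and U-shaped editing
#' levels (Beta(0.6, 0.6) truncated at `level_min`).
#'
#' @param seed Integer seed fixing the full output.
#' @param n_chrom,chrom_length Autosome count and length (bp).
#' @param n_genes Total genes, spread over the autosomes.
#' @param n_snps Planted germline SNPs (het dose 0.5 or hom-alt dose 1).
#' @param n_sites Named vector: planted sites per class
#'   (`A-to-I`, `C-to-U`).
#' @param dna_depth,rna_depth Depth distributions, `c(mean, dispersion)`
#'   of a negative binomial.
#' @param base_error_rate Per-base sequencing error rate, uniform over the
#'   3 non-reference bases.
#' @param level_shape Beta shape parameters `c(a, b)` of true editing
#'   levels.
#' @param level_min Lower truncation of true editing levels.
#' @param populations,tissues,n_individuals Study design labels.
#' @param design_fractions Fractions of sites labelled none /
#'   tissue_specific / population_specific / population_differential.
#' @param differential_delta Editing-level gap planted at
#'   population-differential sites.
#' @param expression_correlation Target Spearman rho between designated
#'   site levels and their catalyzer gene expression.
#' @param n_correlated Number of sites tied to catalyzer expression.
#' @param expr_mean,expr_dispersion Negative-binomial expression counts.
#' @param include_sex_chrom Add a chrX with genes and sites, exercising
#'   the autosome filter.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 30000L,
                       n_genes = 24L, n_snps = 100L,
                       n_sites = c("A-to-I" = 300L, "C-to-U" = 200L),
                       dna_depth = c(mean = 30, dispersion = 10),
                       rna_depth = c(mean = 50, dispersion = 10),
                       base_error_rate = 0.002,
                       level_shape = c(a = 0.6, b = 0.6),
                       level_min = 0.05,
                       populations = c("highland", "lowland"),
                       tissues = c("heart", "lung", "kidney", "muscle"),
                       n_individuals = 5L,
                       design_fractions = c(none = 0.7,
                                            tissue_specific = 0.1,
                                            population_specific = 0.1,
                                            population_differential = 0.1),
                       differential_delta = 0.3,
                       expression_correlation = 0.8, n_correlated = 40L,
                       expr_mean = 500, expr_dispersion = 10,
                       include_sex_chrom = FALSE) {
  stopifnot(base_error_rate >= 0, base_error_rate <= 1,
            level_min >= 0, level_min < 1,
            dna_depth[["mean"]] >= 0, rna_depth[["mean"]] >= 0,
            abs(sum(design_fractions) - 1) < 1e-9,
            expression_correlation >= 0, expression_correlation <= 1,
            length(populations) == 2L, n_individuals >= 1L,
            differential_delta >= 0, differential_delta <= 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

rtrunc_beta <- function(n, a, b, min) {
  lo <- stats::pbeta(min, a, b)
  stats::qbeta(stats::runif(n, lo, 1), a, b)
}

spliced_to_genomic <- function(exons, strand, a, b) {
  # spliced [a, b] (1-based, transcript orientation) -> genomic intervals
  ex <- sort_iv(exons)
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, lens))
  out <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(a, offs[i] + 1L)
    hi <- min(b, offs[i + 1L])
    if (lo > hi) next
    if (strand == "+") {
      out[[length(out) + 1L]] <- data.frame(
        start = ex$start[i] + (lo - offs[i] - 1L),
        end = ex$start[i] + (hi - offs[i] - 1L))
    } else {
      out[[length(out) + 1L]] <- data.frame(
        start = ex$end[i] - (hi - offs[i] - 1L),
        end = ex$end[i] - (lo - offs[i] - 1L))
    }
  }
  sort_iv(do.call(rbind, out))
}

#' Generate a toy genome and annotation
#'
#' Genes are placed sequentially on each chromosome, alternating strands,
#' each with one multi-exon transcript; protein-coding transcripts carry a
#' CDS of length divisible by 3 flanked by annotated UTRs. The first six
#' protein-coding genes are named after the editing catalyzers
#' (ADAR/ADARB1/ADARB2/APOBEC1/APOBEC2/APOBEC4).
#'
#' @param config A [sim_config].
#' @return List with `genome` (named character vector), `genes` (list of
#'   [gene_model]), and `autosomes` (chromosome names for the cohort
#'   filter).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  all_chroms <- c(chroms,
                  if (config$include_sex_chrom) "chrX" else character(0))
  genome <- vapply(all_chroms, function(ch)
    paste(sample(BASES, config$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  names(genome) <- all_chroms

  n_total <- config$n_genes +
    if (config$include_sex_chrom) 2L else 0L
  host_chrom <- c(rep(chroms, length.out = config$n_genes),
                  if (config$include_sex_chrom) c("chrX", "chrX"))
  # slot-based placement: each gene gets an equal share of its chromosome
  # and is drawn (shrunk if needed) to fit, so any seed fits any config
  # whose slots leave >= 500 bp per gene
  per_chrom <- table(factor(host_chrom, levels = all_chroms))
  slot_w <- stats::setNames(
    as.integer((config$chrom_length - 400L) / pmax(per_chrom, 1L)),
    all_chroms)
  if (any(per_chrom > 0L & slot_w < 500L))
    stop("requested genes do not fit chromosome ",
         names(which(per_chrom > 0L & slot_w < 500L))[1L])
  slot_used <- stats::setNames(rep(0L, length(all_chroms)), all_chroms)
  genes <- list()
  n_pc <- 0L
  for (g in seq_len(n_total)) {
    ch <- host_chrom[g]
    n_ex <- sample(2:4, 1L)
    exon_lens <- sample(150:400, n_ex, replace = TRUE)
    intron_lens <- if (n_ex > 1L) sample(60:200, n_ex - 1L, replace = TRUE)
                   else integer(0)
    avail <- slot_w[[ch]] - 100L
    span <- sum(exon_lens) + sum(intron_lens)
    if (span > avail) {  # shrink proportionally, keep >= 90 bp exons
      f <- avail / span
      exon_lens <- pmax(90L, as.integer(exon_lens * f))
      intron_lens <- pmax(30L, as.integer(intron_lens * f))
      span <- sum(exon_lens) + sum(intron_lens)
    }
    start <- 200L + slot_used[[ch]] * slot_w[[ch]] +
      sample.int(max(slot_w[[ch]] - span - 50L, 1L), 1L)
    slot_used[[ch]] <- slot_used[[ch]] + 1L
    starts <- start + cumsum(c(0L, exon_lens[-n_ex] +
                                 intron_lens))
    exons <- iv_df(starts, starts + exon_lens - 1L)
    strand <- if (g %% 2L == 0L) "-" else "+"
    biotype <- sample(c("protein_coding", "lincRNA", "pseudogene",
                        "processed_pseudogene"), 1L,
                      prob = c(0.8, 0.1, 0.05, 0.05))
    gid <- sprintf("GENE%04d", g)
    tid <- paste0(gid, ".t1")
    tr <- list(transcript_id = tid, exons = exons, cds = empty_iv(),
               utr5 = empty_iv(), utr3 = empty_iv())
    gname <- NA_character_
    if (biotype == "protein_coding") {
      n_pc <- n_pc + 1L
      if (n_pc <= length(CATALYZER_NAMES))
        gname <- CATALYZER_NAMES[n_pc]
      total <- sum(exon_lens)
      utr5_len <- sample(30:60, 1L)
      utr3_len <- sample(50:90, 1L)
      cds_len <- total - utr5_len - utr3_len
      cds_len <- cds_len - cds_len %% 3L
      utr3_len <- total - utr5_len - cds_len
      tr$utr5 <- spliced_to_genomic(exons, strand, 1L, utr5_len)
      tr$cds <- spliced_to_genomic(exons, strand, utr5_len + 1L,
                                   utr5_len + cds_len)
      tr$utr3 <- spliced_to_genomic(exons, strand,
                                    utr5_len + cds_len + 1L, total)
    }
    genes[[gid]] <- gene_model(gid, ch, strand, biotype,
                               stats::setNames(list(tr), tid),
                               gene_name = gname)
  }
  list(genome = genome, genes = genes, autosomes = chroms)
}

site_alt_base <- function(true_class, strand) {
  # edited-strand A>G / C>T expressed in forward-reference orientation
  ifelse(true_class == "A-to-I", ifelse(strand == "+", "G", "C"),
         ifelse(strand == "+", "T", "A"))
}

#' Plant germline SNPs and editing sites
#'
#' SNP and site positions are disjoint. A-to-I sites sit on reference A in
#' plus-strand genes and T in minus-strand genes; C-to-U on C / G. True
#' per-sample editing levels are truncated-Beta draws; tissue_specific
#' sites have level 0 outside their tissue, population_specific sites
#' level 0 in the other population, and population_differential sites
#' carry a planted between-population gap of `differential_delta`.
#' Designated sites are level-coupled to a catalyzer gene through a shared
#' per-sample Gaussian latent factor (targeting Spearman rho
#' `expression_correlation`).
#'
#' @param config A [sim_config].
#' @param reference Output of [generate_reference].
#' @return List of class `truth_table`: `snps`, `sites`, `levels` (sites x
#'   RNA samples), `samples` (sample sheet), `catalyzer_link`,
#'   `catalyzer_z`.
#' @export
plant_truth <- function(config, reference) {
  set.seed(config$seed + 1L)
  samples <- data.table::rbindlist(lapply(config$populations, function(p)
    data.table::rbindlist(lapply(config$tissues, function(t)
      data.table::data.table(
        sample = sprintf("%s_%s_%d", p, t, seq_len(config$n_individuals)),
        population = p, tissue = t,
        individual = sprintf("%s_%d", p, seq_len(config$n_individuals)),
        dna_sample = sprintf("%s_%d_DNA", p,
                             seq_len(config$n_individuals)))))))
  n_samp <- nrow(samples)
  genome_chars <- lapply(reference$genome,
                         function(s) strsplit(s, "", fixed = TRUE)[[1L]])

  # SNPs: uniform over autosomes
  snp_list <- list()
  per_chrom <- table(sample(reference$autosomes, config$n_snps,
                            replace = TRUE))
  for (ch in names(per_chrom)) {
    pos <- sort(sample(seq_len(config$chrom_length), per_chrom[[ch]]))
    ref <- genome_chars[[ch]][pos]
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
    snp_list[[ch]] <- data.table::data.table(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      dose = sample(c(0.5, 1), per_chrom[[ch]], replace = TRUE))
  }
  snps <- data.table::rbindlist(snp_list)

  # eligible in-gene positions per class
  eligible <- function(cls) {
    rows <- list()
    for (gm in reference$genes) {
      gb <- gene_body(gm)
      want <- if (cls == "A-to-I") {
        if (gm$strand == "+") "A" else "T"
      } else {
        if (gm$strand == "+") "C" else "G"
      }
      pos <- gb[1L]:gb[2L]
      pos <- pos[genome_chars[[gm$chrom]][pos] == want]
      if (length(pos))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = gm$chrom, pos = pos, gene_id = gm$gene_id,
          strand = gm$strand)
    }
    el <- data.table::rbindlist(rows)
    el[!paste(el$chrom, el$pos) %in% paste(snps$chrom, snps$pos)]
  }
  site_list <- list()
  taken <- character(0)
  for (cls in names(config$n_sites)) {
    el <- eligible(cls)
    el <- el[!paste(el$chrom, el$pos) %in% taken]
    need <- config$n_sites[[cls]]
    if (nrow(el) < need)
      stop("not enough eligible bases for ", cls, " sites (",
           nrow(el), " < ", need, ")")
    pick <- el[sample(nrow(el), need)]
    taken <- c(taken, paste(pick$chrom, pick$pos))
    pick$true_class <- cls
    site_list[[cls]] <- pick
  }
  sites <- data.table::rbindlist(site_list)
  sites$ref <- mapply(function(ch, p) genome_chars[[ch]][p],
                      sites$chrom, sites$pos)
  sites$alt <- site_alt_base(sites$true_class, sites$strand)
  data.table::setnames(sites, "gene_id", "host_gene")

  # design labels
  n_total <- nrow(sites)
  sites <- sites[sample(n_total)]
  n_lab <- round(config$design_fractions * n_total)
  n_lab["none"] <- n_total - sum(n_lab[-1L])
  lab_rep <- function(prefix, values, n) {
    if (n == 0L) return(character(0))
    paste0(prefix, rep(values, length.out = n))
  }
  design <- c(rep("none", n_lab[["none"]]),
              lab_rep("tissue_specific:", config$tissues,
                      n_lab[["tissue_specific"]]),
              lab_rep("population_specific:", config$populations,
                      n_lab[["population_specific"]]),
              rep("population_differential",
                  n_lab[["population_differential"]]))
  sites$design <- design

  a <- config$level_shape[["a"]]; b <- config$level_shape[["b"]]
  lv <- matrix(rtrunc_beta(n_total * n_samp, a, b, config$level_min),
               n_total, n_samp,
               dimnames = list(paste0(sites$chrom, ":", sites$pos),
                               samples$sample))
  for (i in seq_len(n_total)) {
    des <- sites$design[i]
    if (startsWith(des, "tissue_specific:")) {
      t <- sub("tissue_specific:", "", des)
      lv[i, samples$tissue != t] <- 0
    } else if (startsWith(des, "population_specific:")) {
      p <- sub("population_specific:", "", des)
      lv[i, samples$population != p] <- 0
    } else if (des == "population_differential") {
      base <- stats::runif(1, max(config$level_min, 0.05),
                           1 - config$differential_delta - 0.05)
      hi_pop <- config$populations[1L + i %% 2L]
      lo <- base + stats::runif(n_samp, -0.03, 0.03)
      hi <- base + config$differential_delta +
        stats::runif(n_samp, -0.03, 0.03)
      lvl <- ifelse(samples$population == hi_pop, hi, lo)
      lv[i, ] <- pmin(pmax(lvl, 0.01), 1)
    }
  }

  # catalyzer-coupled sites among the "none" stratum
  cat_genes <- Filter(function(gm) !is.na(gm$gene_name) &&
                        gm$gene_name %in% CATALYZER_NAMES,
                      reference$genes)
  cat_ids <- vapply(cat_genes, `[[`, character(1), "gene_id")
  cat_names <- vapply(cat_genes, `[[`, character(1), "gene_name")
  adar <- cat_ids[grepl("^ADAR", cat_names)]
  apobec <- cat_ids[grepl("^APOBEC", cat_names)]
  none_idx <- which(sites$design == "none")
  n_cor <- min(config$n_correlated, length(none_idx))
  cor_idx <- none_idx[seq_len(n_cor)]
  z <- matrix(stats::rnorm(length(cat_ids) * n_samp), length(cat_ids),
              n_samp, dimnames = list(cat_ids, samples$sample))
  # The site level is a monotone map of (rho_lat * z + noise); the
  # expression is NB around mean * exp(0.5 z). To land the *observed*
  # Spearman on the target we de-attenuate analytically: (i) Spearman of
  # a Gaussian copula with correlation r is (6/pi) asin(r/2), so r_needed
  # = 2 sin(pi rho / 6); (ii) NB noise dilutes the expression latent by
  # alpha = sd(signal)/sd(signal + noise) on the log scale, with signal
  # variance (0.5)^2 and noise variance log(1 + 1/size + 1/mu).
  rho <- config$expression_correlation
  cv2 <- 1 / config$expr_dispersion + 1 / config$expr_mean
  alpha <- sqrt(0.25 / (0.25 + log(1 + cv2)))
  rho_lat <- min(0.999, 2 * sin(pi * rho / 6) / alpha)
  link <- list()
  lo_q <- stats::pbeta(config$level_min, a, b)
  for (k in seq_along(cor_idx)) {
    i <- cor_idx[k]
    pool <- if (sites$true_class[i] == "A-to-I" && length(adar)) adar
      else if (length(apobec)) apobec else cat_ids
    g <- pool[1L + (k - 1L) %% length(pool)]
    eps <- stats::rnorm(n_samp)
    u <- stats::pnorm(rho_lat * z[g, ] + sqrt(1 - rho_lat^2) * eps)
    lv[i, ] <- stats::qbeta(lo_q + u * (1 - lo_q), a, b)
    link[[k]] <- data.table::data.table(
      site = rownames(lv)[i], gene_id = g,
      gene_name = cat_names[match(g, cat_ids)])
  }
  structure(list(snps = snps, sites = sites, levels = lv,
                 samples = samples,
                 catalyzer_link = data.table::rbindlist(link),
                 catalyzer_z = z),
            class = "truth_table")
}

rdepth <- function(n, par) stats::rnbinom(n, mu = par[["mean"]],
                                          size = par[["dispersion"]])

split_errors <- function(n_err) {
  # distribute n_err error reads uniformly over 3 non-reference slots
  out <- matrix(0L, length(n_err), 3L)
  one <- n_err == 1L
  out[cbind(which(one), sample.int(3L, sum(one), replace = TRUE))] <- 1L
  for (i in which(n_err > 1L))
    out[i, ] <- as.integer(stats::rmultinom(1L, n_err[i], rep(1 / 3, 3)))
  out
}

qual_col <- function(n) pmin(pmax(round(stats::rnorm(n, 37, 1.5), 1), 2), 41)

counts_from_parts <- function(ref_base, ref_n, alt_base, alt_n, oth) {
  # assemble A/C/G/T columns from ref, alt (may be NA) and 'other' errors
  n <- length(ref_base)
  cnt <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  cnt[cbind(seq_len(n), match(ref_base, BASES))] <- as.integer(ref_n)
  has_alt <- !is.na(alt_base)
  cnt[cbind(which(has_alt), match(alt_base[has_alt], BASES))] <-
    cnt[cbind(which(has_alt), match(alt_base[has_alt], BASES))] +
    as.integer(alt_n[has_alt])
  if (!is.null(oth)) {
    # j-th non-reference base in A<C<G<T order, skipping ref
    slot <- t(vapply(ref_base, function(rb) setdiff(BASES, rb),
                     character(3)))
    for (j in 1:3) {
      idx <- cbind(seq_len(n), match(slot[, j], BASES))
      cnt[idx] <- cnt[idx] + as.integer(oth[, j])
    }
  }
  cnt
}

#' Simulate matched DNA/RNA pileups and expression counts
#'
#' RNA alternative-base counts at planted sites follow
#' `Binomial(depth, level * (1 - e) + e/3)`; background errors are uniform
#' over the three non-reference bases; planted SNPs appear in both DNA and
#' RNA at the genotype dose, so the DNA-purity filter (not only the VCF
#' mask) must remove them. RNA coverage is genome-wide and not
#' expression-weighted (a deliberate simplification). Only positions with
#' at least one RNA mismatch -- plus all planted positions -- are emitted;
#' zero-mismatch positions can never become candidates. DNA pileups cover
#' every emitted position of the individual's four RNA libraries.
#'
#' @param truth A `truth_table` from [plant_truth].
#' @param reference Output of [generate_reference].
#' @param config A [sim_config].
#' @return List with `pileups` (one table, both sources, all samples),
#'   `expression` (genes x RNA samples counts), `gene_lengths`, `samples`.
#' @export
simulate_pileups <- function(truth, reference, config) {
  set.seed(config$seed + 2L)
  e <- config$base_error_rate
  genome_chars <- lapply(reference$genome,
                         function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  chroms <- names(reference$genome)
  samples <- truth$samples
  site_key <- rownames(truth$levels)

  special <- rbind(
    data.table::data.table(chrom = truth$sites$chrom,
                           pos = truth$sites$pos,
                           ref = truth$sites$ref, alt = truth$sites$alt,
                           kind = "site",
                           pkey = paste0(truth$sites$chrom, ":",
                                        truth$sites$pos)),
    data.table::data.table(chrom = truth$snps$chrom, pos = truth$snps$pos,
                           ref = truth$snps$ref, alt = truth$snps$alt,
                           kind = "snp",
                           pkey = paste0(truth$snps$chrom, ":",
                                        truth$snps$pos)))
  snp_dose <- stats::setNames(truth$snps$dose,
                              paste0(truth$snps$chrom, ":",
                                     truth$snps$pos))

  rna_parts <- list()
  cand_pos <- list()  # per individual: chrom -> positions needing DNA
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample[si]
    ind <- samples$individual[si]
    # planted positions
    sp <- special
    p_alt <- ifelse(sp$kind == "site",
                    truth$levels[match(sp$pkey, site_key), s],
                    snp_dose[sp$pkey])
    depth <- rdepth(nrow(sp), config$rna_depth)
    alt_n <- stats::rbinom(nrow(sp), depth, p_alt * (1 - e) + e / 3)
    oth_n <- stats::rbinom(nrow(sp), depth - alt_n, 2 * e / 3)
    o1 <- stats::rbinom(nrow(sp), oth_n, 0.5)
    oth <- cbind(o1, oth_n - o1)
    # assign 'other' errors to the two bases that are neither ref nor alt
    cnt <- matrix(0L, nrow(sp), 4L, dimnames = list(NULL, BASES))
    cnt[cbind(seq_len(nrow(sp)), match(sp$ref, BASES))] <-
      depth - alt_n - as.integer(rowSums(oth))
    cnt[cbind(seq_len(nrow(sp)), match(sp$alt, BASES))] <-
      cnt[cbind(seq_len(nrow(sp)), match(sp$alt, BASES))] + alt_n
    for (i in seq_len(nrow(sp))) {
      rest <- setdiff(BASES, c(sp$ref[i], sp$alt[i]))
      cnt[i, rest] <- cnt[i, rest] + oth[i, ]
    }
    sp_dt <- data.table::data.table(chrom = sp$chrom, pos = sp$pos,
                                    sample = s, source = "RNA")
    sp_dt <- cbind(sp_dt, data.table::as.data.table(cnt))
    # background errors over the rest of the genome
    bg_parts <- list()
    for (ch in chroms) {
      L <- nchar(reference$genome[[ch]])
      excl <- sp$pos[sp$chrom == ch]
      pos <- setdiff(seq_len(L), excl)
      depth_b <- rdepth(length(pos), config$rna_depth)
      err <- stats::rbinom(length(pos), depth_b, e)
      keep <- err > 0L
      if (!any(keep)) next
      pos <- pos[keep]; depth_b <- depth_b[keep]; err <- err[keep]
      refb <- genome_chars[[ch]][pos]
      oth_b <- split_errors(err)
      cnt_b <- counts_from_parts(refb, depth_b - err, NA_character_,
                                 integer(length(pos)), oth_b)
      bg <- data.table::data.table(chrom = ch, pos = pos, sample = s,
                                   source = "RNA")
      bg_parts[[ch]] <- cbind(bg, data.table::as.data.table(cnt_b))
    }
    part <- data.table::rbindlist(c(list(sp_dt), bg_parts))
    part$mean_qual <- qual_col(nrow(part))
    data.table::setorderv(part, c("chrom", "pos"))
    rna_parts[[s]] <- part
    cp <- cand_pos[[ind]]
    if (is.null(cp)) cp <- character(0)
    cand_pos[[ind]] <- union(cp, paste0(part$chrom, ":", part$pos))
  }

  dna_parts <- list()
  for (ind in unique(samples$individual)) {
    dna_id <- samples$dna_sample[match(ind, samples$individual)]
    keys <- cand_pos[[ind]]
    chrom <- sub(":.*", "", keys)
    pos <- as.integer(sub(".*:", "", keys))
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]
    key <- paste0(chrom, ":", pos)
    refb <- mapply(function(ch, p) genome_chars[[ch]][p], chrom, pos,
                   USE.NAMES = FALSE)
    depth <- rdepth(length(pos), config$dna_depth)
    is_snp <- key %in% names(snp_dose)
    alt_n <- integer(length(pos))
    altb <- rep(NA_character_, length(pos))
    if (any(is_snp)) {
      dose <- snp_dose[key[is_snp]]
      alt_n[is_snp] <- stats::rbinom(sum(is_snp), depth[is_snp],
                                     dose * (1 - e) + e / 3)
      altb[is_snp] <- truth$snps$alt[match(key[is_snp],
                                           names(snp_dose))]
    }
    err <- stats::rbinom(length(pos), depth - alt_n, e)
    oth <- split_errors(err)
    cnt <- counts_from_parts(refb, depth - alt_n - err, altb, alt_n, oth)
    dt <- data.table::data.table(chrom = chrom, pos = pos,
                                 sample = dna_id, source = "DNA")
    dt <- cbind(dt, data.table::as.data.table(cnt))
    dt$mean_qual <- qual_col(nrow(dt))
    dna_parts[[ind]] <- dt
  }

  pileups <- data.table::rbindlist(c(rna_parts, dna_parts))
  data.table::setcolorder(pileups, PILEUP_HEADER)
  data.table::setorderv(pileups, c("sample", "source", "chrom", "pos"))

  # expression counts
  gene_ids <- names(reference$genes)
  gene_lengths <- vapply(reference$genes, function(gm) {
    ex <- gm$transcripts[[1L]]$exons
    sum(ex$end - ex$start + 1L)
  }, numeric(1))
  base_mean <- stats::rlnorm(length(gene_ids),
                             meanlog = log(config$expr_mean), sdlog = 1)
  names(base_mean) <- gene_ids
  mu <- matrix(rep(base_mean, nrow(samples)), length(gene_ids),
               nrow(samples),
               dimnames = list(gene_ids, samples$sample))
  z_ids <- rownames(truth$catalyzer_z)
  if (length(z_ids))
    mu[z_ids, ] <- mu[z_ids, ] * exp(0.5 * truth$catalyzer_z)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$expr_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(pileups = pileups, expression = counts,
       gene_lengths = gene_lengths, samples = samples)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: [generate_reference], [plant_truth],
#' [simulate_pileups] under the config's seed substreams.
#'
#' @param config A [sim_config].
#' @return List with `reference`, `truth`, and the simulated `pileups`,
#'   `expression`, `gene_lengths`, `samples`.
#' @export
simulate_editome <- function(config = sim_config()) {
  reference <- generate_reference(config)
  truth <- plant_truth(config, reference)
  sim <- simulate_pileups(truth, reference, config)
  c(list(reference = reference, truth = truth), sim)
}

#' Compare called sites against the planted truth
#'
#' @param called_sites Site table with `chrom`, `pos` and optionally
#'   `canonical_class`.
#' @param truth A `truth_table`.
#' @return List with `tp`, `fp`, `fn`, `precision` (NA when nothing was
#'   called), `recall`, and `confusion` (true class x called class over
#'   matched sites, classes collapsed to A-to-I / C-to-U / other).
#' @export
evaluate_recovery <- function(called_sites, truth) {
  called <- data.table::as.data.table(called_sites)
  ck <- if (nrow(called)) paste0(called$chrom, ":", called$pos)
        else character(0)
  tk <- paste0(truth$sites$chrom, ":", truth$sites$pos)
  tp <- sum(ck %in% tk)
  fp <- sum(!ck %in% tk)
  fn <- sum(!tk %in% ck)
  collapse <- function(x) ifelse(x %in% c("A-to-I", "C-to-U"), x, "other")
  confusion <- NULL
  if ("canonical_class" %in% names(called)) {
    match_idx <- match(ck, tk)
    ok <- !is.na(match_idx)
    confusion <- table(
      true = factor(collapse(truth$sites$true_class[match_idx[ok]]),
                    levels = c("A-to-I", "C-to-U", "other")),
      called = factor(collapse(called$canonical_class[ok]),
                      levels = c("A-to-I", "C-to-U", "other")))
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       confusion = confusion)
}
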