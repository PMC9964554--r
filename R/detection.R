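# Point-by-point DNA/RNA pileup comparison and the editing filter cascade.
#
# An "observation" is one candidate editing event in one sample; a
# "non-redundant site" is a unique (chrom, pos) aggregated over samples.
# Filters split into per-sample primary rules (coverage, support, frequency,
# DNA purity, multiallelic), a known-variant mask, and cohort-level rules
# (sample support, all-ones exclusion, autosome restriction).

#' Filter configuration for editing-site detection
#'
#' Defaults mirror the filter cascade commonly used in comparative
#' DNA/RNA editome surveys:
#' RNA coverage >= 10, DNA coverage >= 5, >= 2 reads supporting the edited
#' base, 0 reads supporting a DNA mutation, RNA variant frequency >= 0.01,
#' DNA reference frequency >= 0.95, multiallelic positions excluded; at
#' cohort level a site must be detected in >= 3 samples, must not have
#' editing level 1 in every detected sample, and must lie on a named
#' autosome.
#'
#' @param min_rna_cov Minimum RNA coverage per sample.
#' @param min_dna_cov Minimum DNA coverage per sample.
#' @param min_alt_reads Minimum reads supporting the edited base; also the
#'   support threshold used to flag a position multiallelic.
#' @param max_dna_alt_reads Maximum reads supporting a DNA mutation.
#' @param min_rna_alt_freq Minimum RNA variant frequency (editing level).
#' @param min_dna_ref_freq Minimum DNA reference-base frequency.
#' @param exclude_multiallelic Drop positions with >= 2 distinct RNA
#'   alternative bases each supported by `min_alt_reads` reads.
#' @param min_samples Cohort rule: minimum samples a site is detected in.
#' @param drop_all_ones Cohort rule: drop sites whose editing level is 1 in
#'   every detected sample.
#' @param autosomes_only Cohort rule: keep only sites on `autosome_names`.
#' @param autosome_names Character vector of autosome names.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_rna_cov = 10L, min_dna_cov = 5L,
                          min_alt_reads = 2L, max_dna_alt_reads = 0L,
                          min_rna_alt_freq = 0.01, min_dna_ref_freq = 0.95,
                          exclude_multiallelic = TRUE, min_samples = 3L,
                          drop_all_ones = TRUE, autosomes_only = TRUE,
                          autosome_names = character(0)) {
  stopifnot(min_rna_cov >= 0, min_dna_cov >= 0, min_alt_reads >= 0,
            max_dna_alt_reads >= 0,
            min_rna_alt_freq >= 0, min_rna_alt_freq <= 1,
            min_dna_ref_freq >= 0, min_dna_ref_freq <= 1,
            min_samples >= 1)
  structure(list(min_rna_cov = as.integer(min_rna_cov),
                 min_dna_cov = as.integer(min_dna_cov),
                 min_alt_reads = as.integer(min_alt_reads),
                 max_dna_alt_reads = as.integer(max_dna_alt_reads),
                 min_rna_alt_freq = min_rna_alt_freq,
                 min_dna_ref_freq = min_dna_ref_freq,
                 exclude_multiallelic = isTRUE(exclude_multiallelic),
                 min_samples = as.integer(min_samples),
                 drop_all_ones = isTRUE(drop_all_ones),
                 autosomes_only = isTRUE(autosomes_only),
                 autosome_names = autosome_names),
            class = "filter_config")
}

#' Editing level of a site in a sample
#'
#' The fraction of RNA reads carrying the edited base.
#'
#' @param alt_count Reads supporting the alternative base.
#' @param coverage Total RNA reads covering the position (> 0).
#' @return `alt_count / coverage`.
#' @export
compute_editing_level <- function(alt_count, coverage) {
  if (any(coverage == 0)) stop("editing level undefined at zero coverage")
  stopifnot(all(alt_count >= 0), all(alt_count <= coverage))
  alt_count / coverage
}

check_sorted <- function(dt, what) {
  # C-locale ranks, consistent with data.table::setorderv
  r <- data.table::frankv(dt, cols = c("chrom", "pos"),
                          ties.method = "first")
  if (!identical(r, seq_len(nrow(dt))))
    stop(what, " pileup must be sorted by (chrom, pos)")
}

#' Call candidate editing observations for one sample
#'
#' Compares matched DNA and RNA pileups position by position. The reference
#' base at each position is the DNA majority base (ties broken A < C < G <
#' T); one observation is emitted per RNA non-reference base with count > 0.
#' Positions without RNA mismatch, absent from the DNA pileup, or with zero
#' DNA coverage are not emitted (the latter could not define a reference
#' base and would fail the DNA-coverage rule regardless).
#'
#' @param dna,rna Pileup tables (see [read_pileup_tsv]) for one sample,
#'   sorted by (chrom, pos).
#' @param sample_id Sample label recorded in the output (defaults to the
#'   RNA pileup's sample column).
#' @param min_alt_reads Support threshold used to flag multiallelic
#'   positions (>= 2 distinct alternative bases at or above it).
#' @return data.table of observations with columns chrom, pos, sample,
#'   ref_base, alt_base, rna_cov, rna_alt_count, rna_alt_freq, dna_cov,
#'   dna_ref_freq, dna_alt_count, mean_qual, multiallelic.
#' @export
call_candidates <- function(dna, rna, sample_id = NULL, min_alt_reads = 2L) {
  dna <- data.table::as.data.table(dna)
  rna <- data.table::as.data.table(rna)
  check_sorted(dna, "DNA")
  check_sorted(rna, "RNA")
  if (is.null(sample_id))
    sample_id <- if (nrow(rna)) rna$sample[1L] else NA_character_

  dm <- as.matrix(dna[, BASES, with = FALSE])
  ref_i <- max.col(dm, ties.method = "first")
  d <- data.table::data.table(
    chrom = dna$chrom, pos = dna$pos,
    ref_base = BASES[ref_i],
    dna_cov = as.integer(rowSums(dm)),
    dna_ref_count = dm[cbind(seq_len(nrow(dm)), ref_i)])
  d <- d[d$dna_cov > 0L]
  d[, `:=`(dna_alt_count = d$dna_cov - d$dna_ref_count,
           dna_ref_freq = d$dna_ref_count / d$dna_cov)]

  r <- data.table::data.table(chrom = rna$chrom, pos = rna$pos,
                              rna_cov = as.integer(rowSums(
                                as.matrix(rna[, BASES, with = FALSE]))),
                              mean_qual = rna$mean_qual)
  r <- cbind(r, rna[, BASES, with = FALSE])
  m <- merge(d, r, by = c("chrom", "pos"))
  if (nrow(m) == 0L) return(empty_observations())

  long <- data.table::rbindlist(lapply(BASES, function(b) {
    sel <- m$ref_base != b & m[[b]] > 0L
    if (!any(sel)) return(NULL)
    s <- m[sel]
    data.table::data.table(
      chrom = s$chrom, pos = s$pos, sample = sample_id,
      ref_base = s$ref_base, alt_base = b,
      rna_cov = s$rna_cov, rna_alt_count = s[[b]],
      rna_alt_freq = s[[b]] / s$rna_cov,
      dna_cov = s$dna_cov, dna_ref_freq = s$dna_ref_freq,
      dna_alt_count = s$dna_alt_count, mean_qual = s$mean_qual)
  }))
  if (nrow(long) == 0L) return(empty_observations())
  n_supported <- strong <- NULL # data.table NSE
  long[, n_supported := sum(rna_alt_count >= min_alt_reads),
       by = c("chrom", "pos")]
  long[, multiallelic := n_supported >= 2L]
  long[, n_supported := NULL]
  data.table::setorderv(long, c("chrom", "pos", "alt_base"))
  long[]
}

empty_observations <- function() {
  data.table::data.table(
    chrom = character(), pos = integer(), sample = character(),
    ref_base = character(), alt_base = character(), rna_cov = integer(),
    rna_alt_count = integer(), rna_alt_freq = numeric(),
    dna_cov = integer(), dna_ref_freq = numeric(),
    dna_alt_count = integer(), mean_qual = numeric(),
    multiallelic = logical())
}

primary_rules <- function(cfg) {
  list(
    min_rna_cov      = function(o) o$rna_cov >= cfg$min_rna_cov,
    min_dna_cov      = function(o) o$dna_cov >= cfg$min_dna_cov,
    min_alt_reads    = function(o) o$rna_alt_count >= cfg$min_alt_reads,
    dna_variant      = function(o) o$dna_alt_count <= cfg$max_dna_alt_reads,
    min_rna_alt_freq = function(o) o$rna_alt_freq >= cfg$min_rna_alt_freq,
    min_dna_ref_freq = function(o) o$dna_ref_freq >= cfg$min_dna_ref_freq,
    multiallelic     = function(o) !(cfg$exclude_multiallelic &
                                       o$multiallelic))
}

#' Apply the per-sample primary filter cascade
#'
#' Evaluates the rules in fixed order -- RNA coverage, DNA coverage,
#' edited-base support, DNA mutation reads, RNA variant frequency, DNA
#' reference frequency, multiallelic -- and records the first violated rule.
#' All thresholds are inclusive.
#'
#' @param obs Observation table from [call_candidates].
#' @param cfg A [filter_config].
#' @return `obs` with added logical `pass` and character `fail_reason`
#'   (`NA` for passing rows).
#' @export
apply_primary_filters <- function(obs, cfg = filter_config()) {
  obs <- data.table::as.data.table(obs)
  pass <- rep(TRUE, nrow(obs))
  reason <- rep(NA_character_, nrow(obs))
  for (nm in names(primary_rules(cfg))) {
    ok <- primary_rules(cfg)[[nm]](obs)
    newly <- pass & !ok
    reason[newly] <- nm
    pass <- pass & ok
  }
  obs$pass <- pass
  obs$fail_reason <- reason
  obs[]
}

#' Remove observations overlapping known variants
#'
#' Drops observations at a known SNP position or inside a known INDEL
#' interval (1-based inclusive).
#'
#' @param obs Observation table.
#' @param variants A [variant_set].
#' @return Filtered observation table.
#' @export
mask_known_variants <- function(obs, variants) {
  obs <- data.table::as.data.table(obs)
  if (nrow(obs) == 0L) return(obs)
  drop <- rep(FALSE, nrow(obs))
  if (nrow(variants$snps) > 0L) {
    key <- paste(obs$chrom, obs$pos)
    drop <- drop | key %in% paste(variants$snps$chrom, variants$snps$pos)
  }
  if (nrow(variants$indels) > 0L) {
    for (ch in unique(variants$indels$chrom)) {
      iv <- variants$indels[variants$indels$chrom == ch, , drop = FALSE]
      sel <- obs$chrom == ch
      if (!any(sel)) next
      hits <- IRanges::overlapsAny(
        IRanges::IRanges(obs$pos[sel], obs$pos[sel]),
        IRanges::IRanges(iv$start, iv$end))
      drop[sel] <- drop[sel] | hits
    }
  }
  obs[!drop]
}

#' Apply cohort-level filters and derive non-redundant sites
#'
#' A site (unique chrom, pos) survives iff it is detected -- i.e. passed
#' all primary filters -- in at least `min_samples` samples, its editing
#' level is not 1 in every detected sample, and it lies on a named
#' autosome. Surviving observations are all observations at surviving
#' sites.
#'
#' @param obs Observations that passed per-sample primary filtering (and
#'   variant masking), across all samples.
#' @param cfg A [filter_config]; `autosome_names` must be non-empty when
#'   `autosomes_only` is set.
#' @return List with `observations` (surviving observations), `sites`
#'   (non-redundant site table with per-site support and level summaries),
#'   and `n_observations` / `n_sites` counts.
#' @export
apply_cohort_filters <- function(obs, cfg = filter_config()) {
  if (cfg$autosomes_only && length(cfg$autosome_names) == 0L)
    stop("autosomes_only is set but autosome_names is empty")
  obs <- data.table::as.data.table(obs)
  if (nrow(obs) == 0L) {
    empty_sites <- data.table::data.table(
      chrom = character(), pos = integer(), n_samples = integer(),
      ref_base = character(), alt_base = character(),
      mean_level = numeric(), median_level = numeric())
    return(list(observations = obs, sites = empty_sites,
                n_observations = 0L, n_sites = 0L))
  }
  n_samples <- all_ones <- rna_alt_freq <- rna_alt_count <- NULL
  per_site <- obs[, {
    tot <- tapply(rna_alt_count, alt_base, sum)
    list(n_samples = length(unique(sample)),
         all_ones = all(rna_alt_freq == 1),
         ref_base = ref_base[1L],
         alt_base = names(tot)[which.max(tot)],
         mean_level = mean(rna_alt_freq),
         median_level = stats::median(rna_alt_freq))
  }, by = c("chrom", "pos")]
  keep <- per_site$n_samples >= cfg$min_samples
  if (cfg$drop_all_ones) keep <- keep & !per_site$all_ones
  if (cfg$autosomes_only) keep <- keep & per_site$chrom %in% cfg$autosome_names
  sites <- per_site[keep]
  sites[, all_ones := NULL]
  data.table::setorderv(sites, c("chrom", "pos"))
  key <- paste(obs$chrom, obs$pos)
  surv <- obs[key %in% paste(sites$chrom, sites$pos)]
  data.table::setorderv(surv, c("chrom", "pos", "sample"))
  list(observations = surv, sites = sites,
       n_observations = nrow(surv), n_sites = nrow(sites))
}

#' Percentage with 2-decimal rounding
#'
#' The formatting convention used by all summary tables: `100 * n / d`
#' rounded to two decimals.
#'
#' @param n Numerator. @param d Denominator.
#' @return Numeric percentage.
#' @export
percent <- function(n, d) round(100 * n / d, 2)

#' Editing-level distribution summary
#'
#' Counts and fractions of observations with editing level above 0.5,
#' above 0.95, and exactly 1 ("completely edited"), using the observation
#' count as denominator, plus a per-site sample-support histogram over
#' non-redundant sites.
#'
#' @param obs Observation table (post-filter).
#' @return List with `n_obs`, a `levels` data.frame (threshold, count,
#'   percent), and `support_hist` (named vector: sites detected in k
#'   samples).
#' @export
level_summary <- function(obs) {
  obs <- data.table::as.data.table(obs)
  n <- nrow(obs)
  cnt <- c(gt_0.5 = sum(obs$rna_alt_freq > 0.5),
           gt_0.95 = sum(obs$rna_alt_freq > 0.95),
           eq_1 = sum(obs$rna_alt_freq == 1))
  support <- if (n > 0L) {
    per_site <- obs[, list(k = length(unique(sample))),
                    by = c("chrom", "pos")]
    table(per_site$k)
  } else table(integer(0))
  list(n_obs = n,
       levels = data.frame(threshold = names(cnt), count = as.integer(cnt),
                           percent = if (n > 0L) percent(cnt, n)
                                     else rep(NA_real_, 3L)),
       support_hist = support)
}

#' Detect editing sites across a cohort of samples
#'
#' Runs the full detection cascade: per RNA sample, candidate calling
#' against the matched DNA pileup, primary filters and known-variant
#' masking; then cohort filters over all samples.
#'
#' @param pileups Combined pileup table (both sources, all samples).
#' @param metadata Sample sheet: data.frame with `sample` (RNA sample id)
#'   and `dna_sample` (matched DNA pileup sample id); extra columns such as
#'   population/tissue/individual are carried along.
#' @param variants Optional [variant_set] of known SNPs/INDELs to mask.
#' @param cfg A [filter_config].
#' @return As [apply_cohort_filters], plus `fail_counts` (table of primary
#'   fail reasons) and the per-sample candidate count.
#' @export
detect_editing <- function(pileups, metadata, variants = NULL,
                           cfg = filter_config()) {
  pileups <- data.table::as.data.table(pileups)
  passed <- list()
  fail_counts <- integer(0)
  n_candidates <- integer(0)
  for (i in seq_len(nrow(metadata))) {
    s <- metadata$sample[i]
    rna <- pileups[pileups$sample == s & pileups$source == "RNA"]
    dna <- pileups[pileups$sample == metadata$dna_sample[i] &
                     pileups$source == "DNA"]
    obs <- call_candidates(dna, rna, sample_id = s,
                           min_alt_reads = cfg$min_alt_reads)
    n_candidates[s] <- nrow(obs)
    obs <- apply_primary_filters(obs, cfg)
    tab <- table(obs$fail_reason[!obs$pass])
    for (nm in names(tab))
      fail_counts[nm] <- sum(fail_counts[nm], tab[[nm]], na.rm = TRUE)
    passed[[s]] <- obs[obs$pass == TRUE]
  }
  all_obs <- data.table::rbindlist(passed)
  if (!is.null(variants)) all_obs <- mask_known_variants(all_obs, variants)
  res <- apply_cohort_filters(all_obs, cfg)
  res$fail_counts <- fail_counts
  res$n_candidates <- n_candidates
  res
}
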