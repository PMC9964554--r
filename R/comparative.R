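# Editing matrices across samples; tissue-specific (tSES),
# population-specific (pSES) and population-differential (pDES) site
# calling; editing-level vs expression correlation; expression
# normalization.
#
# "Detected" everywhere below means: present in the high-quality
# observation set after all detection filters (a non-missing matrix cell).

#' Build the sites-by-samples editing matrix
#'
#' Cells hold the editing level where the site was detected in the sample
#' and NA otherwise. Rows are ordered deterministically by (chrom, pos).
#'
#' @param observations High-quality observation table.
#' @param metadata Sample sheet with `sample`, `population`, `tissue`,
#'   `individual`; every observed sample must appear.
#' @return An `editing_matrix`: list with `levels` (numeric matrix, rows
#'   `chrom:pos`), `sites` (data.table chrom/pos) and `samples` (the
#'   metadata, ordered as the columns).
#' @export
build_matrix <- function(observations, metadata) {
  obs <- data.table::as.data.table(observations)
  missing <- setdiff(unique(obs$sample), metadata$sample)
  if (length(missing) > 0L)
    stop("sample without metadata: ", paste(missing, collapse = ", "))
  if (anyDuplicated(obs[, c("chrom", "pos", "sample")]))
    stop("duplicate (site, sample) observations")
  sites <- unique(obs[, c("chrom", "pos")])
  data.table::setorderv(sites, c("chrom", "pos"))
  key <- paste0(sites$chrom, ":", sites$pos)
  m <- matrix(NA_real_, nrow = nrow(sites), ncol = nrow(metadata),
              dimnames = list(key, metadata$sample))
  m[cbind(match(paste0(obs$chrom, ":", obs$pos), key),
          match(obs$sample, metadata$sample))] <- obs$rna_alt_freq
  structure(list(levels = m, sites = sites,
                 samples = data.table::as.data.table(metadata)),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf("<editing_matrix> %d sites x %d samples (%.1f%% detected)\n",
              nrow(x$levels), ncol(x$levels),
              100 * mean(!is.na(x$levels))))
  invisible(x)
}

#' Reads Per Kilobase per Million mapped reads
#'
#' @param count Read count(s). @param gene_length_bp Gene length in bp.
#' @param library_size Total mapped reads of the sample.
#' @return `count / (gene_length_bp/1e3 * library_size/1e6)`.
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count / (gene_length_bp / 1e3 * library_size / 1e6)
}

#' Counts per million
#'
#' @inheritParams rpkm
#' @return `count / (library_size/1e6)`.
#' @export
cpm <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library size must be positive")
  count / (library_size / 1e6)
}

#' Expression matrix with CPM and RPKM layers
#'
#' @param counts Genes x samples matrix of non-negative integer counts.
#' @param gene_lengths Named vector of gene lengths in bp.
#' @return List with `counts`, `cpm`, `rpkm`, `gene_lengths`,
#'   `library_sizes` (column sums of counts).
#' @export
expression_matrix <- function(counts, gene_lengths) {
  stopifnot(all(counts >= 0), all(rownames(counts) %in% names(gene_lengths)))
  libs <- colSums(counts)
  gl <- gene_lengths[rownames(counts)]
  list(counts = counts,
       cpm = sweep(counts, 2L, libs / 1e6, "/"),
       rpkm = sweep(counts / (gl / 1e3), 2L, libs / 1e6, "/"),
       gene_lengths = gl, library_sizes = libs)
}

rank_avg <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; pairs with a missing value are dropped. The
#' two-sided p-value uses `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees
#' of freedom; for n <= 8 an exact permutation p-value is available.
#'
#' @param levels,expression Paired numeric vectors.
#' @param exact Use exact permutation p for n <= 8.
#' @return List with `rho`, `p_value`, `n`; both NA when n < 4.
#' @export
spearman_correlation <- function(levels, expression, exact = FALSE) {
  ok <- !is.na(levels) & !is.na(expression)
  x <- levels[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 4L) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rank_avg(x), rank_avg(y))
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  if (exact && n <= 8L) {
    perms <- permutations_of(n)
    ry <- rank_avg(y)
    rx <- rank_avg(x)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Correlate site editing levels with catalyzing-gene expression
#'
#' For each site x catalyzer pair, Spearman correlation over the samples
#' where the site is detected; significance at p < 0.05.
#'
#' @param matrix An `editing_matrix`.
#' @param expression An [expression_matrix] (CPM layer is used).
#' @param catalyzer_genes Named character vector or plain vector of gene
#'   ids present in the expression matrix (e.g. ADAR/APOBEC family);
#'   missing ids are skipped with a warning.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `table` (site, gene, rho, p, n, significant) and
#'   `summary` (fraction of sites with >= 1 significant catalyzer, split
#'   by correlation sign).
#' @export
correlate_with_catalyzers <- function(matrix, expression, catalyzer_genes,
                                      alpha = 0.05) {
  present <- catalyzer_genes %in% rownames(expression$counts)
  if (any(!present))
    warning("catalyzer gene(s) absent from expression matrix: ",
            paste(catalyzer_genes[!present], collapse = ", "))
  genes <- catalyzer_genes[present]
  rows <- list()
  for (g in genes) {
    expr <- expression$cpm[g, colnames(matrix$levels)]
    for (i in seq_len(nrow(matrix$levels))) {
      sc <- spearman_correlation(matrix$levels[i, ], expr)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        site = rownames(matrix$levels)[i], gene = g, rho = sc$rho,
        p_value = sc$p_value, n = sc$n,
        significant = !is.na(sc$p_value) && sc$p_value < alpha)
    }
  }
  tab <- data.table::rbindlist(rows)
  significant <- rho <- NULL
  per_site <- tab[, list(any_sig = any(significant),
                         any_pos = any(significant & rho > 0),
                         any_neg = any(significant & rho < 0)),
                  by = "site"]
  list(table = tab,
       summary = list(
         n_sites = nrow(per_site),
         n_significant = sum(per_site$any_sig),
         fraction_significant = mean(per_site$any_sig),
         n_positive = sum(per_site$any_pos),
         n_negative = sum(per_site$any_neg)))
}

one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) return(list(F = NA_real_, p_value = NA_real_))
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_between <- sum(gn * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 <= 0L) return(list(F = NA_real_, p_value = NA_real_))
  if (ss_within == 0) {
    if (ss_between == 0) return(list(F = 0, p_value = 1))
    return(list(F = Inf, p_value = 0))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' One-way ANOVA of editing levels across tissues
#'
#' Per site, a fixed-effects one-way ANOVA on the detected levels pooled
#' per tissue (no pairing structure). Sites with fewer than 2 tissues
#' having >= 2 detected values yield NA.
#'
#' @param matrix An `editing_matrix`.
#' @return data.table with site, n_tissues, F, p_value.
#' @export
anova_tissue_levels <- function(matrix) {
  tis <- matrix$samples$tissue
  rows <- lapply(seq_len(nrow(matrix$levels)), function(i) {
    lv <- matrix$levels[i, ]
    ok <- !is.na(lv)
    g <- tis[ok]
    usable <- names(which(table(g) >= 2L))
    keep <- ok
    keep[ok] <- g %in% usable
    res <- if (length(usable) >= 2L)
      one_way_anova(matrix$levels[i, keep], tis[keep])
    else list(F = NA_real_, p_value = NA_real_)
    data.table::data.table(site = rownames(matrix$levels)[i],
                           n_tissues = length(usable), F = res$F,
                           p_value = res$p_value)
  })
  data.table::rbindlist(rows)
}

detection_counts <- function(matrix, by) {
  det <- !is.na(matrix$levels)
  groups <- matrix$samples[[by]]
  ug <- unique(groups)
  out <- matrix(0L, nrow(det), length(ug),
                dimnames = list(rownames(det), ug))
  for (g in ug) out[, g] <- rowSums(det[, groups == g, drop = FALSE])
  out
}

#' Call tissue-specific editing sites (tSES)
#'
#' A site is a tSES for tissue T iff it is detected in at least
#' `min_support` samples of T and in zero samples of every other tissue.
#'
#' @param matrix An `editing_matrix`.
#' @param min_support Minimum supporting samples in the exclusive tissue
#'   (default 3).
#' @return data.table with site, tissue, n_support for each called tSES.
#' @export
call_tses <- function(matrix, min_support = 3L) {
  cnt <- detection_counts(matrix, "tissue")
  rows <- list()
  for (i in seq_len(nrow(cnt))) {
    nz <- which(cnt[i, ] > 0L)
    if (length(nz) == 1L && cnt[i, nz] >= min_support)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        site = rownames(cnt)[i], tissue = colnames(cnt)[nz],
        n_support = cnt[i, nz])
  }
  if (length(rows) == 0L)
    return(data.table::data.table(site = character(), tissue = character(),
                                  n_support = integer()))
  data.table::rbindlist(rows)
}

#' Call population-specific editing sites (pSES) in one tissue
#'
#' A site is a pSES for population P in tissue T iff detected in at least
#' `min_support` samples of (P, T) and in zero samples of the other
#' population in T.
#'
#' @param matrix An `editing_matrix`.
#' @param tissue Tissue to analyse.
#' @param min_support Minimum supporting samples (default 3).
#' @return data.table with site, population, tissue, n_support.
#' @export
call_pses <- function(matrix, tissue, min_support = 3L) {
  sel <- matrix$samples$tissue == tissue
  det <- !is.na(matrix$levels[, sel, drop = FALSE])
  pops <- matrix$samples$population[sel]
  upops <- unique(pops)
  if (length(upops) != 2L) stop("pSES calling requires two populations")
  rows <- list()
  for (i in seq_len(nrow(det))) {
    n1 <- sum(det[i, pops == upops[1L]])
    n2 <- sum(det[i, pops == upops[2L]])
    hit <- if (n1 >= min_support && n2 == 0L) c(upops[1L], n1)
      else if (n2 >= min_support && n1 == 0L) c(upops[2L], n2)
      else NULL
    if (!is.null(hit))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        site = rownames(det)[i], population = hit[1L], tissue = tissue,
        n_support = as.integer(hit[2L]))
  }
  if (length(rows) == 0L)
    return(data.table::data.table(site = character(),
                                  population = character(),
                                  tissue = character(),
                                  n_support = integer()))
  data.table::rbindlist(rows)
}

#' Call population-differential editing sites (pDES) in one tissue
#'
#' Sites detected in at least `min_per_group` samples of both populations
#' in the tissue are tested with a two-sided Wilcoxon rank-sum on the
#' detected levels; p-values are BH-adjusted across all tested sites in
#' the tissue and called significant below `alpha`.
#'
#' @param matrix An `editing_matrix`.
#' @param tissue Tissue to analyse.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_per_group Minimum detected samples per population (default 3).
#' @return data.table with site, tissue, n per group, group medians, W
#'   statistic, p_value, p_adjusted, significant.
#' @export
call_pdes <- function(matrix, tissue, alpha = 0.05, min_per_group = 3L) {
  sel <- matrix$samples$tissue == tissue
  lv <- matrix$levels[, sel, drop = FALSE]
  pops <- matrix$samples$population[sel]
  upops <- sort(unique(pops))
  if (length(upops) != 2L) stop("pDES calling requires two populations")
  rows <- list()
  for (i in seq_len(nrow(lv))) {
    x <- lv[i, pops == upops[1L]]
    y <- lv[i, pops == upops[2L]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < min_per_group || length(y) < min_per_group) next
    wt <- wilcoxon_rank_sum(x, y)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      site = rownames(lv)[i], tissue = tissue,
      n_1 = length(x), n_2 = length(y),
      median_1 = stats::median(x), median_2 = stats::median(y),
      W = wt$statistic, p_value = wt$p_value)
  }
  if (length(rows) == 0L)
    return(data.table::data.table(
      site = character(), tissue = character(), n_1 = integer(),
      n_2 = integer(), median_1 = numeric(), median_2 = numeric(),
      W = numeric(), p_value = numeric(), p_adjusted = numeric(),
      significant = logical()))
  tab <- data.table::rbindlist(rows)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  tab$significant <- tab$p_adjusted < alpha
  tab
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration of the U distribution when `n_x + n_y <= 12` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. The two-sided exact p is twice the smaller
#' tail, capped at 1.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `statistic` (U for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L)
    return(list(statistic = nx * ny / 2, p_value = 1))
  r <- rank_avg(all_v)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  if (nx + ny <= 12L && !ties) {
    sums <- utils::combn(nx + ny, nx, function(idx) sum(r[idx]))
    us <- sums - nx * (nx + 1) / 2
    p_lo <- mean(us <= u + 1e-9)
    p_hi <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(all_v)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p_value = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_(j >= i) (p_(j) * m / j)` over ascending p-values,
#' capped at 1, mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Sites shared across tissues or populations
#'
#' Partitions the detected sites by the number of groups (tissues or
#' populations) they are detected in.
#'
#' @param matrix An `editing_matrix`.
#' @param axis `"tissue"` or `"population"`.
#' @return List with `by_k` (sites detected in exactly k groups, counts
#'   and percents over all detected sites), `shared` (detected in every
#'   group) and `exclusive` (in exactly one).
#' @export
shared_site_summary <- function(matrix, axis = c("tissue", "population")) {
  axis <- match.arg(axis)
  cnt <- detection_counts(matrix, axis)
  k <- rowSums(cnt > 0L)
  total <- sum(k > 0L)
  ngroups <- ncol(cnt)
  by_k <- data.frame(k = seq_len(ngroups),
                     count = as.integer(table(factor(k[k > 0L],
                                                     levels = 1:ngroups))))
  by_k$percent <- percent(by_k$count, total)
  list(by_k = by_k, n_sites = total,
       shared = sum(k == ngroups), exclusive = sum(k == 1L))
}
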