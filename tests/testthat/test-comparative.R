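meta3 <- data.frame(sample = c("s1", "s2", "s3"),
                    population = c("highland", "highland", "lowland"),
                    tissue = "kidney", individual = c("i1", "i2", "i3"))

test_that("build_matrix lays out levels with missingness and fixed order", {
  obs <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr1", "chr2"),
                    pos = c(10L, 10L, 5L, 10L, 5L),
                    sample = c("s1", "s2", "s1", "s3", "s3"),
                    rna_alt_freq = c(0.5, 0.6, 0.2, 0.7, 0.4))
  em <- build_matrix(obs, meta3)
  expect_equal(dim(em$levels), c(2L, 3L))
  expect_equal(rownames(em$levels), c("chr1:10", "chr2:5"))
  expect_equal(sum(is.na(em$levels)), 1)
  expect_equal(em$levels["chr2:5", "s2"], NA_real_)
  expect_equal(em$levels["chr1:10", "s2"], 0.6)

  dup <- rbind(obs, obs[1, ])
  expect_error(build_matrix(dup, meta3), "duplicate")
  expect_error(build_matrix(obs, meta3[1:2, ]), "without metadata")
})

test_that("rpkm and cpm implement the normalization formulas", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 2e6), 0)
  expect_equal(rpkm(3, 1500, 3e6), 3 / (1.5 * 3))
  expect_equal(cpm(10, 2e6), 5)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(cpm(1, 0), "library size")

  counts <- matrix(c(10L, 20L, 30L, 40L), 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  exm <- expression_matrix(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(exm$library_sizes, c(a = 30, b = 70))
  expect_equal(exm$rpkm["g1", "a"], 10 / (1 * 30 / 1e6))
  expect_equal(exm$cpm["g2", "b"], 40 / (70 / 1e6))
})

test_that("spearman_correlation matches the rank formula and cor.test", {
  expect_equal(spearman_correlation(1:5, 2:6)$rho, 1)
  expect_equal(spearman_correlation(1:5, 6:2)$rho, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)  # tie in y
  sc <- spearman_correlation(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(sc$rho, unname(ct$estimate))
  # hand-ranked: the two 7s share rank 3.5, the 8 gets rank 5
  expect_equal(sc$rho, stats::cor(1:5, c(1, 2, 3.5, 5, 3.5)))

  expect_true(is.na(spearman_correlation(1:3, 3:1)$rho))
  # missing pairs are dropped
  sc2 <- spearman_correlation(c(1, 2, NA, 4, 5), c(2, 3, 9, 5, 6))
  expect_equal(sc2$n, 4)
  expect_equal(sc2$rho, 1)

  # t-approximation p agrees with cor.test for untied data
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    sc3 <- spearman_correlation(a, b)
    ct3 <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    expect_equal(sc3$rho, unname(ct3$estimate))
    expect_equal(sc3$p_value, ct3$p.value, tolerance = 1e-8)
  }
})

test_that("one-way ANOVA on editing levels matches lm and has power", {
  mk_em <- function(levels_mat, tissues) {
    samples <- data.table::data.table(
      sample = colnames(levels_mat),
      population = "highland", tissue = tissues,
      individual = colnames(levels_mat))
    structure(list(levels = levels_mat,
                   sites = data.frame(chrom = "c", pos = 1L),
                   samples = samples), class = "editing_matrix")
  }
  # identical groups: F ~ 0, p ~ 1
  lv <- matrix(rep(c(0.2, 0.4, 0.6), 2), nrow = 1,
               dimnames = list("c:1", paste0("s", 1:6)))
  a <- anova_tissue_levels(mk_em(lv, rep(c("heart", "lung"), each = 3)))
  expect_equal(a$F, 0)
  expect_equal(a$p_value, 1)

  # hand-computable 3 groups x 2 values against lm/anova
  vals <- c(0.1, 0.2, 0.5, 0.6, 0.8, 1.0)
  tis <- rep(c("heart", "lung", "kidney"), each = 2)
  lv2 <- matrix(vals, nrow = 1,
                dimnames = list("c:1", paste0("s", 1:6)))
  a2 <- anova_tissue_levels(mk_em(lv2, tis))
  ref <- anova(lm(vals ~ factor(tis)))
  expect_equal(a2$F, ref$`F value`[1])
  expect_equal(a2$p_value, ref$`Pr(>F)`[1])

  # planted shift of +0.3 at n=20/group, sigma=0.05 is detected
  set.seed(3)
  g1 <- rnorm(20, 0.3, 0.05); g2 <- rnorm(20, 0.6, 0.05)
  lv3 <- matrix(c(g1, g2), nrow = 1,
                dimnames = list("c:1", paste0("s", 1:40)))
  a3 <- anova_tissue_levels(mk_em(lv3, rep(c("heart", "lung"),
                                           each = 20)))
  expect_lt(a3$p_value, 0.001)

  # a single usable tissue yields NA
  lv4 <- matrix(c(0.1, 0.2, NA, NA), nrow = 1,
                dimnames = list("c:1", paste0("s", 1:4)))
  a4 <- anova_tissue_levels(mk_em(lv4, rep(c("heart", "lung"), each = 2)))
  expect_true(is.na(a4$p_value))
})

make_design_matrix <- function(lv_list) {
  # lv_list: named list site -> named numeric over samples (NA = missing)
  samples <- expand.grid(individual = 1:5,
                         tissue = c("heart", "lung", "kidney", "muscle"),
                         population = c("highland", "lowland"),
                         stringsAsFactors = FALSE)
  samples$sample <- with(samples,
                         paste(population, tissue, individual, sep = "_"))
  m <- matrix(NA_real_, length(lv_list), nrow(samples),
              dimnames = list(names(lv_list), samples$sample))
  for (s in names(lv_list)) m[s, names(lv_list[[s]])] <- lv_list[[s]]
  structure(list(levels = m,
                 sites = data.frame(chrom = "c",
                                    pos = seq_along(lv_list)),
                 samples = data.table::as.data.table(
                   samples[c("sample", "population", "tissue",
                             "individual")])),
            class = "editing_matrix")
}

named_lv <- function(pop, tissue, inds, value = 0.5) {
  stats::setNames(rep(value, length(inds)),
                  paste(pop, tissue, inds, sep = "_"))
}

test_that("tSES calling requires exclusivity and support", {
  em <- make_design_matrix(list(
    a = c(named_lv("highland", "kidney", 1:4)),
    b = c(named_lv("highland", "kidney", 1:4),
          named_lv("lowland", "lung", 1)),
    c = c(named_lv("highland", "kidney", 1:2))))
  t3 <- call_tses(em, min_support = 3)
  expect_equal(t3$site, "a")
  expect_equal(t3$tissue, "kidney")
  expect_equal(t3$n_support, 4L)
  # with min_support 2 the weakly supported site joins
  expect_setequal(call_tses(em, min_support = 2)$site, c("a", "c"))
})

test_that("pSES calling requires >= 3 supporters and absence elsewhere", {
  em <- make_design_matrix(list(
    yes = named_lv("lowland", "kidney", 1:3),
    mixed = c(named_lv("lowland", "kidney", 1:3),
              named_lv("highland", "kidney", 1)),
    weak = named_lv("lowland", "kidney", 1:2)))
  p <- call_pses(em, "kidney")
  expect_equal(p$site, "yes")
  expect_equal(p$population, "lowland")
  # other-tissue detections do not disqualify a pSES in this tissue
  em2 <- make_design_matrix(list(
    yes = c(named_lv("lowland", "kidney", 1:3),
            named_lv("highland", "lung", 1:3))))
  expect_equal(nrow(call_pses(em2, "kidney")), 1)
  expect_equal(nrow(call_pses(em2, "lung")), 1)
})

test_that("wilcoxon_rank_sum matches enumeration and wilcox.test", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # 5v5 complete separation: exact two-sided p = 2/choose(10,5)
  w5 <- wilcoxon_rank_sum(rep(0.1, 5) + (1:5) * 1e-3,
                          rep(0.9, 5) + (1:5) * 1e-3)
  expect_equal(w5$p_value, 2 / choose(10, 5))
  expect_equal(round(w5$p_value, 4), 0.0079)

  set.seed(8)
  # exact regime against stats::wilcox.test
  for (i in 1:20) {
    x <- sample(100, sample(2:6, 1)); y <- sample(200:300, sample(2:6, 1))
    w1 <- wilcoxon_rank_sum(x, y)
    w2 <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(w1$statistic, unname(w2$statistic))
    expect_equal(w1$p_value, w2$p.value)
  }
  # approximate regime with ties against wilcox.test(correct = TRUE)
  for (i in 1:20) {
    x <- sample(5, 10, replace = TRUE); y <- sample(6, 12, replace = TRUE)
    w1 <- wilcoxon_rank_sum(x, y)
    w2 <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    expect_equal(w1$p_value, w2$p.value, tolerance = 1e-8)
  }
  # normal approximation close to exact at 6+6
  x <- c(1, 5, 7, 11, 13, 17); y <- c(2, 3, 6, 8, 19, 23)
  exact_p <- wilcoxon_rank_sum(x, y)$p_value
  big <- c(x, 1e6 + 1:7)  # force approximation via n > 12
  # instead compare approximation formula directly on the same data
  r <- rank(c(x, y))
  u <- sum(r[1:6]) - 6 * 7 / 2
  mu <- 18; sig <- sqrt(6 * 6 * 13 / 12)
  z <- (u - mu - sign(u - mu) * 0.5) / sig
  approx_p <- 2 * pnorm(-abs(z))
  expect_lt(abs(exact_p - approx_p), 0.01)
})

test_that("bh_adjust equals the step-up rule and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(15)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    # brute-force step-up oracle
    m <- length(p); o <- order(p)
    brute <- numeric(m)
    for (k in seq_len(m))
      brute[o[k]] <- min(1, min(p[o][k:m] * m / (k:m)))
    expect_equal(adj, brute)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[o]) >= -1e-12))  # monotone in rank
  }
})

test_that("pDES calling tests, adjusts and respects group minima", {
  lv <- list(
    flat = c(named_lv("highland", "kidney", 1:5, 0.5),
             named_lv("lowland", "kidney", 1:5, 0.5)),
    sep = c(named_lv("highland", "kidney", 1:5, 0.1),
            named_lv("lowland", "kidney", 1:5, 0.9)),
    small = c(named_lv("highland", "kidney", 1:2, 0.1),
              named_lv("lowland", "kidney", 1:5, 0.9)))
  # make 'sep' genuinely untied within groups
  lv$sep <- lv$sep + seq_along(lv$sep) * 1e-4
  em <- make_design_matrix(lv)
  pd <- call_pdes(em, "kidney")
  expect_setequal(pd$site, c("flat", "sep"))  # 'small' not tested
  expect_equal(pd$p_value[pd$site == "flat"], 1)
  expect_equal(pd$p_value[pd$site == "sep"], 2 / choose(10, 5))
  expect_equal(pd$p_adjusted, bh_adjust(pd$p_value))
  expect_false(pd$significant[pd$site == "flat"])
})

test_that("pSES sites are never tested as pDES in the same tissue", {
  em <- make_design_matrix(list(
    ps = named_lv("lowland", "kidney", 1:5),
    both = c(named_lv("lowland", "kidney", 1:5, 0.2),
             named_lv("highland", "kidney", 1:5, 0.8))))
  ps <- call_pses(em, "kidney")
  pd <- call_pdes(em, "kidney")
  expect_length(intersect(ps$site, pd$site), 0)
})

test_that("null pDES keeps the BH-significant fraction within bounds", {
  frac <- vapply(1:3, function(seed) {
    set.seed(seed)
    n_sites <- 200
    lv <- matrix(runif(n_sites * 40, 0.05, 0.95), n_sites, 40)
    lv_list <- lapply(seq_len(n_sites), function(i)
      stats::setNames(lv[i, ],
                      make_design_matrix(list(x = c()))$samples$sample))
    names(lv_list) <- paste0("s", seq_len(n_sites))
    em <- make_design_matrix(lv_list)
    pd <- data.table::rbindlist(lapply(
      c("heart", "lung", "kidney", "muscle"),
      function(t) call_pdes(em, t)))
    mean(pd$significant)
  }, numeric(1))
  n_tested <- 200 * 4
  se <- sqrt(0.05 * 0.95 / n_tested)
  expect_true(all(frac <= 0.05 + 3 * se))
})

test_that("shared_site_summary partitions detected sites", {
  em <- make_design_matrix(list(
    everywhere = c(named_lv("highland", "heart", 1),
                   named_lv("highland", "lung", 1),
                   named_lv("highland", "kidney", 1),
                   named_lv("highland", "muscle", 1)),
    one_tissue = named_lv("highland", "kidney", 1:2)))
  st <- shared_site_summary(em, "tissue")
  expect_equal(st$by_k$count, c(1L, 0L, 0L, 1L))
  expect_equal(st$shared, 1)
  expect_equal(st$exclusive, 1)
  expect_equal(sum(st$by_k$count), st$n_sites)
  expect_equal(sum(st$by_k$percent), 100, tolerance = 0.02)

  sp <- shared_site_summary(em, "population")
  expect_equal(sp$by_k$count, c(2L, 0L))
})

test_that("correlate_with_catalyzers flags planted and skips absent genes", {
  set.seed(42)
  n <- 40
  z <- rnorm(n)
  lv <- plogis(2 * z + rnorm(n, 0, 0.5))
  expr_counts <- matrix(
    c(rpois(n, exp(5 + 0.8 * z)), rpois(n, 200)), nrow = 2, byrow = TRUE,
    dimnames = list(c("CAT1", "FLAT"), paste0("s", 1:n)))
  samples <- data.table::data.table(sample = paste0("s", 1:n),
                                    population = "x", tissue = "y",
                                    individual = paste0("s", 1:n))
  em <- structure(list(
    levels = matrix(lv, 1, n, dimnames = list("c:1", paste0("s", 1:n))),
    sites = data.frame(chrom = "c", pos = 1L), samples = samples),
    class = "editing_matrix")
  exm <- expression_matrix(expr_counts, c(CAT1 = 1000, FLAT = 1000))
  expect_warning(
    cc <- correlate_with_catalyzers(em, exm, c("CAT1", "MISSING")),
    "MISSING")
  hit <- cc$table[cc$table$gene == "CAT1"]
  expect_true(hit$significant)
  expect_gt(hit$rho, 0.5)
  expect_equal(cc$summary$n_positive, 1)

  # too few detected samples: NA result, not significant
  em$levels[1, 4:40] <- NA
  cc2 <- correlate_with_catalyzers(em, exm, "CAT1")
  expect_false(any(cc2$table$significant))
})
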