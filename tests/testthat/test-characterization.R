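test_that("extract_flank centers, pads and reverse-complements", {
  genome <- c(chr1 = "AAAACAAAAAGAAAAGAAAAA")
  # center character equals the reference base at the site
  w <- extract_flank(genome, "chr1", 11, "+", k = 10)
  expect_equal(nchar(w), 21)
  expect_equal(substr(w, 11, 11), "G")
  expect_equal(w, genome[["chr1"]])

  # minus strand is the reverse complement of the plus window
  g2 <- c(c1 = "ACGTTACGGA")
  plus <- extract_flank(g2, "c1", 5, "+", k = 3)
  minus <- extract_flank(g2, "c1", 5, "-", k = 3)
  expect_equal(minus, paste(rev(strsplit(chartr("ACGT", "TGCA", plus),
                                         "")[[1]]), collapse = ""))

  # off-chromosome windows are N-padded
  left <- extract_flank(g2, "c1", 3, "+", k = 10)
  expect_equal(nchar(left), 21)
  expect_equal(substr(left, 1, 8), strrep("N", 8))
  expect_error(extract_flank(g2, "c1", 5, "*"), "resolved strand")
})

test_that("flank extraction strand property holds on random sequences", {
  set.seed(77)
  for (rep_i in 1:20) {
    len <- sample(30:60, 1)
    g <- c(x = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
    pos <- sample(seq_len(len), 1)
    k <- sample(2:10, 1)
    plus <- extract_flank(g, "x", pos, "+", k)
    minus <- extract_flank(g, "x", pos, "-", k)
    expect_equal(minus,
                 paste(rev(strsplit(chartr("ACGTN", "TGCAN", plus),
                                    "")[[1]]), collapse = ""))
  }
})

test_that("flank_frequency normalizes per position and finds motifs", {
  m <- flank_frequency(c("AAGAA", "AAGAA"))
  expect_true(all(m %in% c(0, 1)))
  expect_equal(unname(colSums(m)), rep(1, 5))
  expect_equal(m["G", "0"], 1)
  # planted motif: G always at +1
  flanks <- c("ACAGT", "TTAGC", "GCAGA")
  m2 <- flank_frequency(flanks)
  expect_equal(m2["G", "1"], 1)
  # all-N columns contribute nothing
  m3 <- flank_frequency(c("NAANN", "NACNN"))
  expect_equal(unname(colSums(m3)), c(0, 1, 1, 0, 0))
  expect_error(flank_frequency(c("AAA", "AAAAA")), "length")
})

test_that("cds_offset handles both strands and split CDS", {
  tx1 <- list(cds = data.frame(start = 101L, end = 109L))
  expect_equal(cds_offset(101, tx1, "+"), 0)
  expect_equal(cds_offset(109, tx1, "-"), 0)
  expect_equal(cds_offset(101, tx1, "-"), 8)
  tx2 <- list(cds = data.frame(start = c(101L, 201L),
                               end = c(106L, 206L)))
  expect_equal(cds_offset(202, tx2, "+"), 7)
  expect_equal(cds_offset(202, tx2, "-"), 4)
  expect_error(cds_offset(150, tx2, "+"), "not in CDS")
})

test_that("cds_offset is a bijection onto 0..len-1 for generated models", {
  ref <- std_sim()$reference
  checked <- 0L
  for (gm in ref$genes) {
    tr <- gm$transcripts[[1L]]
    if (nrow(tr$cds) == 0L) next
    cds_pos <- unlist(lapply(seq_len(nrow(tr$cds)),
                             function(i) tr$cds$start[i]:tr$cds$end[i]))
    offs <- vapply(cds_pos, cds_offset, numeric(1), transcript = tr,
                   strand = gm$strand)
    expect_setequal(offs, seq_along(cds_pos) - 1L)
    checked <- checked + 1L
    if (checked >= 6L) break
  }
  expect_gte(checked, 4L)
})

test_that("codon_index maps offsets to codon number and position", {
  expect_equal(codon_index(0), list(codon_number = 1L, codon_pos = 1L))
  expect_equal(codon_index(7), list(codon_number = 3L, codon_pos = 2L))
  expect_equal(codon_index(2), list(codon_number = 1L, codon_pos = 3L))
})

test_that("recode substitutes and translates single codons", {
  r <- recode("AGC", 1, "A-to-I")
  expect_equal(r$edited_codon, "GGC")
  expect_equal(c(r$ref_aa, r$edited_aa), c("S", "G"))
  expect_false(r$synonymous)

  r2 <- recode("AGC", 3, "C-to-U")
  expect_equal(r2$edited_codon, "AGT")
  expect_true(r2$synonymous)

  r3 <- recode("CGA", 1, "C-to-U")  # stop gain
  expect_equal(r3$edited_codon, "TGA")
  expect_equal(r3$edited_aa, "*")
  expect_false(r3$synonymous)

  expect_error(recode("AGC", 2, "A-to-I"), "incompatible")
})

test_that("recode agrees with the genetic-code oracle everywhere", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                  collapse = "")
  for (codon in codons) {
    for (p in 1:3) {
      for (cls in c("A-to-I", "C-to-U")) {
        want <- if (cls == "A-to-I") "A" else "C"
        sub <- if (cls == "A-to-I") "G" else "T"
        if (substr(codon, p, p) != want) {
          expect_error(recode(codon, p, cls))
          next
        }
        r <- recode(codon, p, cls)
        edited <- codon
        substr(edited, p, p) <- sub
        expect_equal(r$ref_aa, unname(Biostrings::GENETIC_CODE[[codon]]))
        expect_equal(r$edited_aa,
                     unname(Biostrings::GENETIC_CODE[[edited]]))
        expect_equal(r$synonymous, r$ref_aa == r$edited_aa)
      }
    }
  }
})

test_that("site_recoding finds codons through spliced minus-strand CDS", {
  genes <- tiny_genes()
  # all-T genome: the minus-strand sense sequence reads all A
  g <- c(chr1 = strrep("T", 600))
  # genomic 556 is sense position 1 of the gminus CDS (rightmost base)
  sites <- data.frame(chrom = "chr1", pos = 556L, ref_base = "T",
                      alt_base = "C", canonical_class = "A-to-I",
                      cds_transcripts = "tminus")
  rec <- site_recoding(sites, genes, g)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$codon_number, 1L)
  expect_equal(rec$codon_pos, 1L)
  expect_equal(rec$ref_codon, "AAA")
  expect_equal(rec$edited_codon, "GAA")
  expect_equal(c(rec$ref_aa, rec$edited_aa), c("K", "E"))
  expect_false(rec$synonymous)

  # third-from-last sense base = genomic 503 -> codon 1 position 3
  sites2 <- data.frame(chrom = "chr1", pos = 554L, ref_base = "T",
                       alt_base = "C", canonical_class = "A-to-I",
                       cds_transcripts = "tminus")
  rec2 <- site_recoding(sites2, genes, g)
  expect_equal(rec2$codon_number, 1L)
  expect_equal(rec2$codon_pos, 3L)
})

test_that("recoding_summary counts classes and site-level nonsynonymy", {
  res <- data.frame(
    chrom = "chr1", pos = c(1L, 1L, 2L, 3L),
    canonical_class = "A-to-I",
    transcript_id = c("t1", "t2", "t1", "t1"),
    ref_aa = c("S", "S", "K", "M"), edited_aa = c("G", "S", "R", "M"),
    synonymous = c(FALSE, TRUE, FALSE, TRUE))
  s <- recoding_summary(res)
  # site 1 nonsyn in ANY transcript; site 3 synonymous
  expect_equal(s$nonsyn[["A-to-I"]]$nonsynonymous, 2)
  expect_equal(s$nonsyn[["A-to-I"]]$sites, 3)
  expect_equal(s$nonsyn[["A-to-I"]]$fraction, 2 / 3)
  expect_equal(sum(s$aa_matrix[["A-to-I"]]), 4)
  expect_equal(sum(s$aa_matrix[["C-to-U"]]), 0)
  expect_equal(unname(rowSums(s$aa_matrix[["A-to-I"]])[c("K", "M", "S")]),
               c(1, 1, 2))
})

test_that("nearest_site_distances computes per-chromosome gaps", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 110L, 400L))
  nn <- nearest_site_distances(sites)
  expect_equal(nn$distances, c(10, 10, 290))
  expect_equal(nn$n_below, 2)
  expect_equal(nn$fraction_below, 2 / 3)

  # sites alone on their chromosome have no neighbour
  lonely <- data.frame(chrom = c("chr1", "chr2"), pos = c(1L, 1L))
  expect_true(all(is.na(nearest_site_distances(lonely)$distances)))

  # symmetry-in-contribution: if i's nearest is j at d, j's distance <= d
  set.seed(5)
  rnd <- data.frame(chrom = sample(c("a", "b"), 40, replace = TRUE),
                    pos = sample.int(500L, 40))
  rnd <- rnd[!duplicated(rnd), ]
  d <- nearest_site_distances(rnd)$distances
  for (i in which(!is.na(d))) {
    j_pool <- which(rnd$chrom == rnd$chrom[i])
    j_pool <- j_pool[j_pool != i]
    j <- j_pool[which.min(abs(rnd$pos[j_pool] - rnd$pos[i]))]
    expect_lte(d[j], d[i])
  }
})

test_that("exon boundary distances and splice candidate filter", {
  tr <- list(exons = data.frame(start = c(100L, 300L),
                                end = c(200L, 400L)))
  expect_equal(exon_boundary_distance(100, tr), 0)
  expect_equal(exon_boundary_distance(110, tr), 10)
  expect_equal(exon_boundary_distance(390, tr), 10)
  expect_error(exon_boundary_distance(250, tr), "not exonic")

  expect_equal(sum(splice_candidate_filter(c(0, 4, 7), 5)), 2)
  expect_equal(sum(splice_candidate_filter(c(0, 4, 7), 10)), 3)
  expect_length(splice_candidate_filter(numeric(0), 5), 0)
})

test_that("site_exon_distances reports per-transcript rows with min flag", {
  genes <- tiny_genes()
  # second transcript on gplus with a different exon end
  genes$gplus$transcripts$tplus2 <- list(
    transcript_id = "tplus2",
    exons = data.frame(start = 101L, end = 130L),
    cds = empty_iv_test(), utr5 = empty_iv_test(),
    utr3 = empty_iv_test())
  sites <- data.frame(chrom = "chr1", pos = 120L, ref_base = "A",
                      alt_base = "G", canonical_class = "A-to-I",
                      exon_transcripts = "tplus,tplus2")
  d <- site_exon_distances(sites, genes)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$distance), c(10, 19))  # |120-130|=10, |120-101|=19
  expect_equal(d$distance[d$is_min], 10)
})
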