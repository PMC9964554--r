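---
title: "Methods: detection, classification and comparison of RNA editing sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, classification and comparison of RNA editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An RNA editing observation is a genomic position in one sample where the
RNA base composition disagrees with the matched genomic DNA. The package
works entirely from per-site base counts (a pileup TSV dialect with
columns `chrom pos sample source A C G T mean_qual`), not reads:
alignment, duplicate marking and base-quality recalibration are upstream
responsibilities. Counts are in forward-reference orientation because the
poly(A) RNA library is assumed unstranded.

At each position the DNA majority base defines the reference — not the
FASTA base, because detection is DNA-vs-RNA comparative; the FASTA is
only used for flanking sequence and codon lookup. Ties in the DNA counts
are broken deterministically in A < C < G < T order. Every RNA
non-reference base with count > 0 yields one observation carrying the
editing level `alt/coverage`. Positions absent from the DNA pileup or
with zero DNA coverage are skipped: no reference base can be defined
there, and they could never survive the DNA-coverage rule.

## The filter cascade and its parameters

Per-sample rules are applied in a fixed order and the first violated rule
is recorded, which makes filter attrition auditable:

| rule | default | meaning |
|---|---|---|
| `min_rna_cov` | 10 reads | RNA coverage at the site |
| `min_dna_cov` | 5 reads | DNA coverage at the site |
| `min_alt_reads` | 2 reads | support for the edited base |
| `max_dna_alt_reads` | 0 reads | reads supporting a DNA mutation |
| `min_rna_alt_freq` | 0.01 | minimum editing level |
| `min_dna_ref_freq` | 0.95 | DNA purity at the site |
| `exclude_multiallelic` | on | ≥ 2 distinct RNA alt bases supported |

All "at least"/"minimum" thresholds are inclusive (≥). The multiallelic
flag reuses `min_alt_reads` as its support threshold: a stray single
error read on a second base should not kill a genuine site, so only
positions where two distinct alternative bases each reach the support
threshold are excluded.

Observations at known SNP positions or inside known INDEL intervals
(VCF; an INDEL at POS with alleles REF/ALT spans
`POS .. POS + max(len) − 1`) are masked. Cohort rules then act on
*non-redundant sites* (unique chrom:pos): a site must be detected — i.e.
have passed all per-sample rules — in at least `min_samples = 3`
samples; sites with editing level exactly 1 in *every* detected sample
are dropped as likely unannotated homozygous variants; and only named
autosomes are kept. "Detected" has exactly this meaning everywhere
downstream, including the tSES/pSES/pDES callers; it is the only
definition under which the minimum-sample rule is well-posed.

The completely-edited exclusion is deliberately per-site while the level
summaries are per-observation: an observation with level 1 survives as
long as some other sample shows partial editing at the same site, so
"completely edited" observation counts and the all-ones site exclusion
coexist without contradiction.

Mean base quality is carried through but no quality threshold is applied
here; the read-level quality filters belong upstream of the pileup.

## Strand collapse and classification

With an unstranded library the edited strand must be inferred from gene
annotation: A>G in plus-strand genes and T>C in minus-strand genes are
A-to-I; C>T (+) and G>A (−) are C-to-U. Host genes are found by
intersecting the position with *gene-body* intervals (min exon start to
max exon end over transcripts) — per-gene, not per-transcript,
intersection, matching BEDtools-style usage. Sites with no host gene are
ambiguous (`*` strand). Sites hosted by genes on both strands are
classified ambiguous rather than duplicated, unless the raw change maps
to the same class on both strands (only possible for the non-canonical
"other" types); the ambiguous stratum is reported, never silently
resolved. Feature labels follow the precedence CDS > 5'UTR > 3'UTR >
exon_other > intron within and across hosting transcripts, and
intergenic otherwise, so the labels partition the sites.

## Recoding, flanks, distances

Codon localization counts coding bases 5′ of the site in transcript
orientation after removing non-coding sequence; minus-strand transcripts
count from the rightmost CDS base. `codon_number = offset ÷ 3 + 1`,
`codon_pos = offset mod 3 + 1` (1-based positions 1/2/3). The edited
codon substitutes A→G or C→T at that position — codons are sense-strand
oriented, so the substitution is class-typed, and a precondition failure
(the codon base not matching the class) is an error, not a silent skip.
Translation uses the standard genetic code; a site in the CDS of several
transcripts is recoded per transcript, and the site-level synonymous flag
used in summaries is "nonsynonymous if nonsynonymous in ANY transcript".
The trailing incomplete codon of a CDS flagged as length-incomplete is
skipped.

Flanking windows are the 2k+1 bases centered on the site (k = 10 by
default), reverse-complemented for minus-strand sites so matrices are in
edited-strand orientation; windows running off a chromosome are N-padded
rather than truncated to keep the frequency matrix rectangular, and
all-N columns contribute nothing. Nearest-neighbour and exon-boundary
distances are genomic-axis base distances; boundary distance 0 means the
site is the first or last exon base. The splice-candidate threshold is a
parameter (5 bp is used for tissue-specific analyses, 10 bp for
population-level ones).

## Comparative statistics

The editing matrix holds levels where detected and NA otherwise; rows
are ordered by (chrom, pos) so all outputs are deterministic.

* **Wilcoxon rank-sum**: exact enumeration of the U distribution when
  `n_x + n_y ≤ 12` and there are no ties (two-sided p = twice the
  smaller tail, capped at 1); otherwise the normal approximation with
  tie and continuity corrections. With 5 vs 5 samples the smallest exact
  two-sided p is `2/choose(10,5) = 0.0079`, so BH-adjusted significance
  at 0.05 is unreachable unless very few sites are tested. The callers
  surface raw and adjusted p per site precisely so this power constraint
  is visible; the acceptance report states the measured power rather
  than hiding it.
* **BH adjustment** is the step-up rule
  `adj_(i) = min_(j≥i) p_(j)·m/j`, capped at 1.
* **Spearman correlation** uses average ranks for ties and the
  t-approximation for p (exact permutation available for n ≤ 8); pairs
  with a missing level are dropped and n < 4 yields NA.
* **ANOVA** across tissues is one-way and fixed-effects on pooled
  detected levels, ignoring individual pairing (no pairing structure is
  assumed by the design); tissues contribute only with ≥ 2 detected
  values.
* **tSES / pSES**: detection-pattern callers (exclusive tissue with ≥ 3
  supporting samples; ≥ 3 samples in one population and zero in the
  other, per tissue). A pSES is by construction never tested as pDES in
  the same tissue, since pDES requires ≥ 3 detected samples in *both*
  populations.
* **Expression**: RPKM `count/(len/1e3 · lib/1e6)` and CPM on raw
  library sizes. TMM-style normalization factors are deliberately not
  implemented: the correlation analyses are rank-based and insensitive
  to a per-sample scale factor, and differential expression is out of
  scope.

## The synthetic world

The generator emulates the study design the analysis assumes: two
populations × four tissues × five individuals (40 RNA libraries), one
blood DNA library per individual shared by that individual's four
tissues. Defaults: 2 × 30 kb autosomes, 24 genes with one multi-exon
transcript each (CDS length divisible by 3, annotated UTRs), 100
germline SNPs (heterozygous dose 0.5 or homozygous-alt dose 1, planted
in both DNA and RNA so the DNA-purity rules — not only the VCF mask —
must remove them), 300 A-to-I + 200 C-to-U sites planted on the
strand-appropriate reference base inside gene bodies, ~30× DNA and ~50×
RNA negative-binomial depth, and 0.2% per-base error spread uniformly
over the three non-reference bases (the simplest model consistent with a
mean-quality summary). True editing levels are Beta(0.6, 0.6) truncated
below at `level_min` — U-shaped, giving the broad level distribution
with a substantial completely-edited tail that editome surveys report;
the truncation floor avoids planting sites that are undetectable by
construction. Design labels zero out levels outside the designated
tissue or population; population-differential sites carry a planted gap
of 0.3 between populations.

RNA alt counts at planted sites are `Binomial(depth, level(1−e) + e/3)`.
Only positions with at least one RNA mismatch are emitted — a
zero-mismatch position can never become a candidate, so this sparse
emission is semantically lossless — and DNA pileups cover every emitted
position of the individual's libraries.

Editing–expression coupling works through a shared per-sample Gaussian
latent factor per catalyzer gene (six protein-coding genes named after
the ADAR/APOBEC families). The observed Spearman correlation is
attenuated twice relative to the latent correlation: by the Gaussian
copula (Spearman = (6/π)·asin(r/2)) and by negative-binomial expression
noise (variance `log(1 + 1/size + 1/mu)` on the log scale against signal
variance 0.25). Both attenuations are inverted analytically when
choosing the latent correlation, so the generator lands the *observed*
rank correlation on the configured target without empirical tuning.

All randomness flows from a single seed through fixed per-stage
substreams (`seed`, `seed+1`, `seed+2`), making every artifact —
including on-disk TSVs — byte-reproducible. Gene placement is slot-based
(each gene draws its structure inside an equal share of the chromosome,
shrunk to fit), so any configuration whose slots leave ≥ 500 bp per gene
generates successfully for *every* seed; infeasible configurations fail
fast.

What the generator does **not** emulate: read-level artifacts
(misalignment around splice junctions and INDELs, strand bias, PCR
duplicates), expression-weighted RNA coverage (coverage is genome-wide
and expression-independent), hyper-editing read clusters, and any
chromosome-scale structure. A green recovery test therefore establishes
that the filter cascade and callers are implemented correctly under the
stated statistical model — not that they are robust to alignment
artifacts, which the real pipeline delegates to upstream tools.

## Design choices where the design was open

* **Pileups, not BAMs.** The package defines a documented TSV contract
  for `samtools mpileup`-derived counts instead of parsing BAM. This
  keeps the artifact desk-scale; read-level filters are documented as
  upstream responsibility.
* **Candidate definition.** The upstream tools' per-sample "candidate"
  counts before filtering depend on unstated definitions; the package
  defines candidates as positions with any RNA mismatch and makes all
  counting start from there.
* **Config files are JSON**, not YAML: the R ecosystem ships jsonlite
  everywhere and the config is flat; nothing in the contract needs YAML.
* **tSES selection.** Published tissue-exclusive counts are sometimes
  sub-selected for downstream analysis by unstated criteria; here the
  support threshold (`min_support`, default 3) is the only selection
  knob, exposed as a parameter rather than claimed as anyone's rule.
* **Boundary-distance test choice.** Mean exon-boundary distances are
  compared between classes with a rank-sum p-value; no claim is made
  that this matches any particular published test choice.
* **Host-gene biotype** reported for a multi-gene site is the first host
  gene's, with all host ids retained alongside.

## Limitations

* Headline editome counts from real data (tens of thousands of
  observations over a full genome) are not reproducible at desk scale;
  correctness is established by internal arithmetic, oracles, and
  synthetic recovery instead.
* The pDES caller at n = 5 vs 5 has essentially no power after BH
  adjustment across hundreds of sites (see above); this is a property of
  the design, faithfully reproduced.
* GO/KEGG enrichment, protein-interaction networks, TMM normalization
  and differential gene expression are out of scope.
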