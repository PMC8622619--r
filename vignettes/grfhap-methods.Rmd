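---
title: "Methods: single-gene haplotype diversity, markers and association in grfhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-gene haplotype diversity, markers and association in grfhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

grfhap analyses allelic diversity of a single gene region — the bread wheat
growth-regulating factor gene *TaGRF3-2A* (chromosome 2A, plus about 1 kb of
flanking sequence on either side) — across a panel of inbred accessions, and
connects that diversity to agronomic phenotypes. Wheat accessions are treated
as homozygous lines, so each accession contributes one gene-region sequence;
accessions with byte-identical sequences form a *haplotype*. The pipeline

1. aligns each accession sequence to a reference gene model and extracts
   variants with HGVS names (genomic `g.`, coding `c.`, protein `p.`),
2. measures the length of the (AG)~n~ microsatellite in the 5'UTR,
3. groups haplotypes by encoded protein isoform and designates alleles as
   `letter.rank` (letter = isoform by frequency, rank = haplotype frequency
   within the isoform group),
4. predicts the outcomes of three laboratory marker assays in silico
   (a deletion-spanning PCR, a CAPS digest, and fluorescent SSR sizing),
5. builds SNP-only neighbor-joining phylogenies with bootstrap support and
   outgroup rooting, and
6. tests marker–trait associations with per-year one-way F-tests, three-year
   least-squares means and Fisher's exact test for score traits.

Everything runs on synthetic data produced by the package's own generator, so
the full pipeline is exercised offline; real sequences (e.g. GenBank records
for the locus) can be substituted wherever a FASTA is accepted.

## The coordinate model

A `gene_model` stores one plus-strand genomic slice, its exon intervals, the
CDS span, a promoter window and optionally the SSR locus. HGVS coding
addresses follow the standard convention: CDS bases `1..L` along the spliced
coding strand; 5'UTR bases `c.-N` counting back from the A of ATG; 3'UTR
bases `c.*N` counting forward from the base after the stop; intronic bases
`c.N+M` / `c.N-M` from the nearer exon edge, midpoint ties assigned to the 5'
edge. Upstream and downstream flank positions continue the `c.-N` / `c.*N`
numbering linearly — the package does not distinguish "UTR" from "flank" in
`c.` space, which matches how promoter and terminator variants are named in
practice. Minus-strand genes are handled by operating on the reverse
complement internally; the synthetic property tests draw random models on
both strands.

All coordinates are 1-based inclusive. Insertions are represented by their
flanking base pair.

## Variant extraction and normalization

Accession sequences are aligned to the reference with global
Needleman–Wunsch (Biostrings), match +1, mismatch −2, and affine gap
penalties in the convention where a gap of length *L* costs
`gap_open + L * gap_extend` with open 6 and extend 1. These defaults recover
every planted variant on the replayed panel (regression-tested); they are
exposed as arguments for unusual inputs.

Aligned columns are classified and maximal runs of non-matching columns
become single events: one mismatch column is an SNV, a pure reference gap an
insertion, a pure query gap a deletion, and any longer mixed run a delins.
Events separated by at least one matching column are never merged — two
substitutions two bases apart therefore stay separate DNA variants, while at
the protein level consecutive altered residues collapse into one `delins`,
exactly the presentation used for the locus's exon-3 double substitution.

Indels are normalized by 3'-shifting on the coding strand: a deletion slides
toward the 3' end while the base after the deleted block equals its first
base; an insertion rotates similarly. Shifting is performed on the
contiguous genomic axis of the coding strand (not the spliced transcript);
for this locus the two conventions agree because no catalog indel touches an
exon boundary. The VCF writer emits the complementary convention —
left-aligned, left-anchored records — because that is what VCF consumers
expect; the HGVS name rides along in the ID column.

The microsatellite window is masked during variant calling and measured
separately: the longest run of the repeat unit in the window, with two runs
merged (and flagged `interrupted`) when their separation is shorter than one
full unit. This reproduces the "single A loss" tract forms whose total
lengths are 55 and 61 nt. The measurer reports both the full-unit count and
the tract length in nucleotides so either convention can be compared against
electropherogram figures.

## Isoforms, lettering and allele designation

Haplotype proteins are obtained by applying the CDS subset of each variant
set to the spliced reference CDS and translating. Frameshifted or
internally-stopped CDSs are excluded with a warning (none occur in the
catalog). Isoform groups are lettered `A, B, C, ...` by total accession
count; within a group haplotypes are ranked `1, 2, ...` the same way, giving
allele names like `b.1`. Frequencies count accessions, not haplotypes. Ties
are not addressed by the naming convention itself, so the package breaks
them deterministically: first by the earliest-sorting member accession name,
then by fewer variants (and lexicographically by protein sequence when two
isoform groups tie). This makes designation invariant to input order and
reproducible across runs.

## In-silico markers

*PCR.* Primer sites are exact matches by default; a `max_mismatch` knob
tolerates internal mismatches but always requires an exact 3'-terminal
5-mer, since 3' mismatches abolish extension. Both template strands are
searched and all qualifying placements within `max_product` are reported —
the locus's markers are subgenome-specific by design, so a unique product is
the expected outcome, but the caller decides uniqueness. Product length
counts both primer footprints.

*CAPS.* A restriction enzyme is a recognition sequence plus staggered cut
offsets downstream of the recognition 3' end — SfaN I is `GCATC(5/9)`. Every
site on either strand yields one double-strand cut. Reported fragment
lengths follow the top-strand cut positions by default (`convention =
"top"`); for a 5/9 stagger the bottom-strand convention shifts the boundary
by 4 nt, and both are available because gel sizes are printed as single
numbers per fragment without stating the convention. Cut positions falling
outside the amplicon are ignored with a warning (a truncated site is not
cleaved), and fragment lengths always sum to the amplicon length.

*SSR.* Product sizes are assigned to disjoint per-locus bins (2A: 230–282
bp, 2D: 211–223 bp). Capillary sizing error (±1 nt) and the fluorescent
label are not modeled; the bins absorb them.

## Phylogeny

Haplotype trees use the SNP-only site matrix: substitution columns over the
gene + flanks, with any position overlapped by a deletion in any included
haplotype eliminated, insertions contributing no column, and the
microsatellite excluded. This implements the "positions containing gaps
eliminated" rule, and has the consequence — verified by a test — that a
haplotype differing from another only by an indel sits at distance zero, so
the deletion haplotype groups with the reference haplotype.

Distances are p-distances (optionally Jukes–Cantor corrected; the correction
is undefined at p ≥ 0.75 and errors naming the offending pair). Trees are
built by canonical neighbor joining via ape, which is exact on additive
distances; the package does not re-implement the maximum-likelihood
HKY/JTT inference of desktop phylogenetics suites — NJ over p/JC distances
is the in-package method, and qualitative group memberships are the level at
which its trees should be read. Bootstrap support resamples matrix columns
with replacement (seeded), rebuilds the NJ tree per replicate and maps
bipartition frequencies onto the full-data tree. Rooting places the root on
an outgroup's pendant edge, mirroring the use of homoeologous subgenome
sequences as outgroups.

Protein trees reuse the same machinery on a taxa × residue character matrix
projected against the reference protein, with `-` filling deleted positions
and counting as an ordinary (21st) state, so polyglutamine-tract length
variation contributes to protein distances.

## Association statistics

The genotype–phenotype panel is a pair of long tables: one value per
accession × year × trait, and one allele class per accession × marker.

* `anova_per_year()` is the one-way between-genotype F-test within a year,
  with group means and normal-theory 95% confidence intervals (per-group
  t-quantiles). "F-test" here means the ANOVA F between allele classes; the
  two-way variant is available through `lsmeans_two_way()`.
* `lsmeans_two_way()` fits the additive `value ~ allele + year` model by
  least squares and reports genotype LS means averaged over year levels with
  equal weight (via emmeans). Balanced data reduce to arithmetic means;
  inestimable levels under rank-deficient designs are flagged rather than
  guessed.
* `fisher_exact_2x2()` is the exact two-sided hypergeometric test. For score
  traits (e.g. lodging scored 1–9), `score_trait_fisher()` builds the 2×2
  table as carrier status × score dichotomized at the median — the table
  construction is the package's choice, stated here because score-trait
  testing is usually reported without one; an r×c exact test is out of
  scope.
* Raw p-values are reported per trait/year, matching field-trial
  presentation; a Benjamini–Hochberg column is available but off by default.
  Missing phenotype or genotype cells are dropped listwise per trait.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, chosen once:

* **Geometry.** A 4-exon plus-strand gene on chr2A with a 1035-nt CDS
  (345 codons), introns of 320/410/500 nt after CDS positions 100/325/689,
  a 490-nt 5'UTR and 330-nt 3'UTR, stored with 1075 nt of sequence before
  the start codon and 1389 nt after the stop. The slice offset is chosen so
  CDS position 495 falls at chr2A:687050412 and all printed promoter/flank
  variant coordinates land inside the slice. The real locus's intron and
  UTR lengths are *not* reproduced — the surrogate honors every printed
  coordinate constraint, nothing more. Splice-site dinucleotides are
  cosmetic; splicing follows the annotated exon intervals.
* **Sequence content.** Random background under the seed; fixed codons
  create the polyglutamine tract (7 consecutive Gln from residue 38), the
  CAPS-site context at codons 164–166 (so c.495G>T creates the single SfaN I
  site), the exon-3 double-substitution context and codon 243. The published
  primer sequences are planted so the deletion marker yields 344/335-bp
  products, the CAPS amplicon is 454 bp with the top-strand cut 201 nt from
  its 5' end, and the SSR product is `208 + 2n` bp. A cleanup pass removes
  any background-generated SfaN I site from the CAPS amplicon without
  introducing stops.
* **Catalog.** `grf_allele_catalog()` replays the printed variant sets as
  twelve named alleles with fixed SSR repeat counts (11–37 units, two
  interrupted tracts of 55 and 61 nt) and frequencies summing to 1. The
  c.495T carrier frequency defaults to 0.39, the printed population anchor;
  the two singleton-in-the-study groups are set to 0.02 (the multi-variant
  wild-relative-like allele) and 0.01 (the deletion allele) so the letter
  assignment reproduces the published C/D lettering — the study observed
  each exactly once, which leaves their relative order to the package.
* **Allocation.** Panel counts come from largest-remainder rounding of the
  frequencies rather than multinomial sampling, so counts are deterministic
  and every allele whose expected count reaches one is present regardless of
  the seed (at the default 199
  accessions the carrier count is exactly 77, i.e. 38.7%). The accession →
  allele assignment order is shuffled under the seed.
* **Phenotypes.** For each of three years, trait value = baseline + year
  effect + allele effect (for carriers of the `b` isoform) + Gaussian noise;
  the lodging score is `1 + Binomial(8, p)` with a carrier-shifted p.
  Defaults: heading −2 days (noise sd 2), test weight +10 g/L (sd 15),
  1000-kernel weight +2 g (sd 3), protein +0.3% (sd 0.8), yield −0.2 t/ha
  (sd 0.8) — effect directions and rough magnitudes as reported for the
  carrier allele, noise levels typical of replicated yield-trial means. At
  n ≈ 200 the planted heading effect gives essentially unit power for the
  per-year F-test, and under zero effects its type-I error is verified to
  sit inside binomial bounds of the nominal level.

What the generator does **not** emulate: sequencing reads and their errors
(inputs are assembled sequences), heterozygosity, recombination or pedigree
structure, genotype × year interaction beyond the additive model, trait
correlations, and the real locus's intron/UTR lengths or background
sequence. A green test suite therefore shows the *operations* are correct on
inputs with the printed structure — not that the biological conclusions
transfer to any particular real panel.

## Numerical and design choices

* Alignment scoring convention (gap of length L costs `open + L*extend`) is
  stated above and mirrored by the test suite's independent
  dynamic-programming oracle.
* Exact-match PCR by default; tie-breaking in NJ follows ape's
  implementation; isoform/rank ties as described under designation.
* Fisher's exact and the ANOVA/LS-means fits call the standard R
  implementations (`fisher.test`, `aov`/`lm` + emmeans); the test suite
  checks them against hand-computed sums of squares and full hypergeometric
  enumeration rather than re-deriving them in package code.
* Degenerate inputs error loudly and early: positions outside the slice,
  overlapping variants in one allele, frameshifts at protein naming, SNP
  matrices with no polymorphic column, JC69 at p ≥ 0.75, ANOVA with fewer
  than two groups of two.

## Problem sizes in the test suite

The suite replays the full 199-accession catalog panel once (twelve distinct
haplotypes, each aligned over the 4.7-kb slice), runs 1000 random
plant-and-recall variants over 25 random gene models, recovers 100 random
5–8-taxon additive trees, enumerates all 2×2 tables with total ≤ 40 against
the exact-test oracle, and estimates the null rejection rate of the per-year
F-test from 500 seeded replicates at n = 200. These sizes were chosen to
give tight statistical checks while keeping a full run in the minutes range
on one CPU.

## Limitations

Single transcript per gene; no ambiguity codes inside the CDS; no
heterozygous calls; protein-matrix projection does not support insertions
relative to the reference protein; NJ trees are a distance-based substitute
for likelihood inference and should be read at the level of group
membership, not branch-length detail near the root.
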