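---
title: "Mapping single-strand DNA breaks at nucleotide resolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-strand DNA breaks at nucleotide resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakome)
```

## The measurement model

A single-strand DNA break (SSB) is represented here as a free 3'-OH terminus
on one strand. The tagging chemistry appends an untemplated polyA tail to
every 3'-OH end with terminal deoxynucleotidyl transferase (TdT); chromatin
is first fragmented with micrococcal nuclease (MNase), whose 3'-phosphate
ends are not TdT substrates, so fragment boundaries stay invisible and only
pre-existing 3'-OH breaks are tagged. Two sequencing chemistries read the
tags:

* **Paired-end (ILM)**: read 1 begins with 10 G's (a priming anchor), read 2
  begins with 12 T's (the oligo-dT primer annealed to the tail) followed by
  the reverse complement of the broken strand ending at, and including, the
  3'-OH terminal base.
* **Single-molecule (SMS)**: single reads primed on the tail; the
  fill-and-lock step consumes the first template base after the tail
  without reading it, so the read starts one base 5' of the break.

All coordinates are BED-convention 0-based half-open throughout, converted
at the SAM boundary. The calling rules follow directly from the chemistry:

| chemistry | alignment | SSB interval | SSB strand |
|---|---|---|---|
| ILM | read 2 `+` at `[s,e)` | `[s, s+1)` | `-` |
| ILM | read 2 `-` at `[s,e)` | `[e-1, e)` | `+` |
| SMS | `+` at `[s,e)` | `[s-1, s)` | `-` |
| SMS | `-` at `[s,e)` | `[e, e+1)` | `+` |

The SMS rule includes the one-base 5' extension that compensates for the
unsequenced fill-and-lock base; extensions that would leave the chromosome
drop the call (clamping would create spurious terminal hotspots).

```{r worked-example}
aln <- data.frame(read_id = "x", chrom = "chr17",
                  start = 7677036L, end = 7677064L, strand = "+")
call_ssb_sms(aln)$calls[, c("chrom", "start", "strand")]
```

## Filters and their order

1. **Read structure/quality** (`filter_ilm_pairs`, `filter_sms_reads`).
   ILM pairs need >= 10 leading G's on read 1, >= 12 leading T's on read 2,
   and every base of both untrimmed reads at Phred > 20 (strict). Read 1 is
   trimmed by exactly 10 bases — base 11 can be a genomic G, and the anchor
   base in the primer guarantees it is non-G only on clean data, so fixed
   trimming avoids eating genomic G's. Read 2 is trimmed of its *maximal*
   leading T-run: sequencing errors can lengthen or shorten the run, and on
   clean data the 13th base is templated and non-T, making maximal-run and
   fixed-12 trimming coincide. SMS reads are kept at length >= 25.
2. **Unique alignment** (`load_alignments`). "Uniquely mapped" is
   operationalised for BAM input as primary + non-supplementary + MAPQ >= 20
   (the threshold is a parameter, not a derived quantity); pairs must
   additionally be face-to-face on one chromosome within 1000 bp (fragments
   are 150-500 bp, so 1000 leaves headroom). The packaged exact-match
   aligner is a test fixture for error-free simulated reads, not a
   production aligner.
3. **Internal-priming filter** (`internal_priming_filter`). Oligo-dT can
   prime on genomic A-runs, mimicking a tail. For each source alignment the
   20-base 5'-upstream window *on the alignment strand* is examined; the
   call is removed iff its T fraction is strictly > 40%. Windows truncated
   at contig ends use the available bases with the same fractional
   threshold by default (dropping such calls is flag-selectable); the
   affected genome fraction is negligible and using the bases avoids a
   positional bias against contig ends.
4. **Untailed-control subtraction** (`subtract_control`), base- and
   strand-exact: a matching window is not defined anywhere, so exact
   matching is the conservative default.
5. **Repeat masking** (`mask_repeats`), strand-blind, half-open.

The order — priming, control, repeats — mirrors the protocol's processing
sequence. Control subtraction and repeat masking provably commute (both are
key-wise removals), which the suite verifies.

All analyses run on unique (chrom, base, strand) coordinates with read
counts preserved; hotspot analysis (positions with >= 4 reads) is the one
place read multiplicity itself is the signal.

## The statistics suite

**Element enrichment** uses the exact two-sided binomial test: with `k` of
`n` breaks in an element of intersected length $L_e$ on background $L_{bg}$,
the null hit probability is $p_0 = L_e/L_{bg}$ and

$$\mathrm{OR} = \frac{k/(n-k)}{L_e/(L_{bg}-L_e)},$$

with a Clopper-Pearson 95% CI on $k/n$ transformed to the OR scale. Because
breaks are repeat-masked upstream, the natural background is the genome
minus repeats; the background is an explicit argument so either convention
is available.

**Strand asymmetry**: a break in a region of a `+` gene is *template* iff
its strand is `-` (the template strand is complementary to the mRNA-like
strand), and mirrored. Regions covered by genes annotated on both strands
are excluded by default — their template assignment is ambiguous; counting
them once per gene strand is a flag.

**Variant overlap** extends breaks by ±0/2/5/10 bp; the expected hit
probability under uniform variant density $\rho$ is $1-(1-\rho)^{2w+1}$.
Allele-frequency classes use 1000 Genomes conventions (common >= 0.05,
low-frequency >= 0.005, rare below) since no thresholds are otherwise
stated.

**Signal tracks** (replication timing, nucleosome occupancy, conservation)
are piecewise-constant interval tracks. The replication ratio is the mean
track value at break positions divided by the length-weighted background
mean — our operationalisation of "enrichment (>1) or depletion (<1)
relative to the whole-genome background", which is stated only verbally.
Distributional comparisons use the two-sided Wilcoxon rank-sum test against
a seeded uniform background sample. Conservation profiles average positive
scores over positions with score > 0 and |negative| scores over positions
with score < 0 within ±5/10/20 bp windows (same-sign-only averaging; the
zeros-included alternative was considered and rejected because flat zero
stretches would dilute both means, but it remains a one-line change).

**Site profiles** report the fraction of all sample breaks at each
site-relative offset and strand, with minus-strand site occurrences
coordinate-flipped. The normalized score is
$\mathrm{breaks\ at\ position} \times 10^9 / \mathrm{total\ breaks}$, which
sums to exactly $10^9$ over the genome — the suite asserts this identity
exactly, not approximately.

**Detection sensitivity and complexity** subsample read-level calls without
replacement at a seeded grid of depths. For a site carrying $c$ of $N$
reads, detection at depth $d$ has the hypergeometric closed form
$1-\binom{N-c}{d}/\binom{N}{d}$; the unique-coordinate count under uniform
recurrence has the matching occupancy closed form. Both are used as
oracles in the tests.

**Gene selection and gene sets**: promoters are assigned to the gene whose
annotated 5' end lies within 5 kb (nearest wins, ties broken by gene
order, deterministically); genes with >= 3 distinct break positions in
assigned promoters (or exons) are selected; over-representation uses the
one-sided hypergeometric test with Benjamini-Hochberg adjustment across
sets. The universe in promoter mode is the promoter-assigned gene set.

## Sample-level profiling

The breakome matrix holds break densities per (gene, strand):
$\mathrm{count} / (\mathrm{gene\ kb} \times \mathrm{total\ breaks}) \times
10^6$ — breaks per kb per million sample breaks. The normalisation makes
rows invariant under uniform depth changes; only the formula's *shape* is
stated in prose anywhere, so the per-kb-per-million scaling is this
package's choice and is documented as such. PCA centres features and does
not scale by default (densities share one unit); scaling is a flag.

The eight sample features for the age models are the enrichment odds ratios
for exons, introns, promoters, insulators and enhancers; the ±20 bp mean
positive and mean |negative| conservation scores; and the chrM break
fraction. The classifier is a maximum-likelihood logistic fit (young/old
thresholds are parameters, defaulting to <= 30 / >= 58 years) reporting
training-set accuracy at probability 0.5, ROC/AUC and McFadden's
pseudo-$R^2 = 1 - \ln L_{model}/\ln L_{null}$; an optional k-fold mode
evaluates accuracy and AUC out of fold, which is the mode the permutation
null is validated in (in-sample AUC of a multi-feature fit is biased above
0.5 even for pure noise). The regressor is ordinary least squares with the
fitted-versus-chronological Pearson r and the overall F-test p.

## The simulator and what it does (not) emulate

`make_genome` builds i.i.d. genomes at a target GC (default 0.41, the
human genome-wide value) with planted motifs, polyA runs (flanked by C so
T-run trimming is unambiguous), AT-biased repeat intervals and element
annotations; everything is seeded and byte-reproducible. `simulate_breaks`
places breaks i.i.d. over eligible positions, optionally with per-element
relative rates; recurrent coordinates model recurrent breaks and become
read counts downstream.

Default eligibility encodes three simulator design choices:

* **Non-A terminal base.** When the break's terminal base is A, the
  anchored oligo-dT shifts the first genomic base past the terminal A-run,
  producing a systematic shift of up to the run length that the chemistry
  cannot distinguish. The default avoids such positions; a flag enables
  them as a documented known-bias case.
* **Priming-safe context.** Positions whose tail-side 20-base window would
  itself exceed the 40% T-fraction threshold are excluded by default: a
  break planted there is *correctly* removed by the priming filter, so
  including such positions (about 5-10% of a 41%-GC genome) would make
  exact-recovery truth accounting impossible rather than more realistic.
  The flag exists to study exactly that loss.
* **Repeat avoidance**, matching the downstream masking.

Fragments are drawn uniformly from 150-500 bp; ILM read length defaults to
50, SMS lengths to uniform 25-60 (the platform's length distribution above
the >= 25 filter is not documented anywhere we know of; 25-60 is a
stand-in, not a measured value). Qualities are flat Phred 30 with an
optional one-base Phred-20 corruption channel to exercise the strict
quality rule; substitution errors are i.i.d. per base. Artifact reads prime
at planted polyA runs so that their upstream window T-fraction is >= 0.45,
comfortably above the threshold. Untailed controls suppress break-derived
reads only.

The simulator intentionally omits PCR duplicates, indels, MNase sequence
preference, crosslinking effects and base-composition-dependent error —
passing its recovery tests demonstrates the correctness of the coordinate
arithmetic, filters and accounting, not robustness to the biochemical noise
of real libraries (where published site-level exactness is ~43-51% at the
exact base and ~87-95% within ±1 nt).

## Problem sizes and numerical choices

The test suite validates end-to-end recovery on a 1 Mb genome with 1,000
planted breaks and a 200-artifact untailed control; enrichment calibration
and power on 100 seeds of 10,000 breaks over 1 Mb; and every
overlap/window/threshold operation against brute-force oracles on
hundreds of random instances. These sizes were chosen to make sampling
error small relative to the assertion bands while keeping the whole suite
in a few minutes on one core. Exact identities (normalized-score
conservation, worked-example coordinates, small-sample binomial,
hypergeometric and rank-sum p-values) are asserted exactly, not within
tolerances.

Two statistical subtleties are worth recording. First, i.i.d. placement
with per-element rates must sample positions *with* replacement: weighted
sampling without replacement depletes the high-rate element at large n and
biases the recovered odds ratio downward by several percent. Second, a 95%
CI covers its true value ~95% of the time per seed, so "CI contains the
planted OR" across 100 seeds is assessed against the exact binomial
rejection point for nominal 95% coverage (>= 90/100) together with a tight
unbiasedness band on the mean OR, rather than demanding above-nominal
coverage per run.

## Known limitations

* Breaks whose 3' termini are not TdT substrates (3'-P, protein-adducted)
  are invisible to the chemistry and out of scope for the simulator beyond
  the untailed-fragment bookkeeping.
* The exact-match fixture aligner requires error-free reads; real data
  should be aligned externally and ingested as SAM/BAM.
* The gene-set machinery implements the generic hypergeometric test only;
  curated term databases are deliberately not bundled.
* `strand_asymmetry` excludes both-strand gene regions rather than
  apportioning them; in gene-dense genomes this discards signal.
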