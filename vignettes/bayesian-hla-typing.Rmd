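---
title: "Noise-tolerant Bayesian HLA typing: model and methods"
author: "BayesHLA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-tolerant Bayesian HLA typing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

HLA genes are the most polymorphic loci in the human genome; two alleles
often differ by a single substitution. Clinical typing needs the pair of
alleles of a sample, and sequence-based typing concentrates on exon 2 and
exon 3 (class I) or exon 2 (class II), the regions encoding the
peptide-binding groove. Long circular-consensus (CCS) amplicon reads can
span exon 2, intron 2 and exon 3 in one molecule, which removes the
phasing ambiguity that short-read platforms face — at the price of a
residual ~2% error rate and, under barcode multiplexing, of *noise
reads*: reads assigned to the wrong sample by barcode-calling errors.

BayesHLA implements a Bayesian genotype caller for this setting, plus the
full supporting pipeline: allele-database construction, a CCS read
simulator, alignment/trimming/filtering, and an experiment harness.

## The genotype model

Let $r_1,\dots,r_n$ be the reads assigned to a sample at one locus and
$(a_i, a_j)$ a candidate allele pair. By Bayes' theorem the posterior of
the pair is proportional to $p(a_i,a_j)\,p(r_1,\dots,r_n \mid a_i,a_j)$;
with a flat prior it suffices to compare likelihoods (a per-allele
population prior can be supplied, adding
$\log p(a_i) + \log p(a_j) + \log 2\,[i \neq j]$).

Reads are conditionally independent given the pair, and each read is
produced by exactly one allele of the pair, so

$$\log p(r_1,\dots,r_n \mid a_i,a_j)
  = \sum_{k=1}^n \max\{\log p(r_k \mid a_i),\ \log p(r_k \mid a_j)\}.$$

With sequencing error rate $\delta$ and an alignment of $r_k$ to $a_i$
with $M$ matches and $X$ mismatches,

$$\log p(r_k \mid a_i) = M \log(1-\delta) + X \log(\delta/3),$$

the unique form under which the probabilities of all $4^{L}$ possible
length-$L$ reads sum to one (an erroneous base is one of the three
alternatives uniformly; at $\delta = 3/4$ all outcomes are equally
likely). This is the `counts` mode of `TypingParams()`. The default
`score` mode uses the local-alignment score itself as per-read support:
scores capture indels, which the match/mismatch form ignores, and only
the ranking of pairs matters for the argmax. The caller maximizing this
sum over all unordered pairs (homozygous pairs $i=j$ included) is
`bayesTyping0()`.

### Trimmed likelihood for noise reads

Noise reads pull the argmax towards alleles that fit *both* the sample's
reads and the contaminants. `bayesTyping1()` assumes a fraction $m$ of
the input reads are noise: per candidate pair, indicator variables
$\rho_k \in \{0,1\}$ ($\rho_k = 1$ marks read $k$ as noise) are chosen to
maximize the retained sum subject to $\sum_k \rho_k = \lfloor mn
\rfloor$. The maximizing choice is simply to drop the $\lfloor mn
\rfloor$ reads with the lowest support under that pair — a trimmed
likelihood. At $m=0$ the caller is exactly `bayesTyping0()`; at $m=1$
every pair's trimmed sum is empty and all pairs tie. The default
$m = 0.2$ assumes 20% of input reads are misassigned.

We read the noise term as *exclusion* (a flagged read contributes
nothing) rather than as a background likelihood; the two readings agree
at the $m=0$ and $m=1$ limits, and the exclusion form is isolated in one
internal function should the alternative ever be wanted.

`floor` is used for $m \cdot n$; ties in the pair objective are detected
at a relative tolerance of $10^{-9}$ (supports are sums of
integer-valued alignment scores, so true ties are exact).

### Zygosity and ambiguity

After a pair $(a_p, a_q)$ wins, each retained read is assigned to the
member with the higher support (ties credit 0.5 to each). If the
minority count falls strictly below half the majority count
(`homozygousRatio = 0.5`), the sample is called homozygous for the
majority allele. *All* retained reads are counted, including those the
trimmed caller flagged as noise: in score mode the flagged reads are
essentially the shortest reads, real molecules at low true noise, and
excluding them measurably skews the allele balance of heterozygous
samples (we observed exactly this failure mode on synthetic panels
before settling the rule). The flags are still reported per read.

Homozygous truth creates systematic ties: if no read supports $b$ over
$a$, the pairs $(a,a)$ and $(a,b)$ attain the same objective. All
co-optimal pairs are therefore collapsed through the zygosity rule and
the call is *ambiguous* only when more than one distinct final genotype
remains — the natural reading of "more than one answer". In accuracy
tables an ambiguous call containing the truth is tallied separately and
counts as an error.

`maxTwo()` is the baseline: count, per allele, the reads whose maximum
alignment score is attained at that allele (ties credit every attaining
allele), call the two top-count alleles (ties broken by name), then
apply the same zygosity rule.

## Allele database construction

Most HLA alleles have only a coding sequence in the public database, so
per-locus genomic *target* sequences are reconstructed:

1. `parseCdsAlignment()` reads the nuc-alignment dialect: the first row
   is the reference allele spelled out; `-` means identity with the
   reference base, `*` unsequenced, `.` an alignment gap; `|` marks exon
   boundaries. Identity dashes are expanded at parse time.
2. `locateExons()` places the reference CDS exons on the reference
   genomic sequence by exact spliced-substring search (the reference CDS
   is by construction a spliced substring of its own genomic, so exact
   placement suffices; zero or multiple placements are errors).
3. `buildGenomicSeq()` replaces the reference exons with each allele's
   exon sequences. Unsequenced (`*`) positions are filled from a donor:
   the reference base at that column when the reference is sequenced
   there, otherwise the first row in file order with a base. The donor
   identity is a free choice — the convention is only that the filling
   comes from *another sequenced allele* — and is deliberately
   deterministic. Gap (`.`) columns contribute no base.
4. `extractTarget()` trims the typing window. Window starts are
   interpreted 1-based inclusive (the convention of published locus
   tables, e.g. start 380 / length 1100 for HLA-A on
   A\*01:01:01:01); a `oneBasedStart = FALSE` switch is provided since
   the convention is not universal. The window is applied on each
   allele's own reconstructed genomic coordinates; alleles with exonic
   indels therefore shift downstream window content by the indel length
   — immaterial for the deduplication-by-equality that follows, but
   worth knowing for very indel-rich loci.
5. `dedupeTargets()` keeps one representative per group of alleles with
   identical targets (the lexicographically smallest name, C-locale);
   typing accuracy is judged at this representative level, which is the
   entire point of the deduplication.

## Pre-processing pipeline

Reads are mapped to the reference genomic sequence, trimmed to their
exon-aligned columns, scored against every unique allele, and filtered:

* **Alignment.** A compiled Smith–Waterman/Gotoh aligner with affine
  gaps; match +90, mismatch −100, gap open 100, gap extension 20 (low
  gap penalties because CCS errors are indel-rich). A gap of length $L$
  costs $100 + 20L$. Traceback ties prefer diagonal, then a gap in the
  subject, then a gap in the query, making results fully deterministic.
  Both strands are tried; since a read meeting the mapping thresholds on
  the forward strand is in its biological orientation, the reverse
  strand is only computed when the forward strand fails them.
* **Two identity flavours.** *Column identity* (matches over all
  alignment columns, gaps included) is used by the reference-mapping
  filter (≥ 0.90, coverage ≥ 0.70): under the deliberately cheap gap
  costs an exact aligner will happily thread unrelated sequence through
  gap-riddled "meander" alignments whose matched bases look clean, and
  only a gap-inclusive denominator exposes them. *Base identity*
  (matches / (matches + mismatches), the LASTZ reporting convention) is
  used by the read filter (≥ 0.96): a 2%-error read loses about half its
  errors to indels, so its base identity concentrates near
  $1 - \delta/2$ and the filter passes good reads while still discarding
  reads whose best remaining allele disagrees at divergent sites.
* **Exon trimming.** Read columns whose reference column lies in an exon
  are kept, concatenated in read order (insertions relative to the
  reference carry no reference column and are dropped); results under
  50 bp are eliminated. The exon fragments are concatenated rather than
  scored separately — the coding sequence is itself a concatenation, and
  a single local alignment of the spliced read against the spliced CDS
  is the natural dual. Trimmed reads come out oriented to the reference
  forward strand, so panel scoring aligns that strand only.
* **Allele filter.** An allele is dropped when strictly fewer than 10%
  of reads attain their per-read maximum score at it (ties credit every
  attaining allele). Per-read maxima are taken from the full matrix and
  never recomputed: the filter is a pruning device and must not cascade.
* **Read filter.** A read is dropped when its best base identity over
  the remaining alleles is strictly below 96%. Because a noise read's
  own allele has usually just been pruned, this is where most noise
  reads die.

Both filters are idempotent, and on noise-free simulated samples at the
default error model ≥ 95% of reads survive the full pipeline.

## The read simulator

`simulateCcsReads()` emulates model-based CCS simulation: per read a
length from $\mathcal N(450, 170^2)$ bp and an accuracy from
$\mathcal N(0.98, 0.02^2)$, errors placed i.i.d. per template base at
rate $1 - \text{accuracy}$ and split substitution : insertion : deletion
= 50 : 25 : 25 (configurable; the published description delegates the
mix to the simulator's internals, and an even sub/indel split is a
reasonable stand-in for CCS consensus error). Length is clipped to
[`minLength` = 100, target length] and accuracy to [0.5, 1]. Truncation
is by *clipping*, not rejection, a deliberate choice: the stated means
are the model's calibration targets, and rejection at the upper accuracy
bound (1.0 sits one standard deviation above the mean) would drag the
realized mean accuracy to ~0.974. Clipping keeps the realized means at
~0.978 and ~451 bp, and the resulting point mass of perfect reads at
accuracy 1 is itself a realistic feature of consensus reads.

Genotypes are drawn from a two-digit allele-group frequency table
(zero-frequency groups receive a 0.1% pseudo-frequency before
renormalization); the representative within a group is uniform because
the census stops at two-digit resolution. Exactly
$\lfloor 0.3\,n \rfloor$ samples are homozygous by design; the second
allele of a heterozygous-designated sample is redrawn on a coincidental
match so the realized identical-pair fraction equals the design
fraction. Loci are independent (no linkage disequilibrium).

Noise is modelled downstream of its cause: per locus, a pool of all
samples' reads in the run is built and `nNoise` reads are drawn
uniformly without replacement into each sample. A drawn read originating
from the focal sample keeps its noise flag (truth labels retain origin);
a switch can exclude the focal sample from the draw. Reads are emitted
on the forward strand only — the alignment stage, not the simulator, is
strand-aware.

What the simulator does **not** emulate: platform-specific error
profiles or quality values (FASTQ qualities, if requested, would be
constant), chimeric molecules, barcode sequences themselves (only their
downstream effect, misassigned reads), or length/accuracy correlation.
Passing tests on these synthetics therefore demonstrate the inference
machinery under the stated error model, not performance on any
particular instrument's artefacts.

## Experiment harness

`runExperiment()` runs the full factorial — groups × iterations ×
samples × noise levels × methods — with genotypes drawn once per group
and reads regenerated per iteration; pre-processing is shared across
methods within a cell. All randomness flows from one master seed, so a
run is exactly reproducible. The standard designs keep the total number
of correct reads per locus at 960 (40 reads/allele × 12 samples, 20 ×
24, 10 × 48); assumed-noise sweeps ($m$) and pool-diversity sweeps are
parameterizations of the same harness (`poolSamples` restricts the noise
pool to the first $k$ samples of the group).

`zygosityContingency()` tabulates correct/wrong calls for homozygous and
heterozygous samples; `fisherExactTable()` reports the *sample* odds
ratio (correctHom/errorHom)/(correctHet/errorHet) — not the
conditional-MLE estimate — together with the two-sided exact p-value
from the hypergeometric sum (`stats::fisher.test`); a zero cell triggers
a flagged 0.5 Haldane correction (the reference analyses never hit one).

## Problem sizes and test design

The packaged tests and the acceptance script use desk-scale versions of
the study design, chosen as the package's own defaults: 8-allele
synthetic panels at ≥ 2% pairwise target divergence with 200 samples for
genotype-recovery checks; 10,000 reads for simulator calibration;
10,000 samples for the zygosity design fraction; exhaustive-enumeration
cross-checks on ≤ 6 alleles × ≤ 10 reads, where enumerating all noise
subsets is still cheap. Full-scale reproduction of the published tables
additionally needs the official allele database release and population
frequency table; the pipeline accepts those files as drop-ins
(`buildPanelFromFiles()`, a frequency TSV), but no download is required
for anything the package itself claims.

## Known limitations

* Correctness is defined at the unique-target representative level;
  alleles merged by the deduplication are not distinguished (by design).
* The target window is applied on each allele's own coordinates; exonic
  indels shift the downstream window boundary.
* The trimmed-likelihood noise model discounts a *fixed* number of
  reads; it has no notion of where noise comes from, and with zero true
  noise it can still flag (and report) real reads.
* Score mode couples per-read support to read length; long reads carry
  more weight in the argmax. This is intended (longer reads carry more
  information) but it is why the zygosity rule counts all retained
  reads.
* The aligner is exact (no heuristics), quadratic per (read, allele)
  pair; panels of thousands of alleles rely on the allele filter's
  pruning being applied after a full scoring pass, which is the main
  cost.
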