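---
title: "Heuristic somatic SNV calling in low-purity tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic somatic SNV calling in low-purity tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvpure)
```

## The problem

In solid tumors the sequenced DNA is a mixture of tumor and stromal cells.
When tumor purity $p$ is low, a heterozygous, copy-number-neutral somatic
mutation is expected at variant allele fraction (VAF)

$$\mathrm{VAF} \approx \frac{p}{2},$$

so at 20% purity a true mutation is supported by only ~10% of reads, a
regime where Poisson sampling of alleles defeats likelihood-based callers
tuned for the diploid 0/0.5/1 genotype grid. `snvpure` implements the
alternative that has proven effective in this regime: trigger candidate
variants on a deliberately small amount of evidence, make the
germline/somatic decision jointly from tumor and matched normal, and then
control the false-discovery rate with a battery of explicit,
individually-interpretable post-processing checks rather than a single
p-value. No p-value is ever computed; a call's reliability is communicated
entirely through its flag set and the derived confidence tier.

## The calling procedure

1. **Read filtering.** Reads failing a configurable boolean filter
   expression (mapping quality, alignment length, mismatch count,
   pairing/duplicate flags; see `parse_filter_spec()`) are excluded before
   pileup. Two presets match the platforms the heuristics were tuned on:
   SOLiD v4 (`align_len >= 35 or (second_in_pair and proper_pair)`, single
   mapping quality > 15, at most 2 mismatches, no duplicates) and Illumina
   paired-end (single mapping quality > 10, at most 3 mismatches, no
   duplicates).

2. **Stranded pileup with novel-start tracking.** For each position,
   per-allele forward/reverse read counts, base-quality sums, and the
   number of *novel starts*: distinct (strand, 5′-most aligned position)
   keys among the allele's reads, computed without mate information. Reads
   amplified from one PCR molecule share their 5′ start; duplicate pairs
   whose mates mis-map to a homologous locus escape coordinate-based
   duplicate marking but still collapse to one novel-start key, which is
   exactly the failure mode this statistic exists to catch.

3. **Minimum-evidence genotyping.** An allele is *supported* when both a
   banded count rule and a base-quality-fraction rule hold:

   | coverage $c$ | count requirement |
   |---|---|
   | $c \le 20$ | $\ge 3$ reads |
   | $20 < c \le 50$ | $\ge 4$ reads |
   | $c > 50$ | $\ge 5\%$ of reads, or $\ge 2.5\%$ if on both strands; always $\ge 3$ reads |

   and the allele's share of the position's summed Phred quality must be
   $\ge 10\%$ ($\ge 5\%$ when both strands carry it and $c > 50$). The two
   most common alleles are then examined: both supported ⇒ heterozygous,
   one ⇒ homozygous.

4. **Joint classification.** The normal and tumor genotypes are compared
   with a rule table that reduces to: the call is **somatic** exactly when
   the tumor introduces an allele absent from the normal genotype, with one
   exception — a variant-homozygous normal gaining the *reference* allele
   heterozygously is germline (and noted as possible LOH, as is
   heterozygous-to-homozygous allele loss).

5. **Post-processing flags.** Somatic calls are checked for thin normal
   coverage (COVN12, < 12 reads), presence of the variant in the filtered
   (MIN) and unfiltered-non-duplicate (MIUN) normal pileups, membership in
   a germline database from other patients (GERM), a mutant allele equal
   to the reference (MER), and Illumina-only strand bias (SBIAS). Germline
   calls get coverage and same-allele floors (COVN8/COVT8, SAN3/SAT3).
   Both kinds require ≥ 5 mutant reads (MR) and ≥ 4 novel starts (NNS).
   Calls with no flags are PASS (high confidence); somatic calls whose
   only flag is COVN12 are medium; everything else is low.

## Parameters that matter

All thresholds are exposed through `evidence_rules()` and
`annotation_thresholds()` and can be overridden in the `[thresholds]`
section of the INI run configuration. The defaults are the tuned operating
point: the 5-mutant-read / 4-novel-start PASS gate trades precision
against sensitivity (raising the read floor to 10 raises precision
substantially at a steep sensitivity cost), and the COVN12 floor is the
depth below which a missed germline variant in the normal becomes the
dominant error mode.

Two readings of the rules deserve note, since they were genuinely open:

* *Band edges are strict.* "Over 20×" and "above 50×" exclude 20 and 50,
  which the boundary tests pin down: 3 reads suffice at 20×, 4 are needed
  at 21× and still at 50×, and at 51× the fraction rules take over — where
  3 reads (5.9%) again suffice. The high band is therefore locally more
  permissive in count terms just above 50×; we keep the plain reading
  rather than smoothing it, and additionally enforce the global 3-read
  trigger as an absolute floor there (2.5% of 51× would otherwise admit 2
  reads).
* *The quality fraction is a real constraint at mid coverage.* With
  uniform base qualities the quality share approximates the read share,
  so a 4-read variant at 45× (~9%) fails the 10% quality rule even though
  it meets the count rule. This interaction is intended — low-quality
  mutant bases should not trigger — and the rule-sweep tests therefore
  fix quality shares explicitly when probing count minima.

Other numerical choices: bases called N or with Phred quality 0 contribute
neither evidence nor coverage; ties for "two most common alleles" break by
summed quality then alphabetically; when no allele is supported the
position is homozygous-reference if the reference was observed, else a
no-call; the novel-start key for a minus-strand read is its rightmost
aligned position (its 5′ end). SBIAS, which is named but nowhere defined
for the original implementation, is defined here as ≥ 5 variant reads all
on one strand while the opposite strand holds ≥ 5 reads of any allele —
the coverage condition makes one-sidedness informative rather than an
artifact of one-sided coverage — and is gated to Illumina because
one-strand-only true positives are common on SOLiD. MIN/MIUN trigger on a
single variant read in the respective normal pileup (the most conservative
reading of "found in pileup"). Germline calls are exported to the shared
database only when flag-free, and re-export is idempotent.

## The synthetic-data generator

`simulate_pair()` emulates the structure of a controlled tumor/normal
mixture experiment: a diploid, copy-neutral genome; germline heterozygous
(VAF 1/2) and homozygous (VAF 1) variants in both samples; heterozygous
somatic mutations at VAF $p/2$ in the tumor only; per-position Poisson
depth (default 65×); uniform substitution errors (default 0.2%); normal
base qualities (mean 32, sd 4); and PCR duplicates cloned from source
reads (default 5%), of which a fraction (default 10%) are *disguised* —
left unmarked with mates scattered across chromosomes. Reads are
single-locus-informative fragments: a 35 bp footprint whose only
informative base is the focal one, so novel-start behavior matches real
fragments while pileups stay proportional to depth rather than depth ×
read length.

What it does **not** model — and what passing benchmarks therefore cannot
show — includes coverage heterogeneity and capture bias, mapping error
concentrated in homologous regions, indels and copy-number change,
subclonality, and correlated (context-specific) sequencing error. Real
mixture experiments show sensitivities well below 100% even at full
purity for exactly these reasons; simulated sensitivities sit higher at
equal nominal purity, so the benchmark assertions are about *monotone
decay* of sensitivity with purity (and its recovery with depth), not about
reproducing printed decay values.

## Problem sizes used in the packaged analyses

The genotype-caller oracle check enumerates every allele partition of
coverage ≤ 12 under two strand layouts (~3,700 columns) against a
brute-force transliteration of the printed rules. The mixture benchmark
in the acceptance tests runs purities {1, 0.8, 0.6, 0.4, 0.2, 0.1} at 65×
with 200 planted somatic mutations per seed over 10 seeds; smaller
configurations of the same harness appear in the unit tests. These sizes
give binomial standard errors of ~1% on per-mixture sensitivity, which is
what the monotonicity tolerance (0.02) reflects.

## Limitations

The caller is SNV-only: deletions and reference skips contribute no
coverage, and multi-allelic (3+) genotypes are not modeled (a
heterozygous-to-heterozygous change introducing two novel alleles is
classified somatic on the better-supported allele, with the second
recorded). Purity is never estimated — the heuristics are *robust to* low
purity rather than purity-aware, and samples known to be high-purity can
be called more stringently by raising thresholds in the configuration.
The platform filter presets operate on precomputed per-read mismatch
counts; color-space handling for SOLiD data is out of scope.
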