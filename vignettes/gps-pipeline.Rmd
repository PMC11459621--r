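---
title: "Guide positioning sequencing: model, simulator and pipeline design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide positioning sequencing: model, simulator and pipeline design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsmeth)
```

## The GPS library model

Guide positioning sequencing (GPS) is a whole-genome bisulfite library
chemistry built around one enzymatic trick.  After sonication to 200–500 bp
fragments, T4 DNA polymerase chews back 36–150 nucleotides from each 3′
end and re-synthesises the excised stretch with 5-methyl-dCTP.  Every
cytosine in that re-synthesised "patch" is therefore methylated and
survives bisulfite treatment unconverted.  After conversion, PCR and 150 bp
paired-end sequencing:

* **Read1** starts at a fragment's 5′ end and carries ordinary bisulfite
  signal: unmethylated C reads as T, methylated C stays C.
* **Read2** starts at the opposite (patched) 3′ end, so its first 36–150 nt
  retain reference base composition.  This *protected prefix* (the
  "anchor") aligns like ordinary DNA, guides the placement of its
  bisulfite-degenerate mate, and doubles as substrate for variant calling
  — which is what makes single-library allele-specific methylation (ASM)
  analysis possible.

The analysis problem is that the patch length varies per molecule and per
end, so both reads contain a read-intrinsic *treatment boundary* that must
be estimated before any base is interpreted:

* **Read2**: since over 98 % of somatic methylation is CpG, a guanine not
  preceded by C on Read2's own strand (the dinucleotide `[A/T/G]G`) can
  only come from a protected, non-CpG cytosine on the opposite strand.
  `detect_r2_boundary()` scans 5′→3′ for the **last** such dinucleotide;
  the prefix up to and including that G is the anchor.  Anchors shorter
  than 35 nt are discarded as unalignable.  We include the boundary G in
  the anchor: it is provably protected, and one extra informative base
  helps short anchors (the protocol's wording, "from the 5′ end to this
  boundary", does not state inclusivity).
* **Read1**: scanning 3′→5′ along the alignment, the first genuine
  conversion (read T over reference C on plus-strand fragments, read A
  over reference G on minus) marks where patch contamination certainly
  ends.  `trim_paired()` keeps `[0, k)` up to that point; everything 3′ of
  the first conversion might be patch and would otherwise inflate
  methylation levels.  Two degenerate cases are resolved conservatively:
  a read with no conversion anywhere is wholly unusable (`r1_keep = 0`,
  fully patched), while a read whose alignment covers no reference
  cytosine carries no evidence of over-cutting and is kept whole.  By
  default any C context counts as conversion evidence; setting
  `strict_noncpg_trim = TRUE` restricts the scan to non-CpG cytosines,
  which trades a small risk of patch leakage against not trimming at
  methylated CpGs.

## Guided alignment

Anchors are placed by exact 20-mer seeding (k-mers from the anchor's
start, middle and end, both strands) followed by Smith–Waterman
verification; up to 20 placements of score ≥ `min_sw_score` are reported,
best first.  Externally produced anchor alignments can be substituted via
a SAM file.

Read1 is then aligned only inside the 1 kb window extending inward from
each anchor, with the protocol's scoring — +5 match, 0 mismatch, −6 per
gapped base — and an asymmetric bisulfite wildcard: on plus-strand windows
a read T over reference C scores as a match (`CT` mode); minus-strand
fragments are handled by aligning the reverse complement of Read1 under
`GA` mode.  The reverse pairings deliberately do not match, which is what
lets a converted read still prefer its true origin.  The highest-scoring
(anchor, Read1) combination wins; equal best scores across windows are
reported as ambiguous rather than guessed.

Two consequences of the published scoring deserve emphasis:

* With mismatches costing nothing, local alignments extend freely through
  disagreement, and even an unrelated 150-mer accrues roughly 5/16 chance
  matches per diagonal position (~230 points) somewhere in a 1 kb window.
  Specificity therefore comes from the exact-seeded anchor and from
  best-candidate selection, not from the score floor.  `min_sw_score`
  defaults to 100 (≈ 20 matched bases) per the published parameter set;
  users wanting the score itself to reject spurious placements should
  raise it towards ~475 (≈ 95 matched bases of a 150 bp read).
* All tie-breaks are deterministic: smallest reference offset, then
  smallest query offset, then fewest gaps, with the plus strand first.
  The whole pipeline is byte-reproducible under a fixed seed; no step
  consults wall-clock time or traversal order.

Gaps are linear (−6 per base); affine gaps are out of scope.

## Methylation, variants and ASM

Only trimmed Read1 spans enter the methylation pileup — the protected
Read2 prefix is *artificially* methylated by the patch and is excluded
structurally, not by a flag.  At each reference cytosine on the fragment
strand the level is `100 × C / (C + T)` (read G/A on minus strand), with
CpG/nonCpG context taken from the reference dinucleotide.  Records are
strand-resolved by default; `merge_strands = TRUE` collapses CpG dyads.
Sites with zero coverage are omitted.  Conversion efficiency is estimated
from the unmethylated λ spike-in as the percentage of converted cytosine
observations on control contigs.

Variant candidates come exclusively from protected prefix bases (never
from beyond the Read2 boundary), with artifact-level defaults of
`alt_count ≥ 2` and alt fraction ≥ 0.1, both configurable.  For each
candidate site, pairs are partitioned by the base their protected segment
shows; for every cytosine covered ≥ 5× in both allele groups the
group-wise methylation difference is computed, and a cytosine is flagged
ASM at a difference ≥ 70 percentage points — the protocol's fixed
thresholds, with no multiple-testing correction, mirrored deliberately.
One record is emitted per (site, cytosine) pair; aggregation across
nearby sites is left to the user.

## What the simulator emulates

`simulate_gps()` draws, per fragment: a haplotype and strand (uniform), a
length from a normal law (mean 330, sd 60) clipped to [200, 500] — the
protocol states the range and the 300–350 bp mode; clipping keeps the
printed bounds exact — and one patch length per 3′ end uniform on
[36, 150], the least-informative choice over the published admissible
range (the true excision-length law is not published; only the range is).
Conversion is per molecule: each cytosine of the sequenced strand draws
its methylation state from the per-site truth probability, then converts
with probability `conversion_rate` (0.995 by default, matching the >99 %
efficiency the protocol reports) if unmethylated, or
`meth_protection_failure` (0.005) if methylated; cytosines inside the
3′-end patch never convert.  Read2 is emitted as the reverse complement
of the converted strand's 3′ end — one logical PCR step, so conversion
appears as A at reference-G positions.  λ fragments are drawn with
probability 0.001 (0.1 % wt/wt spike), a configured duplicate fraction
(2 %) re-emits byte-identical pairs, substitution errors occur at 0.001
per base, and qualities are a constant Q37 so the Q35/70 % quality filter
passes by default.

CpG methylation probabilities come from a mixture model shared across the
two strands of each dyad: either Beta mixture (default 30 % Beta(1,8) low
/ 70 % Beta(8,1) high, the bimodal shape of somatic methylomes) or a
binary 0/1 model used for exact round-trip validation.  Non-CpG
methylation defaults to 0, consistent with the >98 % CpG statement that
justifies the boundary rule; a nonzero value stress-tests that rule's
failure mode.

Heterozygous SNVs are planted on a jittered grid (guaranteeing the ≥ 2 kb
spacing whenever the genome admits it) at A/T positions with an A↔T
substitution, so no CpG is created or destroyed and the variant is
invisible to bisulfite chemistry on either strand.  ASM loci link CpGs
within ±300 bp to the alleles at probability 1.0 (alt) versus 0.0 (ref);
the remaining sites are methylation-neutral controls.

The simulator does **not** model: indels in reads, adapter read-through,
position- or quality-dependent error profiles, amplification bias, 5hmC,
CpG-island structure or any non-i.i.d. genome composition, or
non-palindromic (CHH/CHG-resolved) methylation.  Passing tests therefore
demonstrate correctness of the *data processing* under the stated
chemistry, not robustness to every artifact of real libraries; in
particular, real repeat structure will produce multi-mapping anchors far
more often than an i.i.d. genome does.

## Validation choices and problem sizes

The paper's own performance figures are tied to a human-scale dataset and
are not reproducible at desk scale, so validation is property-based, at
these sizes (chosen to give tight statistics at interactive runtimes):

* Smith–Waterman against an independently coded brute-force DP oracle on
  500 random pairs (lengths ≤ 60, all three wildcard modes), exact score
  equality; the boundary rule against an exhaustive dinucleotide scan on
  1,000 random reads.
* Simulator bound checks on 10,000 fragments; the λ spike rate on 100,000
  fragments against a 3σ binomial band.
* An exact round-trip at 100 kb / 20,000 pairs with binary methylome,
  conversion 1 and error 0: every emitted level must be exactly 0 or 100
  and equal truth, ≥ 99 % of Read1s at their true coordinate, all pair
  distances ≤ 1 kb.
* A stochastic run (conversion 0.995, error 0.001, Beta methylome) checks
  per-site counts against the exact central 99 % binomial region of the
  *observation* probability `q = p(1 − failure) + (1 − p)(1 − conversion)`
  — the quantity the counts are actually distributed around — at ≥ 10×
  coverage.  For the conversion-efficiency estimate this run uses a 5 %
  λ spike: at the protocol's 0.1 % and desk-scale depth the control
  yields only a few hundred informative cytosines, far too few to pin a
  99.5 % efficiency; 5 % yields the ≥ 10,000 observations the binomial
  check needs.  The 0.1 % default itself is validated separately by the
  spike-rate check above.
* Variant/ASM recovery at 120 kb / 60,000 pairs with 50 planted
  heterozygous SNVs (10 of them ASM loci): recall, absence of calls
  outside planted sites, ≥ 9/10 ASM loci detected and zero false ASM at
  the neutral loci, all at the protocol thresholds (≥ 70 pp, ≥ 5×).
* Full-pipeline byte-determinism on a 50 kb / 5,000-pair demo run twice.

`scripts/acceptance.R` re-runs all of the above from scratch and writes
the measured quantities as JSON.

## Other numerical and interface choices

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based happens only at SAM emission.  TSV reports are 0-based.
* `N` bases never count as match, methylation observation, or allele.
* Duplicate removal keys on exact `(R1, R2)` sequence identity — the
  protocol's own duplicate step pastes raw sequence lines — and keeps the
  first occurrence in input order.
* Pair ids are matched positionally between mate files, with `/1`, `/2`
  or comment suffixes stripped.
* `trim_default_len` (100 nt, the original trimmer's nominal Read1
  length) is accepted for configuration compatibility but superseded by
  the alignment-based boundary scan, which adapts per read.  Relatedly,
  the original trimmer seeds a random tie-break from system time; this
  implementation is deterministic by design.
* Fragments shorter than the read length yield truncated reads (recorded
  in truth), not an error.
* The candidate-variant filters (`alt_count ≥ 2`, fraction ≥ 0.1) are
  artifact choices: the protocol's variant step prints no thresholds.

## Known limitations

Under realistic (incomplete) conversion a few percent of Read2
boundaries overrun the true patch: a conversion failure in the converted
tail creates a spurious `[A/T/G]G` dinucleotide, and the overrun segment
then shows reference-incompatible T-at-C or A-at-G bases.  In the variant
caller these surface as C>T / G>A *candidates* — the usual bisulfite
ambiguity, here confined to boundary overruns.  They carry no methylation
contrast between their "allele" groups, so they do not propagate to false
ASM calls, but candidate lists from real-chemistry runs should treat
conversion-type substitutions with caution (or filter them downstream).
Exact-chemistry simulations, where boundaries cannot overrun, are used to
validate that the caller itself produces no false positives.

Anchor seeding needs one exact 20-mer, so anchors with errors in all
three seed positions are lost (negligible at the simulated 0.1 % error
rate, more relevant on noisy real data — use the SAM import path with an
external aligner there).  The built-in aligner indexes the reference in
memory and is meant for desk-scale genomes, not a full human genome.
Methylation levels are simple count ratios with no smoothing or coverage
model, and ASM uses fixed thresholds rather than a statistical test,
faithfully to the source protocol.

## A minimal worked run

```{r demo, eval = FALSE}
cfg <- list(sim = list(genome_length = 50000, n_pairs = 5000, seed = 7),
            params = list())
res <- run_pipeline(cfg, out_dir = "gps_demo")
res$manifest$counters
head(res$methylation)
res$conversion_efficiency
```
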