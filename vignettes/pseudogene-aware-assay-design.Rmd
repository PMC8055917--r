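---
title: "Pseudogene-aware assay design: methods and design choices"
author: "psvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudogene-aware assay design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psvkit)
library(GenomicRanges)
```

# The problem

Some clinically important genes have a pseudogene copy of very high
sequence identity (on the order of 99% over a couple of kilobases, with a
handful of short indels).  Two failure modes follow for PCR-based
diagnostics:

* **Co-amplification.**  A primer pair that matches both copies amplifies
  a mixture of gene and pseudogene template.  Because the pseudogene often
  constitutively carries the very frameshift that is pathogenic in the
  gene, a co-amplified trace can mimic a heterozygous (or even homozygous)
  patient genotype.
* **Allele dropout.**  A frequent SNP under a primer binding site can
  abolish amplification of one allele, so a true heterozygote reads as a
  homozygote.

psvkit operationalizes the countermeasures: find the fixed differences
between the paralogs (paralog-specific variants, PSVs), anchor primer 3'
ends on them, keep primers away from frequent polymorphisms, verify the
design by in-silico PCR, and read a small panel of PSV sites from each
trace as a positive control that only the gene was amplified.  A final
module reproduces the descriptive statistics of a screening cohort.

# Paralog alignment and PSV discovery

`alignParalogs()` computes an optimal global (Needleman–Wunsch) alignment
with affine gap costs via `Biostrings::pairwiseAlignment`.  The default
scoring is blastn-like — match +2, mismatch −3, and a gap of length $L$
costs $5 + 2L$ — because identity figures for such paralog pairs are
conventionally quoted from BLAST alignments.  Scoring is fully
configurable through `alignmentScoring()`.  The test suite checks the
implementation against an independent Gotoh dynamic-programming oracle on
an exhaustive sample of short sequence pairs.

`identityStats()` tallies columns (identical, mismatch, gap) and counts
maximal runs of gap columns as single gap events, which is how "identity
2295/2320 with three gaps" style summaries are produced.

`enumeratePsvs()` converts difference columns into variants:

* one PSV per maximal run of same-type difference columns (adjacent
  mismatch columns merge into one substitution; adjacent gap columns in
  one row merge into one indel);
* indels are normalized to their **3'-most** equivalent position, the HGVS
  convention used for variant names such as `g.45069023del`.  Note that
  VCF normalization left-aligns instead; `annotatePsvFrequencies()`
  therefore trims anchored VCF alleles before comparing.
* `N` bases never count as identical, and a difference run consisting only
  of `N` columns is dropped; runs containing `N` are flagged `ambiguous`.

Coordinates are 1-based inclusive externally (the HGVS `g.` frame, via
`GRanges`); any 0-based arithmetic is internal.  `transcriptModel()` and
`mapCoordinates()`/`mapGenomic()` convert between cDNA (`c.`) and genomic
(`g.`) positions, with minus-strand transcripts counted in transcript
orientation.

# Population frequencies and Grantham distances

`loadFrequencyTable()` accepts VCF (`AF`, or `AC/AN` as fallback,
multi-allelic records split per alt allele) and a 4-column TSV dialect in
which percent-formatted values ("21.94%") are divided by 100.  The
dropout rule is **strictly greater than** the threshold: the default of
0.01 encodes the usual "avoid SNPs with population frequency > 1%"
guidance, so a variant at exactly 1% does not trigger a collision.

Missense severity annotation uses the Grantham (1974) physiochemical
distance, embedded as the published 20×20 matrix on its 0–215 scale
(e.g. Ser→Leu = 145, Gly→Asp = 94, Gly→Arg = 125).  The tests assert
symmetry and the published extremes.

# Primer design rules

`generatePrimerCandidates()` enumerates every substring of the search
window within the length constraints and applies three filters:

1. **Specificity**: at least one PSV within the last `window` bases of the
   3' end (default 3) — a mismatch in the 3'-terminal bases is what most
   effectively blocks extension on the pseudogene template;
2. **Dropout safety**: no population variant above the SNP threshold under
   the footprint;
3. **Thermodynamics**: GC fraction within 0.35–0.65 and nearest-neighbor
   Tm within 57–63 °C (target 60 °C).  These ranges are standard primer
   design practice rather than published values, and are configurable via
   `primerConstraints()`.

Melting temperatures use the unified nearest-neighbor parameter set
(SantaLucia 1998) with the entropic salt correction at 50 mM monovalent
cation and 500 nM primer; the Wallace rule ($2(A{+}T)+4(G{+}C)$) is
available as a cheap alternative.  The parameter set is strand-symmetric,
so a reverse primer's Tm is computed from its top-strand footprint.

Ranking is deterministic: smallest 3' offset to a PSV first, then
distance from the target Tm, then leftmost position — so the same input
always yields the same design.

`inSilicoPcr()` predicts products under a simple binding model: a primer
binds where it aligns with at most 2 total substitutions and **zero**
mismatches in its 3'-terminal 3 bases (no indels in the site); every
convergent pair of binding sites within 5 kb yields a product.  The model
deliberately over-calls binding (any 2-mismatch site "amplifies"), which
makes the pseudogene-exclusion check conservative.  The test suite
verifies the product set against an exhaustive scan on short templates.

`designAssay()` chains the steps — align, enumerate PSVs, generate
flanking candidates, and accept the first ranked pair that yields exactly
one product on the gene and none on the pseudogene — then adds an internal
sequencing primer (SNP-avoidance is mandatory for it, PSV-anchoring is
preferred but not required, since a sequencing primer only needs to read
through the target, not discriminate during amplification) and a
diagnostic panel.  Infeasibility is reported as a classed error whose
`stage` field names the exhausted stage, e.g.
`"no paralog-discriminating site"` for an identical gene/pseudogene pair.

# Diagnostic panels and trace classification

`selectPanel()` picks the `k = 3` in-amplicon PSV sites with the lowest
gene-internal polymorphism frequency (ties broken by position), excluding
the assay's target variant site.  Three sites is the recommended
redundancy: a single control site that happens to be polymorphic in the
gene can mislead.  Because no published cutoff separates "usable" from
"confusing" site frequencies — panels in practice retain sites around 2%
while rejecting sites around 25% — psvkit warns (default `maxFreqWarn =
0.05`) instead of excluding; the bound is configurable.  The
sort-and-take selection provably minimizes (max frequency, then sum);
tests confirm equality with an exhaustive k-subset search.

`classifyTrace()` interprets observed genotypes at the panel sites:

* any pseudogene allele at a site with gene-internal frequency 0 can only
  come from co-amplified pseudogene template → `co_amplification_suspected`;
* all sites showing only the gene allele → `gene_specific`;
* pseudogene-allele signal confined to sites that are genuinely
  polymorphic in the gene → `inconclusive`, because a real gene
  polymorphism is indistinguishable from contamination at such a site.

The middle ground is deliberately conservative: a heterozygous call at a
known polymorphic site is *not* accepted as proof of clean amplification,
which is exactly why low-frequency panel sites are preferred.

# Cohort statistics

`alleleFrequency()` implements the allele-count arithmetic
($2\,\mathrm{hom} + \mathrm{het}$ over $2n$ alleles, two decimal places);
`alleleSpectrum()` counts pathogenic alleles (2 per homozygote, 1 per
compound-het allele, 1 per single-het carrier) with integer percentages;
`cascadeSummary()` reports per-arm detection rates to one decimal place
(two below 1%).  Raw fractions are always retained next to the rounded
values.  When a `GenotypeCount` carries an externally printed allele count
or percentage that contradicts its own genotype counts, the functions
raise a `psvkitCountInconsistency` warning and report the computed value —
published tables do occasionally contain such internal inconsistencies,
and silently repairing them would hide exactly what a reviewer needs to
see.

`fragmentGenotype()` calls `hom_wt` / `het` / `hom_del` from capillary
peak lengths with a ±0.4 base tolerance (typical capillary sizing
precision; configurable).  With a 1-base deletion shift the two expected
peaks are 1 base apart, so the bins stay disjoint.

# The synthetic-data generator

`simulateParalogPair()` emulates the gene/pseudogene relationship the
package targets: by default 2320 bp with 22 substitutions and 3
single-base indels, i.e. roughly 99% identity with three gaps — the
geometry of a real high-homology pair.  Planted edits are separated by at
least `max(2 × maxIndel, 6)` bases and kept 25 bp from the ends so the
planted truth is alignment-unambiguous; this is a simulator constraint
chosen so that "recovered PSVs equal planted PSVs" is a well-defined
test, not a claim about real paralog evolution.  Real pairs additionally
contain clustered differences, repeats and homopolymer-mediated
ambiguity that the generator deliberately avoids, so passing recovery
tests demonstrate correctness of the machinery, not performance on every
real locus.

`simulateSnpTable()` plants SNPs with exactly the requested frequencies
(optionally at PSV sites, to reproduce the scenario of a control site
that is itself polymorphic); `simulateCohort()` draws genotypes under
Hardy–Weinberg equilibrium; `simulateFragmentPeaks()` adds Gaussian
sizing noise to the expected peak lengths.  Every generator takes an
explicit integer seed and routes all randomness through
`withr::with_seed`, so outputs are byte-for-byte reproducible and the
caller's RNG state is untouched.

# Problem sizes used by the test suite

The suite exercises: the alignment oracle on all-length-≤8 random pairs
(120 in the acceptance block); PSV recovery on 100 seeded pairs at the
default 2320-bp conditions; assay design specificity on 200 seeded
700-bp pairs with ten planted substitutions (design windows of ~120 bp
flanking a 100-bp target); panel selection versus brute force on up to 8
sites; Hardy–Weinberg recovery over 1000 seeded cohorts of 931
individuals at allele frequency 0.0896; and fragment-genotype recovery
over 1000 noisy draws at noise SD 0.1.  The 700-bp design fixtures keep
the per-design cost sub-second while preserving realistic primer-window
geometry.

# Known limitations

* Primer thermodynamics stop at Tm and GC: no hairpin/dimer free-energy
  screening beyond what the constraints imply, and no multiplex or probe
  design.
* The in-silico PCR binding model is substitution-only (no indels in a
  binding site) and treats all mismatch positions outside the 3' window
  as equivalent.
* Frequency annotation matches variants by normalized allele identity at
  a site; it does not attempt cross-assembly liftover, and population
  frequencies are user-supplied rather than fetched.
* `alleleSpectrum()` assumes each listed allele is pathogenic; it does not
  model phase or segregation.
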