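---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

relapsekit analyses matched pre- and post-treatment tumor cohorts — the
motivating setting is non-muscle-invasive bladder cancer treated with
intravesical BCG, profiled by whole-exome, copy-number and TCR-beta
repertoire sequencing — and ships a seeded synthetic-cohort generator so
that every stage of the pipeline is exercised without access to patient
sequencing data.  This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic world does and
does not establish.

## Mutation spectra and signatures

**Channels.** Every single-nucleotide variant is mapped to one of 96
channels: six pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C,
T>G) crossed with the 5' and 3' flanking bases.  Purine-reference records
are reverse-complemented first, so a mutation and its reverse complement
always share a channel.  Channel order is fixed once (class, then 5' base,
then 3' base, each alphabetical) and is the contract for every matrix in
the package.

**Extraction.** `extract_signatures()` factorises the samples-by-96 count
matrix with KL-divergence multiplicative-update NMF.  The original
analyses this package generalises used a Bayesian NMF; we substitute plain
KL-NMF with multi-restart rank selection because it is deterministic given
a seed, dependency-free, and the quantity that matters downstream —
recovery of the generating signatures — is unchanged.  For each candidate
rank `k` in `k_range` (default 1..4) we run `n_restarts` (default 30)
random initialisations and measure *stability*: components of every
restart are greedily cosine-matched to the best-loss restart and the
matched cosines averaged.

Restart stability alone turned out to be insufficient: on effectively
rank-1 data the surplus components of an overfit rank converge,
reproducibly, to near-duplicates of the dominant profile — they fit the
same fixed noise realisation in every restart, so stability stays above
0.99 for every `k`.  A rank is therefore *admissible* only if it is stable
(mean matched cosine >= `stability`, default 0.85) **and** its components
are mutually distinct (maximum pairwise cosine <= `distinctness`, default
0.9).  The selected rank is the largest admissible `k`; if none is
admissible, `k = 1` is returned with `stable = FALSE`.  The 0.9
distinctness bound sits far from both failure modes we observe (true
distinct signatures pair below ~0.3; duplicate components above ~0.95).

**Matching and refitting.** Extracted components are matched to the
packaged catalog by cosine similarity (ties broken by catalog order and
flagged, never silently).  Exposures against a fixed catalog subset are
refit per sample by Lawson–Hanson non-negative least squares and reported
both on the mutation-count scale and as relative contributions summing
to 1.

**The packaged catalog is synthetic.** A real COSMIC v2 catalog cannot be
redistributed with this package, so
`inst/extdata/signature_catalog_v2like_synthetic.csv` (equivalently
`synthetic_signature_catalog()`, pure arithmetic, no RNG) is a 30 x 96
stand-in.  Four signatures carry the field-standard peaks the pipeline's
defaults rely on: "1" (5-methylcytosine deamination: C>T at NpCpG), "2"
(APOBEC: C>T at tCw), "13" (APOBEC: C>G at tCw) and "22"
(aristolochic-acid-like: T>A peaking at the TTG>TAG motif).  The remaining
26 are smooth fillers.  Like real signatures, the four named vectors are
*class-concentrated* — all mass inside their substitution class(es).  This
is not cosmetic: with a uniform floor over all 96 channels the generator
property "an empirical 10,000-draw spectrum lies within L1 0.05 of the
generating vector" is unattainable for any sampler, because the expected
multinomial L1 distance alone exceeds 0.06.  Do not treat the stand-in's
numerical values as COSMIC estimates.

## APOBEC enrichment

For each sample, enrichment = (n_tcw_mut / n_c_mut) / (ctx_tcw / ctx_c),
where tCw means a mutated cytosine with 5' T and 3' A or T (pyrimidine
representation) and the counted mutations are C>T and C>G.  The original
method's background counts come from a +/-20 bp window around each
mutation; that window is not recoverable from a MAF-like table, so the
background context fractions are an explicit parameter.  The default is a
uniform-trinucleotide exome (`ctx_tcw/ctx_c = 0.125`), which is also the
synthetic generator's truth.  Significance is a one-sided Fisher's exact
test (enrichment direction) of mutated vs background context counts — the
fractions are converted to counts with a documented `background_n` of 1e6
— followed by Benjamini–Hochberg correction across samples.  A sample is
APOBEC-high iff enrichment > 2 *and* FDR < 0.05; both conditions are
required, so a large enrichment with weak evidence stays APOBEC-low.
Samples with no cytosine mutations are flagged and excluded from the FDR
rather than given a label.  Gene-level comparison between label groups
uses two-sided Fisher tests (no direction is privileged there) with BH
across genes.

## Chromosomal instability

Controls define, on a fixed genomic bin grid (`bin_size`, default 1 Mb), a
per-bin mean and SD (n-1 denominator; the controls are a sample) of log2
copy ratio; an SD floor of 1e-6 guards degenerate bins and floored bins
are counted in the output.  A tumor segment's Z-score V is the
length-weighted mean over its bins of (segment value − bin mean)/bin SD.
The CIN score is the sum over segments of V_k × L_k with L the segment
length in bp; the printed index "k = 0" in the source formula is read as
k = 1 (a 0th segment does not exist).  The literal formula is signed, so
amplifications and deletions cancel; `cin_score()` therefore offers
`as_printed` (the literal default for score reporting) and `absolute`
(|V_k| × L_k, a cancellation-free magnitude) and records the mode in its
output; the pipeline uses `absolute` for group comparisons.  Elevation is
score > mean(controls) + 3 × SD(controls), strictly.  How the original
plasma-control normalisation maps onto exome bins is unstated in the
source method; the fixed-bin scheme here is a declared reconstruction.

## Burden, MSI and neoantigens

TMB counts missense mutations divided by the targeted coding territory
(default 34 Mb).  MSI scores classify as stable (< 3), indeterminate (3 to
10, both boundaries inclusive — "from 3 to 10" read inclusively), or
unstable (> 10).  Neoantigen candidates pass when the predicted mutant
K_D is at most 500 nM and strictly below the wild-type K_D ("greater
binding affinity" decoded as lower dissociation constant); an optional
expression flag can be required.  The neoantigen percentage of a sample is
100 × (distinct nonsynonymous mutations with at least one passing
candidate) / (nonsynonymous mutations) — the source never defines the
denominator; the mutation-level rate is primary because it reads as an
antigenicity rate of the mutation catalog, and a per-candidate rate is
available via `all_candidates`.

## Clonality

Clonal clusters (from any clonal-deconvolution tool; one row per
cluster × sample with a cellular prevalence in [0,1]) are retained iff
they hold >= 2 variants, or contain a driver-gene variant, or attain the
per-sample maximum prevalence in more than one sample; prevalence ties
count every tied cluster as top (conservative retention).  Mutation
sharing across a patient's serial samples uses the identity (chrom, pos,
ref, alt) — gene annotation is excluded so annotation-version drift cannot
split identical variants — and classifies common (all samples), shared
(> 1, not all), private (exactly one).

## TCR repertoire

A clonotype is a unique CDR3 amino-acid sequence; V/J calls are ignored
for diversity and identical CDR3s are merged before frequencies are
formed.  Only productive, in-frame sequences enter any calculation.  The
Shannon diversity index is −Σ p_i ln p_i (natural log); read-weighted
frequencies are primary (p_i is the clonotype's read fraction), and a
clonotype-uniform weighting (SDI = ln n) is exposed because the source
formula's weighting is ambiguous.  CDR3 length distributions report the
modal length with ties resolved to the smallest length and flagged; the
source figure labels lengths "nt" but plots amino acids — lengths here are
amino acids.  Abundance classes on clonotype read frequency default to
rare (0,1e-4], small (1e-4,1e-3], medium (1e-3,1e-2], large (1e-2,1e-1],
hyperexpanded (1e-1,1]; the bins are declared configuration, not a
published standard.

## Statistics

`wilcoxon_signed_rank()` drops zero differences (Wilcoxon's original
procedure; n is reported after dropping), uses mid-ranks for ties, and
computes the exact two-sided p (2 × min tail, capped at 1) for n <= 25 by
a dynamic program over doubled ranks — algebraically identical to full
2^n enumeration, ties included, so no separate tied-data branch exists.
Above the cutoff a normal approximation with tie correction and
continuity correction is used.  `wilcoxon_rank_sum()` is exact for
tie-free samples with m + n <= 25 (null distribution via R's `pwilcox`)
and mid-rank normal otherwise.  `fisher_exact_2x2()` sums hypergeometric
tables with probability <= observed (two-sided) or the directional tail.
`kaplan_meier()` is the product-limit estimator with Greenwood variance
and log-scale confidence bounds (undefined once the curve reaches zero);
`log_rank()` is the two-group 1-df chi-square and is flagged undefined
when no events occur.  Pairing is never guessed: `compare_groups()`
requires an explicit `paired` declaration and matches by patient.

## The synthetic cohort

The generator's defaults state the cohort the pipeline targets, chosen
once: 24 patients of whom 11 relapse; 10 healthy copy-number controls;
per-sample SNV counts negative-binomial with mean 230 (≈ 6.8 per Mb of a
34 Mb territory) and dispersion 2; primary tumors drawing 70% of
mutations from the APOBEC C>T signature and 30% from the deamination
signature, relapses drawing 72.4% / 16.2% / 11.4% from the APOBEC C>G,
aristolochic-acid-like and deamination signatures; T>A mutations placed on
the untranscribed strand with probability 0.7 (others 0.5, 5% of records
unknown and excluded from strand tests); 30% of a relapsing patient's
primary mutations carried into the relapse; copy-number aberrations 4–5
segments (|log2 shift| ~ 0.5) in primaries vs 12 (~0.8) in relapses over a
4 × 50 Mb toy genome with per-bin Gaussian noise sd 0.1; neoantigen yield
0.30 (primary) vs 0.15 (relapse) per nonsynonymous mutation with passing
mutant K_D log-normal (meanlog log 120, sdlog 0.9) truncated at 500 nM;
TCR repertoires of 800 Zipf-distributed clones (exponent 1.0 primary, 1.3
relapse — steeper = more clonal), 5 000 reads, CDR3 lengths normal around
15 aa (primary) or 14 aa (relapse) with sd 1.5; survival exponential with
monthly hazard 0.025 (relapsers) vs 0.004, administratively censored at 60
months.  Group mixture weights are the only quantities taken from the
published per-group contribution figures; everything else derives from the
stated cohort structure or is a realism choice made once.

Contexts are realised by sampling a channel and emitting its literal
trinucleotide (half the records re-expressed in purine orientation to
exercise normalisation); no reference genome exists, so loci are random
and the generator cannot test locus-dependent behaviour.  Clone identity,
CNV–expression linkage and indel contexts are not modelled.  A green test
on this world establishes that the estimators recover the parameters of
the stated generative model at the stated sample sizes — not that the
defaults describe any real cohort.

One master seed fans out to fixed per-table child seeds
(`child_seed()`), so identical seeds give byte-identical output
directories while single tables can be regenerated in isolation.

## Known limitations

The NMF rank selector is tuned for desk-scale cohorts (a handful of
signatures, tens of samples), not de novo discovery across hundreds of
genomes.  The APOBEC background is a declared constant rather than a
per-mutation window.  The CIN binning reconstruction, the neoantigen
denominator and the SDI weighting are documented interpretations of
underspecified methods; each is parameterised so the alternative reading
is one argument away.
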