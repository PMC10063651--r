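---
title: "Models and methods behind offbase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind offbase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offbase)
library(dplyr)
```

`offbase` packages the computational arm of a base-editor off-target safety
study: the filtering cascade that turns raw multi-caller variant sets into
editor-attributable de novo SNVs, the signature statistics that demonstrate
deaminase activity, and a synthetic-data layer that makes all of it testable
against planted truth. This vignette explains the models, the parameters
that matter, and the choices made where the underlying procedure was open
to interpretation.

## The variant-identification cascade

The DNA cascade mirrors a matched-control transgenic design. Variants are
called per sample by three independent somatic callers; only calls reported
by all three are retained, because caller-specific artifacts are largely
disjoint while true variants are not. Consensus matching uses the exact
4-tuple (contig, pos, ref, alt) *after left-normalization*: indels are
shifted to their leftmost equivalent padded representation, so two callers
that place the same homopolymer deletion differently still agree on one
key. Annotations of a consensus record are taken from the first caller;
this is an arbitrary but fixed convention, and only that record's
DP/qual/QD/FS feed later filters.

Successive filters then subtract, in order: the WT reference sample's
consensus calls, exact key matches against a common-variant panel
(dbSNP-like), variants inside repeat/high-complexity mask intervals, and
keys present in two or more individuals of the same editor group. The
group-shared rule is read as "present in ≥ 2 individuals", the maximal
reading that best serves its purpose of removing residual germline
leakage. Finally, for trio offspring the parents' consensus calls are
subtracted, leaving de novo candidates. Whether the panel and region
filters run before or after consensus is immaterial — subtraction against
fixed sets commutes — and the package fixes consensus-first; the test
suite verifies the commutativity on random inputs.

The RNA cascade operates on single-caller call sets (RNA variant calling
is typically a single GATK-style pipeline, so there is no consensus step).
Records failing any hard threshold — depth below 20 reads, call quality
below 30, quality-by-depth below 2, Fisher-strand above 30 — are removed
first; the inequalities are strict on the removal side, so DP = 20,
qual = 30, QD = 2 and FS = 30 all survive. Then same-organ WT subtraction,
panel and region filters, and subtraction of the matched DNA call set
(when WGS of the same sample exists) remove genetic background. No minimum
alternate-allele count beyond DP is imposed, since none is defined for the
procedure being modelled.

Because the package operates at the call-set level, matched-normal
*calling* (the WT sample used as the normal control inside the caller) is
modelled as call-set subtraction. This is a semantic approximation: a
read-level somatic caller uses the normal's reads, not its calls. At the
simulation scales used here the two coincide, but results on real data
would differ near the caller's detection limits.

Every cascade emits an audit table (`stage`, `n_in`, `n_out` per sample).
Stage-wise counts are the primary read-out of this kind of study, so they
are first-class outputs, not log lines.

## The synthetic-data model

The generator produces exactly the statistical structure the analysis
assumes, and nothing more:

* **Reference**: i.i.d. bases at a target GC content (default 0.42,
  mammalian-like), multi-contig; a mask of non-overlapping 1-kb blocks
  covering a set fraction of each contig (default 5%) stands in for repeat
  regions; a panel of known common sites (ref allele matching the genome)
  stands in for dbSNP.
* **Trios**: at every panel site each parental allele is alternate with
  probability `het_rate` (an allele frequency, default 0.5); each offspring
  allele is drawn uniformly from the corresponding parent's two alleles.
  Mendelian consistency is therefore exact by construction and checked
  exhaustively in tests.
* **Planted events**: substitution types are drawn from a 12-type
  probability vector. Cytosine- and guanine-centered candidate sites whose
  pyrimidine-oriented trinucleotide context is WCW (W = A or T) are
  accepted with relative weight `context_weight` (G-centered sites are
  evaluated on the reverse complement, because one motif describes both
  C>T and G>A). Acceptance sampling gives a planted WCW fraction of
  `w·f / (w·f + 1 − f)` where `f` is the genomic WCW fraction among
  C/G-centered trinucleotides — a closed form the tests verify by Monte
  Carlo. Events avoid panel sites, masked regions, contig edges and each
  other. Indels (optional, probability `indel_prob`) are single-base
  insertions/deletions planted in homopolymer-free context so their
  left-normalized representation is unique and consensus matching is
  unambiguous.
* **Callers**: caller *c* reports each true call independently with
  probability `1 − fn_c` and adds Poisson(`fp_c ×` accessible bases) false
  calls at fresh positions. Depth is Poisson with mean 36 (a typical WGS
  coverage for this design); qual, QD and FS are uniform over ranges whose
  defaults lie entirely on the passing side of the RNA hard filters, with
  `filter_fail_rate` optionally pushing a chosen fraction of records over
  a randomly selected threshold for boundary testing. No quantitative
  error rates are published for the real callers in this setting; the
  defaults are free simulation parameters, not estimates of Mutect2,
  Lofreq or Strelka behaviour.
* **RNA SNVs**: per gene and tissue, counts are Poisson with mean
  `rate_coefficient × FPKM_g,t × editorFPKM_t` — the generative form of
  "more editor, more RNA off-targets; more expression, more RNA
  off-targets". Variants live in transcript space (contig = gene id,
  position uniform along a nominal 1-kb transcript): the downstream
  analyses need per-gene counts and variant identities, not genomic
  placement. Types are recorded in cDNA space (a C→U edit appears as
  C>T). Contexts are synthesized per variant with the same WCW acceptance
  rule, since there is no genomic neighbourhood to read them from.
* **Amplicon reads**: gapless copies of the amplicon; each target base
  converts independently at its per-position rate, then uniform sequencing
  errors are added per base.

What the generator does **not** emulate: read-level sequencing (alignment,
base qualities, strand artifacts), linked errors between callers, mutation
clustering, structural variants, allele-frequency spectra within samples,
and RNA variants whose sharing between samples reflects true hotspot
positions. Passing tests therefore demonstrate that the cascade and
statistics are correct *given* call sets with the assumed error structure —
they do not validate the external callers or aligner behaviour on real
sequencing data.

## Signature and association statistics

Spectra are reported strandless and uncollapsed over 12 substitution types
(C>T and G>A listed separately); pyrimidine collapsing happens only inside
motif analysis. The "adjacent 3-bp sequence" of an SNV is read as the
trinucleotide (−1, 0, +1) centered on the variant, taken from the
*reference* (the pre-edit base); a wider window is available via `flank`,
and the 3-mer is the default because that is the scale of the deaminase
preference being tested. PWM information content uses a uniform background
with no pseudocount, `IC_j = 2 + Σ_b f_jb log2 f_jb` bits (`0·log 0 := 0`),
and masked regions are excluded from the background trinucleotide tally of
the WCW enrichment test, which is a one-sided exact binomial test of the
observed WCW count against the genomic background fraction.

Coding consequences use toy CDS-only gene models (0-based half-open
intervals, strand-aware frame anchored at the CDS start) and the standard
nuclear code; overlapping genes report all consequences ordered
stop_gained > missense > synonymous. The reverse-strand path is tested
against the forward-strand result of the reverse-complemented construction.

The SNV-count-versus-expression association is an ordinary least-squares
fit computed from the closed-form normal equations — the quantity of
interest is the reported R², so OLS (not a rank correlation) is the right
estimator, and the closed form keeps the package's own statistic
independent of `lm()`, which the tests then use as a cross-check. The fit
accepts per-tissue or per-sample points; which was used is recorded by the
caller, since either aggregation is defensible. Expression deciles sort
genes by FPKM ascending with ties broken by gene id (stable), and any
remainder genes go one each to the *top* bins — the procedure is otherwise
underdetermined, and a fixed deterministic rule keeps runs reproducible.
Phenotype thresholds are control mean ± 3 SEM with strict inequalities, so
a weight exactly at a threshold is normal.

## Amplicon quantification

Reads are treated as gapless amplicon-length sequences; reads of the wrong
length, or with more mismatches than a ceiling (default 20% of the
amplicon length), are discarded and tallied rather than aligned. The real
study's pre-filtering was done by unpublished in-house scripts, so the
ceiling is an explicit package choice; indel-containing reads are handled
by the discard rule, a documented limitation relative to alignment-based
tools. Protospacer positions are numbered 1..20 from the PAM-distal end
(so "A6" is protospacer base 6), and efficiency at a position is
`100 × (converted-base reads) / (retained reads)`.

## Determinism and numerical conventions

Every stochastic function takes an explicit integer seed; the pipeline
derives per-module seeds from the single top-level seed by fixed offsets,
so module-level reruns reproduce in isolation and two runs of the same
config are byte-identical (the manifest stores the config hash and seed,
never timestamps). Variant coordinates are 1-based (VCF) everywhere except
region masks, which are 0-based half-open (BED); one internal conversion
function owns that boundary. TSV outputs round doubles to 6 decimals; VCF
numeric fields are written with `as.character()`, which round-trips
exactly through `as.numeric()`, making write–read–write cycles bit-stable.
Empty call sets, empty spectra (percentages flagged `NA`), zero-variance
predictors (fit flagged undefined) and empty shared-ratio rows (`NaN`) are
all explicit degenerate cases rather than errors.

## Problem sizes

The package's own checks run on 5-Mb genomes (five 1-Mb contigs, 5% mask,
5000 panel sites), trios with hundreds to thousands of germline variants,
200–2000 planted events, 100-seed sweeps for the association analyses and
10 000-read amplicon simulations — sizes chosen so that binomial and
multinomial 3σ bands are tight enough to detect real defects while a full
run of suite plus acceptance script stays in the minutes range on a single
CPU. The default `run_pipeline()` configuration uses a 1-Mb genome with
two groups (a CBE-like editor and a background control) of two trios each,
which reproduces the qualitative study read-outs — an elevated de novo
count in the editor group, C>T/G>A dominance, WCW enrichment, and
expression-scaled RNA SNV counts — in seconds.

## Known limitations

Call-set-level simulation cannot expose errors that live below the caller
interface (alignment artifacts, strand bias, duplicate handling). The
consensus rule assumes caller errors are independent, which flatters
consensus specificity relative to real callers sharing an aligner. The
RNA arm has no splicing, allele fraction or editing-site-recurrence model,
so shared-ratio matrices on simulated data understate the structure real
editor hotspots produce. Consequence annotation covers CDS substitutions
only — no splice sites, UTRs, or non-standard codes.
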