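---
title: "Detecting antiviral defence systems with defloc: models, thresholds and design choices"
author: "defloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antiviral defence systems with defloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defloc)
```

## The detection model

Prokaryotic antiviral defence systems are usually encoded as operons: a
small set of protein families that must co-occur within a short stretch of
the genome, occasionally joined by non-coding elements (CRISPR arrays,
retron msr-msd RNAs). `defloc` formalizes each system type as a
declarative *system-definition model*:

* **core families** — the components that define the system;
* **accessory families** — optional components that count toward the
  total quorum but are not required;
* **prohibited families** — components whose presence in the cluster
  rejects the classification (they diagnose a *different* system: for
  DISARM, *drmE* in an otherwise type I locus indicates type II);
* **quorum** — the minimum number of *distinct* core families
  (`minimum_core`) and distinct families overall (`minimum_total`);
* **maximum separation** — how many consecutive genes carrying none of
  the model's families may sit between two cluster members.

Detection is then two deterministic steps. First, genes are labelled with
protein families via profile-HMM homology, filtered on E-values and
alignment coverage. Second, for each model, maximal runs of labelled genes
are built under the separation limit and each run is tested for
prohibition, then quorum. Relaxed `"_other"` models with a quorum of two
run alongside the canonical definitions so that fragmented systems (contig
breaks, mobile-element insertions, gene-calling failures, divergent
homologs) still surface for manual review.

### Assumptions

The approach assumes (i) annotated gene boundaries are trustworthy enough
that gap counting in *genes* is meaningful; (ii) homology to a family
profile is evidence of that family's function; and (iii) synteny is
informative — defence genes scattered far apart are not called as one
system. Single-gene systems are supported (`minimum_core = 1`) but, as
with any homology-only call, carry less specificity than multi-gene
systems.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `evalue_max` | 1e-5 | E-value | ceiling on *both* the full-sequence and the best-domain independent E-value |
| `target_cov_min` | 0.4 | fraction | floor on aligned fraction of the target protein |
| `hmm_cov_min` | 0.4 | fraction | floor on aligned fraction of the HMM |
| `max_separation` | 4 | genes | global colocalization limit for models that set none |
| `ncrna_evalue` | 0.01 | E-value | inclusion threshold for covariance-model ncRNA hits |

Per-HMM thresholds in `hmm_meta.txt` override the global score defaults,
so a promiscuous profile can be held to a stricter standard without
touching code. All threshold comparisons are **inclusive** (`<=` ceiling,
`>=` floor) — a fixed convention so that runs are reproducible and
boundary hits behave identically everywhere. The E-value ceiling is
applied to both the full-sequence and the domain value, the stricter of
the plausible readings. Coverage is computed from the *alignment* bounds
of the best-scoring domain (not the envelope), i.e. aligned span divided
by full length.

The CRISPR array detector and the covariance-model search are external
tools whose outputs the package ingests; the parameter set the wrappers
pass through is recorded in `defaultNoncodingParams()`
(array quality cutoff 2.5, minimum 3 repeats, word length 11, repeat
length cutoff 11, maximum 250 nt between arrays; `cmsearch` with Z 10 and
FZ 500, inclusion E ≤ 0.01) so a run log always states the effective
configuration.

## Numerical and tie-breaking choices

* **Best hit per (gene, family):** lowest domain independent E-value,
  ties broken by bit score (descending), then accession (ascending).
  Within one model each gene contributes exactly **one** family — its
  best-scoring among the model's families — so duplicated copies of a
  family count once toward quorum (copy-number invariance) while still
  being reported as members.
* **Prohibition scope** is the run, not the genome: a prohibited gene
  elsewhere on the chromosome is irrelevant.
* **`_other` suppression:** an `_other` call is dropped only when its
  member set is a subset of an accepted canonical call of the same system
  family. Cross-family overlaps are always reported side by side; the
  package never silently resolves ambiguous classifications.
* **Multi-interval CDS** (GenBank `join(...)`) collapse to their outer
  span; features are ordered by start, ties by end then locus tag.
* **Coordinates** are 1-based inclusive (GFF3 convention) everywhere,
  and outputs echo input coordinates exactly.
* **Degenerate inputs:** an empty genome yields an empty hit list; a
  header-only hit table yields no hits; zero calls yield a header-only
  CSV. Circular contigs are treated as linear — a system spanning the
  origin is seen as two fragments (a documented limitation that the
  `_other` models partially compensate).

## Pseudogene rescue

Annotation pipelines flag frameshifted or truncated genes as pseudogenes
and omit their proteins, so a defence system containing one broken gene
fails its quorum. Each pseudogene, however, is annotated with the
accession of the full-length protein used to infer its product.
`substitutePseudogenes()` attaches that protein wherever a lookup resolves
the accession, leaving coordinates and gene order untouched; rescued
members are flagged `pseudo_sub_` in the per-gene CSV so users can judge
whether they are looking at a functional system or a decaying one. The
operation is idempotent and best-effort: unresolved pseudogenes simply
stay invisible to the HMM stage.

## What the synthetic data emulate — and what they do not

The fixture generator builds genomes from *plans*: operons of named
families, decoy genes, pseudogenized members, ncRNA hits and CRISPR
arrays, laid left-to-right with seeded random intergenic gaps (so planted
elements can never overlap; a contig too short for its plan is a
validation error). Planted proteins are 5% point-substituted copies of
fixed per-family seed proteins, so the toy HMMs (built with `hmmbuild`
from 10-sequence alignments of such copies) score them strongly but not
identically. Alongside the sequences, the generator fabricates per-domain
hit tables directly: strong hits with log-uniform E-values in
[1e-30, 1e-10] and coverages above 0.9 for planted genes, and weak decoy
hits (E in [1e-3, ~3], coverage below 0.35) that must fail the default
thresholds. This gives two test routes — real `hmmsearch` on the generated
proteins, and engine-free runs from the fabricated tables — that must
agree on every shipped plan.

The generator does **not** attempt realistic sequence composition:
nucleotide sequences are uniform random and unrelated to the protein
translations, intergenic spacing is uniform rather than drawn from real
operon statistics, and fabricated E-values are sampled rather than
computed from alignments. Passing tests therefore demonstrate that the
*decision logic* — filtering, synteny, quorum, prohibition, suppression,
serialization — is correct, not that the toy HMMs have the sensitivity or
specificity of a curated production database on real genomes.

## Problem sizes used by the test suite

The shipped checks run ten demo genomes of roughly 15–30 genes each, a
nine-model toy database with 19 HMM profiles, and property suites that
compare the engine against an independently written brute-force oracle on
200 random contigs of at most 30 features under a fixed seed. These sizes
were chosen to exercise every rule interaction (reclassification, quorum
failure, fragmentation across contigs, pseudogene rescue, non-coding
quorum contributions) while keeping the whole suite fast enough to run on
every change.

## Design decisions on open points

* Model files use a flat YAML schema (`core`, `accessory`, `prohibited`,
  `minimum_core`, `minimum_total`, `maximum_separation`) for
  interoperability with existing public model collections. When quorum
  keys are omitted, *all* core families are required — the strict reading
  in which any missing core gene rejects the system; when the separation
  key is omitted the global default (4 genes) applies.
* Relaxed models are recognized by the `_other` name suffix rather than a
  dedicated flag, matching the naming convention of the model databases
  this package interoperates with.
* Separation is counted in annotated genes rather than base pairs: gene
  counts are robust to intergenic length variation and match how operon
  neighbourhoods are described in the literature. Both the per-model
  value and the global default are configurable.
* Per-model score thresholds (beyond per-HMM ones) are not supported;
  scoring policy lives with the HMMs, classification policy with the
  models.
* For genome summaries, an `_other` call counts toward abundance under
  its system *family* (the suffix is a confidence marker, not a type),
  while canonical calls count under their model name.
* Gene calling on unannotated input is delegated to an external caller,
  run in single-genome mode above 100 kb of input and in
  anonymous/metagenomic mode below — short inputs cannot train reliable
  single-genome gene models.

## Known limitations

Beyond the toy-database caveats above: the GenBank reader covers the
common prokaryotic flat-file subset (CDS features, `join`/`complement`
locations, standard qualifiers), not the full format; overlap between an
ncRNA and a CDS keeps both as separate ordered features (no merging
heuristic); and no scoring-based ranking is attempted between alternative
system assignments for the same locus — overlapping calls are reported
for the user to resolve.
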