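# defloc — locating antiviral defence systems in prokaryotic genomes

Bacteria and archaea carry arsenals of antiviral defence systems —
restriction–modification, CRISPR-Cas, DISARM, Wadjet, retrons and many
others — typically encoded as compact clusters of co-localized genes,
sometimes together with non-coding elements such as CRISPR arrays or retron
msr-msd ncRNAs. `defloc` annotates these systems in genome assemblies. It
is aimed at microbial genomicists screening isolates, plasmids or
metagenomic contigs for defence loci, and at method developers who need a
fully scriptable, deterministic detection pipeline with synthetic test
data.

## The method

Detection proceeds in two stages.

**1. Gene labelling by profile-HMM homology.** Every protein (CDS, plus
pseudogenes whose inferred full-length product has been substituted back
in) is scored against a database of profile HMMs. A hit on target protein
*t* by profile *h* is retained iff

```
E_full(t,h) <= E_max   and   E_dom(t,h) <= E_max
cov_target(t,h) >= c_t and   cov_hmm(t,h) >= c_h
```

where `E_full` is the full-sequence E-value, `E_dom` the best domain's
independent E-value, and the coverages are the aligned fraction of the
target and of the HMM (defaults `E_max = 1e-5`, `c_t = c_h = 0.4`;
per-HMM thresholds in the database metadata override the defaults).
Retained hits label genes with the protein family each HMM evidences; per
(gene, family) only the best hit is kept.

**2. System calling against declarative models.** Each system definition
lists core families `C`, accessory families `A`, prohibited families `P`,
a quorum (`minimum_core`, `minimum_total`), and a colocalization limit
`maximum_separation` (intervening non-member genes). Candidate clusters
are maximal runs of genes labelled with any family in `C ∪ A ∪ P` in which
consecutive members are separated by at most `maximum_separation`
unlabelled genes. A run is rejected if any member carries a family in `P`
(prohibition), or if it contains fewer than `minimum_core` distinct core
families or `minimum_total` distinct families overall (quorum); otherwise
it is reported as a system call. Relaxed `"_other"` models (quorum of two
co-localized components) run alongside the canonical definitions to catch
fragmented, truncated or divergent systems; an `_other` call is suppressed
only when it is subsumed by a canonical call of the same system family.

CRISPR arrays (from a detector's GFF) and covariance-model ncRNA hits
(from `cmsearch` tabular output, inclusion threshold E ≤ 0.01) are spliced
into the gene order as non-protein components and satisfy the tokens
`CRISPR_array` and `ncRNA` in any model. Annotation-flagged pseudogenes
can be rescued by substituting the full-length protein the annotation
pipeline used to infer their product; members called this way are flagged
with a `pseudo_sub_` prefix in the output.

## Worked example

The package ships a deterministic fixture generator; no downloads are
needed. The example below builds the toy database, generates the
frameshifted-*jetC* Wadjet genome, and runs the pipeline with pseudogene
substitution:

```r
library(defloc)
db <- file.path(tempdir(), "db"); makeToyDb(db)
fx <- makeGenome(demoPlans(seed = 1)$wadjet_pseudo,
                 file.path(tempdir(), "demo"))
res <- runDefloc(gff = fx$gff, faa = fx$faa, data = db,
                 domtbl = fx$domtbl_substituted,
                 pseudo_proteins = fx$pseudo_proteins,
                 out_dir = file.path(tempdir(), "out"))
res$calls[[1]]
#> SystemCall #1 wadjet_I on g_wadjet2_ctg1 [4686-7667], 4 member(s): JetA, JetB, JetC, JetD
```

`defence_systems.csv` holds one member gene per row; the substituted
pseudogene is flagged:

```
"system.number","seqid","system","target.name","hmm.accession","hmm.name","protein.name","full.seq.E.value","domain.iE.value","target.coverage","hmm.coverage","start","end","strand","target.description"
1,"g_wadjet2_ctg1","wadjet_I","g_wadjet2_g0007","PLDC00009","JetA_seed","JetA","2.50e-14","1.00e-13","0.958","0.962",4686,5480,"+","JetA protein"
1,"g_wadjet2_ctg1","wadjet_I","g_wadjet2_g0008","PLDC00010","JetB_seed","JetB","2.70e-27","1.30e-26","0.979","0.973",5508,6074,"+","JetB protein"
1,"g_wadjet2_ctg1","wadjet_I","pseudo_sub_g_wadjet2_g0009","PLDC00011","JetC_seed","JetC","1.60e-18","2.80e-18","0.996","0.978",6111,6809,"+","JetC protein"
1,"g_wadjet2_ctg1","wadjet_I","g_wadjet2_g0010","PLDC00012","JetD_seed","JetD","1.90e-25","1.20e-24","0.996","0.971",6837,7667,"+","JetD protein"
```

Without `pseudo_proteins` (and using `fx$domtbl`), the broken *jetC*
leaves only a `wadjet_other` fragment — the E-values and coverages in the
CSV are the evidence to weigh in such borderline cases. The run also
writes `defence_systems.gff` (one parent row per system, one child per
member) and `genome_summary.tsv` with the genome's defence-system
*diversity* (number of distinct system types) and *abundance* (total
systems):

```
assembly_id  diversity  abundance  per_type
g_wadjet2    1          1          wadjet_I=1
```

A command-line front end is installed at
`system.file("scripts", "defloc.R", package = "defloc")` with `run`,
`fixtures` and `validate` subcommands mirroring `runDefloc()`,
`makeToyDb()`/`makeGenome()` and `crossValidateDb()`.

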