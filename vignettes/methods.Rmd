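---
title: "Scoring splicing-derived neoantigen burden: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring splicing-derived neoantigen burden: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetope)
```

# The problem

Tumors with dysregulated splicing express transcripts absent from normal
tissue. When such a transcript is translated, peptides spanning the
aberrant junction (or the frameshifted tail downstream of it) can be
presented on MHC class I and recognised by T cells. splicetope
quantifies this *splicing antigenicity*: starting from split-read
junction tables produced by a splicing-aware aligner and a table of
group-biased junctions produced by an upstream differential- or
outlier-splicing analysis, it estimates, per gene and per sample, how
much antigenic material the sample's aberrant splicing is expected to
produce.

The package deliberately consumes the outputs of established upstream
tools rather than reimplementing them: alignment, differential splicing
(intron-cluster methods), HLA genotyping, MHC-binding prediction and
stromal-contamination scoring (ESTIMATE) all enter through files or
plug-in contracts.

# Junction representation and classification

Junctions are intron intervals in 1-based, fully closed coordinates
(the STAR `SJ.out.tab` convention: `intron_start` is the first intronic
base, `intron_end` the last). The `.junc` writer converts to 0-based,
half-open BED-style coordinates; the reader converts back, so the two
representations round-trip exactly.

Canonical-motif filtering keeps STAR motif codes 1–6 (GT/AG and its
variants on either strand); code 0 is dropped. The read floor defaults
to 3 uniquely mapped reads, matching the conventional minimum evidence
for clustering a junction. Junctions with undefined strand are retained
by the parser but cannot be classified or engineered; the command-line
converter drops them with a logged count.

Classification compares each junction's two splice sites with the
annotated splice sites of the reference, in *transcriptional*
orientation (on the minus strand the donor is the genomic-right edge of
the intron):

* both sites annotated and used together as consecutive exon boundaries
  of one transcript — `annotated`;
* both annotated, never co-spliced — `novel_annotated`;
* donor known only — `cryptic_threeprime` (the 3' site is novel);
* acceptor known only — `cryptic_fiveprime`;
* neither — `cryptic_unanchored`.

Site matching is exact (0 nt slack): any tolerance would make labels
depend on an arbitrary window and break the determinism of the truth
tables used in testing. Junction clusters — the unit of
"alternative event" used by cross-group filtering — are connected
components of intron-interval overlap on the same chromosome and
strand; a shared-splice-site rule is available as
`cluster_junctions(mode = "shared-site")` for users who prefer the
intron-cluster definition of their upstream tool. Clusters whose summed
unique reads fall below 3 are dropped as a unit.

# Transcript engineering

For a junction, the upstream flank is the last transcribed base before
the intron and the downstream flank the first base after it. A
transcript is a flank candidate when an exon *contains* that base; if
the base falls inside one of the transcript's introns the transcript
simply is not a candidate (an acceptor deep inside an intron therefore
yields an empty pair list with a logged reason, not an arbitrary
nearest-exon guess).

All upstream x downstream combinations are formed and then pruned.
Annotated junctions keep only pairs where both flanks come from the
same transcript and the flanking exons are directly consecutive in it —
"matching annotation names" is interpreted at the transcript level,
which is the stricter of the two possible readings (gene level would
admit cross-isoform chimeras for junctions that are, per annotation,
internal to one isoform). Unannotated junctions keep the full cross
product unless some pair is same-transcript-adjacent, in which case
only those pairs survive. A configurable cap (`max_pairs`) guards
against combinatorial blow-up on promiscuous loci; truncation is
recorded.

Fusion concatenates the upstream spliced sequence up to the donor with
the downstream spliced sequence from the acceptor onward, so joining an
annotated junction of a transcript to itself reproduces that transcript
byte for byte — the self-reconstruction identity that anchors the test
suite. The product is flagged protein-coding if and only if both flanks
carry annotated UTRs; only coding products are ORF-scanned.

ORF finding takes the first ATG scanning from position 1 (the fused
sequence of a coding product begins with the upstream 5'UTR, so this
subsumes starting the scan at the UTR and also handles fusions whose
UTR boundary has shifted) and extends in that frame to the first stop
codon. Sequences whose first ATG reaches no in-frame stop have no ORF:
the ORF is defined as a start-to-stop region, and a read-through with
no stop has no such region. Only ATG initiates (no non-canonical
starts). Codons containing N translate to X, and kmers containing X are
excluded from antigen scoring rather than guessed.

# Coding potential

Coding status of the modified transcripts is scored with an
ORF-length/GC-content (LGC) model. The probability of observing an ORF
of $n$ sense codons when each codon independently terminates with
probability $f$ is geometric,

$$P = (1-f)^{\,n-1} f,$$

and $f$ is modelled as a cubic in the GC fraction $P_{GC}$ of the
transcript,

$$f = a_0 + a_1 P_{GC} + a_2 P_{GC}^2 + a_3 P_{GC}^3,$$

with separate coefficient sets trained on coding and noncoding
sequence. The differential coding potential is
$L = \log_2(P_c / P_{nc})$; genes whose scored transcripts have mean
$L > 0$ are retained. Scoring applies to fused transcripts of at least
100 nt (measured on the fused nucleotide sequence), $n$ counts the
sense codons of the found ORF (stop excluded), and $P_{GC}$ is computed
over the whole fused transcript by default (`gc_on = "orf"` switches to
the ORF only). The cubic is clamped to $[10^{-9}, 1-10^{-9}]$ before
use so that $P$ and $L$ stay finite for any coefficients.

`fit_lgc_coefficients()` estimates the cubic from labelled transcripts:
per transcript it measures the empirical per-codon stop frequency over
non-overlapping codons in all three frames, bins transcripts by GC
fraction (20 bins), and fits the cubic by codon-weighted least squares.
Under an i.i.d. base model with A/T and G/C symmetry the true stop
frequency is the cubic $(1-p)^2(1+p)/8$ (e.g. $3/64$ at $p = 0.5$,
from enumerating TAA, TAG, TGA), which gives the fit an analytic
recovery target used in the tests.

The packaged default coefficients were fit on the package's own seeded
synthetic corpus (`lgc_synthetic_corpus(400, seed = 20240101)`:
noncoding examples are i.i.d. sequences over a GC gradient, coding
examples are constructed ORFs whose reading frame depletes stops), and
a test regenerates them from that corpus. Scores are therefore
meaningful *relative to a stated coefficient set*; users with a real
transcriptome should fit their own coefficients and pass them via a
coefficient file.

# Binder kmers and the three filtering layers

Translated proteins are cut into unique kmers (length 9 by default,
the modal MHC class-I peptide length; lengths 8–11 are supported).
Binding predictions enter through a plug-in contract — any function
`(kmers, alleles) -> data.frame(kmer, allele, ic50)` — and a
deterministic seeded stub predictor ships for testing: it hashes
(kmer, allele), maps a configurable fraction (default 2%) to IC50 at
or below 500 nmol/L (log-uniform on [1, 500]) and the rest log-uniform
on (500, 50000]. The stub exists so that every downstream stage can be
exercised reproducibly; it encodes no biochemistry.

Three filters apply, in order:

1. **IC50**: a kmer binds an allele when the predicted IC50 is at most
   500 nmol/L (boundary inclusive); a kmer is a binder for a sample
   when it binds any allele of that sample's genotype.
2. **Cross-group** (differential mode only): tumor binders also present
   among the kmers of the same cluster's normal-specific transcripts
   are removed, and symmetrically. The scope is the junction cluster —
   the alternative event — not the whole cohort. Outlier mode skips
   this filter entirely, since there is no second group.
3. **Reference peptidome**: binders found verbatim (exact substring, no
   I/L equivalence) in the kmerized reference proteome are removed, so
   only peptides that cannot arise from annotated transcripts survive.
   This is the false-positive control: a joined transcript that merely
   reproduces a reference transcript contributes zero surviving
   binders.

Each stage's output is a subset of its input, so surviving binder
counts are monotonically non-increasing along the cascade — an
invariant the pipeline logs per stage and the tests assert.

# Antigenicity

For gene $G$ with group-specific junction set $I$ in a given sample,

$$SA(G) \;=\; \frac{1}{|I|}\sum_{i \in I} R_i \,\frac{k_{g,i}}{k_i},$$

where $R_i$ is the sample's variance-stabilized read count for junction
$i$, $k_{g,i}$ the number of group-specific binders surviving all
filters for the transcript modified by junction $i$, and $k_i$ the
total number of kmers of that transcript. Tumor samples are scored on
tumor-specific junctions, normal samples on normal-specific junctions;
in outlier mode every sample is scored on the outlier junction set.
Junctions with $k_i = 0$ are excluded from $I$. $k_i$ counts *unique*
kmers, matching the unique-kmer extraction used for prediction;
positional counting would double-weight repetitive sequence.

Variance stabilization defaults to $\log_2(\text{count}+1)$ — monotone,
zero-preserving and adequate at junction-count scale; the transform is
pluggable (`vst =`) and recorded with the result, since the choice is a
convention rather than a derived quantity. $R_i$ is taken per sample:
junction lists are cohort-level, counts are sample-level, which is what
makes the metric a per-sample statistic.

Pseudo purity is computed from ESTIMATE scores as
$P = 1 - \mathrm{est} / (\max + \max\cdot\varepsilon)$ with
$\varepsilon$ the double-precision machine epsilon, so the cohort-max
sample keeps a strictly positive purity (~2.2e-16) and is then excluded
by the purity floor $P \le 0.01$ rather than dividing by zero.
Normalized antigenicity is $SA_{norm} = SA / P$; the identity
$SA_{norm}/SA = 1/P$ holds exactly, and multiplying all $R_i$ by a
constant scales both flavours by that constant (scale equivariance).

Per-sample summaries average $SA_{norm}$ over the sample's scored
genes. Differential agretopicity per gene is
$DA(G) = \log_2(\overline{SA_{T,norm}} / \overline{SA_{N,norm}})$ with
the means taken over included tumor and normal samples respectively;
genes observed in only one group are reported missing rather than
zero-filled, because imputing zeros would manufacture infinite ratios.
Cohen's d uses the pooled standard deviation. TMB stratification places
the conventional boundary (10 mutations/Mb) in the high group.

# The synthetic cohort generator

`generate_cohort()` emits every input the pipeline consumes — genome
FASTA, GTF with UTR features, per-sample STAR-style junction tables, a
count matrix, a splicing result table, genotypes, ESTIMATE scores, a
reference proteome and truth tables — deterministically from a seed.

Design points worth knowing when interpreting test results:

* Each gene has three exons; the CDS is built from A/C/G-only sense
  codons (stop codons all contain T), so a frameshift reads through to
  a stop cassette placed at the start of the 3'UTR. Injected cryptic
  junctions reuse the annotated first-intron donor and shift the
  acceptor 10 nt (tumor-biased) or 17 nt (normal-biased) into exon 2 —
  two different frame shifts, hence two distinct long novel peptide
  tails. GT/AG dinucleotides are patched into the genome at every
  injected boundary, placed so that no patch can create a premature
  stop in the reference frame.
* Per gene the generator also emits an exon-skipping junction
  (novel-annotated), a shifted-donor junction (cryptic 5'), a
  doubly-shifted junction (unanchored) and, optionally, a motif-0
  decoy, so all five classification classes appear on both strands.
* Counts are negative binomial (dispersion 10). Group-biased junctions
  have mean 30 in their own group (times `effect_size`, default 4, for
  tumor-specific junctions in tumor samples) and mean 2 in the other
  group. One designated top-effect gene gets a 16-fold extra boost on
  its tumor junction and a suppressed (mean 2) normal junction, making
  it the expected leader of the DA ranking.
* ESTIMATE scores are uniform per group (tumors 2000–8000, normals
  500–2500 by default), giving a realistic purity gradient; because
  purity is defined relative to the cohort maximum, the max-ESTIMATE
  sample always lands at ~2.2e-16 purity and is excluded at the 0.01
  floor — mirroring how the normalization behaves on real cohorts. For
  null (type-I) experiments the two groups should share one ESTIMATE
  range, making the design exchangeable; the packaged null
  configuration does exactly that, since a type-I control with a
  built-in purity confound would not be a null.
* The reference proteome contains the translation of every unmodified
  transcript, which guarantees the self-reconstruction control can be
  evaluated (kmers of faithfully rebuilt transcripts must all be
  filtered).

What the generator does *not* emulate: realistic splice-site sequence
context beyond the GT/AG dinucleotide, overlapping genes, multiple
isoforms per gene, intron retention (out of scope for the pipeline as
a whole), read-level noise, or any true MHC binding biochemistry (the
stub predictor is a hash). Passing tests therefore demonstrate the
correctness and stability of the computational pipeline under known
truth, not predictive accuracy on real tumors.

# Problem sizes and runtime conventions

The packaged study conditions are 50 genes and 6 tumor + 6 normal
samples per cohort (the sizes at which the effect-direction and
type-I properties are evaluated; 20 seeded null cohorts for the
type-I fraction), 75 genes for the 500+-junction classification truth
check, 1,000 random sequences for the ORF oracle comparison, 300
transcripts per label for coefficient recovery, and 100-protein
proteomes for the reference-filter oracle. These sizes were chosen so
a full verification run completes in a few minutes on one CPU while
keeping every Monte-Carlo margin comfortably away from its threshold.

# Known limitations

* One junction per modified transcript: co-occurring alternative
  events on the same molecule are not represented.
* Intron retention is not modelled (junctions are exon-spanning by
  definition here).
* The cross-group filter's scope is the overlap-defined cluster; with
  `shared-site` clustering the scope changes accordingly.
* Binder calling uses a single universal IC50 threshold; allele-
  specific thresholds would need a predictor-side lookup.
* DA is undefined (NA) for genes with zero antigenicity in either
  group; downstream rankings must handle missingness explicitly.
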