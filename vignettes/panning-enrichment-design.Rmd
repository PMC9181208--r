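---
title: "Panning enrichment analysis and amplification-aware CDR library design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panning enrichment analysis and amplification-aware CDR library design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandesign)
```

## The problem

In phage-display antibody selection, the output of a panning campaign is
shaped by two forces: binding to the antigen, and the amplification
efficiency of each clone in the bacterial host. Clones that display poorly,
fold badly, or grow slowly are depleted regardless of their affinity, and
fast-amplifying non-binders can dominate late panning rounds. `pandesign`
implements the computational side of an *amplification-centric* library
design strategy: a fixed-framework scFv library with predefined
(non-combinatorial) CDR diversity is panned on protein A — a superantigen
that binds the VH3 framework itself, so selection acts on display and
amplification rather than on the paratope — and deep sequencing of the
repertoire before and after panning reveals which CDR sequences amplify
well. Those observations then drive the design of a new synthetic CDR
repertoire.

The package covers the full design loop:

1. **Ingest** (`extract_cdrs()`, `apply_whitelist()`): CDRs are cut out of
   merged amplicon reads between invariant framework anchors and counted per
   unique amino-acid sequence; reads whose CDR does not match a designed
   sequence (parallel-synthesis errors) are set aside.
2. **Germline enrichment** (`assign_germline()`,
   `germline_frequencies()`): non-H3 CDRs, designed by simulated somatic
   hypermutation of human germline CDRs, are traced back to their nearest
   germline ancestor and enrichment is compared at the germline level.
3. **Enrichment score** (`es_table()`, `fold_histogram()`,
   `positional_shifts()`): a per-sequence statistic for CDR-H3 (below).
4. **Model** (`fit_es_model()`, `decile_diagnostic()`): one ridge
   regression per CDR-H3 length on one-hot positional residue features.
5. **Design** (`simulate_cdrh3()`, `screen_candidates()`,
   `filter_strong_binders()`, `assemble_oligos()`): simulate candidate
   CDR-H3s, keep those predicted to be enriched, drop predicted MHC class II
   epitopes, and emit fixed-length oligos for synthesis.
6. **Ground truth** (`simulate_panning()`, `emit_reads()`): a panning
   simulator with planted per-clone fitness used throughout the test suite.

## The enrichment score

For a designed CDR-H3 sequence with read counts $n_{pre}$ and $n_{post}$ in
repertoires of total size $N_{pre}$ and $N_{post}$,

$$
ES = \log_2\!\frac{n_{post}/N_{post}}{n_{pre}/N_{pre}} \;\times\;
\frac{n_{post}+n_{pre}}{\mathrm{median}(n_{post})+\mathrm{median}(n_{pre})}
$$

The log term is the frequency change through panning; the second factor is a
confidence weight that up-ranks sequences observed at high depth, for which
the ratio is well determined, relative to the typical (median) sequence.
Numerical choices, made where the formula leaves room:

* **Pseudocount.** A raw count of zero is replaced by 0.5 in both factors
  and the record is flagged `pseudocounted`. Dropping unobserved-in-one-side
  sequences instead would censor exactly the most enriched and most depleted
  clones. The pseudocount is absolute, so the exact scale-invariance of the
  score under joint rescaling of counts, totals, and medians holds for
  positive counts only.
* **Medians** are computed over the designed, whitelisted sequence set
  within each repertoire, after pseudocounting. The totals default to the
  same set's sums but can be overridden with `es_table(totals = )` when
  frequencies should refer to the complete sequenced library.
* **Two logarithm bases coexist.** The score itself uses $\log_2$; the
  fold-enrichment histogram (`fold_histogram()`) uses $\log_{10}$ so that
  the conventional "20-fold" tail sits at $|\log_{10}| > 1.3$. Both are
  stored per record.
* **Positional shift testing** uses a pooled-variance two-proportion z-test
  without continuity correction, reported with `*`/`**` stars at 0.05 and
  0.01; Benjamini–Hochberg adjustment is available via
  `positional_shifts(p_adjust = "BH")` but is off by default so that
  per-cell stars match the unadjusted convention of repertoire reports.

## The per-length model

`fit_es_model()` fits ES on one-hot (position, residue) indicators with an
L2 penalty, one model per CDR-H3 length (9–16 aa); positional categoricals
are the only features. The penalty default, $10^{-6}$, is mild by intent:
it stabilizes the collinear one-hot design (each position's indicators sum
to one) rather than shrinking the fit. The solver is a closed-form
augmented-QR least squares — the objective, not the optimizer, defines the
model, and a deterministic solve makes training exactly reproducible from
the split seed. The data are split 70/30 into training and evaluation by a
seeded uniform draw without stratification; held-out $R^2$ and Spearman
correlation are reported by `glance()`, and `decile_diagnostic()` gives the
calibration view: mean predicted-ES percentile rank within each decile of
actual ES (midpoints 5, 15, …, 95 for a perfect predictor; a flat 50 for an
uninformative one). Screening (`screen_candidates()`) keeps candidates with
predicted ES strictly greater than zero — a prediction of exactly zero is
not kept.

## Candidate generation and liability filtering

`simulate_cdrh3()` samples sequences position-by-position from a positional
amino-acid frequency table over 18 residues — cysteine and methionine are
excluded from designed CDRs — rejecting duplicates and sequences carrying
liability motifs. The default motif set covers deamidation (NG, NS),
isomerization (DG, DS), acid-labile cleavage (DP), and the N-glycosylation
sequon `N[^P][ST]`; it ships as an editable rule list
(`default_motif_rules()`, `read_motif_rules()`) because liability
definitions are project policy, not algorithm. The bundled
`default_cdrh3_frequencies()` table is a *synthetic stand-in* that mimics
coarse features of natural CDR-H3 usage (G/S/Y/D-rich, D-then-Y bias at the
C-terminal end); design work should supply a measured table. Motif
rejection slightly depletes the participating residues (N, D and partners)
relative to the input table — an intended distortion, since the designed
library excludes those contexts.

## Epitope exclusion and oligo assembly

Deimmunization follows a windowing rule: each CDR is flanked by its
adjoining 8-residue framework context, every overlapping 9-mer (L + 8 of
them for a CDR of length L) is scored against a 20-allele HLA-DRB panel,
and the CDR is discarded if any window scores within the top 0.5 percentile
rank for any allele. The threshold is inclusive (a rank of exactly 0.5 is a
strong binder), and filtering is monotone in the threshold. The MHC-II
predictor itself is pluggable: percentile ranks are imported from TSV
(`read_mhc2_predictions()`) as produced by an external predictor, and a
deterministic toy scorer (`toy_mhc2_predict()`) exists so that the
filtering logic is testable without one; the toy scorer carries no biology.
Flanks are per-region configuration — framework context necessarily differs
between CDRs.

Accepted CDRs are reverse-translated with a deterministic codon scheme (the
most-used human codon per residue, demoted to the next-ranked human codon
when the top choice is in a configurable E. coli rare-codon list) and
assembled into 136-nt oligos: adaptor + framework flank + CDR + framework
flank + adaptor. Flanks keep their CDR-adjacent bases — the PCR priming
context — and are trimmed distally to make the total exactly 136; an odd
flank budget puts the extra base on the 5′ side. CDR-H3 pools are binned by
length (9–16 aa), mirroring the gel-based length separation used during
library construction. Adaptor sequences, flank sequences, and both codon
tables are configuration with documented defaults, since they are
vendor- and construct-specific.

## The panning simulator and what passing tests mean

`simulate_panning()` provides the ground truth the analysis stages are
tested against. Pre-panning clone frequencies are drawn from a symmetric
Dirichlet (concentration 5 — a mildly skewed starting library); each clone
gets an amplification fitness $w = \sum_p \beta_{p,a(p)} + \varepsilon$,
linear in its positional residue identities with clone-level noise
$\varepsilon \sim N(0, 0.05)$; frequencies are propagated through three
selection rounds as $f_{post} \propto f_{pre}\,e^{3w}$; and both
repertoires are sampled multinomially at $10^6$ reads. The default effect
table draws $\beta_{p,a} \sim N(0, 0.12)$: with nine positions this gives a
log10 fold-change spread of roughly half a unit with a small tail of clones
beyond 20-fold enrichment or depletion, the shape a protein-A panning
histogram of a designed repertoire shows. The test suite and acceptance
script use 5,000 length-9 clones at this depth, sizes chosen to exercise
the full pipeline in seconds.

The exponential-growth model is a minimal test harness, not a claim about
panning physics: it omits display-valency effects, host-interaction
dynamics, PCR and sequencing error, and synthesis indels (off-design reads
are emulated only as whole-CDR contaminant spike-ins by `emit_reads()`).
Passing tests therefore demonstrate that the statistics and the design
filters do what they claim on data with exactly the assumed structure; they
do not validate the biological model of amplification.

One property of the ES statistic deserves emphasis. Because post-panning
counts respond exponentially to fitness and the confidence weight grows
with counts, the expected ES is a *convex*, not linear, function of clone
fitness. A linear model fit to ES therefore recovers the planted effects'
ranking and sign structure faithfully (the acceptance script reports sign
agreement and mean absolute recovery error), but systematically distorts
the largest effects, and the Dirichlet skew of the starting library enters
the confidence weight as multiplicative noise that caps the achievable
ES–fitness rank correlation. Under the default study conditions the
ES–fitness Spearman correlation exceeds 0.9 and the decile diagnostic is
monotone, while the maximum absolute error of ridge-recovered effects
(mapped to the per-round fitness scale via the selection rounds and the
mean confidence weight) remains several times larger than its mean — the
acceptance suite records this known limitation rather than narrowing the
simulated enrichment spread until the response becomes linear.

## Other design decisions

* **Anchor matching is exact.** Frameworks are invariant by library design;
  fuzzy matching would blur the designed/non-designed split the analysis
  relies on. Reads with ambiguous bases, missing or duplicated anchors,
  stop codons, or out-of-range CDR lengths are rejected and tallied by
  reason (`rejection_summary()`); out-of-range is a rejection, not a
  separate class, and is reported.
* **Nearest-germline assignment** uses the global unit-cost edit distance:
  hypermutated CDRs differ from their ancestor mostly by substitutions, but
  germline CDRs of one region can differ in length. Ties are broken
  lexicographically and flagged `ambiguous`. Fold-change edge cases: a
  germline absent pre-panning gets `Inf` (enriched), absent post-panning
  gets 0 (depleted), absent from both is omitted.
* **Kabat labels are a reporting convention only**: positional-shift tables
  label CDR-H3 positions H95, H96, … sequentially; extraction itself is
  anchor-defined.
* **Paired-end merging, quality filtering, UMI handling, and chimera
  detection are out of scope** — inputs are pre-merged reads, as produced
  by standard upstream tooling.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  package is a library, and every stage is a pipeable function over
  tibbles.
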