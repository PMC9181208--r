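# pandesign

Computational design of synthetic antibody CDR libraries from phage-display
biopanning deep-sequencing data.

In antibody phage display, selection outcomes are driven not only by antigen
binding but also by how efficiently each clone amplifies in the bacterial
host. Panning a fixed-framework scFv library against protein A — which binds
the VH3 framework itself — selects on display and amplification rather than
on the paratope, and sequencing the repertoire before and after panning
reveals which CDR sequences amplify well. `pandesign` implements the
analysis and design workflow around that experiment, for researchers
building synthetic antibody libraries with predefined CDR diversity:

- **CDR extraction** from merged amplicon reads between invariant framework
  anchors, with per-reason rejection accounting and designed-sequence
  whitelisting (`extract_cdrs()`, `apply_whitelist()`);
- **germline-level enrichment** of non-H3 CDRs via nearest-germline
  assignment by edit distance (`assign_germline()`,
  `germline_frequencies()`);
- the per-sequence **enrichment score** for CDR-H3

  $$ES = \log_2\!\frac{n_{post}/N_{post}}{n_{pre}/N_{pre}} \times
  \frac{n_{post}+n_{pre}}{\mathrm{median}(n_{post})+\mathrm{median}(n_{pre})}$$

  combining the log2 frequency change with a read-depth confidence weight,
  plus fold-change histograms, enriched/depleted splits for sequence logos,
  and positional residue-shift tests (`es_table()`, `fold_histogram()`,
  `split_by_fold()`, `positional_shifts()`);
- **per-length ridge models** predicting ES from one-hot positional residue
  features, with a decile-rank calibration diagnostic and broom-style
  `tidy()`/`glance()` methods (`fit_es_model()`, `decile_diagnostic()`);
- **candidate CDR-H3 simulation** from positional amino-acid frequencies,
  excluding Cys/Met and PTM liability motifs, and **screening** at
  predicted ES > 0 (`simulate_cdrh3()`, `screen_candidates()`);
- **deimmunization** by sliding 9-mer windows over framework-flanked CDRs
  against a 20-allele HLA-DRB panel with a pluggable MHC-II predictor
  (`epitope_queries()`, `filter_strong_binders()`);
- **136-nt oligo assembly** with a human-preferred / E. coli-aware codon
  scheme and length binning (`assemble_oligos()`, `bin_by_length()`);
- a **panning simulator** with planted per-clone fitness for end-to-end
  validation (`simulate_panning()`, `emit_reads()`);
- bundled summary tables of a two-library validation campaign and helpers
  that recompute their printed aggregates (`panning_outcomes()`,
  `mean_kd()`, `unique_fraction()`, `library_size_summary()`, ...).

## Worked example

A full design loop on simulated data — simulate a panning experiment with
planted fitness, emit anchored reads with 30% off-design contaminants,
re-extract and whitelist, score, model, screen, deimmunize, and assemble:

```r
library(pandesign)

scheme <- framework_scheme("H3", "TAVYYCAK", "WGQGTLVT")
sim <- simulate_panning(panning_sim_config(
  n_clones = 1000, reads_per_repertoire = 2e5, seed = 42))

pre  <- emit_reads(sim$counts, scheme, "pre",  seed = 1, contaminant_fraction = 0.3)
post <- emit_reads(sim$counts, scheme, "post", seed = 2, contaminant_fraction = 0.3)
counts <- bind_count_tables(
  extract_cdrs(pre, scheme, "pre"),
  extract_cdrs(post, scheme, "post"))
designed <- apply_whitelist(counts, sim$counts$aa_seq)
attr(designed, "retained_fraction")
#> [1] 0.7

es <- es_table(designed)
head(es, 3)
#> # A tibble: 3 x 7
#>   aa_seq    length n_pre n_post     es log10_fold pseudocounted
#>   <chr>      <int> <int>  <int>  <dbl>      <dbl> <lgl>
#> 1 AAAPQGQDY      9   196     16 -2.49     -1.09   FALSE
#> 2 AADFYFRQG      9   109    128  0.178     0.0698 FALSE
#> 3 AAYSKVEDY      9   290     54 -2.71     -0.730  FALSE
```

The first sequence fell from 196 to 16 reads — an ~12-fold depletion
(log10 fold −1.09), weighted to ES −2.49; 24 clones dropped more than
20-fold (`attr(fold_histogram(es), "tail_counts")`). A per-length model
trained on the scores predicts enrichment from sequence alone:

```r
model <- fit_es_model(es, seed = 7)
model
#> <es_model> CDR-H3 length 9: 162 features, l2 = 1e-06
#>   held-out (n = 300): R2 = 0.458, Spearman = 0.779

cand <- simulate_cdrh3(default_cdrh3_frequencies(9), 1000, seed = 11)
screened <- screen_candidates(model, cand)
sum(screened$kept)
#> [1] 469

q <- epitope_queries(screened$aa_seq[screened$kept], "AVYYCAKG", "WGQGTLVT")
filt <- filter_strong_binders(q, toy_mhc2_predict(q$window))
oligos <- assemble_oligos(filt$kept, default_h3_region_config())
nrow(oligos); unique(oligos$total_len)
#> [1] 196
#> [1] 136
```

Of 1,000 simulated candidates, 469 are predicted to be panning-enriched;
after discarding predicted MHC-II strong binders (here with the
deterministic toy scorer — real work imports percentile ranks from an
external predictor via `read_mhc2_predictions()`), 196 survive and are
emitted as 136-nt oligos ready for synthesis. See the vignette
(`vignettes/panning-enrichment-design.Rmd`) for the model, its assumptions,
and every tunable default.

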