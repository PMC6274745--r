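# bovlnc

Identification and cis-regulatory interpretation of long non-coding
RNAs (lncRNAs) from assembled bulk RNA-seq transcripts.

`bovlnc` is aimed at transcriptomics analysts who have assembled and
merged transcripts (e.g. from a cufflinks/stringtie-style workflow)
against a reference genome and want a tested, reproducible
implementation of the classic lncRNA discovery cascade and its
downstream interpretation — the kind of analysis used to characterize
lncRNAs in the bovine mammary gland under two dietary-oil treatments
(LSO and SFO) sampled at three timepoints (D-14, D+7, D+28) in six
cows each, i.e. 36 libraries with 18 per treatment.

## What it computes

**Identification.** Candidates shorter than 200 nt are removed; the
rest are compared against the known annotation by exon chain and
given a cuffcompare-style class code with precedence
`=` > `c` > `j` > `o` > `x` > `i` > `u`; codes `i`, `o`, `u`, `x` are
retained. Coding potential is scored by a logistic model over four
sequence features — longest ORF length *L*ₒᵣf, ORF coverage
*L*ₒᵣf/*L*, the Fickett TESTCODE statistic, and the mean in-frame
hexamer log-likelihood ratio (1/H)Σ ln(f_c(h)/f_n(h)) — with coding
probability ≥ 0.4 removed. Survivors are labelled *known* (codes
`=`/`c`/`j` against a lncRNA catalogue) or *novel*, and placed into an
11-class positional taxonomy relative to protein-coding genes.

**Interpretation.** Median-of-ratios size factors
(s_j = median_i k_ij / (∏_j k_ij)^{1/m}); a truly-expressed filter
(normalized count ≥ 5 in ≥ 10% of libraries); FPKM
(k_ij·10⁹/(N_j·L_i)); per-treatment negative-binomial Wald tests for
the three day contrasts with BH correction, significant at adjusted
p < 0.1; cis-target calling — coding genes within 50 kb whose
log-normalized expression correlates with the lncRNA at Pearson
r > 0.7 over the treatment's 18 libraries, with two-sided p from
t = r√(n−2)/√(1−r²) — and hypergeometric enrichment
P(X ≥ k), X ~ Hypergeom(N, K, n) of the cis-target gene lists (GO at
BH-adjusted p ≤ 0.05, pathways at raw p < 0.05). A `2^−ΔΔCt` helper
with two reference genes covers qPCR validation assays.

Seeded synthetic-data generators (`sim_config()`,
`simulate_annotation()`, `simulate_sequences()`, `simulate_counts()`)
produce every pipeline input with planted ground truth — positional
classes, known/novel status, log2 fold changes, cis correlations —
and identical configurations reproduce every file byte for byte.

## Worked example

```r
library(bovlnc)

cfg  <- sim_config(seed = 42)                       # 36-library study design
ann  <- simulate_annotation(cfg)                    # reference + assembled GTF models
seqs <- simulate_sequences(cfg, ann$truth)
train <- simulate_labeled_sequences(60, 60, seed = 42)

idf <- run_identify(ann$assembled, ann$reference, seqs,
                    train$seqs, train$labels)
idf$stage_log
#>              stage n_in n_removed n_retained
#> 1    length_filter  153         3        150
#> 2 classcode_filter  150         8        142
#> 3    coding_filter  142         1        141
#> 4   exclusion_list  141         0        141
table(idf$status)
#> known novel
#>     7   134
```

Three planted sub-200-nt transcripts die at the length stage, the
eight assembled copies of coding transcripts die at the class-code
stage, and one candidate is lost to the coding-potential filter; the
planted known lncRNAs are all recognized. Quantification and
interpretation then run off the simulated counts:

```r
cm <- simulate_counts(cfg, ann$truth)
qt <- run_quantify(idf, cm$counts, cm$design,
                   annotation_subset(ann$reference, "protein_coding"))
head(qt$de[qt$de$significant, ], 3)
#>   feature_id treatment dayA dayB   FC log2FC        p     padj
#>  TCONS_00017       LSO  D+7 D+28 2.35   1.23 9.86e-38 1.39e-35
#>  TCONS_00009       LSO  D+7 D+28 2.92  -1.54 2.02e-25 1.42e-23
#>  TCONS_00016       SFO  D+7 D+28 2.60   1.38 3.26e-22 4.59e-20
head(qt$cis_all, 3)
#>  treatment   lncrna_id gene_id      r         p distance
#>        SFO TCONS_00002  CG0002 0.9023 3.058e-07     2000
#>        SFO TCONS_00007  CG0007 0.9017 3.217e-07     2000
#>        LSO TCONS_00002  CG0002 0.9012 3.328e-07     2000
```

The DE table shows the planted two-fold (|log2FC| ≈ 1.2) effects in
their planted contrasts, reported in the signed-magnitude convention
(FC = 2^|log2FC|); the cis table recovers the planted lncRNA–gene
pairs at their target correlation r ≈ 0.9 within their 50 kb windows.
`run_all_synthetic(cfg, dir)` writes all reports as TSVs,
byte-identically on rerun.

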