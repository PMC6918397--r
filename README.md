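# cannamark

Genetic markers that separate drug-type (marijuana) from fiber-type
(hemp) *Cannabis sativa* using the coding sequences of the two synthase
genes *THCAS* and *CBDAS*. The two encoded enzymes compete for the same
precursor (cannabigerolic acid), so fixed differences in *both* genes —
not *THCAS* alone — carry the chemotype signal. `cannamark` implements
the complete marker pipeline for forensic and breeding applications
where plants (or seeds) must be classified before any cannabinoid has
accumulated:

* **Variant discovery** — global alignment of per-sample gene sequences
  to reference CDSs, SNP/indel calls in 1-based CDS coordinates
  (left-normalised indels, IUPAC codes for heterozygous Sanger calls),
  and a samples x loci categorical genotype matrix.
* **Association scan** — per-locus Firth penalized-likelihood logistic
  regression (finite estimates even under the complete separation that a
  perfect marker produces) with a profile penalized likelihood-ratio
  test, and Benjamini–Hochberg FDR control jointly across both genes.
* **Discriminant scoring** — per-locus points against the class
  consensus alleles (+1 drug consensus, −1 fiber consensus, 0
  otherwise), indel presence/absence points, AUC-optimised weights under
  a "most weights non-negative" constraint, and threshold evaluation
  with stratified bootstrap confidence intervals.
* **Population structure & chemotype** — Gower distances over
  categorical loci, classical MDS biplot coordinates, Shannon-entropy
  variation summaries, and THC/CBD ratio arithmetic with the standard
  four chemotype groups (cut at 0.05, 0.2 and 10).
* **Protein consequences** — translation with premature-stop detection,
  synonymous/non-synonymous accounting per codon, side-chain impact
  grading, frameshift detection.
* **Synthetic panels** — a seeded generator emitting FASTA, metadata,
  genotype matrices and ground-truth tables with the full planted marker
  structure (25 THCAS-like + 8 CBDAS-like discriminating SNPs, a 4-bp
  deletion at 153–156 and an AAC insertion after 755 in drug-type
  CBDAS), so the entire pipeline runs end-to-end with no downloads.

The score of a sample with genotype cells $g_1,\dots,g_k$ at the chosen
loci is $S = \sum_j w_j\,\mathrm{pts}(g_j)$, with $\mathrm{pts} \in
\{-1,0,1\}$ for SNP loci and $\{0,1\}$ (presence) for indel loci, and the
rule $S > 0 \Rightarrow$ drug-type. The AUC is the Mann–Whitney
probability that a random drug-type score exceeds a random fiber-type
score. With the published-style indel weights (+1.1 deletion, −1
insertion) the attainable scores are exactly {−1, 0, 0.1, 1.1}.

## Worked example

```r
library(cannamark)

cfg   <- panel_config(seed = 1, n_drug_plants = 12, n_fiber_plants = 12,
                      n_drug_seeds = 0, n_fiber_seeds = 0)
panel <- simulate_panel(cfg)
panel
#> Synthetic cannabis marker panel
#>   samples: 24 (12 drug / 12 fiber; 24 leaf / 0 seed)
#>   genes: THCAS (1638 nt), CBDAS (1635 nt)
#>   planted loci: 33 (+2 indel)

calls <- call_panel_variants(panel$sequences, panel$references)
gm    <- build_matrix(calls, labels = panel$metadata[, c("sample_id", "class")])
scan  <- scan_loci(gm, q = 0.05)
head(scan, 4)
#> # A tibble: 4 × 7
#>   locus         gene    pos kind           p_raw       p_adj significant
#>   <chr>         <chr> <int> <chr>          <dbl>       <dbl> <lgl>
#> 1 CBDAS_153_del CBDAS   153 deletion 0.000000152 0.000000499 TRUE
#> 2 CBDAS_407     CBDAS   407 snp      0.000000152 0.000000499 TRUE
#> 3 CBDAS_545     CBDAS   545 snp      0.000000152 0.000000499 TRUE
#> 4 CBDAS_583     CBDAS   583 snp      0.000000152 0.000000499 TRUE
sum(scan$significant)
#> [1] 35
```

All 33 planted SNPs plus the two indel loci are recovered as significant;
the random background variants are not. A single optimally weighted locus
already separates the classes, and the deletion/insertion score at the
zero threshold is perfect on this panel:

```r
profile <- consensus_profile(gm, scan$locus[scan$significant])
optimize_weights(gm, profile, k = 1)
#> Discriminant score: 1 loci, threshold 0, AUC 1.0000
#> # A tibble: 1 × 3
#>   locus         kind     weight
#>   <chr>         <chr>     <dbl>
#> 1 CBDAS_153_del deletion      1

sc <- score_samples(gm, indel_score_spec())   # +1.1 del / -1 ins
evaluate_score(sc, threshold = 0, B = 2000, seed = 1)
#> Score evaluation at threshold 0 (12 drug / 12 fiber, B = 2000)
#> # A tibble: 3 × 4
#>   metric      estimate ci_low ci_high
#>   <chr>          <dbl>  <dbl>   <dbl>
#> 1 auc                1      1       1
#> 2 sensitivity        1      1       1
#> 3 specificity        1      1       1
```

The drug-type CBDAS variant set truncates the protein — the A→T change
at CDS position 583 creates a stop in codon 195 (against 544 residues
for the intact protein), on top of the frameshifting 4-bp deletion that
removes Leu51/Val52:

```r
truth <- panel$truth$loci
vars  <- dplyr::transmute(truth[truth$gene == "CBDAS" & truth$kind == "snp", ],
                          pos, kind, ref = ref_allele, alt = drug_allele)
annotate_consequences(panel$references[2, ], vars)
#> Consequences: 8 SNPs (7 non-syn / 1 syn, 7 aa changes, ratio 7.0); truncated at codon 195
```

`run_pipeline(panel_config(seed = 1))` chains all stages (scan, scoring,
MDS, entropy, chemotype, consequences) into one seeded, reproducible run
with a JSON-able report.

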