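# mipronet

Constructing microRNA-mediated regulatory networks from genome-wide RNA
polymerase II (RPol II) and transcription-factor ChIP-seq binding data.

Primary microRNA transcripts are transcribed by RPol II from their own
promoters, but those promoters are mostly unannotated: the mature miRNA
gives no direct handle on where transcription starts. `mipronet`
implements a three-step strategy for researchers studying
transcription-factor control of miRNA expression:

1. **miRNA promoter discovery.** RPol II occupancy around an active TSS
   follows a characteristic shape summarised by five features — peak
   intensity `h_p`, background `h_b`, steady transcript-region intensity
   `h_t` (reads/bp), and promoter/transcript decay rates `lambda_p`,
   `lambda_t` (1/bp):

   ```
   mu(x) = h_b + (h_p - h_b) exp( lambda_p x)   for x <= 0
   mu(x) = h_t + (h_p - h_t) exp(-lambda_t x)   for x >  0
   ```

   Binned counts are Poisson with mean `bin_width * mu(x)`. The model is
   fitted by maximum likelihood on expressed protein-coding genes, the
   upstream regions of intergenic miRNAs are scanned for statistically
   similar patterns with a log-likelihood-ratio score, and promoters are
   called at an empirical FDR of 0.2 against a max-over-scan null.
2. **Collaborating factors.** ChIP-enriched regions of the assayed factor
   are scanned with a PSSM library (normalised log-odds scores); a matrix
   is enriched when its binding-site density in ChIP regions reaches five
   times the density in background promoters — a density-ratio FDR of
   at most 20% — at some score cutoff.
3. **Network assembly.** Promoter calls, binding instances, interval
   statistics (permutation overlap tests, binomial co-occurrence, CpG
   islands, TSS-distance profiles) and seed-match target sites (8mer,
   7mer-m8, 7mer-1A) combine into TF->miRNA->gene feedback and incoherent
   feed-forward motifs.

A fully seeded synthetic-data generator with planted ground truth stands
in for the external resources (coverage tracks, ChIP regions, matrix
libraries, UTR sets) and makes every stage testable end to end.

## Worked example

Simulate a ground-truth bundle and run the full pipeline:

```r
library(mipronet)

sim    <- simulation_config(seed = 7)          # study-condition defaults
bundle <- simulate_bundle(sim, "bundle7")      # writes inputs + ground truth
cfg    <- pipeline_config("bundle7", n_perm = 2000, seed = 7)
res    <- run_all(cfg)
#> mipronet run complete: 22 promoter calls, 3 enriched PSSMs,
#> 12 feedback and 39 feed-forward motifs
```

The promoter stage reports held-out ROC performance and the accepted
calls with their regions:

```r
res$promoters$roc
#> $auc
#> [1] 0.9711538
#> $auc_by_tier
#>       low    medium      high
#> 0.9166667 1.0000000 1.0000000

head(res$promoters$calls[res$promoters$calls$accepted, ], 4)
#>   mirna_id    tss distance    score        fdr region_start region_end
#> 2  mir_002  19900     4850  53.4759 0.00617284        19100      20050
#> 3  mir_003 120250     8250 457.5869 0.00000000       119050     120550
#> 5  mir_005 270600     9950 145.0651 0.00617284       270050     270800
#> 6  mir_006 256750     9150 323.3788 0.00617284       256500     257900
```

The AUC is the probability that an expressed gene outscores an
unexpressed one; per-tier AUCs rise with expression level. Each accepted
call gives the predicted TSS, its distance upstream of the pre-miRNA, the
log-likelihood-ratio score and the empirical FDR, plus the called
regulatory region. Against the bundle's ground truth this run recovers
all 20 planted active promoters with 2 false calls among 22.

Motif enrichment ranks the assayed factor's own matrices first, as a
positive control, and reports the density-ratio FDR at each selected
cutoff:

```r
res$motifs$enrichment$report
#>    pssm_id     tf cutoff chip_density bg_density    fdr enriched
#> 1 STAT1_01  STAT1   0.78        7.603     1.1176 0.1470     TRUE
#> 2 STAT1_02  STAT1   0.76        8.055     1.5778 0.1959     TRUE
#> 3   AP1_01    AP1     NA           NA         NA 0.2663    FALSE
#> 4  CEBP_01   CEBP   0.88        0.451     0.0438 0.0971     TRUE
#> 5 DECOY_01 DECOY1     NA           NA         NA 1.0105    FALSE
#> 6 DECOY_02 DECOY2     NA           NA         NA 1.0000    FALSE
```

Overlap statistics and the assembled motifs:

```r
res$stats$overlap
#> overlap: 20 / 22 query regions (p_hat = 0.0163, P = 4.13e-34, 2000 permutations)

head(res$network$feedback, 3)
#>   motif_type   mirna target_gene        tfs cycle
#> 1   feedback mir_002        IFNG      STAT1 FALSE
#> 2   feedback mir_003         JUN      STAT1 FALSE
#> 3   feedback mir_005        IFNG CEBP,STAT1 FALSE
```

20 of the 22 called promoter regions overlap ChIP regions — far more
than the ~1.6% per-region chance rate the permutation null estimates,
hence the vanishing p-value. Each feedback row is a TF-regulated miRNA
targeting a focal gene (ligand, the factor itself, or an AP-1 component);
feed-forward rows are (TF, miRNA, gene) triples where the factor binds
the gene promoter and also drives a miRNA that represses the gene. All
outputs are written as seed- and config-stamped TSV/BED/GraphML files
under `bundle7/results/`.

A command-line wrapper with per-stage subcommands (`simulate`,
`call-promoters`, `enrich-motifs`, `region-stats`, `find-targets`,
`build-network`, `run-all`) is installed at `inst/scripts/mipronet.R`.

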