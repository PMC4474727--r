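# barcodiv

Phylogenetic-diversity partitioning and minimum-risk barcode assignment for
community DNA-barcoding surveys.

## The problem

Community barcoding campaigns — sequencing a standard marker such as the
~658 bp COI fragment across everything collected in a region — produce two
kinds of questions:

1. **How evolutionarily diverse is a region's fauna, and how much of that
   diversity evolved in place?** Given a branch-length gene tree whose
   leaves are annotated to biogeographic provinces, the *inclusive*
   phylogenetic diversity of a province is the total branch length retained
   when all other leaves are trimmed,

   PD_I(G) = Σ { len(e) : e has ≥ 1 descendant leaf in G },

   and the *exclusive* phylogenetic diversity is the branch length found
   only on lineages leading exclusively to the province's members,

   PD_E(G) = Σ { len(e) : all descendant leaves of e are in G }
           = total length − PD_I(complement of G).

   The ratio PD_E/PD_I is a proxy for in-situ diversification: a province
   assembled by dispersal scatters over the tree (low ratio), while an
   endemic radiation concentrates whole clades (high ratio). Because
   provinces are unevenly sampled, PD_I is compared at standardized sample
   sizes via Monte-Carlo rarefaction over leaf subsamples.

2. **How reliably does the barcode identify species?** Query sequences are
   assigned to candidate species with a segregating-sites Bayesian
   classifier: at each alignment column where the reference database varies,
   species *k* emits the query base *q* with probability
   (c_kq + 1)/(n_k + 4) (Laplace-smoothed per-site base frequencies); with a
   uniform prior the posterior P(k|S) is the normalised product over sites.
   The decision is by minimum expected risk, R(i) = Σ_k P(k|S) L(i,k) with
   L(i,i) = 0 and L(i,k) = d(S, consensus_i), the uncorrected p-distance to
   the species consensus, which collapses to

   R(i) = d(S, consensus_i) · (1 − P(i|S)).

   Accuracy is estimated by leave-one-out cross-validation, with singletons
   scored as correct when the call matches the query's genus, and risks
   range-standardized per trial as (R − min R)/(max R + min R).

A synthetic-data module (random coalescent-style trees, random or
clade-clustered province annotations, Jukes-Cantor barcode alignments with
known species truth) makes every stage testable end to end.

## Worked example

```r
library(barcodiv)

tr <- read_newick("((A:1,B:2):3,C:4);")
mp <- tibble::tibble(species  = c("A", "B", "C"),
                     province = c("P1", "P1", "P2"))
pd_report(tr, mp)
#> # A tibble: 2 × 5
#>   province     n  pd_i  pd_e ratio
#>   <chr>    <int> <dbl> <dbl> <dbl>
#> 1 P1           2     6     6     1
#> 2 P2           1     4     4     1

rarefy_pd(tr, c("A", "B", "C"), n_reps = 1000, seed = 1)
#> # A tibble: 3 × 7
#>       k mean_pd sd_pd   q05   q95 n_reps  seed
#>   <int>   <dbl> <dbl> <dbl> <dbl>  <int> <int>
#> 1     1    4.33 0.470     4     5   1000     1
#> 2     2    7.66 1.25      6     9   1000     1
#> 3     3   10    0        10    10   1000     1
```

`P1 = {A, B}` keeps edges 1 + 2 + 3 = 6, all of which lead only to `P1`, so
PD_E = PD_I and the ratio is 1; the rarefaction curve climbs from the mean
root-to-leaf path (4.33) to the full tree length (10) with zero spread at
`k = N`.

Barcode assignment on a two-species toy database:

```r
db <- barcode_db(c("x1", "y1", "y2"),
                 c("Xus alba", "Yus flava", "Yus flava"),
                 c("ACGT", "AGGT", "AGGA"))
tidy(assignment_risk("ACGT", db))
#> # A tibble: 2 × 5
#>   query_id species   posterior p_distance  risk
#>   <chr>    <chr>         <dbl>      <dbl> <dbl>
#> 1 query    Xus alba      0.742        0   0
#> 2 query    Yus flava     0.258        0.5 0.371
```

The query matches *Xus alba*'s consensus exactly (p-distance 0, hence risk
0) and carries 74% of the posterior; the call is *Xus alba*. Validating a
simulated 10-species database:

```r
lo <- ssa_loocv(simulate_barcodes(10, 3, seed = 1))
lo
#> Leave-one-out barcode validation: 30 sequences, 10 species (0 singletons)
#>   sequence-level accuracy: 0.800
#>   species-level accuracy:  0.800
```

`autoplot(lo)` draws the standardized risk heat map;
`run_pd_pipeline()` / `run_barcoding_pipeline()` run the same analyses from
files to CSV/JSON outputs, and `inst/cli/barcodiv.R` wraps them for the
shell.

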