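# gecscan

Phenotype-aware genetic exchange community (GEC) analysis for bacterial
pan-genomes.

Bacteria exchange genes preferentially with partners that share their
ecological niche; dense regions of the resulting horizontal gene transfer
(HGT) network are genetic exchange communities. `gecscan` asks whether a
measured phenotype — the motivating case is the sugar-utilization value of
*Lactobacillaceae* strains, i.e. the number of sugar types (0–17, glucose
excluded) a strain can metabolize — structures gene sharing within a
bacterial family. Starting from three plain TSV tables (strain phenotypes
and genome features; ortholog-cluster membership in SonicParanoid-style
wide or generic long layout; cluster→COG map), the package:

1. drops strain-specific singleton clusters and partitions the rest into
   **core** and **accessory** genomes by the *n*-core rule
   (`support / n_strains ≥ n/100`, default *n* = 97, with a 100→91 scan
   profile);
2. computes each cluster's **ASU** (Average Sugar Utilization: the mean
   sugar-utilization value of its distinct support strains) and classifies
   clusters as **generalist** (ASU > mean + SD), **specialist**
   (ASU < mean − SD) or intermediate, using the strain-level mean and
   sample SD;
3. profiles **COG functional-category ratios** per cluster set and
   compares categories between sets with Welch *t*-tests on per-cluster
   indicators plus Benjamini–Hochberg correction (ND-aware);
4. fits two **standardized multiple regressions** (objectives: genome
   size, HGT-derived CDS count; ten phenotypic/genomic predictors with
   mean imputation then Z-scoring);
5. builds **shared-ortholog networks** over genomes (edge when two strains
   share strictly more than 5 group clusters), extracts communities
   (connected components by default), and quantifies within- versus
   cross-genus mixing — the signature of a phenotype-driven GEC being a
   specialist network confined within genera and a generalist network that
   crosses them.

A seeded synthetic-data generator (`simulate_gec_dataset()`) emulates all
three inputs with planted communities, planted generalist/specialist
sharing structure and a planted sugar-utilization effect on genome size
(10 kb per sugar type against 50 kb noise), providing ground truth for
every downstream stage; `make_toy_fixture()` is a 12-strain hand-checkable
version shipped under `inst/extdata/toy/`.

## Worked example

```r
library(gecscan)
run <- run_gec(gec_config(simulate = sim_config(seed = 42), seed = 42),
               quiet = TRUE)
print(run)
```

```
gec_run
  strains: 96 (mean SU 8.266)
  clusters: 436 after singleton filter; 97-core 52 / accessory 384
  ASU groups: generalist=45, intermediate=342, specialist=49
  generalist network: 30 edges, 3 communities, cross-genus fraction 0.967
  specialist network: 26 edges, 6 communities, cross-genus fraction 0
  regressions: R^2 genome_size 0.586, n_hgt_cds 0.965
```

The three planted cross-genus communities are recovered exactly (3
generalist communities, cross-genus edge fraction 0.97), specialist
sharing stays inside genera (fraction 0), and the 97-core contains the 52
planted core clusters. The regression recovers the planted effect:

```r
summary(run$regressions$genome_size)
```

```
Standardized multiple regression — objective: genome_size
               predictor   coefficient std_error   p_value
       sugar_utilization +57011.4851 * 5387.4881 3.033e-17
              growth_15C    -3295.0682 5242.8909    0.5314
              ...
R^2 = 0.5864, R = 0.7658, n = 96 (rank 10)
```

The starred sugar-utilization coefficient (≈ 57 kb per SD ≈ 5.2 sugars,
i.e. ≈ 11 kb per sugar type) matches the planted 10 kb/sugar effect;
`rank 10 < 11` columns reflects the exact collinearity of the three
oxygen-class dummies with the intercept, resolved by minimum-norm least
squares (see the methods vignette).

The same pipeline runs from files on disk:

```r
toy <- system.file("extdata", "toy", package = "gecscan")
run <- run_gec(gec_config(strains = file.path(toy, "strains.tsv"),
                          groups  = file.path(toy, "ortholog_groups.tsv"),
                          cog_map = file.path(toy, "cog_map.tsv"),
                          out_dir = "toy_out"))
```

which writes core/accessory lists, the ASU table, COG comparison tables,
regression tables, GraphML + edge-list networks, community memberships and
a machine-readable `report.json`. A thin command-line wrapper lives at
`inst/scripts/gecscan.R` (`simulate` and `run` subcommands).

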