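# SFBench

Does the accuracy of machine-learning scoring functions for
protein–ligand binding affinity merely reflect test proteins being
similar to training proteins? SFBench implements, as a tested R package,
the benchmark design that answers this: nested training sets carved by
train-versus-test protein-similarity cutoffs, four scoring functions
spanning the classical-versus-machine-learning divide, a repeated
stochastic training protocol, and Pearson-correlation learning curves —
plus a synthetic complex generator so the whole analysis runs at desk
scale with no external structural database.

It is aimed at method developers in structure-based drug discovery who
want to stress-test a scoring function's dependence on training-set
similarity, and at anyone who needs a reproducible, self-contained
re-implementation of this benchmark design.

## The design in brief

A fixed diverse test set is held out (by default 195 complexes: three
representatives of each of 65 protein families). For an ascending cutoff
schedule *c₁ < … < cₖ*, the training set at cutoff *c* retains the
complexes whose **maximum** similarity to *any* test complex is ≤ *c* —
one similar test protein is enough to exclude a training complex, and
ties at the cutoff are retained. The sets are nested by construction.
Each scoring function is retrained on every set and scored on the fixed
test set by the Pearson correlation Rp between predicted and measured
affinities (pKd units). Deterministic multiple linear regression (MLR)
is fitted once per set; random forests (RF) are retrained 10 times with
seeds baseSeed + 0…9, and the mean/median Rp and its min–max range are
reported. Learning curves plot Rp against the number of training
samples.

The default roster: **X-Score** (four X-Score-like energy terms, MLR),
**RF::X-Score** (the identical four terms, RF), **RF-Score** (36
intermolecular atom-pair counts within 12 Å, RF), and **RF-Score-v3**
(the 36 counts plus six AutoDock-Vina-style terms, RF).

## Worked example

```r
library(SFBench)

cfg <- runConfig("synthetic", masterSeed = 7L,
  synthConfig = benchmarkConfig(nTrain = 200,
    familyModel = familyModel(nTestFamilies = 12, nTrainOnlyFamilies = 6,
                              testRepresentatives = 3)),
  cutoffs = c(0.35, 0.5, 0.8, 1.0),
  roster = list(
    list(name = "X-Score", scheme = "xscore4",
         spec = modelSpec("MLR", nRepeats = 3)),
    list(name = "RF-Score-v3", scheme = "rf_v3",
         spec = modelSpec("RF", nTrees = 300, nRepeats = 3))))
res <- runPipeline(cfg)

res$report
#>   cutoff n_train percent
#> 1   0.35      27    13.5
#> 2   0.50      67    33.5
#> 3   0.80      88    44.0
#> 4   1.00     200   100.0

curveSummary(res$curve)
#>            sf cutoff n_train mean_rp median_rp min_rp max_rp range_rp
#> 1     X-Score   0.35      27   0.247     0.247  0.247  0.247   0.0000
#> 2     X-Score   0.50      67   0.183     0.183  0.183  0.183   0.0000
#> 3     X-Score   0.80      88   0.173     0.173  0.173  0.173   0.0000
#> 4     X-Score   1.00     200   0.202     0.202  0.202  0.202   0.0000
#> 5 RF-Score-v3   0.35      27   0.206     0.201  0.197  0.222   0.0247
#> 6 RF-Score-v3   0.50      67   0.389     0.388  0.387  0.391   0.0041
#> 7 RF-Score-v3   0.80      88   0.353     0.355  0.347  0.358   0.0112
#> 8 RF-Score-v3   1.00     200   0.589     0.591  0.572  0.603   0.0316
```

Reading the output: the partition report gives the size of each nested
training set (here 27 dissimilar-only complexes at cutoff 0.35 up to the
full 200). The curve summary shows the deterministic MLR scoring
function hovering around Rp ≈ 0.2 regardless of training size (its
repeat range is exactly 0), while the random-forest scoring function
climbs from 0.21 to 0.59 as increasingly similar training complexes
become available — the qualitative signature the benchmark is designed
to expose. `res$stability` additionally reports, at the largest cutoff,
each stochastic SF's repeat range and its gap-to-variability ratio
against the MLR baseline (here (0.591 − 0.202)/0.032 ≈ 12.3).

At full study scale (`benchmarkConfig()` defaults: 1105 training / 195
test complexes, 13-cutoff schedule, 10 repeats, 500 trees) the same run
takes a few minutes; `plotLearningCurve(res$curve)` draws Rp against
n_train, one line per scoring function.

Real data enter through files mode: point `runConfig(mode = "files",
inputDir = ...)` at a directory containing per-complex PDB/SDF
structures, an `affinities.csv`, a train×test `similarity.csv` and a
`manifest.json` split (the layout `exportBenchmark()` writes).
Precomputed descriptor tables (e.g. externally calculated energy terms)
can be ingested with `loadDescriptorTable()`.

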