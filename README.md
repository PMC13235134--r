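# maskDRP

Biologically masked neural networks for classifying cancer cell-line drug
response from multi-omics data.

## The problem

Cell-line screening corpora measure, for thousands of (cell line, drug)
pairs, the concentration at which a drug halves cell viability (IC50). A
pair is called **sensitive** when the IC50 does not exceed the drug's
maximum screening concentration:

```
R(c, d) = 1  if  exp(ln IC50(c, d)) <= max_conc(d),   else 0.
```

Predicting this label for unseen pairs, unseen drugs, unseen cell lines and
unseen cancer types is useful for drug prioritization — but conventional deep
models are black boxes. maskDRP is for computational biologists who want the
prediction *and* the interpretation: its hidden layers are protein
complexes, pathways and drugs, wired only along annotated biology.

## The model

The network input is one integrated feature vector per cell line, built from
gene expression, copy-number variation, mutation VAF and protein expression
by availability-weighted averaging: a feature present in |M| omics layers
gets the mean of those |M| values (all layers min-max scaled to [0, 1]
first). Each layer `l` of the network computes

```
y(l) = ReLU[ (M(l) * W(l))ᵀ x(l-1) + b(l) ]
```

where `M(l)` is a binary mask with a 1 exactly where an annotated edge
exists (gene–protein complex from PPI, complex–pathway from pathway
membership with enrichment p <= 0.05, pathway–drug from target indicators)
and `*` is the Hadamard product — masked weights carry no signal and receive
no gradient. The hierarchy is pruned to nodes lying on a full
gene→complex→pathway→drug path before masks are built. The drug layer's
output is concatenated with the sample drug's 1024-bit Morgan (ECFP4)
fingerprint and a single sigmoid unit yields the sensitivity probability;
training minimizes binary cross-entropy with Adam (batch 64, 50 epochs,
learning rate 0.001 by default).

On top of the classifier sits a multi-level importance suite: per-gene
gradient / activation / variance / permutation scores and their normalized
combination, per-node activation importance at each hidden layer, and
frequency aggregation of top entities across independent training runs.

Because real screening corpora require large downloads, the package ships a
seeded synthetic-data generator that emulates every input table with a
planted response mechanism (known driver genes routed through the generated
hierarchy), so the whole pipeline — including importance recovery — is
testable offline.

## Worked example

```r
library(maskDRP)

spec <- syntheticSpec(nCells = 120, nGenes = 80, nProteins = 30, nPathways = 10,
                      nDrugs = 6, nDriverGenes = 8, fingerprintBits = 256, seed = 7)
study <- simulateDataset(spec)
study$hierarchy
#> BioHierarchy (unpruned)
#>   80 genes -> 30 protein complexes -> 10 pathways -> 6 drugs
#>   edges: 123 gene-protein, 79 protein-pathway, 20 pathway-drug

table(study$responses$label)
#>   0   1
#> 480 240

plan <- splitPairKFold(study$responses, k = 5, seed = 7)
res <- runExperiment(study$omics, study$hierarchy, study$drugs, study$responses,
                     plan, trainConfig(batchSize = 8, seed = 7))
print(attr(res, "summary"), digits = 3)
#>     metric  mean     sd n_folds
#> 1      auc 0.785 0.0308       5
#> 2     aupr 0.653 0.0702       5
#> 3 accuracy 0.726 0.0435       5
```

The 720 generated pairs split 2:1 resistant:sensitive by construction. The
summary rows are the across-fold mean ± sd of ROC AUC, area under the
precision–recall curve, and accuracy at 0.5; an AUC of 0.785 on this small,
noisy study means the network recovered most of the planted driver signal
from 576 training pairs per fold. `splitLODO()`, `splitLOCLO()` and
`splitLOCO()` give the drug-, cell-line- and cancer-type-exclusion
protocols, `ablationStudy()` the omics leave-one-out comparison, and
`geneImportanceReport()` / `aggregateRuns()` the interpretation layer.

A thin CLI over the same functions is installed at
`inst/scripts/maskdrp` with subcommands `simulate`, `build-graph`, `train`,
`evaluate`, `interpret`.

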