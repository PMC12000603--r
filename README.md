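# rxnproto

Few-shot meta-learning for predicting whether a transition-metal-catalyzed
asymmetric hydrogenation of an olefin will be highly enantioselective.

## The problem

Asymmetric hydrogenation (AHO) installs a stereocenter by adding H2 across
a C=C bond under a chiral Ir/Rh/Co catalyst; the outcome of interest is the
enantiomeric excess (%ee), binarized here at a threshold (80 %ee by
default) into high/low selectivity. Literature AHO data is large in
aggregate but splinters into many small families of related reactions — a
few measurements per substrate/ligand combination. That regime defeats both
a single global classifier (the new family is under-represented) and a
per-family classifier (too few points). `rxnproto` is for computational and
synthetic chemists who want selectivity estimates for a new reaction family
from only a handful of labelled examples — or, with the cluster-matched
support protocol, from already-published reactions similar to the new ones,
with no new experiments at prediction time.

## The method

Reactions are featurized as 1544-dim composite vectors: 512-bit radius-2
circular fingerprints (or message-passing graph embeddings with a set2set
readout) of olefin, ligand and solvent, one-hot metal (3) and additive (2)
encodings, and three scaled condition scalars (pressure, temperature,
log10 S/C). The meta-learner is a **prototypical network**: an embedding
network `f` is trained episodically over many small tasks so that, given a
labelled support set `S`, each class is summarized by its prototype

```
c_k = mean{ f(x_i) : (x_i, y_i) in S, y_i = k }
```

and a query reaction `x` is classified by a softmax over negative
(squared-Euclidean) distances to the prototypes:

```
P(y = k | x) = exp(-||f(x) - c_k||^2) / sum_k' exp(-||f(x) - c_k'||^2)
```

Training minimizes the query negative log-likelihood over batches of 5
tasks (support/query 512/64). Tasks are built either by random
partitioning or by clustering the reaction space (UMAP to 10 dims +
k-means); evaluation reports AUPRC (primary, imbalance-sensitive) and
AUROC as mean ± standard error over repeated support/query splits, on
episode manifests shared exactly with the single-task baselines (random
forest, GNN, SVM, gradient boosting).

Everything is testable offline: a synthetic generator emulates the
statistical shape of literature AHO data (latent clusters of related
reactions, Rh-heavy metal imbalance, ~65% positive at 80 %ee,
cluster-linked selectivity).

## Worked example

The full pipeline on 2,000 synthetic reactions (a few minutes on one CPU;
shrink the sizes for a quicker demo):

```r
library(rxnproto)

# 1. synthetic reaction table with latent cluster structure
gen <- generateReactions(generatorConfig(nRecords = 2000, seed = 3))
ds  <- binarizeLabels(gen$reactions, threshold = 80)
ds
#> ReactionSet with 2000 reactions
#>   metals: Co=191 Ir=701 Rh=1108
#>   labels: 1302 high / 698 low selectivity

# 2. split, encode, build tasks
splits <- splitReactions(ds, c(1400, 400, 200), seed = 3)
scaler <- fitConditionScaler(splits$train)
X      <- encodeReactions(ds, scaler)          # 2000 x 1544
tasks  <- randomTasks(splits$train, 10, seed = 1)
vtask  <- randomTasks(splits$valid, 1, seed = 2)
ttask  <- randomTasks(splits$test,  2, seed = 3)

# 3. meta-train, then evaluate at support size 16, 10 support/query splits
model <- metaTrain(tasks, vtask, X,
                   protoNetConfig(maxEpisodes = 1000, valCheckEvery = 100,
                                  patience = 6, seed = 1),
                   scaler = scaler)
eps <- sampleEvalEpisodes(ttask, "episodic", 16, 128, 10, seed = 5)
metaTest(model, ttask, X, "episodic", 16, 128, 10, seed = 5, episodes = eps)
#> EvalReport [protonet | episodic | support 16]
#>   AUPRC 0.7678 +/- 0.0099  AUROC 0.7061 +/- 0.0145  (10 repeats)

# 4. a from-scratch random forest on byte-identical episodes
evaluateBaseline(baselineSpec("random_forest", seed = 2), ttask, X,
                 "episodic", 16, 128, 10, seed = 5, episodes = eps)
#> EvalReport [random_forest | episodic | support 16]
#>   AUPRC 0.7514 +/- 0.0078  AUROC 0.6687 +/- 0.0132  (10 repeats)
```

With 16 labelled examples of each new task, the meta-trained prototypical
network reaches AUPRC 0.768 ± 0.010 where a random forest trained from
scratch on the same 16 examples reaches 0.751 ± 0.008 (and AUROC 0.706 vs
0.669) — the meta-learner reuses embedding structure learned across all
training tasks, which a from-scratch model cannot extract from 16 points. `fitClusters()` /
`clusterTasks()` enable the cluster-matched support protocol
(`metaTest(..., protocol = "cluster_support")`), and `runExperiment()`
drives full grids (random/cluster/leave-one-cluster-out schemes, both
representations, thresholds 70/80/90) from one config. A thin CLI lives at
`inst/scripts/rxnproto` (`generate`, `experiment`, `report`).

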