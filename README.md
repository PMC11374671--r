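# ifnic

Spatial analysis of interferon-induced cell (IFNIC) colonies in infarcted
heart tissue.

After myocardial infarction, cardiomyocytes at the infarct borderzone can
activate cytosolic DNA sensing (cGAS–STING–IRF3) and mount a type I
interferon response. In spot-based spatial transcriptomics this appears as
small, contiguous patches of spots with elevated interferon-stimulated gene
(ISG) expression — IFNIC colonies — decorating the borderzone (BZ) between
the infarct zone (IZ) and remote myocardium (RZ). `ifnic` implements the
statistical machinery to detect, segment, and localize these colonies, to
characterize their niche microenvironment, and to analyze single-molecule
(MERFISH-style) point data for colony composition, extranuclear DNA and
nuclear morphology. It ships a fully synthetic data generator with known
ground truth, so every component is validated by parameter recovery.

## What it computes

- **ISG scoring and thresholding.** Per-spot ISG scores are gene-set sums
  (counts or log-normalized). A binary ISG−/ISG+ state is produced either
  with the published defaults (0.70 for *Ifit1*, 0.45 for *Rsad2*, 3.0 for
  the log-normalized ISG score, 10.0 for the counts-based score) or by
  calibrating a quantile threshold on negative-control samples that cannot
  mount an interferon response.
- **Colony segmentation.** On the hexagonal Visium lattice (55 µm spots,
  100 µm pitch, up to 6 first-order neighbours) a neighbourhood matrix
  `N ∈ {0..6}` counts ISG+ neighbours; colonies are connected components of
  ISG+ spots with ≥ 2 members (singletons are "scattered"). Colony area
  follows the 55 µm circular spot convention, `n · π(27.5)²`, with the full
  hexagonal cell `n · (√3/2)·100²` as an alternative.
- **Spatial statistics.** Moran's
  `I = (n/W) Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) / Σᵢ(xᵢ−x̄)²` with binary contiguity
  weights, one-sided genome-wide testing (analytic randomization moments
  plus a seeded permutation null, BH-adjusted), and a diffusion-time
  ("sepal-style") score: the time for explicit Euler diffusion on the
  degree-normalized lattice Laplacian to homogenize a pattern.
- **Monte Carlo localization.** Random connected spot sets are grown by
  uniform N+1 accretion (500 trials per size, sizes 1–12) and tested for
  overlap/adjacency with BZ-high spots; observed colonies are compared
  per size and pooled with two-sided Fisher exact tests (Yates-corrected
  chi-squared reported alongside).
- **Niche analysis.** Centroid/primary/secondary/tertiary rings around
  colony centroids (one ring = 100 µm), ring-vs-centroid Wilcoxon
  differential expression, IZ→BZ line scans, and 0–400 µm neighbour
  fraction profiles.
- **Point-cloud analyses.** DBSCAN (ε = 70 µm, min 10 points; ε selectable
  from the k-NN distance knee) separates clustered from scattered ISG
  transcripts; colony cell-type composition over positive cells; DNA loci
  are nuclear when ≥ 10 decoded spots fall within a 5 µm radius (5 µm
  z-edges excluded), otherwise extranuclear; nuclear solidity = mask area /
  convex-hull area.

## Worked example

```r
library(ifnic)

cfg <- sim_config(seed = 7)                 # ~3,000 spots, 3 BZ colonies
sample  <- make_lattice_sample(cfg)

isg <- gene_set("ISG_score", cfg$panel$gene[cfg$panel$role == "ISG"], "ISG")
pooled <- do.call(pool_scores, lapply(1:3, function(r)
  score_gene_set(make_control_sample(cfg, r)$counts, isg, "summed_counts")))
thr <- calibrate_threshold(pooled, quantile = 1 - 1/length(pooled))
thr$value
#> [1] 50

states <- binarize_score(score_gene_set(sample$counts, isg, "summed_counts"), thr)
colonies <- segment_colonies(unname(states), sample$graph)
colonies
#> colony_set: 3 colonies (sizes 5,6,4), 2 scattered spots

colonies <- colony_stats(colonies, sample$lattice, sample$graph,
                         scores = score_gene_set(sample$counts, isg, "summed_counts"))
colonies$stats$area_um2
#> [1] 11879.15 14254.98  9503.32

loc <- localization_test(colonies, unname(sample$truth$zone_of_spot == "BZ"),
                         sample$graph, seed = 7)
loc$pooled$p_fisher   # do colonies sit on the borderzone more than chance?
```

The threshold 50 is the top order statistic of the ISG score across three
pooled control replicates (~9,000 spots); the three planted colonies are
recovered exactly (sizes 5, 6, 4), two isolated spots remain "scattered",
and areas are spot counts times the 2,375.8 µm² circular spot area. All
three colonies touch the borderzone while only ~16% of random connected
sets do, giving a pooled Fisher p of 0.0039.

Or run everything at once:

```r
run_pipeline(list(seed = 7), outdir = "run7")   # full report bundle + manifest
```

```sh
Rscript scripts/run_pipeline.R --config my_config.yaml --outdir out --seed 7
```

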