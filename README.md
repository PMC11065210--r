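# phenomdiv

Image-based phenomic characterization and functional-diversity analysis of
genebank germplasm collections.

Genebanks hold many accessions (seed lots) per species but have few
quantitative tools to decide which accessions are phenotypically redundant
(candidate duplicates) and which are distinct (candidates for a core
collection). phenomdiv implements a complete pipeline:

1. **Image preprocessing** — color-card white balance, Otsu segmentation of
   organs photographed on white backgrounds, closed-outline tracing.
2. **Phenomic descriptors** — elliptical Fourier analysis of seed/leaf/pod
   outlines with normalized coefficients
   (`x(t) = A0 + Σ aₙ cos(2πnt/T) + bₙ sin(2πnt/T)`, likewise `y(t)` with
   `cₙ, dₙ`), summarized as PCA morphospaces (`PC1S`, `PC1L`, ...), and
   k-means colorimetry of organ pixels (10 colorimetric groups per organ,
   descriptors `R_i`, `G_i`, `B_i`, `prop_i`), plus exact earth-mover
   distances between color histograms for QC.
3. **Descriptor selection** — a 100-tree random-forest accession classifier
   (stratified 70/30 split) ranks descriptors by mean minimal depth (MDM,
   lower = more discriminating) and keeps the top 15 per descriptor set
   (phenomic, classical, combined).
4. **Functional diversity** — Gower distances over mixed-type descriptors,
   PCoA trait spaces, convex-hull area and vertex accessions on the first
   two axes, and per-species indices: functional specialization (FSpe),
   originality (FOri) and identity (FIde), all max-normalized to [0, 1].

A synthetic accession generator with known ground truth (species-structured
shapes in elliptical-Fourier coefficient space, Gaussian-mixture palettes,
classical trait tables with a designated duplicate pair and a designated
outlier species) makes every stage testable without field imagery.

## Worked example

The four numbered scripts under `analysis/` run the whole study on a
simulated panel of 16 accessions (5 species × 3 accessions plus a displaced
singleton species, 10 plants each, seed + leaf images):

```sh
Rscript analysis/01_simulate.R   # renders 320 organ images + classical table
Rscript analysis/02_extract.R    # images -> outlines -> EFA + colorimetry
Rscript analysis/03_select.R     # random-forest MDM selection per descriptor set
Rscript analysis/04_funcdiv.R    # Gower/PCoA spaces, hulls, FSpe/FOri/FIde
```

Output of the last two stages on the default seed (42):

```
Phe: OOB error 0.089 | validation error 0.042 | top 5: G_1S, PC3L, B_1S, R_4S, PC5L
Cla: OOB error 0.098 | validation error 0.042 | top 5: rhs_flower_color, secondary_seed_color, primary_seed_color, leaf_length, pod_length
Com: OOB error 0.000 | validation error 0.000 | top 5: rhs_flower_color, leaf_length, secondary_seed_color, R_1S, weight_100seed
Designated discriminative descriptor rhs_flower_color ranks 1 by classical MDM
Duplicate pair ACC001/ACC002 mutual OOB confusion: 0.71

      FE n FSpe_Phe FOri_Phe FSpe_Cla FOri_Cla FSpe_Com FOri_Com
1 SP_OUT 1     1.00     0.91     1.00     1.00     1.00     0.82
2   SP01 3     0.51     0.54     0.53     0.41     0.42     0.58
...
  type hull_area n_vertices n_axes
1  Phe     0.149          6      4
2  Cla     0.269          8      4
3  Com     0.184          6      4

Lowest nearest-neighbor originality (duplicate screen):
ACC001 ACC002 ACC005 ACC006
0.0116 0.0116 0.1438 0.1438
```

Reading it: every descriptor set classifies accessions with OOB error well
below the 25% precision bar; the engineered RHS color code is the top
classical descriptor by MDM; the designated duplicate pair ACC001/ACC002 is
heavily confused by the phenomic classifier (0.71 mutual OOB confusion) and
has by far the lowest nearest-neighbor originality — exactly the signature a
genebank would use to flag duplicates. The displaced singleton species
SP_OUT attains the maximum FSpe (exactly 1.00 under max-distance
normalization) in all three descriptor sets, and the hull vertex accessions
list the core-collection candidates per descriptor set.

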