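---
title: "Spatially aware colorization: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware colorization: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Categorical colorings of single-cell-resolution spatial maps usually come
from a fixed hue cycle: the color a cluster receives has nothing to do with
where its cells sit. When two clusters interdigitate, a palette that happens
to give them similar hues makes their boundary invisible. colorweave treats
coloring as an optimization problem over the spatial arrangement itself:
measure how strongly every pair of clusters is spatially interlaced, measure
how perceptually different every pair of palette colors is, and assign colors
to clusters so that the two structures agree — strongly interlaced pairs get
strongly contrasting colors.

# The interlacement model

## Degree of interlacement (DOI)

For cells with planar coordinates in micrometers, each cell's `k` nearest
neighbors (default `k = 30`) are found with an exact k-d tree. Two outlier
rules refine the neighbor graph before any score is computed:

* **sparse-type** — a cell with fewer than `k` other cells within radius
  `radius` (default 50 µm) sits in a sparsely populated region. Its neighbor
  list is truncated to neighbors at distance ≤ `radius`, so it cannot form
  long-range links that would overstate cluster contact.
* **orphan-type** — a cell with fewer than `orphan_min_n` same-cluster cells
  (default 1) among its retained neighbors is likely a stray; it is masked
  out entirely, as a source *and* as a target of neighbor relations, so it
  cannot inflate the apparent coverage of its cluster.

On the refined graph, the interlacement score from cluster $x$ toward
cluster $y$ is

$$I_{xy} \;=\; \sum_{i \in C_x} \frac{1}{|N_i|}
  \sum_{j \in N_i,\, j \in C_y} \frac{1}{\mathrm{Dist}(i,j)},$$

the per-cell mean inverse distance to neighboring cells of the other
cluster, summed over the cluster. Cells whose retained neighbor list is
empty contribute zero. The cluster interlacement graph (CI-graph) has the
clusters as vertices and $\max(I_{xy}, I_{yx})$ as symmetric edge weights,
with a zero diagonal.

Three readings of the formula were genuinely open and are pinned as follows:

* $|N_i|$ counts the neighbors retained after sparse-type truncation.
  Orphan-masked neighbors are excluded from the numerator but still counted
  in $|N_i|$; removing them from the denominator as well would silently
  re-normalize cells near masked strays upward.
* The division by $|N_i|$ is per source cell (each cell contributes the mean
  inverse distance over its own neighborhood), not a single global division.
* No additional normalization by $|C_x|$ is applied; the score scales with
  the number of participating cells, which is what lets sparse clusters
  register deliberately lower interlacement.

Numerical choices: coincident cells would make $1/\mathrm{Dist}$ diverge, so
distances are floored at $10^{-6}$ µm before inversion; neighbor ties at
identical distance are broken by cell index so repeated runs see identical
graphs. Coordinates are treated as planar Euclidean; three-dimensional input
is accepted with a warning, because the defaults (`k`, `radius`) are
calibrated against planar sections and a volume changes the density a radius
of 50 µm implies.

## What the simulation emulates

`simulate_cluster_pair()` draws two isotropic Gaussian point sets with
standard deviation 25 µm whose centers sit a scenario-specific distance
apart along the x-axis: mixed 10, overlapped 50, adjacent 70, isolated 120,
distant 300 µm. Dense sets have 100 cells, sparse sets 25. These five
topologies are the canonical pairwise relationships of cellular-resolution
spatial data, and the defaults are the package's study conditions: the tests
require the mean DOI over 20 replicates to fall strictly from mixed to
distant, and sparse–sparse mixed pairs to score below dense–dense ones.

`simulate_cluster_field()` extends this to many clusters on a jittered
square grid (default spacing 70 µm — the adjacent-scenario distance — with
±10 µm center jitter). At that spacing grid neighbors interlace to varying
degrees while opposite corners are isolated, so a single field exhibits the
full range of DOI values; that variation is what makes rank-based checks of
DOI-versus-color-contrast meaningful. What the generator does **not**
emulate: anisotropic or curved tissue domains, density gradients within a
cluster, segmentation noise, or label error. A passing test therefore shows
that the machinery is correct under idealized Gaussian geometry, not that
defaults are optimal for any particular assay.

# Palettes

## Graph-embedded palettes

`embed_palette()` embeds CI-graph vertices in 3D and reads the axes as
CIELab: axis 1 is min-max rescaled to lightness `L_range` (default
[20, 85], avoiding unusably dark or bright colors), axes 2 and 3 to the
full a/b ranges [−128, 127]. The embedding operates on the distance between
DOI *profiles* — each vertex's adjacency row as a feature vector. This
orientation matters: clusters that interlace nobody have near-zero profiles
and aggregate into a hub of near-identical colors, while a strongly
interlaced pair, each member carrying a large DOI entry at the other's
position, is pushed far apart. Low-DOI pairs therefore receive similar
colors (subtle variation is enough to separate clusters that never touch)
and high-DOI pairs receive distinct ones. The bounded transform
`1/(1+DOI)` used as a pairwise dissimilarity was considered and rejected:
it sends heavily interlaced pairs *close* in the embedding, the opposite of
the coloring requirement.

UMAP (uwot, single-threaded, seeded) is the default embedding;
classical MDS on the same profile distances is available as a deterministic
linear alternative and is used automatically for graphs with ≤ 3 vertices,
where neighbor-based manifold methods degenerate. UMAP is initialized from
the MDS coordinates rather than a spectral decomposition: the
initialization is then deterministic and well-defined even for very small
graphs.

Two numerical guards: an embedding axis whose range is below $10^{-6}$ of
the widest axis is pure eigen-noise and is mapped to the midpoint of its
target channel rather than min-max stretched — otherwise coincident
vertices would be scattered across a 255-unit channel by noise of order
$10^{-8}$. And because min-max rescaling is per-axis, relative distance
*orderings* are only coarsely preserved; the palette is a starting point,
and the assignment stage (below) is what finally aligns contrast with
interlacement. Generated Lab triples may fall outside the sRGB gamut; the
stored Lab values are canonical and the hex rendering is the channel-wise
clipped projection.

## Image-guided theme palettes

`image_histogram()` converts every pixel to CIELab and bins it on a
`bins_per_channel`³ grid (default 20³ = 8,000 possible binned colors). An
occupied bin is represented by the mean Lab of its member pixels — the
weighted centroid, so a solid region is recovered exactly rather than
snapped to a geometric bin center. Bins with centroid L outside
`L_range` and bins below the 3rd frequency percentile (strictly below, so a
flat histogram loses nothing) are discarded as non-theme colors.

`select_theme_palette()` pulls colors in descending frequency order,
damping every remaining frequency after each pull of color $b$:

$$f_a \leftarrow f_a\,\bigl(1 - e^{-(E(a,b)/\sigma)^2}\bigr),$$

with $E$ the CIEDE2000 difference and $\sigma = 80$ by default. A pulled
bin's own frequency is driven to zero ($E = 0$), so no bin is selected
twice; near-duplicates of a pulled color are all but eliminated while
distant colors keep most of their frequency.

`refine_palette()` then runs farthest point sampling: the `k_candidates`
(default 3) unselected bins farthest from the palette (minimum CIEDE2000)
are scored $S_a = w_s s_a + w_f f_a + d_a$, where $d_a$ is the FPS
distance, $f_a$ the frequency, and $s_a$ a linear-separation score. The
weights default to $w_s = 0.15$ and $w_f = 1/(0.0003\,P)$ for an image of
$P$ pixels. Three points were left open by the formula and are pinned here:
$s_a$ is the candidate's minimum redmean distance to the current palette;
$s_a$ and $d_a$ are min-max normalized over the candidate shortlist (the
raw terms are dimensionally incommensurate); and the member replaced is the
member of the current closest pair whose removal most increases the minimum
pairwise distance, ties broken by palette index. A replacement is accepted
only on strict improvement of the minimum pairwise separation — this
forbids oscillation, and because the procedure is deterministic, a rejected
replacement means a fixed point has been reached and iteration stops.
Otherwise iteration ends when the coefficient of variation of pairwise
palette distances (CIEDE2000) exceeds the CV of the CI-graph edge weights,
or at `20 × palette size` iterations.

# Color difference and CVD support

The color-difference graph (CD-graph) weights every palette pair with the
redmean difference

$$\bar r = \tfrac{1}{2}(R_1+R_2), \qquad
\Delta C = \sqrt{(2+\tfrac{\bar r}{256})\Delta R^2 + 4\,\Delta G^2 +
  (2+\tfrac{255-\bar r}{256})\Delta B^2},$$

computed on non-linear 8-bit sRGB channels as the constants imply.
CIEDE2000 is used only inside image-palette extraction and FPS refinement;
the CD-graph itself stays on redmean.

Dichromacy is simulated by a fixed single-plane projection in
Hunt–Pointer–Estévez LMS space: sRGB is linearized, mapped to LMS, the
missing cone response (L, M, or S for protanopia, deuteranopia, tritanopia)
is reconstructed as a linear combination of the remaining two with
coefficients solved so that the white point and one anchor primary (blue
for protan/deutan, red for tritan) are fixed, and the result is mapped back
and clipped to gamut. Because grays lie on the preserved white axis the
simulation leaves them unchanged, and being a projection it is idempotent
up to 8-bit quantization — both properties are tested. Under
`cvd_mode = "general"` an edge weight is the mean of four redmean values
(full vision plus the three simulated types); under a single type, only
that simulation is used. Severity-graded anomalous trichromacy is out of
scope.

# Assignment

With CI-graph adjacency $A_{CI}$ and CD-graph adjacency $A_{CD}$, an
assignment is a permutation matrix $P$ and its loss is

$$L(P) = \lVert P A_{CI} P^{\top} - A_{CD} \rVert_F .$$

Minimizing $L$ over permutations is a quadratic-assignment-type problem;
the optimizer is deliberately plain, matching the modest cluster counts of
real sections. A coarse stage samples `n_initial = 2000` uniform
permutations and keeps the best; a fine stage repeatedly swaps the colors
of a uniformly random cluster pair, accepting only strict decreases, and
stops after `max_swaps = 5000` attempts or `patience = 100` consecutive
non-improving attempts ("attempts", not accepted swaps, on both counters).
One seeded generator drives both stages in a documented order (coarse
draws, then fine-stage pair draws), so a seed reproduces the mapping
bit-for-bit. Strict-decrease acceptance keeps the incumbent on ties, which
prevents plateau cycling. The tests require this optimizer to hit the
brute-force global optimum (all $n!$ permutations) in ≥ 95% of runs for
$n \le 6$.

User-fixed colors (`fixed = c(cluster = "#RRGGBB")`) are honored by
restricting both stages to permutations that respect the fixes. A palette
larger than the cluster count is first trimmed to size by farthest point
sampling under redmean (fixed colors always retained); a smaller palette is
an error rather than a silent recycle.

# Multi-section integration

Cluster correspondence across two sections is scored either by Pearson
correlation of log1p-transformed cluster-mean expression over the top
`n_hvg = 5000` highly variable genes (variance of the log profiles,
computed jointly on both sections' cluster means — the simplest reproducible
rule) or, when both labelings cover the same cells, by intersection over
union of the member sets. A greedy pass repeatedly takes the global
maximum, records the pair, and zeroes its row and column, guaranteeing an
injective mapping; it stops when the maximum falls to the threshold or
below (0 for IoU, so zero-overlap pairs never match; 0.5 for expression
correlation). Ties are broken lexicographically by (row, column).

Matched clusters take the first section's label; unmatched clusters stay
distinct (name collisions get a section suffix). CI-graphs are then merged
over the unified labels with element-wise maxima — the same
max-symmetrization philosophy the CI-graph itself uses — and a single
assignment is optimized on the merged graph, which is exactly what makes
matched clusters render in identical hex colors across sections.

# Discernibility metrics

`fov_discernibility()` tiles the bounding box into `fov_size` squares
(default 500 µm, anchored at the minimum corner, half-open so boundary
cells belong to one tile) and scores each tile as the mean color difference
over *all* unordered cell pairs — same-cluster pairs contribute zero, which
is intentional: a tile dominated by one cluster scores low no matter how
good the palette is, reproducing the behavior of the metric on
low-diversity regions. The per-tile mean is computed from per-cluster
counts, and a brute-force pairwise loop is kept in the tests as the oracle.
For the synthetic grid fields used in the tests, a 100 µm tile is used
instead: the fields span only a few hundred micrometers, and a 500 µm tile
would swallow the entire field, making the score permutation-invariant
(with equal cluster sizes every color pairing is counted equally).
`palette_discernibility()` is the same idea without geometry: all
$\binom{n}{2}$ pairwise differences and their mean.

# Problem sizes and limitations

The test suite and the acceptance script run at desk scale by design:
5 × 20 simulated replicates for the DOI ordering, brute-force optimizer
comparisons at $n \le 6$ (50 random graph pairs per size), an 8-cluster
field for DOI-versus-contrast rank checks against 1,000 random assignments,
and 16-block images for theme recovery. The 8-bit/sRGB/D65 conventions are
fixed throughout; no appearance model (viewing conditions, background
adaptation) is applied. Known limitations: per-axis min-max rescaling of
the embedding preserves coincidence but only coarsely preserves distance
orderings (the assignment stage compensates); theme extraction cannot
produce more mutually distant colors than the sRGB gamut admits — the
maximin separation achievable inside L ∈ [20, 85] drops below ΔE00 ≈ 30
already at 8 colors; and DOI defaults assume planar sections at
single-cell resolution, not spot-level or 3D data.
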