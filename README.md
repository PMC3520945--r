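# tinterrain

Multi-scale terrain-complexity measures — rugosity, slope and aspect — on
triangulated irregular networks (TINs), for people who work with
fine-scale bathymetric reconstructions: benthic ecologists, marine
geomorphologists and the robotics groups that produce the meshes.

Divers traditionally measure rugosity by draping a chain over the
substrate and dividing the chain length by the taped distance between its
ends, `R_c = L / D`. `tinterrain` performs that measurement *virtually* on
a mesh, and replaces it with a more robust area-based index: for a
rectangular window of triangles,

```
R = A_s / A_p ,   A_s = Σ A_i ,   A_p = Σ A_i |n̂_i · n̂_p| ,
```

the ratio of the contoured surface area to its orthogonal projection onto
a reference plane. Projecting onto the horizontal plane (`R_ne`)
confounds rugosity with slope — a flat plane at slope α scores `1/cos α`.
Projecting onto the **PCA plane of best fit** through the window vertices
(`R_pca`) decouples the two: a tilted plane scores exactly 1, and the
fitted normal yields slope `α = acos(n̂·k̂)` and compass aspect
`ψ = atan2(n_E, n_N)` (plus northness/eastness) essentially for free.
The package also ships seeded synthetic terrain generators with known
analytic structure, mesh I/O (PLY/OBJ/STL, XYZ/CSV point clouds with 2.5D
Delaunay triangulation), a placement-sensitivity experiment and
correlation reports, and a small CLI (`exec/tinterrain`) over the same
functions.

## Worked example

```r
library(tinterrain)

# a 6 m x 6 m peak-and-trough surface at 2 cm resolution with 5 mm
# reconstruction noise: a rough stand-in for a diver-rig survey patch
terrain <- add_vertex_noise(
  generate_terrain(terrain_spec("peak_trough", extent = c(6, 6),
                                resolution = 0.02)),
  sigma = 0.005, seed = 1)

# virtual chain-tape rugosity along a 3 m transect
tr <- chain_transect(terrain, start = c(-1.5, 0.2), end = c(1.5, 0.2))
#> chain: L = 3.200 m, D = 3.000 m, R_c = 1.067 (151 vertices)

# windowed features at two scales over a grid of centres
ff <- multiscale_features(terrain, window_sizes = c(0.5, 1),
                          centres = "grid", stride = 0.5)
head(ff[["1"]][, c("centre_E", "centre_N", "R_pca", "R_ne", "slope", "aspect")], 3)
#>   centre_E centre_N R_pca  R_ne   slope aspect
#> 1     -3.0       -3 1.117 1.117 0.15693 -24.04
#> 2     -2.5       -3 1.114 1.114 0.09749 -27.80
#> 3     -2.0       -3 1.119 1.119 0.05990  59.54

# how repeatable is each measure under small placement errors?
ps <- translate_placements(c(-1.5, 0.2), c(1.5, 0.2))   # 49 placements
placement_sensitivity(terrain, ps, metric = "chain")
#> placement sensitivity (chain metric, 49 placements, 0 undefined)
#>   original 1.0666 | mean 1.2668  min 1.0545  max 2.7450  spread 1.6905
placement_sensitivity(terrain, ps, metric = "window", width = 1)
#> placement sensitivity (window metric, 49 placements, 0 undefined)
#>   original 1.1338 | mean 1.1381  min 1.1242  max 1.1666  spread 0.0424

correlation_report(ff[["1"]][, c("slope", "R_pca", "R_ne")])
#> correlation report over 169 records ( 0 incomplete )
#>       slope R_pca R_ne
#> slope  1.00  0.33 0.92
#> R_pca  0.33  1.00 0.44
#> R_ne   0.92  0.44 1.00
```

Reading the output: the 1 m-window records show `R_pca ≈ R_ne` where the
terrain is near-horizontal and aspect is erratic where slope is tiny
(expected — the facing direction of an almost-flat window is poorly
defined). Moving the transect by ≤ 40 cm changes chain rugosity by up to
1.7 (the worst placements snag two parallel vertex ribbons of the gridded
mesh), while the windowed measure moves by 0.04: the area-based index is
the repeatable one. The correlation matrix shows the decoupling
signature: slope predicts horizontal-projection rugosity almost entirely
(0.92) but PCA-plane rugosity only weakly (0.33).

The same pipelines are scriptable from a shell:

```sh
Rscript exec/tinterrain simulate --family peak_trough --res 0.02 --out mesh.ply
Rscript exec/tinterrain chain --mesh mesh.ply --start=-1.5,0.2 --end=1.5,0.2
Rscript exec/tinterrain features --mesh mesh.ply --window 0.5,1 \
    --centres grid --stride 0.5 --output feats.csv --asc R_pca
```

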