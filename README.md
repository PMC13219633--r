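# lhctools

Geometry and map-validation toolkit for photosystem–antenna supercomplexes.

Photosystems in algae and plants are wrapped by belts of light-harvesting
antenna proteins (LHC/FCP). Three geometric observations recur in recent
cryo-EM structures of these supercomplexes and this package turns each of
them into a reproducible measurement:

1. **Helix heights and membrane "rippling".** The photosystem core carries
   tall transmembrane helices (≈45–48 Å) while the surrounding antenna belt
   helices are much shorter (≈30 Å). Where the two meet, the membrane must
   locally deform — a rippled bilayer. `lhctools` detects transmembrane
   helices from Cα geometry alone, measures per-helix heights (arc length
   *and* projected span, since the two differ for curved helices),
   estimates the membrane frame, and summarises height mismatches between
   neighbouring subunits as a graph.
2. **Chlorophyll networks.** Excitation energy transfer (EET) is governed
   by macrocycle edge-to-edge distances. The package reduces each
   chlorophyll to its conserved tetrapyrrole ring, builds distance-cutoff
   EET candidate networks with stromal/lumenal sidedness, and compares
   chromophore complements between superposed models (gains/losses per
   binding site).
3. **Subfamily assignment from focused maps.** Antenna subfamilies differ
   in subtle helix geometry. Map–model Q-scores, deterministic rigid
   fitting and a model×map cross-fit matrix quantify when a focused map of
   a given resolution can — and cannot — discriminate candidate subfamily
   models.

A synthetic-data module generates helix bundles, core+belt scenes and
subfamily analog pairs with exact analytic ground truth, so every
measurement is validated end to end without any external files.

## Worked example

```r
library(lhctools)

# a synthetic supercomplex: 3 x 48 A core helices inside a belt of
# 6 x 31 A antenna helices, with five chlorophyll-like macrocycles
scene <- make_scene(
  rings = list(list(kind = "chl_a", center = c(0, 8, 9)),
               list(kind = "chl_c", partner = 1, distance = 6.0,
                    direction = c(1, 0, 0))),
  n_random_rings = 3, seed = 42)

mh <- measure_heights(scene$model, annotation = scene$annotation,
                      stromal_reference = c(0, 0, 50))
measures_table(mh$measures)[, c("chain_id", "subunit_label",
                                "height_A", "height_projected_A")]
#>   chain_id subunit_label height_A height_projected_A
#> 1        A          core    48.05              48.01
#> 2        A          core    48.05              48.01
#> 3        A          core    48.05              48.01
#> 4        B         belt1    31.08              31.01
#> 5        C         belt2    31.08              31.01
#> ...

g <- build_ripple_graph(mh$measures, mh$frame)
g
#> <ripple_graph> 9 helices, 18 neighbour edges (cutoff 16.0 A)
mismatch_between(g, "core", paste0("belt", 1:6), statistic = "max")
#> [1] 16.97   # the ~17 A core/belt height step

ch <- extract_chromophores(scene$model, mh$frame)
net <- build_eet_network(ch, cutoff = 15)
net
#> <eet_network> 5 chromophores, 10 edges (edge-to-edge <= 15.0 A)
head(net$edges, 3)
#>   source target edge_to_edge same_side cross_subunit mg_mg
#> 1      1      2        6.000      TRUE         FALSE 12.90
#> 2      1      3        4.233      TRUE         FALSE 10.31
#> 3      1      4       13.219      TRUE         FALSE 19.62
```

Can a 5 Å focused map tell two antenna subfamilies apart?

```r
an <- make_subfamily_analogs()    # two models differing only in helix C
M <- crossfit_matrix(an$models, an$maps[["5"]])
M
#> <crossfit_matrix> mean Q, candidates x maps:
#>        short   long
#> short 0.8314 0.7065
#> long  0.7212 0.8361
discriminate(M)
#>     map  best    best_q    margin ambiguous
#> 1 short short 0.8314257 0.1102264     FALSE
#> 2  long  long 0.8360900 0.1295418     FALSE
```

At 5 Å both maps are assigned to the correct model with a comfortable
margin; repeating this at 15 Å (`an$maps[["15"]]`) collapses the margins
to ≈0.01–0.03 and flags assignments as ambiguous — the point where
subfamily claims from a focused map stop being supportable.

## Command-line interface

`inst/cli/lhct` exposes the analyses as subcommands:

```sh
lhct synth   --out_dir scene --seed 7
lhct heights --structure scene/scene.pdb --annotation scene/annotation.csv --out_dir out
lhct ripple  --structure scene/scene.pdb --annotation scene/annotation.csv --out_dir out
lhct chroma  --structure scene/scene.pdb --out_dir out
lhct defaults
```

Exit codes: 0 success, 2 input error, 3 computation error. All cutoffs can
be overridden with `--key value` flags or a YAML config (`--config`).

## Methods

See the vignette source `vignettes/antenna-geometry.Rmd` for detection
thresholds, binning conventions, the Q-score reference profile, the rigid
fitter's acceptance tolerance, and the scope and limitations of the
synthetic generator.
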