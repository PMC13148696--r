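# nichescape

`nichescape` is an R package for macroecologists who want to ask whether the
geography of species richness is shaped by the climatic niches of the species
that co-occur: do species-rich assemblages hold species with *narrower*
niches (niche packing), with niches *closer to the average climate* of the
region (marginality), or with niches *closer to the reconstructed ancestral
niche* of their clade (phylogenetic niche conservatism)?

It implements the full analysis chain as tested, reusable functions:

1. **Occurrence cleaning** — coordinate-precision filter (decimal digits as
   written), one record per raster pixel, seeded distance thinning, and a
   minimum-unique-localities rule.
2. **Climate space** — raster-stack handling, study-area masking, and a
   standardized (correlation-matrix) PCA with fixed component signs.
3. **Ellipsoid niche models** — minimum-volume ellipsoids containing exactly
   `ceiling(0.95 n)` of the occurrence environments (5% omission), fitted by
   a seeded multi-start concentration search; a point is "suitable" iff its
   squared Mahalanobis distance to the niche centroid is within the coverage
   radius:

   `inside(x) ⇔ (x − μ)ᵀ Σ⁻¹ (x − μ) ≤ c²`,  `volume = V_d √det(Σ) c^d`

4. **Ranges and assemblages** — binary projection to geography, a minimum
   convex polygon + buffer accessibility constraint, and a presence–absence
   matrix (PAM) on a coarse equal-area grid from which richness and per-cell
   mean niche properties are mapped.
5. **Comparative analysis** — BM, OU, early-burst and rate-trend models of
   niche-centroid evolution fitted by ML on a phylogeny, AIC/Akaike-weight
   selection, GLS root reconstruction, and Mahalanobis/Euclidean distances to
   the ancestral niche.
6. **Spatial statistics** — simultaneous autoregressive error models
   `y = Xβ + u`, `u = λWu + ε` over three weight schemes × two distance
   classes with AIC selection, Moran's I, and a Spearman screen (|ρ| > 0.7)
   that keeps correlated predictors in separate models.
7. **Null models** — a spreading-dye geometric-constraint null (cohesive
   random ranges of conserved size) and a property-shuffle null, each
   refitting the SAR specification to give an add-one permutation p-value per
   property.
8. **Synthetic scenarios** — seeded generators for autocorrelated climate
   landscapes, pure-birth phylogenies, OU-evolved niches and occurrence
   samples, so the entire pipeline is testable offline with known truth.

## Worked example

```r
library(nichescape)

scen <- make_scenario("breadth_gradient", master_seed = 42,
                      n_species = 20, n_rows = 120, n_cols = 120,
                      n_points = 40)
run  <- run_pipeline(run_config(scenario = scen, master_seed = 42,
                                n_null_reps = 100, null_predictors = "NB"))
print(run)
#> <pipeline_run> 20/20 species modeled, 144 assemblage cells
#>   stages: clean -> pca -> enm -> ranges -> pam -> properties -> comparative -> sar -> nulls
```

All 20 synthetic species pass cleaning and modelling, and the nine stages run
under one master seed. The SAR weight selection table for the multivariate
model (`richness ~ NB + ...` after the correlation screen) looks like:

```r
run$sar$fits$multivariate[[1]]$selection$table
#>   weights      AIC    logLik    lambda error
#> 1   W/min 291.2347 -140.6174 0.7598268
#> 2   S/min 292.5090 -141.2545 0.8556094
#> 3   C/min 294.6547 -142.3274 0.8116414
#> ...
```

i.e. the row-standardized weights at the smaller distance band minimize AIC,
and `lambda` is the spatial-error parameter of each candidate fit. The
breadth-gradient preset builds "rich assemblages are made of narrow-niche
species" into the data, and the pipeline recovers it: the SAR slope of
richness on mean niche breadth is negative (`run$nulls$observed["NB"]` is
-0.53 here) and more extreme than all 100 spreading-dye replicates
(`p = 1/101 ≈ 0.0099`); at this toy size the property-shuffle null is less
sharp (`p = 0.14`), and reaches significance at the default scenario scale
of 60 species on a 300 x 300 km landscape.

`report(run, "out/")` writes a coefficient table (Approach, Model, Estimate,
p-value per retained predictor) and a PDF of richness/property maps plus
null-slope histograms. A thin command-line wrapper lives at
`inst/scripts/nichescape.R` (`simulate` and `run` verbs).

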