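# benthoscape

Rule-based seabed habitat classification and predictive biotope mapping for
brackish shelf seas, after the workflow used to map the German Baltic Sea.

Marine-strategy reporting needs three congruent full-coverage map layers:

* **BHT** — broad habitat types, zone x substrate (EUNIS level 2), e.g.
  *Infralittoral sand*, *Circalittoral mud*;
* **OHT** — separately assessed protected habitat types (reefs 1170,
  sandbanks 1110, seagrass meadows, species-rich gravel/coarse-sand/shell
  areas, aphotic *Arctica islandica* mud);
* **HUB** — HELCOM underwater biotope codes down to the dominant taxon,
  e.g. `AB.H3L3` = Baltic aphotic muddy sediment dominated by ocean quahog.

benthoscape implements the whole chain as tested R functions:

1. **Sediment**: Folk-triangle / BSH level A-C classification of grain-size
   compositions and EUNIS substrate rules (mud >= 20 % fines; coarse when
   gravel > 30 % of gravel+sand; sand when sand > 70 %; mixed at 10-90 %
   hard cover), plus the Tauber-map translation.
2. **Hard bottom**: boulder points -> per-cell counts -> density classes
   (0 / 1-5 / > 5 boulders) and the geogenic hard-substrate rule (class 3,
   or class 2 on lag sediment).
3. **Stations**: dominance labelling (endobenthos > 50 % biomass;
   epibenthos >= 10 % total-area cover or >= 90 % on hard substrate; ACFOR
   midpoints) and the modelling conventions (merges, rare-dominant and
   Ophelia/Travisia exclusions), with a full HUB code parser/composer.
4. **Model**: per-realm multiclass random forests (implemented in-package,
   C++) with a 70/30 split, out-of-bag hyperparameter tuning, imbalance
   strategies, and Clopper-Pearson CI / Cohen's kappa / Hand-Till AUC.
5. **Maps**: majority rasterization (harder substrate wins ties), BHT
   composition with < 1 ha patch elimination, endo/epi intersection on
   hard-substrate dominance, HUB completion, OHT layering with
   reef-over-species-rich precedence, and exact area accounting.
6. **Synthetic seascapes**: seeded generators (gradients + smoothed noise,
   patchy sediment, Poisson boulders, Dirichlet biomass noise) with a known
   community rule, so label recovery is testable end to end.

## Worked example

```r
library(benthoscape)

samples <- data.frame(
  sample_id = c("st01", "st02", "st03"),
  mud    = c(0.42, 0.03, 0.10),
  sand   = c(0.55, 0.92, 0.55),
  gravel = c(0.03, 0.05, 0.35),
  fine = c(0.30, 0.70, 0.10), medium = c(0.20, 0.15, 0.20),
  coarse = c(0.05, 0.07, 0.25))
classify_sediment_table(samples)[c("sample_id", "bsh_a", "bsh_b", "eunis")]
#>   sample_id bsh_a bsh_b           eunis
#> 1      st01  Fsed    mS             mud
#> 2      st02  Csed    gS            sand
#> 3      st03 MxSed   msG coarse_sediment
```

st01 is muddy sand on the Folk triangle and, at 42 % fines, EUNIS mud;
st02 is a gravelly sand whose gravel share (5 %) stays below the 30 %
coarse-sediment criterion, hence EUNIS sand.

```r
dominant_endobenthos(c("Arctica islandica" = 61.2,
                       "Macoma balthica" = 30.1, "Peringia ulvae" = 8.7))
#> [1] "Arctica islandica"
compose_hub(photic = FALSE, substrate = "mud", community = "3L3")
#> [1] "AB.H3L3"
```

A grab with 61 % ocean quahog biomass is quahog-dominated (> 50 % rule);
in an aphotic mud cell that community becomes HUB `AB.H3L3` — which is also
the OHT category *Baltic aphotic muddy sediment dominated by ocean quahog*.

The full pipeline on a synthetic seascape:

```r
cfg <- seascape_config(width = 25000, height = 20000, cell_size = 1000,
                       seed = 42, n_grab = 300, n_video = 100)
res <- run_pipeline(cfg, "run42", ntree_grid = c(250, 500))
res$fits$endo
#> <biotope_fit> accuracy 1.000 (95% CI 0.960-1.000), kappa 1.000, AUC 1.000
#>   ntree 250, mtry 3, OOB 0.005
head(res$fits$endo$importance, 3)
#>  sediment     depth       doc
#> 23639.698  2096.068  1986.015
head(area_summary(res$bht, 1000), 4)
#>                                           class km2  pct
#> 1                            Circalittoral sand 156 31.2
#> 2 Circalittoral mixed sediment (hard substrate)  84 16.8
#> 3                             Circalittoral mud  79 15.8
#> 4                 Circalittoral coarse sediment  53 10.6
head(res$hub$areas, 4)
#>      class km2  pct
#> 1  AB.J3L9  95 19.0
#> 2    AB.J3  61 12.2
#> 3  AB.H3L3  58 11.6
#> 4 AB.I3L10  53 10.6
```

The synthetic community rule is deterministic in sediment, salinity and
depth, so the held-out accuracy of 1.0 and the importance ranking headed by
`sediment` and `depth` confirm label recovery, and the area tables show the
composed BHT and HUB layers (km² and percent of the mapped area). `run42/`
holds the layers (ESRI ASCII + legend CSVs), labelled stations, fit
reports, area tables and a reproducibility manifest.

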