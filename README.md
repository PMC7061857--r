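# lignoquant

Quantitative *in situ* analysis of the Wiesner test (phloroglucinol/HCl),
the classic histochemical stain whose purple chromophore reports
coniferaldehyde residues in lignified plant cell walls. The package is
aimed at plant cell-wall researchers who image paired unstained/stained
brightfield sections and want cell-type-, layer- and neighbour-resolved
absorbance numbers with honest statistics — plus a synthetic-section
generator so every stage of the analysis can be validated against known
ground truth without any micrographs.

## The model in brief

Brightfield pixels are read as optical density, `A = log10(255 / pv)` on
the 8-bit grey intensity, and the stain-specific signal is the per-pixel
difference between the registered stained and unstained frames,

ΔA = log10(255 / pv_stained) − log10(255 / pv_unstained),

with a scalar offset from a non-lignified reference region removed.
On top of that quantitative surface the package builds:

* **registration** — rigid (phase correlation + Nelder–Mead on a
  gradient-magnitude correlation cost, ≈0.03 px / 0.01° on clean pairs)
  and elastic (per-block Lucas–Kanade flow, smooth composed field);
* **quantify** — absorbance-difference maps, seeded non-overlapping
  circular points per cell type (50 × 12 px by default, i.e. 0.7 µm at
  0.179 µm/px), staining time courses with plateau detection,
  area-weighted totals, false-colour maps, cambium-distance binning;
* **layers** — double-wall transects classified into CML / S1 / S2 / S3
  (CML central 500 nm; S1 adjacent 500 nm; S2 at 0.1–0.35 & 0.65–0.9 and
  S3 at 0.02–0.1 & 0.9–0.98 of normalised width);
* **cooperativity** — adjacency-conditioned correlation differences
  Δr = r(A adj B, B) − r(A self, B), Williams' test for dependent
  correlations (t, n−3 df), relative-impact fold changes, directed
  network export (JSON/DOT);
* **stats** — Tukey-HSD and Kruskal–Wallis/Holm compact letter displays,
  range-normalised hierarchical clustering, centred PCA with 95 % data
  ellipses, correlation panels and per-wavenumber spectral correlation
  maps;
* **colorimetry** — hue from absorbance spectra via the CIE 1931 2°
  observer, per-point HSV, fixed-primary colour deconvolution;
* **polymer** — GPC metrics (Mp, Mn, Mw, PDI) and the
  phloroglucinol-condensation estimate from a weight-average mass shift.

## Worked example

Render three synthetic wild-type stem sections (sensor noise 2 grey
levels, 3-px misregistration), register and subtract each pair, sample 50
twelve-pixel points per cell type, and compare cell types to metaxylem:

```r
library(lignoquant)
exp <- run_section_experiment("arabidopsis", n_sections = 3, seed = 7,
                              noise_sd = 2, shift_mag_px = 3)
type_deficits(exp$table, reference = "MX")
#>   cell_type   mean_dA deficit_pct
#> 1        IF 0.4844375 49.68911142
#> 2        LP 0.4836977 49.76593774
#> 3        MX 0.9628879  0.00000000
#> 4        PX 0.2367577 75.41170830
#> 5        XF 0.9622360  0.06770436
```

The generator encoded relative wall absorbances MX = XF = 1,
IF = LP = 0.5, PX = 0.25; the pipeline reads back the interfascicular
fiber deficit at 49.7 % and the protoxylem deficit at 75.4 % — the
wild-type contrast pattern, recovered through registration, subtraction
and sampling rather than copied from the truth raster.

The polymer worked example is one call:

```r
condensation_fraction(1595, 2431, monomer_da = 160, adduct_da = 125)
#> [1] 67
```

a 1595 → 2431 Da weight-average shift with 160-Da coniferaldehyde
residues and 125-Da phloroglucinol adducts means about 67 % of residues
formed condensation products. And the chromophore's spectrum maps to the
expected purple:

```r
spectrum_to_hue(make_spectrum(list(c(550, 30, 1))))$hue
#> [1] 288.6
```

A full orchestrated run (sections → registration → quantification →
layer profiles → cooperativity → statistics, with a hash-stamped
manifest) is:

```r
run_pipeline(pipeline_config(out_dir = "wiesner-run", seed = 1))
```

or from a shell, `Rscript inst/scripts/wiesner-run.R --seed 1 --out wiesner-run/`.

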