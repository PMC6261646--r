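# snorkelr

Quantitative analysis of **membrane-snorkeling basic residues** and the
intramembrane ionic protein–lipid interactions they mediate, modeled on the
integrin αLβ2 (LFA-1) transmembrane heterodimer in T cells.

Many single-span transmembrane domains (TMDs) carry a lysine or arginine
near the TMD/cytoplasmic-domain (CD) border whose charged sidechain
"snorkels" up into the lipid headgroup region. In integrin β2, this
snorkeling Lys (K702, six residues from the TMD/CD border of the I679–L707
TMD) ionically binds the phosphate group of acidic phospholipids,
stabilizing the αL/β2 transmembrane dimer and keeping the integrin in its
low-affinity conformation; intracellular Ca²⁺ competes for the phosphate
and releases the brake. `snorkelr` implements the analysis chain such a
study runs, with tidyverse-style data-frame-in/tibble-out functions:

- **Survey** — scan TMD annotation tables for intramembrane Lys/Arg,
  classify content (`K_only` / `R_only` / `K_and_R` / `none`), and
  histogram the distance of each basic residue from the TMD/CD border
  (distance 1 = the border-most TMD residue).
- **NMR titration statistics** — chemical shift perturbation
  Δδ = √((Δδ_HN)² + (0.154·Δδ_15N)²); per-residue intensity ratios I/I₀;
  paired t comparison of dimerization profiles; the Ca²⁺ **double ratio**
  R_D/R_M = (I_Ca/I_0Ca)_dimer / (I_Ca/I_0Ca)_monomer, which cancels
  nonspecific salt attenuation and isolates specific dimer
  destabilization; paramagnetic (16-DSA) depth classification.
- **FRET** — donor-dequenching efficiency E = 1 − F_pre/F_post per cell,
  labeling QC, group summaries with Welch/pooled t tests.
- **Calcium** — Grynkiewicz-style Indo-1 ratiometric calibration
  ([Ca²⁺] = K_d·(R − R_min)/(R_max − R)), bicelle q = long-chain/DHPC,
  mole percentages, and titration-ratio → absolute-concentration
  arithmetic.
- **Lipid SDF** — voxel-based spatial distribution function of a lipid
  species (1 Å³ voxels over the inner-leaflet box
  [−40, 40]×[−40, 40]×[−40, 0] Å³), xy projection, protein Cα overlay,
  enrichment scores and radial profiles.
- **Synthetic data** — deterministic generators with recorded ground truth
  for every input the pipeline consumes, so the whole chain is testable
  without external data.

## Worked example

```r
library(snorkelr)

# the beta2 TMD and its snorkeling lysine
span_length(residue_span(679, 707))
#> [1] 29
border_distance(702, 679, 707, "C")
#> [1] 6

# NMR sample composition: 24 mM POPG + 48 mM POPC over 240 mM DHPC
bicelle_q(c(POPG = 24, POPC = 48), 240)
#> [1] 0.3
mole_percent(c(POPG = 24, POPC = 48))
#> # A tibble: 2 x 3
#>   species    mM mole_percent
#>   <chr>   <dbl>        <dbl>
#> 1 POPG       24         33.3
#> 2 POPC       48         66.7

# a synthetic Ca titration: the double ratio recovers the specific
# destabilization of the dimer (1.15 at the top Ca level by default)
t <- gen_titration(seed = 2)
dr <- double_ratio(t$dimer, t$monomer)
double_ratio_summary(dr)
#> # A tibble: 5 x 4
#>   ca_ratio     n  mean     sd
#>      <dbl> <int> <dbl>  <dbl>
#> 1   0.03      29  1.02 0.0476
#> 2   0.06      29  1.04 0.0368
#> 3   0.1       29  1.09 0.0453
#> 4   0.14      29  1.13 0.0530
#> 5   0.167     29  1.14 0.0516
```

The summary shows R_D/R_M rising with the Ca:phospholipid ratio toward the
injected destabilization factor — the signature of Ca²⁺ specifically
weakening the transmembrane dimer, independent of the per-level salt
attenuation (which cancels exactly in the double ratio).

Result objects have `tidy()`/`glance()` methods and `autoplot()` views
(`autoplot(survey_fractions(records))`, `autoplot(project_xy(grid))`, ...).

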