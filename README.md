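# rrnasip

High-sensitivity rRNA stable isotope probing (SIP) analysis for
identifying pollutant-degrading microorganisms in complex communities,
with a full synthetic-data generator for validating the inference.

## The problem

Recalcitrant pollutants such as 1,4-dioxane are degraded by rare,
slow-growing taxa that cannot be identified from 16S surveys alone. In an
rRNA-SIP experiment, a ¹³C-labeled substrate is fed to the community;
taxa that assimilate the label synthesize isotopically heavy rRNA, which
migrates to higher buoyant density (BD) in a CsTFA ultracentrifugation
gradient. Deep amplicon sequencing of the heavy gradient fractions of
labeled versus unlabeled incubations then reveals the incorporators —
even those at well below 1% relative abundance.

`rrnasip` implements the analysis side of such an experiment end to end:

* **Isotope chemistry** — δ¹³C (‰, VPDB) ↔ atom % via
  a = (1 + δ/1000) × 1.124; bicarbonate equilibrium
  δ_HCO₃⁻ = (δ_CO₂ − ε)/(1 + ε/1000) with ε = −7.93‰ at 25 °C; ideal-gas
  headspace pools; and a closed-vial ¹³C tracer budget
  (recovery = 100 × (gaseous + dissolved)/degraded).
* **Incorporator detection** — for every OTU *i* and heavy fraction
  *f* ∈ {1H, 2H, 3H}, a pooled-variance Student's *t*-test on replicate
  relative abundances (n = 3 per treatment) against the matched (or
  nearest lighter) unlabeled fraction, plus the fold change of group
  means; taxa significant in ≥2 independent fraction assays are
  multi-fraction confirmed.
* **Expression dynamics** — per-OTU rRNA copies/ml from qPCR totals ×
  amplicon relative abundances, qPCR standard curves
  (efficiency = 10^(−1/slope) − 1), and trajectory classification
  (linear increase / two-step increase / none) by a BIC contest between
  a line and a rising broken stick.
* **Monitoring** — removal efficiency, MLSS-scaled absolute abundances,
  yearly means and alpha diversity (Chao1, Shannon, reciprocal Simpson)
  for long-term full-scale reactor surveys.
* **Simulator** — seeded gradients (lognormal community, Gaussian BD
  bands, density shift linear in atom-fraction excess, multinomial
  sequencing at ~64,000 reads/library, RT-PCR amplification floor),
  chemistry series with an exactly closing mass balance, and expression
  time courses with known trajectory shapes.

## Worked example

```r
library(rrnasip)

sim <- simulate_gradients(sip_scenario(seed = 42))   # 200 OTUs, 5 labeled
res <- detect_incorporators(sim$counts, sim$metadata, sip_config())
head(res$summary, 5)
#>   otu_id   fractions_tested fractions_significant n_confirmations max_fold_change
#> 1 OTU_0053                3 1H,2H,3H                            3           45.1
#> 2 OTU_0024                3 1H,2H,3H                            3           20.4
#> 3 OTU_0166                3 1H,2H,3H                            3           19.4
#> 4 OTU_0120                3 1H,2H                               2           30.8
#> 5 OTU_0100                3 1H,2H                               2           26.5
```

The five top-ranked taxa — all multi-fraction confirmed, with heavy/light
fold changes of 19–45 and p-values below 1e-8 — are exactly the five
OTUs the scenario labeled (atom-fraction excess 0.5–0.99 at baseline
abundances 0.1–2%). Lower-ranked single-fraction calls at fold ≤ 3.3 are
the expected type-I background of uncorrected per-OTU testing.

The tracer mass balance over the simulated incubation:

```r
chem <- simulate_chemistry()            # 200 mg/l substrate, 74% mineralized
analyze_chemistry(chem$samples)$budget
#>   degraded_13c_mmol gaseous_13c_mmol dissolved_13c_mmol recovery_percent
#> 1            0.0454           0.0111             0.0218             72.4
```

0.0454 mmol of substrate-derived carbon was degraded per vial; the
background-corrected excess recovered in headspace CO₂ and dissolved
bicarbonate is 72.4% — the configured 74% mineralization times
(99 − 1.1)/100, because excess ¹³C under-counts gross tracer carbon by
the tracer-purity/background margin.

And the printed-arithmetic checks:

```r
tracer_budget(0.0466, 0.0144, 0.0201)$recovery_percent  # 74.03
delta_to_atom_percent(0)                                # 1.124
alpha_diversity(rep(5L, 8))                             # chao1 8, shannon ln 8
```

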