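# scquantal

Quantal analysis of single-cell qPCR gene induction.

When pituitary gonadotrope cells receive pulses of GnRH, immediate-early
genes (*Fos*, *Egr1*, *Egr2*, *Fosb*) do not ramp up smoothly: each cell
either switches a gene fully on or leaves it off, and raising the GnRH
concentration recruits *more expressing cells* at an unchanged per-cell
level. scquantal implements the analysis pipeline for Fluidigm-Biomark-style
single-cell qPCR experiments built around this all-or-none ("quantal")
picture, for researchers analyzing dose-response and time-course single-cell
Ct matrices.

## The model

With $n$ cells assayed at dose $c$, the number expressing gene $g$ is

$$k \sim \mathrm{Binomial}\!\left(n,\ p_g(c)\right),\qquad
p_g(c) = p_0 + (p_{\max} - p_0)\,\frac{c^h}{\mathrm{EC50}_g^{\,h} + c^h},$$

while the expression level in the on-state, measured as $41 - \mathrm{Ct}$,
is Gaussian and dose-independent. The per-dose MLE $\hat p = k/n$ with exact
Clopper–Pearson intervals is the assumption-free estimate; the
Hill-constrained binomial fit provides an EC50 per gene, and ordering genes
by EC50 reproduces the induction sensitivity hierarchy. The package covers:

* **IO** — Biomark-style Ct CSVs (sentinels `999`/`Undetermined`/empty), the
  $41-\mathrm{Ct}$ expression transform, long-format and MTX export;
* **QC & calling** — removal of wells with no housekeeping expression
  (*Eef1a*, *H2fz*, *Rps11*, *Rps25*), detected/mixture expressing calls,
  unimodal/bimodal modality labels;
* **Induction statistics** — activation probabilities with binomial SDs,
  induced-level dose-invariance ANOVA, exact time-point contrasts,
  co-induction (Venn) region counts;
* **Quantal model** — per-dose and Hill-binomial fits, profile-likelihood
  EC50 intervals, sensitivity ranking, posterior-predictive dispersion
  check;
* **Cell-cycle scoring** — five-phase gene-set scores with refinement,
  two-stage normalization, progression ordering;
* **Correlation reports** — log2(CPM+1) and from-definition pairwise
  Pearson matrices;
* **Synthetic ground truth** — generators for chips, cell-cycle counts and
  bulk profiles with the exact statistical structure the analysis assumes.

## Worked example

```r
library(scquantal)

sim   <- simulate_sc_qpcr(condition_design(times = 35, seed = 101))
e     <- ct_to_expression(sim$ct)              # 41 - Ct, undetected -> 0
qc    <- filter_failed_wells(e)                # housekeeping-based well QC
calls <- call_expressing(qc$expression)        # expressing iff expression > 0
s     <- summarize_induction(calls, qc$expression)
round(100 * xtabs(p_hat ~ gene + dose_nM, s), 1)
```

```
      dose_nM
gene      0  0.5    2    8   20
  Egr1  8.8  9.7 46.1 87.5 92.3
  Egr2  8.0  6.2 32.2 86.6 91.5
  Fos   4.4  3.5 42.6 90.2 96.6
  Fosb  4.4  1.8 11.3 75.0 94.9
```

Percentages of cells expressing each IEG rise steeply with dose — under 10%
with vehicle or 0.5 nM GnRH, above 90% at 20 nM — while the mean level in
expressing cells stays flat (one-way ANOVA per gene, all p > 0.15 here).
Fitting the Hill-binomial model and ranking by EC50:

```r
IEG  <- c("Egr1", "Fos", "Egr2", "Fosb")
fits <- lapply(setNames(IEG, IEG), function(g) {
  sg <- s[s$gene == g, ]
  fit_hill(sg$dose_nM, sg$n_expressing, sg$n_cells)
})
rank_sensitivity(fits, confidence = "profile")$ranking
```

```
     gene ec50 lower upper
Egr1 Egr1 2.20  1.81  2.80
Fos   Fos 2.35  1.97  2.86
Egr2 Egr2 2.76  2.24  3.50
Fosb Fosb 5.08  4.18  6.15
```

Egr1 and Fos are activated at lower concentrations than Egr2 and Fosb — the
recovered EC50 order (with 95% profile-likelihood intervals) matches the
generating hierarchy. The numbered scripts in `analysis/` run the complete
workflow (simulation, QC, calling, induction statistics, quantal fits,
cell-cycle scoring, correlation reports) and write all tables and figures
under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

## Package layout

```
R/                  implementation (IO, QC/calling, induction, quantal model,
                    cell cycle, correlation, generators, plots)
analysis/           numbered workflow drivers writing to results/
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
inst/extdata/       default cell-cycle phase gene sets (editable CSV)
```
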