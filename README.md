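# baepstd

Standardized intraoperative BAEP indexes for predicting hearing
preservation in cerebellopontine-angle (vestibular schwannoma) surgery.

## What it is for

Intraoperative brainstem auditory evoked potentials (BAEPs) are the standard
monitor of cochlear nerve function during vestibular schwannoma resection,
but their sub-microvolt amplitude makes the raw indicators — wave I–V
latencies (`La-I` … `La-V`), interpeak latencies (`La-I-III`, `La-III-V`,
`La-I-V`) and the wave I/V amplitudes (`Am-I`, `Am-V`) — unreliable: most of
what corrupts them (anaesthesia, temperature, electrical noise) hits both
ears equally. `baepstd` is for neuromonitoring and clinical-research teams
who record **binaural** BAEPs and want to use the healthy ear as a
synchronous reference that cancels this common-mode interference.

For an indicator value `a` on the affected side paired (recording interval
≤ 3 min) with `h` on the healthy side, the package computes

* the **standardized index** `STI = a/h − 1` (dimensionless; invariant under
  any interference factor multiplying both ears),
* the **intraoperative difference** `D = a_post − a_pre` between the
  pre-resection and post-resection phases, and
* the **standardized difference** `STD = D − (h_post − h_pre)`,

labels hearing preservation (HP = AAO-HNS class A–C) from pure tone average
(PTA) and word recognition score (WRS), and evaluates every indicator as a
predictor of HP with univariate and stepwise multivariate logistic
regression, ROC/AUC with Youden cutoffs, and paired DeLong AUC comparisons.
A seeded synthetic cohort generator (binaural feature streams with shared
common-mode drift, affected-side-only injury tied to a latent
cochlear-function variable, and audiometry generated from the same latent)
makes the whole pipeline testable without patient data; a waveform
synthesis/extraction layer round-trips the measurement conventions.

## Worked example

```r
library(baepstd)

report <- run_pipeline(pipeline_config(
  simulation = sim_config(n_patients = 127, seed = 1)))
print(report)
#> BAEP analysis report: 127 patients (seed 1)
#>   preop HP 78/127 (61.4%); postop HP 40/78 (51.3%)
#>   AUC raw_post_am_v = 0.921
#>   AUC sti_post_am_v = 0.984
```

78 of 127 simulated patients have preserved hearing before surgery (the
generator targets the ~66% preoperative HP rate typical of surgical series;
61.4% is one binomial draw), and 51.3% of those keep it afterwards. The
post-resection standardized wave-V amplitude (`sti_post_am_v`) discriminates
postoperative HP better than the raw amplitude, and the paired DeLong test
says the difference is real:

```r
print(report$auc_tests$post_sti_am_v_vs_raw_am_v)
#> Paired AUC comparison: 0.984 vs 0.921 (z = 2.594, p = 0.009494)

print(report$roc$sti_post_am_v)
#> ROC sti_post_am_v: AUC 0.984, cutoff >= -0.4278 (sens 95.0%, spec 94.3%), 40 pos / 87 neg
```

i.e. patients whose affected-side wave-V amplitude stays above 57% of the
healthy side's (`STI ≥ −0.43`) are predicted to keep hearing, with 95.0%
sensitivity and 94.3% specificity on this cohort.

The chain underneath is available piecewise: pair one patient's streams,
summarize a phase, and standardize —

```r
coh   <- simulate_cohort(sim_config(n_patients = 2, seed = 42))
feats <- subset(cohort_features(coh), patient_id == "P001")
pairs <- pair_streams(subset(feats, side == "affected"),
                      subset(feats, side == "healthy"))
compute_sti(summarize_phase(pairs, "pre_resection"))
#> Standardized indexes (STI, pre_resection)
#>     la_i    la_ii   la_iii    la_iv     la_v la_i_iii la_iii_v   la_i_v
#>  -0.0041  -0.0054   0.0021  -0.0031   0.0595  -0.0087   0.1841   0.0759
#>     am_i     am_v
#>   0.0447  -0.4358
```

This patient's pre-resection wave-V latency already runs 6% above the
healthy side and its amplitude 44% below — an affected ear at risk —
while waves I–IV sit within a percent of the reference, as they should.

A shell entry point wraps the same functions
(`inst/scripts/baep-pipeline.R`): subcommands `simulate`, `extract`,
`standardize`, `evaluate`, `report`, `all`, e.g.

```sh
Rscript inst/scripts/baep-pipeline.R all --config c.yaml --seed 7 --out run1
```

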