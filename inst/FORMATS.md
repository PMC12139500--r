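# File formats

All tabular files are comma-separated with a header row; all model and
summary files are JSON. Numbers are written at full precision.

## Cohort tables

A cohort is a pair of CSV files in one directory.

**concentrations.csv** — one row per sample.

| column | type | notes |
|---|---|---|
| `sample_id` | string | unique; join key |
| *one column per lipid species* | positive real | concentration, arbitrary but consistent units per lipid; column name = lipid name (whitespace trimmed; duplicates fatal) |

**metadata.csv** — one row per sample.

| column | type | notes |
|---|---|---|
| `sample_id` | string | join key |
| `age` | years | |
| `sex` | 0/1 | 1 = female |
| `bmi` | kg/m² | |
| `smoking` | 0/1 | current smoking |
| `hypertension_med` | 0/1 | |
| `diabetes` | 0/1 | |
| `sbp` | mmHg | systolic blood pressure |
| `total_cholesterol`, `hdl_c`, `triglycerides` | mmol/L | clinical lipids |
| `statin` | 0/1 | outcome of the prediction model |
| `cvd` | 0/1 | prevalent cardiovascular disease |

`read_cohort()` inner-joins the two files on `sample_id` and reports
dropped rows; malformed numeric cells are fatal with their location.

## Reference panel and correction factors

**panel.csv**: columns `lipid`, `concentration` (positive).
**correction_factors.csv**: columns `lipid`, `factor` (positive),
`method` (`qc_ratio` or `matched_subcohort`), `n_used` (replicate or pair
count).

QC replicate matrices are CSV with one column per lipid, one row per
replicate.

## Transfer bundles (`*.ftm.json`)

JSON object with fields:

| field | content |
|---|---|
| `format_version` | `"1.0"` |
| `variable_names` | all design columns, `"(Intercept)"` first |
| `lambda`, `n_train`, `penalty_factors`, `always_keep`, `provenance` | model metadata |
| `M_base64`, `v_base64`, `center_base64`, `scale_base64` | little-endian IEEE-754 doubles, base64; `M` is column-major `q×q` |
| `checksum` | byte sum of the encoded numeric payload mod 2^31−1 |

Round trips are bit-exact; version mismatches and checksum failures are
fatal.

## Ridge fits (`*.json`)

Plain-array JSON: `predictor_names`, `beta0`, `betas` (input scale),
`beta_std` (standardized scale, intercept first), `lambda`, `center`,
`scale`, `penalty_factors`, `standardize`, convergence metadata,
`reweighted`, `package_version`.

## Association tables

CSV with columns `lipid`, (`term`,) `beta`, `se`, `p`, `q`, `model_tag`
plus per-scan flags (`skipped`, `separation`). Crosstabs are JSON 3×3
count matrices.

## Sweep results

`sweep_long.csv`: `fraction`, `rep`, `method`, `cohort`, `auc`,
`n_lipids_kept`, `subset_seed` (one row per cell; methods within a
(fraction, rep) share `subset_seed` and hence the lipid subset).
`sweep_summary.json`: rows of `cohort`, `fraction`, `method`, `mean_auc`,
`sd_auc`, `n_reps`.

## Run metadata

Every CLI run writes `run_info.json` (resolved options, package version,
UTC timestamp) into its output directory. Ground truth from `simulate` is
`ground_truth.json` (`statin_deltas`, `cvd_betas`,
`statin_assignment_betas`, `cvd_model`, `log_means`; all named).
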