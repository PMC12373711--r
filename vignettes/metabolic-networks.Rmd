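---
title: "Point, line, plane: region, edge and network analysis of FDG-PET metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point, line, plane: region, edge and network analysis of FDG-PET metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The measurement model

`metaconn` analyses brain glucose metabolism measured by FDG-PET at three
nested scales. A subject's preprocessed PET volume in MNI space is first
**globally normalized**: every voxel is divided by the mean uptake over a
whole-brain binary mask, removing between-subject variability in injected
dose and clearance. All downstream quantities are therefore unitless SUV
ratios with a whole-brain mean of exactly 1.

- **Point** — the mean normalized uptake (SUVmean) of each atlas region,
  compared between groups with a pooled-variance two-sample *t* test,
  effect size as Cohen's *D* with the pooled SD,
  $d = (\bar x_1 - \bar x_2)\,/\,s_p$, and Benjamini–Hochberg FDR applied
  within each network's family of regions. A voxel-wise variant runs the
  same *t* test at every voxel of a network mask, takes FDR over the
  masked voxels, and reports suprathreshold 26-connected clusters with
  their size, unweighted centroid in MNI mm, and signed peak *t*.
- **Line** — metabolic connectivity. Because PET gives one number per
  region per subject, an "edge" between two regions is defined at the
  group level as the Pearson correlation of their SUVmeans **across the
  subjects of that group** (inter-subject covariance). Groups are
  compared edge-wise by the raw correlation difference
  $\Delta r = r_{1} - r_{2}$ under a permutation null: all subjects are
  pooled and re-split at random into the original group sizes $B$ times
  (default $B = 10000$), and the two-tailed p-value is
  $(\#\{|\Delta r^*| \ge |\Delta r_{\mathrm{obs}}|\} + 1)/(B + 1)$.
- **Plane** — whole-network metabolism. The seven canonical resting-state
  networks (visual, somatomotor, dorsal attention, ventral attention,
  limbic, frontoparietal, default) are treated as ROIs themselves; their
  SUVmean is the voxel-weighted mean over the network mask. The package
  correlates network SUVmeans with each other and with each member
  region across the pooled cohort, with the exact *t* transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ supplying two-tailed p-values.

## Assumptions

- Volumes arrive spatially normalized (MNI) and, typically, smoothed;
  the package performs no registration. When a pre-extracted
  subject-by-region table is supplied instead of volumes, global
  normalization is assumed already applied (a flag re-normalizes rows).
- Region SUVmeans are approximately normal within group — reasonable for
  averages over hundreds of voxels — so *t* statistics and Pearson
  correlations are meaningful; the edge comparison avoids any
  distributional assumption on $\Delta r$ by using permutation.
- Subjects are exchangeable under the null of no group difference; the
  subject is the only exchangeable unit because group-level connectivity
  admits no per-subject connectome.

# The atlas and its partition

Analyses are parameterized by an `atlas_definition`: a region catalogue
(id, name, abbreviation, network) plus an optional integer label volume
with its voxel-to-mm affine. The published 246-region parcellation does
not come with an authoritative mapping onto the seven cortical networks,
so the network assignment is a **required input column**, not a table
hard-coded in the package. Regions not assigned to any of the seven
(e.g. subcortical nuclei) carry `unassigned` and are excluded from all
network-level computation — excluded loudly, never dropped silently.
`make_fixture_atlas()` builds small deterministic atlases (cuboid regions
packed with a background margin, MNI-like 3 mm affine) for tests and
simulations.

# What the synthetic cohort emulates

`simulate_cohort()` draws, per group, subject region-vectors from a
multivariate normal with block covariance — one equicorrelated block per
network, zero off-block — with means equal to per-region baselines plus
any designed "point" effects, and per-pair overrides of single
correlations as "line" effects. The equicorrelated block is exactly the
shared-latent-factor construction
$x_r = \mu_r + \sigma_r(\sqrt{\rho}\, z_{\mathrm{net}} +
\sqrt{1-\rho}\,\varepsilon_r)$; the covariance is built explicitly
because edge overrides need it anyway, and every block is checked for
positive definiteness (nearest-PD repair with a warning, error if
irreparable). Draws below 0.01 SUV are resampled; at realistic
parameters this is a $<10^{-15}$ event.

Default study conditions: group sizes 174 and 206; baselines drawn once
per design seed from 0.78–1.35 with SDs 0.04–0.10, the range typical of
globally normalized grey-matter SUVmean; within-network inter-subject
correlation $\rho = 0.3$ — a **test default**, chosen as a moderate,
realistic coupling, not an empirical claim, since no published estimate
of this magnitude exists; covariates (age, sex, BMI, fasting glucose,
four vascular risk factors) drawn with the prevalences of the reference
cohort, independent of SUV. `render_volumes()` turns a cohort into
voxel data by painting each region's value into its voxels, adding
independent Gaussian voxel noise, and smoothing with a stated FWHM
(sigma = FWHM/2.3548; default 10 mm, the conventional PET kernel).

What the generator does **not** emulate: scanner physics, partial-volume
effects, anatomical variability, spatially structured noise, non-normal
heavy tails, or covariate–metabolism coupling (a hypertension hook
exists but is off, matching the reference analysis which reports and
does not adjust for the imbalance). Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the stated
model — not that real cohorts satisfy that model.

# Numerical and design choices

- **Pooled *t* by default.** Back-computing the reference effect-size
  column from its printed means/SDs is consistent with pooled-SD
  Cohen's *D*; Welch is available by flag. Sign convention everywhere:
  group 1 = patients, positive *t*/*D* = patient hypermetabolism.
- **$\Delta r$, not Fisher-z.** The raw correlation difference is exact
  under the permutation null and matches the "compare the matrices"
  framing; a Fisher-z variant would change nothing material at these
  sample sizes. The add-one p-value correction keeps $p \ge 1/(B+1)$,
  a valid FDR input.
- **FDR families.** Region tests: one family per network. Voxel tests:
  one family per network mask. Intra-network edges: one family per
  network matrix (analyses run per network, with per-network RNG
  streams derived by a stable string hash of the network name, so adding
  a network never changes another's p-values). The 21 inter-network
  edges form their own family. Network-level correlation analyses
  report raw p by default (FDR on request), matching how such results
  are conventionally reported.
- **Permutation reproducibility.** The pooled matrix is put into a
  canonical (lexicographic) row order before re-splitting, so results
  are invariant to how subjects happen to be ordered within a group;
  identical rows are exchangeable, so ties are inert.
- **Chi-square default is Pearson without continuity correction**; Yates
  and the exact hypergeometric test are exposed because printed clinical
  tables do not always state the variant. (The reference hypertension
  p of 0.016 sits between Pearson's 0.013 and Yates' 0.018 on the
  printed counts; the package reports, and does not guess, the variant.)
- **Pooled-cohort correlations.** The network-correlation analyses run
  on both groups pooled (n = 380) by default: the printed p-values of
  the reference analysis back-compute from the printed r exactly at
  n = 380 via the *t* transform, and at neither group size alone.
  Per-group mode is available.
- **Part-whole coupling.** The member region is *not* removed from its
  network mean before correlating (the reference analysis shows no sign
  of leave-one-out), but a leave-one-out mode exists because the
  coupling artefact is real — on fixture data it moves the median
  region-network correlation from ~0.8 to the designed ~0.3.
- **Network SUVmean is voxel-weighted** (the network is itself an ROI,
  and ROI SUVmean is a voxel average); the unweighted mean of region
  means is available for sensitivity checks. The volume path and the
  weighted-region-vector path agree to 1e-12 by construction and by test.
- **Label volumes must be integer** after load; floats are rounded only
  within 1e-6 of an integer, else the load fails. Voxel-to-mm mapping
  follows the NIfTI convention (R index $i$ maps through
  $A\,(i-1)$); cluster centroids are unweighted means of member voxel
  centres mapped through the affine.
- **Cluster connectivity is 26-neighbourhood with no minimum extent** —
  reference cluster tables report clusters as small as 25 voxels with no
  stated extent rule.
- **BH-FDR properties.** The adjustment is order-preserving with
  $q \ge p$; note it is *not* idempotent — re-adjusting an adjusted
  vector can only raise values (constant vectors are fixed points), and
  the package documents and tests exactly that.

# Problem sizes used by the test-suite and acceptance script

Simulation-backed checks run at the study's group sizes (174/206) on
compact fixture atlases — 14 regions (2 per network) on a 24-cubed grid
for calibration and the end-to-end pipeline, 21 regions (3 per network)
where null edges must be counted: type-I calibration uses 150 null
cohorts (2100 region tests, observed rejection ~0.04–0.05 at
$\alpha = 0.05$); edge-detection power uses 25 replicates of a designed
$\rho = 0.6$ vs $0.0$ edge at $B = 2000$ (detected at $q < 0.05$ in
every replicate, null-edge median $q \approx 0.7$); the exhaustive
enumeration oracle for the permutation p runs at $n_1 = n_2 = 4$ where
all 70 re-splits can be listed. These sizes were chosen so each property
is measured with comfortable statistical margin while the whole suite
stays quick to run.

# Known limitations

- Group-level connectivity cannot see individual differences: an edge is
  a property of a group sample, so no subject-level connectivity
  covariates or regressions are possible by construction.
- The voxel stage assumes the analysis mask is the FDR family; no
  random-field or cluster-extent inference is offered.
- The synthetic generator's independence of covariates and SUV means
  covariate-adjusted models are out of scope (none are implemented).
- With few regions per network, a single-region effect propagates
  visibly into its whole-network mean; the dilution seen in full
  246-region analyses is a property of atlas granularity, not of the
  code.
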