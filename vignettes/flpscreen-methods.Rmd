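---
title: "Models and methods behind flpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flpscreen)
library(dplyr)
```

# Scope

`flpscreen` reconstructs, as tested and reusable code, the quantitative
workflow of a cross-species neuropeptide GPCR pharmacology study: the
*C. elegans* FMRFamide-like peptides (FLPs) and their NPR receptors screened
side by side with the human NPY/RFamide system in HEK293 second-messenger
assays, followed by behavioral assays in worms and a matrix-intersection
argument that nominates the in vivo ligand of a receptor. The package covers
simulation of plate-reader screening data from explicit ground truth,
normalization and activation calling, five-grade interaction-matrix
construction, G-protein coupling-preference calling, four-parameter logistic
(4PL) concentration-response fitting with reference-normalized Emax,
C-terminal peptide motif classification, avoidance/bordering statistics, and
candidate-ligand inference. Wet-lab protocols, phylogenetics, receptor
sequence analysis and figure-faithful rendering are out of scope.

# The readout model

Second-messenger screens are simulated per receptor x pathway stratum from a
4PL ground truth. Let $o(c) = c^h / (c^h + \mathrm{EC}_{50}^h)$ be the
fractional occupancy at concentration $c$ with Hill slope $h$. Stimulatory
readouts (CRE-luciferase cAMP for G$_s$; IP accumulation for G$_q$,
G$\alpha_{16}$ and the chimeric G$\alpha_{\Delta 6qi4myr}$) have mean well
signal

$$\mu(c) = b\,\bigl(1 + (w - 1)\, E\, o(c)\bigr),$$

where $b$ is the basal signal, $w > 1$ the receptor's maximal fold-of-basal
window and $E \in [0,1]$ the pair's efficacy as a fraction of that window.
The G$_{i/o}$ readout measures inhibition of forskolin-stimulated cAMP:

$$\mu(c) = b\, f\, \bigl(1 - E\, o(c)\bigr),$$

with $f$ the forskolin fold over basal (default 20; only the *fold of
forskolin* ratio matters downstream, so the absolute value is a free scale).
Buffer wells measure $b$; forskolin control wells $b f$. The two promiscuous
IP channels are modelled as G$_q$-like readouts with their own windows, which
is how chimeric-G$\alpha$ rerouting behaves in practice.

Noise is multiplicative log-normal per well, parameterized by a coefficient
of variation (default 10%): plate-reader luminescence/HTRF signals are
positive and heteroscedastic, which an additive Gaussian would misrepresent.
An optional log-normal experiment-level scale factor (default 5% CV)
emulates plate-to-plate variability; because normalization divides each well
by its own experiment's control mean, this factor cancels and only inflates
control-estimation noise, as in real campaigns. Replication defaults to
three independent experiments in technical triplicate, and the primary
screen uses 100 nM and 10 uM, the conventional two-point design for this
receptor family.

What the generator does **not** emulate: receptor expression and trafficking
differences, transfection efficiency, signal drift within a plate, edge
effects, or kinetic (non-equilibrium) responses. Passing the recovery
benchmarks therefore shows the statistical machinery is correct under the
stated noise model, not that any real campaign meets that model.

# Normalization and activation calling

Wells are normalized per receptor x pathway x experiment to *fold of basal*
(buffer mean) or *fold of forskolin* (forskolin-control mean, G$_{i/o}$
only); condition summaries are means +/- SEM across experiments, with the
experiment as the unit of replication.

A condition is **active** when it passes the threshold AND is statistically
distinct from its control: threshold 2-fold over buffer for stimulatory
readouts, 20% inhibition of the forskolin signal for G$_{i/o}$ (both
boundary-inclusive -- the source conventions state the cut numbers only),
and significance from a one-way ANOVA over all conditions of the stratum
followed by Dunnett's many-to-one comparisons against the control at
adjusted $p < 0.05$ (via `multcomp`). The ANOVA runs on per-well folds; on
degenerate zero-variance input (noise-free simulation) significance falls
back to exact mean comparison, so noise-free calls reduce to pure threshold
calls.

The receptor's **maximal signal** follows two rules: for nematode receptors,
the strongest response any panel peptide elicits (their true endogenous
maximum is unknowable from a finite panel); for human receptors, the
response to the declared endogenous agonist at top concentration. Responses
are then expressed as fractions of the window,
$\phi = (\text{fold} - 1)/(\text{fold}_{\max} - 1)$ for stimulatory
readouts and $\phi = (1 - \text{fold})/(1 - \text{fold}_{\max})$ for
G$_{i/o}$, so 0 is basal and 1 the receptor maximum on either scale. The
normalization scale (fold-of-basal rather than raw signal) is a design
choice; it makes windows comparable across receptors.

## The five-grade scheme

The verbal grading of two-concentration screens is made mechanical with
three configurable cutpoints: `full = 0.8` (what counts as full receptor
activation), `mid = 0.35` (separating a just-above-threshold from a roughly
half-maximal 10 uM response), and `delta = 0.10` (the equality band for the
partial-agonist flag). With $\phi_L, \phi_H$ the window fractions at 0.1 and
10 uM and $a_L, a_H$ the active flags:

| grade | rule |
|-------|------|
| none  | neither active |
| i     | only 10 uM active, $\phi_H <$ mid |
| ii    | only 10 uM active, $\phi_H \ge$ mid |
| iii   | 0.1 uM active, $\phi_H <$ full |
| iv    | both active, $\phi_L <$ full $\le \phi_H$ |
| v     | 0.1 uM active, $\phi_L \ge$ full |

The asterisk (high-affinity partial agonism) is an orthogonal flag: both
concentrations active, $|\phi_H - \phi_L| \le$ delta, and $\phi_H <$ full.
The combination "inactive at 0.1 uM but full at 10 uM" has no slot in the
verbal scheme and is assigned grade ii here. The cutpoints quantify verbal
descriptions ("~50% of maximal", "full activation", "equal responses"); they
are declared defaults, not values inferred from data. Window fractions
outside $[-0.2, 1.5]$ abort with a normalization-fault error rather than
silently grading corrupted input.

Grades map to coarse EC50 bands for full agonists (i/ii: 10-100 uM; iii:
0.3-3 uM; iv: 30-300 nM; v: < 100 nM), which `grade_band_check()` uses as a
consistency probe between the screen and fitted curves; partial agonists are
excluded since the bands assume full agonism.

## Coupling preference

A pathway is considered activated when at least one peptide condition shifts
its second messenger significantly from control -- two-way ANOVA (factors:
pathway, stimulation) with Bonferroni-adjusted cell contrasts across the
whole family (via `emmeans`) -- and passes the activation threshold. Among
activated pathways, the strongest is primary and the rest secondary; for
the inhibitory readout, fold-suppression of the forskolin signal
($1/\text{fold}$) serves as the comparable strength, a convention we adopt
because an inhibition has no fold-of-basal. Balanced designs make the
sums-of-squares type moot; the implementation simply uses the cell-mean
contrasts, which coincide with type-II results there.

# Concentration-response fitting

`fit_4pl()` fits $y = \text{bottom} + (\text{top} -
\text{bottom})/(1 + 10^{h(\log_{10}\mathrm{EC}_{50} - \log_{10} c)})$ by
Levenberg-Marquardt least squares (`minpack.lm`), on the log10-concentration
scale. Initialization is multi-start: response extremes for the asymptotes,
a five-point log-EC50 grid over the observed range, Hill starts
$\{0.5, 1, 2\}$; the best converged start by residual sum of squares wins.
The Hill slope is free by default and fixable to 1 ("normal steepness").
Standard errors come from the Jacobian-based covariance;
profile-likelihood intervals are out of scope. A fit is flagged
non-converged when no start succeeds or the response window is
indistinguishable from zero (below twice its own standard error or
$10^{-6}$ of the data scale) -- flat data has no identifiable EC50.
Relative Emax is `100 * window / reference window` against the receptor's
reference agonist on the same readout, the convention behind statements
like "Emax 53% of the FLP-21 response". Fitting on fold-of-basal (the
default) or raw signal gives identical EC50 and relative Emax because the
model is equivariant under multiplicative rescaling.

`reference_pharmacology()` records the literature potencies used by the
recovery benchmark: FLP-21 (1 nM) and FLP-14 (24 nM, Emax 53%) at NPR-1 on
the G$_{i/o}$ readout; FLP-34-1 (19 nM), FLP-34-2 (0.7 nM), PYY (24 nM,
86%) and NPY (256 nM, 49%) at NPR-11 on the chimeric-G$\alpha$ IP readout.
The FLP-21 potency at NPR-11 anchors only the reference window there and is
set to 50 nM, a typical sub-100 nM potency for this receptor's strongest
agonists; it does not enter the reported recoveries.

# Peptide motif classification

Amidated peptides are classified on their last four residues, in precedence
order: NPF/Y-like (`RxRF/Ya`; Arg at -4 and -2, Phe/Tyr at -1), then
FMRFamide-type ($\Omega\Psi$RFa; aromatic at -4, hydrophobic at -3), then
sNPF-type ($\Psi\Psi$RFa). Non-amidated or short peptides are OTHER. The
residue sets are a declared choice -- $\Omega = \{F, W, Y\}$,
$\Psi = \{A, V, L, I, M, F, W, C\}$ -- and configurable, because the
consensus symbols are defined verbally in the literature and whether
$\Omega$ includes His or $\Psi$ includes Gly/Pro varies between authors.
The NPF/Y-like class takes precedence as the RxRF/Ya peptides form a
distinct, more NPY-like group; FMRFamide precedes sNPF wherever the
aromatic set (a subset of the hydrophobic set) causes overlap. Alignments
are anchored at the amidated C-terminus with N-side `-` padding -- purely
positional, no scoring -- and can carry Lesk property categories per
residue. `arg_to_ala()` builds the classical negative controls with the
penultimate Arg swapped for Ala, labelled `[R{n}A]` by 1-based position.

# Behavioral statistics

The avoidance index of a quadrant plate is (worms on methyl-salicylate
sides - worms on ethanol sides) / total, the printed formula, under which
avoiders score negative; `sign_convention = "avoidance_positive"` flips it,
since published bar charts often plot avoidance upward and the text alone
does not fix the figure's convention. The denominator is the scored count
(`n_mesa + n_eoh`) by default -- sodium azide paralysis captures nearly all
animals at endpoint -- with `include_unscored = TRUE` switching to all
placed worms. The bordering fraction is the share of animals within the
2 mm lawn-edge zone. The plate is the statistical unit throughout.
`compare_groups()` uses one-way ANOVA with Bonferroni-corrected comparisons
against a reference genotype (pooled-variance t statistics on the ANOVA
mean square), or an unpaired t-test for exactly two groups, with the usual
`*`/`***` star annotation at 0.05/0.001. The simulators draw each worm's
destination independently (multinomial per plate), which ignores worm-worm
interaction -- adequate for calibration checks, not a behavioral model.

# Candidate inference

If heterologous receptors can substitute a receptor's in vivo function,
the ligand driving that function must activate the native receptor and
every substituting receptor. `infer_candidates()` intersects the
interaction matrix accordingly: peptides with grade at or above `min_grade`
(default i, i.e. any activation) at the target and all rescuers, ranked by
their weakest grade across those receptors. Asterisk (partial-agonist)
cells count as activation -- a high-affinity partial agonist is exactly the
kind of ligand this logic must keep. Non-rescuing receptors serve as
specificity controls and are not a filter by default
(`exclude_non_rescuers = TRUE` enables the stricter variant).

# Numerical choices and degenerate inputs

* Occupancy is evaluated as a logistic in log-concentration, avoiding
  overflow at extreme Hill slopes.
* Log-normal noise uses mean-one parameterization
  ($\mu_{\log} = -\sigma_{\log}^2/2$), so expectations match the readout
  model exactly and CV 0 reproduces it to machine precision.
* Zero-variance strata fall back to exact mean comparison in significance
  testing; receptors where no peptide responds have an undefined window and
  grade `none` across the row.
* All simulators are deterministic given a seed; identical seeds give
  bit-identical tables.

# Benchmark problem sizes

The package ships its own benchmarks, which the test suite asserts and the
acceptance script reports: potency recovery over 50 simulated campaigns
(8-point curves, CV 10%, 3 experiments x triplicate), grading-engine
equivalence on 10,000 noise-free parameter triples against a brute-force
oracle, grade recovery of `example_screen_truth()` (one pair per grade,
one asterisk case) over 100 screens at CV 5%, type-I calibration over
1000 null strata / null experiments, and candidate-inference equivalence
on 1000 random matrices. These sizes give Monte-Carlo errors well below
the decision margins being checked.

# Known limitations

* The grading cutpoints quantify verbal categories; borderline cells
  (e.g. $\phi_H$ near 0.8) are inherently convention-dependent.
* Emax recovery assumes the reference agonist is itself well fit; a poor
  reference propagates into every relative Emax on that receptor.
* The two-way coupling ANOVA assumes comparable variance across pathways
  on the fold scale; wildly different windows violate this and would call
  for a per-pathway analysis.
* Potency bands for grades assume Hill slope 1 and full agonism; steep or
  partial curves fall outside them by construction.

# A worked micro-example

```{r example}
truth <- example_screen_truth()
design <- screen_design(noise_cv = 0.05)
plates <- simulate_screen(truth, design, seed = 42)
folds <- normalize_folds(plates)
spec <- tibble::tibble(receptor = "R1", species = "C. elegans",
                       pathway = "Gq_IP")
calls <- call_activation(folds, spec)
build_interaction_matrix(calls)
```
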