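---
title: "Scoring kinase phospho-readiness on RS-repeat substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring kinase phospho-readiness on RS-repeat substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosready)
```

## The scientific problem

Arginine/serine (RS) repeat domains are phospho-regulated hubs: in splicing
factors and in the inner-nuclear-membrane protein Lamin B Receptor (LBR),
serines inside RS repeats are phosphorylated by SR-protein kinases (SRPK1)
and, on a subset of sites, by AGC kinases of the Akt/PKB family. The two
kinase families read the same stretch of sequence very differently. SRPK1
phosphorylates essentially any serine inside an Arg-Ser or Ser-Arg
dipeptide. Akt requires its minimal consensus
R(-5)-x-R(-3)-x-x-**S/T**(0), normally followed by a large hydrophobic
residue at +1, so within an RS repeat only alternate serines can qualify,
and the +1 position is occupied by an arginine rather than a hydrophobic
residue.

`phosready` implements the computational side of asking *which* serines of
an RS domain a given kinase can actually phosphorylate:

1. **Sequence level** — scan for consensus sites, cut 10-mer candidate
   substrate peptides (register -6..+3 around the phosphoacceptor p0), and
   classify each candidate by its recognition determinants.
2. **Structure level** — thread each candidate onto the backbone of a
   peptide crystallised in the kinase active site, producing binary
   (kinase + peptide) and ternary (+ATP, +2 Mg) initial models.
3. **Ensemble level** — given conformational ensembles of those complexes
   (real MD snapshots read as multi-model PDB, or the package's synthetic
   ensembles), measure convergence, cluster conformers, and estimate
   per-atom fluctuation (RMSF) and Debye-Waller B-factors.
4. **Readiness level** — combine the catalytic geometry (Ser-O&gamma; to
   ATP-P&gamma; distance), the mobility of the p0 hydroxyl oxygen, and the
   kinase-substrate contact inventory into a per-site competence call, and
   correlate mobility with measured phosphorylation efficiency.

The turkey LBR N-terminal fragment is the running example. In author
numbering its RS domain occupies residues 75-84; the segment spanning
residues 72-87 is `PSRRSRSRSRSRSPGR`.

```{r scan}
lbr <- rs_region("PSRRSRSRSRSRSPGR", start = 72, name = "LBR")
scan_akt_sites(lbr)     # minimal Akt consensus
scan_srpk_sites(lbr)    # any Arg-adjacent serine
```

Candidate enumeration deliberately requires only the mandatory -3 arginine
(plus a complete -6..+3 window). The -5 arginine is *not* required at this
stage, because sites lacking it can still be weakly recognised; they are
retained and classified `weak` rather than silently discarded. On the
segment above this yields four overlapping 10-mers with phosphosites at
Ser78, Ser80, Ser82 and Ser84:

```{r candidates}
cands <- enumerate_candidates(lbr)
vapply(cands, `[[`, character(1), "sequence")
lapply(cands[c(2, 4)], classify_akt_site)
```

The classification hierarchy is: no -3 Arg &rarr; `non_site`; Pro at +1
&rarr; `impaired` (proline is incompatible with the +1 pocket and distorts
the local backbone); no -5 Arg &rarr; `weak`; otherwise `optimal`. Flags
record -6/-7 arginine reinforcement and whether the +1 residue suits the
hydrophobic +1 pocket. The pocket-compatible set is {F, L, I, M, V, W, Y}
plus arginine: although not hydrophobic, the arginine guanidinium group can
pack against the pocket aromatics through cation-&pi; interactions, which
is precisely what lets RS repeats present an acceptable +1 residue.

## Threading and the template complex

Initial 3D models are built by *threading*: the candidate's backbone atoms
(N, CA, C, O) take the coordinates of the template substrate peptide —
bit-exactly, so the backbone RMSD to the template is exactly 0 — CB is
copied where both residue types carry one, and side chains beyond CB are
rebuilt from ideal residue geometry (chemical-component-dictionary
fragments, a fixed canonical conformer) rigidly fitted to the threaded
backbone. No clash relief or minimisation is performed: the design intent
is that downstream *ensemble statistics*, not a polished initial geometry,
carry the conclusions, and a deterministic builder makes every result
reproducible to the byte.

The canonical template is the crystal structure of the Akt2 kinase domain
bound to a GSK3-&beta; 10-mer (sequence `GRPRTTSFAE`, phosphoacceptor at
position 7) with the non-hydrolysable ATP analogue AMP-PNP (`ANP`) and two
Mn ions — PDB entry 1O6K. Users holding that file pass it through
`read_pdb()` and `extract_template()`. Because this package must also be
fully testable offline, `synthetic_template()` builds a clearly-labelled
synthetic stand-in with the same component layout (kinase chain A,
hydrophobic-motif tail 466-479 with Asp474, peptide chain B, ANP, 2 Mn, 3
coordinated waters) whose catalytic geometry is calibrated to the published
values for the crystal template (O&gamma;...P&gamma; = 3.57 &Aring;,
O&gamma; B-factor = 14.8 &Aring;&sup2;). It contains no experimental
coordinates and is only a measurement-path stand-in.

```{r template}
tmpl <- extract_template(synthetic_template(), tail_span = c(466, 479))
catalytic_distance(tmpl)
thread_peptide(tmpl, cands[[2]])
```

Ternary ATP/Mg systems are modelled from the ANP/Mn template by
`relabel_cofactor()`: a pure renaming (ANP&rarr;ATP, bridging
N3B&rarr;O3B, Mn&rarr;Mg) that never touches coordinates. The
activation-loop phospho-threonine is deliberately *not* remodelled — the
template kinase residues are taken as given and the choice is recorded as
manifest metadata, since chemically modelling pThr309 belongs to a
simulation protocol, not to threading.

## Ensemble analytics

All ensemble operations rest on the Kabsch closed-form least-squares
superposition (proper rotation, det = +1), with every atom in a selection
weighted equally — no mass weighting, as none of the downstream statistics
requires it. Conventions that matter:

* **Convergence** (`assess_convergence`): a trajectory counts as
  equilibrated when every RMSD value in the trailing window (default, the
  last 20% of frames, mirroring a 10 ns window of a 50 ns run) stays at or
  below the threshold (default 2 &Aring;).
* **Clustering** (`cluster_gromos`): iterative neighbour-count clustering
  at an RMSD cutoff (default 1 &Aring;). Ties in neighbour count break
  towards the lowest frame index, making the partition deterministic. Both
  the cluster *center* (most neighbours) and the *representative* (smallest
  mean RMSD to co-members) are recorded, because the two definitions serve
  different purposes (founding the cluster vs. exporting one structure).
* **Fluctuation** (`rmsf_profile`): frames are superposed onto their own
  average, which is computed iteratively (average, re-superpose,
  re-average; 2 passes — further passes change nothing at these
  amplitudes). Then `RMSF_i = sqrt(<|r_i - mean_i|^2>)` and
  `B_i = (8*pi^2/3) * RMSF_i^2`. Replica aggregation averages RMSF across
  replicas (sample-sd convention, n-1, because replica counts are small)
  and recomputes B from the mean RMSF.
* Whether the superposition before measuring peptide fluctuation should fit
  the whole complex or the kinase alone is a genuinely open choice; the
  pipeline fits on the *kinase backbone* so that peptide mobility is
  expressed in the kinase frame, and `rmsf_profile()` exposes
  `fit_selection` to override this.

## Readiness scoring

A ternary model plus its fluctuation profile yields a per-site verdict:

* `competent` — O&gamma;...P&gamma; below 4 &Aring; and a low-mobility
  hydroxyl oxygen: stably positioned for phosphoryl transfer;
* `transient` — adequate distance but high O&gamma; mobility: the
  near-attack geometry is only transiently visited (a weak substrate);
* `displaced` — distance at or above 4 &Aring;.

Two thresholds govern this. The distance boundary is a single cutoff at
4.0 &Aring;: reported geometries cluster either below 4 (adequate) or above
6 (clearly displaced), and folding the unobserved 4-6 &Aring; gap into the
displaced class keeps the rule deterministic; the gap is simply never
exercised by realistic inputs. The mobility boundary `b_high` defaults to
60 &Aring;&sup2;, splitting the published low-mobility O&gamma; values
(13.6-44.9) from the high-mobility ones (65.8, 67.9); both are arguments,
not constants. The contact inventory (Glu236 &harr; -3 Arg salt bridge,
Glu279 &harr; -5 Arg, Glu315 &harr; -4, Asp440 &harr; -6/-7, and the +1
pocket Phe310/Phe359/Leu317/Pro314) is evaluated by minimal side-chain
heavy-atom distance with kind-specific cutoffs (salt bridge 4.0 &Aring; on
charged N/O pairs, H-bond 3.5 &Aring; on N/O, hydrophobic/stacking proxy
4.5 &Aring;); ring-geometry criteria for stacking and cation-&pi; are
deliberately out of scope — proximity is the only proxy. Phosphorylation
efficiencies entering the efficiency-mobility correlation are always
user-supplied measurements (e.g. densitometry of mutant assays); the
pipeline never fabricates them.

## The synthetic-ensemble generator

`gaussian_ensemble()` displaces every atom of a base model by i.i.d.
isotropic Gaussian noise, with per-residue amplitudes prescribed on the
consensus register by a `fluctuation_spec()`. The two built-in profiles
emulate the characteristic behaviours of bound substrate peptides:

* `optimal_like` — &sigma; = 0.65 &Aring; over the consensus core (-5..+1),
  1.0 &Aring; at the frayed termini. The implied O&gamma; B-factor,
  `8*pi^2*sigma^2` &asymp; 33 &Aring;&sup2;, sits in the published
  low-mobility range of efficient sites (36.5, 44.9).
* `weak_like` — &sigma; = 0.95 &Aring; throughout, implying
  &asymp; 71 &Aring;&sup2;, matching the high-mobility range of poor sites
  (65.8, 67.9).

Non-peptide atoms fluctuate with &sigma; = 0.1 &Aring; (a rigid, well-packed
kinase core). These defaults are the generator's study conditions and are
not adjusted per run. `synthesize_study()` expands candidates ×
{binary, ternary} × replicas into multi-model PDB files plus a ground-truth
manifest (200 frames per replica by default, which keeps full-study
generation around a minute); `make_toy_complex()` places the cofactor's
&gamma;-phosphorus so the catalytic distance is exact by construction,
with per-class defaults (optimal 3.5, weak 3.65, impaired 6.6 &Aring;)
when no distance is prescribed.

What the generator does *not* emulate matters for interpreting green tests:
frames are statistically independent, so there is no temporal
autocorrelation, no anharmonicity, no conformational substates (unless
`two_state_trajectory()` injects them), and pairwise frame RMSD is
inflated by a factor of sqrt(2) relative to frame-to-mean RMSF. One visible
consequence: at high &sigma; the 1 &Aring; neighbour clustering fragments
Gaussian ensembles into many clusters, whereas correlated MD frames inside
one basin would form a single cluster. Passing tests therefore demonstrate
that the *estimators* are correct and calibrated (RMSF &rarr; &sigma;
recovery, B = 8&pi;&sup2;&sigma;&sup2;, exact cluster recovery of separated
conformer families), not that the generator reproduces MD physics.

## End-to-end pipeline

```{r pipeline, eval = FALSE}
cfg <- list(
  region = list(residues = "PSRRSRSRSRSRSPGR", start = 72, name = "LBR"),
  replicas = 4, frames = 250, seed = 1,
  distances = list(`78` = 3.65, `80` = 3.44, `82` = 3.59, `84` = 6.63),
  efficiencies = list(`78` = 40, `80` = 90, `82` = 85, `84` = 25),
  output_dir = "lbr_run"
)
res <- run_pipeline(cfg)
res$report
```

The run directory receives the site table, the validated study manifest,
per-system RMSF tables, the readiness report (TSV) and a log; everything
except the log's timestamps is a pure function of (inputs, config, seed).
`scripts/acceptance.R` drives exactly this computation (4 replicas of 250
frames per system — sizes chosen so the O&gamma; B-factor estimator's
sampling error stays well inside the competence margins) and additionally
recomputes the sequence-level worked examples and the estimator
calibrations.

## Numerical choices and limitations

* PDB fixed-width v3 is the only structure dialect (no mmCIF): templates
  and ensembles here are small, and a single dialect keeps round trips
  bit-exact at the declared precision (10^-3 &Aring;, 10^-2
  &Aring;&sup2;). Alternate locations other than blank/`A` are dropped;
  hydrogens are kept on input but excluded from every selection.
* The metal-water coordination cutoff defaults to 3.0 &Aring; (typical
  first-shell Mn-O distances are ~2.2 &Aring;).
* The backbone atom set is the conventional {N, CA, C, O}.
* Degenerate inputs fail loudly: fewer than 3 or collinear atoms refuse to
  superpose, empty selections and zero-variance correlations are errors,
  and coordinates &ge; 10^4 &Aring; do not fit the fixed-width format.
* The threading builder does not resolve clashes or optimise rotamers; for
  bulky substitutions in tight pockets the initial side-chain pose can
  overlap the kinase, which is acceptable for ensemble statistics but not
  for energy-based scoring.
* `run_pipeline()` analyses synthetic or user-supplied multi-model PDB
  ensembles; trajectory formats that require an MD engine's libraries
  (xtc/trr/dcd) are out of scope and should be converted to multi-model
  PDB upstream.
* The SRPK scanner reports *any* Arg-adjacent serine; restricting the
  report to an annotated RS-domain span (e.g. 75-84, which excludes the
  Ser-Arg dipeptide at Ser73 outside the domain) is the caller's decision,
  made by passing the appropriate region.
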