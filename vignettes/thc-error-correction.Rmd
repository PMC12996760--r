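---
title: "Learning and removing LS-THC errors in MP2/MP3 energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and removing LS-THC errors in MP2/MP3 energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thccorrect)
```

## The model

### Closed-shell MP2/MP3 and its diagrammatic decomposition

For a canonical closed-shell reference, the correlation treatment needs only
the opposite-spin spatial-orbital quantities. The first-order doubles
amplitudes are

$$t_{ij}^{ab} = \frac{g_{ij}^{ab}}{\varepsilon_i + \varepsilon_j -
\varepsilon_a - \varepsilon_b},$$

with singles identically zero; occupied labels are $i,j,m,n$, virtuals
$a,b,e,f$, and $g$ is the two-electron integral tensor, reconstructed from
three-index density-fitting (DF) factors as $(pq|rs) = \sum_J B_{pqJ}
B_{rsJ}$. Because the Fock matrix is diagonal in the canonical basis, only
the orbital energies $\varepsilon_p$ are carried; no SCF machinery exists in
this package — the reference energy is an input.

The second- plus third-order correlation energy decomposes into
$E_\mathrm{C} + E_\mathrm{X} + \sum_{n=1}^{10} E_n$:

* $E_\mathrm{C} = 2\sum t_{ij}^{ab} g_{ij}^{ab}$ and
  $E_\mathrm{X} = -\sum t_{ji}^{ab} g_{ij}^{ab}$ at second order (the
  conventional spin components follow as $E_\mathrm{OS} = E_\mathrm{C}/2$,
  $E_\mathrm{SS} = E_\mathrm{C}/2 + E_\mathrm{X}$ and are derived, never
  stored);
* ten third-order components, each one Goldstone diagram: the
  particle-particle ladder pair (prefactors $+2, -1$ against
  $\langle ab|ef\rangle$), the hole-hole ladder pair ($+2, -1$ against
  $\langle mn|ij\rangle$), and six ring terms ($+8, -4, -4, +2, -8, +4$).

The six ring terms require two distinct ring integral blocks,
$\langle mb|ej\rangle = (me|bj)$ (an ov$\times$ov pairing) and
$\langle mb|je\rangle = (mj|be)$ (an oo$\times$vv pairing); both are carried
as named dense blocks. The component order `E1..E10` is fixed to the term
order above and documented in `mp3_components()`; feature columns inherit
it. Where a component is conventionally written as a sum of two Hermitian
conjugate diagrams, the printed-term convention is adopted — the sum is what
enters the component, so no separate pairing bookkeeping is needed.

Internally all orbital indexing is 1-based (the natural R convention);
frozen-core orbitals are excluded from every stored block at archive
creation, so no index arithmetic ever sees them.

The component-scaled energy $E(c) = E_\mathrm{SCF} + E_\mathrm{C} +
E_\mathrm{X} + \sum_n c_n E_n$ and its difference form $E_\Delta(c') =
\sum_n c'_n E_n$ with $c'_n = c_n - 1$ satisfy
$E(c) - E(\mathbf{1}) = E_\Delta(c - \mathbf{1})$ identically; the test
suite asserts this to machine precision for arbitrary $c$.

### LS-THC

A four-index block in chemists' pair form is factorized through grid
collocation matrices $X$ (orbital values at grid points) and a small core:

$$g_{(pq)(rs)} \approx \sum_{PQ} X_{pP} X_{qP}\, V_{PQ}\, X_{rQ} X_{sQ}.$$

Distinct grids are kept per orbital-pair occupancy type (oo, ov, vv). The
grid is pruned from a redundant parent grid by pivoted Cholesky
factorization of the metric $S_{PQ} = \sum_{pq} X_{pP}X_{qP}X_{pQ}X_{qQ}$:
points are taken in pivot order (largest residual diagonal first, lowest
index on exact ties, for determinism) while the pivot diagonal stays above
$10^{-\delta}$ times the **largest initial diagonal** — a relative
convention that makes $\delta$ invariant to an overall rescaling of the
grid. The core is the least-squares minimizer of the Frobenius
reconstruction residual, computed from the metric pseudo-inverse and the
grid-projected DF factors. The amplitude core `T1` is fitted the same way
against the denominator-weighted THC integrals; the fit is performed densely
rather than in a matrix-free fashion — at the package's problem sizes the
dense normal-equation route is identical in result and far simpler, and
performance is explicitly out of scope.

Three approximate energy variants result: **MP2a** replaces the integrals by
their THC reconstruction but divides exactly by the orbital-energy
denominators (the "approximation of only $g$" reading: amplitudes are the
exact functional of the approximate integrals); **MP2b** additionally
replaces the amplitudes by their THC reconstruction; **MP3b** applies both
approximations throughout the third-order components. MP3d — a THC fit of
the second-order wavefunction — is not implemented; the feature layer
accepts its ten components as optional external columns instead, giving a
34-feature mode next to the buildable 24-feature default.

### The correction layer

The THC error $\Delta E = E_\mathrm{MP3} - E_\mathrm{MP3b}$ is learned from
per-species features: the SCF energy, the two MP2a and two MP2b components,
the ten MP3b components, the HOMO–LUMO gap and the total orbital eigenvalue
span (the "highest-virtual minus lowest-occupied" reading of the span), the
three per-pair-type goodness-of-fit measures
$f_{pq} = 1 - \|B - B_\mathrm{THC}\|_F/\|B\|_F$ transformed as
$\tilde f = \log(1 - f)$, and the Frobenius and max-abs norms of the
`oovv` integral block and the amplitudes. Energies and Frobenius norms are
divided by the number of active valence electrons to make them
size-intensive; the max-abs norms, gap, span and fit measures are not. The
norms are computed from the DF (pre-THC) quantities: they describe the
system, not the approximation, and remain defined when no THC step has run.

Three model classes are exposed:

* **scs** — linear scaling of the ten MP3b components, no intercept, no
  feature scaling (the spin-component-scaling construction generalized to
  the MP3 diagram decomposition);
* **mlr** — ordinary least squares on all features with intercept, features
  *and* labels standardized to unit normal on the training rows (label
  scaling is applied to MLR as well as KRR — the scaled-space formulation is
  uniform across the models that use scaling, with SCS exempt by
  construction);
* **krr** — RBF-kernel ridge regression in the scaled space,
  $(K + \alpha I)\,w = y$ with $K_{ik} = \exp(-\gamma\|x_i - x_k\|^2)$,
  every training row a support row.

Hyperparameters $(\alpha, \gamma)$ are tuned by an exhaustive decade-spaced
grid search ($\alpha \in 10^{-9..3}$, $\gamma \in 10^{-7..1}$) of the k-fold
cross-validated RMSE, refined by Nelder–Mead in
$(\log_{10}\alpha, \log_{10}\gamma)$ with the standard
reflection/expansion/contraction coefficients $(1, 2, 0.5, 0.5)$, a
200-iteration cap and $10^{-4}$ relative tolerance; the refined point is
never accepted if its CV loss exceeds the grid optimum.

Evaluation follows the k-fold protocol: a seeded shuffle and round-robin
split, scalers and models fitted per training fold only, held-out rows
predicted in original units, and the fold-mean RMSE/MAE/MAPE compared to the
uncorrected THC baseline via
$\%\mathrm{IMP} = (X_\mathrm{MP3b} - X_\mathrm{pred})/X_\mathrm{MP3b}
\times 100$, reported rounded half away from zero to integer percent. MAPE
excludes rows with $|y| \le 10^{-12}$ (in label units) and logs the count —
the statistic is undefined at $y = 0$ and synthetic data can hit it exactly.

Reaction energies are evaluated through molecule-trained models: each
species' out-of-fold prediction (from the model that held it out, so no
training row ever predicts itself) is rescaled by its valence-electron count
and combined with the stoichiometric numbers $\nu_i$ (products positive,
reactants negative). The $\sum_i |\nu_i|$ normalization of reaction labels
is a training-only device; since reaction models are trained on molecule
sets in the standard protocol, it only enters the optional
direct-reaction-training mode (off by default), which resolves the apparent
tension between "normalize for training" and "train on molecules" without
guessing further intent.

## The synthetic-data generator

No quantum-chemistry backend is bundled; the generator is the canonical data
source and is first-class, tested code. A corpus is a **structural family**:
from the corpus seed a master template is drawn — occupied and virtual
orbital-energy ladders, one collocation template per occupancy block, and a
Gaussian pool for auxiliary mixing — and each species is a truncation of the
template to its sampled dimensions ($n_\mathrm{occ} \in [2,4]$,
$n_\mathrm{vir} \in [4,8]$, $n_\mathrm{aux} \in [20,40]$, parent grids of
$3 \times (n_l + n_r)$ points) plus a small perturbation (orbital-energy
jitter of 0.01 Hartree, an SCF energy following a size trend). A
counter-based seed fan-out makes corpora extensible without reshuffling
existing species.

Two design choices matter and deserve their rationale:

* **Collocation spectrum.** The template's orbital weights decay as a
  floored stretched exponential $w_r = \max\{e^{-2.5\sqrt{r-1}}, 0.03\}$.
  The pair-metric spectrum then falls over several decades with no cliffs,
  so the pivoted-Cholesky selection grows smoothly with $\delta$ and the
  THC error decreases monotonically in $\delta$; the floor keeps the
  complete grid's metric far enough above the pseudo-inverse cutoff that
  the exact-grid limit is numerically exact.
* **Grid-aligned DF factors.** The DF factors are built inside the parent
  grid's pair-product span, spectrally aligned with the metric
  ($B = P\,Q_k\,\Omega$ over the well-resolved metric directions, with
  $\Omega$ semi-orthogonal mixing from the master pool, scaled to an RMS of
  0.025 so MP2 energies land at a few hundredths of a Hartree). This
  mirrors how real orbital-product densities live in the span of orbital
  products at grid points. It guarantees the full pair matrix is PSD, makes
  the complete-grid fit exact, and — crucially — makes the pruning residual
  a *systematic spectral tail*, so THC errors are consistent across the
  corpus the way they are for real molecules computed under one fixed
  basis-set/parent-grid protocol.

What the generator **does** emulate: positive HOMO–LUMO gaps,
positive-semidefinite pair integrals, grid-size-controlled THC fit quality,
systematic and therefore learnable THC errors, and the qualitative model
ordering (SCS worst, MLR intermediate, KRR best, all with positive
improvement) at both loose and tight pruning. What it does **not**: real
chemical composition, basis sets, geometry, or the diversity of a real
benchmark database. In particular, species within one family are far more
similar to one another than real molecules are, so nearest-neighbour
interpolation is easier and the KRR improvements here are optimistic
relative to what the same pipeline would achieve on heterogeneous real
data. Passing tests demonstrate correctness of the machinery and the
qualitative error-correction phenomenology, not quantitative transfer to
any real molecule set.

The planted-regression generator
($y = Xc + A e^{-\|x-x_0\|^2/2\ell^2} + \varepsilon$) provides ground truth
for the regression layer: noiseless linear recovery, residual-moment
checks, and bandwidth recovery by the tuner (the planted $\gamma$ is
$1/2\ell^2$).

## Numerical choices

* **Metric pseudo-inverse**: symmetric eigendecomposition with a relative
  cutoff of $10^{-10}\lambda_\mathrm{max}$ — pruned LS-THC metrics are
  routinely rank-deficient.
* **Iterative refinement**: the least-squares core fits (integral and
  amplitude) take two refinement passes on the residual; near the
  complete-grid limit the metric condition number reaches $10^8$–$10^9$ and
  a single normal-equation solve would leave a $\sim 10^{-8}$ Hartree
  floor in the variant energies, which refinement removes.
* **Degeneracy guard**: orbital-energy denominators below $10^{-8}$ Hartree
  raise an error naming the offending index quadruple; degeneracy is never
  regularized, since the canonical nondegenerate reference is assumed
  throughout.
* **OLS numerical rank**: `fit_linear()` solves through the SVD and treats
  singular values below $10^{-6}\sigma_\mathrm{max}$ as numerically zero,
  returning the minimum-norm solution with a warning. Family corpora make
  feature columns strongly collinear, and bounding the coefficient noise
  amplification at $10^6$ is what keeps out-of-fold linear predictions
  finite on standardized designs; on any well-conditioned design the
  estimator is plain OLS.
* **Fit-quality transform**: $\log(1-f)$ clamps its argument at
  $10^{-16}$; $f = 1$ occurs in the exact limit and must not produce
  $-\infty$.
* **Pivoted Cholesky ties**: lowest index wins on exactly equal residual
  diagonals, so selections are deterministic.
* **Model files**: numeric payloads are serialized as 17-significant-digit
  strings inside the JSON, which round-trips IEEE doubles exactly;
  reloaded models predict bit-identically.
* **Unit conversion**: 627.5094740631 kcal·mol⁻¹ per Hartree, applied at
  reporting boundaries only.

## Problem sizes

The default corpus is 60 species with the dimension ranges above — the full
pipeline (two $\delta$ values, three models, ten-fold CV with tuning) runs
in well under a minute on one CPU, and the replicated ordering study (ten
corpora) in a few minutes. These sizes were chosen so that every orbital
pair space stays at most a few dozen dimensions while all rank regimes
(complete, marginal, strongly pruned) still occur; nothing in the
implementation exploits smallness except the use of dense linear algebra.

## Known limitations

* Closed-shell, canonical, nondegenerate references only; no open-shell or
  spin-orbital formulation, no gradients or properties.
* Because the generator's occupied-virtual integrals are (truncations of)
  the grid's own pair kernel, they carry an extra occupied-exchange
  symmetry that real molecular integrals do not have: `(ia|jb) = (ja|ib)`,
  hence `E_X = -E_C/2` (vanishing same-spin MP2 correlation) and exact
  pairings among the ring components (e.g. `E5 = -E9`). The diagram
  machinery itself is verified against index-loop oracles on unstructured
  random integrals, where no such identities hold; but on synthetic corpora
  the exchange-type feature columns are linearly dependent on their direct
  partners, which is one reason the standardized feature designs are
  numerically rank-deficient (see the OLS numerical-rank policy above).
* MP3d exists only as an optional external feature block.
* Dense $O(N^6)$-style contractions throughout — accuracy, not performance,
  is the subject; the factorized low-scaling algorithms of production THC
  codes are deliberately absent.
* The qualitative ordering study is a stochastic acceptance: with 60-species
  corpora, fold noise makes near-ties between MLR and KRR possible in a
  minority of replicates, which is why the criterion is framed as at least
  8 of 10 seeded replicates rather than all 10.
* Direct training on reaction labels is provided but off by default; the
  standard protocol is molecule-trained models combined stoichiometrically.
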