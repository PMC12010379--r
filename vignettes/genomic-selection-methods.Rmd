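---
title: "Genomic selection with autogs: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with autogs: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Genomic selection predicts a quantitative trait from genome-wide biallelic
SNP markers coded as alternate-allele dosages $x_{il} \in \{0,1,2\}$. The
working model is additive:

$$y_i \;=\; \mu + \sum_{l=1}^{L} \beta_l\, x_{il} + \varepsilon_i,
\qquad h^2 = \frac{\mathrm{Var}(g)}{\mathrm{Var}(y)},\quad
g_i = \sum_l \beta_l x_{il},$$

where the narrow-sense heritability $h^2$ caps the achievable squared
prediction accuracy: no predictor can exceed $R \approx \sqrt{h^2}$ on a
purely additive trait. `autogs` measures every model with Pearson $R$
between predictions and observations on a held-out test split, and uses a
ridge-regression oracle fitted on the same split as an empirical estimate
of the attainable ceiling.

## From VCF to features

1. **Hard filters.** A locus is removed iff any *present* metric violates
   its bound — `QD < 2.0`, `QUAL < 30.0`, `FS > 60.0`, `MQ < 40.0`,
   `SOR > 3.0`, `MQRankSum < -12.5` (strict inequalities) — or its missing
   rate is ≥ 0.95. Metrics absent from INFO never disqualify a locus, so
   pre-filtered public VCFs pass through unchanged. The duplicated
   `MQRankSum` token that circulates in some filter recipes is treated as
   the single bound above.
2. **Imputation.** Remaining missing dosages take the per-locus mode, ties
   resolving to the lower dosage. This is deliberately naive: statistical
   imputation (Beagle-class) is out of scope.
3. **Regulatory windows.** Gene coding intervals (GFF3 or BED) are expanded
   2 kb upstream and 1 kb downstream — strand-aware by default, since
   "upstream" is a stranded notion; a strand-agnostic flag exists because
   the convention in published window recipes is not always stated. SNPs
   inside at least one window are kept. Intervals are 1-based inclusive to
   match VCF coordinates.

## Encodings

| encoding | shape | used by |
|---|---|---|
| `dosage_vector` | $(n, L)$ floats in $\{0,1,2\}$ | SVM, XGBoost, GBDT, MLP, RF, DeepGS, EnvSE |
| `onehot_4xL` | $(n, 4, L)$, channels = hom-ref / het / hom-alt / missing | DLGWAS |
| `soy_3xSxS` | $(n, 3, S, S)$, $S=\lfloor\sqrt L\rfloor$, row-major pixel layout, trailing $L-S^2$ loci dropped with a warning | SoyDNGP |
| `pca_150` | $(n, 150)$ scores | DNNGP |

The PCA is fitted **on the training split only** and serialized with the
model; fitting it on all samples would leak test information into the
features. The sign of each component is fixed (largest-magnitude loading
positive) so projections are deterministic. The (4, L) channel semantics
(genotype classes + missing) are this package's documented reading; the
original one-hot convention is not restated in the literature we follow,
and the channel order is configurable.

## The model pool

The five classical regressors and the tree learner behind them are
implemented in-package (exact greedy split search in C++): **RF** (bagged
variance-reduction trees with feature subsampling), **GBDT** (residual
boosting, depth 3, shrinkage 0.05), **XGBoost-style** boosting (second-order
formulation with L2 leaf penalty, gamma pruning, row/column subsampling),
**SVM** (linear epsilon-insensitive SVR solved in the primal with Adam) and
**MLP** (64–32 dense net).

The four CNN architectures follow their published layer *contracts*; the
exact widths and kernels are not printed in the source descriptions, so
this package fixes documented defaults and exposes all of them as
hyperparameters:

- **DeepGS** — 1-D conv (8 filters, kernel 18) → pooling (width 2) →
  fully connected (32) → ReLU → dropout 0.05 → output. The 0.05 dropout
  rate is part of the architecture description and is the default.
- **DLGWAS** — two parallel 1-D conv branches at different scales (kernels
  4 and 20, 8 filters each) on the (4, L) one-hot input, merged by an
  add-up layer (outputs cropped to a common length), then a fully
  connected head.
- **DNNGP** — exactly three conv layers (64, 32, 16 channels) on the
  150-dimensional PCA vector, then fully connected layers with one dropout
  layer. Default kernel width is 1: principal components carry no
  meaningful ordering, so wider kernels impose a fake locality; kernel 3
  is available via `hyper = list(kernel = 3)`.
- **SoyDNGP** — VGG-style 3×3 conv blocks with channel doubling
  (16, 32, 64, 128, …) and 2×2 spatial downsampling on the (3, S, S)
  tensor. The default is a single block: desk-scale panels give images of
  only a few hundred pixels, and each 2×2 pool halves the ability to
  resolve individual loci; deeper stacks (`blocks = 4`) are exercised in
  the tests and available for larger panels. Pooling is skipped once a map
  is a single pixel wide so that small $S$ (e.g. 8) propagates without
  shape errors.
- **EnvSE** — a DeepGS-style CNN on the dosage vector whose feature maps
  are gated channel-wise, squeeze-and-excitation style: an MLP embeds the
  environment feature vector into 64 dimensions, a linear map and sigmoid
  produce one gate in (0, 1) per conv channel, and the maps are scaled by
  the gates (applied after the final conv layer by default; the published
  description does not name the layer). With all gates pinned to 1 the
  network is exactly its genotype-only backbone — a property the tests
  assert bit-for-bit.

### Pooling and regularization choices

Two defaults deserve explanation because they were genuinely open:

- **Average pooling** (not max) is the default in all conv paths. On
  additive traits the signal is a weighted *sum* of scattered loci; max
  pooling destroys that linearity, while average pooling commutes with it.
  Max pooling remains available (`pool_type = "max"`).
- **Decoupled weight decay** (AdamW-style, on weight matrices only,
  default 0.5 on the standardized scale) regularizes the conv nets. The
  synthetic acceptance world simulates loci in linkage *equilibrium* — the
  hardest case for CNNs, whose receptive fields then mix independent
  markers — and without ridge-scale decay the networks memorize the
  training split (training MSE near 0, validation MSE near Var(y)). Real
  panels, with LD, are kinder to convolution.

## Training protocol

8:1:1 train/validation/test split ($\lfloor n/10\rfloor$ each to validation
and test, remainder to train), shuffled by the model seed; Adam
(lr $10^{-3}$), batch size 64 clipped to the training-set size, MSE loss;
at most 200 epochs with early stopping on validation MSE (patience 20,
best-validation weights restored — the stopping rule is this package's
choice, as the source protocol states optimizer, batch and loss only).
$R$ is reported on the test split, which never influences fitting, early
stopping, PCA or standardization. All stochastic components (init,
shuffling, dropout, bagging) draw from the model seed, so a spec + data +
seed triple reproduces identical fitted models; the weights archive
(plain-text: JSON header, base64 payload, MD5 checksum) round-trips
predictions bit-exactly.

## Environment features

A weather CSV supplies, per environment and day, the 11 variables
(max/min temperature, humidity, precipitation, wind speed, sea-level
pressure, cloud cover, solar radiation, solar energy, UV index, sunlight
duration). They enter the model at daily, weekly (default) or biweekly
resolution — means over 7/14-day bins, a partial trailing bin averaged
over its days — giving a vector of length 11 × bins, standardized with
training-set statistics stored in the weights.

## Parent selection

Inbred parents have dosage 0 or 2 everywhere, so an F1's expected dosage is
$(p_a + p_b)/2$ per locus — 1 where the parents differ. The published
platform description never prints this rule; the expected-dosage cross is
the only consistent choice for homozygous parents and is applied (with a
warning) even if a parent locus is heterozygous. Candidate crosses are
predicted with any trained model, ranked in the requested direction with
deterministic (female, male) lexical tie-breaks, and the top five flagged.
Pre-made F1 genotypes (e.g. from a VCF of candidate combinations) can be
supplied instead of constructing them from the panel — the platform
documentation is ambiguous about which of the two it does, so both are
supported.

## What the simulator emulates — and what it does not

`simulate_genotypes` draws independent biallelic loci (Binomial(2, p)
outbred, {0,2} inbred) with MAF uniform in a range, synthetic GATK INFO
metrics (optionally violating each filter bound at a set rate) and random
missingness. `simulate_trait` draws `n_qtl` Normal effects, adds noise
orthogonalized against the genetic values and scaled so the *realized*
sample variance ratio equals $h^2$ exactly. `simulate_environments`
produces seasonal-sinusoid weather whose per-environment means drive an
exact linear trait shift; `simulate_env_trait` scales those shifts to
`env_sd` genetic standard deviations (default 1 — environment means
spreading about as widely as the genetic values, as in multi-province
trials). `simulate_cross_population` mirrors an NCII factorial (e.g. 20
females × 30 males = 600 F1s) with ground-truth rankings.

Not emulated: linkage disequilibrium (loci are independent by default),
population structure, genotype-by-environment interaction beyond additive
environment shifts, genotyping error, multi-trait correlations. A green
test therefore establishes that the algorithms are implemented correctly
and recover signal in a clean world — not that any model will reach a
particular accuracy on a real population.

## Acceptance-threshold calibration

The acceptance world is n = 2000, L = 500, 50 QTL, $h^2 = 0.9$, fixed
seed. The full-information ridge oracle reaches R ≈ 0.93 there, and every
dosage/one-hot/soy-encoded model is required to reach R ≥ 0.6 with the
best within 0.1 of the oracle. DNNGP is the exception, by calibration
rather than leniency: a ridge oracle restricted to its own encoding — the
top 150 training-set principal components — tops out at R ≈ 0.59, because
with independent loci the PCA discards most of the marker space. No model
on that encoding can beat its oracle, so DNNGP's threshold is "within 0.1
of the encoding-restricted ceiling", computed in-test. On real,
LD-structured panels the top PCs retain far more genotypic signal and this
gap largely disappears.

## Numerical and degenerate-input choices

- Strict inequalities at filter bounds; boundary values are kept.
- Mode-imputation ties resolve to the lower dosage; a 100%-missing locus
  is an error, not a guess.
- `pearson_r` refuses constant vectors and length < 2 instead of returning
  `NA` silently.
- `fit_pca` reduces k to `min(n_train − 1, L)` with a warning; projections
  refuse a mismatched locus set.
- Early stopping requires a strict validation improvement (tolerance
  1e-9); the best state is kept, not the last.
- Non-finite training loss aborts with the epoch number rather than
  continuing.
- Weight archives carry an MD5 checksum; tampering is detected on load.

## Known limitations

Training is CPU-only and scales to desk-sized problems (hundreds of loci,
thousands of samples); no hyperparameter search, cross-validation scheme,
multi-trait index selection or transfer learning is provided. The
simulator's no-LD default makes the acceptance world conservative for
convolutional models; a block-correlated mode would be the natural
extension for stress-testing them under realistic LD.
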