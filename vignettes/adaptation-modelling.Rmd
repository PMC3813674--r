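---
title: "Modelling rapid syntactic expectation adaptation in self-paced reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rapid syntactic expectation adaptation in self-paced reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synadapt)
```

## The phenomenon and the model

Readers of English strongly expect a past-tense verb form like *warned* in
*The experienced soldiers warned about the dangers...* to be a main verb
(MV). When the sentence instead continues *...conducted the midnight raid*,
revealing a reduced relative clause (RC), reading times spike at the
disambiguating words -- the classic garden-path (ambiguity) effect. The size
of that spike tracks how unexpected the revealed structure is, and repeated
exposure to RCs inside an experiment makes them progressively less
unexpected. `synadapt` packages a quantitative account of this adaptation
together with everything needed to study it end to end on synthetic data.

The belief model is a Dirichlet-multinomial over three continuation
categories after an MV/RC-ambiguous verb: `MV`, `RC`, and `OTHER` (all
remaining continuations). The comprehender enters the experiment with
pseudocounts

$$\alpha_c = \alpha_0 \, p_c, \qquad c \in \{\mathrm{MV}, \mathrm{RC},
\mathrm{OTHER}\},$$

where $p_c$ are corpus-derived base probabilities (defaults $p_{MV} = .7$,
$p_{RC} = .008$, remainder to OTHER) and $\alpha_0$ is the total prior mass,
the model's single free parameter. Each critical sentence read counts as
one observation of its category, so after $n_c$ observations the posterior
predictive probability is the conjugate closed form

$$p(c \mid \text{data}) = \frac{\alpha_0 p_c + n_c}{\alpha_0 + n}.$$

Processing cost is linked to beliefs through surprisal in bits,
$s(c) = -\log_2 p(c)$, and reading time is assumed linear in surprisal.
The predicted garden-path effect at the disambiguating region is
`rt_slope * s(structure) - unambig_offset` ms.

Why three categories rather than a two-outcome beta-binomial? MV and RC do
not exhaust the continuations (their prior probabilities sum to .708), and
carrying OTHER explicitly is what makes MV and RC compete for probability
mass -- the mechanism behind the predicted garden-path *reversal* in the
blocked design, where heavy RC exposure drives $p(\mathrm{MV})$ down without
any MV ever being observed.

```{r}
tr <- simulate_trajectory(exp1_schedule(), prior_config(), query = "RC")
head(tr, 4)
max_change_ratio(prior_config(), 0.5)
```

## Tunable parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `p_mv`, `p_rc` | prior structure probabilities | -- | .7, .008 |
| `alpha0` | prior pseudocount mass | pseudo-observations | 1 |
| `rt_intercept` | baseline word RT | ms | 350 |
| `rt_slope` | surprisal sensitivity | ms/bit | 20 |
| `unambig_offset` | unambiguous disambiguating-region cost | ms | 0 |
| `task_adapt_coef` | practice speed-up on log stimulus order | ms | -30 |
| `noise_sd` | word-level Gaussian noise | ms | 60 |
| `subj_intercept_sd` | by-subject baseline SD | ms | 40 |
| `subj_length_slope_mean`, `_sd` | by-subject length effect | ms/char | 15, 5 |
| `outlier_fraction` | out-of-range RT contamination | -- | .005 |

`alpha0 = 1` is a deliberately weak prior: a single observation moves
beliefs substantially, which is what "rapid adaptation within one
experimental session" requires. `alpha0 = 1e9` is the no-adaptation limit
used for null simulations. The published trajectory summaries for this
paradigm (MV surprisal of 3.99 bits at third-block onset, block means of
1.86 and 1.12 bits, a mixed-design mean of .76 bits) do not pin the
parameter down: they are internally inconsistent about the logarithm base
(the onset probability of .019 gives 5.72 bits in base 2 but 3.96 in nats),
so `calibrate_alpha0()` reports the best single-`alpha0` least-squares fit
to those four values (about `r round(calibrate_alpha0()$alpha0, 2)`, with
substantial residual error) and a both-bases diagnostic, and nothing in the
package asserts them. All other surprisal arithmetic is base 2, anchored by
the exact printed check $-\log_2(.008) = 6.97$ bits.

The ms/bit slope and the other generative magnitudes are fixture
conventions -- no published estimate of the paradigm's ms/bit scaling
exists -- chosen so that simulated effect sizes (a first-encounter RC cost
near 140 ms decaying toward 20 ms) sit in the range typical of self-paced
reading garden-path studies.

## The experiment designs

`build_design_exp1()` produces the mixed-exposure design: 36 critical items
(18 RC, 18 MV, half of each ambiguous, rotated over 4 counterbalancing
lists) interleaved with 50 fillers, so half of all ambiguous trials resolve
to the a-priori-rare RC. `build_design_exp2()` produces the blocked
two-group design: 71 sentences in three implicit blocks, with the RC-First
group reading 16 RCs in block 1 where the Filler-First group reads fillers,
and identical blocks 2 (10 RCs + 20 fillers) and 3 (10 MVs + 15 fillers)
thereafter.

Two ordering variables matter downstream and are distinguished throughout:
*stimulus order* (position among all sentences; indexes task practice) and
*item order* (position among critical sentences; indexes syntactic
evidence). Fillers are constructed to avoid the ambiguity entirely, so they
carry no MV/RC evidence; by default they do not update beliefs at all
(`exp2_schedule(include_fillers = TRUE)` lets them count as OTHER
observations, which matters only for the calibration diagnostic). Beliefs
update once per critical sentence, at sentence offset, because the model's
trajectories are indexed by item order, not word position. Randomisation
places no constraints beyond a seeded uniform shuffle (within block, for
the blocked design); no minimum spacing between criticals is enforced.

## What the generator emulates, and what it does not

`generate_dataset()` inverts the analysis model. Per word,

```
rt = subject_intercept + subject_length_slope * word_length
     + task_adapt_coef * log(stimulus_order) + region_effect + noise
```

with the disambiguating-region effect of ambiguous criticals given by the
surprisal link at the reader's current beliefs, and `unambig_offset` for
unambiguous criticals. Critical sentences follow a 4-region template of
3/4/3/1 words (preamble, ambiguous region, disambiguating region, final
word); fillers are 8-14 words of a single region. Word lengths are drawn
uniformly from 2-12 characters per list (sentence shapes are list
properties, so all subjects on a list read the "same" stimuli). A 0.5%
contamination fraction replaces word RTs with values outside the 100-2000 ms
analysis window to exercise the exclusion stage. Each subject owns a
derived random stream, so enlarging a simulated sample never perturbs
existing subjects.

The generator deliberately omits much that real reading data contain:
lexical and item-specific variability, spillover dynamics (effects are
injected only at the disambiguating region, though the analysis still
inspects all four regions), heavy-tailed RT distributions (noise is
truncated Gaussian), word-level incremental parsing, and any per-verb
belief tracking. Passing tests therefore show that the *pipeline* behaves
as specified under the model's own assumptions -- not that the model fits
human data.

## The analysis chain and its conventions

The chain mirrors standard practice for self-paced reading:

1. **Exclusion**: drop words with raw RT below 100 ms or above 2000 ms.
   The boundaries are read strictly ("below"/"above"), so values exactly at
   100 or 2000 are kept.
2. **Length correction**: mixed regression of raw RT on word length with a
   by-subject random intercept and length slope, fit by REML over all
   remaining words (criticals and fillers -- the procedure's scope is
   ambiguous in published descriptions; all words is the default here).
   Residuals are the dependent variable everywhere downstream. If the
   mixed model cannot be fit, a per-subject OLS fallback is used, with a
   warning.
3. **Aggregation**: mean residual per subject x item x region.
4. **Regression**: linear mixed models on the region of interest.

Factors are coded $\pm.5$ (MV, ambiguous, the RC-First group, and block 2
mapping to $+.5$) and all predictors are mean-centered, which keeps
higher-order interactions interpretable and matches the sign conventions
used to argue for adaptation: the RC garden path appears as a negative
sentence type x ambiguity interaction, and its shrinkage as a *positive*
three-way interaction with item order. Significance uses the large-sample
convention $|t| \ge 1.96$; no degrees-of-freedom correction is applied.
Bonferroni correction is applied exactly where the original analysis
applied it -- the continuous re-analysis of the blocked design's second
question, which tests the ambiguity x RC-evidence-count interaction
alongside the blocked version.

The random-effects specification starts maximal (by-subject slopes for all
within-subject factors, by-item intercepts) and backs off on convergence
failure in a fixed documented order: slope correlations first, then
interaction slopes, then main-effect slopes, then intercepts only. The
published "maximal structure justified by the data" model-comparison
procedure is not reproduced (its details are not available); this ladder is
the package's stand-in, and every fit records the rung it retained.
Singular fits are accepted: zero variance estimates are the truth for
synthetic data generated without the corresponding random effects. Because
the trial CSV dialect carries no item-identity column, the by-item grouping
uses list x item-position slots; the generator injects no item-specific
effects, so this grouping is exact for synthetic data.

## Numerical and degenerate-input choices

* Surprisal is only defined on $(0, 1]$; the functions refuse $p \le 0$ and
  $p > 1$ rather than returning infinities.
* `max_change_ratio()` guards the degenerate case where the prior RC
  surprisal equals the target surprisal (a 0/0 ratio) with an error.
* A dataset with constant word length makes the length regressor collinear
  with the intercept; `length_correct()` detects this and drops the length
  term. This degenerate setting, together with zero noise and frozen
  symmetric beliefs, is what makes the pipeline *algebraically* exact: the
  factorial model then returns an injected 20 ms ambiguity effect to
  machine precision, which the tests use as an end-to-end correctness
  anchor. With random word lengths exactness is impossible (the stage-one
  length slope absorbs chance correlations with the region effect), which
  is why the exactness fixture fixes lengths.
* Replicate-loop simulations (sign recovery and null calibration) fit the
  intercepts-only rung directly: the generator draws no by-subject slopes
  for the focal factors, so that is the correctly specified structure, at a
  fraction of the cost. Single-dataset analyses default to the full ladder.
* Null (type-I) calibration runs 200 replicates of 36 simulated subjects --
  the error rate of a correctly calibrated test does not depend on the
  sample size, and this size keeps the simulation affordable; sign
  recovery uses the design's full 72 subjects.

## Known limitations

The model updates beliefs only from critical sentences and only once per
sentence; it tracks three coarse structure categories with no lexical
specificity; the surprisal link is linear with fixture-scaled magnitudes;
and the analysis treats the hyperbolically decaying garden-path cost with
linear item-order terms, exactly as the conventional analysis does -- the
linear coefficient therefore understates early, fast adaptation. None of
the package's quantities are estimates from human data.
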