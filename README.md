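# synadapt

Computational psycholinguists studying garden-path sentences face a moving
target: readers' syntactic expectations are not fixed, but adapt within a
single experimental session to the statistics of the sentences they are
shown. `synadapt` is an R package for studying that adaptation
quantitatively. It provides, end to end and with no human data required:

* a **Dirichlet-multinomial belief-updating model** over sentence-structure
  categories (main verb `MV`, reduced relative clause `RC`, and `OTHER`),
  with a surprisal link to reading times;
* **design builders** for two classic self-paced-reading paradigms: a mixed
  design in which half of all ambiguous sentences resolve to the
  a-priori-rare RC structure, and a blocked two-group design (RC-First
  vs. Filler-First) built to elicit a *reversed* garden path for MVs;
* a **synthetic data generator** producing word-by-word reading times with
  known effect structure (subject variation, word-length effects, task
  practice, belief-driven garden-path costs, outlier contamination);
* the **standard analysis chain**: 100-2000 ms exclusion, mixed-model
  length correction, region aggregation, and factorial linear mixed-effects
  regressions (via `lme4`) measuring how ambiguity effects change with
  exposure.

## The model

Entering a new linguistic environment, a reader holds pseudocounts
`alpha_c = alpha0 * p_c` over the three continuation categories, where
`p_c` are corpus priors (`p(MV) = .7`, `p(RC) = .008` by default) and
`alpha0` (default 1, a weak prior) is the model's one free parameter. Every
critical sentence read adds one count to its category, giving the posterior
predictive

    p(c | data) = (alpha0 * p_c + n_c) / (alpha0 + n)

Processing cost is surprisal in bits, `s(c) = -log2 p(c)` (so the RC prior
of .008 carries 6.97 bits), and reading time at the disambiguating region
is linear in surprisal. As RC exposure accumulates, `p(RC)` climbs toward
the experiment's statistics and the RC garden path shrinks; because the
categories compete for probability mass, sufficiently heavy RC exposure
*raises* MV surprisal enough to garden-path readers on ordinary main-verb
sentences.

## Worked example

Simulate the mixed-exposure design at full size and run the adaptation
analysis:

```r
library(synadapt)

cfg    <- run_config("exp1", n_subjects = 72, seed = 2025)
trials <- cmd_generate(cfg, out_path = tempfile(fileext = ".csv"))
pre    <- preprocess_trials(trials)        # exclusion, length correction,
                                           # region aggregation
fit_adaptation_model(pre$region_table, random = "intercepts")
#> <adaptation_fit> factorial adaptation model [disambiguating_region]
#>   n = 2592 | random effects: (1 | subject_id) + (1 | item_key)
#>                                predictor    beta t_value significant
#> 1                          Sentence type  -8.184   -2.81        TRUE
#> 2                              Ambiguity  23.937    8.32        TRUE
#> 3                             Item order   0.336    1.09       FALSE
#> 4                     Log stimulus order -40.947  -11.44        TRUE
#> 5              Sentence type : Ambiguity -12.370   -2.15        TRUE
#> 6             Sentence type : Item order   1.530    5.41        TRUE
#> 7                 Ambiguity : Item order  -0.877   -3.12        TRUE
#> 8 Sentence type : Ambiguity : Item order   2.194    3.92        TRUE
```

Reading the table: ambiguous sentences cost extra time at the
disambiguating region (+24 ms), that cost is concentrated on RC sentences
(the negative sentence type x ambiguity interaction, -12 ms), readers
speed up with practice (-41 ms per log stimulus position), and -- the
adaptation signature -- the RC disadvantage shrinks as critical-sentence
exposure accumulates, surfacing as the *positive* three-way
sentence type x ambiguity x item order coefficient (+2.2 ms per item,
t = 3.9). The RC-only simple-effects model shows the same thing directly:

```r
simple_effects(pre$region_table, "RC", random = "intercepts")
#> ...
#> 4 Ambiguity : Item order  -1.68    -3.39        TRUE
```

The predicted (noise-free) counterpart comes from the belief model itself:

```r
tr <- simulate_trajectory(exp1_schedule(), prior_config(), query = "RC")
range(tr$surprisal_bits)   # 6.97 bits at first exposure -> ~1 bit
max_change_ratio(prior_config(), 0.5)  # MV shift is ~8.1% of the RC shift
```

`cmd_simulate_beliefs()`, `cmd_generate()`, `cmd_analyze()` and
`cmd_recover()` wrap these stages behind a `run_config()` (or a flat
key-value config file); `inst/cli/synadapt` exposes the same four commands
as a shell script.

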