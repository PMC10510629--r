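# retroplan

Disconnection-aware multistep retrosynthesis planning in R.

## The problem

Computer-aided synthesis planning works backwards from a target molecule,
replacing it step by step with plausible precursors until every leaf of the
route tree is a commercially available building block. Generic single-step
retrosynthesis models decide *where* to disconnect on their own and tend to
concentrate on one or two obvious bonds. `retroplan` implements the
alternative: candidate reactive atoms are marked explicitly in a tagged
SMILES dialect (a `!` token after each marked atom, e.g. `CC(=O)O!CC` for
the ester oxygen of ethyl acetate), the single-step model is conditioned on
that choice, and three complementary strategies — systematic enumeration of
atoms/pairs/triplets, mined tagging templates, and a pluggable learned
tagger — propose the marks.

Each tagged variant runs through a triple-predictor loop: a retrosynthesis
model T1 proposes starting-material sets, a reagent model T2 proposes
reagent sets, and a forward model T3 re-predicts the product; a step is
kept only when T3's top-1 prediction equals the query product, and its
confidence is T3's score. A best-first search assembles validated steps
into multistep routes down to a building-block set, ranked by the route
penalty score

```
RPScore = SP^N * prod_i CS_i * prod_{m in U SM_i} Simplicity(m)
```

for a route of `N` steps with forward confidences `CS_i`; `SP = 0.8` by
default, `Simplicity` maps a 1–5 synthetic-complexity score linearly onto
[0, 1] and is 1 for building blocks. `CScore = prod_i CS_i` is reported
alongside. Short, confident routes through simple intermediates rank first.

The predictor contracts are backend-agnostic. No trained model ships with
the package; instead a deterministic rule-based toy chemistry (ester,
amide and ether couplings over a small building-block library) provides
consistent mock implementations of all four contracts plus atom-mapped
corpora, so the entire pipeline — tagging, template mining, validation,
scoring, search — runs and is testable end to end at desk scale. For whom:
cheminformatics developers who want a transparent, fully specified
orchestration layer to put their own single-step models behind.

## Worked example

```r
library(retroplan)

w      <- generate_world(world_spec(seed = 7))   # toy universe
models <- mock_models(w)                          # T1/T2/T3/tagger + templates
bb     <- bb_set(w$bb)
target <- w$targets$smiles[1]

run_ttl(target, default_config(), models)[[1]]
#> <single step> C(c1ccccc1)(=O)OCCCC(=O)OC(C)C => C(C)(C)O.C(c1ccccc1)(=O)OCCCC(=O)O  (CS = 0.950)

report <- search_routes(target, models, bb, default_config())
report
#> <search report> target C(c1ccccc1)(=O)OCCCC(=O)OC(C)C
#>   2 solved / 0 unsolved routes after 3 iteration(s), 3 single-step call(s)
#>   best solved: 2 step(s), RPScore 0.4765, CScore 0.9025
```

The target is a diester built in two toy esterifications. The single-step
loop finds both disconnections (confidence 0.95 each, the ester rule's
forward score). The search solves it in two steps: `CScore = 0.95^2 =
0.9025`, and `RPScore = 0.8^2 * 0.9025 * Simplicity(...)` ≈ 0.4765 once
the one non-building-block intermediate's simplicity enters the product.
Both solved routes end exclusively in building blocks, and the ground-truth
minimum length recorded by the generator (2) is achieved.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/retroplan.R mockworld --seed 7 --out mw
Rscript inst/cli/retroplan.R extract-templates --reactions mw/corpus.rsmi --radius 2 --out tpl.csv
Rscript inst/cli/retroplan.R run --target "$(head -1 mw/targets.smi | cut -f1)" --bb mw/bb.smi --out routes.json
```

## Layout

| Path | Contents |
| --- | --- |
| `R/smiles-parse.R`, `R/smiles-write.R`, `R/canonical.R` | molecular graphs, SMILES reader/writer, canonical ordering |
| `R/tagged.R` | the `!` tagged-SMILES dialect |
| `R/reaction.R`, `R/template.R` | mapped reactions, reaction centers, template mining |
| `R/sites.R`, `R/predictors.R`, `R/ttl.R` | site enumeration, predictor contracts, the validated single-step loop |
| `R/scoring.R`, `R/search.R` | RPScore/CScore, best-first multistep search |
| `R/world.R` | the rule-based toy chemistry and mock models |
| `R/config.R`, `R/io.R`, `inst/cli/retroplan.R` | configuration, file formats, command line |
| `vignettes/route-planning.Rmd` | methods: models, scores, design choices, limitations |
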