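# engraftr

Quantify engraftment after fecal microbiota transplantation (FMT) from
amplicon feature tables. Given a donor community, each recipient's
pre-FMT (day-0) community and one or more post-FMT communities — as
presence sets $D$, $R$, $P$ of genera — every genus is classified into
one of six ecological outcomes, normalized by the post-FMT richness
$|P|$:

- **colonization** $|D \cap P \setminus R|/|P|$ — donor genus that established
- **rejection** $|D \setminus R \setminus P|/|P|$ — donor genus that never appeared
- **coexistence** $|D \cap R \cap P|/|P|$ — shared genus that survived
- **persistence** $|R \cap P \setminus D|/|P|$ — recipient-only genus that survived
- **novel** $|P \setminus D \setminus R|/|P|$ — genus from neither source
- **loss** $|R \setminus D \setminus P|/|P|$ — recipient-only genus that vanished

The four within-$P$ categories partition $P$, so their fractions sum to 1.

Around that core the package provides the supporting toolchain a
microbiome analyst needs: rarefaction, ASV-to-genus collapse and presence
sets; alpha diversity (observed features, Pielou evenness, Faith PD),
beta diversity (Jaccard, Bray–Curtis, unweighted/weighted UniFrac), PCoA
and PERMANOVA, all implemented from first principles and cross-checked
against vegan/picante in the tests; a repeated cross-validated elastic
net (own coordinate-descent solver,
$\tfrac{1}{2n}\lVert y-X\beta\rVert^2 + \lambda(\alpha\lVert\beta\rVert_1
+ \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2)$) predicting per-recipient
colonization and rejection from 17 baseline features; a synthetic cohort
generator with known ground truth; and a seeded, manifest-writing
pipeline runner. It is aimed at analysts of FMT trials (the defaults
emulate a four-arm weaning-piglet design) and at anyone who wants a
tested, reproducible implementation of presence/absence engraftment
accounting.

## Worked example

Classify the canonical toy triad:

```r
library(engraftr)
classify_triad(donor = c("a", "b", "c"), pre = c("b", "d"),
               post = c("a", "b", "d", "e"))[, 1:8]
#> # A tibble: 1 × 8
#>   colonization rejection coexistence persistence novel  loss shared_loss n_post
#>          <dbl>     <dbl>       <dbl>       <dbl> <dbl> <dbl>       <dbl>  <int>
#> 1         0.25      0.25        0.25        0.25  0.25     0           0      4
```

Genus `a` colonized (donor and post only), `c` was rejected, `b`
coexists, `d` persisted, `e` is novel — one genus each out of the four
observed post-FMT, hence 0.25 everywhere and zero loss. `shared_loss`
tracks the one membership pattern (donor-and-recipient genus that
disappeared) falling outside the six canonical outcomes.

A full synthetic cohort, end to end:

```r
co <- simulate_cohort(simulation_config(days = c(0, 2), seed = 42))
profiles <- presence_sets(co$counts) |>
  build_triads(co$metadata) |>
  classify_triads()
summarize_outcomes(profiles)[, 1:8]
#>   treatment day colonization rejection coexistence persistence novel   loss
#> 1   control   2        0.071     0.300       0.381       0.129 0.419 0.0145
#> 2   in_feed   2        0.113     0.234       0.358       0.119 0.410 0.0149
#> 3      oral   2        0.142     0.200       0.353       0.120 0.386 0.0129
#> 4    rectal   2        0.131     0.218       0.358       0.123 0.389 0.0126
```

Mean day-2 colonization is highest in the oral arm (14.2%) and ordered
oral > rectal > in-feed, with rejection moving the opposite way — the
generator's designed engraftment gradient, recovered by the classifier.
Predicting colonization from the 17 baseline features of one arm:

```r
preds <- build_predictors(co$counts, co$metadata, tree = co$tree)
oral  <- preds[preds$treatment == "oral", ]
y     <- profiles$colonization[match(oral$subject_id, profiles$subject_id)]
cross_validate(predictor_matrix(oral), y, seed = 1)
#> Repeated cross-validated elastic net (5 x 5-fold, n = 10, seed 1)
#>   selected alpha = 0.00, lambda = 9.703
#>   held-out RMSE = 0.01482, held-out R2 = -0.1859 (training R2 = 0.3450)
#>   nonzero coefficients: 14 of 17
```

With only ten recipients the held-out $R^2$ is negative — the model has
no predictive signal here, and the package reports that honestly rather
than quoting the (misleadingly positive) training fit. `tidy()`,
`glance()` and `autoplot()` methods expose coefficients, summaries and
plots; `run_pipeline()` chains simulate → prep → diversity → outcomes →
predict from a YAML config and writes a manifest of artifact digests and
seeds.

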