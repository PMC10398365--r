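# cessalex

Lexicon-based emotion profiling of text posts from online support forums,
built for the comparison of substance-cessation communities (alcohol,
nicotine, cannabis) against general-interest control forums, and for
tracking emotional expression across self-reported abstinence duration.

## What it computes

For each forum corpus, every post body is normalised (markup removed,
punctuation stripped to spaces, lowercased) and matched against a curated
emotion word bank of K = 21 categories. The forum's profile is the vector
of **occurrence frequencies**

f_c = 100 · n_c / Σ_k n_k,

the percentage of all emotion-word matches falling in category *c* (the
21 percentages sum to 100). On top of this primary measure the package
provides:

- **Corpus filters** — a fixed-window text-density inclusion rule
  (≥ 3000 textual posts of a 5025-post window), truncation to the most
  recent 3003 text posts, and a median split on the total match count that
  drops emotion-poor forums (retaining ⌊n/2⌋ of n distinct scores: 54 of
  108, 47 of 95).
- **Outlier detection** — a forum is an outlier on a category when its
  frequency exceeds the 95th percentile of the control forums there
  (linear interpolation between order statistics).
- **Similarity profiling** — pairwise cosine similarity between the
  K-dimensional profile vectors, with deterministic top-k neighbour lists.
- **Abstinence dynamics** — for posts tagged with days-since-last-use:
  the first-24-hours posting share versus the uniform-chance level
  (100/10000 = 0.01%), 15 log-spaced duration bins to 1000 days split
  into short- (< 100 days, 9 bins) and long-term (≥ 100 days, 6 bins),
  a two-way emotion × abstinence ANOVA on per-bin-normalised percentages
  (whose abstinence main effect is algebraically zero — a built-in check),
  and Bonferroni-corrected pooled-variance post-hoc t tests.
- **A synthetic corpus generator** — multinomial emotion-word composition
  per forum, negative-binomial post lengths, punctuation/HTML noise,
  image-only posts, and an abstinence model (7% first-day point mass,
  log-uniform tail to 10,000 days, post-100-day composition shift), with
  exact ground-truth records for parameter-recovery tests.

Everything is tibble-in/tibble-out and pipe-friendly; results have
`autoplot()`, `tidy()` and `glance()` methods.

## Worked example

A synthetic study stands in for a real forum extraction: 30 control forums
and 3 cessation-style targets, 1205 posts each, two targets carrying
abstinence metadata.

```r
library(cessalex)

study  <- generate_study(n_control = 30, n_target = 3, seed = 17,
                         n_posts = 1205)
report <- run_pipeline(list(
  posts      = study$posts,
  targets    = study$target_forums,
  abstinence = list(forums = c("cess_alcohol", "cess_nicotine"))
))
report$log
#>   stage        n_before n_after rule
#> 1 ingest          39765   39765 33 forums read
#> 2 text_filter     39765   39765 body yields >= 1 token
#> 3 median_split       33      16 emotion score strictly above sample median
#> 4 abstinence          2       2 tagged text posts, most recent 1205, ...
```

Targets are flagged on their constructed outlier emotions:

```r
subset(report$outliers, is_outlier)[1:3, ]
#>   forum        category  frequency threshold is_outlier
#> 1 cess_alcohol anxiety        12.9      6.14 TRUE
#> 2 cess_alcohol gratitude      12.4      6.39 TRUE
#> 3 cess_alcohol pride           9.6      7.34 TRUE
```

(the frequency column is the forum's percentage of emotion-word matches in
that category; the threshold is the control sample's 95th percentile), and
the cessation forums are each other's nearest emotional neighbours:

```r
report$top_k
#>   target        rank forum         similarity
#> 1 cess_alcohol     1 cess_nicotine      0.892
#> 2 cess_alcohol     2 cess_cannabis      0.866
#> 3 cess_alcohol     3 control_030        0.803
```

The abstinence analysis shows the first-day posting burst (8.38% of tagged
posts in the first 24 hours against a 0.01% uniform-chance level, with
anxiety the leading first-day emotion), the forced-zero abstinence main
effect, a real emotion × abstinence interaction, and the post-100-day
anxiety decrease with a gratitude increase:

```r
ab <- report$abstinence$cess_alcohol
ab$first_day_pct            # 8.38
ab$first_day_top[1:2]       # "anxiety" "gratitude"
ab$anova[, c("f_emotion", "f_abstinence", "f_interaction")]
#>   f_emotion f_abstinence f_interaction
#> 1      58.0            0          6.36
ab$ttests
#>   emotion   estimate statistic df  p.value significant
#> 1 anxiety       9.84     8.21  13 1.69e-06 TRUE
#> 2 disgust      -0.05    -0.06  13 9.50e-01 FALSE
#> 3 pride         0.38     0.22  13 8.31e-01 FALSE
#> 4 gratitude    -5.18    -3.30  13 5.70e-03 TRUE
```

`estimate` is the short-term minus long-term mean percentage, so the
positive anxiety contrast is a decrease with sustained abstinence.
`compare_runs()` summarises how outlier sets and neighbour lists replicate
across two snapshots, and `write_report()` emits every surface as CSV.

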