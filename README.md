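# groomcircles

Concentric social circle analysis of grooming networks.

Social animals rarely spread affiliative effort evenly: a few partners
receive intense investment, more receive a little. `groomcircles` measures
this layering per individual from weighted grooming ego-networks, for
behavioral ecologists working with dyadic interaction data (the package's
conventions follow captive bonobo/chimpanzee studies, but any directed
positive-weight interaction data fit).

## The model

For an ego with tie weights $s_1,\dots,s_L$, each tie gets a normalized
distance $t_i = (s_{\max}-s_i)/(s_{\max}-s_{\min})$ (0 = strongest tie,
1 = weakest). Under a maximum-entropy model of budget allocation, the
cumulative fraction of ties with distance at most $t$ is

$$\chi(t) = \frac{e^{\eta t}-1}{e^{\eta}-1},$$

and the single parameter $\eta$ is estimated by maximum likelihood via the
implicit equation $\bar t = e^\eta/(e^\eta-1) - 1/\eta$, with
likelihood-ratio confidence intervals ($\delta = 0.025$, i.e. 95%).
$\eta > 0$: normal concentric layering (few intense ties, expanding weaker
circles); $\eta < 0$: inverted (almost everything in the innermost
circle). The discrete $r$-layer counterpart and the map
$\eta \approx (r-1)(e^\mu - 1)$ — which gives the canonical $\eta \approx
6$ for $r = 4$ layers with scaling ratio $e^\mu \approx 3$ — are included.

Around the estimator the package provides the standard pipeline: reading
directed interaction records and demographic metadata, the usual inclusion
filters (groups of at least 6; egos that groomed at least 5 partners) with
a full audit trail, weighted modularity and seeded community detection per
group, gradient-boosted attribution of $\eta$ to covariates with exact
TreeSHAP values and partial-dependence curves, and a synthetic cohort
generator with planted, covariate-driven $\eta$ for end-to-end validation.

## Worked example

```r
library(groomcircles)

ints <- read_interactions(system.file("extdata", "toy_interactions.csv",
                                      package = "groomcircles"))
meta <- read_metadata(system.file("extdata", "toy_metadata.csv",
                                  package = "groomcircles"))

egos <- apply_filters(ego_table(ints, meta))
filter_audit(egos)
#> Filter audit: 2/3 groups retained, 9/18 egos retained
#> # A tibble: 3 × 2
#>   reason                 n
#>   <chr>              <int>
#> 1 degenerate_weights     1
#> 2 min_group_size         5
#> 3 min_partners           3

fit_ego(c(1, 1, 10))
#> Continuous circle-model fit
#>   eta = 2.1491  [-1.9151, 7.4152]  (delta = 0.025, normal regime)
#>   L = 3 ties, sigma = 4.000, t_bar = 0.6667
```

The audit shows the 5-member group dropped whole, three egos below the
5-partner threshold, and one ego with all-equal weights (for which $\eta$
is undefined). The single-ego fit reads: one strong partner and two weak
ones give a normal, concentric structure ($\hat\eta \approx 2.15$), with a
wide interval at only $L = 3$ ties.

On a synthetic cohort the whole pipeline is three calls:

```r
cfg <- synthetic_config(n_groups = 6, group_size_range = c(34, 40),
                        ego_size_range = c(8, 30), seed = 7)
coh <- generate_cohort(cfg)
res <- run_pipeline(coh$interactions, coh$metadata, out_dir = "report")
```

which writes `eta_estimates.csv`, `filter_audit.csv`, `group_summary.csv`
(mean $\hat\eta$ vs modularity per group), `community_assignments.csv`,
`eta_histogram.csv` (per-species proportions), the attribution outputs
(`importance.csv`, `shap_values.csv`, `pdp_*.csv`) and a `manifest.json`
recording every setting and seed. `autoplot()` methods cover the fit
table, the attribution model, the Shapley values and the
partial-dependence curves; see the methods vignette
(`vignettes/circle-model-methods.Rmd`) for the model, the estimation and
interval machinery, the generator's assumptions and the package's design
choices.

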