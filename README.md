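# nestwebs

Succession and local stability of ant nest symbiont food webs.

Red wood ant mounds harbour a diverse community of arthropod symbionts —
obligate myrmecophiles found only with ants, and facultative soil
generalists. As nests age, obligate functional groups build up large
populations while facultative groups stagnate or decline, making old-nest
communities more even. `nestwebs` is an R package for ecologists who want
to ask what such successional shifts do to the *dynamic stability* of the
nest food web, and whether any stability difference is carried by the
relative abundances of the groups or by the topology of their interactions.

## The model

Each nest's community becomes a local food web: functional groups present
and not rare there (rarity = count below the group's 0.1 empirical quantile
across nests), with trophic links induced from a general adjacency over 16
functional groups and two aggregate basal resources (ant brood, nest food),
and competition between members sharing a basal resource. Stability is
local asymptotic stability of the community matrix of Lotka–Volterra
dynamics,

    M = D A*,     a*_ij ~ N(mu, sigma),

with `D` the diagonal of relative abundances and `A*` a signed
interaction-strength matrix (consumer-on-resource mean −0.1,
resource-on-consumer +0.1, competition −0.1, sigma 0.05, diagonal −1;
coincident trophic and competition effects are summed). The statistic is
ℜ(λ₁), the leading eigenvalue's real part, averaged over 50 replicate
matrices per nest; the analysis response is `log |mean ℜ(λ₁)|`. Four
scenarios cross observed vs even abundances with observed vs randomized
(off-diagonal shuffled) topology; per scenario, the response is regressed
on nest age × community size (communities of fewer than six groups
excluded). If evenness drives stability, the age effect survives rewiring
but vanishes when abundances are evened out.

The package also provides the supporting community statistics — Pielou
evenness, Bray–Curtis distances, a re-implemented PERMANOVA (verified
against `vegan::adonis2` and brute-force enumeration), PERMDISP, beta
regression of evenness on nest predictors, rank-abundance summaries — and a
seeded synthetic-data generator (`generate_dataset()`) that emulates a
survey of 51 nests in two age classes so the whole pipeline is testable
without field data.

## Worked example

```r
library(nestwebs)

ds <- generate_dataset(preset_paperlike(seed = 1))
ds
#> Study dataset: 51 nests x 16 functional groups
#>   age classes: new=20, old=31

ev <- evenness_table(ds)
aggregate(J ~ age_class, ev, function(x) round(mean(x), 3))
#>   age_class     J
#> 1       new 0.541
#> 2       old 0.725

report <- analyse_scenarios(ds, n_reps = 50, seed = 1)
report
#> Scenario comparison (alpha = 0.05 )
#>             scenario        age_F        age_p     size_F       size_p  size_slope
#>    observed_observed 38.797573161 1.120323e-07   28.23665 2.747076e-06 -0.17246266
#>  observed_randomized 37.067592955 1.837678e-07   27.63190 3.346368e-06 -0.17312452
#>        even_observed  0.004722497 9.454976e-01 2240.65023 6.072366e-42 -0.09457577
#>      even_randomized  0.046814288 8.296193e-01 2032.08260 6.022518e-41 -0.10368432
#> Verdict pattern HOLDS (age effect under observed abundances only; size destabilising everywhere)
```

Reading the table: old nests are more even (J 0.725 vs 0.541), and under
*observed* abundances nest age strongly predicts stability whether or not
the topology is rewired (age F ≈ 38). Once abundances are evened out the
age effect disappears (p ≈ 0.8–0.9) while the destabilising effect of
community size remains — the stability difference between old and new
nests is carried by the evenness of the abundance distribution, not by the
arrangement of the interactions.

Real data can be supplied as a three-file bundle (abundance CSV, metadata
CSV, adjacency edge-list CSV plus a JSON manifest); see `read_bundle()`,
`read_abundance_table()` and `default_general_adjacency()`. The packaged
adjacency is a role-based synthetic reconstruction — replace it with a
field-calibrated diet table for real analyses.

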