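# referralnet

Organizational network analysis (ONA) of client-referral networks among
health service providers, built for the study design in which HIV care and
family planning are delivered by a fragmented mix of government facilities,
NGOs, faith-based organizations and private clinics, and the question is
whether the referral structure leaves clients' service needs uncovered.

The package is aimed at health-systems researchers and M&E analysts running
sub-city / county scale referral censuses: a few dozen organizations, a
snowball roster, a sociometric interview per organization.

## What it computes

For a directed simple graph of `n` organizations and `m` referral arcs:

- **Roster construction** from snowball nominations: transitive closure from
  seed organizations, then the inclusion rule *named by ≥ 2 distinct others*
  with a private-clinic exception (admitted when named once).
- **Network descriptives**: density `m/(n(n−1))`; in-/out-degree; the dyad
  census `(M, A, N)` with `M+A+N = n(n−1)/2`, `m = 2M+A`; reciprocity both
  as the proportion of symmetric dyads `(M+N)/(M+A+N)` (default; null dyads
  count as symmetric) and as `2M/m`; Freeman degree centralization
  `Σ(c_max − c_i)/D`; attribute mixing matrices.
- **ERGMs for homophily/heterophily**: `P(G) ∝ exp(θ·s(G))` over a
  dyadic-independent term vocabulary (`edges`, `nodematch`, `nodemix`,
  `absdiff`, `nodeocov`, `nodeicov`, `edgecov`), fitted by maximum
  pseudolikelihood — which is exact maximum likelihood for these terms —
  with Newton/IRLS, plus a Metropolis simulator and an association screen
  (Wald z, α = 0.05) for attributes and dyadic covariates such as driving
  distance.
- **Service-gap audit**: an organization is flagged for a service domain
  when it neither provides the domain nor refers to any provider of it
  (whole-domain and partial-coverage rules), plus the referral-nature grid
  used for visual auditing.
- **Workshop artifacts**: organization directory, complementary-service
  table, DOT/GraphML sociogram export.
- **Synthetic fixtures**: deterministic networks for two sub-cities
  ("kirkos", n = 25, m = 69; "kolfe", n = 26, m = 101) reproducing the
  published marginal constraints of the motivating study, and seeded random
  ERGM networks and nomination censuses for statistical testing.

## Worked example

```r
library(referralnet)

k <- make_paper_fixture("kirkos")
summary(k)
#> Relational characteristics (Kirkos)
#>   Organizations                 25
#>   Links                         69
#>   Density                       0.115
#>   Centralization (in-degree)    0.184
#>   Referrals sent (out-degree)   2.76
#>   Referrals received (in-degree) 2.76
#>   Reciprocity (dyadic)          0.83
#>   Reciprocity (arc)             0.26
#>   Dyad census (M, A, N)         9, 51, 240
```

Density 0.115 means 11.5% of all possible ordered referral ties exist; the
dyadic reciprocity 0.83 says 83% of organization pairs are symmetric
(mutually referring or mutually silent). The family-planning gap scan finds
the two HIV-only organizations that refer to no family-planning provider:

```r
subset(detect_gaps(k), flagged)
#>    org_id service_domain provided_codes n_qualifying_targets flagged
#> 17    K24             FP                                   0    TRUE
#> 18    K25             FP                                   0    TRUE
```

Homophily by organization type (the fixture plants a faith-based-organization
clique), via the ERGM fitting function:

```r
summary(ergm_mple(k ~ edges() + nodematch("org_type")))
#> ERGM fit by maximum pseudolikelihood
#> Dyads: 600   logLik: -209.453   converged: TRUE
#>
#>                    estimate       se        z   p_value
#> edges              -2.38647  0.18473 -12.9190 < 2.2e-16 ***
#> nodematch.org_type  0.78790  0.25810   3.0527  0.002268 **
```

A positive `nodematch.org_type` of 0.79 multiplies the odds of a referral
by `exp(0.79) ≈ 2.2` when the two organizations are of the same type. And
the roster, recovered from a nomination census:

```r
fx <- nomination_fixture(k, seed = 1)
length(build_roster(fx$seeds, fx$nominations, fx$private_clinics))
#> [1] 25
```

A command-line wrapper over the same functions is installed at
`inst/scripts/referralnet-cli.R` (subcommands `fixture`, `metrics`,
`roster`, `gaps`, `report`, `ergm-fit`).

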