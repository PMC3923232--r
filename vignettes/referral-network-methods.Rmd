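---
title: "Methods: organizational referral network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organizational referral network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(referralnet)
```

## The setting and the data model

Health services for people living with HIV are frequently fragmented across
many specialised providers — government facilities, NGOs, faith-based
organizations, private clinics — and a client's access to, say, family
planning often depends on whether her HIV-care organization refers her to one
that provides it. Organizational network analysis (ONA) treats the providers
of a catchment area as nodes of a directed graph whose arcs are client
referrals, "organization i sends clients to organization j", and asks
whether the observed referral structure leaves service needs uncovered.

`referralnet` represents such a system as a `referral_network`: a table of
organizations (type, management, service codes, staffing, client volume,
optional coordinates) plus a simple directed arc set. Ties are analyzed as
binary. Interview instruments typically also record a referral frequency
(never/rarely/sometimes/often); we carry it as an optional arc attribute but
no metric uses it, because the published network characteristics this package
is organised around are computed on binary ties. All surveyed ties are kept
by default — dropping, e.g., "never" ties is a caller-side filter on the arc
table, deliberately not a hidden option of the constructors.

Services are described by a *catalogue* mapping domains to code sets. The
default has one family-planning code and four HIV codes (testing, ART,
care/support, PMTCT). The study setting distinguishes only "HIV", "FP" and
"both", plus a narrative notion of offering "few" HIV services; a multi-code
HIV domain is the minimal structure under which both the whole-domain and the
partial-coverage gap rules below are expressible. The catalogue is a plain
argument everywhere, so other granularities are drop-in.

## Roster construction

The analyzable roster comes from a snowball census: seed organizations
(those known to the coordinating agency) name others, the newly named are
asked in turn, until no new names arise (`snowball_closure()`, a transitive
closure over nomination reachability). The inclusion rule
(`apply_inclusion_rule()`) then admits an organization named by at least two
*distinct* others; private clinics — structurally under-named by the
public-sector organizations — are admitted with a single nomination.
Two choices here were genuinely open:

* *Distinct-nominator counting.* "Named by at least two other organizations"
  is read as two distinct namers; repeated nominations from one nominator
  count once. The brute-force oracle in the test suite enumerates both
  readings and pins this one.
* *Seeds are always retained.* The census starts from the seeds, which are
  interviewed rather than nominated; their own nomination counts are an
  artifact of who happened to name them back. Retaining them unconditionally
  anchors the census and makes the roster monotone in the nomination set.

## Whole-network descriptives

For a directed simple graph with `n` nodes and `m` arcs:

* density `m / (n(n-1))`;
* in-/out-degree (referrals received/sent), whose means both equal `m/n`;
* the dyad census `(M, A, N)` of mutual, asymmetric and null unordered
  pairs, with `M + A + N = n(n-1)/2` and `m = 2M + A`;
* reciprocity, in two conventions: **dyadic** `(M + N) / (M + A + N)` — the
  proportion of dyads that are symmetric, counting null dyads as symmetric —
  and **arc** `2M / m`. The dyadic-including-null convention is the default:
  with `n = 25`, `m = 69`, a reciprocity of 0.83 is arithmetically
  attainable only under it (arc reciprocity would require an odd count of
  mutual arcs), so it is the convention that reproduces the published tables
  this package's fixtures are built around. Both are always reported by
  `summary()`.
* Freeman degree centralization `sum(c_max - c_i) / D` with `D = (n-1)^2`
  for in- or out-degree and `D = (n-1)(2n-4)` for total degree (the value
  attained by the fully mutual star). In-degree is the default mode: the
  substantive signal in referral systems is the received-ties hub (a
  general hospital drawing referrals from everyone). The published
  centralizations (0.192, 0.525) cannot be recomputed exactly without the
  raw data — the variant used is not stated — so the fixtures treat them as
  soft targets (±0.05 in in-degree mode) rather than exact constraints.

`mixing_matrix()` cross-tabulates arcs by a categorical attribute of sender
and receiver (organization type, management), the numeric backbone of
"dominant referral pattern" summaries.

## The ERGM core

Homophily questions — do FBOs refer to FBOs? does board management suppress
cross-referrals? does driving distance matter? — are posed as exponential
random graph models, `P(G) ∝ exp(θ·s(G))`. The fitting function is
`ergm_mple()`, with the conventional formula interface:

```{r, eval = FALSE}
fit <- ergm_mple(net ~ edges() + nodematch("org_type") + edgecov(D))
summary(fit)
```

The term vocabulary (`edges`, `nodematch`, `nodemix`, `absdiff`,
`nodeocov`, `nodeicov`, `edgecov`) is deliberately restricted to
*dyadic-independent* statistics: each term's change statistic
`δ_t(i,j) = s_t(G + ij) − s_t(G − ij)` depends only on the endpoint
attributes or an exogenous covariate matrix, never on the rest of the graph.
Within this family the pseudolikelihood — the product of Bernoulli dyad
likelihoods with log-odds `θ·δ(i,j)` — *is* the likelihood, so maximum
pseudolikelihood (a logistic regression of the arc indicators on the change
statistics, here by Newton/IRLS to score norm ≤ 1e-8) is exact maximum
likelihood, and no MCMC-MLE machinery is needed. The test suite verifies
this identity directly by exhaustive likelihood maximisation over all
4-node digraphs. Dyadic-dependent terms (triangles, GWESP) are out of scope
by design; adding one would silently break the MPLE=MLE property, which is
why the vocabulary is closed.

Numerical choices: Newton steps are damped to a maximum coordinate move of
5; a fit whose Hessian becomes singular or whose coefficients run past 25 in
absolute value is flagged `converged = FALSE` (separation — e.g. a network
where every cross-category dyad is empty — is reported, never silently
returned as a finite estimate); a rank-deficient design (constant or
collinear term, e.g. `nodematch` on a one-category attribute) is an error
up front. Standard errors come from the inverse Fisher information at the
optimum.

`simulate_ergm()` is a single-arc-toggle Metropolis sampler (acceptance
`min(1, exp(θ·δ))`). Dyadic independence again pays off: the change
statistics are state-free, computed once per chain, which makes the sampler
a few array lookups per toggle. Defaults are a burn-in of `10·n(n-1)`
toggles and thinning of `n(n-1)`; for the models in scope the stationary
distribution makes each arc an independent Bernoulli, so these defaults are
generous. Chains are reproducible given `seed` and leave the caller's RNG
state untouched.

`homophily_report()` operationalises the "associated / not associated"
screen: one `edges + term` model per attribute or covariate, Wald z at the
two-sided 5% level, no multiple-testing correction (matching the reporting
convention of the motivating analysis). Client:staff ratio is available as
the derived attribute `client_staff_ratio` and enters as `absdiff` in the
screen (`nodeocov`/`nodeicov` parameterizations are exposed for direct use;
which one the original analysis used is not recoverable).

## Service-gap audit

A *service gap* is an organization that could have, but did not, refer
clients for services it does not itself provide. `detect_gaps()` implements
two rules per catalogue domain:

* **domain mode** — flagged iff the organization provides no code of the
  domain and has no out-arc to any provider of the domain;
* **partial mode** — flagged iff it provides a nonempty strict subset of the
  domain's codes ("few HIV services") and has no out-arc to any *other*
  provider of the domain.

"Could have referred" is operationalised as: any out-arc to a qualifying
provider counts, whatever its surveyed frequency — the motivating analyses
count "at least one client". Both rules are monotone: adding an arc never
creates a flag, removing a service never removes a domain-mode flag; the
suite checks this over a thousand random perturbations, plus exhaustive
oracle equivalence on small networks. `gap_grid()` emits the audit grid used
for visual inspection: cell (i,j), nonempty only where the arc exists, lists
the domains i needs that j covers; a row scan of the grid reproduces the
domain-mode flags.

## Workshop artifacts

`directory()` (one entry per organization with services rendered as domain
labels) and `complementary_table()` (for each organization, the others
offering at least one service it lacks) reproduce the two handouts used to
feed results back to the network members; contact fields are synthetic
placeholders. `export_sociogram()` writes DOT or GraphML for downstream
drawing — data export only, no layout; GraphML round-trips through
`import_sociogram()` with node/edge sets and the mixing matrix preserved.

## The synthetic fixtures

The raw sociometric data of the motivating study are unpublished, so the
packaged networks are *synthetic stand-ins* built to satisfy every printed
marginal simultaneously (`make_paper_fixture()`): organization-type counts,
service mixes, client/staffing medians (pinned by construction at the middle
order statistic), arc counts, dyad censuses, the four-FBO clique with a
single outgoing arc, the family-planning gap counts (exactly two uncovered
HIV-only organizations in Kirkos, none in Kolfe), and the hospital hub.
Edge placement is constraint-first: the planted structures and the
mutual-dyad quota are placed explicitly, then asymmetric arcs are filled in
by seeded rejection sampling under caps (no new arcs out of the clique or
the gap organizations; in-degrees capped below the designated hub). The
dyad censuses are (9, 51, 240) for Kirkos — the unique integer solution
consistent with m = 69 and dyadic reciprocity 0.83 — and (15, 71, 239) for
Kolfe, one of the two integer solutions rounding to 0.78 (the alternative,
(14, 73, 238), differs only in the third decimal; one had to be chosen and
the choice is fixed). The Kirkos hub in-degree of 7 and the Kolfe hospital
in-degree of 17 place the in-degree centralizations at 0.184 and 0.546,
inside the ±0.05 soft band around the printed 0.192 and 0.525.

One printed inconsistency is resolved in favour of the attribute table: the
narrative says six Kolfe organizations provided no family planning, while
the attribute table's arithmetic (5 HIV-only + 1 FP-only + 20 both = 26)
gives five; the fixture has five HIV-only organizations and the narrative
count is not targeted.

What the fixtures do *not* emulate: the true (unpublished) adjacency
structure beyond these marginals, per-organization client:staff ratio
medians (medians of ratios over-constrain samples of 25; they land within
roughly ±15% but are not pinned), real geography (coordinates are uniform in
a 10 × 10 km box and "driving distance" is Euclidean), and any attribute–tie
dependence that was not printed. Tests passing on the fixtures therefore
validate the *machinery* against the published marginal constraints; they
are not evidence about the real networks.

`random_network()` and `nomination_fixture()` generate the stochastic side:
ERGM-simulated networks over sampled attributes for parameter-recovery and
calibration experiments, and nomination censuses that exactly recover a
network's roster while planting the cases the inclusion rule must
discriminate (a once-named non-private distractor to exclude, private
clinics named only once to admit). Fixture generation is deterministic —
fixed internal seeds, pinned RNG kind — down to the bytes of the written
CSVs.

## Problem sizes and statistical checks

The suite's statistical checks run at sizes chosen to make their expected
sampling error an order of magnitude below the asserted tolerance: 200
Metropolis draws for closed-form mean checks (density 0.5 ± 0.02 at θ = 0;
mean arc count 69 ± 3 at θ = logit(0.115)); 100 replicates at n = 25 for
parameter recovery (both coefficients within 2 SE in ≥ 90 of 100) and for
the null-distance calibration (declared not-associated in ≥ 90 of 100
seeds); exhaustive enumeration of all 4096 digraphs on 4 nodes for the
metric oracles and the MPLE = MLE identity; 1000 perturbations for gap
monotonicity.

## Known limitations

* Only dyadic-independent ERGM terms; no structural dependence terms, no
  MCMC-MLE, no goodness-of-fit suite beyond recovery tests.
* No cross-sub-city ties (the motivating census did not measure them), no
  longitudinal structure, no exchanges other than client referrals.
* Gap detection is organization-level; it says nothing about client-level
  unmet need.
* The printed centralizations and the original ERGM coefficient table are
  not reproduction targets: the raw data and the exact model specification
  are unavailable.
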