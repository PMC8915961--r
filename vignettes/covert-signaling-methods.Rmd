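---
title: "Methods: covert and overt identity signaling under mixed audiences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covert and overt identity signaling under mixed audiences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covertsig)
```

## The problem

People signal their political identity online both overtly (slogans,
partisan declarations) and covertly, through references that only
like-minded insiders decode. Covert signals let a sender collect some of
the assortment benefit of being recognized by the ingroup while avoiding
part of the cost of being recognized -- and disliked -- by the outgroup.
`covertsig` implements the quantitative machinery for studying this
trade-off: a closed-form payoff model, a rater-based procedure that flags
covert and overt messages from how differently located raters perceive
them, a follower-network pipeline that finds accounts likely to produce
such messages, and the statistical analysis of a sharing experiment in
which audience composition and dislike costs vary.

Everything runs offline: a synthetic-data module generates every input the
pipeline consumes, with planted ground truth, so each stage is testable
end to end.

## The payoff model

An audience of size $n$ contains a proportion $d$ of outgroup members.
Overt signals are received (their identity content perceived) by every
audience member with probability $R$. Covert signals are received by
ingroup members with probability $r_I < R$ and by outgroup members with
probability $r_O < r_I$. A receiving ingroup member likes the signal
(benefit $b$), a receiving outgroup member dislikes it (cost $c$), and
$w_0$ is the baseline payoff. The expected payoffs to pure strategies are

$$W_O = w_0 + R\,[(1-d)\,n\,b - d\,n\,c], \qquad
  W_C = w_0 + r_I\,(1-d)\,n\,b - r_O\,d\,n\,c.$$

The covert advantage $W_C - W_O$ is affine and increasing in $d$; it
crosses zero at

$$d^* = \frac{b\,(R - r_I)}{b\,(R - r_I) + c\,(R - r_O)},$$

so covert signaling is favored exactly when the audience is more than
$d^*$ outgroup. The calibration used throughout the package and its tests
is $n = 10$, $b = 1$ cent, $c \in \{0.5, 1\}$ cents, and reception
probabilities $R = 0.8$, $r_I = 0.6$, $r_O = 0.5$ (estimated from
first-stage like/dislike rates; note $r_O > 0$ -- covert signals reduce
but do not eliminate outgroup dislikes):

```{r payoff}
env <- signaling_env(n = 10, d = 0.9, R = 0.8, r_I = 0.6, r_O = 0.5,
                     b = 1, c = 1)
payoff_advantage(env)
covert_threshold(env)                      # high cost: d* = 0.4
covert_threshold(signaling_env(n = 10, R = 0.8, r_I = 0.6, r_O = 0.5,
                               b = 1, c = 0.5))  # low cost: d* = 4/7
```

`simulate_signaling_round()` is the Monte-Carlo counterpart (per-member
Bernoulli reception); its sample mean converges to the closed form and is
used as an independent check in the tests. Numerical choices: $d\,n$ is
rounded to the nearest integer outgroup count in simulation (the
experiment only uses $d\,n \in \{1,4,6,9\}$), with the realized $d$
recorded; the analytic functions treat $d$ continuously. The ordering
$r_O \le r_I \le R$ is validated non-strictly by default (ties warn,
`strict = TRUE` errors), because ties are degenerate but not meaningless.
When the advantage does not depend on $d$ at all, `covert_threshold()`
returns a flagged `NA` rather than a number. Mixed strategies are exposed
as the linear interpolation `mixed_strategy_payoff()`; the analysis itself
concerns pure strategies.

## Rater-based classification of covert and overt messages

Raters from four political groups (far left, moderate left, moderate
right, far right) judge each message on two dimensions: perceived
political orientation of its author (7 points, coded $-3..+3$, left
negative, or "not political") and an affective response (two items --
felt negativity and expected offensiveness to similar people -- averaged
into one score; higher = more negative). Messages need at least three
raters from every group to be included. Per tweet and group we compute the
mean orientation among raters who judged it political, the fraction
judging it political, and the mean affect score.

A message is a *covert* candidate for a side when (1) the far-vs-moderate
copartisan orientation gap and (2) affect gap are large, (3) moderates are
neutral or predominantly answer "not political", (4) moderates' affect is
neutral-or-positive, and (5) far copartisans recognize it as political.
It is an *overt* candidate when (1) all groups agree on the author's side
(small cross-partisan orientation gap), (2) the cross-partisan affect gap
is large, (3) the copartisan affect gap is small, and (4) all four groups
recognize it as political. Both families additionally require the far
copartisans' mean orientation to lean toward the candidate side, which is
what anchors a candidate to "left" or "right". A message passing more
than one category is recoded as neither and flagged.

Design choices worth stating explicitly:

* *Gap cutoffs are percentiles of the dataset at hand* (pooled over both
  sides, which makes the procedure exactly symmetric under a left/right
  mirror -- a property the tests check bitwise). Bands and minima are
  absolute values on the response scales. All defaults live in
  `classification_thresholds()`; none are hidden. The percentile defaults
  are calibrated on the default synthetic world, where each archetype is
  20% of messages; with rarer candidates (as in a real corpus) they should
  be raised.
* *"Not political" handling*: excluded from the orientation mean (a
  conditional mean among recognizers) but counted in the recognition
  fraction. A group with no recognizers has an undefined orientation mean,
  which enters gap statistics at the scale midpoint (0) -- the
  "not recognized" reading -- rather than erroring.
* *Affect polarity*: higher = more negative/offended, so
  "neutral or positive" means *at most* the neutrality cutoff. The two
  items' correlation is checked; a negative dataset-level correlation
  warns of a reversed scale.
* *Ranking*: within a category, candidates are ordered by the mean of
  per-criterion percentile ranks (equal weights), ties broken by tweet ID.
  The composite orders candidates for the preselection cap (default 30);
  it never decides pass/fail.

### Interrater reliability decomposition

`rating_variance_decomposition()` fits intercept-only random-effects
models of the orientation ratings over all subsets of the factors
{tweet, rater, rater group} (maximum likelihood), measures each subset's
explained variance by McFadden's pseudo-$R^2$ against the fixed-intercept
model, and attributes the full model's explained share to factors by their
Shapley values. Efficiency (shares summing exactly to the total explained
share) holds by construction and is asserted to $10^{-10}$ in tests. The
output separates "share of total variance" from "share of explained
variance", whose product relationship is the arithmetic behind statements
like "raters explain 10% of the explained variance, i.e. 5% of the
total".

## Follower-network pipeline

An account's side comes from its media diet: the proportions of a curated
list of 43 far-left and 50 far-right news accounts it follows
(argmax; equal proportions give `none` with a tie flag). Accounts are
*engaged* if they follow at least the side's median threshold (3 left, 4
right) of copartisan news accounts and *disengaged* if they follow at most
one in total. Seeds are classified per side by two top-20% rankings over
their followers: highest proportion of engaged followers -> *homogeneous*
network; highest proportion of disengaged followers -> *heterogeneous*.
A seed in both top sets is `neither` with a conflict flag; ties in any
ranking break deterministically by account ID.

`filter_tweets()` implements the ratability rules, in order: at most 6
weeks old (42 x 86400 s, UTC), not a reply, no image or news link,
English, and long enough -- fewer than 5 whitespace-delimited words *or*
fewer than 50 characters (measured on link-stripped text) removes the
tweet unless it contains a hashtag token. Remaining links are stripped
from the kept text, then retweets and exact-text duplicates are removed.
The disjunctive reading of the length rule is the stricter, literal one.
Language is a tag carried by the record (a pluggable predicate), so tests
never depend on a detector. The filter is idempotent and its per-rule
tallies are order-invariant.

## The behavioral experiment and its analysis

Participants (one audience arm each: strictly copartisan or partly
cross-partisan) play 8 rounds crossing outgroup size
$\{1, 4, 6, 9\}$ of $n = 10$ with dislike cost $\{0.5, 1\}$ cents, sharing
up to 20 covert and 20 overt messages per round from a 40-item menu.
`compute_round_payout()` applies the majority rule: +$b$ per member who
liked a *strict* majority (> half) of the shares, $-c$ per member who
disliked a strict majority, 0 otherwise; with zero shares nobody holds a
majority and the baseline is returned, flagged. The worst-case difference
in losses between cost conditions, `max_cost_exposure_difference()`, is
20 cents for this design -- small, which is why a weak cost effect is
expected. `reception_rates()` recovers $R$, $r_I$, $r_O$ from first-stage
like/dislike data as the cell rates described above.

Counts of tweets shared per round are modeled with a mixed-effects Poisson
regression (`fit_poisson_glmm()`, via `lme4`): outgroup size enters as a
categorical factor (the design contrasts specific sizes, so no linearity
is imposed), cost as a factor, and age, gender, race, education and
political group as adjustment covariates. The default random-effects
structure nests the outgroup condition within individuals (participant
intercept plus participant x outgroup-size intercept); a participant-only
sensitivity mode is provided. With a single scalar random effect the
likelihood uses adaptive Gauss-Hermite quadrature (default 15 nodes); with
the nested structure `lme4` offers only the Laplace approximation, which
is what the default uses. A constant response makes the random effects
unidentifiable, and the fit falls back to the plain Poisson regression
(the exact maximum-likelihood solution of that degenerate case). The
degenerate zero-variance case is also the oracle used in tests: with
$\sigma_u = 0$ planted, the GLMM's fixed effects must match an independent
`glm()` fit to $10^{-6}$ relative tolerance.

*Average predictive margins* set every observation's condition to a cell
value, predict, and average over the sample's covariate distribution.
Under the log link, integrating a Gaussian random intercept out multiplies
the fixed-effect prediction by $e^{\sigma^2/2}$; this marginal prediction
is the default, with a conditional (random effects at zero) mode for
comparison. The *average marginal effect* (AME) between two cells is the
difference of margins, with a delta-method standard error over the
fixed-effects covariance (the random-variance estimate is treated as
fixed) and normal 95% intervals. Model comparison uses the BIC
approximation to the Bayes factor, $BF_{01} = e^{\Delta BIC / 2}$ with
$\Delta BIC = BIC_1 - BIC_0$, values above 1 favoring the null;
`bic_bayes_factor()` refuses models fit to different observation counts.

`strategy_profile()` summarizes covert proportions per condition cell
(zero-share rounds have an undefined proportion: excluded from proportion
summaries, counted separately, retained in count models), and
`theory_consistency_score()` asks whether participants who shifted toward
covert sharing as the outgroup grew earned more: the per-participant slope
of covert proportion on outgroup size, correlated with total earnings.

## What the synthetic world emulates -- and what it does not

The generators plant known structure at the study's conditions so that
every downstream stage has a recoverable ground truth:

* **Ratings** (`generate_rating_dataset()`): 100 tweets per archetype
  (covert/overt x left/right, plus apolitical), four rater groups of 60,
  five raters per group per tweet assigned by a balanced incomplete design
  (so the inclusion rule holds by construction; a pool too small to cover
  it errors, naming the shortfall). The perception matrix encodes the
  study's perceptual assumptions -- far copartisans recognize covert
  copartisan signals (95%) and like them; moderates mostly miss them
  (10%); overt signals are recognized by nearly everyone, liked by
  copartisans, disliked by cross-partisans; apolitical tweets are rarely
  judged political (5%). Far cross-partisans partially recognize covert
  signals (35%), matching the calibrated reception rates, under which
  covert signals reduce but do not eliminate outgroup detection
  ($r_O = 0.5 > 0$). The two affect items are drawn with a
  within-cell correlation of 0.70.
* **Follower worlds** (`generate_follower_world()`): 40 engaged seeds per
  side, 20% planted homogeneous (75% engaged followers), 20%
  heterogeneous (75% disengaged), the rest intermediate -- matching the
  top-20% selection so planted labels are recoverable.
* **Experiment** (`generate_experiment_dataset()`): 481 participants split
  across arms, shared Gaussian random intercept ($\sigma_u = 0.3$ on the
  log scale) across a participant's covert and overt intensities, planted
  *marginal* cell means: covert rising 2.00 -> 2.73 across outgroup sizes
  in the cross-partisan arm (a planted covert AME of +0.73 tweets) and
  totals falling 12.0 -> 6.62 (planted total AME of -5.38); flat in the
  copartisan arm and across cost conditions (the planted nulls for the
  Bayes-factor checks). Counts are clipped at the menu caps (20 covert /
  40 total) with the truncation rate recorded; at the planted means
  truncation is negligible.

Real data differ in ways the synthetic world deliberately ignores: rating
scales arrive with house-specific anchors and missingness; covertness is
continuous rather than five clean archetypes; rater assignment is not
balanced; audience behavior is richer than independent Bernoulli
reception; and participants' strategies are mixed and heterogeneous.
Passing the planted-recovery tests therefore demonstrates that the
*procedures* are implemented correctly, not that the thresholds or the
perception matrix describe any particular real corpus. The adapters
(`read_table()` with a column map) exist so deposited data in a foreign
column layout can be fed through the same pipeline unchanged.

## Problem sizes and reproducibility

The test suite and the acceptance script use: $10^5$ Monte-Carlo
replications for payoff agreement (3-standard-error bands); 500 tweets x
20 ratings for classification recovery; 481 x 8 rounds for the
coefficient-recovery fit; and 100 replications of a 60-participant world
for AME confidence-interval coverage (accepted between 90% and 99%).
Every generator takes an explicit seed and reproduces its output
bit-for-bit; `run_pipeline()` writes a manifest (config, seed, package
version) alongside its artifacts so a run can be regenerated exactly.

## Known limitations

* The selection criteria's exact cutoff values and affect-item scale
  anchors are corpus-specific; the implementation exposes them all as
  configuration and documents its defaults as synthetic-world
  calibrations.
* The nested random-effects structure is a reconstruction of "condition
  nested within individuals"; the participant-only mode exists precisely
  so the structure can be varied.
* Margins treat the estimated random-intercept variance as known when
  propagating uncertainty; with hundreds of participants this is a
  second-order effect.
* The payoff model is a pure-strategy, single-round account; audience
  feedback across rounds and continuous covertness are out of scope.
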