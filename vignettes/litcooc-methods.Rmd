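---
title: "Keyword co-occurrence analysis of abstract corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyword co-occurrence analysis of abstract corpora: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litcooc)
```

## The problem

Clinical syndromes that cut across medical disciplines — the constellation
of osteoporosis, sarcopenia, malnutrition, gait impairment, fall risk and
frailty converging on fragility fractures in older adults is the motivating
example — are hard to delineate from any single specialty's literature.
One way to ask whether such a constellation is coherent *as a body of
literature* is bibliometric: annotate every abstract in a large corpus with
a curated set of binary keyword indicators and quantify (i) which keywords
are disproportionately prevalent in abstracts about the condition of
interest relative to a comparison set, and (ii) how strongly keywords
co-occur pairwise across the whole corpus. `litcooc` implements that
pipeline end to end, together with a synthetic corpus generator whose
ground truth is known in closed form, so every stage can be validated
without access to a multi-million-document bibliographic database.

## Corpus cleaning

Readers ingest MEDLINE/PubMed citation XML (structured abstracts are
concatenated in document order, section labels dropped) or a line-delimited
JSON record format. Cleaning applies three filters to the
whitespace-trimmed abstract, attributing each exclusion to the first
failing rule so the report is a partition of the input:

1. the abstract must be non-empty;
2. its length must lie in the inclusive range 250–4000 characters
   (Unicode code points; the bounds are configurable);
3. its final character must be `.`, `?` or `!` — a proxy for truncated
   records.

The range endpoints are treated as inclusive — the natural reading of a
dash range — and length is measured on the abstract only, not the title.
Year and journal are carried through but never filtered on.

## Keyword annotation

The default taxonomy holds 29 terms in six concept groups: fracture
outcomes (hip/femur/spine/fragility fracture, fracture, fragility), their
underlying pathologies (osteoporosis, sarcopenia, malnutrition, gait,
fall, frail, cognitive impairment), old-age terms (older adult, `elderl*`,
`geriatr*`), trauma controls expected to associate with high-energy rather
than fragility fractures (sport, `athlet*`, trauma, young, high-energy),
and metabolic syndrome outcomes and pathologies as an established
reference syndrome.

Matching semantics are deliberately strict and fully specified:

* tokens are maximal runs of letters; digits, punctuation and hyphens
  delimit;
* matching is case-insensitive;
* a plain term matches a whole token only (`fall` does not fire on
  "falling" — the wildcard is reserved for explicitly marked prefixes);
* a trailing `*` matches any token starting with the stem (`geriatr*`
  fires on "Geriatrics");
* multi-word patterns match their token sequence in order, separated by
  runs of whitespace and/or hyphens, so `high-energy` fires on
  "high energy" and `hip fracture` on "hip-fracture", but not on
  "hip, fracture" and not on the plural "hip fractures". A per-pattern
  wildcard on the final phrase word (`hip fract*`) is available for
  sensitivity analyses.

No stemming, negation handling or MeSH expansion is attempted: the design
is a bag-of-words presence model, and "no osteoporosis" counts as
presence. Only abstracts are searched; titles are metadata. The matchers
are regular-expression based but are tested for exact agreement with a
brute-force token-window scanner on randomized fixtures.

Annotation produces a sparse binary documents-by-keywords matrix — the
pipeline's central object. Note the *textual nesting* this creates: any
abstract containing the phrase "hip fracture" necessarily contains the
token "fracture", so container keywords are supersets of their phrases.

## Prevalence contrast

The corpus is split by annotation into a **query** set (abstracts
containing both "fragility" and "fracture") and a **background** set
("fracture" without "fragility"); abstracts with neither the anchor term,
or "fragility" alone, belong to neither. For each keyword the two
prevalences are compared with the pooled two-proportion z-test

$$z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)}},
  \qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

two-sided, without continuity correction (the intended setting is
corpora of thousands to millions of documents; small-sample fixtures test
the formula, not the approximation). The pooled form is the standard
choice under the null of equal proportions. P-values are
Bonferroni-adjusted over the keywords actually tested; the two
subset-defining keywords are excluded by default because their contrast
is degenerate by construction (prevalence 1 vs 0, and 1 vs 1). Results
are ranked by signed prevalence difference.

## Pairwise association

Every unordered keyword pair is tabulated into a 2×2 contingency table
over *all* corpus documents (no subset restriction). Association strength
is the phi coefficient

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
  {\sqrt{r_1\,r_0\,c_1\,c_0}},$$

identically the Pearson correlation of the two binary indicators.
Independence is tested with the Pearson chi-squared statistic (no
continuity correction; on a 2×2 table it equals $N\phi^2$) when every
cell holds at least five documents, and with Fisher's exact test
otherwise; the threshold of five is exposed as a parameter. The
two-sided Fisher p-value uses the minimum-likelihood convention — the sum
of hypergeometric point probabilities not exceeding that of the observed
table, with ties accepted at a relative tolerance of $10^{-7}$ — because
several two-sided definitions exist and this is the most common one.
Tables with a zero margin (a constant keyword) admit neither $\phi$ nor a
test; they are recorded as degenerate, masked, and excluded from the
multiple-testing family.

Raw p-values are adjusted over the family of all tested pairs with the
**Holm step-down** procedure, reported as `q`. Holm controls the
familywise error rate; it is sometimes loosely described as an FDR
procedure, and to keep that ambiguity explicit rather than silently
resolved, Benjamini–Hochberg and Bonferroni are selectable alternatives.
Cells with $q \ge 0.05$ are blanked in the rendered matrix; a flag can
switch the mask to raw p-values, since either convention appears in
published heatmaps of this kind.

## The synthetic corpus generator

The generator is a **latent-class (finite mixture) model**: each document
draws a hidden class $c$ with probability $\pi_c$, then includes each
keyword $k$ independently with probability $\theta_{kc}$. This choice —
rather than directly specifying pairwise correlations — guarantees a
valid joint distribution for all 29 binary indicators and yields all
moments in closed form:

$$p_k = \sum_c \pi_c \theta_{kc}, \qquad
  p_{11}(i,j) = \sum_c \pi_c \theta_{ic}\theta_{jc}, \qquad
  \phi_{ij} = \frac{p_{11} - p_i p_j}{\sqrt{p_i(1-p_i)\,p_j(1-p_j)}}.$$

A single class makes all keywords independent (every analytic $\phi$ is
zero) — the null configuration used for calibration studies. Two
equi-weighted classes with $\theta = 0.9$ and $0.1$ for a pair of
keywords give $p = 0.5$, $p_{11} = 0.41$ and analytic $\phi = 0.64$
exactly — the reference configuration for recovery tests.

Included keywords are realised once as a canonical surface form
("geriatric" for `geriatr*`), always separated by neutral filler words, so
that matcher semantics — not string accidents — determine annotation. The
filler vocabulary is checked at construction time: no filler word may fire
any matcher or equal a component word of any phrase (which could otherwise
complete a phrase across an insertion boundary). Abstracts are padded to
a length inside the cleaning window and terminated with a period, so every
sampled document passes the default filters by construction. Sampling is
deterministic given the seed and restores the caller's RNG state.

`sample_annotation()` draws the indicator matrix directly from the same
law without realising text. For keyword sets without textual nesting the
two routes are identically distributed (the suite checks their moments
agree), and the direct route is used for large replicate studies such as
null calibration, where text realisation would add cost but no
information.

**What the generator does not emulate:** real language (filler is a
closed neutral vocabulary), inflected or misspelled keyword variants,
correlated document lengths, journal/discipline structure beyond a
class-indexed synthetic journal name, and — most importantly — textual
nesting effects: when a configuration plants both a phrase ("hip
fracture") and its container token ("fracture"), the annotated prevalence
of the container exceeds its planted marginal, because insertion of the
phrase also realises the token. Analytic moments describe the planted
indicator law; moment-recovery tests therefore use non-nested keyword
pairs, and the packaged scenario handles the query/background membership
tokens explicitly (below). Passing tests show the statistics recover a
known joint law from realised text; they cannot show anything about
matcher recall on real-world prose variation.

## The packaged fracture scenario

`make_ofs_scenario()` plants four classes: an orthogeriatric class (10%)
in which the tokens "fragility" and "fracture" are always present (as
separate insertions, so the phrase "fragility fracture" is planted
independently at a lower rate), osteoporosis at 0.50 and the other
fracture pathologies and old-age terms elevated; a trauma class (15%)
with "fracture" always present, no "fragility", osteoporosis at 0.10 and
elevated sport/athlete/trauma/young/high-energy terms; a metabolic class
(15%) with elevated metabolic outcomes and pathologies; and a neutral
background (60%). Fracture-containing keywords are disabled outside the
two fracture classes, so query membership (fragility AND fracture) is
exactly the orthogeriatric class and background membership (fracture
without fragility) exactly the trauma class, up to sampling. The planted
osteoporosis contrast is therefore 0.50 vs 0.10 — the largest planted
difference of any keyword — and within-class elevation produces the
block-positive phi structure (pathology–pathology, outcome–outcome,
old-age–pathology) with near-zero or negative phi across classes that the
association stage should, and in the test suite does, recover.

The baseline rates (2% background inclusion for non-fracture keywords,
5% cross-class leakage for most terms) keep every margin positive at
realistic corpus sizes so no pair is degenerate, while remaining an order
of magnitude below the planted within-class rates.

## Numerical and design choices

* **Problem sizes.** Recovery tests run at $N = 10^5$ documents, where
  binomial error on a prevalence of 0.5 over a 10%-weight class is about
  0.005 — comfortably inside the ±0.02 assertions. Null calibration uses
  1000 replicate corpora of $N = 2000$; the familywise rate of any
  Holm-significant pair is asserted against
  $0.05 + 2\sqrt{0.05\cdot0.95/1000} \approx 0.064$.
* **Exactness checks.** $\phi$ is compared to `cor()` on expanded 0/1
  vectors at $10^{-12}$; the Fisher p-value is compared exactly (within
  $10^{-12}$) to an independent binomial-coefficient enumeration on *all*
  2×2 tables with $N \le 40$, and spot-checked against
  `stats::fisher.test`.
* **Chi-squared vs exact p.** The two-sided exact p-value is a discrete
  statistic; its pointwise gap to the uncorrected chi-squared p-value at
  moderate cell counts (20–80) can reach ~0.1 in the mid-range even
  though both tests agree asymptotically. The suite asserts the mean gap
  shrinks across cell-size bands rather than a pointwise bound that does
  not hold.
* **Degenerate inputs.** Zero-margin tables return `NA` phi with a
  reason, p = 1 with a degeneracy flag from the tests, and are excluded
  from adjustment families. A pooled proportion of 0 or 1 in the z-test
  likewise returns a flagged p = 1.
* **Tie-breaks.** Contrast ranking is by signed difference; ties keep
  matrix column order. Keyword panel order is the concept-group order
  with input order within groups.
* **Seeds.** Generator configurations carry their seed; all stochastic
  tests fix seeds explicitly; sampling never perturbs the caller's RNG
  stream.

## Limitations

The pipeline measures literature co-occurrence, not clinical association:
phi on a corpus reflects writing and indexing practice. The matcher's
strict phrase semantics undercount inflected phrase variants ("hip
fractures"); the wildcard opt-in exists precisely to measure that
sensitivity. The discipline profiler is structural — it applies a
user-supplied journal→discipline map and makes no attempt to classify
journals itself, because any bundled taxonomy would be editorial
invention. Corpus-scale headline numbers from multi-million-record
bibliographic databases depend on the database snapshot and are outside
what a synthetic validation can or should reproduce; the package
validates the *method*, and applies to such corpora when the user
supplies them.

## A worked example

```{r example, eval = FALSE}
cfg <- make_ofs_scenario(20000, seed = 1)
corpus <- sample_corpus(cfg)
cleaned <- clean_corpus(corpus)
m <- annotate(cleaned$corpus)

head(contrast_keywords(m), 3)
net <- association_network(m)
net
round(masked_phi(net)[1:6, 1:6], 3)
```
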