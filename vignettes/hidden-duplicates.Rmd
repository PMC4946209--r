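---
title: "Estimating hidden duplicate registrations in multi-registry trial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hidden duplicate registrations in multi-registry trial data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialdedup)
```

## The problem

A clinical trial may be registered in several registries (and, in the EU
register, once per member state), so a consolidated portal such as the WHO
ICTRP contains multiple *records* for one *trial*. The portal groups some
records as duplicates by matching free-text secondary identifiers against
registry IDs; pairs it fails to group are *hidden duplicates*. Hidden
duplicates inflate trial counts, distort systematic reviews, and bias
registry-based meta-research. `trialdedup` implements a complete,
design-based pipeline for quantifying them:

1. **Consolidation** (`parse_corpus()`, `consolidate_variants()`): variants
   are collapsed to one record per registration, choosing the
   first-registered variant; titles are concatenated (public title,
   scientific title, acronym) because registries use those fields
   inconsistently.
2. **ID linkage** (`match_ids_to_records()`, `build_groups()`): secondary-ID
   tokens that equal another record's registry ID create edges; duplicate
   groups are the connected components. This reconstructs the portal-style
   *known* duplicates.
3. **Similarity** (`build_field_index()`, `all_pairs_above()`): records are
   scored with an IDF-weighted, binary, field-tagged cosine; every pair at
   or above a threshold (0.5 by default) is found exactly.
4. **Estimation** (`estimate_hidden()`): candidate pairs (not known
   duplicates) are sampled per similarity range, rated, and the rated
   proportions are converted into hidden-duplicate counts with exact
   binomial confidence intervals and extrapolated to an overall
   percentage.

## The similarity model

Each scored field (the concatenated title, condition, intervention,
outcome, inclusion criteria) gets its own index. Text is case-folded,
deaccented and tokenized into maximal runs of `[a-z0-9]`. A term occurring
in `df` of `N` records receives weight

$$w(t) = \ln(N / \mathrm{df}(t)),$$

zero for stop words. Term multiplicity within a field is ignored (binary
presence), and the same word in two fields is two distinct features, so a
record is a sparse vector of field-tagged weights and similarity is the
cosine

$$s(a, b) = \frac{\sum_t w_a(t)\, w_b(t)}{\lVert a \rVert\, \lVert b \rVert} \in [0, 1].$$

Redacted records — public title `"N/A"` or the device-redaction marker —
always score zero. The title field is the operational field: on both real
and synthetic corpora it separates duplicates from non-duplicates best,
because titles concentrate trial-specific rare tokens that IDF weighting
amplifies.

The IDF form $\ln(N/\mathrm{df})$ without smoothing is a deliberate fixed
choice; any monotone variant would order pairs almost identically, but a
single formula keeps scores reproducible across runs and machines.

### The lossless thresholded join

`all_pairs_above()` returns *exactly* the pairs with cosine at or above the
threshold, without scoring all $n(n-1)/2$ pairs. Two prunings are used,
both provable:

* a pair with no shared positively weighted term has cosine exactly 0, so
  candidate generation can be restricted to an inverted index;
* processing a record's features in decreasing-weight order while tracking
  the Euclidean norm of the unprocessed suffix, a pair first encountered
  when that norm is below the threshold satisfies
  $\mathrm{dot} \le \lVert\text{suffix}\rVert \cdot 1 < \text{threshold}$
  and can be skipped; pairs already open keep accumulating.

A brute-force enumeration oracle (dense cross-product of the normalized
record-term matrix) is kept in the test suite and the join is checked
against it exactly on a hundred random corpora. Scores at the threshold are
included (`>=`), guarded by a `1e-12` epsilon against floating-point
round-off; the same epsilon is applied in the oracle so both routes use one
comparison convention.

## The estimator

For a score range $(l, u]$ containing $N$ candidate pairs and $K$ known
duplicate pairs, a uniform without-replacement sample of $n$ candidates is
rated; $x$ are judged duplicates. Then

$$\hat{U} = \frac{x}{n} N, \qquad
  \text{pct hidden} = 100\,\frac{\hat{U}}{K + \hat{U}},$$

and the exact Clopper–Pearson bounds for $x/n$ are pushed through the same
formula — valid because the percentage is strictly increasing in the
proportion. The Clopper–Pearson interval is computed via the beta-quantile
identity and validated in the tests against a binomial-tail bisection
oracle (tolerance `1e-9`) and `stats::binom.test`.

The overall percentage extrapolates beyond the examined ranges by dividing
the summed unknown estimates by the *coverage* — the fraction of known
duplicate pairs inside the examined ranges — under the assumption that a
duplicate's probability of being hidden does not depend on its similarity
score. The overall confidence interval sums the per-range bound-mapped
unknown counts; for a sum of independent conservative intervals this is
itself conservative, which simulation confirms (empirical coverage of the
planted value is well above 95%).

`required_sample_size()` inverts the interval: the smallest $n$ whose
Clopper–Pearson interval at the expected success count lies inside a
target band, which is how one decides whether rating the next, sparser
score range is affordable.

Reported percentages are rounded half-away-from-zero to integers
(`round_half_up()`) only at reporting time.

## The synthetic registry generator

`generate_corpus()` emulates the statistical structure of a multi-registry
corpus, with full ground truth (`registry_truth`), not registry prose:

* **Titles** mix ~8 words from a Zipf vocabulary (size 2000, exponent
  1.07) with two trial-specific rare tokens, so IDF weighting is
  informative — the same mechanism that makes real titles discriminative.
* **Duplicate clusters**: `dup_rate` (default 0.09) of trials carry 2–3
  records across distinct registries; `known_link_fraction` (default 0.55)
  of clusters link their records by secondary ID (later records cite the
  first record's registry ID, for EUCTR sometimes as a bare EudraCT
  number, sometimes packed with the protocol ID into one field). Hidden
  clusters carry no linking IDs but share a sponsor protocol ID, so the
  adjudication rules have something to find. The defaults echo a corpus in
  which 9% of records have a known duplicate and roughly half of all
  duplicates are identified.
* **Exact planting**: the known fraction is assigned as a fixed,
  size-stratified count of clusters rather than per-cluster coin flips.
  The planted hidden fraction is the estimand that recovery simulations
  are judged against, so the generator realizes it up to rounding
  (residual spread ~0.2 percentage points) instead of adding binomial
  noise (~2.5 points at 5000 trials) that no sampling-stage confidence
  interval could absorb. `dup_rate`, redaction, nonsense-ID and grant-ID
  rates remain Bernoulli.
* **Perturbation**: each title word is independently perturbed per record
  with probability 0.08 (half deletions, half substitutions). This value
  was chosen so known-duplicate title scores centre near 0.86 with most
  above 0.5, the regime reported for real registry data.
* **Confounders**: `confounder_rate` of trials spawn a non-duplicate twin
  — same sponsor, same-format protocol ID with a different serial, and a
  near-identical title differing by a contradictory phrase
  (fed/fasting) or an extension-study marker. These populate the
  high-similarity non-duplicate region, without which range sampling would
  be trivially all-duplicates.
* **Registry dialects**: ClinicalTrials.gov-style records carry extra
  outcome terms, EUCTR-style records extra intervention terms and 1–2
  member-state variants with later registration dates.

What the generator does **not** emulate: real prose and multilingual EUCTR
variants, field-format heterogeneity beyond verbosity, portal
false-positive groupings, and secondary-ID schemes that collide between
sponsors. Passing recovery tests therefore demonstrates the estimator's
design-based correctness under its stated independence assumption, not
robustness to every pathology of real registry text.

## Adjudication rules

`adjudicate_pair()` encodes the manual judgment criteria as an ordered
rule engine (first firing rule decides): contradictory near-identical
titles → non-duplicate; shared sponsor plus a shared identifying secondary
ID (longer than five characters, not a US federal grant number) →
duplicate; shared sponsor with distinct same-format IDs (equal
letter/digit skeleton) → non-duplicate; otherwise sufficient title
similarity with non-contradictory start dates (window one year) and
sponsors → duplicate; doubt → non-duplicate. Grant numbers are matched by
an NIH-shaped pattern (optional application-type digit, activity code,
institute code, serial). The engine is a machine-reproducible
approximation of a human rater: on low-noise synthetic corpora it agrees
with planted truth on more than 90% of pairs, and it is deliberately *not*
claimed to reproduce human judgments on real data — the estimation
pipeline takes any rating function (imported human ratings, the rule
engine, or a synthetic-truth oracle).

## Numerical and design choices

* Candidate pools for the published worked examples are derived from the
  printed point estimates as `round(unknown * n / x)`, since pool sizes are
  not printed.
* Score ranges use the `(lo, hi]` convention — a score of exactly 0.8
  belongs to `(0.7, 0.8]`; the default partition is five ranges of width
  0.1 over `(0.5, 1]`. Pairs at exactly the join threshold are kept by the
  join but fall outside the estimation ranges, mirroring the strict
  "above 0.5" estimation regime.
* Variant consolidation ties (equal dates, or missing dates, which sort
  last) break by lexicographic variant suffix for determinism.
* Secondary-ID tokenization splits on whitespace and `,;.` — so dotted
  identifiers split; tokens shorter than 4 characters or on a nonsense
  stop list never create linkage edges.
* The unique-trial adjustment subtracts one trial per estimated hidden
  pair, ignoring overlaps of three or more records; it is reported as an
  approximation.
* `strip_html()` delegates to libxml2's lenient HTML parser, inserting a
  space before each tag so that adjacent words do not merge; strings whose
  *entities* encode markup (e.g. `&lt;b&gt;`) decode to literal markup
  text and would be stripped again by a second pass — an inherently
  ambiguous corner that registry exports do not exercise.

## Problem sizes used in the shipped checks

Worked-example reproductions are desk-scale (closed-form, instant). The
lossless-join validation runs 100 random corpora of 80–850 trials at three
thresholds against the brute-force oracle. The parameter-recovery study
runs 200 replicates at 5000 trials, cycling planted hidden fractions
{0.2, 0.45, 0.6}, and requires the 95% intervals to cover the planted
value in at least 90% of replicates; these sizes keep a full run in the
tens of minutes on one CPU while leaving the binomial machinery exercised
at realistic sample sizes (100 rated pairs per range, as in practice).

## Limitations

The estimator inherits the design's assumptions: hiddenness independent of
similarity score (if violated, hidden duplicates below the threshold are
under-extrapolated), a rating process treated as error-free, and the
one-pair-one-trial merge approximation. The similarity measure is
intentionally simple — no stemming, term frequency, or learned weighting —
because the sieve only needs to concentrate duplicates above the
threshold, not to classify them.
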