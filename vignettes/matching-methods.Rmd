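---
title: "Matching methods: phonetic keys, similarity thresholds, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching methods: phonetic keys, similarity thresholds, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbsmatch)
```

## The problem

HIV case-based surveillance follows individual people from diagnosis
through linkage to care, treatment, and outcomes. Where no universal
health care identifier exists, the same person appears in the register
several times — retested at another facility, re-enrolled after a
transfer, re-entered with a spelling variant — and every duplicate
inflates the cascade. `cbsmatch` implements a deduplication workflow for
this setting: records carry only demographic fields (names, gender, birth
date, diagnosis date, sometimes a facility-issued clinic number), and
matching has to tolerate exactly the corruption that register data
exhibit — typos, punctuation and case variation, dropped middle names,
reformatted clinic numbers, and small disagreements in age.

## Standardization and match keys

Names are cleaned (spaces, commas, apostrophes, and dashes stripped;
lowercased) and then *phonetically* standardized:

* **First names** get an American Soundex code. First names in the
  target population are mostly English baptismal names, which is the tradition
  Soundex was designed for. The variant used keeps the first letter,
  maps consonants to six digit classes, and treats `h`/`w` as
  transparent; `robert` and `rupert` both encode `R163`.
* **Middle names and surnames** get a double metaphone code. These are
  mostly Kenyan (Luo, Swahili, Kalenjin, ...) names, where Soundex's
  initial-letter anchoring misbehaves; double metaphone's
  consonant-skeleton coding discriminates better. The *secondary* code is
  used (falling back to the primary when no ambiguous-pronunciation rule
  fires), capped at the published default length of 4.

Two keys are assembled per record:

* the **match key** for score-based matching — gender initial + Soundex
  of the first name + metaphone of the middle name (omitted entirely when
  absent) + metaphone of the surname + 4-digit year of birth, e.g.
  `fF465aknannk1983` or, without a middle name, `fG620ans1994`;
* the **pseudo-unique key** for deterministic matching — Soundex of the
  first name + gender initial + the cleaned *raw* surname + year of
  birth. Exact equality of this key declares a match; among care-bearing
  records, equality of the normalized clinic (CCC) number is a second
  deterministic rule that catches surname typos the pseudo-key misses.

Keys contain no separators (segment boundaries are retained separately
for diagnostics). An absent middle name shortens the key rather than
inserting a placeholder; the consequences for thresholding are discussed
below.

## Blocking

Records are compared only within blocks, which here are the three
care-cascade scenarios: testing only (HTS), testing-to-care (HTS-care),
and within care. In `exclusive` mode the three scenarios are matched
separately; in `combined` mode HTS and HTS-care form one block, making
pairs that straddle those two scenarios comparable at quadratic cost over
the union. Blocking is the only scale control: within a block every
unordered pair is scored.

## Score-based matching

Four kernels are offered, all operating on match keys:

* **Jaro**: \(d_j = \tfrac13\left(m/|s_1| + m/|s_2| + (m-t)/m\right)\),
  with `m` matching characters inside the standard window
  \(\lfloor\max(|s_1|,|s_2|)/2\rfloor - 1\) and `t` half the transposed
  matches.
* **Jaro-Winkler**: \(d_{jw} = d_j + \ell\,p\,(1-d_j)\), prefix length
  \(\ell \le 4\), penalty factor \(p = 0.1\). The boost encodes that
  recording errors are more likely after the first four characters —
  which is also why the key puts its most reliable segments (gender,
  Soundex initial) first.
* **Weighted Levenshtein** and **weighted Damerau-Levenshtein**: minimum
  edit cost with deletion 0.8, insertion 0.8, substitution 1.0, and (for
  Damerau only) transposition 0.5, normalized to a similarity as
  \(1 - \mathrm{cost}/\max(|s_1|,|s_2|)\). The normalization is a design
  choice — the convention that keeps a 98% threshold meaningful for keys
  of 12–18 characters.

A pair is accepted iff its similarity is at least the threshold (default
**0.98**) *and* the ages are compatible: with full birth dates, the
absolute difference in days divided by 30.44 (rounded half-up) must not
exceed **12 months**; with year-only precision, 12 times the year
difference is used. Rejected pairs within an audit margin (default 0.05)
of the threshold are kept in the output with a reason
(`BELOW_THRESHOLD` / `AGE_MISMATCH`) so a human reviewer can adjudicate
near misses.

### Damerau-Levenshtein semantics

The Damerau variant is the *full* (Lowrance–Wagner) distance, not the
restricted optimal-string-alignment one: a transposed pair may be
separated by material that is itself deleted or inserted (so
`ca → abc` costs one transposition plus one insertion), but each
character participates in at most one transposition. Under the default
weights a chain of adjacent swaps that walks one character across several
positions would be cheaper than any single-participation script; such
chains are outside this model, which matches the convention of the
record-linkage software tradition this measure comes from. The test suite
pins the implementation to an independent edit-script enumeration oracle
over a full small alphabet.

### What the threshold implies at these key lengths

With keys of at most 17 characters, the 98% bar is strict enough that
the edit-distance similarities accept *only* identical keys (a single
transposition on 17 characters already scores \(1 - 0.5/17 = 0.971\)).
Jaro accepts identical keys plus a single transposition at length 17
exactly; Jaro-Winkler additionally accepts transpositions and late
substitutions rescued by the prefix boost. Three consequences, all
verified by the test suite:

* Jaro-Winkler always accepts a superset of Jaro (pointwise dominance),
  and on mixed-corruption synthetic data yields the most duplicates of
  the four — the qualitative ordering the method comparison is about.
* Edit-accepted pairs are a subset of Jaro-accepted pairs, so Jaro can
  yield marginally *more* than Levenshtein here, the reverse of the
  ordering sometimes reported in field comparisons of these kernels.
  Normalization conventions differ across implementations; under a
  different normalization (or longer keys) the edit kernels admit
  near-misses that Jaro rejects, which restores that ordering.
* The age comparator is unreachable at 0.98 on internally consistent
  records: a >12-month birth shift changes the key's year segment, which
  caps every kernel below 0.98, while identical keys force equal years
  of birth and hence age differences of at most 11 months. The
  comparator therefore acts as a guard for (a) looser thresholds, where
  it demonstrably rejects shifted pairs (tested at 0.95), and (b)
  records whose recorded year of birth disagrees with the full birth
  date, as happens when age and birth date come from different source
  documents (tested at the engine level).

## Post-match processing

Accepted pairs are clustered by connected components; each cluster is
resolved to one retained record: the member with the earliest date of
diagnosis (ties: most complete record, then lowest record id), whose
missing fields are filled by an append merge from the other members in
diagnosis-date order. Nonmissing values are never overwritten;
disagreements between nonmissing values (two different clinic numbers,
say) go to a conflict log for adjudication rather than being merged. The
result carries a master patient index (every record id mapped to its
cluster), per-scenario yield counts in the shape used for surveillance
reporting, and the accounting identities
`unique = total − Σ(cluster size − 1)` and `All = Σ scenarios` hold by
construction and are asserted in the tests, as is idempotence: re-running
deduplication on its own output finds nothing.

## The synthetic study

The register data this workflow is designed for are confidential, so
the package ships a generator that emulates their structure and
provides ground truth; all empirical claims in the test suite are claims about this
synthetic population.

* **Structure**: scenario mix 33.5% HTS / 9.0% HTS-care / 57.5% care;
  middle-name completeness 72%; years of birth 1935–2005 (pediatric and
  adult cases); diagnosis dates in a 6-month window in 2015; 124
  facilities; care-bearing records carry canonical-formattable CCC
  numbers. Name pools are curated illustrative lists — English first
  names, Kenyan-style middle names and surnames — and are replaceable;
  no attempt is made to reproduce any particular register's exact
  uniqueness ratios, which depend on pool sizes in ways the package
  documents but does not calibrate.
* **Separability**: distinct generated persons are resampled until no
  two match keys reach Jaro-Winkler 0.98 and no two pseudo-keys collide.
  This is what makes ground truth well defined — no pair of *different*
  persons is indistinguishable to the matcher — and it is why
  formatting-only corruption must be recovered with precision and recall
  exactly 1.0. Real registers offer no such guarantee; with phonetically
  close real populations, precision below 1 at the same threshold is
  expected, and the audit margin exists precisely for that review.
* **Corruption**: a configurable duplicate rate (default 5%, the low end
  of reported duplicate prevalence in medical records) with per-operator
  probabilities: character typos (substitution/transposition at 0.25
  each, deletion/insertion at 0.10 — positions weighted 3:1 toward
  indices past the fourth character), punctuation/spacing/case
  reformatting (0.40), middle-name dropout (0.15), CCC reformatting
  (0.50), birth-date shifts within (0.15) and beyond (0.03) the
  12-month tolerance, cross-scenario placement (0.05), and a
  later-diagnosis offset. The mixed-corruption defaults were chosen once
  as a plausible register-error profile and drive the method-ordering
  study; special-purpose profiles (formatting-only, shift-only,
  cross-scenario-only) isolate single mechanisms for the property tests.
* **Sizes**: the method-ordering study runs at 10,000 base records, the
  recovery study at 5,000, the blocking study at 4,000, and property
  suites at 400–2,000 — sizes at which the quadratic within-block
  comparison completes in seconds while scenario counts are large enough
  for stable orderings.

What passing these tests does *not* show: performance on real Kenyan
registers (name-culture effects are only sketched by the pools), behavior
under systematic transliteration variants (no nickname dictionaries, no
Kenyan-language Soundex — deliberately out of scope), or calibration of
the threshold to a target precision, which the workflow leaves to
adjudication against a local gold standard.

## Numerical and degenerate-input choices

* Jaro of two empty strings is 1, of one empty string 0; keys are never
  empty in practice.
* Edit-similarity normalization floors at 0; equal strings always score
  1 and, with positive weights, score-1 implies equality.
* Two-digit years resolve through a pivot (default 30: `"83"` is 1983,
  `"07"` is 2007); the pivot and the day-first date dialect are
  configuration, never guessed from the data.
* CCC serials are zero-padded, never truncated; more than five serial
  digits is an error rather than a guess.
* A record missing both the diagnosis date and the birth date is
  excluded once, under the diagnosis-date reason (the exclusion counts
  stay disjoint).
* All pair output is canonically ordered (`id_a < id_b`, sorted), and
  matching is purely deterministic given the configuration; the
  generator is the only component holding a random source.

## A worked run

```{r, eval = FALSE}
pop <- generate_population(population_params(n_records = 2000, seed = 1))
inj <- inject_duplicates(pop, corruption_params(), seed = 2)
res <- dedup(inj$records, match_config("jaro_winkler"))
summary(res)
evaluate_matches(res$pairs, inj$truth, inj$records)
```

The same pipeline is scriptable end to end via `run_pipeline()` or the
CLI in `inst/cli/cbsmatch.R` (subcommands `generate`, `profile`,
`dedup`, `evaluate`, `report`), which write pair files, the
deduplicated dataset, the master index, conflict logs, the per-scenario
yield report, and a JSON run manifest.
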