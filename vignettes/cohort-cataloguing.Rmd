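---
title: "Cataloguing cohort metadata: model, search, comparison and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing cohort metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortcat)
```

## The problem

Population-based cohorts collect enormous amounts of data, but the
documentation that would let an outside investigator judge *what* was
collected, *from whom* and *when* is often missing or unstructured. A
metadata catalogue answers three practical questions: is the data
accessible, could it answer my research question, and is it similar enough
across studies to co-analyse? `cohortcat` is a desk-scale toolkit for
building and querying such catalogues.

## The metadata model

The unit of description is the **study** (outline, investigators,
timeline, participant counts, access conditions). A study has ordered
**subpopulations** (e.g. Mothers, Partners, Children), each with
recruitment and selection criteria; each subpopulation has ordered
**data collection events** (waves/follow-ups) with dates and data
sources. **Datasets** — data dictionaries — attach to exactly one data
collection event and list **variables**: name, label, value type, unit,
question text, **categories** (code/label/missing flag) and taxonomy
**annotations**.

Two deliberate looseness decisions: metadata may be incomplete (missing
recommended fields such as objectives or access conditions produce
warnings, never errors, because real catalogues are assembled from sources
of very uneven completeness), and all structural problems are *reported*
(`validate_study()`, `resolve_links()`, `validate_annotations()` return a
report object) rather than thrown, so a whole catalogue can be checked in
one pass.

Partial dates (`2002`, `2001-05`) are ordered by their **earliest concrete
interpretation** (Jan 1, day 1). This is deterministic and conservative:
`start = 2002, end = 2002-01` is legal, `start = 2002, end = 2001-05` is
not. Study timelines are plain years; only collection events carry dates.

## The classification taxonomy

Variables are annotated with terms from a two-level controlled vocabulary
(domain → subdomain). The packaged default, `builtin_taxonomy()`, has 18
domains and 135 subdomains with fixed per-domain counts
(14, 14, 5, 6, 20, 9, 3, 7, 4, 3, 11, 9, 4, 4, 4, 5, 7, 6). Only five
subdomain names are publicly printed (Education; Income, possessions, and
benefits; Tobacco; Alcohol; Pregnancy, childbirth and the puerperium
(O00-O9A)); the rest are **stable placeholders** `<domain-slug>_sub<k>`.
Tests and comparisons therefore rest on counts and on the five real names,
never on placeholder semantics. A variable may carry terms from several
domains; whether production catalogues restrict to one term per domain is
not documented, so this package deliberately allows many.

Term resolution is exact and case-sensitive; display labels are free text.

## Dictionary import/export

Dictionaries are a pair of CSV tables (variables + categories), always
UTF-8, comma-delimited, RFC-4180. Three dialects capture the
*column-naming and missing-code conventions* of common exports:

| dialect | variables columns | missing convention |
|---|---|---|
| `plain_csv` | `name,label,valueType,unit,question` | explicit `missing` flag column |
| `spss_export` | `Variable,Label,Type,Units,Question` | numeric codes ≥ 77 |
| `sas_export` | `NAME,LABEL,TYPE,UNITS,QUESTION` | numeric codes ≥ 97 |

Parsing native `.sav`/`.sas7bdat` binaries is out of scope by design. For
the code-list dialects the missing flag is not stored explicitly, so the
guaranteed identity is the **read → write → read fixpoint** (and full
write → read identity for `plain_csv`); the reserved-code thresholds are
fixed, documented stand-ins for tool-specific conventions. When a type
column is absent, a variable is `integer` if all its category codes parse
as integers, else `text`.

`export_ddi_lite()` writes a minimal DDI-Codebook-flavoured XML
(`codeBook/dataDscr/var/labl|qstn|units|varFormat|catgry`); the fixed
element list ships in `inst/extdata/ddi-lite-schema.txt`. Which DDI
version a production catalogue would target is unstated, hence the
explicit "lite" label.

## Search

Tokenization — shared by the index, the query parser and the classifier —
is case-folding plus splitting on runs of non-alphanumeric characters, no
stemming, no stop-words. This is a reproducible baseline, *not* a claim of
equivalence with any production analyzer.

* `search_variables()`: AND over text tokens (trailing `*` = prefix),
  OR over term annotations, optional study/population/DCE scope.
* `search_studies()`: AND over property clauses (participant counts,
  start-year range, countries, data sources, age-range overlap with
  population selection criteria; an age clause requires at least one
  documented bound).
* Scores are transparent clause counts; ties break lexicographically on
  the locator, so results are totally ordered and deterministic.
* `facet_counts()` partitions a match set by study, domain or term; under
  domain/term facets each annotation counts, so sums can exceed the
  match-set size.

The index is validated by construction: `build_index()` refuses inputs
with validation errors, and the test suite checks **scan-equivalence** —
indexed results identical to a hand-written brute-force linear scan — over
thousands of random catalogue/query pairs.

## Comparison tables

`harmonization_table()` pivots a catalogue into the familiar
(study × subpopulation × collection event) by subdomain grid of variable
counts. Numerical conventions, stated once:

* all-zero rows are kept — a wave that collected nothing on a topic is
  informative;
* columns are counted independently: a variable annotated with two
  selected subdomains counts once in each column (whether production
  catalogues deduplicate within a domain is undocumented; this rule is the
  simpler and is stated prominently here);
* datasets not linked to a selected event are ignored, not errors.

`render_comparison()` emits flat CSV (losslessly re-parsable) or grouped
markdown.

## Term classifier

A multinomial naive Bayes model with additive smoothing over the
label ∪ name ∪ question token bag (`alpha = 1` by default; any positive
value). Priors are class frequencies; likelihoods
`(n_ct + alpha)/(n_c + alpha |V|)`; out-of-vocabulary tokens use the same
formula with zero count, so no input has zero probability; posteriors are
normalized in log space and the top-k returned with lexicographic
tie-breaks. Nothing is published about the original in-house classifier
(features, algorithm, training data), so this model is a deterministic
stand-in chosen for hand-checkable posteriors, not a reproduction. One
subtlety: the variable *name* always contributes a token, so the textbook
"empty label falls back to priors" behaviour holds exactly when class
token totals are equal (the denominators cancel); otherwise the name token
shifts the posterior slightly.

## Synthetic data

`generate_catalogue()` emulates a multi-study catalogue: studies with
plausible timelines and participant counts, 1–3 subpopulations with age/
sex/country selection criteria, 1–4 waves each, one dictionary per wave
with 5–25 variables, ~30% categorical, labels drawn from a small
health-survey word pool, and taxonomy annotations at a configurable rate
(default 0.8). These defaults are a realistic desk-scale miniature of a
cohort catalogue; they are fixed and not tuned to tests. What it does
*not* emulate: natural-language label distributions, multilingual text,
inconsistent legacy codebooks, or catalogue-scale volumes (hundreds of
studies, 10^5–10^6 variables). A green property test therefore
establishes correctness of the machinery, not performance or linguistic
robustness at production scale.

`generate_labelled_variables()` controls class separability directly: each
class vocabulary shares `overlap_fraction` of its tokens with a common
pool (0 = disjoint, 1 = indistinguishable, where accuracy necessarily
falls to the prior). `table3_fixture()` expands the packaged transcription
of a published two-cohort comparison grid (15 collection events, five
subdomains) into a fully annotated catalogue; cell counts and structure
are transcribed, variable names/labels are synthetic by construction, and
the transcription itself lives in one reviewable CSV
(`inst/extdata/table3-counts.csv`).

All generators take an explicit integer seed, save and restore the
session RNG state, and are byte-reproducible across processes.

## Known limitations

* Single default locale; no multilingual label maps beyond free text.
* Rebuild-only indexing (no incremental updates) — adequate at desk scale.
* The spss/sas dialects capture conventions, not the binary formats.
* Placeholder subdomain names carry no semantics.
* The classifier is bag-of-tokens only; no embeddings or active learning.
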