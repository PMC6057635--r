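# cohortcat

A desk-scale cataloguing toolkit for population-based cohort studies,
for epidemiologists, data managers and harmonization teams who need to
document *what* a set of cohorts collected, *from whom* and *when* — and
to query that documentation.

The package provides:

* a **typed metadata model**: study → subpopulation → data collection
  event (DCE) → dataset/variable/category, with report-style validation
  (`validate_study()`, `resolve_links()`, `validate_annotations()`);
* a **classification taxonomy** of 18 domains / 135 subdomains
  (`builtin_taxonomy()`) for controlled-vocabulary variable annotation;
* **data-dictionary import/export** as CSV variable + category tables in
  `plain_csv` / `spss_export` / `sas_export` dialects, plus a
  DDI-flavoured XML codebook export (`export_ddi_lite()`);
* a **deterministic search engine** over studies (property filters) and
  variables (conjunctive token text search with `*` prefixes, taxonomy
  term filters, scoping, facet counts) built on inverted indexes that are
  property-tested against a brute-force linear scan;
* **harmonization-potential comparison tables**: for selected subdomains
  `c` and rows `r = (study, subpopulation, DCE)`,

  `cell(r, c) = #{ variables in datasets linked to r annotated with c }`,

  the standard grid for judging whether similar variables exist across
  cohorts and waves;
* a **multinomial naive Bayes term classifier** with additive smoothing
  (`P(t|c) = (n_ct + α) / (n_c + α|V|)`), a deterministic aid for manual
  variable classification;
* **seeded synthetic generators** (random catalogues, labelled variable
  sets with controllable class-vocabulary overlap, and a packaged
  two-cohort comparison-grid fixture);
* a **CLI** (`cohortcat_main()`, wrapper script in `inst/cli/cohortcat`)
  with `validate`, `import`, `export-ddi`, `taxonomy`, `search`,
  `compare`, `classify`, `generate` and `fixture` subcommands
  (exit codes: 0 ok, 1 validation/data error, 2 usage error).

## Worked example

Expand the packaged two-birth-cohort fixture, index it, and compare three
subdomains across every subpopulation and collection event:

```r
library(cohortcat)

fx  <- table3_fixture()
cat <- build_index(fx$studies, fx$datasets, builtin_taxonomy())
tbl <- harmonization_table(cat, fx$selection$columns[3:5], fx$selection$study_ids)
cat(render_comparison(tbl, "markdown"))
```

```
| Study | Tobacco | Alcohol | Pregnancy, childbirth and the puerperium (O00-O9A) |
|---|---|---|---|
| **All Our Babies and All Our Families (AOB/F)** |  |  |  |
| *Mothers* |  |  |  |
| 24 weeks gestation | 5 | 14 | 0 |
| 36 weeks gestation | 7 | 9 | 0 |
| ...
| **Alberta Pregnancy Outcomes and Nutrition (APrON)** |  |  |  |
| *Mothers* |  |  |  |
| First trimester | 15 | 15 | 49 |
| Second trimester | 7 | 5 | 35 |
| ...
```

Each cell counts the variables on that topic collected at that wave: the
APrON mothers' first-trimester questionnaire has 15 tobacco variables, 15
alcohol variables and 49 on pregnancy/childbirth — rich ground for
harmonization with AOB/F's 24-weeks-gestation wave (5 and 14), absent for
the pregnancy subdomain, which AOB/F did not document.

Search the same catalogue:

```r
hits <- search_variables(cat, variable_query(
  text = "tobacco*",
  scope = list(study_id = "APrON", dce_id = "trimester1")))
head(hits, 3); nrow(hits)
```

```
                                  locator score
1  APrON/APrON_mothers_trimester1/v7_c3_1     1
2 APrON/APrON_mothers_trimester1/v7_c3_10     1
3 APrON/APrON_mothers_trimester1/v7_c3_11     1
[1] 15
```

15 hits — the same count as the Tobacco × First-trimester cell, since the
fixture's variable labels name their subdomain. Train and evaluate the
term classifier on near-separable synthetic labels:

```r
ex <- generate_labelled_variables(labelled_set_spec(
  n_classes = 5, n_examples = 500, overlap_fraction = 0.1, seed = 41))
m  <- train_classifier(ex[1:400])
evaluate_classifier(m, ex[401:500])$accuracy
#> [1] 1
```

## Layout

Catalogues live on disk as plain text: `studies/<id>.yaml`,
`datasets/<id>/{dataset.yaml,variables.csv,categories.csv,annotations.csv}`
and an optional `taxonomy.yaml`. See the vignette
(`vignettes/cohort-cataloguing.Rmd`) for the model's assumptions,
numerical conventions and known limitations.
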