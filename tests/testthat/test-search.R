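table3_catalogue <- local({
  fx <- table3_fixture()
  build_index(fx$studies, fx$datasets, builtin_taxonomy())
})

test_that("build_index refuses invalid catalogues with a report", {
  st <- minimal_study()
  dangling <- smoke_dataset(); dangling$link$dce_id <- "wave99"
  err <- tryCatch(build_index(list(st), list(dangling)), error = identity)
  expect_s3_class(err, "cc_build_error")
  expect_s3_class(err$report, "cc_report")
  expect_gt(n_errors(err$report), 0)
})

test_that("the comparison-grid fixture indexes as two studies", {
  expect_length(table3_catalogue$studies, 2)
  expect_setequal(names(table3_catalogue$studies), c("AOBF", "APrON"))
  # rebuilding from identical inputs gives identical index content
  fx <- table3_fixture()
  again <- build_index(fx$studies, fx$datasets, builtin_taxonomy())
  expect_equal(again$text_index, table3_catalogue$text_index)
  expect_equal(again$term_index, table3_catalogue$term_index)
  expect_equal(again$variables, table3_catalogue$variables)
})

test_that("empty catalogues index and answer queries with zero hits", {
  empty <- build_index(list(), list(), builtin_taxonomy())
  expect_equal(nrow(search_variables(empty, variable_query())), 0)
  expect_equal(nrow(search_variables(empty, variable_query(text = "smoke"))), 0)
  expect_equal(nrow(search_studies(empty, study_query())), 0)
  expect_length(facet_counts(empty, variable_query(), "study"), 0)
})

test_that("term search scoped to one DCE matches the printed cell", {
  q <- variable_query(
    terms = list(term_ref("Lifestyle and behaviours", "Tobacco")),
    scope = list(study_id = "APrON", population_id = "mothers",
                 dce_id = "trimester1"))
  hits <- search_variables(table3_catalogue, q)
  expect_equal(nrow(hits), 15)
  expect_true(all(hits$score == 1))
})

test_that("conjunctive text search tokenizes labels", {
  st <- minimal_study()
  tax <- builtin_taxonomy()
  ds <- smoke_dataset()
  ds$variables <- lapply(ds$variables, annotate_variable,
                         ref = term_ref("Lifestyle and behaviours", "Tobacco"),
                         tax = tax)
  cat_ <- build_index(list(st), list(ds), tax)
  hits <- search_variables(cat_, variable_query(text = c("current", "smoker")))
  expect_equal(hits$locator, "cohort1/demo/smoke")
  expect_equal(hits$score, 2)
  # prefix clause
  hits2 <- search_variables(cat_, variable_query(text = "smok*"))
  expect_equal(hits2$locator, "cohort1/demo/smoke")
  # AND semantics: an unmatched token empties the hit set
  expect_equal(nrow(search_variables(cat_,
    variable_query(text = c("current", "zzz")))), 0)
  # text + term scoring adds one per matched term
  hits3 <- search_variables(cat_, variable_query(
    text = "smoker", terms = list(term_ref("Lifestyle and behaviours", "Tobacco"))))
  expect_equal(hits3$score, 2)
  # unresolvable term refs are query errors
  expect_error(search_variables(cat_,
    variable_query(terms = list(term_ref("Nope", "Nope")))), "resolve")
  # malformed study ranges are query errors
  expect_error(study_query(participants_min = 10, participants_max = 5),
               "malformed")
  expect_error(study_query(start_year_range = c(2010, 2000)), "malformed")
})

test_that("study search filters and scores by satisfied clauses", {
  cc <- generate_catalogue(catalogue_spec(n_studies = 6, seed = 5))
  cat_ <- build_index(cc$studies, cc$datasets, builtin_taxonomy())
  all_hits <- search_studies(cat_, study_query())
  expect_equal(all_hits$locator, sort(vapply(cc$studies, `[[`, "", "id")))
  expect_true(all(all_hits$score == 0))
  none <- search_studies(cat_, study_query(participants_min = 10^7))
  expect_equal(nrow(none), 0)
})

test_that("indexed search equals a brute-force scan on random catalogues", {
  n_cat <- 6; n_q <- 8  # scaled down here; the full 50 x 20 sweep runs in the acceptance suite
  for (i in seq_len(n_cat)) {
    spec <- catalogue_spec(n_studies = 2, populations_per_study = c(1, 2),
                           dces_per_population = c(1, 3),
                           variables_per_dce = c(0, 20), seed = 100 + i)
    cc <- generate_catalogue(spec)
    cat_ <- build_index(cc$studies, cc$datasets, spec$tax)
    set.seed(500 + i)
    for (j in seq_len(n_q)) {
      vq <- random_variable_query(cat_, spec$tax)
      expect_equal(search_variables(cat_, vq),
                   oracle_variable_hits(cc$studies, cc$datasets, vq))
      sq <- random_study_query()
      expect_equal(search_studies(cat_, sq), oracle_study_hits(cc$studies, sq))
    }
  }
})

test_that("adding a filter clause never enlarges the hit set", {
  cc <- generate_catalogue(catalogue_spec(n_studies = 3, seed = 9))
  cat_ <- build_index(cc$studies, cc$datasets, builtin_taxonomy())
  set.seed(77)
  for (i in 1:10) {
    q <- random_variable_query(cat_, builtin_taxonomy())
    hits <- search_variables(cat_, q)$locator
    # tighten by ADDING a scope clause (keep any existing ones)
    q2 <- q
    if (is.null(q2$scope$study_id)) {
      q2$scope <- c(q2$scope, list(study_id = cat_$variables$study_id[1]))
    }
    expect_true(all(search_variables(cat_, q2)$locator %in% hits))
    # tighten by ADDING a text token that matches nothing
    q3 <- q
    q3$text <- c(q3$text, list(list(token = "zzznope", prefix = FALSE)))
    expect_true(all(search_variables(cat_, q3)$locator %in% hits))
  }
})

test_that("facet counts partition the match set", {
  by_study <- facet_counts(table3_catalogue, variable_query(), "study")
  expect_equal(by_study[["AOBF"]], 4 + 8 + 5 + 14 + 0 + 3 + 7 + 9 + 6 + 5 + 4 +
                 8 + 5 + 4 + 1 + 2 + 5 + 4 + 2)
  expect_equal(sum(by_study), nrow(table3_catalogue$variables))

  by_term <- facet_counts(table3_catalogue, variable_query(), "term")
  expect_equal(by_term[["Lifestyle and behaviours/Tobacco"]],
               5 + 7 + 5 + 5 + 5 + 0 + 15 + 7 + 6 + 6 + 2 + 3 + 4 + 3 + 0)
  by_domain <- facet_counts(table3_catalogue, variable_query(), "domain")
  expect_equal(sum(by_domain), sum(by_term))

  # zero-hit query gives an empty mapping
  expect_length(facet_counts(table3_catalogue,
    variable_query(text = "zzznothing"), "term"), 0)

  # a variable with several annotations contributes once per annotation
  tax <- builtin_taxonomy()
  v <- variable("dual", "wine and cigarettes")
  v <- annotate_variable(v, term_ref("Lifestyle and behaviours", "Tobacco"), tax)
  v <- annotate_variable(v, term_ref("Lifestyle and behaviours", "Alcohol"), tax)
  ds <- dataset("dual_ds", study_id = "cohort1", population_id = "adults",
                dce_id = "baseline", variables = list(v))
  cat2 <- build_index(list(minimal_study()), list(ds), tax)
  ft <- facet_counts(cat2, variable_query(), "term")
  expect_equal(sum(ft), 2)
  expect_gt(sum(ft), nrow(search_variables(cat2, variable_query())))
})

test_that("results are deterministic and totally ordered", {
  q <- variable_query(terms = list(
    term_ref("Lifestyle and behaviours", "Tobacco"),
    term_ref("Lifestyle and behaviours", "Alcohol")))
  h1 <- search_variables(table3_catalogue, q)
  h2 <- search_variables(table3_catalogue, q)
  expect_identical(h1, h2)
  # scores descending, ties broken lexicographically
  expect_true(all(diff(h1$score) <= 0))
  for (s in unique(h1$score)) {
    loc <- h1$locator[h1$score == s]
    expect_identical(loc, sort(loc, method = "radix"))
  }
})
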