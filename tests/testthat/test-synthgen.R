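test_that("generated catalogues always pass every validator", {
  for (seed in c(1, 99, 4242)) {
    spec <- catalogue_spec(n_studies = 3, seed = seed)
    cc <- generate_catalogue(spec)
    for (st in cc$studies) expect_equal(n_errors(validate_study(st)), 0)
    expect_equal(n_errors(resolve_links(cc$studies, cc$datasets)), 0)
    for (ds in cc$datasets) {
      expect_equal(n_errors(validate_annotations(ds, spec$tax)), 0)
    }
  }
})

test_that("generation is seed-deterministic down to the serialized bytes", {
  spec <- catalogue_spec(n_studies = 3, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cc1 <- generate_catalogue(spec)
  cc2 <- generate_catalogue(spec)
  write_catalogue(cc1$studies, cc1$datasets, d1)
  write_catalogue(cc2$studies, cc2$datasets, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the output
  cc3 <- generate_catalogue(catalogue_spec(n_studies = 3, seed = 8))
  expect_false(identical(cc1, cc3))
  # and generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(generate_catalogue(spec)); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("spec ranges and rates are honoured", {
  spec <- catalogue_spec(n_studies = 2, populations_per_study = c(2, 2),
                         dces_per_population = c(3, 3),
                         variables_per_dce = c(0, 0), seed = 5)
  cc <- generate_catalogue(spec)
  expect_length(cc$studies, 2)
  expect_length(cc$datasets, 2 * 2 * 3)
  expect_true(all(vapply(cc$datasets,
                         function(d) length(d$variables), 0L) == 0))
  expect_equal(n_errors(resolve_links(cc$studies, cc$datasets)), 0)

  full <- generate_catalogue(catalogue_spec(n_studies = 2, annotation_rate = 1,
                                            seed = 6))
  annotated <- vapply(unlist(lapply(full$datasets, `[[`, "variables"),
                             recursive = FALSE),
                      function(v) length(v$annotations) > 0, logical(1))
  expect_true(all(annotated))

  none <- generate_catalogue(catalogue_spec(n_studies = 1, annotation_rate = 0,
                                            seed = 6))
  annotated0 <- vapply(unlist(lapply(none$datasets, `[[`, "variables"),
                              recursive = FALSE),
                       function(v) length(v$annotations) > 0, logical(1))
  expect_false(any(annotated0))

  expect_error(catalogue_spec(annotation_rate = 2), "annotation_rate")
  expect_error(catalogue_spec(variables_per_dce = c(5, 1)), "variables_per_dce")
})

test_that("labelled-set vocabularies respect the overlap dial", {
  spec0 <- labelled_set_spec(n_classes = 4, n_examples = 100,
                             overlap_fraction = 0, seed = 3)
  ex0 <- generate_labelled_variables(spec0)
  by_class <- split(vapply(ex0, function(e) e$variable$label, ""),
                    vapply(ex0, function(e) e$term$term_name, ""))
  vocabs <- lapply(by_class, function(labs) unique(unlist(strsplit(labs, " "))))
  for (i in seq_along(vocabs)) {
    for (j in seq_along(vocabs)) {
      if (i < j) expect_length(intersect(vocabs[[i]], vocabs[[j]]), 0)
    }
  }
  # same seed, same set
  expect_identical(generate_labelled_variables(spec0), ex0)

  # full overlap: all classes share one vocabulary, accuracy ~ max prior
  ex1 <- generate_labelled_variables(labelled_set_spec(
    n_classes = 5, n_examples = 600, overlap_fraction = 1, seed = 13))
  m <- train_classifier(ex1[1:480])
  acc <- evaluate_classifier(m, ex1[481:600])$accuracy
  expect_lt(acc, 0.4)  # chance level is ~0.2 for 5 balanced classes
})

test_that("the packaged comparison fixture is pure and self-consistent", {
  f1 <- table3_fixture()
  f2 <- table3_fixture()
  expect_identical(f1, f2)
  # declared structure: AOB/F has Mothers (5 DCEs) and Children (1 DCE)
  aobf <- f1$studies[[1]]
  expect_equal(aobf$id, "AOBF")
  expect_equal(vapply(aobf$populations, `[[`, "", "id"), c("mothers", "children"))
  expect_length(aobf$populations[[1]]$data_collection_events, 5)
  expect_length(aobf$populations[[2]]$data_collection_events, 1)
  apron <- f1$studies[[2]]
  expect_equal(vapply(apron$populations, `[[`, "", "id"),
               c("mothers", "partners", "children"))
  # 15 events in total, one dataset per event
  expect_length(f1$datasets, 15)
  # row-sum expansion check: APrON mothers 24 weeks postpartum = 0+0+2+2+0
  ds <- Filter(function(d) d$id == "APrON_mothers_24w_postpartum", f1$datasets)[[1]]
  expect_length(ds$variables, 4)
  # everything validates
  for (st in f1$studies) expect_equal(n_errors(validate_study(st)), 0)
  expect_equal(n_errors(resolve_links(f1$studies, f1$datasets)), 0)
  for (ds in f1$datasets) {
    expect_equal(n_errors(validate_annotations(ds, builtin_taxonomy())), 0)
  }
})
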