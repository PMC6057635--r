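vars_csv <- 'name,label,valueType,unit
age,"Age of participant",integer,years
smoke,"Current smoker",integer,
'
cats_csv <- 'variable,code,label,missing
smoke,0,No,false
smoke,1,Yes,false
smoke,9,Refused,true
'

test_that("read_dictionary parses the worked two-variable dictionary", {
  ds <- read_dictionary(vars_csv, cats_csv, dialect("plain_csv"))
  expect_length(ds$variables, 2)
  expect_equal(vapply(ds$variables, `[[`, "", "name"), c("age", "smoke"))
  expect_equal(ds$variables[[1]]$unit, "years")
  expect_equal(ds$variables[[1]]$value_type, "integer")
  smoke <- ds$variables[[2]]
  expect_length(smoke$categories, 3)
  expect_equal(sum(vapply(smoke$categories, `[[`, TRUE, "is_missing")), 1)
  expect_equal(smoke$categories[[3]]$code, "9")
})

test_that("read errors carry row numbers and offending names", {
  dup <- 'name,label\nage,"Age"\nage,"Age again"\n'
  expect_error(read_dictionary(dup, NULL, dialect("plain_csv")), "row 3")
  orphan <- 'variable,code,label,missing\nweight,1,One,false\n'
  expect_error(read_dictionary(vars_csv, orphan, dialect("plain_csv")),
               "unknown variable 'weight'")
  expect_error(read_dictionary('label\n"x"\n', NULL, dialect("plain_csv")),
               "mandatory column 'name'")
  expect_error(read_dictionary("Variable,Label\nx,y\n", NULL, dialect("plain_csv")),
               "mandatory column")
})

test_that("value type defaults to integer/text from category codes", {
  no_type <- 'name,label\nsmoke,"Current smoker"\ncolour,"Eye colour"\n'
  cats <- paste0('variable,code,label,missing\n',
                 'smoke,0,No,false\nsmoke,1,Yes,false\n',
                 'colour,brown,Brown,false\ncolour,blue,Blue,false\n')
  ds <- read_dictionary(no_type, cats, dialect("plain_csv"))
  expect_equal(ds$variables[[1]]$value_type, "integer")
  expect_equal(ds$variables[[2]]$value_type, "text")
})

test_that("write then read is the identity for flag-column dialects", {
  ds <- read_dictionary(vars_csv, cats_csv, dialect("plain_csv"))
  tabs <- write_dictionary(ds, dialect("plain_csv"))
  # shape: one data row per variable / category
  expect_equal(length(strsplit(tabs$variables_table, "\n")[[1]]), 3)
  expect_equal(length(strsplit(tabs$categories_table, "\n")[[1]]), 4)
  back <- read_dictionary(tabs$variables_table, tabs$categories_table,
                          dialect("plain_csv"))
  expect_equal(back, ds)

  empty <- dataset("nocats", study_id = "s", population_id = "p", dce_id = "d",
                   variables = list(variable("v1", "Plain text")))
  tabs2 <- write_dictionary(empty, dialect("plain_csv"))
  expect_equal(length(strsplit(tabs2$categories_table, "\n")[[1]]), 1)  # header only
  expect_equal(read_dictionary(tabs2$variables_table, tabs2$categories_table,
                               dialect("plain_csv"), dataset_id = "nocats",
                               link = empty$link),
               empty)
})

test_that("read-write-read reaches a fixpoint in every dialect", {
  cc <- generate_catalogue(catalogue_spec(n_studies = 2, seed = 11))
  for (dia_name in c("plain_csv", "spss_export", "sas_export")) {
    dia <- dialect(dia_name)
    for (ds in head(cc$datasets, 4)) {
      t1 <- write_dictionary(strip_annotations(ds), dia)
      r1 <- read_dictionary(t1$variables_table, t1$categories_table, dia,
                            dataset_id = ds$id, name = ds$name,
                            description = ds$description, link = ds$link)
      t2 <- write_dictionary(r1, dia)
      r2 <- read_dictionary(t2$variables_table, t2$categories_table, dia,
                            dataset_id = ds$id, name = ds$name,
                            description = ds$description, link = ds$link)
      expect_identical(t2, write_dictionary(r2, dia))
      expect_equal(r2, r1)
    }
  }
})

test_that("code-list dialects infer missingness from reserved high codes", {
  spss_cats <- 'Variable,Value,ValueLabel\nsmoke,0,No\nsmoke,1,Yes\nsmoke,99,Refused\n'
  spss_vars <- 'Variable,Label\nsmoke,"Current smoker"\n'
  ds <- read_dictionary(spss_vars, spss_cats, dialect("spss_export"))
  miss <- vapply(ds$variables[[1]]$categories, `[[`, TRUE, "is_missing")
  expect_equal(miss, c(FALSE, FALSE, TRUE))  # 99 >= 77
})

test_that("DDI-lite export is well-formed and count-faithful", {
  ds <- read_dictionary(vars_csv, cats_csv, dialect("plain_csv"))
  xml <- export_ddi_lite(ds)
  doc <- xml2::read_xml(xml)
  expect_equal(xml2::xml_name(doc), "codeBook")
  vars <- xml2::xml_find_all(doc, "//var")
  expect_length(vars, 2)
  smoke <- vars[[2]]
  expect_equal(xml2::xml_attr(smoke, "name"), "smoke")
  cats <- xml2::xml_find_all(smoke, "catgry")
  expect_length(cats, 3)
  expect_equal(xml2::xml_attr(cats, "missing"), c("N", "N", "Y"))
  expect_equal(xml2::xml_text(xml2::xml_find_first(cats[[3]], "catValu")), "9")

  # empty dataset: codebook root with zero variable elements
  empty <- dataset("void", study_id = "s", population_id = "p", dce_id = "d")
  doc0 <- xml2::read_xml(export_ddi_lite(empty))
  expect_length(xml2::xml_find_all(doc0, "//var"), 0)

  # every synthetic dataset re-parses, with element counts matching
  cc <- generate_catalogue(catalogue_spec(n_studies = 1, seed = 3))
  for (ds in cc$datasets) {
    d <- xml2::read_xml(export_ddi_lite(ds))
    expect_length(xml2::xml_find_all(d, "//var"), length(ds$variables))
    expect_length(xml2::xml_find_all(d, "//catgry"),
                  sum(vapply(ds$variables, function(v) length(v$categories), 0L)))
  }
})
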