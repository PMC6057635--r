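#' @title Data-dictionary import and export
#' @description
#' Reads and writes data dictionaries as a pair of CSV tables — a variables
#' table (one row per variable) and a categories table (one row per
#' category code) — in several dialects that emulate the column-naming and
#' missing-code conventions of dictionaries exported from common
#' statistical tools. Only CSV text (UTF-8, comma-delimited, RFC-4180
#' quoting) is parsed; native binary `.sav` / `.sas7bdat` files are out of
#' scope. A minimal DDI-flavoured XML codebook export is provided for
#' interoperability with documentation standards.
#' @name dictionary-io
NULL

DIALECT_NAMES <- c("plain_csv", "spss_export", "sas_export")

#' CSV dictionary dialects
#'
#' A dialect maps canonical column names to the headers used in a given
#' export flavour, and fixes how missing-value categories are declared:
#'
#' * `flag_column`: the categories table carries an explicit boolean
#'   `missing` column (`plain_csv`).
#' * `code_list`: there is no flag column; a category is missing when its
#'   code is numeric and at least `missing_code_min`, the usual reserved
#'   high-code convention of SPSS/SAS exports (`spss_export` uses 77,
#'   `sas_export` uses 97).
#'
#' Value types are canonical (`integer`, `decimal`, `text`, `boolean`,
#' `date`) in every dialect; when the type column is absent entirely, the
#' type is inferred (integer if all of a variable's category codes parse as
#' integers, text otherwise).
#'
#' @param name one of `plain_csv`, `spss_export`, `sas_export`.
#' @return a `cc_dialect` with fields `name`, `variables_map`,
#'   `categories_map`, `missing_code_convention`, `missing_code_min`.
#' @export
dialect <- function(name = c("plain_csv", "spss_export", "sas_export")) {
  name <- match.arg(name)
  switch(name,
    plain_csv = structure(list(
      name = name,
      variables_map = c(name = "name", label = "label", value_type = "valueType",
                        unit = "unit", question = "question"),
      categories_map = c(variable = "variable", code = "code",
                         label = "label", missing = "missing"),
      missing_code_convention = "flag_column",
      missing_code_min = NA_real_), class = "cc_dialect"),
    spss_export = structure(list(
      name = name,
      variables_map = c(name = "Variable", label = "Label", value_type = "Type",
                        unit = "Units", question = "Question"),
      categories_map = c(variable = "Variable", code = "Value",
                         label = "ValueLabel"),
      missing_code_convention = "code_list",
      missing_code_min = 77), class = "cc_dialect"),
    sas_export = structure(list(
      name = name,
      variables_map = c(name = "NAME", label = "LABEL", value_type = "TYPE",
                        unit = "UNITS", question = "QUESTION"),
      categories_map = c(variable = "NAME", code = "START",
                         label = "CATLABEL"),
      missing_code_convention = "code_list",
      missing_code_min = 97), class = "cc_dialect"))
}

parse_csv_text <- function(text) {
  utils::read.csv(text = text, header = TRUE, colClasses = "character",
                  check.names = FALSE, na.strings = NULL, fileEncoding = "UTF-8")
}

csv_text <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

is_missing_code <- function(code, dia) {
  if (dia$missing_code_convention == "flag_column") {
    stop("flag_column dialects do not infer missingness from codes")
  }
  num <- suppressWarnings(as.numeric(code))
  !is.na(num) & num >= dia$missing_code_min
}

#' Read a data dictionary from CSV tables
#'
#' @param variables_table CSV text (or path to a CSV file) with one row per
#'   variable, first row a header. Mandatory columns (after dialect
#'   mapping): `name`, `label`. Variables keep file row order.
#' @param categories_table optional CSV text or path; one row per category,
#'   attached to its variable by name, in file row order.
#' @param dia a [dialect()].
#' @param dataset_id,name,description,link dataset envelope fields (the CSV
#'   tables carry only the variables).
#' @return a [dataset()]. Duplicate variable names, category rows naming
#'   unknown variables, and missing mandatory columns are errors (with the
#'   offending data row number, counting the header as row 1).
#' @export
read_dictionary <- function(variables_table, categories_table = NULL,
                            dia = dialect("plain_csv"),
                            dataset_id = "dataset", name = dataset_id,
                            description = "",
                            link = list(study_id = "unlinked",
                                        population_id = "unlinked",
                                        dce_id = "unlinked")) {
  stopifnot(inherits(dia, "cc_dialect"))
  read_input <- function(x) {
    if (is_scalar_chr(x) && !grepl("\n", x) && file.exists(x)) {
      parse_csv_text(paste(readLines(x, encoding = "UTF-8"), collapse = "\n"))
    } else parse_csv_text(x)
  }
  vtab <- read_input(variables_table)
  vmap <- dia$variables_map
  for (col in c("name", "label")) {
    if (!(vmap[[col]] %in% names(vtab))) {
      stop(sprintf("variables table lacks mandatory column '%s' (dialect %s)",
                   vmap[[col]], dia$name), call. = FALSE)
    }
  }
  vnames <- vtab[[vmap[["name"]]]]
  if (anyDuplicated(vnames)) {
    row <- which(duplicated(vnames))[1] + 1L  # +1: header is row 1
    stop(sprintf("duplicate variable name '%s' at row %d", vnames[row - 1L], row),
         call. = FALSE)
  }

  cats_by_var <- list()
  if (!is.null(categories_table)) {
    ctab <- read_input(categories_table)
    cmap <- dia$categories_map
    for (col in c("variable", "code")) {
      if (!(cmap[[col]] %in% names(ctab))) {
        stop(sprintf("categories table lacks mandatory column '%s' (dialect %s)",
                     cmap[[col]], dia$name), call. = FALSE)
      }
    }
    if (nrow(ctab)) {
      for (i in seq_len(nrow(ctab))) {
        vn <- ctab[[cmap[["variable"]]]][i]
        if (!(vn %in% vnames)) {
          stop(sprintf("categories table row %d names unknown variable '%s'",
                       i + 1L, vn), call. = FALSE)
        }
        code <- ctab[[cmap[["code"]]]][i]
        lab <- if (!is.null(cmap[["label"]]) && cmap[["label"]] %in% names(ctab)) {
          ctab[[cmap[["label"]]]][i]
        } else code
        miss <- if (dia$missing_code_convention == "flag_column") {
          mcol <- cmap[["missing"]]
          if (mcol %in% names(ctab)) {
            tolower(ctab[[mcol]][i]) %in% c("true", "t", "1", "yes")
          } else FALSE
        } else {
          is_missing_code(code, dia)
        }
        cats_by_var[[vn]] <- c(cats_by_var[[vn]],
                               list(category(code, lab, miss)))
      }
    }
  }

  vars <- lapply(seq_len(nrow(vtab)), function(i) {
    vn <- vnames[i]
    cats <- cats_by_var[[vn]] %||% list()
    vt_col <- vmap[["value_type"]]
    vt_raw <- if (vt_col %in% names(vtab)) vtab[[vt_col]][i] else ""
    vt <- if (nzchar(vt_raw)) {
      if (!(vt_raw %in% VALUE_TYPES)) {
        stop(sprintf("unknown value type '%s' at row %d", vt_raw, i + 1L),
             call. = FALSE)
      }
      vt_raw
    } else infer_value_type(cats)
    grab <- function(key) {
      col <- vmap[[key]]
      if (!is.null(col) && col %in% names(vtab) && nzchar(vtab[[col]][i])) {
        vtab[[col]][i]
      } else NULL
    }
    variable(name = vn, label = vtab[[vmap[["label"]]]][i], value_type = vt,
             unit = grab("unit"), question_text = grab("question"),
             categories = cats)
  })
  dataset(id = dataset_id, name = name, description = description,
          study_id = link$study_id, population_id = link$population_id,
          dce_id = link$dce_id, variables = vars)
}

# default typing when no explicit type column is present
infer_value_type <- function(cats) {
  if (!length(cats)) return("text")
  codes <- vapply(cats, `[[`, "", "code")
  if (all(grepl("^-?\\d+$", codes))) "integer" else "text"
}

#' Write a data dictionary as CSV tables
#'
#' Inverse of [read_dictionary()]: canonical column order, one row per
#' variable / category, in dataset order. For `code_list` dialects the
#' `is_missing` flag is not written explicitly; it is recoverable from the
#' dialect's missing-code rule, so `read(write(d))` is an identity exactly
#' when the dataset's flags agree with that rule (always true for data read
#' through the same dialect — the read-write-read fixpoint).
#'
#' @param ds a [dataset()].
#' @param dia a [dialect()].
#' @return list with `variables_table` and `categories_table` CSV strings.
#' @export
write_dictionary <- function(ds, dia = dialect("plain_csv")) {
  stopifnot(inherits(ds, "cc_dataset"), inherits(dia, "cc_dialect"))
  vmap <- dia$variables_map
  vtab <- data.frame(
    name = vapply(ds$variables, `[[`, "", "name"),
    label = vapply(ds$variables, `[[`, "", "label"),
    value_type = vapply(ds$variables, `[[`, "", "value_type"),
    unit = vapply(ds$variables, function(v) v$unit %||% "", ""),
    question = vapply(ds$variables, function(v) v$question_text %||% "", ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(vtab) <- vmap[c("name", "label", "value_type", "unit", "question")]

  rows <- list()
  for (v in ds$variables) {
    for (cc in v$categories) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v$name, code = cc$code, label = cc$label,
        missing = tolower(as.character(cc$is_missing)),
        stringsAsFactors = FALSE)
    }
  }
  ctab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(variable = character(), code = character(), label = character(),
               missing = character(), stringsAsFactors = FALSE)
  }
  cmap <- dia$categories_map
  if (dia$missing_code_convention == "flag_column") {
    names(ctab) <- cmap[c("variable", "code", "label", "missing")]
  } else {
    ctab <- ctab[, c("variable", "code", "label")]
    names(ctab) <- cmap[c("variable", "code", "label")]
  }
  list(variables_table = csv_text(vtab), categories_table = csv_text(ctab))
}

#' Export a dataset as a DDI-flavoured XML codebook
#'
#' Produces a minimal, well-formed subset of the DDI Codebook vocabulary
#' (see `inst/extdata/ddi-lite-schema.txt` for the fixed element list):
#' a `codeBook` root with a `dataDscr` section holding one `var` element
#' per variable (attributes `name`, and children `labl`, `qstn`, `units`
#' when present, `varFormat` with a `type` attribute) and one `catgry`
#' element per category (attribute `missing="Y"/"N"`, children `catValu`
#' and `labl`). Document order follows dataset order. Full DDI Codebook
#' conformance is deliberately not claimed.
#'
#' @param ds a [dataset()].
#' @return XML text (a string).
#' @export
export_ddi_lite <- function(ds) {
  stopifnot(inherits(ds, "cc_dataset"))
  doc <- xml2::xml_new_root("codeBook", version = "ddi-lite-0.1")
  stdy <- xml2::xml_add_child(doc, "stdyDscr")
  citation <- xml2::xml_add_child(stdy, "citation")
  titl <- xml2::xml_add_child(citation, "titl")
  xml2::xml_set_text(titl, ds$name)
  if (nzchar(ds$description)) {
    ab <- xml2::xml_add_child(stdy, "abstract")
    xml2::xml_set_text(ab, ds$description)
  }
  dd <- xml2::xml_add_child(doc, "dataDscr")
  for (v in ds$variables) {
    var_el <- xml2::xml_add_child(dd, "var", name = v$name)
    labl <- xml2::xml_add_child(var_el, "labl")
    xml2::xml_set_text(labl, v$label)
    if (!is.null(v$question_text)) {
      q <- xml2::xml_add_child(var_el, "qstn")
      xml2::xml_set_text(q, v$question_text)
    }
    if (!is.null(v$unit)) {
      u <- xml2::xml_add_child(var_el, "units")
      xml2::xml_set_text(u, v$unit)
    }
    xml2::xml_add_child(var_el, "varFormat", type = v$value_type)
    for (cc in v$categories) {
      cat_el <- xml2::xml_add_child(var_el, "catgry",
                                    missing = if (cc$is_missing) "Y" else "N")
      cv <- xml2::xml_add_child(cat_el, "catValu")
      xml2::xml_set_text(cv, cc$code)
      cl <- xml2::xml_add_child(cat_el, "labl")
      xml2::xml_set_text(cl, cc$label)
    }
  }
  as.character(doc)
}
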