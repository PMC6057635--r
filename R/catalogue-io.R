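#' @title Catalogue directory input/output
#' @description
#' A catalogue lives on disk as a plain-text directory tree:
#'
#' ```
#' <catalogue>/
#'   taxonomy.yaml                # optional; default = builtin_taxonomy()
#'   studies/<study-id>.yaml      # one YAML document per study
#'   datasets/<dataset-id>/
#'     dataset.yaml               # name, description, link
#'     variables.csv              # plain_csv dialect variables table
#'     categories.csv             # plain_csv dialect categories table
#'     annotations.csv            # variable,domain,term  (term annotations)
#' ```
#'
#' Field names mirror the constructors in snake_case; everything is UTF-8.
#' @name catalogue-io
NULL

study_to_list <- function(st) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  drop_null(list(
    id = st$id, name = st$name, acronym = st$acronym,
    objectives = st$objectives, website = st$website,
    investigators = if (length(st$investigators)) st$investigators,
    contacts = if (length(st$contacts)) st$contacts,
    start_year = st$start_year, end_year = st$end_year,
    number_of_participants = st$number_of_participants,
    number_with_samples = st$number_with_samples,
    access = st$access, logo_ref = st$logo_ref,
    populations = lapply(st$populations, function(p) drop_null(list(
      id = p$id, name = p$name, description = p$description,
      recruitment_sources = if (length(p$recruitment_sources))
        as.list(p$recruitment_sources),
      selection_criteria = if (length(p$selection_criteria))
        lapply(p$selection_criteria, function(x)
          if (length(x) > 1) as.list(x) else x),
      number_of_participants = p$number_of_participants,
      data_collection_events = lapply(p$data_collection_events,
        function(d) drop_null(list(
          id = d$id, name = d$name, description = d$description,
          start_date = d$start_date, end_date = d$end_date,
          data_sources = if (length(d$data_sources)) as.list(d$data_sources)))))))
  ))
}

study_from_list <- function(x) {
  study(id = x$id, name = x$name %||% x$id, acronym = x$acronym,
        objectives = x$objectives, website = x$website,
        investigators = x$investigators %||% list(),
        contacts = x$contacts %||% list(),
        start_year = x$start_year, end_year = x$end_year,
        number_of_participants = x$number_of_participants,
        number_with_samples = x$number_with_samples,
        access = x$access, logo_ref = x$logo_ref,
        populations = lapply(x$populations %||% list(), function(p) {
          population(id = p$id, name = p$name %||% p$id,
                     description = p$description %||% "",
                     recruitment_sources = unlist(p$recruitment_sources) %||% character(),
                     selection_criteria = lapply(p$selection_criteria %||% list(),
                                                 function(v) unlist(v)),
                     number_of_participants = p$number_of_participants,
                     data_collection_events = lapply(
                       p$data_collection_events %||% list(), function(d) {
                         dce(id = d$id, name = d$name %||% d$id,
                             description = d$description %||% "",
                             start_date = d$start_date, end_date = d$end_date,
                             data_sources = unlist(d$data_sources) %||% character())
                       }))
        }))
}

#' Read / write one study as a YAML document
#'
#' `write_study()` then `read_study()` yields a structurally equal study.
#'
#' @param st a [study()].
#' @param path YAML file path.
#' @return `read_study()` returns a `cc_study`; `write_study()` returns
#'   `path` invisibly.
#' @export
write_study <- function(st, path) {
  stopifnot(inherits(st, "cc_study"))
  yaml::write_yaml(study_to_list(st), path)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) study_from_list(yaml::read_yaml(path))

write_dataset_dir <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(id = ds$id, name = ds$name,
                        description = ds$description, link = ds$link),
                   file.path(dir, "dataset.yaml"))
  tabs <- write_dictionary(ds, dialect("plain_csv"))
  writeLines(tabs$variables_table, file.path(dir, "variables.csv"), sep = "")
  writeLines(tabs$categories_table, file.path(dir, "categories.csv"), sep = "")
  rows <- list()
  for (v in ds$variables) {
    for (a in v$annotations) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v$name, domain = a$domain_name, term = a$term_name,
        stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(variable = character(), domain = character(),
               term = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  invisible(dir)
}

read_dataset_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  cat_path <- file.path(dir, "categories.csv")
  ds <- read_dictionary(
    variables_table = file.path(dir, "variables.csv"),
    categories_table = if (file.exists(cat_path)) cat_path else NULL,
    dia = dialect("plain_csv"),
    dataset_id = meta$id %||% basename(dir), name = meta$name %||% basename(dir),
    description = meta$description %||% "",
    link = meta$link)
  ann_path <- file.path(dir, "annotations.csv")
  if (file.exists(ann_path)) {
    ann <- utils::read.csv(ann_path, colClasses = "character")
    if (nrow(ann)) {
      by_var <- split(ann, ann$variable)
      ds$variables <- lapply(ds$variables, function(v) {
        rows <- by_var[[v$name]]
        if (!is.null(rows)) {
          v$annotations <- canonical_annotations(
            lapply(seq_len(nrow(rows)),
                   function(i) term_ref(rows$domain[i], rows$term[i])))
        }
        v
      })
    }
  }
  ds
}

#' Read / write a whole catalogue directory
#'
#' @param dir catalogue directory (layout documented above).
#' @param studies,datasets entity lists.
#' @param tax a [taxonomy()]; `read_catalogue()` falls back to the packaged
#'   classification when the directory has no `taxonomy.yaml`.
#' @return `read_catalogue()` returns `list(studies, datasets, taxonomy)`.
#' @export
write_catalogue <- function(studies, datasets, dir, tax = NULL) {
  dir.create(file.path(dir, "studies"), recursive = TRUE, showWarnings = FALSE)
  for (st in studies) {
    write_study(st, file.path(dir, "studies", paste0(st$id, ".yaml")))
  }
  for (ds in datasets) {
    write_dataset_dir(ds, file.path(dir, "datasets", ds$id))
  }
  if (!is.null(tax)) write_taxonomy(tax, file.path(dir, "taxonomy.yaml"))
  invisible(dir)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(dir) {
  if (!dir.exists(dir)) stop("catalogue directory not found: ", dir, call. = FALSE)
  study_files <- sort(list.files(file.path(dir, "studies"), pattern = "\\.ya?ml$",
                                 full.names = TRUE))
  studies <- lapply(study_files, read_study)
  ds_dirs <- sort(list.dirs(file.path(dir, "datasets"), recursive = FALSE))
  datasets <- lapply(ds_dirs, read_dataset_dir)
  tax_path <- file.path(dir, "taxonomy.yaml")
  tax <- if (file.exists(tax_path)) load_taxonomy(tax_path) else builtin_taxonomy()
  list(studies = studies, datasets = datasets, taxonomy = tax)
}
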