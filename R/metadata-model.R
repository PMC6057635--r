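#' @title Cohort metadata model
#' @description
#' Typed entities for the conceptual model used to document cohort designs:
#' a study describes one cohort; each study has ordered subpopulations; each
#' subpopulation has ordered data collection events (DCEs, i.e. waves or
#' follow-ups); datasets (data dictionaries) attach to exactly one DCE and
#' list variables with labels, value types, categories and taxonomy
#' annotations. Constructors check syntactic shape (types, closed enum
#' lists) and throw on garbage; semantic invariants are checked by
#' [validate_study()] and [resolve_links()], which report rather than throw.
#' @name metadata-model
NULL

RECRUITMENT_SOURCES <- c("general_population", "specific_population",
                         "participants_of_other_study", "other")
DATA_SOURCES <- c("questionnaires", "physical_measures", "cognitive_measures",
                  "biological_samples", "administrative_databases", "other")
VALUE_TYPES <- c("integer", "decimal", "text", "boolean", "date")
SEX_VALUES <- c("female", "male", "all")

check_enum_set <- function(x, allowed, what) {
  x <- as.character(x %||% character())
  bad <- setdiff(x, allowed)
  if (length(bad)) {
    stop(sprintf("invalid %s tag(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  unique(x)
}

check_people <- function(x, what) {
  x <- x %||% list()
  for (p in x) {
    if (!is.list(p) || is.null(p$name)) {
      stop(sprintf("each %s entry needs at least a 'name'", what), call. = FALSE)
    }
  }
  lapply(x, function(p) {
    out <- list(name = as.character(p$name))
    if (!is.null(p$role)) out$role <- as.character(p$role)
    if (!is.null(p$email)) out$email <- as.character(p$email)
    out
  })
}

opt_num <- function(x) if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else as.numeric(x)
opt_chr <- function(x) if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else as.character(x)

#' Create a variable category
#'
#' @param code category code as stored in the data (non-empty string).
#' @param label display label.
#' @param is_missing logical: does this code represent a missing value
#'   (refused, don't know, not applicable, ...)?
#' @return a `cc_category`.
#' @export
category <- function(code, label = code, is_missing = FALSE) {
  code <- as.character(code)
  stopifnot(is_scalar_chr(code), nzchar(code),
            is.logical(is_missing), length(is_missing) == 1, !is.na(is_missing))
  structure(list(code = code, label = as.character(label),
                 is_missing = is_missing),
            class = "cc_category")
}

#' Create a variable (data-dictionary entry)
#'
#' @param name variable name; a token (`[A-Za-z0-9_-]+`), unique within its
#'   dataset (case-sensitive).
#' @param label human-readable label (the text mined by the search engine).
#' @param value_type one of `integer`, `decimal`, `text`, `boolean`, `date`.
#' @param unit optional measurement unit.
#' @param question_text optional verbatim question used to collect the data.
#' @param categories ordered list of [category()] objects; non-empty means
#'   the variable is categorical.
#' @param annotations list of [term_ref()] annotations (set semantics).
#' @return a `cc_variable`.
#' @export
variable <- function(name, label = "", value_type = "text", unit = NULL,
                     question_text = NULL, categories = list(),
                     annotations = list()) {
  if (!is_token(name)) stop("variable name must be a token string", call. = FALSE)
  value_type <- match.arg(value_type, VALUE_TYPES)
  categories <- lapply(categories, function(cc) {
    if (inherits(cc, "cc_category")) cc else do.call(category, cc)
  })
  codes <- vapply(categories, `[[`, "", "code")
  if (anyDuplicated(codes)) {
    stop(sprintf("duplicate category code(s) in variable '%s': %s", name,
                 paste(unique(codes[duplicated(codes)]), collapse = ", ")),
         call. = FALSE)
  }
  annotations <- canonical_annotations(annotations)
  structure(list(name = name, label = as.character(label),
                 value_type = value_type, unit = opt_chr(unit),
                 question_text = opt_chr(question_text),
                 categories = categories, annotations = annotations),
            class = "cc_variable")
}

# annotations are a set: drop duplicates, sort by (domain, term) so that
# structural equality is representation-independent
canonical_annotations <- function(annotations) {
  annotations <- lapply(annotations %||% list(), function(a) {
    if (inherits(a, "cc_term_ref")) a else term_ref(a$domain_name, a$term_name)
  })
  if (!length(annotations)) return(list())
  keys <- vapply(annotations, term_ref_key, "")
  annotations <- annotations[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  annotations[order(keys, method = "radix")]
}

#' Create a data collection event (wave / follow-up)
#'
#' @param id token id, unique within its population.
#' @param name display name (e.g. `"24 weeks gestation"`).
#' @param description free-text description.
#' @param start_date,end_date partial ISO dates (`YYYY`, `YYYY-MM` or
#'   `YYYY-MM-DD`); `end_date` optional. Ordering is checked under the
#'   earliest-interpretation rule (see [validate_study()]).
#' @param data_sources subset of `questionnaires`, `physical_measures`,
#'   `cognitive_measures`, `biological_samples`, `administrative_databases`,
#'   `other`.
#' @return a `cc_dce`.
#' @export
dce <- function(id, name = id, description = "", start_date = NULL,
                end_date = NULL, data_sources = character()) {
  if (!is_token(id)) stop("dce id must be a token string", call. = FALSE)
  start_date <- opt_chr(start_date); end_date <- opt_chr(end_date)
  for (d in c(start_date, end_date)) {
    if (!is.null(d) && !is_partial_date(d)) {
      stop(sprintf("'%s' is not a partial ISO date (YYYY[-MM[-DD]])", d),
           call. = FALSE)
    }
  }
  structure(list(id = id, name = as.character(name),
                 description = as.character(description),
                 start_date = start_date, end_date = end_date,
                 data_sources = check_enum_set(data_sources, DATA_SOURCES,
                                               "data_sources")),
            class = "cc_dce")
}

#' Create a subpopulation of study participants
#'
#' @param id token id, unique within its study.
#' @param name,description display name and free text.
#' @param recruitment_sources subset of `general_population`,
#'   `specific_population`, `participants_of_other_study`, `other`.
#' @param selection_criteria optional list with any of `age_min`, `age_max`
#'   (years), `sex` (`female`/`male`/`all`), `countries` (ISO-3166 alpha-2
#'   codes), `other` (free text).
#' @param number_of_participants optional non-negative integer.
#' @param data_collection_events ordered list of [dce()] objects.
#' @return a `cc_population`.
#' @export
population <- function(id, name = id, description = "",
                       recruitment_sources = character(),
                       selection_criteria = list(),
                       number_of_participants = NULL,
                       data_collection_events = list()) {
  if (!is_token(id)) stop("population id must be a token string", call. = FALSE)
  sc <- selection_criteria %||% list()
  known <- c("age_min", "age_max", "sex", "countries", "other")
  bad <- setdiff(names(sc), known)
  if (length(bad)) stop("unknown selection_criteria field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(sc$sex)) sc$sex <- match.arg(as.character(sc$sex), SEX_VALUES)
  if (!is.null(sc$age_min)) sc$age_min <- as.numeric(sc$age_min)
  if (!is.null(sc$age_max)) sc$age_max <- as.numeric(sc$age_max)
  if (!is.null(sc$countries)) {
    sc$countries <- toupper(as.character(sc$countries))
    if (!all(grepl("^[A-Z]{2}$", sc$countries))) {
      stop("countries must be ISO-3166 alpha-2 codes", call. = FALSE)
    }
  }
  dces <- lapply(data_collection_events, function(d) {
    if (inherits(d, "cc_dce")) d else do.call(dce, d)
  })
  structure(list(id = id, name = as.character(name),
                 description = as.character(description),
                 recruitment_sources = check_enum_set(recruitment_sources,
                                                      RECRUITMENT_SOURCES,
                                                      "recruitment_sources"),
                 selection_criteria = sc,
                 number_of_participants = opt_num(number_of_participants),
                 data_collection_events = dces),
            class = "cc_population")
}

#' Create a study (cohort) description
#'
#' The catalogue's unit of description: study outline (name, objectives,
#' timeline, participant counts, access), investigators and contacts, and
#' the ordered list of subpopulations.
#'
#' @param id token id, unique within a catalogue.
#' @param name full study name.
#' @param acronym,website,logo_ref optional outline fields.
#' @param objectives free-text objectives (recommended; missing yields a
#'   validation warning).
#' @param investigators,contacts lists of `list(name, role?, email?)`.
#' @param start_year,end_year study timeline in calendar years.
#' @param number_of_participants,number_with_samples non-negative integers;
#'   participants providing biological samples cannot exceed participants
#'   recruited.
#' @param access list with free-text `data` and `samples` fields
#'   (recommended).
#' @param populations ordered list of [population()] objects.
#' @return a `cc_study`.
#' @export
study <- function(id, name = id, acronym = NULL, objectives = NULL,
                  website = NULL, investigators = list(), contacts = list(),
                  start_year = NULL, end_year = NULL,
                  number_of_participants = NULL, number_with_samples = NULL,
                  access = NULL, logo_ref = NULL, populations = list()) {
  if (!is_scalar_chr(id)) stop("study id must be a string", call. = FALSE)
  pops <- lapply(populations, function(p) {
    if (inherits(p, "cc_population")) p else do.call(population, p)
  })
  if (!is.null(access)) {
    bad <- setdiff(names(access), c("data", "samples"))
    if (length(bad)) stop("unknown access field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    access <- lapply(access, as.character)
  }
  structure(list(id = id, name = as.character(name), acronym = opt_chr(acronym),
                 objectives = opt_chr(objectives), website = opt_chr(website),
                 investigators = check_people(investigators, "investigators"),
                 contacts = check_people(contacts, "contacts"),
                 start_year = opt_num(start_year), end_year = opt_num(end_year),
                 number_of_participants = opt_num(number_of_participants),
                 number_with_samples = opt_num(number_with_samples),
                 access = access, logo_ref = opt_chr(logo_ref),
                 populations = pops),
            class = "cc_study")
}

#' Create a dataset (data dictionary) linked to one data collection event
#'
#' @param id token id, unique within a catalogue.
#' @param name,description display name and free text.
#' @param study_id,population_id,dce_id the link: the DCE this dictionary's
#'   data were collected at. Resolvability is checked by [resolve_links()].
#' @param variables ordered list of [variable()] objects; names must be
#'   unique (case-sensitive).
#' @return a `cc_dataset`.
#' @export
dataset <- function(id, name = id, description = "", study_id, population_id,
                    dce_id, variables = list()) {
  if (!is_token(id)) stop("dataset id must be a token string", call. = FALSE)
  vars <- lapply(variables, function(v) {
    if (inherits(v, "cc_variable")) v else do.call(variable, v)
  })
  nms <- vapply(vars, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate variable name(s) in dataset '%s': %s", id,
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(id = id, name = as.character(name),
                 description = as.character(description),
                 link = list(study_id = as.character(study_id),
                             population_id = as.character(population_id),
                             dce_id = as.character(dce_id)),
                 variables = vars),
            class = "cc_dataset")
}

#' @export
print.cc_study <- function(x, ...) {
  np <- length(x$populations)
  nd <- sum(vapply(x$populations, function(p) length(p$data_collection_events), 0L))
  cat(sprintf("<study '%s' (%s): %d population(s), %d data collection event(s)>\n",
              x$id, x$name, np, nd))
  invisible(x)
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("<dataset '%s': %d variable(s), linked to %s/%s/%s>\n",
              x$id, length(x$variables), x$link$study_id, x$link$population_id,
              x$link$dce_id))
  invisible(x)
}

# ---- validation ------------------------------------------------------------

#' Validate a study against the model invariants
#'
#' Checks, and reports (never throws): id well-formedness; participants
#' providing samples not exceeding participants recruited; end year not
#' before start year; uniqueness of population ids within the study and of
#' DCE ids within each population; `age_min <= age_max`; and DCE date
#' ordering, where partial dates are compared by their earliest concrete
#' interpretation (`2002` reads as 2002-01-01, `2001-05` as 2001-05-01).
#' Missing recommended fields (objectives, access) yield warnings, because
#' the model deliberately tolerates varying levels of completeness.
#'
#' The check is pure: the same study always yields an identical report.
#'
#' @param study a [study()] object.
#' @return a [cc_report()].
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "cc_study"))
  rep <- cc_report()
  path <- sprintf("study[%s]", study$id)
  if (!is_token(study$id)) {
    rep <- report_merge(rep, report_issue("error", path,
      "study id must be non-empty and match [A-Za-z0-9_-]+"))
  }
  if (!is.null(study$number_of_participants) && !is_count(study$number_of_participants)) {
    rep <- report_merge(rep, report_issue("error", path,
      "number_of_participants must be a non-negative integer"))
  }
  if (!is.null(study$number_with_samples) && !is_count(study$number_with_samples)) {
    rep <- report_merge(rep, report_issue("error", path,
      "number_with_samples must be a non-negative integer"))
  }
  if (!is.null(study$number_with_samples) && !is.null(study$number_of_participants) &&
      study$number_with_samples > study$number_of_participants) {
    rep <- report_merge(rep, report_issue("error", path,
      sprintf("samples exceed participants (%d > %d)",
              study$number_with_samples, study$number_of_participants)))
  }
  if (!is.null(study$start_year) && !is.null(study$end_year) &&
      study$end_year < study$start_year) {
    rep <- report_merge(rep, report_issue("error", path,
      sprintf("end_year (%d) precedes start_year (%d)",
              study$end_year, study$start_year)))
  }
  if (is.null(study$objectives)) {
    rep <- report_merge(rep, report_issue("warning", path,
      "recommended field 'objectives' is missing"))
  }
  if (is.null(study$access)) {
    rep <- report_merge(rep, report_issue("warning", path,
      "recommended field 'access' is missing"))
  }
  pop_ids <- vapply(study$populations, `[[`, "", "id")
  for (dup in unique(pop_ids[duplicated(pop_ids)])) {
    rep <- report_merge(rep, report_issue("error", path,
      sprintf("duplicate population id '%s'", dup)))
  }
  for (pop in study$populations) {
    ppath <- sprintf("%s/population[%s]", path, pop$id)
    sc <- pop$selection_criteria
    if (!is.null(sc$age_min) && !is.null(sc$age_max) && sc$age_min > sc$age_max) {
      rep <- report_merge(rep, report_issue("error", ppath,
        sprintf("age_min (%g) exceeds age_max (%g)", sc$age_min, sc$age_max)))
    }
    if (!is.null(pop$number_of_participants) && !is_count(pop$number_of_participants)) {
      rep <- report_merge(rep, report_issue("error", ppath,
        "number_of_participants must be a non-negative integer"))
    }
    dce_ids <- vapply(pop$data_collection_events, `[[`, "", "id")
    for (dup in unique(dce_ids[duplicated(dce_ids)])) {
      rep <- report_merge(rep, report_issue("error", ppath,
        sprintf("duplicate data collection event id '%s'", dup)))
    }
    for (ev in pop$data_collection_events) {
      dpath <- sprintf("%s/dce[%s]", ppath, ev$id)
      if (!is.null(ev$start_date) && !is.null(ev$end_date)) {
        s <- partial_date_earliest(ev$start_date)
        e <- partial_date_earliest(ev$end_date)
        if (!is.na(s) && !is.na(e) && e < s) {
          rep <- report_merge(rep, report_issue("error", dpath,
            sprintf("end_date (%s) precedes start_date (%s)",
                    ev$end_date, ev$start_date)))
        }
      }
    }
  }
  rep
}

#' Resolve dataset links against a set of studies
#'
#' Each dataset must attach to exactly one existing data collection event,
#' identified by its `(study_id, population_id, dce_id)` link. Several
#' datasets may attach to the same event (many-to-one is the normal case
#' for, e.g., a questionnaire dictionary plus a physical-measures
#' dictionary from the same wave). Duplicate study or dataset ids are also
#' reported here, since uniqueness is a catalogue-level property.
#'
#' @param studies list of [study()] objects.
#' @param datasets list of [dataset()] objects.
#' @return a [cc_report()]; empty iff every link resolves.
#' @export
resolve_links <- function(studies, datasets) {
  rep <- cc_report()
  sids <- vapply(studies, `[[`, "", "id")
  for (dup in unique(sids[duplicated(sids)])) {
    rep <- report_merge(rep, report_issue("error", sprintf("study[%s]", dup),
      "duplicate study id in catalogue"))
  }
  dids <- vapply(datasets, `[[`, "", "id")
  for (dup in unique(dids[duplicated(dids)])) {
    rep <- report_merge(rep, report_issue("error", sprintf("dataset[%s]", dup),
      "duplicate dataset id in catalogue"))
  }
  by_id <- stats::setNames(studies, sids)
  for (ds in datasets) {
    path <- sprintf("dataset[%s]", ds$id)
    lk <- ds$link
    st <- by_id[[lk$study_id]]
    if (is.null(st)) {
      rep <- report_merge(rep, report_issue("error", path,
        sprintf("link names missing study '%s'", lk$study_id)))
      next
    }
    pop <- NULL
    for (p in st$populations) if (p$id == lk$population_id) pop <- p
    if (is.null(pop)) {
      rep <- report_merge(rep, report_issue("error", path,
        sprintf("link names missing population '%s' in study '%s'",
                lk$population_id, lk$study_id)))
      next
    }
    found <- any(vapply(pop$data_collection_events,
                        function(d) d$id == lk$dce_id, logical(1)))
    if (!found) {
      rep <- report_merge(rep, report_issue("error", path,
        sprintf("link names missing data collection event '%s' in %s/%s",
                lk$dce_id, lk$study_id, lk$population_id)))
    }
  }
  rep
}
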