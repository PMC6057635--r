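#' @title Deterministic study and variable search
#' @description
#' A desk-scale stand-in for a catalogue search engine: an inverted text
#' index over tokenized variable labels, names and question text, a term
#' index over taxonomy annotations, plus property filters over studies.
#' Everything is deterministic: tokenization is [cc_tokenize()] (case-fold,
#' split on non-alphanumerics, no stemming, no stop-words), scores are
#' transparent clause counts, and ties break lexicographically on the
#' locator, so identical inputs always give identical ordered results.
#' @name search
NULL

#' Build a searchable catalogue from studies, datasets and a taxonomy
#'
#' Refuses to build (throws a `cc_build_error` carrying the offending
#' [cc_report()] in its `report` field) when any study invariant is
#' violated, any dataset link dangles, or any annotation fails to resolve.
#' Unannotated variables are legal (they only warn).
#'
#' @param studies list of [study()] objects.
#' @param datasets list of [dataset()] objects.
#' @param tax a [taxonomy()].
#' @return a `cc_catalogue` with text and term inverted indexes.
#' @export
build_index <- function(studies, datasets, tax = builtin_taxonomy()) {
  rep <- do.call(report_merge, c(lapply(studies, validate_study),
                                 list(resolve_links(studies, datasets)),
                                 lapply(datasets, validate_annotations, tax = tax)))
  if (n_errors(rep) > 0) {
    cond <- structure(class = c("cc_build_error", "error", "condition"),
                      list(message = paste0("catalogue has validation errors:\n",
                                            format(rep)),
                           call = sys.call(), report = rep))
    stop(cond)
  }

  sids <- vapply(studies, `[[`, "", "id")
  dids <- vapply(datasets, `[[`, "", "id")
  rows <- list(); tokens <- list(); anns <- list()
  for (ds in datasets) {
    for (v in ds$variables) {
      i <- length(rows) + 1L
      rows[[i]] <- data.frame(
        locator = paste(ds$link$study_id, ds$id, v$name, sep = "/"),
        study_id = ds$link$study_id, population_id = ds$link$population_id,
        dce_id = ds$link$dce_id, dataset_id = ds$id, name = v$name,
        stringsAsFactors = FALSE)
      tokens[[i]] <- unique(cc_tokenize(c(v$name, v$label, v$question_text)))
      anns[[i]] <- vapply(v$annotations, term_ref_key, "")
    }
  }
  vars <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(locator = character(), study_id = character(),
               population_id = character(), dce_id = character(),
               dataset_id = character(), name = character(),
               stringsAsFactors = FALSE)
  }
  invert <- function(lst) {
    if (!length(lst)) return(list())
    n <- lengths(lst)
    if (sum(n) == 0) return(list())
    idx <- rep.int(seq_along(lst), n)
    split(idx, unlist(lst, use.names = FALSE))
  }
  structure(list(studies = stats::setNames(studies, sids),
                 datasets = stats::setNames(datasets, dids),
                 taxonomy = tax, variables = vars,
                 var_tokens = tokens, var_annotations = anns,
                 text_index = invert(tokens), term_index = invert(anns)),
            class = "cc_catalogue")
}

#' @export
print.cc_catalogue <- function(x, ...) {
  cat(sprintf("<catalogue: %d studies, %d datasets, %d variables, %d index tokens>\n",
              length(x$studies), length(x$datasets), nrow(x$variables),
              length(x$text_index)))
  invisible(x)
}

#' Study property query
#'
#' All supplied clauses must hold (AND). Ranges are inclusive; a malformed
#' range (min > max) is rejected here, at construction.
#'
#' @param participants_min,participants_max bounds on the study's number of
#'   recruited participants (studies with an undocumented count never
#'   match a participants clause).
#' @param start_year_range length-2 year vector; the study's start year
#'   must fall inside.
#' @param countries ISO alpha-2 codes; matches when any subpopulation's
#'   selection criteria name at least one of them.
#' @param data_sources tags; matches when any data collection event of the
#'   study uses at least one of them.
#' @param age_range length-2 years vector; matches when some
#'   subpopulation's `[age_min, age_max]` interval (missing bounds open)
#'   overlaps it and at least one bound is documented.
#' @return a `cc_study_query`.
#' @export
study_query <- function(participants_min = NULL, participants_max = NULL,
                        start_year_range = NULL, countries = NULL,
                        data_sources = NULL, age_range = NULL) {
  chk_range <- function(r, what) {
    if (!is.null(r)) {
      if (length(r) != 2 || anyNA(r) || r[1] > r[2]) {
        stop(sprintf("malformed %s: need c(min, max) with min <= max", what),
             call. = FALSE)
      }
    }
    if (is.null(r)) NULL else as.numeric(r)
  }
  if (!is.null(participants_min) && !is.null(participants_max) &&
      participants_min > participants_max) {
    stop("malformed participants range: min exceeds max", call. = FALSE)
  }
  if (!is.null(data_sources)) {
    data_sources <- check_enum_set(data_sources, DATA_SOURCES, "data_sources")
  }
  structure(list(participants_min = opt_num(participants_min),
                 participants_max = opt_num(participants_max),
                 start_year_range = chk_range(start_year_range, "start_year_range"),
                 countries = if (is.null(countries)) NULL else toupper(countries),
                 data_sources = data_sources,
                 age_range = chk_range(age_range, "age_range")),
            class = "cc_study_query")
}

study_matches <- function(st, q) {
  clauses <- 0L
  if (!is.null(q$participants_min)) {
    if (is.null(st$number_of_participants) ||
        st$number_of_participants < q$participants_min) return(NA_integer_)
    clauses <- clauses + 1L
  }
  if (!is.null(q$participants_max)) {
    if (is.null(st$number_of_participants) ||
        st$number_of_participants > q$participants_max) return(NA_integer_)
    clauses <- clauses + 1L
  }
  if (!is.null(q$start_year_range)) {
    if (is.null(st$start_year) || st$start_year < q$start_year_range[1] ||
        st$start_year > q$start_year_range[2]) return(NA_integer_)
    clauses <- clauses + 1L
  }
  if (!is.null(q$countries)) {
    hit <- any(vapply(st$populations, function(p) {
      length(intersect(p$selection_criteria$countries %||% character(),
                       q$countries)) > 0
    }, logical(1)))
    if (!hit) return(NA_integer_)
    clauses <- clauses + 1L
  }
  if (!is.null(q$data_sources)) {
    hit <- any(vapply(st$populations, function(p) {
      any(vapply(p$data_collection_events, function(d) {
        length(intersect(d$data_sources, q$data_sources)) > 0
      }, logical(1)))
    }, logical(1)))
    if (!hit) return(NA_integer_)
    clauses <- clauses + 1L
  }
  if (!is.null(q$age_range)) {
    hit <- any(vapply(st$populations, function(p) {
      sc <- p$selection_criteria
      if (is.null(sc$age_min) && is.null(sc$age_max)) return(FALSE)
      lo <- sc$age_min %||% -Inf; hi <- sc$age_max %||% Inf
      lo <= q$age_range[2] && hi >= q$age_range[1]
    }, logical(1)))
    if (!hit) return(NA_integer_)
    clauses <- clauses + 1L
  }
  clauses
}

#' Search studies by property filters
#'
#' A study is a hit iff it satisfies every supplied clause; its score is
#' the number of supplied (hence satisfied) clauses. With no clauses, all
#' studies match with score 0. Hits are ordered by score (descending) then
#' study id (lexicographic).
#'
#' @param cat a [build_index()] catalogue.
#' @param query a [study_query()].
#' @return data frame with `locator` (study id) and `score`.
#' @export
search_studies <- function(cat, query = study_query()) {
  stopifnot(inherits(cat, "cc_catalogue"), inherits(query, "cc_study_query"))
  scores <- vapply(cat$studies, study_matches, integer(1), q = query)
  hits <- data.frame(locator = names(scores)[!is.na(scores)],
                     score = as.numeric(scores[!is.na(scores)]),
                     stringsAsFactors = FALSE)
  hits[order(-hits$score, hits$locator, method = "radix"), , drop = FALSE] ->
    hits
  rownames(hits) <- NULL
  hits
}

#' Variable query
#'
#' @param text character vector of query tokens, combined with AND; a
#'   trailing `*` makes a token a prefix match. Tokens are case-folded and
#'   must be alphanumeric.
#' @param terms list of [term_ref()] (or `"Domain/Term"` strings), combined
#'   with OR: at least one must annotate the variable.
#' @param scope optional list restricting hits to a study, population
#'   and/or data collection event (`study_id`, `population_id`, `dce_id`).
#' @return a `cc_variable_query`; with no clause at all the query means
#'   "match every variable".
#' @export
variable_query <- function(text = NULL, terms = NULL, scope = NULL) {
  toks <- NULL
  if (!is.null(text) && length(text)) {
    toks <- lapply(as.character(text), function(tk) {
      prefix <- grepl("\\*$", tk)
      core <- tolower(sub("\\*$", "", tk))
      if (!grepl("^[a-z0-9]+$", core)) {
        stop(sprintf("'%s' is not a valid query token", tk), call. = FALSE)
      }
      list(token = core, prefix = prefix)
    })
  }
  refs <- NULL
  if (!is.null(terms) && length(terms)) {
    refs <- lapply(terms, function(t) {
      if (inherits(t, "cc_term_ref")) t else parse_term_ref(t)
    })
  }
  if (!is.null(scope)) {
    bad <- setdiff(names(scope), c("study_id", "population_id", "dce_id"))
    if (length(bad)) stop("unknown scope field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(text = toks, terms = refs, scope = scope),
            class = "cc_variable_query")
}

# indexes -> integer candidate set; NULL means "no text clause"
match_variable_query <- function(cat, query) {
  n <- nrow(cat$variables)
  idx <- seq_len(n)
  score <- numeric(n)

  if (!is.null(query$terms)) {
    keys <- vapply(query$terms, function(r) {
      if (!resolves(cat$taxonomy, r)) {
        stop(sprintf("query term '%s' does not resolve in the taxonomy",
                     format(r)), call. = FALSE)
      }
      term_ref_key(r)
    }, "")
    term_hits <- integer(0)
    n_matched <- integer(0)
    per_key <- lapply(keys, function(k) cat$term_index[[k]] %||% integer(0))
    term_hits <- sort(unique(unlist(per_key)))
    if (length(term_hits)) {
      counts <- table(factor(unlist(per_key), levels = term_hits))
      score[term_hits] <- score[term_hits] + as.numeric(counts)
    }
    idx <- intersect(idx, term_hits)
  }

  if (!is.null(query$text)) {
    for (cl in query$text) {
      hit <- if (cl$prefix) {
        keys <- names(cat$text_index)
        sel <- keys[startsWith(keys, cl$token)]
        sort(unique(unlist(cat$text_index[sel], use.names = FALSE)))
      } else {
        cat$text_index[[cl$token]] %||% integer(0)
      }
      idx <- intersect(idx, hit)
    }
    score[idx] <- score[idx] + length(query$text)
  }

  if (!is.null(query$scope)) {
    sc <- query$scope
    keep <- rep(TRUE, n)
    if (!is.null(sc$study_id)) keep <- keep & cat$variables$study_id == sc$study_id
    if (!is.null(sc$population_id)) {
      keep <- keep & cat$variables$population_id == sc$population_id
    }
    if (!is.null(sc$dce_id)) keep <- keep & cat$variables$dce_id == sc$dce_id
    idx <- intersect(idx, which(keep))
  }
  list(idx = idx, score = score)
}

#' Search variables by text, taxonomy terms and scope
#'
#' A variable matches iff every text token matches its tokenized
#' label-name-question text (whole-token, or prefix for `tok*` clauses),
#' AND at least one supplied term annotates it (when terms are supplied),
#' AND it lies in the requested scope. The score is the number of matched
#' text tokens plus one per matching term; ordering is score descending,
#' then locator `study/dataset/variable` lexicographic.
#'
#' @param cat a [build_index()] catalogue.
#' @param query a [variable_query()].
#' @return data frame with `locator` and `score`.
#' @export
search_variables <- function(cat, query = variable_query()) {
  stopifnot(inherits(cat, "cc_catalogue"), inherits(query, "cc_variable_query"))
  m <- match_variable_query(cat, query)
  hits <- data.frame(locator = cat$variables$locator[m$idx],
                     score = m$score[m$idx], stringsAsFactors = FALSE)
  hits <- hits[order(-hits$score, hits$locator, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Facet counts over a variable query's match set
#'
#' Partitions the variables matched by `query` along one facet. Under the
#' `domain` and `term` facets every annotation of a matched variable
#' contributes one count, so a variable with k annotations adds to k facet
#' values and facet sums can exceed the match-set size; under `study` each
#' variable counts once.
#'
#' @param cat a [build_index()] catalogue.
#' @param query a [variable_query()].
#' @param facet `"domain"`, `"term"` or `"study"`.
#' @return named integer vector (sorted by facet value), empty for a
#'   zero-hit query.
#' @export
facet_counts <- function(cat, query = variable_query(),
                         facet = c("domain", "term", "study")) {
  facet <- match.arg(facet)
  m <- match_variable_query(cat, query)
  idx <- m$idx
  if (!length(idx)) return(stats::setNames(integer(0), character(0)))
  values <- switch(facet,
    study = cat$variables$study_id[idx],
    term = unlist(lapply(cat$var_annotations[idx], function(k)
      gsub("\x1f", "/", k, fixed = TRUE))),
    domain = unlist(lapply(cat$var_annotations[idx], function(k)
      sub("\x1f.*$", "", k))))
  if (is.null(values) || !length(values)) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(values)
  stats::setNames(as.integer(tab), names(tab))
}
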