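#' @title Variable-classification taxonomy
#' @description
#' A two-level controlled vocabulary (domain -> term, a.k.a. subdomain)
#' used to annotate variables so they can be browsed, faceted and compared
#' across studies. The packaged default ([builtin_taxonomy()]) is the
#' 18-domain / 135-subdomain classification used by cohort-cataloguing
#' practice; any taxonomy with the same YAML shape can be substituted.
#' @name taxonomy
NULL

#' Reference to a taxonomy term
#'
#' A `(domain, term)` pair used as a variable annotation, a search filter,
#' a comparison-table column, or a classifier class. Resolution against a
#' taxonomy is exact and case-sensitive on names.
#'
#' @param domain_name domain name, e.g. `"Lifestyle and behaviours"`.
#' @param term_name term (subdomain) name, e.g. `"Tobacco"`.
#' @return a `cc_term_ref`.
#' @export
term_ref <- function(domain_name, term_name) {
  stopifnot(is_scalar_chr(domain_name), is_scalar_chr(term_name))
  structure(list(domain_name = domain_name, term_name = term_name),
            class = "cc_term_ref")
}

# internal canonical key; \x1f cannot occur in names read from YAML/CSV text
term_ref_key <- function(ref) paste(ref$domain_name, ref$term_name, sep = "\x1f")

#' Parse a `"Domain/Term"` string into a term reference
#'
#' Splits on the first `/`. This is the CLI syntax for `--term`.
#' @param x string like `"Lifestyle and behaviours/Tobacco"`.
#' @return a [term_ref()].
#' @export
parse_term_ref <- function(x) {
  stopifnot(is_scalar_chr(x))
  pos <- regexpr("/", x, fixed = TRUE)
  if (pos < 0) stop("term reference must look like 'Domain/Term'", call. = FALSE)
  term_ref(substr(x, 1, pos - 1), substr(x, pos + 1, nchar(x)))
}

#' @export
format.cc_term_ref <- function(x, ...) paste0(x$domain_name, "/", x$term_name)

#' @export
print.cc_term_ref <- function(x, ...) {
  cat("<term ref ", format(x), ">\n", sep = "")
  invisible(x)
}

new_term <- function(name, label = name, keywords = NULL) {
  stopifnot(is_scalar_chr(name), nzchar(name))
  structure(list(name = name, label = as.character(label),
                 keywords = if (is.null(keywords)) NULL else as.character(keywords)),
            class = "cc_term")
}

new_domain <- function(name, description = NULL, terms = list()) {
  stopifnot(is_scalar_chr(name), nzchar(name))
  terms <- lapply(terms, function(t) {
    if (inherits(t, "cc_term")) t else do.call(new_term, t)
  })
  nms <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate term '%s' in domain '%s'",
                 nms[duplicated(nms)][1], name), call. = FALSE)
  }
  structure(list(name = name, description = opt_chr(description), terms = terms),
            class = "cc_domain")
}

#' Construct a taxonomy
#'
#' @param name,version identification of the classification scheme.
#' @param domains list of domains, each `list(name, description?, terms)`
#'   with terms `list(name, label?, keywords?)`. Duplicate domain names, or
#'   duplicate term names within a domain, are errors.
#' @return a `cc_taxonomy`.
#' @export
taxonomy <- function(name, version = "1.0", domains = list()) {
  domains <- lapply(domains, function(d) {
    if (inherits(d, "cc_domain")) d else do.call(new_domain, d)
  })
  nms <- vapply(domains, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate domain name '%s'", nms[duplicated(nms)][1]),
         call. = FALSE)
  }
  structure(list(name = as.character(name), version = as.character(version),
                 domains = domains),
            class = "cc_taxonomy")
}

#' Load a taxonomy from a YAML document
#'
#' @param source path to a YAML file, or a literal YAML string.
#' @return a [taxonomy()]; duplicate domains or duplicate terms within a
#'   domain raise an error naming the duplicate.
#' @export
load_taxonomy <- function(source) {
  doc <- if (is_scalar_chr(source) && !grepl("\n", source) && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(source)
  }
  taxonomy(name = doc$name %||% "unnamed",
           version = doc$version %||% "1.0",
           domains = lapply(doc$domains %||% list(), function(d) {
             list(name = d$name, description = d$description,
                  terms = lapply(d$terms %||% list(), function(t) {
                    list(name = t$name, label = t$label %||% t$name,
                         keywords = t$keywords)
                  }))
           }))
}

#' Write a taxonomy as a YAML document
#' @param tax a [taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "cc_taxonomy"))
  doc <- list(name = tax$name, version = tax$version,
              domains = lapply(tax$domains, function(d) {
                out <- list(name = d$name)
                if (!is.null(d$description)) out$description <- d$description
                out$terms <- lapply(d$terms, function(t) {
                  tt <- list(name = t$name, label = t$label)
                  if (!is.null(t$keywords)) tt$keywords <- as.list(t$keywords)
                  tt
                })
                out
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

.cc_env <- new.env(parent = emptyenv())

#' The packaged 18-domain / 135-subdomain classification
#'
#' Returns the built-in variable classification: 18 domains covering all
#' information typically collected by a population-based cohort, with 135
#' subdomains in total (per-domain counts 14, 14, 5, 6, 20, 9, 3, 7, 4, 3,
#' 11, 9, 4, 4, 4, 5, 7, 6). Subdomain names that are not part of the
#' publicly printed classification are stable placeholders of the form
#' `<domain-slug>_sub<k>`; the five printed subdomains (Education; Income,
#' possessions, and benefits; Tobacco; Alcohol; Pregnancy, childbirth and
#' the puerperium (O00-O9A)) carry their real names.
#'
#' @return a `cc_taxonomy` (cached; load cost paid once per session).
#' @export
builtin_taxonomy <- function() {
  if (is.null(.cc_env$builtin_taxonomy)) {
    path <- system.file("extdata", "classification.yaml", package = "cohortcat",
                        mustWork = TRUE)
    .cc_env$builtin_taxonomy <- load_taxonomy(path)
  }
  .cc_env$builtin_taxonomy
}

#' Count domains / terms in a taxonomy
#' @param tax a [taxonomy()].
#' @return integer.
#' @export
n_domains <- function(tax) length(tax$domains)

#' @rdname n_domains
#' @export
n_terms <- function(tax) {
  sum(vapply(tax$domains, function(d) length(d$terms), integer(1)))
}

#' Test whether a term reference resolves in a taxonomy
#' @param tax a [taxonomy()].
#' @param ref a [term_ref()].
#' @return logical.
#' @export
resolves <- function(tax, ref) {
  for (d in tax$domains) {
    if (d$name == ref$domain_name) {
      return(any(vapply(d$terms, function(t) t$name == ref$term_name, logical(1))))
    }
  }
  FALSE
}

#' @export
print.cc_taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy '%s' v%s: %d domains, %d terms>\n",
              x$name, x$version, n_domains(x), n_terms(x)))
  invisible(x)
}

#' Annotate a variable with a taxonomy term
#'
#' Annotations have set semantics: annotating with a term the variable
#' already carries is a no-op. The input variable is not modified (copy
#' semantics); only the `annotations` field of the returned variable
#' differs.
#'
#' @param var a [variable()].
#' @param ref a [term_ref()]; must resolve in `tax`.
#' @param tax a [taxonomy()].
#' @return the annotated variable.
#' @export
annotate_variable <- function(var, ref, tax) {
  stopifnot(inherits(var, "cc_variable"), inherits(ref, "cc_term_ref"),
            inherits(tax, "cc_taxonomy"))
  if (!resolves(tax, ref)) {
    stop(sprintf("term '%s' not found in domain '%s' of taxonomy '%s'",
                 ref$term_name, ref$domain_name, tax$name), call. = FALSE)
  }
  var$annotations <- canonical_annotations(c(var$annotations, list(ref)))
  var
}

#' Validate a dataset's annotations against a taxonomy
#'
#' One error per annotation that does not resolve; one warning per variable
#' carrying no annotation at all (unclassified variables are legal but
#' invisible to term-based discovery).
#'
#' @param ds a [dataset()].
#' @param tax a [taxonomy()].
#' @return a [cc_report()].
#' @export
validate_annotations <- function(ds, tax) {
  stopifnot(inherits(ds, "cc_dataset"), inherits(tax, "cc_taxonomy"))
  rep <- cc_report()
  for (v in ds$variables) {
    path <- sprintf("dataset[%s]/variable[%s]", ds$id, v$name)
    if (!length(v$annotations)) {
      rep <- report_merge(rep, report_issue("warning", path,
        "variable has no taxonomy annotation"))
      next
    }
    for (a in v$annotations) {
      if (!resolves(tax, a)) {
        rep <- report_merge(rep, report_issue("error", path,
          sprintf("annotation '%s' does not resolve in taxonomy '%s'",
                  format(a), tax$name)))
      }
    }
  }
  rep
}
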