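#' Validation reports
#'
#' All structural checks in the package report problems instead of throwing:
#' a `cc_report` holds a table of issues, each with a severity (`"error"` or
#' `"warning"`), an entity locator path (e.g.
#' `study[aobf]/population[mothers]/dce[wave1]`) and a human-readable
#' message. An empty report means the checked entities satisfy every
#' invariant. Incomplete-but-wellformed metadata yields warnings only, so
#' catalogues with varying levels of completeness remain usable.
#'
#' @param severity character vector of `"error"` / `"warning"`.
#' @param path character vector of entity locators.
#' @param message character vector of messages.
#' @return A `cc_report` object with an `issues` data frame.
#' @export
cc_report <- function(severity = character(), path = character(),
                      message = character()) {
  stopifnot(all(severity %in% c("error", "warning")))
  issues <- data.frame(severity = as.character(severity),
                       path = as.character(path),
                       message = as.character(message),
                       stringsAsFactors = FALSE)
  structure(list(issues = issues), class = "cc_report")
}

report_merge <- function(...) {
  reps <- list(...)
  reps <- reps[!vapply(reps, is.null, logical(1))]
  issues <- do.call(rbind, lapply(reps, function(r) r$issues))
  out <- cc_report()
  if (!is.null(issues)) out$issues <- issues
  rownames(out$issues) <- NULL
  out
}

report_issue <- function(severity, path, message) {
  cc_report(severity = severity, path = path, message = message)
}

#' Count errors or warnings in a report
#' @param report a `cc_report`.
#' @return integer count.
#' @export
n_errors <- function(report) sum(report$issues$severity == "error")

#' @rdname n_errors
#' @export
n_warnings <- function(report) sum(report$issues$severity == "warning")

#' @export
print.cc_report <- function(x, ...) {
  ne <- n_errors(x); nw <- n_warnings(x)
  cat(sprintf("<validation report: %d error(s), %d warning(s)>\n", ne, nw))
  if (nrow(x$issues)) {
    apply(x$issues, 1, function(r) {
      cat(sprintf("  [%s] %s: %s\n", r[["severity"]], r[["path"]], r[["message"]]))
    })
  }
  invisible(x)
}

#' @export
format.cc_report <- function(x, ...) {
  if (!nrow(x$issues)) return("OK: no issues")
  paste(sprintf("[%s] %s: %s", x$issues$severity, x$issues$path, x$issues$message),
        collapse = "\n")
}
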