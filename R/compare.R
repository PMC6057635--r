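#' @title Harmonization-potential comparison tables
#' @description
#' The central data-discovery output for multi-study networks: a grid of
#' variable counts with one row per (study, subpopulation, data collection
#' event) and one column per taxonomy subdomain, showing how much
#' information on each topic each wave collected — the raw material for
#' judging whether similar variables could be harmonized across cohorts.
#' @name compare
NULL

#' Build a comparison table of variable counts
#'
#' Rows are every data collection event of every subpopulation of the
#' selected studies, in declared order (study order = selection order,
#' populations and DCEs in their declared catalogue order); all-zero rows
#' are kept, since knowing that a wave collected nothing on a topic is
#' itself informative. The cell for row r and term column c is the number
#' of variables, across all datasets linked to r's DCE, annotated with c.
#' Columns are counted independently: a variable annotated with two of the
#' selected terms contributes once to each of those two columns (no
#' cross-column deduplication).
#'
#' @param cat a [build_index()] catalogue.
#' @param columns list of [term_ref()] (or `"Domain/Term"` strings); must
#'   resolve in the catalogue's taxonomy.
#' @param study_ids studies to include, in display order; unknown ids are
#'   an error, an empty selection gives a zero-row table.
#' @return a `cc_comparison`: `rows` data frame (`study_id`,
#'   `population_id`, `dce_id`, plus display names), `columns` (term
#'   refs) and integer `cells` matrix.
#' @export
harmonization_table <- function(cat, columns, study_ids) {
  stopifnot(inherits(cat, "cc_catalogue"))
  columns <- lapply(columns, function(t) {
    ref <- if (inherits(t, "cc_term_ref")) t else parse_term_ref(t)
    if (!resolves(cat$taxonomy, ref)) {
      stop(sprintf("term '%s' does not resolve in the taxonomy", format(ref)),
           call. = FALSE)
    }
    ref
  })
  unknown <- setdiff(study_ids, names(cat$studies))
  if (length(unknown)) {
    stop("unknown study id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  for (sid in study_ids) {
    st <- cat$studies[[sid]]
    for (pop in st$populations) {
      for (ev in pop$data_collection_events) {
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sid, population_id = pop$id, dce_id = ev$id,
          study_name = st$name, population_name = pop$name, dce_name = ev$name,
          stringsAsFactors = FALSE)
      }
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(study_id = character(), population_id = character(),
               dce_id = character(), study_name = character(),
               population_name = character(), dce_name = character(),
               stringsAsFactors = FALSE)
  }

  col_keys <- vapply(columns, term_ref_key, "")
  cells <- matrix(0L, nrow = nrow(rows), ncol = length(columns),
                  dimnames = list(NULL, vapply(columns, `[[`, "", "term_name")))
  if (nrow(rows) && nrow(cat$variables)) {
    row_key <- paste(rows$study_id, rows$population_id, rows$dce_id, sep = "\x1f")
    var_key <- paste(cat$variables$study_id, cat$variables$population_id,
                     cat$variables$dce_id, sep = "\x1f")
    var_row <- match(var_key, row_key)
    for (j in seq_along(columns)) {
      hit_vars <- vapply(cat$var_annotations, function(k) col_keys[j] %in% k,
                         logical(1))
      tab <- table(var_row[hit_vars & !is.na(var_row)])
      cells[as.integer(names(tab)), j] <- cells[as.integer(names(tab)), j] +
        as.integer(tab)
    }
  }
  structure(list(rows = rows, columns = columns, cells = cells),
            class = "cc_comparison")
}

#' @export
print.cc_comparison <- function(x, ...) {
  cat(sprintf("<comparison table: %d row(s) x %d term column(s)>\n",
              nrow(x$rows), length(x$columns)))
  cat(render_comparison(x, "markdown"))
  invisible(x)
}

#' Render a comparison table as CSV or markdown
#'
#' CSV is flat (`study,population,dce,<one column per term>`) and
#' re-parses losslessly into the cell grid; markdown mirrors the printed
#' presentation, grouped by study (bold header row) and population (italic
#' sub-header), one DCE per data row.
#'
#' @param tbl a [harmonization_table()] result.
#' @param format `"csv"` or `"markdown"`.
#' @return a single string.
#' @export
render_comparison <- function(tbl, format = c("csv", "markdown")) {
  stopifnot(inherits(tbl, "cc_comparison"))
  format <- match.arg(format)
  term_names <- vapply(tbl$columns, `[[`, "", "term_name")
  if (format == "csv") {
    df <- data.frame(study = tbl$rows$study_id,
                     population = tbl$rows$population_id,
                     dce = tbl$rows$dce_id, stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (j in seq_along(term_names)) df[[term_names[j]]] <- tbl$cells[, j]
    return(csv_text(df))
  }
  lines <- c(paste0("| Study | ", paste(term_names, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(term_names) + 1), collapse = "|"),
                    "|"))
  blank <- paste(rep("", length(term_names)), collapse = " | ")
  prev_study <- prev_pop <- NULL
  for (i in seq_len(nrow(tbl$rows))) {
    r <- tbl$rows[i, ]
    if (!identical(prev_study, r$study_id)) {
      lines <- c(lines, sprintf("| **%s** | %s |", r$study_name, blank))
      prev_study <- r$study_id; prev_pop <- NULL
    }
    if (!identical(prev_pop, r$population_id)) {
      lines <- c(lines, sprintf("| *%s* | %s |", r$population_name, blank))
      prev_pop <- r$population_id
    }
    lines <- c(lines, paste0("| ", r$dce_name, " | ",
                             paste(tbl$cells[i, ], collapse = " | "), " |"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
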