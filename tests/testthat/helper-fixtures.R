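# Shared fixture builders and independent brute-force oracles.
# The oracles deliberately avoid the package's indexes: they evaluate query
# semantics by a direct linear scan over the entity lists, so that
# index-based search can be checked against them.

minimal_study <- function(id = "cohort1") {
  study(id = id, name = "Minimal cohort", objectives = "Follow things over time",
        access = list(data = "open", samples = "none"),
        start_year = 2000, end_year = 2010,
        number_of_participants = 100, number_with_samples = 40,
        populations = list(population(
          id = "adults", name = "Adults",
          selection_criteria = list(age_min = 18, age_max = 65),
          data_collection_events = list(
            dce(id = "baseline", name = "Baseline", start_date = "2000",
                end_date = "2001-06", data_sources = "questionnaires")))))
}

# the worked two-variable dictionary: age + smoke with 3 categories
smoke_dataset <- function(id = "demo", link_study = "cohort1") {
  dataset(id = id, name = "Demo dictionary",
          study_id = link_study, population_id = "adults", dce_id = "baseline",
          variables = list(
            variable("age", "Age of participant", "integer", unit = "years"),
            variable("smoke", "Current smoker", "integer", categories = list(
              category("0", "No"), category("1", "Yes"),
              category("9", "Refused", is_missing = TRUE)))))
}

toy_classifier_examples <- function() {
  list(list(variable("a1", "alcohol wine"),
            term_ref("Lifestyle and behaviours", "Alcohol")),
       list(variable("b1", "tobacco smoke"),
            term_ref("Lifestyle and behaviours", "Tobacco")))
}

strip_annotations <- function(ds) {
  ds$variables <- lapply(ds$variables, function(v) { v$annotations <- list(); v })
  ds
}

# ---- linear-scan oracles ---------------------------------------------------

oracle_variable_hits <- function(studies, datasets, query) {
  rows <- list()
  for (ds in datasets) {
    for (v in ds$variables) {
      toks <- unique(cc_tokenize(c(v$name, v$label, v$question_text)))
      score <- 0
      ok <- TRUE
      if (!is.null(query$terms)) {
        n_match <- sum(vapply(query$terms, function(r) {
          any(vapply(v$annotations, function(a) {
            identical(a$domain_name, r$domain_name) &&
              identical(a$term_name, r$term_name)
          }, logical(1)))
        }, logical(1)))
        if (n_match == 0) ok <- FALSE
        score <- score + n_match
      }
      if (ok && !is.null(query$text)) {
        for (cl in query$text) {
          hit <- if (cl$prefix) any(startsWith(toks, cl$token))
                 else cl$token %in% toks
          if (!hit) { ok <- FALSE; break }
        }
        if (ok) score <- score + length(query$text)
      }
      if (ok && !is.null(query$scope)) {
        sc <- query$scope
        if (!is.null(sc$study_id) && ds$link$study_id != sc$study_id) ok <- FALSE
        if (ok && !is.null(sc$population_id) &&
            ds$link$population_id != sc$population_id) ok <- FALSE
        if (ok && !is.null(sc$dce_id) && ds$link$dce_id != sc$dce_id) ok <- FALSE
      }
      if (ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          locator = paste(ds$link$study_id, ds$id, v$name, sep = "/"),
          score = score, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(locator = character(), score = numeric(), stringsAsFactors = FALSE)
  }
  hits <- hits[order(-hits$score, hits$locator, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

oracle_study_hits <- function(studies, query) {
  rows <- list()
  for (st in studies) {
    n <- 0L; ok <- TRUE
    within <- function(val, lo, hi) !is.null(val) && val >= lo && val <= hi
    if (!is.null(query$participants_min)) {
      if (!within(st$number_of_participants, query$participants_min, Inf)) ok <- FALSE
      n <- n + 1L
    }
    if (ok && !is.null(query$participants_max)) {
      if (!within(st$number_of_participants, -Inf, query$participants_max)) ok <- FALSE
      n <- n + 1L
    }
    if (ok && !is.null(query$start_year_range)) {
      if (!within(st$start_year, query$start_year_range[1],
                  query$start_year_range[2])) ok <- FALSE
      n <- n + 1L
    }
    if (ok && !is.null(query$countries)) {
      hit <- FALSE
      for (p in st$populations) {
        if (length(intersect(p$selection_criteria$countries, query$countries))) hit <- TRUE
      }
      if (!hit) ok <- FALSE
      n <- n + 1L
    }
    if (ok && !is.null(query$data_sources)) {
      hit <- FALSE
      for (p in st$populations) {
        for (d in p$data_collection_events) {
          if (length(intersect(d$data_sources, query$data_sources))) hit <- TRUE
        }
      }
      if (!hit) ok <- FALSE
      n <- n + 1L
    }
    if (ok && !is.null(query$age_range)) {
      hit <- FALSE
      for (p in st$populations) {
        sc <- p$selection_criteria
        if (!is.null(sc$age_min) || !is.null(sc$age_max)) {
          lo <- if (is.null(sc$age_min)) -Inf else sc$age_min
          hi <- if (is.null(sc$age_max)) Inf else sc$age_max
          if (lo <= query$age_range[2] && hi >= query$age_range[1]) hit <- TRUE
        }
      }
      if (!hit) ok <- FALSE
      n <- n + 1L
    }
    if (ok) {
      rows[[length(rows) + 1L]] <- data.frame(locator = st$id,
                                              score = as.numeric(n),
                                              stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(locator = character(), score = numeric(), stringsAsFactors = FALSE)
  }
  hits <- hits[order(-hits$score, hits$locator, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# random query generators used by the scan-equivalence properties;
# draw partly from the catalogue's real vocabulary so queries actually hit
random_variable_query <- function(cat, tax) {
  vocab <- names(cat$text_index)
  refs <- list()
  for (d in tax$domains) {
    for (t in d$terms) refs[[length(refs) + 1L]] <- term_ref(d$name, t$name)
  }
  text <- NULL
  if (length(vocab) && stats::runif(1) < 0.6) {
    toks <- sample(vocab, sample(1:2, 1), replace = TRUE)
    toks <- vapply(toks, function(tk) {
      if (stats::runif(1) < 0.3) paste0(substr(tk, 1, max(1, nchar(tk) - 2)), "*")
      else tk
    }, "")
    if (stats::runif(1) < 0.2) toks <- c(toks, "zzznotoken")
    text <- toks
  }
  terms <- NULL
  if (stats::runif(1) < 0.6) terms <- sample(refs, sample(1:3, 1))
  scope <- NULL
  if (stats::runif(1) < 0.4 && nrow(cat$variables)) {
    i <- sample(nrow(cat$variables), 1)
    scope <- list(study_id = cat$variables$study_id[i])
    if (stats::runif(1) < 0.5) {
      scope$population_id <- cat$variables$population_id[i]
    }
    if (stats::runif(1) < 0.5) scope$dce_id <- cat$variables$dce_id[i]
  }
  variable_query(text = text, terms = terms, scope = scope)
}

random_study_query <- function() {
  q <- list()
  if (stats::runif(1) < 0.5) q$participants_min <- sample(100:40000, 1)
  if (stats::runif(1) < 0.3) {
    base <- if (is.null(q$participants_min)) 0 else q$participants_min
    q$participants_max <- base + sample(1000:40000, 1)
  }
  if (stats::runif(1) < 0.4) {
    y <- sample(1975:2010, 1)
    q$start_year_range <- c(y, y + sample(0:20, 1))
  }
  if (stats::runif(1) < 0.4) q$countries <- sample(c("CA", "FR", "GB", "NL", "SE", "US", "DE"), sample(1:2, 1))
  if (stats::runif(1) < 0.4) {
    q$data_sources <- sample(c("questionnaires", "physical_measures",
                               "cognitive_measures", "biological_samples",
                               "administrative_databases", "other"),
                             sample(1:2, 1))
  }
  if (stats::runif(1) < 0.3) {
    a <- sample(0:70, 1)
    q$age_range <- c(a, a + sample(0:30, 1))
  }
  do.call(study_query, q)
}
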