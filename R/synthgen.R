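#' @title Seeded synthetic catalogues and fixtures
#' @description
#' Deterministic generators used throughout the test suite and available
#' to users: random (but always valid) multi-study catalogues for
#' property-based testing, labelled variable sets with controllable
#' vocabulary overlap for the classifier, and a packaged transcription of
#' a published two-cohort comparison grid expanded into a full annotated
#' catalogue. A single integer seed drives each generator through an
#' explicit save-and-restore of the RNG state, so outputs are reproducible
#' across sessions and never perturb (or depend on) the caller's RNG.
#' @name synthgen
NULL

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# small topic-flavoured word pool for generated labels
WORD_POOL <- c(
  "age", "alcohol", "allergy", "asthma", "birth", "blood", "body", "cancer",
  "checkup", "child", "cholesterol", "cigarette", "clinic", "cognitive",
  "consumption", "country", "daily", "depression", "diabetes", "diet",
  "drinking", "education", "employment", "exercise", "family", "frequency",
  "glucose", "health", "heart", "height", "history", "hospital", "household",
  "income", "infection", "insurance", "intake", "language", "marital",
  "medication", "memory", "mobility", "mother", "occupation", "pain",
  "physical", "pregnancy", "pressure", "quality", "residence", "salary",
  "sample", "school", "score", "sleep", "smoking", "status", "stress",
  "support", "symptom", "test", "tobacco", "vaccination", "visit", "weekly",
  "weight", "wellbeing", "work")

COUNTRY_POOL <- c("CA", "FR", "GB", "NL", "SE", "US")

rand_range <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)

#' Specification for a random synthetic catalogue
#'
#' @param n_studies number of studies.
#' @param populations_per_study,dces_per_population,variables_per_dce
#'   inclusive `c(min, max)` ranges.
#' @param annotation_rate probability that a variable carries at least one
#'   taxonomy annotation.
#' @param tax the [taxonomy()] annotations are drawn from.
#' @param seed integer seed.
#' @return a `cc_catalogue_spec`.
#' @export
catalogue_spec <- function(n_studies = 3, populations_per_study = c(1, 3),
                           dces_per_population = c(1, 4),
                           variables_per_dce = c(5, 25),
                           annotation_rate = 0.8, tax = builtin_taxonomy(),
                           seed = 1) {
  chk <- function(r, what) {
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || anyNA(r) || r[1] > r[2] || r[1] < 0) {
      stop("invalid range for ", what, call. = FALSE)
    }
    as.integer(r)
  }
  stopifnot(is_count(n_studies), n_studies >= 1,
            is.numeric(annotation_rate), annotation_rate >= 0,
            annotation_rate <= 1, inherits(tax, "cc_taxonomy"))
  structure(list(n_studies = as.integer(n_studies),
                 populations_per_study = chk(populations_per_study,
                                             "populations_per_study"),
                 dces_per_population = chk(dces_per_population,
                                           "dces_per_population"),
                 variables_per_dce = chk(variables_per_dce, "variables_per_dce"),
                 annotation_rate = annotation_rate, tax = tax,
                 seed = as.integer(seed)),
            class = "cc_catalogue_spec")
}

all_term_refs <- function(tax) {
  out <- list()
  for (d in tax$domains) {
    for (t in d$terms) out[[length(out) + 1L]] <- term_ref(d$name, t$name)
  }
  out
}

#' Generate a random, always-valid synthetic catalogue
#'
#' The output is guaranteed to pass [validate_study()], [resolve_links()]
#' and [validate_annotations()] with zero errors; the same spec (seed
#' included) always yields a byte-identical serialized catalogue. One
#' dataset is generated per data collection event.
#'
#' @param spec a [catalogue_spec()].
#' @return `list(studies, datasets)`.
#' @export
generate_catalogue <- function(spec = catalogue_spec()) {
  stopifnot(inherits(spec, "cc_catalogue_spec"))
  refs <- all_term_refs(spec$tax)
  with_seed(spec$seed, {
    studies <- list(); datasets <- list()
    for (i in seq_len(spec$n_studies)) {
      sid <- sprintf("study%02d", i)
      start_year <- sample(1980:2015, 1)
      n_part <- sample(500:50000, 1)
      pops <- list()
      for (j in seq_len(rand_range(spec$populations_per_study))) {
        age_min <- sample(0:60, 1)
        dces <- list()
        for (k in seq_len(rand_range(spec$dces_per_population))) {
          y <- start_year + k - 1
          dces[[k]] <- dce(id = sprintf("wave%d", k),
                           name = sprintf("Wave %d", k),
                           description = sprintf("Follow-up %d", k),
                           start_date = sprintf("%d-%02d", y, sample(1:6, 1)),
                           end_date = sprintf("%d-%02d", y, sample(7:12, 1)),
                           data_sources = sample(DATA_SOURCES,
                                                 sample(1:3, 1)))
        }
        pops[[j]] <- population(
          id = sprintf("pop%d", j), name = sprintf("Subpopulation %d", j),
          description = paste("Participants recruited for",
                              sample(WORD_POOL, 1), "follow-up"),
          recruitment_sources = sample(RECRUITMENT_SOURCES, sample(1:2, 1)),
          selection_criteria = list(
            age_min = age_min, age_max = age_min + sample(5:40, 1),
            sex = sample(SEX_VALUES, 1),
            countries = sort(sample(COUNTRY_POOL, sample(1:3, 1)))),
          number_of_participants = sample(100:20000, 1),
          data_collection_events = dces)
      }
      studies[[i]] <- study(
        id = sid, name = paste("Synthetic cohort", i),
        acronym = toupper(sid),
        objectives = paste("Follow", sample(WORD_POOL, 1), "and",
                           sample(WORD_POOL, 1), "over time"),
        start_year = start_year, end_year = start_year + sample(5:30, 1),
        number_of_participants = n_part,
        number_with_samples = sample(0:n_part, 1),
        access = list(data = "on application", samples = "restricted"),
        investigators = list(list(name = sprintf("Investigator %d", i),
                                  role = "principal")),
        populations = pops)
      for (pop in pops) {
        for (ev in pop$data_collection_events) {
          did <- paste(sid, pop$id, ev$id, sep = "_")
          nv <- rand_range(spec$variables_per_dce)
          vars <- lapply(seq_len(nv), function(m) {
            lab <- paste(sample(WORD_POOL, sample(2:4, 1)), collapse = " ")
            categorical <- stats::runif(1) < 0.3
            cats <- list()
            vt <- sample(c("text", "integer", "decimal", "date", "boolean"), 1)
            if (categorical) {
              nlev <- sample(2:5, 1)
              cats <- lapply(seq_len(nlev) - 1L, function(code) {
                category(as.character(code), paste("Level", code))
              })
              if (stats::runif(1) < 0.5) {
                cats <- c(cats, list(category("9", "Missing", TRUE)))
              }
              vt <- "integer"
            }
            ann <- list()
            if (stats::runif(1) < spec$annotation_rate) {
              ann <- sample(refs, sample(1:2, 1))
            }
            variable(name = sprintf("v%03d", m), label = lab, value_type = vt,
                     unit = if (stats::runif(1) < 0.3) sample(c("years", "kg", "cm", "mmHg"), 1),
                     question_text = if (stats::runif(1) < 0.4)
                       paste("How often do you", sample(WORD_POOL, 1), "?"),
                     categories = cats, annotations = ann)
          })
          datasets[[length(datasets) + 1L]] <-
            dataset(id = did, name = sprintf("%s dictionary", ev$name),
                    description = sprintf("Synthetic dictionary for %s", did),
                    study_id = sid, population_id = pop$id, dce_id = ev$id,
                    variables = vars)
        }
      }
    }
    list(studies = studies, datasets = datasets)
  })
}

#' Specification for a labelled synthetic variable set
#'
#' @param n_classes number of classes (>= 2).
#' @param n_examples number of labelled variables.
#' @param tokens_per_label inclusive `c(min, max)` label length.
#' @param vocab_size_per_class tokens in each class vocabulary.
#' @param overlap_fraction fraction of each class vocabulary drawn from a
#'   pool shared by all classes: 0 = pairwise-disjoint vocabularies,
#'   1 = every class shares one vocabulary (labels then carry no class
#'   signal and a classifier can do no better than the priors).
#' @param seed integer seed.
#' @return a `cc_labelled_set_spec`.
#' @export
labelled_set_spec <- function(n_classes = 5, n_examples = 500,
                              tokens_per_label = c(3, 8),
                              vocab_size_per_class = 30,
                              overlap_fraction = 0.1, seed = 1) {
  stopifnot(is_count(n_classes), n_classes >= 2, is_count(n_examples),
            n_examples >= 1, is_count(vocab_size_per_class),
            vocab_size_per_class >= 1,
            is.numeric(overlap_fraction), overlap_fraction >= 0,
            overlap_fraction <= 1)
  if (length(tokens_per_label) == 1) tokens_per_label <- rep(tokens_per_label, 2)
  stopifnot(tokens_per_label[1] >= 1, tokens_per_label[1] <= tokens_per_label[2])
  structure(list(n_classes = as.integer(n_classes),
                 n_examples = as.integer(n_examples),
                 tokens_per_label = as.integer(tokens_per_label),
                 vocab_size_per_class = as.integer(vocab_size_per_class),
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "cc_labelled_set_spec")
}

#' Generate labelled variables with controlled vocabulary overlap
#'
#' Builds one vocabulary per class: `round(overlap_fraction * size)`
#' tokens come from a pool common to every class, the rest are unique to
#' the class. Labels are sampled (with replacement) from the class
#' vocabulary; classes are assigned uniformly. Classes are synthetic term
#' references under the domain `"Synthetic classes"`.
#'
#' @param spec a [labelled_set_spec()].
#' @return list of `list(variable, term)` pairs.
#' @export
generate_labelled_variables <- function(spec = labelled_set_spec()) {
  stopifnot(inherits(spec, "cc_labelled_set_spec"))
  v <- spec$vocab_size_per_class
  n_shared <- as.integer(round(spec$overlap_fraction * v))
  shared <- sprintf("shared%03d", seq_len(max(n_shared, 1)))[seq_len(n_shared)]
  vocabs <- lapply(seq_len(spec$n_classes), function(i) {
    c(shared, sprintf("c%02dtok%03d", i, seq_len(v - n_shared)))
  })
  classes <- lapply(seq_len(spec$n_classes), function(i)
    term_ref("Synthetic classes", sprintf("class%02d", i)))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_examples), function(i) {
      cl <- sample(spec$n_classes, 1)
      nt <- rand_range(spec$tokens_per_label)
      lab <- paste(sample(vocabs[[cl]], nt, replace = TRUE), collapse = " ")
      list(variable = variable(name = sprintf("x%04d", i), label = lab),
           term = classes[[cl]])
    })
  })
}

TABLE3_COLUMNS <- list(
  education = c("Socio-demographic and economic characteristics", "Education"),
  income_possessions_benefits = c("Socio-demographic and economic characteristics",
                                  "Income, possessions, and benefits"),
  tobacco = c("Lifestyle and behaviours", "Tobacco"),
  alcohol = c("Lifestyle and behaviours", "Alcohol"),
  pregnancy_childbirth_puerperium = c("Diseases",
    "Pregnancy, childbirth and the puerperium (O00-O9A)"))

#' The packaged two-cohort comparison fixture
#'
#' Expands the packaged transcription of a published comparison grid —
#' two birth cohorts (AOB/F with subpopulations Mothers and Children;
#' APrON with Mothers, Partners and Children), their 15 data collection
#' events, and per-event variable counts for five subdomains (Education;
#' Income, possessions, and benefits; Tobacco; Alcohol; Pregnancy,
#' childbirth and the puerperium (O00-O9A)) — into a full catalogue: for
#' each cell value k, exactly k deterministically named variables
#' (`v<row>_c<col>_<k>`) annotated with the column's subdomain, in a
#' dataset linked to the row's data collection event. Study and
#' population structure is transcribed; variable names and labels are
#' synthetic by construction. The function is pure: repeated calls are
#' identical.
#'
#' @return `list(studies, datasets, selection)` where `selection` holds
#'   the five column [term_ref()]s and both study ids, ready to feed to
#'   [harmonization_table()].
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3-counts.csv", package = "cohortcat",
                      mustWork = TRUE)
  grid <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  col_slugs <- names(TABLE3_COLUMNS)
  refs <- lapply(TABLE3_COLUMNS, function(p) term_ref(p[1], p[2]))

  studies <- list(); datasets <- list()
  for (sid in unique(grid$study_id)) {
    srows <- grid[grid$study_id == sid, , drop = FALSE]
    pops <- list()
    for (pid in unique(srows$population_id)) {
      prows <- srows[srows$population_id == pid, , drop = FALSE]
      dces <- lapply(seq_len(nrow(prows)), function(i) {
        dce(id = prows$dce_id[i], name = prows$dce_name[i],
            description = sprintf("%s data collection", prows$dce_name[i]),
            data_sources = "questionnaires")
      })
      pops[[length(pops) + 1L]] <- population(
        id = pid, name = prows$population_name[1],
        description = sprintf("%s of the %s cohort", prows$population_name[1],
                              sid),
        recruitment_sources = "general_population",
        data_collection_events = dces)
    }
    studies[[length(studies) + 1L]] <- study(
      id = sid, name = srows$study_name[1], acronym = sid,
      objectives = "Transcribed comparison-grid fixture (variable names and labels are synthetic)",
      access = list(data = "see source study", samples = "see source study"),
      populations = pops)
  }

  tax <- builtin_taxonomy()
  for (r in seq_len(nrow(grid))) {
    row <- grid[r, ]
    vars <- list()
    for (j in seq_along(col_slugs)) {
      k <- as.integer(row[[col_slugs[j]]])
      if (k > 0) {
        for (m in seq_len(k)) {
          v <- variable(name = sprintf("v%d_c%d_%d", r, j, m),
                        label = sprintf("%s item %d (%s)",
                                        refs[[j]]$term_name, m, row$dce_name))
          vars[[length(vars) + 1L]] <- annotate_variable(v, refs[[j]], tax)
        }
      }
    }
    datasets[[length(datasets) + 1L]] <- dataset(
      id = sprintf("%s_%s_%s", row$study_id, row$population_id, row$dce_id),
      name = sprintf("%s %s %s dictionary", row$study_id, row$population_name,
                     row$dce_name),
      description = "Expanded from the packaged comparison-grid transcription",
      study_id = row$study_id, population_id = row$population_id,
      dce_id = row$dce_id, variables = vars)
  }
  list(studies = studies, datasets = datasets,
       selection = list(columns = unname(refs),
                        study_ids = unique(grid$study_id)))
}
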