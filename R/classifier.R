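#' @title Taxonomy-term suggestion by multinomial naive Bayes
#' @description
#' A deterministic, hand-checkable stand-in for the kind of in-house
#' machine-learning aid used to validate manual variable classification:
#' a multinomial naive Bayes model with additive (Laplace) smoothing over
#' the bag of tokens of each variable's name, label and question text
#' (tokenizer shared with the search module). Classes are taxonomy term
#' references. Nothing about production classifiers used by real
#' catalogues is claimed; this model is chosen because every posterior can
#' be verified by hand.
#'
#' For class c with prior p(c) (its training frequency) and token t, the
#' smoothed likelihood is `(n_ct + alpha) / (n_c + alpha * |V|)`, with
#' `n_ct` the count of t in class c's training text, `n_c` the class's
#' total token count and `|V|` the training vocabulary size.
#' Out-of-vocabulary tokens use the same formula with `n_ct = 0`, so no
#' input ever has zero probability. Posteriors are computed in log space
#' and normalized to sum to one.
#' @name classifier
NULL

#' Train a term classifier from labelled variables
#'
#' @param examples list of `list(variable, term)` pairs (a [variable()] and
#'   the gold [term_ref()] assigned by a human classifier).
#' @param alpha additive smoothing constant, > 0 (default 1: Laplace).
#' @return a `cc_classifier` with `alpha`, `classes` (term refs), `priors`,
#'   `token_counts` (class x token matrix), `class_totals` and
#'   `vocabulary`. Training is order-invariant. Fewer than two distinct
#'   classes, or no examples, is an error.
#' @export
train_classifier <- function(examples, alpha = 1) {
  if (!length(examples)) stop("no training examples", call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  keys <- vapply(examples, function(e) term_ref_key(e[[2]]), "")
  if (length(unique(keys)) < 2) {
    stop("training needs at least 2 distinct classes", call. = FALSE)
  }
  classes <- sort(unique(keys), method = "radix")
  tok_lists <- lapply(examples, function(e) {
    v <- e[[1]]
    cc_tokenize(c(v$name, v$label, v$question_text))
  })
  vocab <- sort(unique(unlist(tok_lists)), method = "radix")
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  for (i in seq_along(examples)) {
    toks <- tok_lists[[i]]
    if (length(toks)) {
      tab <- table(toks)
      counts[keys[i], names(tab)] <- counts[keys[i], names(tab)] + as.numeric(tab)
    }
  }
  priors <- as.numeric(table(factor(keys, levels = classes))) / length(keys)
  structure(list(alpha = alpha,
                 classes = lapply(strsplit(classes, "\x1f", fixed = TRUE),
                                  function(p) term_ref(p[1], p[2])),
                 class_keys = classes,
                 priors = stats::setNames(priors, classes),
                 token_counts = counts,
                 class_totals = rowSums(counts),
                 vocabulary = vocab),
            class = "cc_classifier")
}

#' @export
print.cc_classifier <- function(x, ...) {
  cat(sprintf("<naive Bayes term classifier: %d classes, |V| = %d, alpha = %g>\n",
              length(x$classes), length(x$vocabulary), x$alpha))
  invisible(x)
}

# log-posterior over all classes for one bag of tokens
posterior_log <- function(model, tokens) {
  lp <- log(model$priors)
  denom <- log(model$class_totals + model$alpha * length(model$vocabulary))
  if (length(tokens)) {
    tab <- table(tokens)
    known <- names(tab)[names(tab) %in% model$vocabulary]
    oov_n <- sum(tab[!(names(tab) %in% model$vocabulary)])
    for (t in known) {
      lp <- lp + as.numeric(tab[[t]]) *
        (log(model$token_counts[, t] + model$alpha) - denom)
    }
    if (oov_n > 0) lp <- lp + oov_n * (log(model$alpha) - denom)
  }
  lp
}

#' Suggest taxonomy terms for a variable
#'
#' Computes the posterior over every class for the variable's token bag
#' and returns the top k, ties broken lexicographically on the class key.
#' A variable with no tokens at all is ranked by the priors alone.
#'
#' @param model a [train_classifier()] model.
#' @param var a [variable()].
#' @param k number of suggestions, >= 1 (capped at the class count).
#' @return data frame with `domain`, `term` and `posterior` (the full
#'   posterior, over all classes, sums to 1).
#' @export
suggest_terms <- function(model, var, k = 3) {
  stopifnot(inherits(model, "cc_classifier"), inherits(var, "cc_variable"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be >= 1", call. = FALSE)
  }
  toks <- cc_tokenize(c(var$name, var$label, var$question_text))
  lp <- posterior_log(model, toks)
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  ord <- order(-post, names(post), method = "radix")
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(domain = vapply(model$classes[take], `[[`, "", "domain_name"),
             term = vapply(model$classes[take], `[[`, "", "term_name"),
             posterior = as.numeric(post[take]),
             stringsAsFactors = FALSE)
}

#' Evaluate a classifier on held-out labelled variables
#'
#' @param model a [train_classifier()] model.
#' @param held_out non-empty list of `list(variable, term)` pairs.
#' @return list with `accuracy` (fraction whose top-1 suggestion equals
#'   the gold term) and `per_class`, a data frame of precision and recall
#'   per gold-or-predicted class, with 0/0 defined as 0.
#' @export
evaluate_classifier <- function(model, held_out) {
  stopifnot(inherits(model, "cc_classifier"), length(held_out) > 0)
  gold <- vapply(held_out, function(e) term_ref_key(e[[2]]), "")
  pred <- vapply(held_out, function(e) {
    s <- suggest_terms(model, e[[1]], k = 1)
    term_ref_key(term_ref(s$domain[1], s$term[1]))
  }, "")
  classes <- sort(unique(c(gold, pred)), method = "radix")
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tp <- vapply(classes, function(cl) sum(gold == cl & pred == cl), 0)
  per_class <- data.frame(
    class = gsub("\x1f", "/", classes, fixed = TRUE),
    precision = safe_div(tp, vapply(classes, function(cl) sum(pred == cl), 0)),
    recall = safe_div(tp, vapply(classes, function(cl) sum(gold == cl), 0)),
    stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  list(accuracy = mean(gold == pred), per_class = per_class)
}

#' Serialize / restore a classifier as JSON
#'
#' The JSON carries alpha, classes, priors, vocabulary and the count
#' matrix, so a restored model reproduces posteriors exactly.
#'
#' @param model a `cc_classifier`.
#' @param path JSON file path.
#' @return `read_classifier()` returns a `cc_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "cc_classifier"))
  obj <- list(alpha = model$alpha,
              classes = lapply(model$classes, function(r)
                list(domain = r$domain_name, term = r$term_name)),
              priors = as.numeric(model$priors),
              vocabulary = model$vocabulary,
              token_counts = unname(apply(model$token_counts, 1, as.numeric,
                                          simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- if (is.data.frame(obj$classes)) {
    lapply(seq_len(nrow(obj$classes)),
           function(i) term_ref(obj$classes$domain[i], obj$classes$term[i]))
  } else {
    lapply(obj$classes, function(x) term_ref(x$domain, x$term))
  }
  keys <- vapply(classes, term_ref_key, "")
  vocab <- as.character(obj$vocabulary)
  counts <- obj$token_counts
  if (is.list(counts)) counts <- do.call(rbind, lapply(counts, as.numeric))
  counts <- matrix(as.numeric(counts), nrow = length(keys))
  dimnames(counts) <- list(keys, vocab)
  structure(list(alpha = obj$alpha, classes = classes, class_keys = keys,
                 priors = stats::setNames(as.numeric(obj$priors), keys),
                 token_counts = counts, class_totals = rowSums(counts),
                 vocabulary = vocab),
            class = "cc_classifier")
}
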