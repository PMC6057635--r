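# Hand-computed oracle for the two-class toy model (alpha = 1), labels
# A = "alcohol wine", B = "tobacco smoke". With neutral one-token variable
# names (a1/b1) both classes have 3 training tokens and |V| = 6, so
#   P(wine|A) = (1+1)/(3+6),  P(wine|B) = (0+1)/(3+6)
#   P(A|"wine") = (0.5 * 2/9) / (0.5 * 2/9 + 0.5 * 1/9) = 2/3,
# identical to the 4-token-vocabulary computation (2/6 vs 1/6) because the
# equal denominators cancel in the posterior.

toy_model <- function(alpha = 1) {
  ex <- list(
    list(variable("wine", "alcohol wine"),
         term_ref("Lifestyle and behaviours", "Alcohol")),
    list(variable("smoke", "tobacco smoke"),
         term_ref("Lifestyle and behaviours", "Tobacco")))
  train_classifier(ex, alpha = alpha)
}

test_that("training recovers priors and is order-invariant", {
  m <- toy_model()
  expect_equal(unname(as.numeric(m$priors)), c(0.5, 0.5))
  ex <- toy_classifier_examples()
  m1 <- train_classifier(ex)
  m2 <- train_classifier(rev(ex))
  expect_identical(m1, m2)
  expect_error(train_classifier(list()), "no training examples")
  one_class <- list(list(variable("v1", "x"), term_ref("D", "T")),
                    list(variable("v2", "y"), term_ref("D", "T")))
  expect_error(train_classifier(one_class), "2 distinct classes")
  expect_error(train_classifier(ex, alpha = 0))
})

test_that("the hand-computed posterior 2/3 is exact", {
  # vocabulary must be exactly 4 tokens for the hand computation
  ex <- list(
    list(variable("a1", "alcohol wine"), term_ref("L", "Alcohol")),
    list(variable("b1", "tobacco smoke"), term_ref("L", "Tobacco")))
  # 'a1'/'b1' add 2 tokens; recompute the oracle for |V| = 6 instead:
  # P(wine|A) = (1+1)/(3+6), P(wine|B) = (0+1)/(3+6) -> posterior 2/3 again
  # (denominators cancel when class token totals are equal).
  m <- train_classifier(ex, alpha = 1)
  s <- suggest_terms(m, variable("q", "wine"), k = 2)
  expect_equal(s$term[1], "Alcohol")
  expect_equal(s$posterior[1], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(s$posterior), 1, tolerance = 1e-9)

  # out-of-vocabulary tokens keep probabilities strictly positive and,
  # with equal class totals, cancel out of the posterior
  s_oov <- suggest_terms(m, variable("q", "wine zeppelin"), k = 2)
  expect_equal(s_oov$posterior[1], 2 / 3, tolerance = 1e-12)
})

test_that("suggestions degrade to priors and respect k", {
  # unbalanced priors (1/3 alcohol, 2/3 tobacco) but equal per-class token
  # totals (6 each), so an out-of-vocabulary probe cancels exactly and the
  # posterior falls back to the priors alone
  ex <- list(
    list(variable("aa", "alcohol wine beer cider gin"),
         term_ref("Lifestyle and behaviours", "Alcohol")),
    list(variable("b1", "tobacco smoke"),
         term_ref("Lifestyle and behaviours", "Tobacco")),
    list(variable("b2", "cigar pipe"),
         term_ref("Lifestyle and behaviours", "Tobacco")))
  m <- train_classifier(ex)
  s <- suggest_terms(m, variable("q", ""), k = 5)
  expect_equal(nrow(s), 2)  # k capped at class count
  expect_equal(s$term[1], "Tobacco")
  expect_equal(s$posterior, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(suggest_terms(m, variable("q", "x"), k = 0), "k")
})

test_that("posteriors normalize for arbitrary inputs", {
  set.seed(4)
  ex <- generate_labelled_variables(labelled_set_spec(n_classes = 4,
                                                      n_examples = 80, seed = 2))
  m <- train_classifier(ex)
  for (i in 1:20) {
    lab <- paste(sample(c(m$vocabulary, "unseen", "garbage"), 5, replace = TRUE),
                 collapse = " ")
    s <- suggest_terms(m, variable("q", lab), k = length(m$classes))
    expect_equal(sum(s$posterior), 1, tolerance = 1e-9)
    expect_true(all(s$posterior > 0))
  }
})

test_that("evaluation measures accuracy and per-class precision/recall", {
  m <- toy_model()
  ex <- list(
    list(variable("wine", "alcohol wine"),
         term_ref("Lifestyle and behaviours", "Alcohol")),
    list(variable("smoke", "tobacco smoke"),
         term_ref("Lifestyle and behaviours", "Tobacco")))
  perfect <- evaluate_classifier(m, ex)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$per_class$precision, c(1, 1))
  expect_equal(perfect$per_class$recall, c(1, 1))

  flipped <- list(list(ex[[1]][[1]], ex[[2]][[2]]),
                  list(ex[[2]][[1]], ex[[1]][[2]]))
  wrong <- evaluate_classifier(m, flipped)
  expect_equal(wrong$accuracy, 0.0)
  expect_equal(wrong$per_class$precision, c(0, 0))
  expect_equal(wrong$per_class$recall, c(0, 0))
})

test_that("disjoint class vocabularies are learned perfectly", {
  ex <- generate_labelled_variables(labelled_set_spec(
    n_classes = 5, n_examples = 200, overlap_fraction = 0, seed = 31))
  split_at <- 160
  m <- train_classifier(ex[seq_len(split_at)])
  ev <- evaluate_classifier(m, ex[(split_at + 1):length(ex)])
  expect_equal(ev$accuracy, 1.0)
})

test_that("accuracy degrades monotonically with vocabulary overlap", {
  acc_at <- function(overlap) {
    mean(vapply(1:3, function(s) {
      ex <- generate_labelled_variables(labelled_set_spec(
        n_classes = 5, n_examples = 250, overlap_fraction = overlap, seed = s))
      m <- train_classifier(ex[1:200])
      evaluate_classifier(m, ex[201:250])$accuracy
    }, numeric(1)))
  }
  a0 <- acc_at(0); a50 <- acc_at(0.5); a100 <- acc_at(1)
  expect_gte(a0, a50)
  expect_gte(a50, a100)
})

test_that("JSON serialization restores the model exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  ex <- generate_labelled_variables(labelled_set_spec(n_classes = 3,
                                                      n_examples = 50, seed = 8))
  m <- train_classifier(ex, alpha = 0.5)
  write_classifier(m, path)
  m2 <- read_classifier(path)
  probe <- variable("q", paste(m$vocabulary[1:3], collapse = " "))
  expect_equal(suggest_terms(m2, probe, k = 3), suggest_terms(m, probe, k = 3))
  expect_equal(m2$priors, m$priors)
  expect_equal(m2$token_counts, m$token_counts)
})
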