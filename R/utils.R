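# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize free text for indexing, querying and classification
#'
#' The single analyzer used everywhere text is matched: search indexing,
#' query parsing and the bag-of-tokens classifier. Input is case-folded and
#' split on runs of non-alphanumeric characters; empty tokens are dropped.
#' No stemming and no stop-word removal, so matching is fully reproducible.
#'
#' @param x character vector; elements are concatenated, `NA` dropped.
#' @return character vector of lower-case tokens (possibly empty).
#' @examples
#' cc_tokenize("Current smoker (cigarettes/day)")
#' @export
cc_tokenize <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(character())
  x <- tolower(paste(x, collapse = " "))
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# slug used for placeholder subdomain names and file-system friendly ids
cc_slug <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

is_token <- function(x) is_scalar_chr(x) && grepl("^[A-Za-z0-9_-]+$", x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == trunc(x)
}

# Partial ISO dates: YYYY, YYYY-MM or YYYY-MM-DD. Ordering is by earliest
# concrete interpretation (YYYY -> Jan 1, YYYY-MM -> day 1): deterministic
# and conservative for end >= start checks.
is_partial_date <- function(x) {
  is_scalar_chr(x) && grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", x)
}

partial_date_earliest <- function(x) {
  if (!is_partial_date(x)) return(as.Date(NA))
  n <- nchar(x)
  full <- if (n == 4) paste0(x, "-01-01") else if (n == 7) paste0(x, "-01") else x
  out <- tryCatch(as.Date(full), error = function(e) as.Date(NA))
  out
}

# stable run-time seed derivation: keeps derived seeds < 2^31
derive_seed <- function(seed, i) (as.integer(seed) %% 1000003L) * 2017L + i * 7919L
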