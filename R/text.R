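#' @importFrom stringi stri_trans_nfkc stri_trans_tolower stri_split_regex
NULL

#' Normalize a surface string
#'
#' Applies Unicode NFKC normalization followed by case folding (lower case).
#' All surface-form matching in the package goes through this normalization,
#' so matching is deterministic and locale-independent.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_surface <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(as.character(x)))
}

# Trailing/leading sentence punctuation stripped from tokens. Parentheses and
# internal commas are deliberately kept so coordinate-style concept labels such
# as "(1,0)" survive tokenization intact.
.token_trim_re <- "^[.,;:!?'\"]+|[.,;:!?'\"]+$"

#' Tokenize normalized text
#'
#' Splits on whitespace and strips sentence punctuation from token boundaries.
#' Hyphens, parentheses and internal commas are preserved (e.g. "sars-cov-2",
#' "(1,0)").
#'
#' @param x a single string (already normalized via [normalize_surface()]).
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) return(character(0))
  toks <- unlist(stringi::stri_split_regex(x, "\\s+"))
  toks <- gsub(.token_trim_re, "", toks)
  toks[nzchar(toks)]
}

#' Default English stopword list
#'
#' Reads the standard English stopword list shipped with the package.
#'
#' @return character vector of lower-case stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "litgraph")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Default suffix-stripping lemmatizer
#'
#' A small rule-based normalizer covering regular English plurals and a few
#' inflections; sufficient for dictionary matching of biomedical noun phrases.
#' Any function mapping a character vector to a character vector of the same
#' length can replace it.
#'
#' @param tokens character vector.
#' @return character vector of lemmas.
#' @export
default_lemmatizer <- function(tokens) {
  out <- tokens
  n <- nchar(out)
  # -ies -> -y (bodies -> body)
  i <- n > 4L & endsWith(out, "ies")
  out[i] <- paste0(substr(out[i], 1L, n[i] - 3L), "y")
  n <- nchar(out)
  # -ses/-xes/-zes/-ches/-shes -> drop "es"
  i <- n > 4L & (endsWith(out, "ses") | endsWith(out, "xes") | endsWith(out, "zes") |
                   endsWith(out, "ches") | endsWith(out, "shes"))
  out[i] <- substr(out[i], 1L, nchar(out[i]) - 2L)
  n <- nchar(out)
  # plain plural -s (not -ss, -us, -is)
  i <- n > 3L & endsWith(out, "s") &
    !endsWith(out, "ss") & !endsWith(out, "us") & !endsWith(out, "is")
  out[i] <- substr(out[i], 1L, n[i] - 1L)
  out
}

#' Normalized Levenshtein string similarity
#'
#' Similarity between two strings defined as
#' \code{1 - levenshtein(a, b) / max(nchar(a), nchar(b))}. It is symmetric,
#' bounded in \code{[0, 1]}, and equals 1 exactly when the strings are equal.
#' This is the measure used by the entity-curation gate (default threshold 0.7).
#'
#' @param a,b character vectors (recycled to common length). Empty strings are
#'   a domain error.
#' @return numeric vector of similarities in \code{[0, 1]}.
#' @export
#' @examples
#' normalized_similarity("myocarditis", "myopericarditis")  # 1 - 4/15
normalized_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))) {
    stop("normalized_similarity() requires non-empty strings", call. = FALSE)
  }
  d <- mapply(function(x, y) utils::adist(x, y)[1L, 1L], a, b, USE.NAMES = FALSE)
  1 - d / pmax(nchar(a), nchar(b))
}

#' Default English-language heuristic
#'
#' Language filter used on titles during corpus cleaning: a string passes when
#' at least 90% of its alphabetic characters are ASCII letters. A pluggable
#' predicate (any function character -> logical) can replace it, e.g. a
#' statistical language detector.
#'
#' @param x character vector of titles.
#' @return logical vector, `TRUE` where the text looks English.
#' @export
default_language_filter <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    letters_all <- stringi::stri_count_regex(s, "\\p{L}")
    if (letters_all == 0L) return(TRUE)  # numeric/symbol-only titles pass
    ascii <- stringi::stri_count_regex(s, "[A-Za-z]")
    ascii / letters_all >= 0.9
  }, logical(1), USE.NAMES = FALSE)
}
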