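#' UMLS macrocategories admitted as node annotations
#'
#' The sixteen coarse-level UMLS macrocategories plus the `UTILITY` category
#' used for non-ontology terms (level modifiers and causative connectors).
#' `GENES_AND_MOLECOLAR_SEQUENCES` is the source vocabulary's own spelling.
#'
#' @export
MACROCATEGORIES <- c(
  "ACTIVITIES_AND_BEHAVIORS", "ANATOMY", "CHEMICALS_AND_DRUGS",
  "CONCEPTS_AND_IDEAS", "DEVICES", "DISORDERS", "ENTITY",
  "GENES_AND_MOLECOLAR_SEQUENCES", "GEOGRAPHIC_AREAS", "LIVING_BEINGS",
  "OBJECTS", "OCCUPATIONS", "ORGANIZATIONS", "PHENOMENA", "PHYSIOLOGY",
  "PROCEDURES", "UTILITY"
)

#' Default utility terms
#'
#' Level modifiers and causative connectors admitted into the network without
#' an ontology identifier. The shipped default list contains the documented
#' examples and is user-extensible via the `utility` argument of
#' [load_lexicon()] / [make_lexicon()].
#'
#' @export
DEFAULT_UTILITY_TERMS <- c("high", "increased", "induces")

.lexicon_cols <- c("surface", "name", "umls_id", "cido_id", "macrocategory", "type")

.concept_id <- function(umls_id, cido_id) {
  ifelse(!is.na(umls_id) & nzchar(umls_id), umls_id,
         ifelse(!is.na(cido_id) & nzchar(cido_id), cido_id, NA_character_))
}

.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Construct a lexicon from a term table
#'
#' Assembles the ontology vocabulary (UMLS/CIDO-style extracts) plus utility
#' terms into a `litgraph_lexicon`. Surface forms are NFKC-normalized and
#' case-folded; duplicate (surface, concept-id) rows are merged; when two rows
#' share the same concept name and one carries a UMLS id while the other
#' carries a CIDO id, both ids are kept on one merged term.
#'
#' @param terms data frame with columns `surface`, `name`, `umls_id`,
#'   `cido_id`, `macrocategory`, `type`. Missing ids may be `NA` or empty.
#' @param utility character vector of utility terms (surface forms); each is
#'   appended as a term with `is_utility = TRUE` and macrocategory `UTILITY`.
#' @return object of class `litgraph_lexicon`: a list with the merged `terms`
#'   data frame (columns above plus `concept_id`, `is_utility`) and lookup
#'   indexes by surface form and by concept id.
#' @export
make_lexicon <- function(terms, utility = DEFAULT_UTILITY_TERMS) {
  missing_cols <- setdiff(.lexicon_cols, names(terms))
  if (length(missing_cols)) {
    stop(sprintf("lexicon table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)[.lexicon_cols]
  for (cl in .lexicon_cols) terms[[cl]] <- .blank_to_na(terms[[cl]])
  if (nrow(terms) == 0L && length(utility) == 0L) {
    stop("empty lexicon: no ontology terms and no utility terms", call. = FALSE)
  }
  if (nrow(terms)) {
    if (any(is.na(terms$surface))) stop("lexicon rows with empty surface form", call. = FALSE)
    if (any(is.na(terms$name))) stop("lexicon rows with empty concept name", call. = FALSE)
    no_id <- is.na(terms$umls_id) & is.na(terms$cido_id)
    if (any(no_id)) {
      stop(sprintf("%d non-utility lexicon row(s) carry neither a UMLS nor a CIDO id",
                   sum(no_id)), call. = FALSE)
    }
    bad <- !terms$macrocategory %in% setdiff(MACROCATEGORIES, "UTILITY")
    if (any(bad)) {
      stop(sprintf("unknown macrocategory: %s",
                   paste(unique(terms$macrocategory[bad]), collapse = ", ")), call. = FALSE)
    }
    terms$surface <- normalize_surface(terms$surface)
    terms$is_utility <- FALSE

    # merge UMLS/CIDO ids defined for the same concept name
    by_name <- split(seq_len(nrow(terms)), terms$name)
    merged <- lapply(by_name, function(idx) {
      block <- terms[idx, , drop = FALSE]
      umls <- unique(block$umls_id[!is.na(block$umls_id)])
      cido <- unique(block$cido_id[!is.na(block$cido_id)])
      if (length(umls) > 1L || length(cido) > 1L) {
        stop(sprintf("concept name %s maps to multiple %s ids",
                     block$name[1L],
                     if (length(umls) > 1L) "UMLS" else "CIDO"), call. = FALSE)
      }
      block$umls_id <- if (length(umls)) umls else NA_character_
      block$cido_id <- if (length(cido)) cido else NA_character_
      # merge duplicate (surface, concept) rows
      block[!duplicated(block$surface), , drop = FALSE]
    })
    terms <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  } else {
    terms$is_utility <- logical(0)
  }

  utility <- unique(normalize_surface(utility[nzchar(utility)]))
  if (length(utility)) {
    uterms <- data.frame(
      surface = utility, name = utility,
      umls_id = NA_character_, cido_id = NA_character_,
      macrocategory = "UTILITY", type = NA_character_,
      is_utility = TRUE, stringsAsFactors = FALSE
    )
    terms <- rbind(terms, uterms)
  }
  terms$concept_id <- .concept_id(terms$umls_id, terms$cido_id)

  ids <- terms$concept_id[!terms$is_utility]
  # concept ids unique across non-utility terms after merging (a concept may
  # expose several surfaces; (id, surface) pairs must be unique)
  dup <- duplicated(terms[!terms$is_utility, c("concept_id", "surface")])
  if (any(dup)) stop("duplicate (concept id, surface) pairs after merging", call. = FALSE)

  terms <- terms[order(terms$surface, terms$concept_id, method = "radix"), , drop = FALSE]
  rownames(terms) <- NULL

  structure(
    list(
      terms = terms,
      index = split(seq_len(nrow(terms)), terms$surface),
      concept_index = split(seq_len(nrow(terms)), terms$concept_id),
      max_tokens = if (nrow(terms)) max(lengths(strsplit(terms$surface, " ", fixed = TRUE))) else 0L
    ),
    class = "litgraph_lexicon"
  )
}

#' Load a lexicon from delimited files
#'
#' Reads the ontology vocabulary from a TSV file with header columns
#' `surface, name, umls_id, cido_id, macrocategory, type`, and optionally a
#' utility-term file with one term per line (UTF-8).
#'
#' @param path path to the lexicon TSV.
#' @param utility_path optional path to the utility-term list; when `NULL` the
#'   shipped default terms are used.
#' @return a `litgraph_lexicon`; see [make_lexicon()].
#' @export
load_lexicon <- function(path, utility_path = NULL) {
  if (!file.exists(path)) stop(sprintf("lexicon file not found: %s", path), call. = FALSE)
  terms <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character", na.strings = c("NA", ""),
                             quote = "", fileEncoding = "UTF-8",
                             check.names = FALSE)
  utility <- if (is.null(utility_path)) {
    DEFAULT_UTILITY_TERMS
  } else {
    readLines(utility_path, encoding = "UTF-8", warn = FALSE)
  }
  make_lexicon(terms, utility = utility)
}

#' Write a lexicon back to its TSV serialization
#'
#' @param lexicon a `litgraph_lexicon`.
#' @param path output TSV path (ontology terms only).
#' @param utility_path optional output path for the utility-term list.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path, utility_path = NULL) {
  stopifnot(inherits(lexicon, "litgraph_lexicon"))
  tab <- lexicon$terms[!lexicon$terms$is_utility, .lexicon_cols, drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(utility_path)) {
    writeLines(lexicon$terms$surface[lexicon$terms$is_utility], utility_path,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Look up lexicon terms by surface form
#'
#' Exact match on the NFKC-casefolded surface form; the query string receives
#' the same normalization. Results are ordered by concept id (ascending,
#' utility terms last), so lookups are deterministic regardless of file row
#' order.
#'
#' @param lexicon a `litgraph_lexicon`.
#' @param surface a single surface string.
#' @return data frame of matching terms (possibly zero rows).
#' @export
lexicon_lookup <- function(lexicon, surface) {
  stopifnot(inherits(lexicon, "litgraph_lexicon"), length(surface) == 1L)
  key <- normalize_surface(surface)
  idx <- lexicon$index[[key]]
  if (is.null(idx)) return(lexicon$terms[0L, , drop = FALSE])
  hits <- lexicon$terms[idx, , drop = FALSE]
  ord <- order(hits$is_utility, hits$concept_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @export
print.litgraph_lexicon <- function(x, ...) {
  n_ont <- sum(!x$terms$is_utility)
  n_ut <- sum(x$terms$is_utility)
  cat(sprintf("<litgraph_lexicon> %d ontology term(s), %d utility term(s)\n", n_ont, n_ut))
  invisible(x)
}
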