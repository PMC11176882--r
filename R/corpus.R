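.metadata_cols <- c("cord_uid", "title", "abstract", "publish_time", "journal",
                    "authors", "doi", "num_cited_by")

#' Default pre-2020 exclusion terms
#'
#' Publications dated before `min_year` whose title or abstract contains any of
#' these terms (earlier coronavirus literature) are dropped during cleaning.
#'
#' @export
DEFAULT_EXCLUSION_TERMS <- c(
  "MERS", "Middle East Respiratory Syndrome",
  "SARS", "Severe Acute Respiratory Syndrome", "coronavirus"
)

#' Read a publication-metadata table
#'
#' Reads a CSV in the CORD-19 `metadata.csv` dialect (comma separated, quoted
#' fields, header row). Missing optional columns are added as `NA`.
#'
#' @param path CSV path.
#' @return data frame with columns `cord_uid, title, abstract, publish_time,
#'   journal, authors, doi, num_cited_by` (plus any extra input columns).
#' @export
read_corpus_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("metadata file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = c("NA", ""),
                         fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("cord_uid", "title", "abstract")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("metadata table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (cl in setdiff(.metadata_cols, names(raw))) raw[[cl]] <- NA_character_
  raw
}

.parse_publish_time <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  precision <- ifelse(!is.na(d), "day", NA_character_)
  year_only <- is.na(d) & grepl("\\b\\d{4}\\b", x)
  if (any(year_only, na.rm = TRUE)) {
    yr <- regmatches(x, regexpr("\\b\\d{4}\\b", x))
    idx <- which(year_only)
    d[idx] <- as.Date(paste0(vapply(idx, function(i)
      regmatches(x[i], regexpr("\\b\\d{4}\\b", x[i])), character(1)), "-01-01"))
    precision[idx] <- "year"
  }
  list(date = d, precision = precision)
}

.richness <- function(rows) {
  fields <- c("title", "abstract", "publish_time", "journal", "authors",
              "doi", "num_cited_by")
  rowSums(!is.na(rows[, fields, drop = FALSE]) &
            nzchar(as.matrix(rows[, fields, drop = FALSE])))
}

#' Clean and deduplicate a metadata table
#'
#' Applies the corpus-cleaning rules, in order: (a) rows without a record id
#' are dropped with a warning; (b) rows whose publish time has no parseable
#' 4-digit year are dropped with a warning, year-only dates are kept as Jan 1
#' with `date_precision = "year"`; (c) rows with an empty abstract are dropped;
#' (d) rows whose title fails the English-language filter are dropped; (e) rows
#' dated before `min_year` whose title or abstract contains an exclusion term
#' are dropped; (f) within each `cord_uid` cluster exactly one row is kept —
#' the one published in a peer-reviewed journal (journal field present) if
#' available, else the row richest in metadata (greatest count of non-missing
#' fields among title, abstract, publish_time, journal, authors, doi,
#' num_cited_by; ties broken by earliest row order).
#'
#' The operation is idempotent: applying it to its own output changes nothing.
#'
#' @param raw data frame from [read_corpus_metadata()].
#' @param min_year integer; exclusion filter applies to records dated before
#'   this year (default 2020).
#' @param exclusion_terms character vector matched case-insensitively against
#'   title and abstract of pre-`min_year` records.
#' @param language_filter predicate character -> logical applied to titles.
#' @return data frame of publication records: `record_id, title, abstract,
#'   publish_time (Date), date_precision, journal, authors, doi, num_cited_by,
#'   peer_reviewed`; `record_id` is unique.
#' @export
clean_corpus <- function(raw, min_year = 2020,
                         exclusion_terms = DEFAULT_EXCLUSION_TERMS,
                         language_filter = default_language_filter) {
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!"record_id" %in% names(df) && "cord_uid" %in% names(df)) {
    df$record_id <- df$cord_uid
  }
  for (cl in c("journal", "authors", "doi", "num_cited_by", "publish_time")) {
    if (!cl %in% names(df)) df[[cl]] <- NA_character_
  }
  df$record_id <- .blank_to_na(df$record_id)
  drop_id <- is.na(df$record_id)
  if (any(drop_id)) {
    warning(sprintf("dropping %d row(s) without a record id", sum(drop_id)), call. = FALSE)
    df <- df[!drop_id, , drop = FALSE]
  }

  pt <- if (inherits(df$publish_time, "Date")) {
    list(date = df$publish_time,
         precision = if ("date_precision" %in% names(df)) df$date_precision else
           rep("day", nrow(df)))
  } else {
    .parse_publish_time(as.character(df$publish_time))
  }
  bad_date <- is.na(pt$date)
  if (any(bad_date)) {
    warning(sprintf("dropping %d row(s) with unparseable publish time", sum(bad_date)),
            call. = FALSE)
  }
  df <- df[!bad_date, , drop = FALSE]
  df$publish_time <- pt$date[!bad_date]
  df$date_precision <- pt$precision[!bad_date]

  df$abstract <- .blank_to_na(df$abstract)
  df$title <- .blank_to_na(df$title)
  df <- df[!is.na(df$abstract), , drop = FALSE]

  df <- df[language_filter(ifelse(is.na(df$title), "", df$title)), , drop = FALSE]

  if (length(exclusion_terms) && nrow(df)) {
    yr <- as.integer(format(df$publish_time, "%Y"))
    pattern <- paste(sprintf("\\b%s\\b",
                             gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", exclusion_terms)),
                     collapse = "|")
    text <- paste(ifelse(is.na(df$title), "", df$title),
                  ifelse(is.na(df$abstract), "", df$abstract))
    hit <- grepl(pattern, text, ignore.case = TRUE, perl = TRUE)
    df <- df[!(yr < min_year & hit), , drop = FALSE]
  }

  # deduplicate per cluster
  if (nrow(df)) {
    df$.row <- seq_len(nrow(df))
    df$peer_reviewed <- !is.na(.blank_to_na(df$journal))
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$record_id), function(idx) {
      block <- df[idx, , drop = FALSE]
      pool <- if (any(block$peer_reviewed)) which(block$peer_reviewed) else seq_len(nrow(block))
      rich <- .richness(block[pool, , drop = FALSE])
      idx[pool[which.max(rich)]]  # which.max: first maximum = earliest row order
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
    df$.row <- NULL
  } else {
    df$peer_reviewed <- logical(0)
  }

  cols <- c("record_id", "title", "abstract", "publish_time", "date_precision",
            "journal", "authors", "doi", "num_cited_by", "peer_reviewed")
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract entity mentions with a dictionary matcher
#'
#' Concatenates title and abstract, normalizes and tokenizes the text, removes
#' stopwords (except words that are part of a lexicon surface form), and scans
#' candidate n-grams against the lexicon longest-match-first, non-overlapping.
#' A raw n-gram hit has similarity 1; otherwise the lemmatized n-gram is tried
#' and, on a hit, similarity is the normalized Levenshtein similarity between
#' the raw span and the matched surface form.
#'
#' A pluggable backend may replace the scan entirely: any function
#' `(record_id, text, lexicon) -> data frame(record_id, span, concept,
#' similarity)` supplied through `backend` is used unchanged, which is where a
#' statistical NER model would attach.
#'
#' @param records cleaned publication records ([clean_corpus()]).
#' @param lexicon a `litgraph_lexicon`.
#' @param stopwords character vector (default the shipped English list).
#' @param lemmatizer token normalizer, default [default_lemmatizer()].
#' @param backend optional replacement mention extractor (see above).
#' @return data frame of mention records: `record_id, span, concept,
#'   similarity` with `similarity` in `[0, 1]`.
#' @export
extract_mentions <- function(records, lexicon, stopwords = default_stopwords(),
                             lemmatizer = default_lemmatizer, backend = NULL) {
  stopifnot(inherits(lexicon, "litgraph_lexicon"))
  empty <- data.frame(record_id = character(0), span = character(0),
                      concept = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)

  texts <- paste(ifelse(is.na(records$title), "", records$title),
                 ifelse(is.na(records$abstract), "", records$abstract))
  if (!is.null(backend)) {
    out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
      backend(records$record_id[i], texts[i], lexicon)
    }))
    if (is.null(out) || nrow(out) == 0L) return(empty)
    return(out)
  }

  # stopwords that occur inside a lexicon surface must survive tokenization
  lex_words <- unique(unlist(strsplit(lexicon$terms$surface, " ", fixed = TRUE)))
  stopwords <- setdiff(normalize_surface(stopwords), lex_words)
  max_n <- max(1L, lexicon$max_tokens)

  res <- lapply(seq_len(nrow(records)), function(i) {
    toks <- tokenize(normalize_surface(texts[i]))
    toks <- toks[!toks %in% stopwords]
    nt <- length(toks)
    if (nt == 0L) return(NULL)
    lems <- lemmatizer(toks)
    spans <- character(0); concepts <- character(0); sims <- numeric(0)
    pos <- 1L
    while (pos <= nt) {
      advanced <- FALSE
      for (n in seq.int(min(max_n, nt - pos + 1L), 1L)) {
        raw_span <- paste(toks[pos:(pos + n - 1L)], collapse = " ")
        idx <- lexicon$index[[raw_span]]
        sim <- 1
        if (is.null(idx)) {
          lem_span <- paste(lems[pos:(pos + n - 1L)], collapse = " ")
          idx <- lexicon$index[[lem_span]]
          if (!is.null(idx)) {
            sim <- normalized_similarity(raw_span, lexicon$terms$surface[idx[1L]])
          }
        }
        if (!is.null(idx)) {
          hit <- lexicon$terms[idx, , drop = FALSE]
          hit <- hit[order(hit$is_utility, hit$concept_id, method = "radix"), , drop = FALSE]
          spans <- c(spans, rep(raw_span, nrow(hit)))
          concepts <- c(concepts, hit$name)
          sims <- c(sims, rep(sim, nrow(hit)))
          pos <- pos + n
          advanced <- TRUE
          break
        }
      }
      if (!advanced) pos <- pos + 1L
    }
    if (!length(spans)) return(NULL)
    data.frame(record_id = records$record_id[i], span = spans, concept = concepts,
               similarity = sims, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Curate entities with the similarity gate
#'
#' Discards mentions whose similarity falls below the threshold (utility terms
#' are exempt), then aggregates surviving mentions per concept. The entity
#' frequency is the number of distinct documents mentioning the concept (a
#' concept mentioned five times in one abstract counts once). Macrocategory,
#' type and ontology ids are attached from the lexicon.
#'
#' @param mentions mention records from [extract_mentions()].
#' @param lexicon a `litgraph_lexicon`.
#' @param threshold similarity gate in `[0, 1]`, inclusive (default 0.7).
#' @return data frame of entities: `name, umls_id, cido_id, macrocategory,
#'   type, is_utility, frequency`, sorted by name.
#' @export
curate_entities <- function(mentions, lexicon, threshold = 0.7) {
  stopifnot(inherits(lexicon, "litgraph_lexicon"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a number in [0, 1]", call. = FALSE)
  }
  info <- lexicon$terms[!duplicated(lexicon$terms$name),
                        c("name", "umls_id", "cido_id", "macrocategory", "type",
                          "is_utility"), drop = FALSE]
  m <- merge(mentions, info, by.x = "concept", by.y = "name", sort = FALSE)
  m <- m[m$is_utility | m$similarity >= threshold, , drop = FALSE]
  if (nrow(m) == 0L) {
    out <- info[0L, , drop = FALSE]
    out$frequency <- integer(0)
    return(out)
  }
  freq <- tapply(m$record_id, m$concept, function(x) length(unique(x)))
  out <- info[match(names(freq), info$name), , drop = FALSE]
  out$frequency <- as.integer(freq)
  out <- out[order(out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-document entity sets
#'
#' Reduces curated mentions to the two lookup tables used by link mining: for
#' each document the set of curated entities it mentions. Only concepts present
#' in `entities` survive.
#'
#' @param mentions mention records.
#' @param entities curated entity table from [curate_entities()].
#' @return data frame `record_id, name`, one row per distinct
#'   (document, entity) pair, radix-sorted.
#' @export
doc_entity_table <- function(mentions, entities) {
  keep <- mentions$concept %in% entities$name
  de <- unique(data.frame(record_id = mentions$record_id[keep],
                          name = mentions$concept[keep],
                          stringsAsFactors = FALSE))
  de <- de[order(de$record_id, de$name, method = "radix"), , drop = FALSE]
  rownames(de) <- NULL
  de
}
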