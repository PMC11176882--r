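#' Build a relationship name from two concept names
#'
#' Relationship names concatenate the two endpoint names in alphabetical
#' (C-locale byte) order, joined by an em dash by default. Names are display
#' identifiers only; endpoints are always stored as a pair and never re-parsed
#' from the name, so concept names containing the separator are safe.
#'
#' @param x,y concept names (vectors of equal length).
#' @param separator edge-name separator; `"—"` (em dash) by default, an
#'   ASCII `"--"` fallback is available for files or shells that reject
#'   non-ASCII.
#' @return character vector of edge names.
#' @export
edge_name <- function(x, y, separator = "—") {
  p <- .sort_pair(x, y)
  paste0(p$x, separator, p$y)
}

# elementwise pair sort in C-locale (codepoint) order, locale-independent
.sort_pair <- function(x, y) {
  s <- sort(unique(c(x, y)), method = "radix")
  swap <- match(y, s) < match(x, s)
  list(x = ifelse(swap, y, x), y = ifelse(swap, x, y))
}

#' Count pairwise co-occurrences in a single pass
#'
#' Greedy single pass over the documents: each document containing k >= 2
#' entities contributes its choose(k, 2) unordered pairs; pair frequencies are
#' accumulated over documents. Work is proportional to the total number of
#' per-document pairs, far below the worst-case quadratic bound in the number
#' of entities.
#'
#' @param doc_entities data frame `record_id, name` from [doc_entity_table()],
#'   or a named list mapping record id to a character vector of entity names.
#' @return data frame `name_x, name_y, frequency` with `name_x < name_y` in
#'   C-locale order, radix-sorted by the pair; empty corpus gives zero rows.
#' @export
build_cooccurrences <- function(doc_entities) {
  sets <- if (is.data.frame(doc_entities)) {
    lapply(split(doc_entities$name, doc_entities$record_id), unique)
  } else {
    lapply(doc_entities, unique)
  }
  pair_chunks <- lapply(sets, function(ents) {
    if (length(ents) < 2L) return(NULL)
    ents <- sort(ents, method = "radix")
    utils::combn(ents, 2L)
  })
  pair_chunks <- pair_chunks[!vapply(pair_chunks, is.null, logical(1))]
  if (!length(pair_chunks)) {
    return(data.frame(name_x = character(0), name_y = character(0),
                      frequency = integer(0), stringsAsFactors = FALSE))
  }
  pairs <- do.call(cbind, pair_chunks)
  key <- paste(pairs[1L, ], pairs[2L, ], sep = "\x1f")
  tab <- table(key)
  parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
  out <- data.frame(name_x = vapply(parts, `[[`, character(1), 1L),
                    name_y = vapply(parts, `[[`, character(1), 2L),
                    frequency = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$name_x, out$name_y, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-occurrence edge statistics: PMI, NPMI, Cramer's V
#'
#' With document probabilities `p(x) = freq_x/n`, `p(y) = freq_y/n` and
#' `p(x,y) = joint/n`:
#' \itemize{
#'   \item `pmi = log(p(x,y) / (p(x) p(y)))` in the requested base (natural by
#'     default; NPMI is base-invariant).
#'   \item `npmi = pmi / (-log p(x,y))`, the PMI normalized by the Shannon
#'     self-information; bounded in `[-1, 1]`, 0 at independence, 1 when the
#'     pair occurs only together. The degenerate case `p(x,y) = 1` is defined
#'     as 1 by limit.
#'   \item `cramers_v = sqrt(chi2 / n)` from the 2x2 document contingency
#'     table {both, x-only, y-only, neither}, Pearson chi-squared without
#'     continuity correction (for a 2x2 table `min(r-1, c-1) = 1`). When a
#'     marginal fills the whole corpus the table is degenerate and V is 0.
#' }
#'
#' @param joint documents containing both entities (vectorized).
#' @param freq_x,freq_y marginal document frequencies.
#' @param n corpus size (number of documents).
#' @param log_base base for the reported PMI (default `exp(1)`).
#' @return data frame `pmi, npmi, cramers_v`.
#' @export
edge_statistics <- function(joint, freq_x, freq_y, n, log_base = exp(1)) {
  k <- max(length(joint), length(freq_x), length(freq_y))
  joint <- rep_len(as.numeric(joint), k)
  freq_x <- rep_len(as.numeric(freq_x), k)
  freq_y <- rep_len(as.numeric(freq_y), k)
  if (any(freq_x < 1 | freq_y < 1)) {
    stop("zero marginal frequency: every endpoint must occur in >= 1 document",
         call. = FALSE)
  }
  if (any(joint < 1 | joint > pmin(freq_x, freq_y)) || any(pmax(freq_x, freq_y) > n)) {
    stop("requires 1 <= joint <= min(freq_x, freq_y) <= n", call. = FALSE)
  }
  pxy <- joint / n
  pmi_nat <- log(joint * n / (freq_x * freq_y))
  npmi <- ifelse(pxy == 1, 1, pmi_nat / (-log(pxy)))
  if (any(pxy == 1)) {
    message("npmi limit case: pair(s) present in every document, npmi set to 1")
  }
  a <- joint; b <- freq_x - joint; c_ <- freq_y - joint; d <- n - freq_x - freq_y + joint
  denom <- freq_x * (n - freq_x) * freq_y * (n - freq_y)
  chi2 <- ifelse(denom == 0, 0, n * (a * d - b * c_)^2 / denom)
  data.frame(pmi = pmi_nat / log(log_base),
             npmi = npmi,
             cramers_v = sqrt(chi2 / n))
}

#' Prune edges by NPMI
#'
#' Retains exactly the edges with `npmi > min_npmi`; the exclusion is strict
#' (an edge at NPMI exactly 0 is not significant and is removed under the
#' default). The node set is left unchanged, so pruning may isolate nodes —
#' see [connectivity_report()].
#'
#' @param edges edge data frame with an `npmi` column.
#' @param min_npmi threshold, default 0.
#' @return the retained rows of `edges`.
#' @export
prune_edges <- function(edges, min_npmi = 0) {
  out <- edges[edges$npmi > min_npmi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a co-occurrence network
#'
#' Joins per-entity frequencies onto the co-occurrence pair counts, computes
#' the association statistics, names the edges, and prunes non-significant
#' ones.
#'
#' @param entities curated entity table ([curate_entities()]).
#' @param doc_entities per-document entity sets ([doc_entity_table()]).
#' @param corpus_size number of documents in the cleaned corpus (the
#'   probability denominator; includes documents without mentions).
#' @param min_npmi pruning threshold (strict), default 0.
#' @param separator edge-name separator, see [edge_name()].
#' @param log_base PMI base.
#' @return object of class `cooc_network`: list with `nodes` (entity table),
#'   `edges` (`name_x, name_y, name, frequency, pmi, npmi, cramers_v`),
#'   `corpus_size`, `separator`, `log_base`.
#' @export
build_network <- function(entities, doc_entities, corpus_size,
                          min_npmi = 0, separator = "—", log_base = exp(1)) {
  stopifnot(corpus_size >= 1)
  edges <- build_cooccurrences(doc_entities)
  if (nrow(edges)) {
    fx <- entities$frequency[match(edges$name_x, entities$name)]
    fy <- entities$frequency[match(edges$name_y, entities$name)]
    if (any(is.na(fx) | is.na(fy))) {
      stop("co-occurring entity missing from the curated entity table", call. = FALSE)
    }
    stats <- edge_statistics(edges$frequency, fx, fy, corpus_size, log_base = log_base)
    edges <- cbind(edges, stats)
    edges$name <- edge_name(edges$name_x, edges$name_y, separator)
    edges <- prune_edges(edges, min_npmi)
  } else {
    edges <- data.frame(name_x = character(0), name_y = character(0),
                        frequency = integer(0), pmi = numeric(0),
                        npmi = numeric(0), cramers_v = numeric(0),
                        name = character(0), stringsAsFactors = FALSE)
  }
  edges <- edges[, c("name_x", "name_y", "name", "frequency", "pmi", "npmi",
                     "cramers_v"), drop = FALSE]
  structure(list(nodes = entities, edges = edges, corpus_size = corpus_size,
                 separator = separator, log_base = log_base),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d node(s), %d edge(s), corpus of %d document(s)\n",
              nrow(x$nodes), nrow(x$edges), x$corpus_size))
  invisible(x)
}

.network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("name_x", "name_y"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes$name, stringsAsFactors = FALSE)
  )
}

#' Connected-component report
#'
#' A single connected component guarantees that every formulated graph query
#' can be matched on the network; search over a multi-component network is
#' permitted but queries spanning components yield empty expansions.
#'
#' @param network a `cooc_network`.
#' @return list with `component_count`, `sizes` (decreasing), and
#'   `is_single_component`; a warning is attached when the graph is not a
#'   single component.
#' @export
connectivity_report <- function(network) {
  stopifnot(inherits(network, "cooc_network"))
  comp <- igraph::components(.network_igraph(network))
  report <- list(component_count = comp$no,
                 sizes = sort(as.integer(comp$csize), decreasing = TRUE),
                 is_single_component = comp$no == 1L)
  if (!report$is_single_component) {
    warning(sprintf("co-occurrence network has %d connected components; queries spanning components cannot be matched",
                    comp$no), call. = FALSE)
  }
  report
}

#' Build the inverted index
#'
#' For every (pruned) edge, the posting list is the sorted set of record ids
#' of documents mentioning both endpoints. Posting lists are keyed by the
#' relationship name; endpoints are kept alongside so names are never
#' re-parsed.
#'
#' @param edges pruned edge table (needs `name_x, name_y, name`).
#' @param doc_entities per-document entity sets ([doc_entity_table()]).
#' @return object of class `inverted_index`: list with `name_x`, `name_y`,
#'   `key` (edge names) and `postings` (list of sorted record-id vectors).
#' @export
build_inverted_index <- function(edges, doc_entities) {
  if (is.data.frame(doc_entities)) {
    ep <- lapply(split(doc_entities$record_id, doc_entities$name),
                 function(x) sort(unique(x), method = "radix"))
  } else {
    inv <- data.frame(
      record_id = rep(names(doc_entities), lengths(doc_entities)),
      name = unlist(doc_entities, use.names = FALSE), stringsAsFactors = FALSE)
    ep <- lapply(split(inv$record_id, inv$name),
                 function(x) sort(unique(x), method = "radix"))
  }
  postings <- lapply(seq_len(nrow(edges)), function(i) {
    intersect(ep[[edges$name_x[i]]], ep[[edges$name_y[i]]])
  })
  structure(list(name_x = edges$name_x, name_y = edges$name_y,
                 key = edges$name, postings = postings),
            class = "inverted_index")
}

#' Look up a posting list by relationship name
#'
#' @param index an `inverted_index`.
#' @param key relationship name (or an `c(name_x, name_y)` pair).
#' @return sorted character vector of record ids; a key miss returns an empty
#'   vector (logged via message), not an error.
#' @export
index_postings <- function(index, key) {
  stopifnot(inherits(index, "inverted_index"))
  i <- if (length(key) == 2L) {
    p <- .sort_pair(key[1L], key[2L])
    which(index$name_x == p$x & index$name_y == p$y)[1L]
  } else {
    match(key, index$key)
  }
  if (is.na(i)) {
    message(sprintf("inverted index: no posting list for %s",
                    paste(key, collapse = "—")))
    return(character(0))
  }
  index$postings[[i]]
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted_index> %d posting list(s), %d posting(s) total\n",
              length(x$key), sum(lengths(x$postings))))
  invisible(x)
}
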