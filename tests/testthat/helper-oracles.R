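# Independent oracles used to cross-check the implementation. These are
# deliberately naive (dynamic programming, exhaustive enumeration, brute
# force) and share no code with the package internals.

# textbook dynamic-programming Levenshtein distance
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1L, m + 1L]
}

# exhaustive DFS enumeration of every simple path between two nodes, filtered
# to the minimal edge count
oracle_min_paths <- function(edges_df, source, target) {
  adj <- list()
  for (i in seq_len(nrow(edges_df))) {
    x <- edges_df$name_x[i]; y <- edges_df$name_y[i]
    adj[[x]] <- c(adj[[x]], y)
    adj[[y]] <- c(adj[[y]], x)
  }
  paths <- list()
  dfs <- function(node, visited) {
    if (node == target) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (!nb %in% visited) dfs(nb, c(visited, nb))
    }
  }
  if (is.null(adj[[source]]) || is.null(adj[[target]])) return(list())
  dfs(source, source)
  if (!length(paths)) return(list())
  lens <- vapply(paths, length, integer(1))
  paths[lens == min(lens)]
}

# brute-force co-occurrence counter: for every entity pair, scan all documents
oracle_pair_counts <- function(doc_sets) {
  ents <- sort(unique(unlist(doc_sets)), method = "radix")
  out <- list()
  if (length(ents) >= 2L) {
    for (i in seq_len(length(ents) - 1L)) {
      for (j in seq.int(i + 1L, length(ents))) {
        f <- sum(vapply(doc_sets, function(s)
          ents[i] %in% s && ents[j] %in% s, logical(1)))
        if (f > 0L) {
          out[[length(out) + 1L]] <- data.frame(
            name_x = ents[i], name_y = ents[j], frequency = f,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(name_x = character(0), name_y = character(0),
                      frequency = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# union-find connected components over an edge list + isolated nodes
oracle_components <- function(nodes, edges_df) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges_df))) {
    rx <- find(edges_df$name_x[i]); ry <- find(edges_df$name_y[i])
    if (rx != ry) parent[[rx]] <- ry
  }
  roots <- vapply(nodes, find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# random connected network fixture for path-search property tests
random_network <- function(n_nodes, extra_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  # random spanning tree keeps the graph connected
  pairs <- do.call(rbind, lapply(seq.int(2L, n_nodes), function(i) {
    c(nodes[sample.int(i - 1L, 1L)], nodes[i])
  }))
  all_pairs <- t(utils::combn(nodes, 2L))
  key <- function(m) paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  avail <- all_pairs[!key(all_pairs) %in% key(pairs), , drop = FALSE]
  if (extra_edges > 0L && nrow(avail)) {
    take <- sample.int(nrow(avail), min(extra_edges, nrow(avail)))
    pairs <- rbind(pairs, avail[take, , drop = FALSE])
  }
  lo <- pmin(pairs[, 1L], pairs[, 2L]); hi <- pmax(pairs[, 1L], pairs[, 2L])
  edges <- data.frame(name_x = lo, name_y = hi, stringsAsFactors = FALSE)
  edges$name <- edge_name(edges$name_x, edges$name_y)
  edges$frequency <- sample.int(9L, nrow(edges), replace = TRUE)
  edges$pmi <- stats::runif(nrow(edges), 0.1, 2)
  edges$npmi <- stats::runif(nrow(edges), 0.01, 0.99)
  edges$cramers_v <- stats::runif(nrow(edges))
  nodes_df <- data.frame(name = nodes, umls_id = sprintf("C95%05d", seq_len(n_nodes)),
                         cido_id = NA_character_, macrocategory = "CONCEPTS_AND_IDEAS",
                         type = "Synthetic Concept", is_utility = FALSE,
                         frequency = sample.int(20L, n_nodes, replace = TRUE),
                         stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, edges = edges, corpus_size = 100L,
                 separator = "—", log_base = exp(1)),
            class = "cooc_network")
}

# small two-concept + utility lexicon reused across corpus tests
tiny_lexicon <- function() {
  make_lexicon(data.frame(
    surface = c("blood glucose", "covid-19", "cystic fibrosis"),
    name = c("Blood Glucose", "COVID-19", "Cystic Fibrosis"),
    umls_id = c("C0005802", "C5203670", "C0010674"),
    cido_id = NA_character_,
    macrocategory = c("CHEMICALS_AND_DRUGS", "DISORDERS", "DISORDERS"),
    type = c("Organic Chemical", "Disease or Syndrome", "Disease or Syndrome"),
    stringsAsFactors = FALSE
  ), utility = c("high", "increased", "induces"))
}

# minimal metadata row constructor
md_row <- function(cord_uid, title = "A plain English title", abstract = "Some abstract text.",
                   publish_time = "2021-05-01", journal = NA_character_,
                   authors = NA_character_, doi = NA_character_,
                   num_cited_by = NA_character_) {
  data.frame(cord_uid = cord_uid, title = title, abstract = abstract,
             publish_time = publish_time, journal = journal, authors = authors,
             doi = doi, num_cited_by = num_cited_by, stringsAsFactors = FALSE)
}
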