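#' Construct a graph query
#'
#' A graph query is a small connected undirected graph whose nodes are concept
#' names resolvable in the network and whose edges are unordered node pairs.
#'
#' @param nodes character vector of concept names.
#' @param edges list of length-2 character vectors (or a 2-column matrix /
#'   data frame), one per query edge.
#' @return object of class `graph_query` with `nodes` and a 2-column `edges`
#'   data frame (`name_x, name_y`, pair-sorted).
#' @export
graph_query <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  if (is.matrix(edges) || is.data.frame(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(i) as.character(unlist(edges[i, 1:2])))
  }
  if (!length(edges)) stop("a graph query needs at least one edge", call. = FALSE)
  em <- do.call(rbind, lapply(edges, function(e) {
    e <- as.character(e)
    if (length(e) != 2L) stop("each query edge must name exactly two nodes", call. = FALSE)
    sort(e, method = "radix")
  }))
  edf <- unique(data.frame(name_x = em[, 1L], name_y = em[, 2L],
                           stringsAsFactors = FALSE))
  edf <- edf[order(edf$name_x, edf$name_y, method = "radix"), , drop = FALSE]
  rownames(edf) <- NULL
  structure(list(nodes = nodes, edges = edf), class = "graph_query")
}

#' Validate and normalize a graph query against a network
#'
#' Checks that every node resolves to a network node (with near-match
#' suggestions by normalized similarity on failure), that the query has no
#' self-loops, and that it is connected.
#'
#' @param query a `graph_query`.
#' @param network a `cooc_network`.
#' @return the normalized query (edges as sorted pairs, nodes completed from
#'   edges).
#' @export
validate_query <- function(query, network) {
  stopifnot(inherits(query, "graph_query"), inherits(network, "cooc_network"))
  nodes <- union(query$nodes, unlist(query$edges[, c("name_x", "name_y")]))
  unknown <- setdiff(nodes, network$nodes$name)
  if (length(unknown)) {
    suggestions <- vapply(unknown, function(u) {
      sims <- normalized_similarity(rep(u, nrow(network$nodes)), network$nodes$name)
      paste(utils::head(network$nodes$name[order(-sims)], 3L), collapse = ", ")
    }, character(1))
    stop(sprintf("query node(s) not in the network: %s",
                 paste(sprintf("%s (near matches: %s)", unknown, suggestions),
                       collapse = "; ")), call. = FALSE)
  }
  if (any(query$edges$name_x == query$edges$name_y)) {
    stop("query contains a self-loop", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(query$edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    groups <- split(names(comp$membership), comp$membership)
    stop(sprintf("graph query must be connected; found %d components: %s",
                 comp$no,
                 paste(vapply(groups, function(gg)
                   paste0("{", paste(sort(gg, method = "radix"), collapse = ", "), "}"),
                   character(1)), collapse = " ")), call. = FALSE)
  }
  structure(list(nodes = sort(nodes, method = "radix"), edges = query$edges),
            class = "graph_query")
}

#' @export
print.graph_query <- function(x, ...) {
  cat(sprintf("<graph_query> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

.edge_row <- function(network, a, b) {
  p <- .sort_pair(a, b)
  which(network$edges$name_x == p$x & network$edges$name_y == p$y)[1L]
}

.path_candidate <- function(network, node_seq) {
  L <- length(node_seq) - 1L
  rows <- vapply(seq_len(L), function(i)
    .edge_row(network, node_seq[i], node_seq[i + 1L]), integer(1))
  edges <- network$edges[rows, , drop = FALSE]
  rownames(edges) <- NULL
  list(source = node_seq[1L], target = node_seq[L + 1L],
       nodes = node_seq, edges = edges, length = L,
       avg_npmi = mean(edges$npmi))
}

#' Enumerate and rank candidate shortest paths
#'
#' Finds all minimal-hop-length simple paths between two network nodes
#' (unweighted geodesics), ranks them by the average NPMI of the relationships
#' along the path (descending; ties broken by the lexicographic node-name
#' sequence for determinism), and retains the top `k`. A query edge already
#' present in the network needs no expansion: exactly that length-1 path is
#' returned regardless of alternatives. Path length is the number of edges
#' (hops); NPMI ranks among equal-length candidates but never defines length.
#'
#' @param network a `cooc_network`.
#' @param source,target distinct network node names.
#' @param k maximum number of candidates retained (default 10).
#' @return list of path candidates (each with `source`, `target`, `nodes`,
#'   `edges`, `length`, `avg_npmi`), best first; empty list with a warning
#'   when no path exists.
#' @export
find_path_candidates <- function(network, source, target, k = 10L) {
  stopifnot(inherits(network, "cooc_network"))
  if (identical(source, target)) stop("source and target must differ", call. = FALSE)
  if (!all(c(source, target) %in% network$nodes$name)) {
    stop("source and target must be network nodes", call. = FALSE)
  }
  direct <- .edge_row(network, source, target)
  if (!is.na(direct)) {
    return(list(.path_candidate(network, c(source, target))))
  }
  g <- .network_igraph(network)
  asp <- suppressWarnings(igraph::all_shortest_paths(g, from = source, to = target,
                                                     mode = "all"))
  vpaths <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
  if (!length(vpaths)) {
    warning(sprintf("no path between %s and %s (multi-component network); expansion is empty",
                    source, target), call. = FALSE)
    return(list())
  }
  cands <- lapply(vpaths, function(vp) {
    .path_candidate(network, igraph::as_ids(vp))
  })
  seq_key <- vapply(cands, function(p) paste(p$nodes, collapse = "\x1f"), character(1))
  ord <- order(-vapply(cands, `[[`, numeric(1), "avg_npmi"),
               seq_key, method = "radix")
  cands[utils::head(ord, k)]
}

#' Expand a graph query
#'
#' Produces one expansion per query edge: the ranked candidate shortest paths
#' from [find_path_candidates()], with the top-ranked path (highest average
#' NPMI) selected by default. The selection is user-overridable per expansion
#' via [select_path()], mirroring interactive path choice.
#'
#' @param query a validated `graph_query`.
#' @param network a `cooc_network`.
#' @param k candidates retained per expansion (default 10).
#' @return list of class `query_expansions`; each element has `query_edge`
#'   (sorted pair), `candidates`, `selected` (1-based index into candidates,
#'   `NA` when the expansion is empty).
#' @export
expand_query <- function(query, network, k = 10L) {
  query <- validate_query(query, network)
  exps <- lapply(seq_len(nrow(query$edges)), function(i) {
    cands <- find_path_candidates(network, query$edges$name_x[i],
                                  query$edges$name_y[i], k = k)
    list(query_edge = c(query$edges$name_x[i], query$edges$name_y[i]),
         candidates = cands,
         selected = if (length(cands)) 1L else NA_integer_)
  })
  structure(exps, class = "query_expansions")
}

#' Select a candidate path within an expansion
#'
#' @param expansions a `query_expansions` list.
#' @param edge query edge as a character pair (order-insensitive) or the
#'   expansion's integer position.
#' @param rank 1-based rank of the candidate to select.
#' @return the updated expansions.
#' @export
select_path <- function(expansions, edge, rank) {
  stopifnot(inherits(expansions, "query_expansions"))
  i <- if (is.numeric(edge)) {
    as.integer(edge)
  } else {
    p <- .sort_pair(edge[1L], edge[2L])
    which(vapply(expansions, function(e)
      identical(e$query_edge, c(p$x, p$y)), logical(1)))[1L]
  }
  if (is.na(i) || i < 1L || i > length(expansions)) {
    stop("no expansion for the requested query edge", call. = FALSE)
  }
  if (rank < 1L || rank > length(expansions[[i]]$candidates)) {
    stop(sprintf("expansion has %d candidate(s); rank %d is out of range",
                 length(expansions[[i]]$candidates), rank), call. = FALSE)
  }
  expansions[[i]]$selected <- as.integer(rank)
  expansions
}

.selected_path <- function(expansion) {
  if (is.na(expansion$selected)) return(NULL)
  expansion$candidates[[expansion$selected]]
}

#' Score one publication against expanded query edges
#'
#' The score of a publication P relative to a query Q is the number of
#' explained relationships: the sum over query edges of a per-edge addend in
#' `[0, 1]`. For the selected path of an edge (length L), the addend is m/L
#' where m is the number of path relationships whose posting list contains P;
#' it is 1 when P mentions the whole path (in particular a directly matched
#' edge), and 0 when the expansion is empty. `npmi_sum` is the sum of NPMI
#' over all distinct mentioned path relationships.
#'
#' @param record_id publication id.
#' @param expansions a `query_expansions` with selections made.
#' @param index an `inverted_index`.
#' @return list of class `scored_publication`: `record_id`, `score`,
#'   `npmi_sum`, `addends` (named by relationship name of the query edge),
#'   `n_edges`.
#' @export
score_publication <- function(record_id, expansions, index) {
  stopifnot(inherits(expansions, "query_expansions"),
            inherits(index, "inverted_index"))
  addends <- numeric(length(expansions))
  names(addends) <- vapply(expansions, function(e)
    paste(e$query_edge, collapse = "\x1f"), character(1))
  mentioned_keys <- character(0)
  mentioned_npmi <- numeric(0)
  for (i in seq_along(expansions)) {
    path <- .selected_path(expansions[[i]])
    if (is.null(path)) { addends[i] <- 0; next }
    in_post <- vapply(seq_len(path$length), function(j) {
      p <- index$postings[[match(path$edges$name[j], index$key)]]
      !is.null(p) && record_id %in% p
    }, logical(1))
    addends[i] <- sum(in_post) / path$length
    mentioned_keys <- c(mentioned_keys, path$edges$name[in_post])
    mentioned_npmi <- c(mentioned_npmi, path$edges$npmi[in_post])
  }
  keep <- !duplicated(mentioned_keys)
  structure(list(record_id = record_id,
                 score = sum(addends),
                 npmi_sum = sum(mentioned_npmi[keep]),
                 addends = addends,
                 n_edges = length(expansions)),
            class = "scored_publication")
}

#' Retrieve and rank publications for an expanded query
#'
#' The candidate set is the union of the posting lists of all selected-path
#' relationships (union, not intersection, so partially explaining
#' publications surface). Each candidate is scored and the list is ordered by
#' (1) score — the number of explained relationships — descending, (2) NPMI
#' sum descending, (3) publication date (most recent first by default), and
#' (4) record id ascending as a final tier that makes the ranking total.
#' Alternatively the primary key can be the citation count.
#'
#' @param expansions a `query_expansions` with selections made.
#' @param index an `inverted_index`.
#' @param metadata cleaned publication records (for `publish_time` and
#'   `num_cited_by`); may be `NULL`, disabling the date tier.
#' @param top return at most this many rows (default all).
#' @param rank_by `"score"` (default) or `"citations"` (prepends the
#'   `num_cited_by` key, descending).
#' @param recent_first logical; flip to rank older publications first within
#'   ties.
#' @return data frame `rank, record_id, score, npmi_sum, publish_time,
#'   num_cited_by, explained, total, addends_json`, best match first.
#' @export
retrieve_and_rank <- function(expansions, index, metadata = NULL, top = Inf,
                              rank_by = c("score", "citations"),
                              recent_first = TRUE) {
  rank_by <- match.arg(rank_by)
  keys <- unlist(lapply(expansions, function(e) {
    path <- .selected_path(e)
    if (is.null(path)) character(0) else path$edges$name
  }))
  ids <- sort(unique(unlist(lapply(unique(keys), function(k) {
    index$postings[[match(k, index$key)]]
  }))), method = "radix")
  cols <- c("rank", "record_id", "score", "npmi_sum", "publish_time",
            "num_cited_by", "explained", "total", "addends_json")
  if (!length(ids)) {
    out <- data.frame(rank = integer(0), record_id = character(0),
                      score = numeric(0), npmi_sum = numeric(0),
                      publish_time = as.Date(character(0)),
                      num_cited_by = integer(0), explained = numeric(0),
                      total = integer(0), addends_json = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  scored <- lapply(ids, score_publication, expansions = expansions, index = index)
  score <- vapply(scored, `[[`, numeric(1), "score")
  npmi_sum <- vapply(scored, `[[`, numeric(1), "npmi_sum")
  if (!is.null(metadata)) {
    mrow <- match(ids, metadata$record_id)
    dates <- as.Date(metadata$publish_time[mrow])
    cites <- suppressWarnings(as.integer(metadata$num_cited_by[mrow]))
  } else {
    dates <- as.Date(rep(NA, length(ids)))
    cites <- rep(NA_integer_, length(ids))
  }
  date_key <- as.numeric(dates)
  date_key[is.na(date_key)] <- -Inf
  if (!recent_first) date_key <- -date_key
  cite_key <- ifelse(is.na(cites), -1L, cites)
  ord <- if (rank_by == "citations") {
    order(-cite_key, -score, -npmi_sum, -date_key, ids, method = "radix")
  } else {
    order(-score, -npmi_sum, -date_key, ids, method = "radix")
  }
  ord <- utils::head(ord, top)
  addends_json <- vapply(scored[ord], function(s) {
    a <- as.list(unname(s$addends))
    names(a) <- gsub("\x1f", "|", names(s$addends), fixed = TRUE)
    as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA))
  }, character(1))
  data.frame(rank = seq_along(ord), record_id = ids[ord], score = score[ord],
             npmi_sum = npmi_sum[ord], publish_time = dates[ord],
             num_cited_by = cites[ord], explained = score[ord],
             total = length(expansions), addends_json = addends_json,
             stringsAsFactors = FALSE)
}

#' Read a graph query from JSON
#'
#' Expected shape: `{"nodes": [...], "edges": [[a, b], ...],
#' "selections": {"a|b": rank, ...}}`; `selections` is optional and applied
#' after expansion.
#'
#' @param path JSON file path.
#' @return list with `query` (a `graph_query`) and `selections` (named integer
#'   vector, possibly empty; names are `name_x|name_y` sorted pairs).
#' @export
read_query_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- unlist(obj$nodes)
  edges <- lapply(obj$edges, unlist)
  sel <- if (!is.null(obj$selections)) {
    vapply(obj$selections, as.integer, integer(1))
  } else {
    integer(0)
  }
  list(query = graph_query(nodes, edges), selections = sel)
}
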