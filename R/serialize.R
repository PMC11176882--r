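#' Write a co-occurrence network to a directory
#'
#' Portable plain-text serialization: `nodes.tsv`
#' (`name, umls_id, cido_id, macrocategory, type, frequency`), `edges.tsv`
#' (`name_x, name_y, frequency, pmi, npmi, cramers_v`) and `network.json`
#' (corpus size, separator, log base).
#'
#' @param network a `cooc_network`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "cooc_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- network$nodes[, c("name", "umls_id", "cido_id", "macrocategory",
                             "type", "frequency"), drop = FALSE]
  utils::write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE,
                     fileEncoding = "UTF-8")
  edges <- network$edges[, c("name_x", "name_y", "frequency", "pmi", "npmi",
                             "cramers_v"), drop = FALSE]
  edges$pmi <- sprintf("%.15g", edges$pmi)
  edges$npmi <- sprintf("%.15g", edges$npmi)
  edges$cramers_v <- sprintf("%.15g", edges$cramers_v)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(list(corpus_size = network$corpus_size,
                            separator = network$separator,
                            log_base = network$log_base),
                       file.path(dir, "network.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a co-occurrence network from a directory
#'
#' @param dir directory written by [write_network()].
#' @return a `cooc_network`.
#' @export
read_network <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "network.json"))
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"), sep = "\t",
                             colClasses = "character", quote = "",
                             na.strings = c("NA", ""), fileEncoding = "UTF-8")
  nodes$frequency <- as.integer(nodes$frequency)
  nodes$is_utility <- nodes$macrocategory == "UTILITY"
  edges <- utils::read.delim(file.path(dir, "edges.tsv"), sep = "\t",
                             colClasses = "character", quote = "",
                             na.strings = c("NA", ""), fileEncoding = "UTF-8")
  edges$frequency <- as.integer(edges$frequency)
  for (cl in c("pmi", "npmi", "cramers_v")) edges[[cl]] <- as.numeric(edges[[cl]])
  edges$name <- edge_name(edges$name_x, edges$name_y, meta$separator)
  edges <- edges[, c("name_x", "name_y", "name", "frequency", "pmi", "npmi",
                     "cramers_v"), drop = FALSE]
  structure(list(nodes = nodes, edges = edges,
                 corpus_size = as.integer(meta$corpus_size),
                 separator = meta$separator, log_base = meta$log_base),
            class = "cooc_network")
}

#' Write an inverted index as JSON lines
#'
#' One JSON object per line: `{"edge": key, "name_x": ..., "name_y": ...,
#' "postings": [...]}`.
#'
#' @param index an `inverted_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_inverted_index <- function(index, path) {
  stopifnot(inherits(index, "inverted_index"))
  lines <- vapply(seq_along(index$key), function(i) {
    as.character(jsonlite::toJSON(
      list(edge = index$key[i], name_x = index$name_x[i],
           name_y = index$name_y[i], postings = index$postings[[i]]),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an inverted index from JSON lines
#'
#' @param path file written by [write_inverted_index()].
#' @return an `inverted_index`.
#' @export
read_inverted_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON)
  structure(list(name_x = vapply(objs, `[[`, character(1), "name_x"),
                 name_y = vapply(objs, `[[`, character(1), "name_y"),
                 key = vapply(objs, `[[`, character(1), "edge"),
                 postings = lapply(objs, function(o) as.character(o$postings))),
            class = "inverted_index")
}

#' Write a cleaned corpus to CSV
#'
#' Same schema as the input metadata dialect plus `date_precision` and
#' `peer_reviewed`.
#'
#' @param records cleaned publication records.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  df <- records
  df$publish_time <- format(df$publish_time, "%Y-%m-%d")
  df$peer_reviewed <- ifelse(df$peer_reviewed, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cleaned corpus written by [write_corpus()]
#'
#' @param path CSV path.
#' @return publication-record data frame.
#' @export
read_corpus <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = c("NA", ""),
                        fileEncoding = "UTF-8", check.names = FALSE)
  df$publish_time <- as.Date(df$publish_time)
  if ("peer_reviewed" %in% names(df)) df$peer_reviewed <- df$peer_reviewed == "true"
  df
}

#' Write mention records as TSV
#'
#' @param mentions mention records (`record_id, span, concept, similarity`).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  df <- mentions
  df$similarity <- sprintf("%.15g", df$similarity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read mention records written by [write_mentions()]
#'
#' @param path TSV path.
#' @return mention-record data frame.
#' @export
read_mentions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "", na.strings = "NA",
                          fileEncoding = "UTF-8")
  df$similarity <- as.numeric(df$similarity)
  df
}
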