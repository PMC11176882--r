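#' Pipeline run configuration
#'
#' Collects the paths and tuning parameters shared by the pipeline stages.
#' Flags given on the command line override file values; all thresholds are
#' validated against their documented ranges.
#'
#' @param raw_metadata path of the raw metadata CSV.
#' @param clean_metadata path of the cleaned corpus CSV.
#' @param lexicon path of the lexicon TSV.
#' @param utility optional path of the utility-term list.
#' @param mentions path of the mentions TSV.
#' @param network_dir directory of the serialized network.
#' @param index path of the inverted-index JSON-lines file.
#' @param query path of the graph-query JSON.
#' @param results path of the search-results TSV.
#' @param threshold entity-curation similarity gate in `[0, 1]` (default 0.7).
#' @param min_year cleaning exclusion-filter year (default 2020).
#' @param exclusion_terms cleaning exclusion terms.
#' @param min_npmi edge-pruning threshold (strict, default 0).
#' @param k_paths candidates retained per expansion (default 10).
#' @param separator edge-name separator (`"—"`, ASCII fallback `"--"`).
#' @param top maximum result rows.
#' @param rank_by `"score"` or `"citations"`.
#' @param seed RNG seed for fixture generation.
#' @return list of class `run_config`.
#' @export
run_config <- function(raw_metadata = "metadata.csv",
                       clean_metadata = "metadata_clean.csv",
                       lexicon = "lexicon.tsv",
                       utility = NULL,
                       mentions = "mentions.tsv",
                       network_dir = "network",
                       index = "index.jsonl",
                       query = "query.json",
                       results = "results.tsv",
                       threshold = 0.7,
                       min_year = 2020,
                       exclusion_terms = DEFAULT_EXCLUSION_TERMS,
                       min_npmi = 0,
                       k_paths = 10L,
                       separator = "—",
                       top = Inf,
                       rank_by = "score",
                       seed = 1L) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]", call. = FALSE)
  if (min_npmi < -1 || min_npmi > 1) stop("min_npmi must lie in [-1, 1]", call. = FALSE)
  if (k_paths < 1L) stop("k_paths must be >= 1", call. = FALSE)
  structure(list(raw_metadata = raw_metadata, clean_metadata = clean_metadata,
                 lexicon = lexicon, utility = utility, mentions = mentions,
                 network_dir = network_dir, index = index, query = query,
                 results = results, threshold = threshold, min_year = min_year,
                 exclusion_terms = exclusion_terms, min_npmi = min_npmi,
                 k_paths = as.integer(k_paths), separator = separator,
                 top = top, rank_by = rank_by, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a `key = value` file
#'
#' Plain declarative text: one `key = value` per line, `#` comments allowed;
#' `exclusion_terms` is comma-separated. Unknown keys are an error.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p) {
    c(trimws(p[1L]), trimws(paste(p[-1L], collapse = "=")))
  })
  args <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, character(1), 1L))
  known <- names(formals(run_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  for (num in c("threshold", "min_year", "min_npmi", "k_paths", "top", "seed")) {
    if (num %in% names(args)) args[[num]] <- as.numeric(args[[num]])
  }
  if ("exclusion_terms" %in% names(args)) {
    args$exclusion_terms <- trimws(strsplit(args$exclusion_terms, ",", fixed = TRUE)[[1L]])
  }
  do.call(run_config, args)
}

.lg_log <- function(fmt, ...) {
  if (isTRUE(getOption("litgraph.quiet", FALSE))) return(invisible())
  message(sprintf("[litgraph] %s", sprintf(fmt, ...)))
}

.require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact %s; run the '%s' stage first",
                 path, producer), call. = FALSE)
  }
}

.atomic_file <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp, recursive = TRUE))
  writer(tmp)
  if (file.exists(path)) unlink(path, recursive = TRUE)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}

#' Run one pipeline stage
#'
#' Executes one task of the sequential data-provision workflow. Stages:
#' \describe{
#'   \item{clean}{raw metadata CSV -> cleaned corpus CSV.}
#'   \item{annotate}{cleaned corpus + lexicon -> mentions TSV.}
#'   \item{build-network}{mentions + lexicon + cleaned corpus -> network
#'     directory (nodes/edges/meta); logs counts before and after pruning and
#'     the component count.}
#'   \item{index}{network + mentions -> inverted-index JSON lines.}
#'   \item{search}{network + index + query JSON + cleaned corpus -> ranked
#'     results TSV.}
#'   \item{make-fixtures}{writes the running-example fixture files (metadata
#'     CSV, lexicon TSV, utility list, query JSON, expected-results TSV) into
#'     the directory of `raw_metadata`.}
#' }
#' Outputs are written atomically (temp file + rename); a missing upstream
#' artifact raises an error naming the prerequisite stage. Re-running a stage
#' with unchanged inputs reproduces byte-identical outputs.
#'
#' @param name stage name (see above).
#' @param config a `run_config`.
#' @return invisibly, a named list of stage counters.
#' @export
run_stage <- function(name = c("clean", "annotate", "build-network", "index",
                               "search", "make-fixtures"),
                      config = run_config()) {
  name <- match.arg(name)
  stopifnot(inherits(config, "run_config"))
  switch(
    name,
    "clean" = {
      .require_artifact(config$raw_metadata, "make-fixtures (or provide a metadata CSV)")
      raw <- read_corpus_metadata(config$raw_metadata)
      n_clusters <- length(unique(raw$cord_uid))
      cleaned <- clean_corpus(raw, min_year = config$min_year,
                              exclusion_terms = config$exclusion_terms)
      merged <- sum(table(raw$cord_uid[raw$cord_uid %in% cleaned$record_id]) > 1L)
      .atomic_file(config$clean_metadata, function(p) write_corpus(cleaned, p))
      .lg_log("clean: %d row(s) in, %d record(s) kept, %d dropped, %d cluster(s) merged",
              nrow(raw), nrow(cleaned), nrow(raw) - nrow(cleaned), merged)
      invisible(list(rows_in = nrow(raw), kept = nrow(cleaned),
                     dropped = nrow(raw) - nrow(cleaned), clusters_merged = merged))
    },
    "annotate" = {
      .require_artifact(config$clean_metadata, "clean")
      .require_artifact(config$lexicon, "make-fixtures (or provide a lexicon TSV)")
      records <- read_corpus(config$clean_metadata)
      lexicon <- load_lexicon(config$lexicon, config$utility)
      mentions <- extract_mentions(records, lexicon)
      .atomic_file(config$mentions, function(p) write_mentions(mentions, p))
      .lg_log("annotate: %d mention(s) in %d of %d document(s)",
              nrow(mentions), length(unique(mentions$record_id)), nrow(records))
      invisible(list(mentions = nrow(mentions), documents = nrow(records)))
    },
    "build-network" = {
      .require_artifact(config$mentions, "annotate")
      .require_artifact(config$clean_metadata, "clean")
      records <- read_corpus(config$clean_metadata)
      lexicon <- load_lexicon(config$lexicon, config$utility)
      mentions <- read_mentions(config$mentions)
      entities <- curate_entities(mentions, lexicon, threshold = config$threshold)
      de <- doc_entity_table(mentions, entities)
      pre <- nrow(build_cooccurrences(de))
      network <- build_network(entities, de, corpus_size = nrow(records),
                               min_npmi = config$min_npmi,
                               separator = config$separator)
      report <- withCallingHandlers(connectivity_report(network),
                                    warning = function(w) invokeRestart("muffleWarning"))
      .atomic_file(config$network_dir, function(p) write_network(network, p))
      .lg_log("build-network: %d entit(ies), %d edge(s) before pruning, %d after (npmi > %g), %d component(s)",
              nrow(entities), pre, nrow(network$edges), config$min_npmi,
              report$component_count)
      invisible(list(entities = nrow(entities), edges_pre = pre,
                     edges_post = nrow(network$edges),
                     components = report$component_count))
    },
    "index" = {
      .require_artifact(file.path(config$network_dir, "edges.tsv"), "build-network")
      .require_artifact(config$mentions, "annotate")
      network <- read_network(config$network_dir)
      mentions <- read_mentions(config$mentions)
      de <- doc_entity_table(mentions, network$nodes)
      index <- build_inverted_index(network$edges, de)
      .atomic_file(config$index, function(p) write_inverted_index(index, p))
      .lg_log("index: %d posting list(s), %d posting(s)",
              length(index$key), sum(lengths(index$postings)))
      invisible(list(lists = length(index$key),
                     postings = sum(lengths(index$postings))))
    },
    "search" = {
      .require_artifact(file.path(config$network_dir, "edges.tsv"), "build-network")
      .require_artifact(config$index, "index")
      .require_artifact(config$clean_metadata, "clean")
      .require_artifact(config$query, "none (provide a query JSON)")
      network <- read_network(config$network_dir)
      index <- read_inverted_index(config$index)
      records <- read_corpus(config$clean_metadata)
      qj <- read_query_json(config$query)
      expansions <- expand_query(qj$query, network, k = config$k_paths)
      for (key in names(qj$selections)) {
        pair <- strsplit(key, "|", fixed = TRUE)[[1L]]
        expansions <- select_path(expansions, pair, qj$selections[[key]])
      }
      results <- retrieve_and_rank(expansions, index, metadata = records,
                                   top = config$top, rank_by = config$rank_by)
      .atomic_file(config$results, function(p) {
        out <- results
        out$publish_time <- format(out$publish_time, "%Y-%m-%d")
        out$score <- sprintf("%.15g", out$score)
        out$npmi_sum <- sprintf("%.15g", out$npmi_sum)
        out$explained <- sprintf("%.15g", out$explained)
        utils::write.table(out, p, sep = "\t", quote = FALSE, na = "",
                           row.names = FALSE, fileEncoding = "UTF-8")
      })
      .lg_log("search: %d result(s) for %d query edge(s)",
              nrow(results), length(expansions))
      invisible(list(results = nrow(results), query_edges = length(expansions)))
    },
    "make-fixtures" = {
      fix <- figure6_fixture()
      out_dir <- dirname(config$raw_metadata)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      .atomic_file(config$raw_metadata, function(p)
        utils::write.csv(fix$metadata, p, row.names = FALSE, na = "",
                         fileEncoding = "UTF-8"))
      .atomic_file(config$lexicon, function(p) write_lexicon(fix$lexicon, p))
      utility_path <- if (is.null(config$utility)) {
        file.path(out_dir, "utility.txt")
      } else config$utility
      .atomic_file(utility_path, function(p)
        writeLines(fix$lexicon$terms$surface[fix$lexicon$terms$is_utility], p,
                   useBytes = TRUE))
      .atomic_file(config$query, function(p) {
        jsonlite::write_json(
          list(nodes = fix$query$nodes,
               edges = lapply(seq_len(nrow(fix$query$edges)), function(i)
                 c(fix$query$edges$name_x[i], fix$query$edges$name_y[i]))),
          p, auto_unbox = TRUE)
      })
      expected_path <- file.path(out_dir, "expected_ranking.tsv")
      .atomic_file(expected_path, function(p) {
        out <- fix$expected_ranking
        out$score <- sprintf("%.15g", out$score)
        utils::write.table(out, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
      })
      # a ready-to-run config pointing every stage at this directory
      .atomic_file(file.path(out_dir, "run.cfg"), function(p) {
        writeLines(c(
          sprintf("raw_metadata = %s", config$raw_metadata),
          sprintf("clean_metadata = %s", file.path(out_dir, "metadata_clean.csv")),
          sprintf("lexicon = %s", config$lexicon),
          sprintf("utility = %s", utility_path),
          sprintf("mentions = %s", file.path(out_dir, "mentions.tsv")),
          sprintf("network_dir = %s", file.path(out_dir, "network")),
          sprintf("index = %s", file.path(out_dir, "index.jsonl")),
          sprintf("query = %s", config$query),
          sprintf("results = %s", file.path(out_dir, "results.tsv"))
        ), p, useBytes = TRUE)
      })
      .lg_log("make-fixtures: %d document(s), %d lexicon term(s) written to %s",
              nrow(fix$metadata), nrow(fix$lexicon$terms), out_dir)
      invisible(list(documents = nrow(fix$metadata),
                     terms = nrow(fix$lexicon$terms)))
    }
  )
}

#' Run the whole pipeline
#'
#' Convenience wrapper executing clean, annotate, build-network, index and
#' (when a query file is configured and present) search, in order.
#'
#' @param config a `run_config`.
#' @return invisibly, a named list of per-stage counters.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- list(
    clean = run_stage("clean", config),
    annotate = run_stage("annotate", config),
    `build-network` = run_stage("build-network", config),
    index = run_stage("index", config)
  )
  if (!is.null(config$query) && file.exists(config$query)) {
    out$search <- run_stage("search", config)
  }
  invisible(out)
}
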