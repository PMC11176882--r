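#' Specification for a synthetic corpus
#'
#' Defines the generating conditions for a random synthetic corpus: the
#' vocabulary, a per-entity baseline mention probability, and pair affinities
#' that inflate joint mentions of chosen pairs. The seed fully determines the
#' output.
#'
#' @param n_docs number of documents.
#' @param vocabulary a `litgraph_lexicon` or a character vector of concept
#'   names (turned into a synthetic lexicon with generated ids).
#' @param baseline_rate per-entity mention probability in `[0, 1]`
#'   (default 0.05).
#' @param pair_affinities optional data frame `a, b, prob` of entity pairs and
#'   their extra co-mention probability.
#' @param seed integer RNG seed.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs, vocabulary, baseline_rate = 0.05,
                        pair_affinities = NULL, seed = 1L) {
  if (is.character(vocabulary)) {
    if (!length(vocabulary)) stop("empty vocabulary", call. = FALSE)
    vocabulary <- make_lexicon(data.frame(
      surface = normalize_surface(vocabulary), name = vocabulary,
      umls_id = sprintf("C90%05d", seq_along(vocabulary)),
      cido_id = NA_character_, macrocategory = "CONCEPTS_AND_IDEAS",
      type = "Synthetic Concept", stringsAsFactors = FALSE
    ), utility = character(0))
  }
  stopifnot(inherits(vocabulary, "litgraph_lexicon"))
  if (nrow(vocabulary$terms) == 0L) stop("empty vocabulary", call. = FALSE)
  if (baseline_rate < 0 || baseline_rate > 1) {
    stop("baseline_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(pair_affinities)) {
    stopifnot(all(c("a", "b", "prob") %in% names(pair_affinities)))
    if (any(pair_affinities$prob < 0 | pair_affinities$prob > 1)) {
      stop("pair affinities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_docs = as.integer(n_docs), vocabulary = vocabulary,
                 baseline_rate = baseline_rate,
                 pair_affinities = pair_affinities, seed = as.integer(seed)),
            class = "corpus_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.compose_abstract <- function(surfaces) {
  if (!length(surfaces)) {
    return("This synthetic report tracks no study concepts and serves as background text.")
  }
  paste0("In this synthetic report we investigate ",
         paste(surfaces, collapse = " together with "),
         " across a cohort of patients.")
}

#' Render per-document entity sets as a metadata table
#'
#' Deterministic composer used by the synthetic fixtures: each document's
#' abstract is a bag of entity surface forms joined by filler words chosen so
#' that the dictionary matcher recovers the planted entity sets exactly.
#'
#' @param doc_sets named list: record id -> character vector of concept names
#'   (possibly empty).
#' @param dates optional Date vector (one per document); default consecutive
#'   days from `start_date`.
#' @param start_date first publication date (default `"2020-03-01"`).
#' @return metadata data frame in the input-CSV dialect (`cord_uid, title,
#'   abstract, publish_time, journal, authors, doi, num_cited_by`).
#' @export
synthetic_metadata <- function(doc_sets, dates = NULL, start_date = "2020-03-01") {
  n <- length(doc_sets)
  if (is.null(dates)) {
    dates <- as.Date(start_date) + seq_len(n) - 1L
  }
  data.frame(
    cord_uid = names(doc_sets),
    title = sprintf("Synthetic co-mention report %d", seq_len(n)),
    abstract = vapply(doc_sets, function(e) .compose_abstract(e), character(1),
                      USE.NAMES = FALSE),
    publish_time = format(as.Date(dates), "%Y-%m-%d"),
    journal = "Synthetic Journal of Fixtures",
    authors = "Fixture, A.; Fixture, B.",
    doi = sprintf("10.9999/synthetic.%04d", seq_len(n)),
    num_cited_by = as.character(seq_len(n) %% 7L),
    stringsAsFactors = FALSE
  )
}

#' Generate a random synthetic corpus
#'
#' Draws per-document entity sets under the spec (independent baseline
#' mentions plus pair-affinity co-mentions) and renders them as a metadata
#' table via [synthetic_metadata()]. Output is fully determined by the spec's
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec a `corpus_spec`.
#' @return list with `metadata` (data frame), `lexicon`
#'   (`litgraph_lexicon`) and `doc_sets` (the planted entity sets).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  vocab <- spec$vocabulary$terms$name
  .with_seed(spec$seed, {
    doc_sets <- lapply(seq_len(spec$n_docs), function(i) {
      ents <- vocab[stats::runif(length(vocab)) < spec$baseline_rate]
      if (!is.null(spec$pair_affinities)) {
        hit <- stats::runif(nrow(spec$pair_affinities)) < spec$pair_affinities$prob
        ents <- c(ents, spec$pair_affinities$a[hit], spec$pair_affinities$b[hit])
      }
      sort(unique(ents), method = "radix")
    })
    names(doc_sets) <- sprintf("doc%05d", seq_len(spec$n_docs))
    dates <- as.Date("2020-01-01") +
      sample.int(1096L, spec$n_docs, replace = TRUE) - 1L  # 2020-2022
    surfaces <- lapply(doc_sets, function(e) {
      spec$vocabulary$terms$surface[match(e, spec$vocabulary$terms$name)]
    })
    md <- synthetic_metadata(surfaces, dates = dates)
    list(metadata = md, lexicon = spec$vocabulary, doc_sets = doc_sets)
  })
}

.fig6_nodes <- function() {
  data.frame(
    name = c("SARS-CoV-2", "ACE2", "AngII", "Vascular Permeability",
             "Infection", "Hypertension",
             "(1,0)", "(0,1)", "(0,2)", "(1,1)", "(1,2)", "(2,1)", "(2,2)"),
    macrocategory = c("LIVING_BEINGS", "GENES_AND_MOLECOLAR_SEQUENCES",
                      "CHEMICALS_AND_DRUGS", "PHYSIOLOGY", "DISORDERS",
                      "DISORDERS", rep("CONCEPTS_AND_IDEAS", 7L)),
    type = c("Virus", "Gene or Genome", "Hormone", "Organ or Tissue Function",
             "Disease or Syndrome", "Disease or Syndrome",
             rep("Synthetic Concept", 7L)),
    stringsAsFactors = FALSE
  )
}

#' Running-example fixture
#'
#' A fully synthetic, hand-designed corpus reproducing the running-example
#' search: a 6-concept, 5-relationship graph query over a 13-node network in
#' which the SARS-CoV-2—ACE2 edge expands into exactly three candidate paths
#' of length 3, the AngII—Vascular Permeability edge expands into one path of
#' length 2 through the intermediate "(1,0)", and the remaining three query
#' edges are matched directly. Intermediate nodes carry the figure's
#' coordinate-style labels; since those labels are expansion-local in the
#' figure, globally unique variants ("(0,1)", "(0,2)", ...) are used and all
#' concept ids are synthetic.
#'
#' Publication `pub001` explains the whole query except half of the selected
#' AngII path (addends 1, 1, 1, 1, 1/2; score 4.5); `pub002` misses the first
#' relationship of the selected SARS-CoV-2—ACE2 path and the whole AngII path
#' (addends 1, 1, 1, 2/3, 0; score 11/3). Background documents instantiate
#' every designed relationship with positive NPMI and fix the candidate-path
#' ranking; singleton documents depress the NPMI of the alternative paths'
#' intermediates so the "(0,*)" path ranks first.
#'
#' The abstracts regenerate the designed posting lists when pushed through the
#' full pipeline (clean, annotate, build-network, index).
#'
#' @return list with `metadata`, `lexicon`, `doc_sets` (record id -> entity
#'   names), `network` (the designed 14-edge `cooc_network` with honestly
#'   computed statistics), `index`, `query` (a `graph_query`),
#'   `expected_ranking` (data frame `record_id, score`), and `designed_edges`
#'   (the 14 name pairs).
#' @export
figure6_fixture <- function() {
  S <- "SARS-CoV-2"; ACE2 <- "ACE2"; AngII <- "AngII"
  VP <- "Vascular Permeability"; Inf_ <- "Infection"; Hyp <- "Hypertension"

  rep_sets <- function(sets, times) rep(sets, times)
  doc_sets <- c(
    list(pub001 = c(S, "(0,1)", "(0,2)", ACE2, AngII, "(1,0)", Inf_, Hyp),
         pub002 = c(ACE2, AngII, Inf_, Hyp, "(0,1)", "(0,2)")),
    rep_sets(list(c(S, "(0,1)")), 4L), rep_sets(list(c("(0,1)", "(0,2)")), 4L),
    rep_sets(list(c("(0,2)", ACE2)), 4L),
    rep_sets(list(c(S, "(1,1)")), 4L), rep_sets(list(c("(1,1)", "(1,2)")), 4L),
    rep_sets(list(c("(1,2)", ACE2)), 4L),
    rep_sets(list(c(S, "(2,1)")), 4L), rep_sets(list(c("(2,1)", "(2,2)")), 4L),
    rep_sets(list(c("(2,2)", ACE2)), 4L),
    rep_sets(list(c(AngII, "(1,0)")), 4L), rep_sets(list(c("(1,0)", VP)), 4L),
    rep_sets(list(c(ACE2, Inf_)), 6L), rep_sets(list(c(ACE2, AngII)), 6L),
    rep_sets(list(c(AngII, Hyp)), 6L),
    rep_sets(list("(1,1)"), 2L), rep_sets(list("(1,2)"), 2L),
    rep_sets(list("(2,1)"), 6L), rep_sets(list("(2,2)"), 2L)
  )
  nbg <- length(doc_sets) - 2L
  names(doc_sets)[-(1:2)] <- sprintf("bg%03d", seq_len(nbg))

  ndef <- .fig6_nodes()
  lexicon <- make_lexicon(data.frame(
    surface = normalize_surface(ndef$name), name = ndef$name,
    umls_id = sprintf("C91%05d", seq_len(nrow(ndef))),
    cido_id = NA_character_,
    macrocategory = ndef$macrocategory, type = ndef$type,
    stringsAsFactors = FALSE
  ), utility = DEFAULT_UTILITY_TERMS)

  surfaces <- lapply(doc_sets, function(e) {
    lexicon$terms$surface[match(e, lexicon$terms$name)]
  })
  dates <- c(as.Date("2021-06-15"), as.Date("2020-06-15"),
             as.Date("2020-03-01") + seq_len(nbg) - 1L)
  metadata <- synthetic_metadata(surfaces, dates = dates)

  # designed relationships (pair-sorted in C-locale order)
  designed <- rbind(
    c("(0,1)", S), c("(0,1)", "(0,2)"), c("(0,2)", ACE2),
    c("(1,1)", S), c("(1,1)", "(1,2)"), c("(1,2)", ACE2),
    c("(2,1)", S), c("(2,1)", "(2,2)"), c("(2,2)", ACE2),
    c("(1,0)", AngII), c("(1,0)", VP),
    c(ACE2, Inf_), c(ACE2, AngII), c(AngII, Hyp)
  )

  # honest counts from the designed documents
  n <- length(doc_sets)
  freq <- table(unlist(lapply(doc_sets, unique)))
  entities <- data.frame(
    name = ndef$name,
    umls_id = sprintf("C91%05d", seq_len(nrow(ndef))),
    cido_id = NA_character_,
    macrocategory = ndef$macrocategory, type = ndef$type,
    is_utility = FALSE,
    frequency = as.integer(freq[ndef$name]),
    stringsAsFactors = FALSE
  )
  entities <- entities[order(entities$name, method = "radix"), , drop = FALSE]
  rownames(entities) <- NULL

  cooc <- build_cooccurrences(doc_sets)
  dkey <- paste(designed[, 1L], designed[, 2L], sep = "\x1f")
  ckey <- paste(cooc$name_x, cooc$name_y, sep = "\x1f")
  edges <- cooc[match(dkey, ckey), , drop = FALSE]
  stopifnot(!anyNA(edges$frequency))
  fx <- entities$frequency[match(edges$name_x, entities$name)]
  fy <- entities$frequency[match(edges$name_y, entities$name)]
  edges <- cbind(edges, edge_statistics(edges$frequency, fx, fy, n))
  edges$name <- edge_name(edges$name_x, edges$name_y)
  edges <- edges[order(edges$name_x, edges$name_y, method = "radix"),
                 c("name_x", "name_y", "name", "frequency", "pmi", "npmi",
                   "cramers_v"), drop = FALSE]
  rownames(edges) <- NULL
  network <- structure(list(nodes = entities, edges = edges, corpus_size = n,
                            separator = "—", log_base = exp(1)),
                       class = "cooc_network")
  index <- build_inverted_index(edges, doc_sets)

  query <- graph_query(
    nodes = c(S, ACE2, AngII, VP, Inf_, Hyp),
    edges = list(c(S, ACE2), c(ACE2, AngII), c(AngII, VP),
                 c(ACE2, Inf_), c(AngII, Hyp))
  )

  list(metadata = metadata, lexicon = lexicon, doc_sets = doc_sets,
       network = network, index = index, query = query,
       expected_ranking = data.frame(record_id = c("pub001", "pub002"),
                                     score = c(4.5, 11 / 3),
                                     stringsAsFactors = FALSE),
       designed_edges = designed)
}
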