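test_that("co-occurrence counting matches the examples and ignores singleton documents", {
  docs <- list(d1 = c("A", "B"), d2 = c("A", "B", "C"), d3 = "C")
  edges <- build_cooccurrences(docs)
  expect_equal(edges$frequency[edges$name_x == "A" & edges$name_y == "B"], 2L)
  expect_equal(edges$frequency[edges$name_x == "A" & edges$name_y == "C"], 1L)
  expect_equal(edges$frequency[edges$name_x == "B" & edges$name_y == "C"], 1L)
  expect_equal(nrow(edges), 3L)
  expect_equal(nrow(build_cooccurrences(list(d1 = "A"))), 0L)
  expect_equal(nrow(build_cooccurrences(list())), 0L)
})

test_that("single-pass pair counting agrees with brute force on random corpora", {
  for (seed in 1:6) {
    set.seed(seed)
    n_docs <- sample(5:50, 1)
    vocab <- sprintf("e%02d", 1:12)
    docs <- lapply(seq_len(n_docs), function(i) {
      sample(vocab, sample(0:6, 1))
    })
    names(docs) <- sprintf("d%02d", seq_len(n_docs))
    got <- build_cooccurrences(docs)
    want <- oracle_pair_counts(docs)
    want <- want[order(want$name_x, want$name_y, method = "radix"), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("edge statistics reproduce the derived reference values", {
  # N=10, fx=5, fy=4, joint=3
  s <- edge_statistics(3, 5, 4, 10)
  expect_equal(s$npmi, log(1.5) / (-log(0.3)), tolerance = 1e-12)
  expect_equal(s$pmi, log(1.5), tolerance = 1e-12)
  # independence: pmi = npmi = 0
  s0 <- edge_statistics(1, 10, 10, 100)
  expect_equal(s0$pmi, 0)
  expect_equal(s0$npmi, 0)
  # contingency {both=3, x-only=2, y-only=1, neither=4}: V = sqrt((5/3)/10)
  s2 <- edge_statistics(3, 5, 4, 10)
  expect_equal(s2$cramers_v, sqrt((5 / 3) / 10), tolerance = 1e-12)
  # independent cross-check of chi-squared against stats::chisq.test
  tab <- matrix(c(3, 2, 1, 4), 2, 2, byrow = TRUE)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(s2$cramers_v, sqrt(unname(chi$statistic) / 10), tolerance = 1e-12)
})

test_that("NPMI respects its bounds, limits and base invariance", {
  # perfectly co-occurring pair below saturation: npmi = 1
  expect_equal(edge_statistics(3, 3, 3, 10)$npmi, 1)
  # saturated pair p(x,y)=1 defined as 1 by limit
  expect_message(s <- edge_statistics(10, 10, 10, 10), "limit")
  expect_equal(s$npmi, 1)
  # base invariance: npmi identical whatever base reports the pmi
  nat <- edge_statistics(3, 5, 4, 10, log_base = exp(1))
  b2 <- edge_statistics(3, 5, 4, 10, log_base = 2)
  expect_equal(nat$npmi, b2$npmi)
  expect_equal(b2$pmi * log(2), nat$pmi)
  # monotone in joint frequency with marginals fixed
  npmis <- vapply(1:5, function(j) edge_statistics(j, 5, 6, 20)$npmi, numeric(1))
  expect_true(all(diff(npmis) > 0))
  # bounds on a sweep of valid configurations
  for (n in c(10, 40)) {
    for (fx in c(2, 5, n %/% 2)) for (fy in c(2, 5, n %/% 2)) {
      for (j in seq_len(min(fx, fy))) {
        s <- edge_statistics(j, fx, fy, n)
        expect_gte(s$npmi, -1); expect_lte(s$npmi, 1)
        expect_gte(s$cramers_v, 0); expect_lte(s$cramers_v, 1)
      }
    }
  }
  expect_error(edge_statistics(1, 0, 4, 10), "marginal")
  expect_error(edge_statistics(5, 4, 4, 10), "joint")
})

test_that("pruning removes non-positive NPMI edges, strictly", {
  edges <- data.frame(name_x = c("A", "A", "B"), name_y = c("B", "C", "C"),
                      npmi = c(-0.1, 0, 0.2), stringsAsFactors = FALSE)
  kept <- prune_edges(edges)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$npmi, 0.2)
})

test_that("edge names are pair-sorted and endpoints never re-parsed from the name", {
  expect_equal(edge_name("Zeta", "Alpha"), "Alpha—Zeta")
  expect_equal(edge_name("(1,0)", "AngII"), "(1,0)—AngII")
  expect_equal(edge_name("A", "B", separator = "--"), "A--B")
  fix <- figure6_fixture()
  net <- fix$network
  expect_equal(net$edges$name, edge_name(net$edges$name_x, net$edges$name_y))
  # endpoint pair round-trips through the index without parsing the name
  for (i in seq_len(nrow(net$edges))) {
    expect_identical(
      index_postings(fix$index, c(net$edges$name_y[i], net$edges$name_x[i])),
      fix$index$postings[[i]])
  }
})

test_that("connectivity report matches a union-find oracle", {
  mknet <- function(nodes, edges_df) {
    structure(list(
      nodes = data.frame(name = nodes, umls_id = NA_character_, cido_id = NA_character_,
                         macrocategory = "CONCEPTS_AND_IDEAS", type = NA_character_,
                         is_utility = FALSE, frequency = 1L, stringsAsFactors = FALSE),
      edges = edges_df, corpus_size = 10L, separator = "—", log_base = exp(1)),
      class = "cooc_network")
  }
  tri <- data.frame(name_x = c("A", "A", "B"), name_y = c("B", "C", "C"),
                    stringsAsFactors = FALSE)
  rep1 <- connectivity_report(mknet(c("A", "B", "C"), tri))
  expect_true(rep1$is_single_component)
  expect_equal(rep1$component_count, 1L)

  two <- data.frame(name_x = c("A", "C"), name_y = c("B", "D"), stringsAsFactors = FALSE)
  expect_warning(rep2 <- connectivity_report(mknet(c("A", "B", "C", "D"), two)),
                 "components")
  expect_equal(rep2$component_count, 2L)

  # pruning that isolates a node increases the component count accordingly
  for (seed in 1:5) {
    net <- random_network(12, 6, seed)
    net$edges$npmi <- stats::runif(nrow(net$edges), -0.5, 0.5)
    net$edges <- prune_edges(net$edges)
    got <- suppressWarnings(connectivity_report(net))
    want <- oracle_components(net$nodes$name, net$edges)
    expect_equal(got$component_count, length(want))
    expect_equal(got$sizes, want)
  }
})

test_that("inverted-index posting lists recount the documents exactly", {
  docs <- list(d2 = c("A", "B", "C"), d1 = c("A", "B"), d3 = c("C", "A"))
  edges <- build_cooccurrences(docs)
  edges$name <- edge_name(edges$name_x, edges$name_y)
  idx <- build_inverted_index(edges, docs)
  expect_equal(index_postings(idx, "A—B"), c("d1", "d2"))
  # |postings[e]| equals e.frequency for every edge, recounted by brute scan
  for (i in seq_along(idx$key)) {
    brute <- sort(names(Filter(function(s)
      all(c(idx$name_x[i], idx$name_y[i]) %in% s), docs)), method = "radix")
    expect_identical(idx$postings[[i]], brute)
    expect_equal(length(idx$postings[[i]]), edges$frequency[i])
  }
  # key miss: empty postings with a message, not an error
  expect_message(p <- index_postings(idx, "A—Z"), "no posting list")
  expect_equal(p, character(0))
})

test_that("network serialization round-trips", {
  fix <- figure6_fixture()
  dir <- tempfile()
  write_network(fix$network, dir)
  back <- read_network(dir)
  expect_equal(back$edges$name, fix$network$edges$name)
  expect_equal(back$edges$npmi, fix$network$edges$npmi, tolerance = 1e-12)
  expect_equal(back$nodes$frequency, fix$network$nodes$frequency)
  expect_equal(back$corpus_size, fix$network$corpus_size)
  idx_path <- tempfile(fileext = ".jsonl")
  write_inverted_index(fix$index, idx_path)
  idx2 <- read_inverted_index(idx_path)
  expect_identical(idx2$key, fix$index$key)
  expect_identical(idx2$postings, fix$index$postings)
})
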