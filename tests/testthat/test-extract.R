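mention_row <- function(start, end, cui, group, doc = "D1", sent = 1L) {
  data.frame(doc_id = doc, sentence_index = sent, start = start, end = end,
             surface = paste0("m", start), cui = cui,
             semantic_group = group, provenance = "DICTIONARY",
             stringsAsFactors = FALSE)
}

test_that("candidate generation is the within-sentence cross product", {
  drug <- function(s, cui = "CD1") mention_row(s, s + 4L, cui,
                                               "CHEMICALS_AND_DRUGS")
  dis <- function(s, cui = "CE1") mention_row(s, s + 4L, cui, "DISORDERS")
  # one drug, two disorders -> two candidates
  m <- rbind(drug(0L), dis(10L), dis(20L, "CE2"))
  cand <- generate_candidates(m)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$effect_start, c(10L, 20L))
  # drugs only -> none; 2 x 2 -> 4, ordered by drug then effect start
  expect_equal(nrow(generate_candidates(rbind(drug(0L), drug(8L)))), 0L)
  m4 <- rbind(drug(0L), drug(8L, "CD2"), dis(16L), dis(24L, "CE2"))
  cand4 <- generate_candidates(m4)
  expect_equal(nrow(cand4), 4L)
  expect_equal(cand4$drug_start, c(0L, 0L, 8L, 8L))
  # identical spans (ambiguous drug/disorder reading) are excluded
  both <- rbind(drug(0L), mention_row(0L, 4L, "CE9", "DISORDERS"))
  expect_equal(nrow(generate_candidates(both)), 0L)
  # multi-CUI mentions group into one candidate with CUI sets
  mm <- rbind(drug(0L), drug(0L, "CD2"), dis(10L))
  cm <- generate_candidates(mm)
  expect_equal(nrow(cm), 1L)
  expect_setequal(cm$drug_cuis[[1L]], c("CD1", "CD2"))
})

diamond_graph <- function(types_top = "clean", types_bot = "clean") {
  concept_graph(data.frame(
    cui_a = c("D", "B1", "D", "B2"),
    cui_b = c("B1", "E", "B2", "E"),
    relation_type = c(types_top, types_top, types_bot, types_bot),
    stringsAsFactors = FALSE))
}

cand1 <- function(drug_cuis = "D", effect_cuis = "E") {
  out <- data.frame(doc_id = "D1", sentence_index = 1L, drug_start = 0L,
                    drug_end = 4L, drug_surface = "d", effect_start = 10L,
                    effect_end = 14L, effect_surface = "e",
                    stringsAsFactors = FALSE)
  out$drug_cuis <- list(drug_cuis)
  out$effect_cuis <- list(effect_cuis)
  out
}

test_that("the distance threshold governs acceptance", {
  chain <- concept_graph(data.frame(
    cui_a = c("D", "x1", "x2", "x3", "x4"),
    cui_b = c("x1", "x2", "x3", "x4", "E"),
    relation_type = "t", stringsAsFactors = FALSE))
  cfg4 <- extraction_config(distance_threshold = 4)
  dec <- decide_relation(cand1(), chain, cfg4)
  expect_false(dec$accept)            # distance 5 > 4
  expect_equal(dec$distance, 5L)
  cfg5 <- extraction_config(distance_threshold = 5)
  expect_true(decide_relation(cand1(), chain, cfg5)$accept)
  # concepts absent from the graph: infinite distance, rejected quietly
  dec2 <- decide_relation(cand1(drug_cuis = "NOPE"), chain, cfg4)
  expect_false(dec2$accept)
  expect_equal(dec2$distance, Inf)
  # multi-CUI grounding takes the minimum distance
  dec3 <- decide_relation(cand1(drug_cuis = c("NOPE", "x3")), chain, cfg4)
  expect_true(dec3$accept)
  expect_equal(dec3$distance, 2L)
  expect_equal(dec3$drug_cui, "x3")
})

test_that("path-level filtering distinguishes tainted shortest paths", {
  g <- diamond_graph(types_top = "clean", types_bot = "noise")
  cfg <- extraction_config()
  filt <- relation_type_filter(data.frame(
    relation_type = "noise", tp = 0, fp = 20, stringsAsFactors = FALSE))
  expect_equal(filt$discarded, "noise")
  # one of two shortest paths survives
  dec <- decide_relation(cand1(), g, cfg, filt)
  expect_true(dec$accept)
  expect_equal(dec$surviving_path_count, 1L)
  # strict mode rejects when any path is tainted
  cfg_all <- extraction_config(filter_mode = "all_paths_clean")
  expect_false(decide_relation(cand1(), g, cfg_all, filt)$accept)
  # both paths tainted: rejected in either mode
  g2 <- diamond_graph(types_top = "noise", types_bot = "noise")
  dec2 <- decide_relation(cand1(), g2, cfg, filt)
  expect_false(dec2$accept)
  expect_equal(dec2$surviving_path_count, 0L)
  # an empty discard set behaves exactly like no filter at all
  filt0 <- relation_type_filter(data.frame(
    relation_type = "noise", tp = 20, fp = 0, stringsAsFactors = FALSE))
  expect_equal(decide_relation(cand1(), g2, cfg, filt0)$accept,
               decide_relation(cand1(), g2, cfg, NULL)$accept)
})

test_that("the ratio rule uses strict inequality at seven", {
  stats <- data.frame(relation_type = c("at7", "above7", "clean"),
                      tp = c(1, 1, 30), fp = c(13, 20, 2),
                      stringsAsFactors = FALSE)
  filt <- relation_type_filter(stats, type_ratio_threshold = 7)
  # (13+1)/(1+1) = 7 is retained; (20+1)/(1+1) = 10.5 is discarded
  expect_equal(filt$stats$ratio[filt$stats$relation_type == "at7"], 7)
  expect_false("at7" %in% filt$discarded)
  expect_equal(filt$discarded, "above7")
})

test_that("filter training recovers the planted noise type exactly", {
  fx <- default_test_fixture(n_documents = 80L)
  sp <- split_corpus(fx$corpus, 50L, seed = 11L)
  m <- apply_nlp_rules(recognize_corpus(sp$train, fx$res$lexicon),
                       sp$train, fx$res$lexicon)
  filt <- train_relation_type_filter(sp$train, m, fx$res$graph,
                                     extraction_config())
  expect_identical(filt$discarded, fx$spec$noise_relation_type)
  # clean types accumulate true-positive occurrences only
  clean <- filt$stats[filt$stats$relation_type !=
                        fx$spec$noise_relation_type, ]
  expect_true(all(clean$fp == 0))
  expect_true(all(clean$tp > 0))
  # empty training input yields an empty filter with a warning
  empty <- subset_corpus(sp$train, character(0))
  expect_warning(f0 <- train_relation_type_filter(
    empty, m[0L, ], fx$res$graph, extraction_config()), "empty")
  expect_length(f0$discarded, 0L)
})

test_that("filter files round-trip through JSON", {
  stats <- data.frame(relation_type = c("a", "b"), tp = c(3, 0),
                      fp = c(1, 25), stringsAsFactors = FALSE)
  filt <- relation_type_filter(stats)
  path <- withr::local_tempfile(fileext = ".json")
  write_relation_type_filter(filt, path)
  back <- read_relation_type_filter(path)
  expect_equal(back$stats, filt$stats)
  expect_equal(back$discarded, filt$discarded)
  expect_equal(back$type_ratio_threshold, 7)
})

test_that("prediction sets are nested across distance thresholds", {
  fx <- default_test_fixture(n_documents = 40L)
  lex <- fx$res$lexicon
  m <- apply_nlp_rules(recognize_corpus(fx$corpus, lex), fx$corpus, lex)
  keys <- function(r) paste(r$doc_id, r$drug_start, r$effect_start)
  prev <- NULL
  prev_recall <- -1
  for (th in 1:5) {
    cfg <- extraction_config(distance_threshold = th, horizon = 6)
    pred <- extract_relations(fx$corpus, lex, fx$res$graph, cfg,
                              mentions = m, nlp = NULL)
    if (!is.null(prev)) expect_true(all(prev %in% keys(pred)))
    rec <- match_exact(pred, fx$corpus$relations)$metrics$recall
    expect_gte(rec, prev_recall)
    prev <- keys(pred)
    prev_recall <- rec
  }
  # co-occurrence mode accepts every candidate
  cooc <- extract_relations(fx$corpus, lex, fx$res$graph,
                            extraction_config(distance_threshold = Inf),
                            mentions = m, nlp = NULL)
  expect_equal(nrow(cooc), nrow(generate_candidates(m)))
  # applying a relation-type filter never adds relations
  sp <- split_corpus(fx$corpus, 15L, seed = 2L)
  mt <- apply_nlp_rules(recognize_corpus(sp$train, lex), sp$train, lex)
  filt <- train_relation_type_filter(sp$train, mt, fx$res$graph,
                                     extraction_config())
  cfg <- extraction_config()
  no_filter <- extract_relations(fx$corpus, lex, fx$res$graph, cfg,
                                 mentions = m, nlp = NULL)
  with_filter <- extract_relations(fx$corpus, lex, fx$res$graph, cfg,
                                   filter = filt, mentions = m, nlp = NULL)
  expect_true(all(keys(with_filter) %in% keys(no_filter)))
  rec_nf <- match_exact(no_filter, fx$corpus$relations)$metrics$recall
  rec_wf <- match_exact(with_filter, fx$corpus$relations)$metrics$recall
  expect_lte(rec_wf, rec_nf)
})

test_that("extraction is deterministic and carries a run manifest", {
  fx <- default_test_fixture(n_documents = 20L)
  r1 <- extract_relations(fx$corpus, fx$res$lexicon, fx$res$graph)
  r2 <- extract_relations(fx$corpus, fx$res$lexicon, fx$res$graph)
  expect_identical(r1, r2)
  man <- attr(r1, "manifest")
  expect_equal(man$n_accepted, nrow(r1))
  expect_true(man$n_candidates >= man$n_accepted)
  # empty corpus: empty output, still a valid manifest
  e <- extract_relations(subset_corpus(fx$corpus, character(0)),
                         fx$res$lexicon, fx$res$graph)
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "manifest")$n_candidates, 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relations_tsv(r1, path)
  expect_equal(nrow(utils::read.delim(path)), nrow(r1))
})
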