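rel_df <- function(doc, ds, de, es, ee, sent = 1L) {
  data.frame(doc_id = doc, sentence_index = sent,
             drug_text = "d", drug_start = ds, drug_end = de,
             effect_text = "e", effect_start = es, effect_end = ee,
             stringsAsFactors = FALSE)
}

test_that("boundary-exact matching gives no partial credit", {
  gold <- rbind(rel_df("a", 0L, 4L, 10L, 14L),
                rel_df("a", 20L, 24L, 30L, 34L),
                rel_df("b", 0L, 4L, 10L, 14L))
  # one span off by one character: FP + FN, not a match
  pred <- rbind(rel_df("a", 0L, 4L, 10L, 14L),
                rel_df("a", 20L, 24L, 30L, 35L))
  res <- match_exact(pred, gold)
  expect_equal(res$metrics$tp, 1L)
  expect_equal(res$metrics$fp, 1L)
  expect_equal(res$metrics$fn, 2L)
  # identical sets of size k score perfectly
  res2 <- match_exact(gold, gold)
  expect_equal(unlist(res2$metrics[c("tp", "fp", "fn")]), c(3L, 0L, 0L),
               ignore_attr = TRUE)
  expect_equal(res2$metrics$f_score, 100)
  # duplicates collapse before matching; counts stay additive
  res3 <- match_exact(rbind(pred, pred), gold)
  expect_equal(res3$metrics$tp + res3$metrics$fp, 2L)
  expect_equal(res3$metrics$tp + res3$metrics$fn,
               nrow(unique(gold)))
})

test_that("metrics equal a brute-force set comparison on random spans", {
  withr::with_seed(17L, {
    for (k in 1:50) {
      mk <- function(n) rel_df("d", sample(0:5, n, TRUE) * 10L,
                               sample(1:3, n, TRUE) + 60L,
                               sample(0:5, n, TRUE) * 10L + 100L,
                               sample(1:3, n, TRUE) + 160L)
      gold <- mk(sample(1:6, 1L))
      pred <- mk(sample(1:6, 1L))
      res <- match_exact(pred, gold)
      key <- function(x) unique(paste(x$doc_id, x$drug_start, x$drug_end,
                                      x$effect_start, x$effect_end))
      expect_equal(res$metrics$tp, length(intersect(key(pred), key(gold))))
      expect_equal(res$metrics$fp, length(setdiff(key(pred), key(gold))))
      expect_equal(res$metrics$fn, length(setdiff(key(gold), key(pred))))
    }
  })
})

test_that("the F-score is symmetric, bounded, and zero-safe", {
  expect_equal(f_score(100, 100), 100)
  expect_equal(f_score(0, 87.3), 0)
  expect_equal(f_score(0, 0), 0)
  withr::with_seed(3L, {
    p <- stats::runif(50, 0, 100)
    r <- stats::runif(50, 0, 100)
    expect_equal(f_score(p, r), f_score(r, p))
    expect_true(all(f_score(p, r) >= pmin(p, r) - 1e-9))
    expect_true(all(f_score(p, r) <= pmax(p, r) + 1e-9))
  })
})

test_that("error cases partition FP and FN into the four kinds", {
  lex <- toy_lexicon(c("alum" = "DRUG", "seizures" = "DIS",
                       "encephalopathy" = "DIS"))
  text <- "Encephalopathy and seizures induced by intravesical alum."
  corpus <- ade_corpus(
    sentence_row(text),
    rbind(
      data.frame(doc_id = "D1", sentence_index = 1L, drug_text = "alum",
                 drug_start = 52L, drug_end = 56L,
                 effect_text = "seizures", effect_start = 19L,
                 effect_end = 27L, stringsAsFactors = FALSE),
      data.frame(doc_id = "D1", sentence_index = 1L, drug_text = "alum",
                 drug_start = 52L, drug_end = 56L,
                 effect_text = "Encephalopathy", effect_start = 0L,
                 effect_end = 14L, stringsAsFactors = FALSE)))
  mentions <- recognize_corpus(corpus, lex)
  # predictions: entities of the seizures relation found but pair rejected
  # (missed -> FN_RELATION_FILTERED); encephalopathy relation missed with
  # no matching mention span -> would be ENTITY_MISSED if unrecognized
  pred <- rel_df("D1", 52L, 56L, 40L, 51L)  # wrong effect span: FP
  res <- match_exact(pred, corpus$relations)
  errs <- categorize_errors(res$unmatched_predicted, res$unmatched_gold,
                            mentions, corpus)
  expect_equal(nrow(errs$cases),
               res$metrics$fp + res$metrics$fn)
  expect_equal(sum(unlist(errs$summary$counts)), errs$summary$total_errors)
  expect_equal(errs$cases$kind[1L], "FP_RELATION_ENTITIES_WRONG")
  filtered <- errs$cases[errs$cases$kind == "FN_RELATION_FILTERED", ]
  expect_equal(nrow(filtered), 2L)   # all entities found, pairs rejected
  # an FP whose two spans both match gold entities is ENTITIES_CORRECT
  pred2 <- rel_df("D1", 52L, 56L, 0L, 14L)
  res2 <- match_exact(pred2, corpus$relations[1L, ])
  errs2 <- categorize_errors(res2$unmatched_predicted, res2$unmatched_gold,
                             mentions, corpus)
  expect_true("FP_RELATION_ENTITIES_CORRECT" %in% errs2$cases$kind)
  # unrecognized gold entity -> FN_ENTITY_MISSED
  errs3 <- categorize_errors(res$unmatched_predicted[0L, ],
                             res$unmatched_gold, mentions[0L, ], corpus)
  expect_true(all(errs3$cases$kind == "FN_ENTITY_MISSED"))
})

test_that("comparison subsets drop nested gold and hit the target ratio", {
  # positive sentences with one gold relation plus one spurious
  # co-occurrence pair (the second disorder), like the classic
  # complication-of construction
  lex <- toy_lexicon(c("methotrexate" = "DRUG", "cisplatin" = "DRUG",
                       "pneumonia" = "DIS", "asthma" = "DIS",
                       "rash" = "DIS"))
  drugs <- c("methotrexate", "cisplatin")
  effs <- c("pneumonia", "asthma", "rash")
  sents <- list()
  rels <- list()
  for (i in 1:60) {
    d <- drugs[i %% 2L + 1L]
    e1 <- effs[i %% 3L + 1L]
    e2 <- effs[(i + 1L) %% 3L + 1L]
    text <- sprintf("%s as a complication of %s treatment of %s.",
                    e1, d, e2)
    doc <- sprintf("d%02d", i)
    sents[[i]] <- sentence_row(text, doc_id = doc)
    rels[[i]] <- data.frame(
      doc_id = doc, sentence_index = 1L, drug_text = d,
      drug_start = as.integer(regexpr(d, text)) - 1L,
      drug_end = as.integer(regexpr(d, text)) - 1L + nchar(d),
      effect_text = e1, effect_start = 0L, effect_end = nchar(e1),
      stringsAsFactors = FALSE)
  }
  # plant one nested relation: drug span inside the effect span
  ntext <- "acute methotrexate intoxication was seen."
  sents[[61L]] <- sentence_row(ntext, doc_id = "d61")
  nested <- data.frame(doc_id = "d61", sentence_index = 1L,
                       drug_text = "methotrexate", drug_start = 6L,
                       drug_end = 18L,
                       effect_text = "acute methotrexate intoxication",
                       effect_start = 0L, effect_end = 31L,
                       stringsAsFactors = FALSE)
  corpus2 <- ade_corpus(do.call(rbind, sents),
                        rbind(do.call(rbind, rels), nested))
  m <- apply_nlp_rules(recognize_corpus(corpus2, lex), corpus2, lex)
  sub <- build_comparison_subset(corpus2, m, ratio = 1.26, seed = 5L)
  nk <- paste(nested$doc_id, nested$drug_start, nested$effect_start)
  expect_false(nk %in% paste(sub$doc_id, sub$drug_start, sub$effect_start))
  n_pos <- sum(sub$label == "true")
  n_neg <- sum(sub$label == "false")
  expect_equal(n_neg, round(n_pos / 1.26))
  # ratio 1.0 gives exactly as many negatives as positives
  sub1 <- build_comparison_subset(corpus2, m, ratio = 1, seed = 5L)
  expect_equal(sum(sub1$label == "false"), sum(sub1$label == "true"))
  # same seed, same subset; insufficient negatives warn
  expect_identical(sub, build_comparison_subset(corpus2, m, ratio = 1.26,
                                                seed = 5L))
  expect_warning(build_comparison_subset(corpus2, m, ratio = 0.001,
                                         seed = 5L), "achieved ratio")
})

test_that("stage reports are nested and their deltas are row differences", {
  fx <- default_test_fixture(n_documents = 60L)
  sp <- split_corpus(fx$corpus, 15L, seed = 9L)
  mt <- apply_nlp_rules(recognize_corpus(sp$train, fx$res$lexicon),
                        sp$train, fx$res$lexicon)
  filt <- train_relation_type_filter(sp$train, mt, fx$res$graph,
                                     extraction_config())
  rep <- stage_report(sp$test, fx$res$lexicon, fx$res$graph,
                      extraction_config(), filt)
  expect_equal(rep$stage,
               c("dictionary_cooccurrence", "nlp_rules", "knowledge_base",
                 "relation_type_filter"))
  # predictions nest: tp + fp can only shrink after the NLP row
  expect_true(all(diff(rep$tp + rep$fp)[-1L] <= 0))
  expect_equal(rep$delta_f_score[-1L], diff(rep$f_score))
  expect_equal(rep$delta_precision[-1L], diff(rep$precision))
  expect_true(is.na(rep$delta_f_score[1L]))
  # on the planted corpus every stage improves F
  expect_true(all(diff(rep$f_score) > 0))
})
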