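#' Harmonic-mean F-score of precision and recall
#'
#' `2 P R / (P + R)` on percentage inputs, 0 when both are 0. Symmetric in
#' its arguments and always between `min(P, R)` and `max(P, R)`.
#'
#' @param precision,recall percentages in `[0, 100]`.
#' @return the F-score as a percentage (not rounded; reports round to one
#'   decimal).
#' @export
f_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

metrics_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
                 f_score = f_score(p, r)),
            class = "ade_metrics")
}

#' @export
print.ade_metrics <- function(x, ...) {
  cat(sprintf(
    "<ade_metrics> TP %d FP %d FN %d | P %.1f%% R %.1f%% F %.1f%%\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Boundary-exact relation scoring
#'
#' A predicted relation is a true positive iff a gold relation in the same
#' document has an identical drug span and an identical effect span --
#' no partial credit. Unmatched gold relations are false negatives,
#' unmatched predictions false positives. Duplicates (same document and
#' span pair, e.g. from multiple CUIs) collapse before matching, so the
#' counts obey `tp + fn = |gold|` and `tp + fp = |predictions|` on the
#' deduplicated sets.
#'
#' @param predicted data.frame with `doc_id`, `drug_start`, `drug_end`,
#'   `effect_start`, `effect_end` (e.g. [extract_relations()] output).
#' @param gold data.frame of gold relations (`relations` table of an
#'   [ade_corpus()]).
#' @return list with `metrics` (an `ade_metrics`), `matched` (TP
#'   predictions), `unmatched_predicted` (FP), `unmatched_gold` (FN).
#' @export
match_exact <- function(predicted, gold) {
  pk <- relation_keys(predicted)
  gk <- relation_keys(gold)
  pred_u <- predicted[!duplicated(pk), , drop = FALSE]
  gold_u <- gold[!duplicated(gk), , drop = FALSE]
  pk <- pk[!duplicated(pk)]
  gk <- gk[!duplicated(gk)]
  tp_mask <- pk %in% gk
  fn_mask <- !(gk %in% pk)
  list(metrics = metrics_from_counts(sum(tp_mask), sum(!tp_mask),
                                     sum(fn_mask)),
       matched = pred_u[tp_mask, , drop = FALSE],
       unmatched_predicted = pred_u[!tp_mask, , drop = FALSE],
       unmatched_gold = gold_u[fn_mask, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## Error taxonomy

#' Classify false positives and false negatives
#'
#' Four-way exhaustive taxonomy: a false positive is
#' `FP_RELATION_ENTITIES_CORRECT` when both of its entity spans
#' boundary-match some gold entity annotation in the corpus (the relation
#' decision was wrong), else `FP_RELATION_ENTITIES_WRONG`; a false negative
#' is `FN_ENTITY_MISSED` when either gold entity has no boundary-matching
#' system mention in its sentence, else `FN_RELATION_FILTERED` (entities
#' found, knowledge-base or filter rejected the pair). Because the gold
#' standard only annotates entities participating in relations, the
#' "entities correct" reading under-counts correctly recognized entities.
#'
#' @param fp data.frame of false-positive predictions (from
#'   [match_exact()]).
#' @param fn data.frame of false-negative gold relations.
#' @param mentions full recognizer output on the corpus.
#' @param corpus the evaluated [ade_corpus()].
#' @param sample_n optional number of cases to sample for review.
#' @param seed seed for the review sample.
#' @return list with `cases` (data.frame `kind`, `doc_id`,
#'   `sentence_index`, spans, `sentence`), `summary` (counts per kind plus
#'   the false-positive share of all errors, in percent), and optionally
#'   `review_sample`.
#' @export
categorize_errors <- function(fp, fn, mentions, corpus, sample_n = NULL,
                              seed = 1L) {
  gold <- gold_entity_spans(corpus)
  gold_keys <- paste(gold$doc_id, gold$start, gold$end)
  mention_keys <- paste(mentions$doc_id, mentions$start, mentions$end)
  sent_text <- function(doc, idx) {
    s <- corpus$sentences
    s$text[s$doc_id == doc & s$sentence_index == idx][1L]
  }
  cases <- list()
  for (i in seq_len(nrow(fp))) {
    r <- fp[i, ]
    ok <- paste(r$doc_id, r$drug_start, r$drug_end) %in% gold_keys &&
      paste(r$doc_id, r$effect_start, r$effect_end) %in% gold_keys
    cases[[length(cases) + 1L]] <- new_df(
      kind = if (ok) "FP_RELATION_ENTITIES_CORRECT" else
        "FP_RELATION_ENTITIES_WRONG",
      doc_id = r$doc_id, sentence_index = r$sentence_index,
      drug_start = r$drug_start, drug_end = r$drug_end,
      effect_start = r$effect_start, effect_end = r$effect_end,
      sentence = sent_text(r$doc_id, r$sentence_index))
  }
  for (i in seq_len(nrow(fn))) {
    r <- fn[i, ]
    drug_found <- paste(r$doc_id, r$drug_start, r$drug_end) %in%
      mention_keys
    effect_found <- paste(r$doc_id, r$effect_start, r$effect_end) %in%
      mention_keys
    cases[[length(cases) + 1L]] <- new_df(
      kind = if (drug_found && effect_found) "FN_RELATION_FILTERED" else
        "FN_ENTITY_MISSED",
      doc_id = r$doc_id, sentence_index = r$sentence_index,
      drug_start = r$drug_start, drug_end = r$drug_end,
      effect_start = r$effect_start, effect_end = r$effect_end,
      sentence = sent_text(r$doc_id, r$sentence_index))
  }
  cases <- rbind_df(cases, new_df(
    kind = character(), doc_id = character(), sentence_index = integer(),
    drug_start = integer(), drug_end = integer(), effect_start = integer(),
    effect_end = integer(), sentence = character()))
  kinds <- c("FP_RELATION_ENTITIES_CORRECT", "FP_RELATION_ENTITIES_WRONG",
             "FN_RELATION_FILTERED", "FN_ENTITY_MISSED")
  counts <- vapply(kinds, function(k) sum(cases$kind == k), integer(1L))
  total <- sum(counts)
  summary <- list(counts = as.list(counts),
                  total_errors = total,
                  fp_share = if (total == 0) NA_real_ else
                    100 * sum(counts[1:2]) / total,
                  fn_share = if (total == 0) NA_real_ else
                    100 * sum(counts[3:4]) / total)
  out <- list(cases = cases, summary = summary)
  if (!is.null(sample_n) && nrow(cases) > 0L) {
    idx <- with_seed(seed, sample(nrow(cases), min(sample_n, nrow(cases))))
    out$review_sample <- cases[sort(idx), ]
  }
  out
}

## ---------------------------------------------------------------------------
## Comparison subset (balanced positives : negatives)

# gold relation with one entity span nested inside the other
is_nested_relation <- function(rel) {
  (rel$drug_start >= rel$effect_start & rel$drug_end <= rel$effect_end) |
    (rel$effect_start >= rel$drug_start & rel$effect_end <= rel$drug_end)
}

#' Build the balanced labeled pair set for system comparison
#'
#' Mirrors the construction used to compare against sentence-classifier
#' systems: gold relations with nested annotations (one entity span inside
#' the other, e.g. a drug inside its intoxication term) are dropped when
#' `drop_nested` is on; only positive sentences (those with at least one
#' gold relation) are used. Positives are the remaining gold relations
#' whose both entities were found boundary-exactly by the recognizer;
#' negatives are a seeded random sample of recognizer co-occurrence pairs
#' matching no gold relation, sampled until positives : negatives reaches
#' `ratio`. When too few negatives exist, all are emitted with a warning.
#'
#' @param corpus an [ade_corpus()].
#' @param mentions recognizer output on the corpus.
#' @param ratio target positives-to-negatives ratio (default 1.26).
#' @param drop_nested drop nested gold annotations (default TRUE).
#' @param seed integer seed for negative sampling.
#' @return data.frame of labeled pairs (`label` is `"true"` or `"false"`)
#'   with the candidate span columns; the achieved ratio is attached as
#'   attribute `"achieved_ratio"`.
#' @export
build_comparison_subset <- function(corpus, mentions, ratio = 1.26,
                                    drop_nested = TRUE, seed = 1L) {
  stopifnot(ratio > 0)
  gold <- corpus$relations
  if (drop_nested && nrow(gold)) gold <- gold[!is_nested_relation(gold), ]
  pos_sent <- unique(paste(corpus$relations$doc_id,
                           corpus$relations$sentence_index))
  mentions <- mentions[paste(mentions$doc_id, mentions$sentence_index) %in%
                         pos_sent, , drop = FALSE]
  mention_keys <- paste(mentions$doc_id, mentions$start, mentions$end)
  found <- paste(gold$doc_id, gold$drug_start, gold$drug_end) %in%
    mention_keys &
    paste(gold$doc_id, gold$effect_start, gold$effect_end) %in% mention_keys
  positives <- gold[found, , drop = FALSE]
  cands <- generate_candidates(mentions)
  ck <- paste(cands$doc_id, cands$drug_start, cands$drug_end,
              cands$effect_start, cands$effect_end)
  gk <- relation_keys(corpus$relations)
  negpool <- cands[!(ck %in% gk), , drop = FALSE]
  n_neg <- round(nrow(positives) / ratio)
  if (n_neg > nrow(negpool)) {
    warning(sprintf(
      "only %d negatives available for %d positives (achieved ratio %.2f)",
      nrow(negpool), nrow(positives),
      if (nrow(negpool)) nrow(positives) / nrow(negpool) else NA_real_))
    n_neg <- nrow(negpool)
  }
  pick <- if (n_neg > 0L) {
    sort(with_seed(seed, sample(nrow(negpool), n_neg)))
  } else {
    integer()
  }
  neg <- negpool[pick, , drop = FALSE]
  pos_df <- new_df(doc_id = positives$doc_id,
                   sentence_index = positives$sentence_index,
                   drug_start = positives$drug_start,
                   drug_end = positives$drug_end,
                   drug_surface = positives$drug_text,
                   effect_start = positives$effect_start,
                   effect_end = positives$effect_end,
                   effect_surface = positives$effect_text,
                   label = if (nrow(positives)) "true" else character())
  neg_df <- new_df(doc_id = neg$doc_id,
                   sentence_index = neg$sentence_index,
                   drug_start = neg$drug_start, drug_end = neg$drug_end,
                   drug_surface = neg$drug_surface,
                   effect_start = neg$effect_start,
                   effect_end = neg$effect_end,
                   effect_surface = neg$effect_surface,
                   label = if (nrow(neg)) "false" else character())
  out <- rbind(pos_df, neg_df)
  rownames(out) <- NULL
  attr(out, "achieved_ratio") <- if (nrow(neg_df)) {
    nrow(pos_df) / nrow(neg_df)
  } else {
    NA_real_
  }
  out
}

## ---------------------------------------------------------------------------
## Stage-wise reporting

#' Incremental per-stage performance report
#'
#' Evaluates four configurations in order -- dictionary-only co-occurrence,
#' plus NLP rules, plus the distance threshold, plus the relation-type
#' filter -- against the corpus gold standard, reporting boundary-exact
#' metrics per stage and the percentage-point deltas between consecutive
#' stages. The prediction sets are nested by construction, so recall can
#' only decrease (and precision typically increases) down the table.
#'
#' @param corpus an [ade_corpus()].
#' @param lex an `ade_lexicon`.
#' @param graph an [concept_graph()].
#' @param config an [extraction_config()].
#' @param filter a trained [relation_type_filter()] for the final row
#'   (skipped when `NULL`).
#' @param nlp an [nlp_config()].
#' @return data.frame with one row per stage: `stage`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`, `delta_precision`, `delta_recall`,
#'   `delta_f` (first row deltas are `NA`).
#' @export
stage_report <- function(corpus, lex, graph, config = extraction_config(),
                         filter = NULL, nlp = nlp_config()) {
  cooc <- extraction_config(distance_threshold = Inf,
                            path_cap = config$path_cap)
  dict_mentions <- recognize_corpus(corpus, lex)
  nlp_mentions <- apply_nlp_rules(dict_mentions, corpus, lex, nlp)
  stages <- list(
    list(stage = "dictionary_cooccurrence", mentions = dict_mentions,
         config = cooc, filter = NULL),
    list(stage = "nlp_rules", mentions = nlp_mentions, config = cooc,
         filter = NULL),
    list(stage = "knowledge_base", mentions = nlp_mentions, config = config,
         filter = NULL))
  if (!is.null(filter)) {
    stages[[4L]] <- list(stage = "relation_type_filter",
                         mentions = nlp_mentions, config = config,
                         filter = filter)
  }
  rows <- lapply(stages, function(st) {
    pred <- extract_relations(corpus, lex, graph, st$config, st$filter,
                              nlp = NULL, mentions = st$mentions)
    m <- match_exact(pred, corpus$relations)$metrics
    new_df(stage = st$stage, tp = m$tp, fp = m$fp, fn = m$fn,
           precision = m$precision, recall = m$recall,
           f_score = m$f_score)
  })
  out <- rbind_df(rows)
  out <- cbind(out, stage_deltas(out[, c("precision", "recall",
                                         "f_score")]))
  rownames(out) <- NULL
  out
}

#' Row-wise percentage-point deltas of a metric table
#'
#' @param metric_table data.frame of numeric metric columns (percentages),
#'   one row per stage.
#' @return data.frame of the same shape with columns prefixed `delta_`,
#'   holding differences to the previous row (`NA` in the first row).
#' @export
stage_deltas <- function(metric_table) {
  out <- as.data.frame(lapply(metric_table, function(col) {
    c(NA_real_, diff(col))
  }))
  names(out) <- paste0("delta_", names(metric_table))
  out
}

#' Write a metrics report
#'
#' @param report a data.frame (e.g. [stage_report()] output).
#' @param path output path; `.json` extension selects JSON, anything else
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("[.]json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
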