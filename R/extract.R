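#' Extraction configuration
#'
#' @param distance_threshold maximum shortest-path distance between a drug
#'   and a disorder concept for a relation to be asserted (default 4; set
#'   `Inf` for the co-occurrence baseline).
#' @param type_ratio_threshold a relation type is discarded when
#'   `(fp + 1) / (tp + 1)` strictly exceeds this value (default 7).
#' @param path_cap maximum number of shortest paths enumerated per pair.
#' @param horizon search depth limit; must be at least
#'   `distance_threshold` (default `distance_threshold + 1`).
#' @param filter_mode `"any_path_survives"` (a pair is rejected only when
#'   every shortest path contains a discarded type) or `"all_paths_clean"`
#'   (any tainted path rejects the pair).
#' @param count_mode `"occurrence"` (a relation type counts once per hop
#'   occurrence across all enumerated shortest paths) or `"per_pair"`
#'   (once per labeled candidate pair).
#' @return list of class `ade_extraction_config`.
#' @export
extraction_config <- function(distance_threshold = 4,
                              type_ratio_threshold = 7,
                              path_cap = 64L,
                              horizon = NULL,
                              filter_mode = c("any_path_survives",
                                              "all_paths_clean"),
                              count_mode = c("occurrence", "per_pair")) {
  stopifnot(distance_threshold > 0, type_ratio_threshold > 0,
            path_cap >= 1L)
  if (is.null(horizon)) {
    horizon <- if (is.finite(distance_threshold)) {
      distance_threshold + 1
    } else {
      Inf
    }
  }
  if (horizon < distance_threshold) {
    stop("horizon must be at least distance_threshold")
  }
  structure(list(distance_threshold = distance_threshold,
                 type_ratio_threshold = type_ratio_threshold,
                 path_cap = as.integer(path_cap), horizon = horizon,
                 filter_mode = match.arg(filter_mode),
                 count_mode = match.arg(count_mode)),
            class = "ade_extraction_config")
}

empty_candidates <- function() {
  new_df(doc_id = character(), sentence_index = integer(),
         drug_start = integer(), drug_end = integer(),
         drug_surface = character(), effect_start = integer(),
         effect_end = integer(), effect_surface = character())
}

#' Generate drug--disorder candidate pairs within sentences
#'
#' Full cross product of drug-group and disorder-group mentions within each
#' sentence; pairs whose two spans are identical are excluded. Mentions
#' carrying several CUIs on one span are grouped, so a candidate is a span
#' pair with CUI sets attached (list-columns `drug_cuis`, `effect_cuis`).
#' Candidates are ordered by document, sentence, drug start, effect start.
#'
#' @param mentions mention data.frame (see [match_mentions()]).
#' @return candidate data.frame with the columns above.
#' @export
generate_candidates <- function(mentions) {
  proto <- empty_candidates()
  proto$drug_cuis <- list()
  proto$effect_cuis <- list()
  if (is.null(mentions) || nrow(mentions) == 0L) return(proto)
  out <- list()
  skeys <- unique(paste(mentions$doc_id, mentions$sentence_index,
                        sep = "\r"))
  for (key in skeys) {
    m <- mentions[paste(mentions$doc_id, mentions$sentence_index,
                        sep = "\r") == key, ]
    drugs <- m[m$semantic_group == "CHEMICALS_AND_DRUGS", ]
    effects <- m[m$semantic_group == "DISORDERS", ]
    if (nrow(drugs) == 0L || nrow(effects) == 0L) next
    dspan <- unique(drugs[, c("start", "end", "surface")])
    espan <- unique(effects[, c("start", "end", "surface")])
    for (i in order(dspan$start, dspan$end)) {
      for (j in order(espan$start, espan$end)) {
        if (dspan$start[i] == espan$start[j] &&
            dspan$end[i] == espan$end[j]) next
        row <- new_df(doc_id = m$doc_id[1L],
                      sentence_index = m$sentence_index[1L],
                      drug_start = dspan$start[i], drug_end = dspan$end[i],
                      drug_surface = dspan$surface[i],
                      effect_start = espan$start[j],
                      effect_end = espan$end[j],
                      effect_surface = espan$surface[j])
        row$drug_cuis <- list(sort(unique(
          drugs$cui[drugs$start == dspan$start[i] &
                      drugs$end == dspan$end[i]])))
        row$effect_cuis <- list(sort(unique(
          effects$cui[effects$start == espan$start[j] &
                        effects$end == espan$end[j]])))
        out[[length(out) + 1L]] <- row
      }
    }
  }
  rbind_df(out, proto)
}

# Minimum graph distance over the CUI combinations of a candidate, with the
# lexicographically first minimizing (drug CUI, effect CUI) pair.
candidate_distance <- function(candidate, graph, horizon) {
  best <- Inf
  best_pair <- c(NA_character_, NA_character_)
  for (dc in candidate$drug_cuis[[1L]]) {
    for (ec in candidate$effect_cuis[[1L]]) {
      d <- graph_distance(graph, dc, ec, horizon = horizon)
      if (d < best) {
        best <- d
        best_pair <- c(dc, ec)
      }
    }
  }
  list(distance = best, drug_cui = best_pair[1L], effect_cui = best_pair[2L])
}

path_contains_discarded <- function(path, discarded) {
  any(vapply(path, function(types) any(types %in% discarded), logical(1L)))
}

#' Decide whether a candidate pair is an adverse-event relation
#'
#' A relation is asserted iff the shortest-path distance between the drug
#' and disorder concepts is at most `config$distance_threshold`, and --
#' when a trained [relation_type_filter()] is supplied -- the enumerated
#' shortest paths pass the relation-type filter under `config$filter_mode`.
#' When a mention carries several CUIs, the distance is the minimum over
#' all combinations and the minimizing pair's paths feed the filter.
#' Concepts absent from the graph give infinite distance and are rejected,
#' never an error.
#'
#' @param candidate one row of [generate_candidates()] output.
#' @param graph an [concept_graph()].
#' @param config an [extraction_config()].
#' @param filter optional [relation_type_filter()].
#' @return list with `accept` (logical), `distance`,
#'   `surviving_path_count`, `drug_cui`, `effect_cui`, and a
#'   human-readable `decision_trace`.
#' @export
decide_relation <- function(candidate, graph, config, filter = NULL) {
  cd <- candidate_distance(candidate, graph, config$horizon)
  if (!is.finite(cd$distance)) {
    return(c(cd, list(accept = FALSE, surviving_path_count = 0L,
                      decision_trace = "rejected: no path within horizon")))
  }
  if (cd$distance > config$distance_threshold) {
    return(c(cd, list(
      accept = FALSE, surviving_path_count = 0L,
      decision_trace = sprintf("rejected: distance %d > threshold %s",
                               cd$distance,
                               format(config$distance_threshold)))))
  }
  discarded <- if (is.null(filter)) character() else filter$discarded
  if (length(discarded) == 0L || cd$distance == 0L) {
    return(c(cd, list(
      accept = TRUE, surviving_path_count = NA_integer_,
      decision_trace = sprintf("accepted: distance %d <= threshold %s%s",
                               cd$distance,
                               format(config$distance_threshold),
                               if (is.null(filter)) "" else
                                 ", empty discard set"))))
  }
  ps <- shortest_path_summary(graph, cd$drug_cui, cd$effect_cui,
                              horizon = config$horizon,
                              path_cap = config$path_cap)
  tainted <- vapply(ps$paths, path_contains_discarded, logical(1L),
                    discarded = discarded)
  surviving <- sum(!tainted)
  accept <- if (config$filter_mode == "any_path_survives") {
    surviving > 0L
  } else {
    surviving == length(ps$paths)
  }
  trace <- sprintf(
    "%s: distance %d, %d of %d shortest path(s) free of discarded types%s",
    if (accept) "accepted" else "rejected", cd$distance, surviving,
    length(ps$paths), if (ps$truncated) " (enumeration truncated)" else "")
  c(cd, list(accept = accept, surviving_path_count = surviving,
             decision_trace = trace))
}

## ---------------------------------------------------------------------------
## Relation-type filter

#' Relation-type filter
#'
#' Holds, per relation type, the counts of occurrences on shortest paths of
#' true-positive and false-positive training candidates, and the derived
#' set of discarded types: those with
#' `(fp + 1) / (tp + 1) > type_ratio_threshold` (strict inequality).
#'
#' @param stats data.frame with columns `relation_type`, `tp`, `fp`.
#' @param type_ratio_threshold the ratio threshold (default 7).
#' @return list of class `ade_relation_type_filter` with `stats` (including
#'   a `ratio` column and logical `discarded`), `discarded` (character
#'   vector), and `type_ratio_threshold`.
#' @export
relation_type_filter <- function(stats, type_ratio_threshold = 7) {
  stopifnot(is.data.frame(stats),
            all(c("relation_type", "tp", "fp") %in% names(stats)),
            all(stats$tp >= 0), all(stats$fp >= 0))
  stats <- stats[order(stats$relation_type),
                 c("relation_type", "tp", "fp")]
  stats$ratio <- (stats$fp + 1) / (stats$tp + 1)
  stats$discarded <- stats$ratio > type_ratio_threshold
  rownames(stats) <- NULL
  structure(list(stats = stats,
                 discarded = stats$relation_type[stats$discarded],
                 type_ratio_threshold = type_ratio_threshold),
            class = "ade_relation_type_filter")
}

#' @export
print.ade_relation_type_filter <- function(x, ...) {
  cat("<ade_relation_type_filter>", nrow(x$stats), "relation types,",
      length(x$discarded), "discarded (ratio >",
      x$type_ratio_threshold, ")\n")
  if (length(x$discarded)) {
    cat(" discarded:", paste(x$discarded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Train the relation-type filter on a labeled corpus
#'
#' Every distance-accepted candidate on the training corpus is labeled
#' true-positive if it boundary-exactly matches a gold relation, otherwise
#' false-positive. For each enumerated shortest path of the candidate's
#' minimizing concept pair, each relation type increments the label's count
#' once per hop occurrence (`count_mode = "occurrence"`; a type on two hops
#' of one path counts twice) or once per candidate
#' (`count_mode = "per_pair"`). Types whose `(fp + 1) / (tp + 1)` ratio
#' strictly exceeds the threshold are discarded.
#'
#' @param train_corpus the training [ade_corpus()] with gold relations.
#' @param mentions recognizer output on the training corpus.
#' @param graph an [concept_graph()].
#' @param config an [extraction_config()].
#' @return a [relation_type_filter()]; empty training input yields an
#'   empty filter with a warning.
#' @export
train_relation_type_filter <- function(train_corpus, mentions, graph,
                                       config = extraction_config()) {
  cands <- generate_candidates(mentions)
  if (nrow(cands) == 0L) {
    warning("no training candidates; relation-type filter is empty")
    return(relation_type_filter(
      new_df(relation_type = character(), tp = numeric(), fp = numeric()),
      config$type_ratio_threshold))
  }
  gold_keys <- relation_keys(train_corpus$relations)
  tp_counts <- list()
  fp_counts <- list()
  bump <- function(env_list, types, amount) {
    for (t in names(amount)) {
      env_list[[t]] <- (env_list[[t]] %||% 0) + amount[[t]]
    }
    env_list
  }
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    cd <- candidate_distance(cand, graph, config$horizon)
    if (!is.finite(cd$distance) ||
        cd$distance > config$distance_threshold || cd$distance == 0L) {
      next
    }
    ps <- shortest_path_summary(graph, cd$drug_cui, cd$effect_cui,
                                horizon = config$horizon,
                                path_cap = config$path_cap)
    occ <- unlist(lapply(ps$paths, function(p) unlist(p)))
    if (length(occ) == 0L) next
    amount <- if (config$count_mode == "occurrence") {
      tab <- table(occ)
      stats::setNames(as.numeric(tab), names(tab))
    } else {
      u <- unique(occ)
      stats::setNames(rep(1, length(u)), u)
    }
    is_tp <- paste(cand$doc_id, cand$drug_start, cand$drug_end,
                   cand$effect_start, cand$effect_end) %in% gold_keys
    if (is_tp) {
      tp_counts <- bump(tp_counts, names(amount), amount)
    } else {
      fp_counts <- bump(fp_counts, names(amount), amount)
    }
  }
  types <- sort(unique(c(names(tp_counts), names(fp_counts))))
  stats <- new_df(
    relation_type = types,
    tp = vapply(types, function(t) tp_counts[[t]] %||% 0, numeric(1L)),
    fp = vapply(types, function(t) fp_counts[[t]] %||% 0, numeric(1L)))
  relation_type_filter(stats, config$type_ratio_threshold)
}

relation_keys <- function(relations) {
  paste(relations$doc_id, relations$drug_start, relations$drug_end,
        relations$effect_start, relations$effect_end)
}

#' Write / read a relation-type filter as JSON
#'
#' @param filter a [relation_type_filter()].
#' @param path output path.
#' @return `write_relation_type_filter` returns `path` invisibly;
#'   `read_relation_type_filter` returns the filter.
#' @export
write_relation_type_filter <- function(filter, path) {
  jsonlite::write_json(
    list(type_ratio_threshold = filter$type_ratio_threshold,
         stats = filter$stats[, c("relation_type", "tp", "fp")],
         discarded = filter$discarded),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_relation_type_filter
#' @export
read_relation_type_filter <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- as.data.frame(x$stats, stringsAsFactors = FALSE)
  if (nrow(stats) == 0L) {
    stats <- new_df(relation_type = character(), tp = numeric(),
                    fp = numeric())
  }
  relation_type_filter(stats, x$type_ratio_threshold)
}

## ---------------------------------------------------------------------------
## End-to-end extraction

empty_extracted <- function() {
  new_df(doc_id = character(), sentence_index = integer(),
         drug_surface = character(), drug_start = integer(),
         drug_end = integer(), drug_cui = character(),
         effect_surface = character(), effect_start = integer(),
         effect_end = integer(), effect_cui = character(),
         distance = numeric(), surviving_path_count = integer(),
         decision_trace = character())
}

#' Run the full extraction pipeline over a corpus
#'
#' Dictionary recognition, the five NLP submodules (optional), candidate
#' generation, and the knowledge-base relation decision, in corpus order.
#' A run manifest (configuration plus stage-wise mention / candidate /
#' acceptance counts) is attached as attribute `"manifest"`.
#'
#' @param corpus an [ade_corpus()].
#' @param lex an `ade_lexicon`.
#' @param graph an [concept_graph()].
#' @param config an [extraction_config()].
#' @param filter optional trained [relation_type_filter()].
#' @param nlp an [nlp_config()], or `NULL` to skip the NLP stage
#'   (dictionary-only recognition).
#' @param mentions optional precomputed recognizer output, bypassing
#'   recognition.
#' @return data.frame of accepted relations: `doc_id`, `sentence_index`,
#'   drug and effect surface/span/CUI, `distance`,
#'   `surviving_path_count`, `decision_trace`.
#' @export
extract_relations <- function(corpus, lex, graph,
                              config = extraction_config(), filter = NULL,
                              nlp = nlp_config(), mentions = NULL) {
  if (is.null(mentions)) {
    mentions <- recognize_corpus(corpus, lex)
    n_dict <- nrow(mentions)
    if (!is.null(nlp)) {
      mentions <- apply_nlp_rules(mentions, corpus, lex, nlp)
    }
  } else {
    n_dict <- NA_integer_
  }
  cands <- generate_candidates(mentions)
  out <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    dec <- tryCatch(decide_relation(cand, graph, config, filter),
                    error = function(e) {
                      warning("sentence ", cand$doc_id, "/",
                              cand$sentence_index, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(dec) || !dec$accept) next
    out[[length(out) + 1L]] <- new_df(
      doc_id = cand$doc_id, sentence_index = cand$sentence_index,
      drug_surface = cand$drug_surface, drug_start = cand$drug_start,
      drug_end = cand$drug_end, drug_cui = dec$drug_cui,
      effect_surface = cand$effect_surface,
      effect_start = cand$effect_start, effect_end = cand$effect_end,
      effect_cui = dec$effect_cui, distance = dec$distance,
      surviving_path_count = dec$surviving_path_count,
      decision_trace = dec$decision_trace)
  }
  res <- rbind_df(out, empty_extracted())
  attr(res, "manifest") <- list(
    config = unclass(config),
    n_sentences = nrow(corpus$sentences),
    n_dictionary_mentions = n_dict,
    n_mentions = nrow(mentions),
    n_candidates = nrow(cands),
    n_accepted = nrow(res),
    filter_discarded = if (is.null(filter)) character() else
      filter$discarded)
  res
}

#' Write extracted relations as TSV
#'
#' @param relations output of [extract_relations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relations_tsv <- function(relations, path) {
  cols <- c("doc_id", "sentence_index", "drug_surface", "drug_start",
            "drug_end", "drug_cui", "effect_surface", "effect_start",
            "effect_end", "effect_cui", "distance",
            "surviving_path_count")
  utils::write.table(relations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
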