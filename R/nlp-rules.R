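#' NLP rule configuration
#'
#' Switches for the five post-processing submodules applied after
#' dictionary recognition, each individually toggleable, plus the concept
#' filter list used by the concept-filtering rule.
#'
#' @param coordination,abbreviation,variation,boundary,filtering logical
#'   switches.
#' @param filter_list a [concept_filter_list()].
#' @return list of class `ade_nlp_config`.
#' @export
nlp_config <- function(coordination = TRUE, abbreviation = TRUE,
                       variation = TRUE, boundary = TRUE, filtering = TRUE,
                       filter_list = concept_filter_list()) {
  structure(list(coordination = coordination, abbreviation = abbreviation,
                 variation = variation, boundary = boundary,
                 filtering = filtering, filter_list = filter_list),
            class = "ade_nlp_config")
}

## ---------------------------------------------------------------------------
## Abbreviation expansion (parenthesis-anchored short-form/long-form pairs)

# lowercase words never accepted as short forms
sf_reject_words <- function() {
  unique(c(pos_word_lists()$CC, pos_word_lists()$IN, pos_word_lists()$DT,
           pos_word_lists()$PRP))
}

# Classic right-to-left character matching: every character of the short
# form must appear, in order, in the long form, and the first short-form
# character must match the first character of a long-form word. Returns the
# 1-based character index in `lf` where the long form starts, or NA.
long_form_start <- function(sf, lf) {
  sfc <- strsplit(tolower(sf), "")[[1L]]
  lfc <- strsplit(tolower(lf), "")[[1L]]
  si <- length(sfc)
  li <- length(lfc)
  while (si >= 1L) {
    ch <- sfc[si]
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1L; next }
    while (li >= 1L &&
           (lfc[li] != ch ||
            (si == 1L && li > 1L && grepl("[a-z0-9]", lfc[li - 1L])))) {
      li <- li - 1L
    }
    if (li < 1L) return(NA_integer_)
    li <- li - 1L
    si <- si - 1L
  }
  li + 1L
}

#' Detect abbreviation definitions in a sentence
#'
#' Finds parenthesis-anchored short-form/long-form pairs: a candidate short
#' form inside parentheses (2--10 characters, at most two words, at least
#' one letter, alphanumeric first character, not a lower-case function
#' word) is matched right-to-left against the preceding text. Every
#' character of the short form must appear in order in the long form, the
#' first short-form character must start a long-form word, and the long
#' form may span at most `min(|SF| + 5, |SF| * 2)` words.
#'
#' @param analysis an `ade_analyzed_sentence` from [analyze_sentence()].
#' @return data.frame with `short_form`, `sf_start`, `sf_end`, `long_form`,
#'   `lf_start`, `lf_end` (document-level spans); zero rows when no pair is
#'   found.
#' @export
detect_abbreviations <- function(analysis) {
  text <- analysis$sentence$text
  off <- analysis$sentence$start
  proto <- new_df(short_form = character(), sf_start = integer(),
                  sf_end = integer(), long_form = character(),
                  lf_start = integer(), lf_end = integer())
  m <- gregexpr("\\(([^()]{1,15})\\)", text)[[1L]]
  if (m[1L] == -1L) return(proto)
  out <- list()
  for (k in seq_along(m)) {
    p <- as.integer(m[k])                       # 1-based "(" position
    len <- attr(m, "match.length")[k]
    sf <- substr(text, p + 1L, p + len - 2L)
    sf <- trimws(sf)
    if (nchar(sf) < 2L || nchar(sf) > 10L) next
    if (length(strsplit(sf, "\\s+")[[1L]]) > 2L) next
    if (!grepl("[A-Za-z]", sf)) next
    if (!grepl("^[A-Za-z0-9]", sf)) next
    if (sf == tolower(sf) && tolower(sf) %in% sf_reject_words()) next
    before <- sub("\\s+$", "", substr(text, 1L, p - 1L))
    if (!nzchar(before)) next
    max_words <- min(nchar(sf) + 5L, nchar(sf) * 2L)
    wpos <- gregexpr("\\S+", before)[[1L]]
    if (wpos[1L] == -1L) next
    from_word <- max(1L, length(wpos) - max_words + 1L)
    cand_start <- as.integer(wpos[from_word])   # 1-based
    cand <- substr(before, cand_start, nchar(before))
    lf_rel <- long_form_start(sf, cand)
    if (is.na(lf_rel)) next
    lf <- substr(cand, lf_rel, nchar(cand))
    if (nchar(sf) > nchar(lf)) next
    n_words <- length(strsplit(lf, "\\s+")[[1L]])
    if (n_words > max_words) next
    lf_start0 <- cand_start + lf_rel - 2L       # 0-based into sentence
    sf_start0 <- p                               # char after "(" is p+1 1-based
    out[[length(out) + 1L]] <- new_df(
      short_form = sf, sf_start = off + sf_start0,
      sf_end = off + sf_start0 + nchar(sf),
      long_form = lf, lf_start = off + lf_start0,
      lf_end = off + lf_start0 + nchar(lf))
  }
  rbind_df(out, proto)
}

# locate occurrences of a short form as a standalone token sequence;
# returns 0-based document-level spans
find_sf_occurrences <- function(sf, sentence) {
  hits <- gregexpr(sf, sentence$text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(NULL)
  res <- list()
  for (p in as.integer(hits)) {
    before <- if (p > 1L) substr(sentence$text, p - 1L, p - 1L) else ""
    after_pos <- p + nchar(sf)
    after <- substr(sentence$text, after_pos, after_pos)
    if (grepl("[A-Za-z0-9]", before) || grepl("[A-Za-z0-9]", after)) next
    res[[length(res) + 1L]] <-
      c(sentence$start + p - 1L, sentence$start + p - 1L + nchar(sf))
  }
  res
}

#' Propagate abbreviation definitions through a document
#'
#' For each detected pair whose long form maps to a lexicon concept, every
#' later occurrence of the short form in the same document is annotated
#' with that concept (provenance `ABBREVIATION`), replacing any
#' dictionary mention on the same span (including any stray dictionary
#' reading of the short form inside the defining parentheses -- the
#' mislabeling this rule exists to correct). A short form whose long form
#' matches no concept is blocked from dictionary matching in the document:
#' its dictionary mentions are removed. When one short form receives
#' conflicting long forms, the first definition wins and a warning is
#' issued.
#'
#' @param mentions mention data.frame for one document.
#' @param pairs abbreviation pairs for the document, as rows of
#'   [detect_abbreviations()] output plus `sentence_index`.
#' @param lex an `ade_lexicon`.
#' @param sentences the document's rows of the corpus `sentences` table.
#' @return the augmented mention data.frame.
#' @export
propagate_abbreviations <- function(mentions, pairs, lex, sentences) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(mentions)
  pairs <- pairs[order(pairs$sf_start), ]
  seen <- list()
  for (i in seq_len(nrow(pairs))) {
    sf <- pairs$short_form[i]
    lf_key <- normalize_term(pairs$long_form[i])
    if (!is.null(seen[[sf]])) {
      if (seen[[sf]] != lf_key) {
        warning("conflicting long forms for short form '", sf,
                "' in document ", sentences$doc_id[1L],
                "; keeping the first")
      }
      next
    }
    seen[[sf]] <- lf_key
    cuis <- lex$term_index[[lf_key]]
    if (is.null(cuis)) {
      # long form is no concept: block the short form in this document
      drop <- mentions$provenance == "DICTIONARY" & mentions$surface == sf
      mentions <- mentions[!drop, ]
      next
    }
    for (si in seq_len(nrow(sentences))) {
      sent <- sentences[si, ]
      occ <- find_sf_occurrences(sf, sent)
      for (sp in occ) {
        mentions <- mentions[!(mentions$start == sp[1L] &
                                 mentions$end == sp[2L] &
                                 mentions$doc_id == sent$doc_id), ]
        # the defining occurrence itself only loses any stray dictionary
        # reading; concept annotation goes to later occurrences
        if (sp[1L] <= pairs$sf_start[i]) next
        mentions <- rbind(mentions, new_df(
          doc_id = sent$doc_id, sentence_index = sent$sentence_index,
          start = sp[1L], end = sp[2L], surface = sf, cui = cuis,
          semantic_group = semantic_group_of(lex, cuis),
          provenance = "ABBREVIATION"))
      }
    }
  }
  rownames(mentions) <- NULL
  mentions
}

## ---------------------------------------------------------------------------
## Coordination resolution

#' Resolve coordinated noun phrases
#'
#' For a noun phrase of shape `"A and B H"` (conjuncts `A`, `B` sharing
#' head tokens `H`, detected via a coordinating-conjunction tag inside one
#' NP, including hyphenated premodifier coordination `"A and B-H"`), the
#' phrase is rewritten as `"A H"` and `"B H"`, dictionary matching is
#' re-run on each rewrite, and any match involving the first conjunct is
#' mapped back to the minimal original span covering that conjunct
#' (provenance `COORDINATION`).
#'
#' @param analysis an `ade_analyzed_sentence`.
#' @param mentions mention data.frame for the sentence.
#' @param lex an `ade_lexicon`.
#' @return the augmented mention data.frame (unchanged when the sentence
#'   has no coordination).
#' @export
resolve_coordination <- function(analysis, mentions, lex) {
  toks <- analysis$tokens
  sent <- analysis$sentence
  groups <- np_token_indices(analysis)
  added <- list()
  for (g in groups) {
    cc <- g[toks$pos[g] == "CC"]
    if (length(cc) != 1L) next
    a_rows <- g[g < cc & toks$is_word[g] & toks$pos[g] != "DT"]
    after <- g[g > cc & toks$is_word[g]]
    if (length(a_rows) == 0L || length(after) == 0L) next
    b_row <- after[1L]
    tail_rows <- g[g > b_row]
    rewrites <- list(list(rows = c(a_rows, tail_rows), conjunct = a_rows),
                     list(rows = c(b_row, tail_rows), conjunct = b_row))
    for (rw in rewrites) {
      sub <- toks[rw$rows, ]
      hits <- match_token_stream(sub, lex)
      for (h in hits) {
        hit_rows <- rw$rows[h$from:h$to]
        conj_hit <- intersect(hit_rows, rw$conjunct)
        if (length(conj_hit) == 0L) next
        if (all(diff(sort(hit_rows)) == 1L)) {
          # contiguous in the original text: the dictionary pass already
          # covers this span, the rewrite added nothing
          s <- min(toks$start[hit_rows]); e <- max(toks$end[hit_rows])
        } else {
          s <- min(toks$start[conj_hit]); e <- max(toks$end[conj_hit])
        }
        added[[length(added) + 1L]] <- new_df(
          doc_id = sent$doc_id, sentence_index = sent$sentence_index,
          start = s, end = e,
          surface = slice_span(sent$text, s - sent$start, e - sent$start),
          cui = h$cuis, semantic_group = semantic_group_of(lex, h$cuis),
          provenance = "COORDINATION")
      }
    }
  }
  out <- rbind_df(c(list(mentions), added), empty_mentions())
  out[!duplicated(out[, c("doc_id", "sentence_index", "start", "end",
                          "cui")]), ]
}

## ---------------------------------------------------------------------------
## Term variation

#' Look up noun-phrase variants in the lexicon
#'
#' Applies an ordered variant list to a phrase that did not match as-is:
#' drop leading determiners/quantifiers; invert `"H of M"` to `"M H"`;
#' strip one premodifier at a time from the left. The first variant found
#' in the lexicon wins.
#'
#' @param phrase a noun-phrase string.
#' @param lex an `ade_lexicon`.
#' @return `NULL`, or a list with `cuis`, `variant` (the rewritten
#'   phrase), and `rule` (`"determiner_drop"`, `"of_inversion"`, or
#'   `"premodifier_strip"`).
#' @export
vary_term <- function(phrase, lex) {
  words <- strsplit(trimws(phrase), "\\s+")[[1L]]
  if (length(words) == 0L) return(NULL)
  dt <- pos_word_lists()$DT
  lookup <- function(v, rule) {
    cuis <- lex$term_index[[normalize_term(v)]]
    if (is.null(cuis)) NULL else list(cuis = cuis, variant = v, rule = rule)
  }
  w <- words
  while (length(w) > 1L && tolower(w[1L]) %in% dt) w <- w[-1L]
  if (length(w) < length(words)) {
    hit <- lookup(paste(w, collapse = " "), "determiner_drop")
    if (!is.null(hit)) return(hit)
  }
  i <- which(tolower(w) == "of")
  if (length(i) && i[1L] > 1L && i[1L] < length(w)) {
    h <- w[seq_len(i[1L] - 1L)]
    m <- w[(i[1L] + 1L):length(w)]
    while (length(m) > 1L && tolower(m[1L]) %in% dt) m <- m[-1L]
    hit <- lookup(paste(c(m, h), collapse = " "), "of_inversion")
    if (!is.null(hit)) return(hit)
  }
  while (length(w) > 1L) {
    w <- w[-1L]
    hit <- lookup(paste(w, collapse = " "), "premodifier_strip")
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# pipeline wrapper: try variation on every NP with no overlapping mention
apply_variation <- function(analysis, mentions, lex) {
  sent <- analysis$sentence
  nps <- analysis$noun_phrases
  added <- list()
  sent_m <- mentions[mentions$doc_id == sent$doc_id &
                       mentions$sentence_index == sent$sentence_index, ]
  for (k in seq_len(nrow(nps))) {
    s <- nps$start[k]; e <- nps$end[k]
    if (nrow(sent_m) &&
        any(spans_overlap(sent_m$start, sent_m$end, s, e))) next
    phrase <- slice_span(sent$text, s - sent$start, e - sent$start)
    hit <- vary_term(phrase, lex)
    if (is.null(hit)) next
    # anchor the mention on the phrase minus any dropped leading determiners
    toks <- tokenize_text(phrase, offset = s)
    words <- toks[toks$is_word, ]
    n_drop <- 0L
    if (hit$rule %in% c("determiner_drop", "premodifier_strip")) {
      kept <- strsplit(hit$variant, " ", fixed = TRUE)[[1L]]
      n_drop <- nrow(words) - length(kept)
    }
    ms <- words$start[n_drop + 1L]; me <- max(words$end)
    added[[length(added) + 1L]] <- new_df(
      doc_id = sent$doc_id, sentence_index = sent$sentence_index,
      start = ms, end = me,
      surface = slice_span(sent$text, ms - sent$start, me - sent$start),
      cui = hit$cuis, semantic_group = semantic_group_of(lex, hit$cuis),
      provenance = "VARIATION")
  }
  rbind_df(c(list(mentions), added), empty_mentions())
}

## ---------------------------------------------------------------------------
## Boundary correction

#' Trim mention boundaries to content tokens
#'
#' Removes leading and trailing tokens that are determiners, pronouns, or
#' punctuation from each mention span (trim-only; mentions are never
#' extended). A mention whose tokens are all trimmed away is dropped.
#'
#' @param mentions mention data.frame for the sentence.
#' @param analysis an `ade_analyzed_sentence`.
#' @return the corrected mention data.frame; adjusted rows carry provenance
#'   `BOUNDARY_ADJUSTED`.
#' @export
correct_boundaries <- function(mentions, analysis) {
  if (nrow(mentions) == 0L) return(mentions)
  toks <- analysis$tokens
  sent <- analysis$sentence
  trim_tags <- c("DT", "PRP", "PUNCT")
  keep <- logical(nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    if (mentions$sentence_index[i] != sent$sentence_index ||
        mentions$doc_id[i] != sent$doc_id) {
      keep[i] <- TRUE
      next
    }
    rows <- which(spans_overlap(toks$start, toks$end,
                                mentions$start[i], mentions$end[i]))
    while (length(rows) && toks$pos[rows[1L]] %in% trim_tags) {
      rows <- rows[-1L]
    }
    while (length(rows) && toks$pos[rows[length(rows)]] %in% trim_tags) {
      rows <- rows[-length(rows)]
    }
    if (length(rows) == 0L) next                 # fully trimmed: drop
    keep[i] <- TRUE
    s <- toks$start[rows[1L]]; e <- toks$end[rows[length(rows)]]
    if (s != mentions$start[i] || e != mentions$end[i]) {
      mentions$start[i] <- s
      mentions$end[i] <- e
      mentions$surface[i] <- slice_span(sent$text, s - sent$start,
                                        e - sent$start)
      mentions$provenance[i] <- "BOUNDARY_ADJUSTED"
    }
  }
  mentions[keep, ]
}

## ---------------------------------------------------------------------------
## Concept filtering

#' Concept filter list
#'
#' @param cuis concept identifiers to suppress.
#' @param terms surface terms to suppress (normalized before use).
#' @return list of class `ade_concept_filter_list`.
#' @export
concept_filter_list <- function(cuis = character(), terms = character()) {
  structure(list(cuis = unique(as.character(cuis)),
                 terms = unique(normalize_term(terms))),
            class = "ade_concept_filter_list")
}

#' Read a concept filter list from file
#'
#' One CUI or term per line; `#` starts a comment. Entries of the form
#' `C<digits>` are treated as CUIs, anything else as a term.
#'
#' @param file path or character vector of lines.
#' @return a [concept_filter_list()].
#' @export
read_concept_filter_list <- function(file) {
  lines <- trimws(read_lines_arg(file))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  is_cui <- grepl("^C[0-9]+$", lines)
  concept_filter_list(cuis = lines[is_cui], terms = lines[!is_cui])
}

#' Remove mentions outside noun phrases or on the filter list
#'
#' A mention is removed iff (a) its span has empty intersection with every
#' noun-phrase span -- partial overlap suffices to keep it -- or (b) its
#' CUI or normalized surface is on the filter list. Mentions produced by
#' abbreviation propagation are exempt from rule (a): short forms may fall
#' outside weakly chunked noun phrases.
#'
#' @param mentions mention data.frame for the sentence.
#' @param analysis an `ade_analyzed_sentence`.
#' @param filter_list a [concept_filter_list()].
#' @return the surviving mentions, order preserved.
#' @export
filter_concepts <- function(mentions, analysis,
                            filter_list = concept_filter_list()) {
  if (nrow(mentions) == 0L) return(mentions)
  nps <- analysis$noun_phrases
  in_sent <- mentions$doc_id == analysis$sentence$doc_id &
    mentions$sentence_index == analysis$sentence$sentence_index
  overlaps_np <- vapply(seq_len(nrow(mentions)), function(i) {
    nrow(nps) > 0L && any(spans_overlap(nps$start, nps$end,
                                        mentions$start[i], mentions$end[i]))
  }, logical(1L))
  listed <- mentions$cui %in% filter_list$cuis |
    normalize_term(mentions$surface) %in% filter_list$terms
  drop <- in_sent &
    ((!overlaps_np & mentions$provenance != "ABBREVIATION") | listed)
  mentions[!drop, ]
}

#' Derive filter-list candidates from training false positives
#'
#' Counts, per CUI, the system mentions on the training corpus whose spans
#' match no gold entity annotation; CUIs with at least `min_count` such
#' false-positive mentions are proposed for the concept filter list.
#'
#' @param mentions recognizer output on the training corpus.
#' @param corpus the training [ade_corpus()].
#' @param min_count minimum false-positive count for inclusion.
#' @return a [concept_filter_list()] of candidate CUIs.
#' @export
derive_concept_filter <- function(mentions, corpus, min_count = 5L) {
  if (nrow(mentions) == 0L) return(concept_filter_list())
  gold <- gold_entity_spans(corpus)
  is_fp <- !(paste(mentions$doc_id, mentions$start, mentions$end) %in%
               paste(gold$doc_id, gold$start, gold$end))
  tab <- table(mentions$cui[is_fp])
  concept_filter_list(cuis = names(tab)[tab >= min_count])
}

# all gold entity spans (both roles) of a corpus
gold_entity_spans <- function(corpus) {
  rel <- corpus$relations
  new_df(doc_id = c(rel$doc_id, rel$doc_id),
         start = c(rel$drug_start, rel$effect_start),
         end = c(rel$drug_end, rel$effect_end),
         role = rep(c("DRUG", "ADVERSE_EFFECT"), each = nrow(rel)))
}

## ---------------------------------------------------------------------------
## Conflict resolution and the full pipeline

# Overlapping mentions with different spans: keep the longer span; on ties
# dictionary provenance wins. Same-span multi-CUI copies all survive.
resolve_span_conflicts <- function(mentions) {
  if (nrow(mentions) <= 1L) return(mentions)
  out <- list()
  for (key in unique(paste(mentions$doc_id, mentions$sentence_index))) {
    m <- mentions[paste(mentions$doc_id, mentions$sentence_index) == key, ]
    spans <- unique(m[, c("start", "end")])
    spans$len <- spans$end - spans$start
    spans$rank <- vapply(seq_len(nrow(spans)), function(i) {
      min(ifelse(m$provenance[m$start == spans$start[i] &
                                m$end == spans$end[i]] == "DICTIONARY",
                 0L, 1L))
    }, integer(1L))
    spans <- spans[order(-spans$len, spans$rank, spans$start), ]
    acc <- spans[0L, ]
    for (i in seq_len(nrow(spans))) {
      if (nrow(acc) == 0L ||
          !any(spans_overlap(acc$start, acc$end, spans$start[i],
                             spans$end[i]))) {
        acc <- rbind(acc, spans[i, ])
      }
    }
    out[[key]] <- m[paste(m$start, m$end) %in% paste(acc$start, acc$end), ]
  }
  rbind_df(out, empty_mentions())
}

#' Apply the five NLP rule submodules to recognizer output
#'
#' Runs, in order: abbreviation expansion (document level), coordination
#' resolution, term variation, boundary correction, conflict resolution,
#' and concept filtering. The pipeline only touches system mentions --
#' never gold annotations -- and is idempotent.
#'
#' @param mentions dictionary mentions from [recognize_corpus()].
#' @param corpus the [ade_corpus()] the mentions came from.
#' @param lex an `ade_lexicon`.
#' @param config an [nlp_config()].
#' @param analyses optional precomputed list of [analyze_sentence()]
#'   results keyed by `"doc_id\rsentence_index"`, to avoid re-tagging.
#' @return the post-processed mention data.frame, ordered by document,
#'   sentence, span, and CUI.
#' @export
apply_nlp_rules <- function(mentions, corpus, lex, config = nlp_config(),
                            analyses = NULL) {
  sen <- corpus$sentences
  if (is.null(analyses)) analyses <- analyze_corpus(corpus)
  doc_order <- unique(sen$doc_id)
  out <- list()
  for (d in doc_order) {
    drows <- which(sen$doc_id == d)
    dsent <- sen[drows, ]
    m <- mentions[mentions$doc_id == d, ]
    if (config$abbreviation) {
      pairs <- rbind_df(lapply(drows, function(i) {
        p <- detect_abbreviations(analyses[[sent_key(sen[i, ])]])
        if (nrow(p)) p$sentence_index <- sen$sentence_index[i]
        p
      }))
      m <- propagate_abbreviations(m, pairs, lex, dsent)
    }
    for (i in drows) {
      a <- analyses[[sent_key(sen[i, ])]]
      if (config$coordination) m <- resolve_coordination(a, m, lex)
      if (config$variation) m <- apply_variation(a, m, lex)
      if (config$boundary) m <- correct_boundaries(m, a)
    }
    m <- resolve_span_conflicts(m)
    if (config$filtering) {
      for (i in drows) {
        m <- filter_concepts(m, analyses[[sent_key(sen[i, ])]],
                             config$filter_list)
      }
    }
    out[[d]] <- m
  }
  res <- rbind_df(out, empty_mentions())
  res <- res[!duplicated(res[, c("doc_id", "sentence_index", "start", "end",
                                 "cui")]), ]
  ord <- order(match(res$doc_id, doc_order), res$sentence_index, res$start,
               res$end, res$cui)
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

sent_key <- function(sentence) {
  paste(sentence$doc_id, sentence$sentence_index, sep = "\r")
}

#' Tag and chunk every sentence of a corpus
#'
#' @param corpus an [ade_corpus()].
#' @param tagger optional tagger override (see [analyze_sentence()]).
#' @return named list of `ade_analyzed_sentence` objects keyed by
#'   `doc_id` and sentence index.
#' @export
analyze_corpus <- function(corpus, tagger = NULL) {
  out <- list()
  for (i in seq_len(nrow(corpus$sentences))) {
    s <- corpus$sentences[i, ]
    out[[sent_key(s)]] <- analyze_sentence(s, tagger = tagger)
  }
  out
}
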