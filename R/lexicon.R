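#' Term normalization for dictionary matching
#'
#' Applies, in order: case folding, possessive removal, replacement of
#' hyphens and other punctuation by spaces, whitespace collapse, and simple
#' plural stripping on the final token (`-ies` to `-y`, otherwise a trailing
#' `s` is dropped unless the token ends in `ss`, `us`, or `is`). The same
#' normalization is applied to dictionary terms and to text n-grams, which
#' makes matching invariant to casing and hyphen/space alternation.
#'
#' Deterministic and idempotent: `normalize_term(normalize_term(x))` equals
#' `normalize_term(x)`.
#'
#' @param x character vector of terms.
#' @return normalized character vector of the same length.
#' @export
normalize_term <- function(x) {
  if (length(x) == 0L) return(character())
  x <- tolower(x)
  x <- gsub("'s(?![a-z0-9])", "", x, perl = TRUE)   # possessives
  x <- gsub("[^a-z0-9]+", " ", x)                   # punctuation to space
  x <- trimws(gsub("[ ]+", " ", x))
  vapply(x, function(t) {
    if (!nzchar(t)) return(t)
    words <- strsplit(t, " ", fixed = TRUE)[[1L]]
    n <- length(words)
    words[n] <- strip_plural(words[n])
    paste(words, collapse = " ")
  }, character(1L), USE.NAMES = FALSE)
}

strip_plural <- function(w) {
  if (nchar(w) > 3L && grepl("ies$", w)) return(sub("ies$", "y", w))
  if (nchar(w) > 2L && grepl("s$", w) && !grepl("(ss|us|is)$", w)) {
    return(sub("s$", "", w))
  }
  w
}

#' Build a concept lexicon
#'
#' A lexicon maps normalized terms to concept unique identifiers (CUIs),
#' each CUI carrying a coarse semantic group. Entries outside the two
#' target groups (`CHEMICALS_AND_DRUGS`, `DISORDERS`) are dropped unless
#' `keep_all_groups` is set; CUIs with no group assignment are kept as
#' `OTHER` with a warning. Terms on the suppress list never produce matches.
#'
#' @param terms data.frame with columns `term`, `cui`.
#' @param groups data.frame with columns `cui`, `semantic_group`.
#' @param suppress character vector of terms to suppress (normalized before
#'   use).
#' @param keep_all_groups keep concepts outside the two target groups.
#' @param max_term_tokens longest term, in tokens, considered by the
#'   matcher.
#' @return an object of class `ade_lexicon` with elements `entries`
#'   (data.frame `cui`, `preferred_term`, `semantic_group`), `term_index`
#'   (named list: normalized term -> CUI vector), `suppress`, and
#'   `max_term_tokens`.
#' @export
lexicon <- function(terms, groups, suppress = character(),
                    keep_all_groups = FALSE, max_term_tokens = 8L) {
  stopifnot(is.data.frame(terms), all(c("term", "cui") %in% names(terms)),
            is.data.frame(groups),
            all(c("cui", "semantic_group") %in% names(groups)))
  terms$cui <- as.character(terms$cui)
  terms$term <- as.character(terms$term)
  grp <- groups$semantic_group[match(terms$cui, groups$cui)]
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " term row(s) reference a CUI with no group ",
            "assignment; assigned OTHER")
    grp[is.na(grp)] <- "OTHER"
  }
  known <- c("CHEMICALS_AND_DRUGS", "DISORDERS", "OTHER")
  if (!all(grp %in% known)) {
    stop("unknown semantic group label(s): ",
         paste(setdiff(unique(grp), known), collapse = ", "))
  }
  if (!keep_all_groups) {
    keep <- grp %in% c("CHEMICALS_AND_DRUGS", "DISORDERS")
    terms <- terms[keep, ]
    grp <- grp[keep]
  }
  norm <- normalize_term(terms$term)
  keep <- nzchar(norm)
  terms <- terms[keep, ]; grp <- grp[keep]; norm <- norm[keep]

  suppress <- unique(normalize_term(suppress))
  suppress <- suppress[nzchar(suppress)]

  first <- !duplicated(terms$cui)
  entries <- new_df(cui = terms$cui[first], preferred_term = terms$term[first],
                    semantic_group = grp[first])
  entries <- entries[order(entries$cui), ]
  rownames(entries) <- NULL

  idx_keep <- !(norm %in% suppress)
  term_index <- lapply(split(terms$cui[idx_keep], norm[idx_keep]),
                       function(c) sort(unique(c)))
  structure(list(entries = entries, term_index = term_index,
                 suppress = suppress,
                 max_term_tokens = as.integer(max_term_tokens)),
            class = "ade_lexicon")
}

#' @export
print.ade_lexicon <- function(x, ...) {
  cat("<ade_lexicon>", nrow(x$entries), "concepts,", length(x$term_index),
      "index terms,", length(x$suppress), "suppressed terms\n")
  invisible(x)
}

semantic_group_of <- function(lex, cuis) {
  g <- lex$entries$semantic_group[match(cuis, lex$entries$cui)]
  g[is.na(g)] <- "OTHER"
  g
}

#' Load a lexicon from vocabulary files
#'
#' Reads a term table as two-column TSV (`term`, `cui`) or as RRF-style
#' pipe-delimited rows with configurable 0-based column positions (defaults
#' match the public concept-names table layout: CUI at column 0, term
#' string at column 14). The group table is TSV: `cui` TAB group name.
#'
#' @param vocab_file path to the term table (or character vector of lines).
#' @param group_file path to the group table (or lines).
#' @param format `"tsv"` or `"rrf"`.
#' @param rrf_cui_col,rrf_term_col 0-based column indices for RRF input.
#' @param ... passed to [lexicon()] (`suppress`, `keep_all_groups`, ...).
#' @return an `ade_lexicon`.
#' @export
load_lexicon <- function(vocab_file, group_file, format = c("tsv", "rrf"),
                         rrf_cui_col = 0L, rrf_term_col = 14L, ...) {
  format <- match.arg(format)
  vlines <- read_lines_arg(vocab_file)
  if (format == "tsv") {
    parts <- strsplit(vlines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) < 2L)
    if (length(bad)) stop("vocabulary line ", bad[1L], ": expected 2 fields")
    terms <- new_df(term = vapply(parts, `[[`, "", 1L),
                    cui = vapply(parts, `[[`, "", 2L))
  } else {
    parts <- strsplit(vlines, "|", fixed = TRUE)
    need <- max(rrf_cui_col, rrf_term_col) + 1L
    bad <- which(vapply(parts, length, 0L) < need)
    if (length(bad)) stop("vocabulary line ", bad[1L], ": fewer than ", need,
                          " pipe-separated fields")
    terms <- new_df(term = vapply(parts, `[[`, "", rrf_term_col + 1L),
                    cui = vapply(parts, `[[`, "", rrf_cui_col + 1L))
  }
  glines <- read_lines_arg(group_file)
  gparts <- strsplit(glines, "\t", fixed = TRUE)
  bad <- which(vapply(gparts, length, 0L) < 2L)
  if (length(bad)) stop("group table line ", bad[1L], ": expected 2 fields")
  groups <- new_df(cui = vapply(gparts, `[[`, "", 1L),
                   semantic_group = vapply(gparts, `[[`, "", 2L))
  lexicon(terms, groups, ...)
}

read_lines_arg <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, warn = FALSE, encoding = "UTF-8")
  } else {
    x
  }
  lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
}

## ---------------------------------------------------------------------------
## Tokenization and matching

#' Tokenize text with character spans
#'
#' Tokens are maximal alphanumeric runs; every other non-space character is
#' its own token (so hyphens split words). Spans are 0-based half-open
#' offsets into `text`, shifted by `offset` (the sentence's document-level
#' start) when given.
#'
#' @param text a single string.
#' @param offset document-level start of `text`.
#' @return data.frame with `token`, `start`, `end`, `is_word`.
#' @export
tokenize_text <- function(text, offset = 0L) {
  stopifnot(length(text) == 1L)
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9 \t\r\n]", text)[[1L]]
  if (m[1L] == -1L) {
    return(new_df(token = character(), start = integer(), end = integer(),
                  is_word = logical()))
  }
  tok <- regmatches(text, list(m))[[1L]]
  new_df(token = tok, start = offset + as.integer(m) - 1L,
         end = offset + as.integer(m) + attr(m, "match.length") - 1L,
         is_word = grepl("^[A-Za-z0-9]", tok))
}

empty_mentions <- function() {
  new_df(doc_id = character(), sentence_index = integer(),
         start = integer(), end = integer(), surface = character(),
         cui = character(), semantic_group = character(),
         provenance = character())
}

# Leftmost-longest dictionary matching over a token data.frame (columns as
# tokenize_text). n-grams may span hyphen/slash tokens but no other
# punctuation. Returns matches as (start, end, cuis list) token-window hits.
match_token_stream <- function(tokens, lex) {
  widx <- which(tokens$is_word)
  hits <- list()
  i <- 1L
  while (i <= length(widx)) {
    found_n <- 0L
    found_cuis <- NULL
    max_n <- min(lex$max_term_tokens, length(widx) - i + 1L)
    for (n in seq_len(max_n)) {
      # window i .. i+n-1 valid only if intervening tokens are hyphen/slash
      if (n > 1L) {
        lo <- widx[i + n - 2L]; hi <- widx[i + n - 1L]
        if (hi > lo + 1L) {
          between <- tokens$token[(lo + 1L):(hi - 1L)]
          if (!all(between %in% c("-", "/"))) break
        }
      }
      key <- normalize_term(paste(tokens$token[widx[i:(i + n - 1L)]],
                                  collapse = " "))
      cuis <- lex$term_index[[key]]
      if (!is.null(cuis)) {
        found_n <- n
        found_cuis <- cuis
      }
    }
    if (found_n > 0L) {
      hits[[length(hits) + 1L]] <- list(
        from = widx[i], to = widx[i + found_n - 1L], cuis = found_cuis)
      i <- i + found_n
    } else {
      i <- i + 1L
    }
  }
  hits
}

#' Dictionary concept recognition in a sentence
#'
#' Scans the token stream with leftmost-longest matching: at each token
#' position the longest normalized token n-gram present in the lexicon's
#' term index is emitted and scanning resumes after it. Emitted mentions are
#' non-overlapping and ordered; a term mapping to several CUIs yields one
#' mention per CUI on the same span (ambiguity is preserved).
#'
#' @param sentence one row of an [ade_corpus()] `sentences` table (or any
#'   list with `doc_id`, `sentence_index`, `text`, `start`).
#' @param lex an `ade_lexicon`.
#' @return a mention data.frame: `doc_id`, `sentence_index`, `start`, `end`
#'   (document-level), `surface`, `cui`, `semantic_group`,
#'   `provenance = "DICTIONARY"`.
#' @export
match_mentions <- function(sentence, lex) {
  tokens <- tokenize_text(sentence$text, offset = sentence$start)
  hits <- match_token_stream(tokens, lex)
  out <- lapply(hits, function(h) {
    s <- tokens$start[h$from]; e <- tokens$end[h$to]
    new_df(doc_id = sentence$doc_id, sentence_index = sentence$sentence_index,
           start = s, end = e,
           surface = slice_span(sentence$text, s - sentence$start,
                                e - sentence$start),
           cui = h$cuis, semantic_group = semantic_group_of(lex, h$cuis),
           provenance = "DICTIONARY")
  })
  rbind_df(out, empty_mentions())
}

#' Dictionary recognition over a whole corpus
#'
#' @param corpus an [ade_corpus()].
#' @param lex an `ade_lexicon`.
#' @return mention data.frame (see [match_mentions()]) over all sentences.
#' @export
recognize_corpus <- function(corpus, lex) {
  out <- lapply(seq_len(nrow(corpus$sentences)), function(i) {
    match_mentions(corpus$sentences[i, ], lex)
  })
  rbind_df(out, empty_mentions())
}
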