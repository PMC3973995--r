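#' Sentence-level annotated corpus objects
#'
#' An `ade_corpus` holds a collection of abstracts as sentence records plus
#' gold drug--adverse-effect relations annotated at the sentence level. All
#' character offsets are document-level, 0-based, half-open `[start, end)`.
#'
#' @param sentences data.frame with columns `doc_id`, `sentence_index`
#'   (1-based within document), `text`, `start`, `end`.
#' @param relations data.frame with columns `doc_id`, `sentence_index`,
#'   `drug_text`, `drug_start`, `drug_end`, `effect_text`, `effect_start`,
#'   `effect_end`. May have zero rows.
#' @param provenance optional list of notes recorded while reading (e.g. the
#'   offset convention detected in an input file).
#'
#' @details A sentence with no row in `relations` is a "negative" sentence.
#'   The constructor validates that sentence spans within a document are
#'   ordered and non-overlapping and that every gold surface string equals
#'   the document text sliced at its span.
#'
#' @return An object of class `ade_corpus`.
#' @export
ade_corpus <- function(sentences, relations = NULL, provenance = list()) {
  sent_cols <- c("doc_id", "sentence_index", "text", "start", "end")
  stopifnot(is.data.frame(sentences), all(sent_cols %in% names(sentences)))
  sentences <- sentences[, sent_cols]
  sentences$doc_id <- as.character(sentences$doc_id)
  if (is.null(relations) || nrow(relations) == 0L) {
    relations <- empty_relations()
  }
  rel_cols <- names(empty_relations())
  stopifnot(all(rel_cols %in% names(relations)))
  relations <- relations[, rel_cols]
  relations$doc_id <- as.character(relations$doc_id)

  # per-document invariants: ordered, non-overlapping sentence spans
  for (d in unique(sentences$doc_id)) {
    s <- sentences[sentences$doc_id == d, ]
    if (is.unsorted(s$sentence_index, strictly = TRUE)) {
      stop("sentence_index not strictly increasing in document ", d)
    }
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("overlapping sentence spans in document ", d)
    }
    if (any(s$start >= s$end)) stop("empty sentence span in document ", d)
  }
  obj <- structure(
    list(sentences = sentences, relations = relations,
         provenance = provenance),
    class = "ade_corpus"
  )
  check_gold_surfaces(obj)
  obj
}

empty_relations <- function() {
  new_df(doc_id = character(), sentence_index = integer(),
         drug_text = character(), drug_start = integer(),
         drug_end = integer(), effect_text = character(),
         effect_start = integer(), effect_end = integer())
}

empty_sentences <- function() {
  new_df(doc_id = character(), sentence_index = integer(),
         text = character(), start = integer(), end = integer())
}

# every gold surface must equal the owning sentence sliced at its span
check_gold_surfaces <- function(corpus) {
  rel <- corpus$relations
  if (nrow(rel) == 0L) return(invisible(TRUE))
  key <- paste(corpus$sentences$doc_id, corpus$sentences$sentence_index)
  idx <- match(paste(rel$doc_id, rel$sentence_index), key)
  if (anyNA(idx)) stop("relation refers to a missing sentence")
  sen <- corpus$sentences[idx, ]
  for (part in c("drug", "effect")) {
    s <- rel[[paste0(part, "_start")]]
    e <- rel[[paste0(part, "_end")]]
    txt <- rel[[paste0(part, "_text")]]
    if (any(s < sen$start | e > sen$end)) {
      stop("gold ", part, " span falls outside its sentence")
    }
    got <- substr(sen$text, s - sen$start + 1L, e - sen$start)
    bad <- which(got != txt)
    if (length(bad)) {
      stop("gold ", part, " surface/span mismatch in document ",
           rel$doc_id[bad[1L]], ": '", txt[bad[1L]], "' vs '",
           got[bad[1L]], "'")
    }
  }
  invisible(TRUE)
}

#' @export
print.ade_corpus <- function(x, ...) {
  cc <- corpus_counts(x)
  cat("<ade_corpus>", cc$documents, "documents,", cc$sentences, "sentences (",
      cc$positive_sentences, "positive /", cc$negative_sentences,
      "negative ),", cc$relations, "gold relations\n")
  invisible(x)
}

#' Corpus bookkeeping counts
#'
#' @param corpus an [ade_corpus()].
#' @return list with `documents`, `relations`, `sentences`,
#'   `positive_sentences`, `negative_sentences`.
#' @export
corpus_counts <- function(corpus) {
  pos_key <- unique(paste(corpus$relations$doc_id,
                          corpus$relations$sentence_index))
  sen_key <- paste(corpus$sentences$doc_id, corpus$sentences$sentence_index)
  npos <- sum(sen_key %in% pos_key)
  list(documents = length(unique(corpus$sentences$doc_id)),
       relations = nrow(corpus$relations),
       sentences = nrow(corpus$sentences),
       positive_sentences = npos,
       negative_sentences = nrow(corpus$sentences) - npos)
}

#' Restrict a corpus to a set of documents
#'
#' @param corpus an [ade_corpus()].
#' @param doc_ids character vector of document identifiers to keep.
#' @return an [ade_corpus()] containing only those documents.
#' @export
subset_corpus <- function(corpus, doc_ids) {
  ade_corpus(corpus$sentences[corpus$sentences$doc_id %in% doc_ids, ],
             corpus$relations[corpus$relations$doc_id %in% doc_ids, ],
             provenance = corpus$provenance)
}

## ---------------------------------------------------------------------------
## Pipe-delimited relation files

default_field_order <- function() {
  c("doc_id", "sentence", "effect_text", "effect_start", "effect_end",
    "drug_text", "drug_start", "drug_end")
}

# The 8 supported offset conventions, in tie-break preference order. The
# native convention (document-relative, 0-based, half-open) comes first.
offset_conventions <- function() {
  grid <- expand.grid(ref = c("document", "sentence"), base = c(0L, 1L),
                      end = c("half_open", "closed"),
                      stringsAsFactors = FALSE)
  grid[order(grid$ref != "document", grid$base, grid$end != "half_open"), ]
}

# Slice `sent_text` (whose document-level start is `sent_start`) at raw file
# offsets (s, e) interpreted under one convention. Returns NA when the
# adjusted span leaves the sentence.
conv_slice <- function(sent_text, sent_start, s, e, conv) {
  if (conv$base == 1L) { s <- s - 1L; e <- e - 1L }
  if (conv$end == "closed") e <- e + 1L
  if (conv$ref == "document") { s <- s - sent_start; e <- e - sent_start }
  if (is.na(s) || is.na(e) || s < 0L || e > nchar(sent_text) || s >= e) {
    return(NA_character_)
  }
  substr(sent_text, s + 1L, e)
}

#' Read an ADE-style pipe-delimited relation file
#'
#' Each line of the relation file carries one drug--adverse-effect relation:
#' a document identifier, the sentence containing the relation, and the
#' surface text plus character offsets of the adverse effect and of the drug.
#' Lines sharing a document id and sentence text are merged into a single
#' sentence record holding several gold relations. An optional companion
#' file supplies "negative" sentences (`doc_id|sentence`) without gold
#' annotations; they are appended after a document's positive sentences.
#'
#' Document text is reconstructed by joining each document's distinct
#' sentences -- positive ones in file order, then negative ones -- with a
#' single space; documents are ordered lexicographically by id, so the
#' result does not depend on storage order. The offset
#' convention of the input (sentence- vs document-relative, 0- vs 1-based,
#' half-open vs closed) is auto-detected by checking surface/slice agreement
#' on the first parsable records; one consistent correction is then applied
#' to the whole file and recorded under `provenance$offset_convention`.
#'
#' @param relations_file path to the pipe-delimited relation file.
#' @param negatives_file optional path to the negative-sentence file.
#' @param field_order character vector naming the pipe-separated fields, a
#'   permutation of `doc_id`, `sentence`, `effect_text`, `effect_start`,
#'   `effect_end`, `drug_text`, `drug_start`, `drug_end`.
#' @param n_probe number of leading parsable records used for offset
#'   auto-detection.
#' @return an [ade_corpus()]; malformed lines and offset-inconsistent
#'   records are collected (with line numbers) under
#'   `provenance$parse_errors` rather than aborting the read.
#' @export
read_ade_corpus <- function(relations_file, negatives_file = NULL,
                            field_order = default_field_order(),
                            n_probe = 20L) {
  stopifnot(setequal(field_order, default_field_order()))
  lines <- if (length(relations_file) == 1L && file.exists(relations_file)) {
    readLines(relations_file, warn = FALSE, encoding = "UTF-8")
  } else {
    relations_file  # already a character vector of lines
  }
  lines <- lines[nzchar(trimws(lines))]
  errors <- character()
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "|", fixed = TRUE)[[1L]]
    if (length(f) != length(field_order)) {
      errors <- c(errors, sprintf(
        "line %d: expected %d pipe-separated fields, got %d",
        i, length(field_order), length(f)))
      next
    }
    names(f) <- field_order
    offs <- suppressWarnings(as.integer(
      f[c("effect_start", "effect_end", "drug_start", "drug_end")]))
    if (anyNA(offs)) {
      errors <- c(errors, sprintf("line %d: non-integer offset field", i))
      next
    }
    recs[[i]] <- new_df(line = i, doc_id = f[["doc_id"]],
                        sentence = f[["sentence"]],
                        effect_text = f[["effect_text"]],
                        effect_start = offs[1L], effect_end = offs[2L],
                        drug_text = f[["drug_text"]],
                        drug_start = offs[3L], drug_end = offs[4L])
  }
  recs <- rbind_df(recs)

  neg <- NULL
  if (!is.null(negatives_file)) {
    nlines <- if (length(negatives_file) == 1L && file.exists(negatives_file)) {
      readLines(negatives_file, warn = FALSE, encoding = "UTF-8")
    } else {
      negatives_file
    }
    nlines <- nlines[nzchar(trimws(nlines))]
    parts <- strsplit(nlines, "|", fixed = TRUE)
    ok <- vapply(parts, length, 0L) == 2L
    if (any(!ok)) {
      errors <- c(errors, sprintf(
        "negatives line %d: expected 2 fields", which(!ok)))
    }
    if (any(ok)) {
      neg <- new_df(doc_id = vapply(parts[ok], `[[`, "", 1L),
                    sentence = vapply(parts[ok], `[[`, "", 2L))
    }
  }

  if (is.null(recs) && is.null(neg)) {
    return(ade_corpus(empty_sentences(), NULL,
                      provenance = list(parse_errors = errors)))
  }

  # sentence inventory: per doc, positive sentences in file order, then
  # negative ones; document text = single-space join
  sent <- new_df(doc_id = c(recs$doc_id, neg$doc_id),
                 text = c(recs$sentence, neg$sentence))
  sent <- sent[!duplicated(paste(sent$doc_id, sent$text, sep = "\r")), ]
  doc_order <- sort(unique(sent$doc_id))
  sent_list <- lapply(doc_order, function(d) {
    s <- sent[sent$doc_id == d, ]
    ends <- cumsum(nchar(s$text) + 1L) - 1L
    new_df(doc_id = d, sentence_index = seq_len(nrow(s)), text = s$text,
           start = ends - nchar(s$text), end = ends)
  })
  sentences <- rbind_df(sent_list, empty_sentences())

  relations <- empty_relations()
  convention <- NULL
  if (!is.null(recs)) {
    skey <- paste(sentences$doc_id, sentences$text, sep = "\r")
    recs$sent_row <- match(paste(recs$doc_id, recs$sentence, sep = "\r"), skey)
    convs <- offset_conventions()
    probe <- recs[seq_len(min(n_probe, nrow(recs))), ]
    score <- vapply(seq_len(nrow(convs)), function(ci) {
      conv <- convs[ci, ]
      sum(vapply(seq_len(nrow(probe)), function(ri) {
        r <- probe[ri, ]
        st <- sentences[r$sent_row, ]
        isTRUE(conv_slice(st$text, st$start, r$drug_start, r$drug_end,
                          conv) == r$drug_text) &&
          isTRUE(conv_slice(st$text, st$start, r$effect_start, r$effect_end,
                            conv) == r$effect_text)
      }, logical(1L)))
    }, numeric(1L))
    if (max(score) == 0L) {
      errors <- c(errors, paste(
        "no offset convention reproduces the entity surfaces of the probe",
        "records; all relation records dropped"))
      recs <- recs[0L, ]
      convention <- NA_character_
    } else {
      conv <- convs[which.max(score), ]  # ties: native convention first
      convention <- sprintf("%s-relative, %d-based, %s", conv$ref, conv$base,
                            conv$end)
      to_native <- function(s, e, sent_start) {
        if (conv$base == 1L) { s <- s - 1L; e <- e - 1L }
        if (conv$end == "closed") e <- e + 1L
        if (conv$ref == "sentence") { s <- s + sent_start; e <- e + sent_start }
        list(s = s, e = e)
      }
      keep <- logical(nrow(recs))
      for (ri in seq_len(nrow(recs))) {
        r <- recs[ri, ]
        st <- sentences[r$sent_row, ]
        okd <- conv_slice(st$text, st$start, r$drug_start, r$drug_end, conv)
        oke <- conv_slice(st$text, st$start, r$effect_start, r$effect_end,
                          conv)
        if (isTRUE(okd == r$drug_text) && isTRUE(oke == r$effect_text)) {
          keep[ri] <- TRUE
        } else {
          errors <- c(errors, sprintf(
            "line %d: entity surfaces inconsistent with detected offset convention (%s)",
            r$line, convention))
        }
      }
      recs <- recs[keep, ]
      if (nrow(recs)) {
        st <- sentences[recs$sent_row, ]
        d <- to_native(recs$drug_start, recs$drug_end, st$start)
        e <- to_native(recs$effect_start, recs$effect_end, st$start)
        relations <- new_df(doc_id = recs$doc_id,
                            sentence_index = st$sentence_index,
                            drug_text = recs$drug_text,
                            drug_start = d$s, drug_end = d$e,
                            effect_text = recs$effect_text,
                            effect_start = e$s, effect_end = e$e)
        relations <- relations[!duplicated(relations), ]
        ord <- order(match(relations$doc_id, doc_order),
                     relations$sentence_index, relations$drug_start,
                     relations$effect_start)
        relations <- relations[ord, ]
      }
    }
  }
  ade_corpus(sentences, relations,
             provenance = list(offset_convention = convention,
                               parse_errors = errors))
}

#' Write a corpus in ADE pipe-delimited format
#'
#' Positive sentences are written one line per gold relation to
#' `relations_file`; sentences without relations go to `negatives_file`
#' (when given) as `doc_id|sentence`. Offsets are written document-level,
#' 0-based, half-open -- the package's native convention, which
#' [read_ade_corpus()] detects on reading, so write-then-read restores the
#' corpus.
#'
#' @param corpus an [ade_corpus()].
#' @param relations_file output path for the relation lines.
#' @param negatives_file optional output path for negative sentences.
#' @param field_order field layout, as in [read_ade_corpus()].
#' @return invisibly, the number of relation lines written.
#' @export
write_ade_corpus <- function(corpus, relations_file, negatives_file = NULL,
                             field_order = default_field_order()) {
  rel <- corpus$relations
  lines <- character(nrow(rel))
  if (nrow(rel)) {
    skey <- paste(corpus$sentences$doc_id, corpus$sentences$sentence_index)
    sent <- corpus$sentences[match(paste(rel$doc_id, rel$sentence_index),
                                   skey), ]
    fields <- list(doc_id = rel$doc_id, sentence = sent$text,
                   effect_text = rel$effect_text,
                   effect_start = rel$effect_start,
                   effect_end = rel$effect_end,
                   drug_text = rel$drug_text,
                   drug_start = rel$drug_start, drug_end = rel$drug_end)
    lines <- do.call(paste, c(fields[field_order], sep = "|"))
  }
  writeLines(lines, relations_file, useBytes = TRUE)
  if (!is.null(negatives_file)) {
    pos_key <- unique(paste(rel$doc_id, rel$sentence_index))
    neg <- corpus$sentences[!paste(corpus$sentences$doc_id,
                                   corpus$sentences$sentence_index) %in%
                              pos_key, ]
    writeLines(paste(neg$doc_id, neg$text, sep = "|"), negatives_file,
               useBytes = TRUE)
  }
  invisible(length(lines))
}

## ---------------------------------------------------------------------------
## Plain abstracts

# words before a sentence-final period that do not end a sentence
sentence_abbreviations <- function() {
  c("e.g", "i.e", "etc", "vs", "al", "dr", "fig", "figs", "no", "approx",
    "ca", "resp")
}

#' Split a text into sentences with character spans
#'
#' Rule-based segmentation: a sentence ends at terminal punctuation
#' (`.`, `!`, `?`) followed by whitespace and an upper-case letter or digit,
#' unless the preceding word is a known abbreviation.
#'
#' @param text a single string.
#' @param abbreviations lower-cased words (without the final period) that
#'   never end a sentence.
#' @return data.frame with `text`, `start`, `end` (0-based half-open spans
#'   into `text`).
#' @export
split_sentences <- function(text,
                            abbreviations = sentence_abbreviations()) {
  stopifnot(length(text) == 1L)
  if (!nzchar(trimws(text))) {
    return(new_df(text = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[.!?]+[ \t]+", text)[[1L]]
  breaks <- integer()
  if (m[1L] != -1L) {
    for (k in seq_along(m)) {
      p <- m[k]                                   # 1-based punct position
      len <- attr(m, "match.length")[k]
      nxt <- substr(text, p + len, p + len)
      if (!grepl("[A-Z0-9]", nxt)) next
      prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, 1L, p - 1L))
      prev <- tolower(sub("\\.$", "", prev))
      if (prev %in% abbreviations) next
      if (grepl("^[a-z]\\.[a-z]", prev)) next     # internal dotted form
      punct_len <- attr(regexpr("^[.!?]+", substr(text, p, p + len)),
                        "match.length")
      breaks <- c(breaks, p + punct_len - 1L)     # last char of sentence
    }
  }
  starts <- c(1L, vapply(breaks, function(b) {
    rest <- substr(text, b + 1L, nchar(text))
    b + attr(regexpr("^[ \t]*", rest), "match.length") + 1L
  }, integer(1L)))
  ends <- c(breaks, nchar(text))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  new_df(text = substring(text, starts, ends), start = starts - 1L,
         end = ends)
}

#' Load plain abstracts for processing
#'
#' @param source path to a file (or character vector of lines) with one
#'   abstract per line: `doc_id TAB text`.
#' @param sep field separator (default TAB).
#' @return an [ade_corpus()] with empty gold annotations; sentences come
#'   from [split_sentences()].
#' @export
load_plain_abstracts <- function(source, sep = "\t") {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    source
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr(sep, lines, fixed = TRUE),
                      invert = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) stop("abstract line ", bad[1L], " has no '", sep,
                        "' separator")
  ids <- vapply(parts, `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate doc_id in abstracts: ", dup[1L])
  out <- lapply(seq_along(ids), function(i) {
    s <- split_sentences(parts[[i]][2L])
    if (nrow(s) == 0L) return(NULL)
    new_df(doc_id = ids[i], sentence_index = seq_len(nrow(s)),
           text = s$text, start = s$start, end = s$end)
  })
  ade_corpus(rbind_df(out, empty_sentences()), NULL)
}

## ---------------------------------------------------------------------------
## Train/test splitting

#' Deterministic train/test split over documents
#'
#' Document ids are sorted lexicographically before seeded uniform sampling,
#' so the split depends only on the id set and the seed, not on storage
#' order.
#'
#' @param corpus an [ade_corpus()].
#' @param n_train number of documents to place in the training set.
#' @param seed integer seed.
#' @return list of class `ade_corpus_split` with elements `train`, `test`
#'   (both [ade_corpus()]) and `seed`.
#' @export
split_corpus <- function(corpus, n_train, seed) {
  ids <- sort(unique(corpus$sentences$doc_id))
  if (n_train < 0L || n_train > length(ids)) {
    stop("n_train must be between 0 and the number of documents (",
         length(ids), ")")
  }
  train_ids <- with_seed(seed, sample(ids, n_train))
  structure(list(train = subset_corpus(corpus, train_ids),
                 test = subset_corpus(corpus, setdiff(ids, train_ids)),
                 seed = seed),
            class = "ade_corpus_split")
}

#' @export
print.ade_corpus_split <- function(x, ...) {
  cat("<ade_corpus_split> seed", x$seed, "\n train:")
  print(x$train)
  cat(" test: ")
  print(x$test)
  invisible(x)
}
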