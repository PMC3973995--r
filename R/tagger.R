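# Deterministic lexicon + suffix part-of-speech tagger and noun-phrase
# chunker. The rule submodules only need shallow analysis (determiner /
# conjunction / preposition recognition and NP grouping), so a small
# closed-class word list plus suffix heuristics is sufficient and keeps the
# package free of model downloads. The tagger is pluggable: any function
# with the signature of analyze_sentence() can stand in.

pos_word_lists <- function() {
  list(
    DT = c("the", "a", "an", "this", "that", "these", "those", "each",
           "every", "some", "any", "no", "all", "both", "several", "many",
           "few", "most", "such", "another", "other"),
    CC = c("and", "or", "nor", "but"),
    IN = c("of", "in", "on", "at", "by", "for", "with", "to", "from", "as",
           "after", "before", "during", "following", "without", "between",
           "into", "under", "over", "while", "than", "via", "per"),
    PRP = c("he", "she", "it", "they", "we", "i", "you", "his", "her",
            "its", "their", "our", "who", "which", "whom"),
    VB = c("is", "are", "was", "were", "be", "been", "being", "has", "have",
           "had", "do", "does", "did", "can", "could", "may", "might",
           "must", "shall", "should", "will", "would", "developed",
           "presented", "received", "reported", "showed", "occurred",
           "revealed", "underwent", "remains", "remained", "became",
           "resolved", "improved", "appeared", "suffered", "experienced")
  )
}

pos_tag_token <- function(token, lists) {
  if (!grepl("^[A-Za-z0-9]", token)) return("PUNCT")
  lw <- tolower(token)
  for (tag in names(lists)) if (lw %in% lists[[tag]]) return(tag)
  if (grepl("^[0-9]+([.][0-9]+)?$", lw)) return("CD")
  if (nchar(lw) > 4L && grepl("ly$", lw)) return("RB")
  if (nchar(lw) > 4L && grepl("ing$", lw)) return("VBG")
  if (nchar(lw) > 3L && grepl("ed$", lw)) return("VBN")
  if (nchar(lw) > 3L && grepl("s$", lw) && !grepl("(ss|us|is)$", lw)) {
    return("NNS")
  }
  "NN"
}

#' Part-of-speech and noun-phrase analysis of a sentence
#'
#' Tags each token with a coarse part of speech (closed-class word lists
#' plus suffix rules; default `NN`) and assigns IOB noun-phrase chunk tags.
#' A noun phrase is a maximal run of determiner / adjective / noun / number
#' tokens; hyphens, hyphen-attached participles (as in `drug-induced`), and
#' coordinating conjunctions flanked by NP material are absorbed into the
#' run, so coordinated phrases such as `"cisplatin and bleomycin-induced
#' TMA"` form a single NP.
#'
#' @param sentence one row of an [ade_corpus()] `sentences` table.
#' @param tagger optional replacement token tagger,
#'   `function(tokens) -> character` of POS tags.
#' @return list of class `ade_analyzed_sentence`: `sentence`, `tokens`
#'   (data.frame `token`, `start`, `end`, `is_word`, `pos`, `chunk`), and
#'   `noun_phrases` (data.frame `start`, `end`, document-level spans
#'   covering exactly the maximal `B-NP`/`I-NP` runs).
#' @export
analyze_sentence <- function(sentence, tagger = NULL) {
  tokens <- tokenize_text(sentence$text, offset = sentence$start)
  n <- nrow(tokens)
  if (is.null(tagger)) {
    lists <- pos_word_lists()
    pos <- vapply(tokens$token, pos_tag_token, character(1L), lists = lists,
                  USE.NAMES = FALSE)
  } else {
    pos <- tagger(tokens)
  }
  tokens$pos <- pos

  np <- pos %in% c("DT", "NN", "NNS", "NNP", "CD", "FW")
  # adjectives: untagged words before a noun behave as NN already (default
  # NN), so no separate JJ pass is needed; participles join via hyphens:
  if (n >= 3L) {
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        if (!np[i] && pos[i] %in% c("VBN", "VBG") && i >= 3L &&
            tokens$token[i - 1L] == "-" && np[i - 2L]) {
          np[i] <- TRUE; np[i - 1L] <- TRUE; changed <- TRUE
        }
        if (!np[i] && tokens$token[i] == "-" && i > 1L && i < n &&
            np[i - 1L] && np[i + 1L]) {
          np[i] <- TRUE; changed <- TRUE
        }
      }
      if (!changed) break
    }
    # a coordinating conjunction between NP material merges the conjuncts
    for (i in 2:(n - 1L)) {
      if (pos[i] == "CC" && np[i - 1L] && np[i + 1L]) np[i] <- TRUE
    }
  }
  chunk <- rep("O", n)
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (np[i]) chunk[i] <- if (i > 1L && np[i - 1L]) "I-NP" else "B-NP"
    }
  }
  tokens$chunk <- chunk

  runs <- rle(np)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- which(runs$values)
  noun_phrases <- new_df(start = tokens$start[starts[keep]],
                         end = tokens$end[stops[keep]])
  structure(list(sentence = sentence, tokens = tokens,
                 noun_phrases = noun_phrases),
            class = "ade_analyzed_sentence")
}

# token indices (rows of analysis$tokens) of the NP containing token i
np_token_indices <- function(analysis) {
  ch <- analysis$tokens$chunk
  grp <- cumsum(ch == "B-NP" | (ch == "O"))
  split(seq_along(ch)[ch != "O"], grp[ch != "O"])
}
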