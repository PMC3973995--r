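# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately avoid the package's own algorithms: the
# distance oracle uses boolean adjacency-matrix powers (a walk of length k
# exists iff A^k > 0), the path oracle enumerates all simple paths
# recursively, and the matcher oracle enumerates every token window.

toy_lexicon <- function(terms_named_by_group, suppress = character()) {
  # terms_named_by_group: named character vector term -> "DRUG"/"DIS"/other
  cuis <- sprintf("C%04d", seq_along(terms_named_by_group))
  groups <- ifelse(terms_named_by_group == "DRUG", "CHEMICALS_AND_DRUGS",
                   ifelse(terms_named_by_group == "DIS", "DISORDERS",
                          terms_named_by_group))
  lexicon(data.frame(term = names(terms_named_by_group), cui = cuis,
                     stringsAsFactors = FALSE),
          data.frame(cui = cuis, semantic_group = groups,
                     stringsAsFactors = FALSE),
          suppress = suppress)
}

one_sentence_corpus <- function(text, doc_id = "D1") {
  ade_corpus(data.frame(doc_id = doc_id, sentence_index = 1L, text = text,
                        start = 0L, end = nchar(text),
                        stringsAsFactors = FALSE))
}

sentence_row <- function(text, doc_id = "D1", start = 0L,
                         sentence_index = 1L) {
  data.frame(doc_id = doc_id, sentence_index = sentence_index, text = text,
             start = start, end = start + nchar(text),
             stringsAsFactors = FALSE)
}

random_typed_graph <- function(n_nodes, edge_prob, types = c("t1", "t2"),
                               parallel_prob = 0.15) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  edges <- NULL
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (stats::runif(1) < edge_prob) {
        tt <- sample(types, 1L)
        edges <- rbind(edges, data.frame(cui_a = nodes[i], cui_b = nodes[j],
                                         relation_type = tt,
                                         stringsAsFactors = FALSE))
        if (stats::runif(1) < parallel_prob && length(types) > 1L) {
          t2 <- sample(setdiff(types, tt), 1L)
          edges <- rbind(edges, data.frame(cui_a = nodes[i],
                                           cui_b = nodes[j],
                                           relation_type = t2,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(cui_a = character(), cui_b = character(),
                        relation_type = character(),
                        stringsAsFactors = FALSE)
  }
  concept_graph(edges, concepts = nodes)
}

# all-pairs distance oracle via boolean matrix powers
oracle_distances <- function(graph) {
  nodes <- graph$concepts
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    A[e$cui_a[k], e$cui_b[k]] <- TRUE
    A[e$cui_b[k], e$cui_a[k]] <- TRUE
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  reach <- diag(TRUE, n)
  P <- A
  for (d in seq_len(n - 1L)) {
    newly <- P & !reach
    D[newly] <- d
    reach <- reach | P
    if (all(reach)) break
    P <- (P %*% A) > 0
  }
  D
}

# all shortest paths (as node sequences) by exhaustive simple-path search
oracle_shortest_paths <- function(graph, a, b) {
  if (!(a %in% graph$concepts) || !(b %in% graph$concepts)) return(list())
  paths <- list()
  best <- Inf
  rec <- function(v, seen, acc) {
    if (length(acc) - 1L > best) return(invisible())
    if (v == b) {
      d <- length(acc) - 1L
      if (d < best) {
        best <<- d
        paths <<- list(acc)
      } else if (d == best) {
        paths[[length(paths) + 1L]] <<- acc
      }
      return(invisible())
    }
    for (w in graph$adjacency[[v]]) {
      if (!(w %in% seen)) rec(w, c(seen, w), c(acc, w))
    }
    invisible()
  }
  if (a == b) return(list())
  rec(a, a, a)
  paths
}

oracle_hop_types <- function(graph, path_nodes) {
  lapply(seq_len(length(path_nodes) - 1L), function(k) {
    key <- paste(min(path_nodes[k], path_nodes[k + 1L]),
                 max(path_nodes[k], path_nodes[k + 1L]), sep = "\r")
    graph$edge_types[[key]]
  })
}

# brute-force leftmost-longest matcher: enumerate every word-token window,
# keep lexicon hits, then greedily select by position preferring length
oracle_match_spans <- function(text, lex) {
  toks <- tokenize_text(text)
  widx <- which(toks$is_word)
  cand <- NULL
  for (i in seq_along(widx)) {
    for (n in seq_len(min(lex$max_term_tokens, length(widx) - i + 1L))) {
      rows <- widx[i:(i + n - 1L)]
      if (n > 1L) {
        gap_ok <- all(vapply(seq_len(n - 1L), function(k) {
          lo <- rows[k]; hi <- rows[k + 1L]
          hi == lo + 1L ||
            all(toks$token[(lo + 1L):(hi - 1L)] %in% c("-", "/"))
        }, logical(1L)))
        if (!gap_ok) break
      }
      key <- normalize_term(paste(toks$token[rows], collapse = " "))
      if (!is.null(lex$term_index[[key]])) {
        cand <- rbind(cand, data.frame(i = i, n = n,
                                       start = toks$start[rows[1L]],
                                       end = toks$end[rows[n]]))
      }
    }
  }
  sel <- NULL
  if (!is.null(cand)) {
    pos <- 1L
    while (pos <= length(widx)) {
      here <- cand[cand$i == pos, , drop = FALSE]
      if (nrow(here)) {
        best <- here[which.max(here$n), ]
        sel <- rbind(sel, best)
        pos <- pos + best$n
      } else {
        pos <- pos + 1L
      }
    }
  }
  if (is.null(sel)) data.frame(start = integer(), end = integer()) else
    sel[, c("start", "end")]
}

# brute-force short-form/long-form checker: the long form is the suffix
# beginning at the rightmost word start w where the first short-form
# character matches the character at w and the remaining characters appear
# in order afterwards
oracle_long_form <- function(sf, before) {
  sfc <- strsplit(tolower(gsub("[^A-Za-z0-9]", "", sf)), "")[[1L]]
  if (length(sfc) == 0L) return(NA_character_)
  wpos <- gregexpr("\\S+", before)[[1L]]
  if (wpos[1L] == -1L) return(NA_character_)
  lowered <- tolower(before)
  for (w in rev(as.integer(wpos))) {
    if (substr(lowered, w, w) != sfc[1L]) next
    rest <- sfc[-1L]
    p <- w
    ok <- TRUE
    for (ch in rest) {
      hit <- regexpr(ch, substr(lowered, p + 1L, nchar(lowered)),
                     fixed = TRUE)
      if (hit == -1L) { ok <- FALSE; break }
      p <- p + as.integer(hit)
    }
    if (ok) return(substr(before, w, nchar(before)))
  }
  NA_character_
}

default_test_fixture <- local({
  cache <- NULL
  function(n_documents = 80L, seed = 20140304L) {
    key <- paste(n_documents, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    spec <- fixture_spec(n_documents = n_documents, seed = seed)
    res <- generate_fixture_resources(spec)
    corpus <- generate_fixture_corpus(spec, res)
    value <- list(spec = spec, res = res, corpus = corpus)
    cache <<- list(key = key, value = value)
    value
  }
})
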