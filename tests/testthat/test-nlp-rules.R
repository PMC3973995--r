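analyze1 <- function(text, ...) analyze_sentence(sentence_row(text), ...)

test_that("parenthesis-anchored abbreviation pairs are detected", {
  a <- analyze1("A patient with thrombotic microangiopathy (TMA) improved.")
  p <- detect_abbreviations(a)
  expect_equal(p$short_form, "TMA")
  expect_equal(p$long_form, "thrombotic microangiopathy")
  expect_equal(substr(a$sentence$text, p$lf_start + 1L, p$lf_end),
               p$long_form)
  expect_equal(substr(a$sentence$text, p$sf_start + 1L, p$sf_end),
               p$short_form)
  # lowercase function words are never short forms
  expect_equal(nrow(detect_abbreviations(analyze1("The salt (and) acid."))),
               0L)
  # first-character rule: short form must start a long-form word
  expect_equal(nrow(detect_abbreviations(
    analyze1("Chronic renal failure (XQ) was seen."))), 0L)
})

test_that("abbreviation detection matches the brute-force oracle", {
  lfs <- c("thrombotic microangiopathy", "acute renal failure",
           "systemic lupus erythematosus", "white blood cell",
           "upper gastro-intestinal tract", "severe skin rash")
  withr::with_seed(21L, {
    for (k in 1:120) {
      lf <- sample(lfs, 1L)
      words <- strsplit(lf, " ")[[1L]]
      sf <- if (stats::runif(1) < 0.5) {
        toupper(paste(substr(words, 1L, 1L), collapse = ""))  # valid SF
      } else {
        # random letters: usually violates the subsequence condition
        paste(sample(LETTERS, sample(2:4, 1L), replace = TRUE),
              collapse = "")
      }
      text <- sprintf("Patients developed %s (%s) repeatedly.", lf, sf)
      got <- detect_abbreviations(analyze1(text))
      before <- sprintf("Patients developed %s", lf)
      want_lf <- oracle_long_form(sf, before)
      max_words <- min(nchar(sf) + 5L, nchar(sf) * 2L)
      if (!is.na(want_lf) &&
          length(strsplit(want_lf, "\\s+")[[1L]]) <= max_words &&
          nchar(sf) <= nchar(want_lf)) {
        expect_equal(got$long_form, want_lf, info = text)
      } else {
        expect_equal(nrow(got), 0L, info = text)
      }
    }
  })
})

test_that("abbreviation propagation annotates later short forms", {
  lex <- toy_lexicon(c("thrombotic microangiopathy" = "DIS",
                       "cisplatin" = "DRUG",
                       "TMA" = "DRUG"))   # the wrong dictionary sense
  sents <- rbind(
    sentence_row("Thrombotic microangiopathy (TMA) was suspected."),
    sentence_row("Cisplatin caused TMA in this patient.", start = 49L,
                 sentence_index = 2L))
  corpus <- ade_corpus(sents)
  m0 <- recognize_corpus(corpus, lex)
  # dictionary alone mislabels the short form as a drug
  expect_true(any(m0$surface == "TMA" &
                    m0$semantic_group == "CHEMICALS_AND_DRUGS"))
  m1 <- apply_nlp_rules(m0, corpus, lex)
  sf <- m1[m1$surface == "TMA", ]
  expect_true(nrow(sf) >= 1L)
  expect_true(all(sf$semantic_group == "DISORDERS"))
  expect_true(all(sf$provenance == "ABBREVIATION"))
  expect_true(all(sf$sentence_index == 2L))

  # a short form whose long form is no concept is blocked document-wide
  lex2 <- toy_lexicon(c("GH" = "DRUG", "aspirin" = "DRUG"))
  sents2 <- rbind(
    sentence_row("Severe general headache (GH) after aspirin."),
    sentence_row("GH persisted for days.", start = 44L,
                 sentence_index = 2L))
  corpus2 <- ade_corpus(sents2)
  m2 <- apply_nlp_rules(recognize_corpus(corpus2, lex2), corpus2, lex2)
  expect_false(any(m2$surface == "GH"))
  expect_true(any(m2$surface == "aspirin"))

  # a document without parentheses is untouched
  corpus3 <- one_sentence_corpus("Aspirin was given.")
  lex3 <- toy_lexicon(c("aspirin" = "DRUG"))
  m3 <- recognize_corpus(corpus3, lex3)
  expect_equal(apply_nlp_rules(m3, corpus3, lex3)[, names(m3)], m3,
               ignore_attr = TRUE)
})

test_that("coordinated conjuncts are recovered on their own spans", {
  lex <- toy_lexicon(c("magnesium hydroxide" = "DRUG",
                       "aluminium hydroxide" = "DRUG",
                       "renal failure" = "DIS"))
  text <- "Magnesium and aluminium hydroxide caused renal failure."
  a <- analyze1(text)
  m0 <- match_mentions(sentence_row(text), lex)
  expect_equal(m0$surface, c("aluminium hydroxide", "renal failure"))
  m1 <- resolve_coordination(a, m0, lex)
  co <- m1[m1$provenance == "COORDINATION", ]
  expect_equal(co$surface, "Magnesium")
  expect_equal(co$cui, lex$term_index[["magnesium hydroxide"]])
  # hyphenated premodifier coordination, conjuncts already in the lexicon:
  # re-running matching on the rewrites adds nothing new
  lex2 <- toy_lexicon(c("cisplatin" = "DRUG", "bleomycin" = "DRUG",
                        "tma" = "DIS"))
  text2 <- "Probable cisplatin and bleomycin-induced TMA is presented."
  m2 <- match_mentions(sentence_row(text2), lex2)
  m3 <- resolve_coordination(analyze1(text2), m2, lex2)
  expect_equal(m3[, c("start", "end", "cui")], m2[, c("start", "end", "cui")],
               ignore_attr = TRUE)
  # no conjunction: identity
  text3 <- "Cisplatin caused TMA."
  m4 <- match_mentions(sentence_row(text3), lex2)
  expect_equal(resolve_coordination(analyze1(text3), m4, lex2), m4,
               ignore_attr = TRUE)
})

test_that("term variation tries determiner drop, inversion, stripping", {
  lex <- toy_lexicon(c("acute intoxication" = "DIS",
                       "lung carcinoma" = "DIS"))
  expect_equal(vary_term("the acute intoxication", lex)$cuis,
               lex$term_index[["acute intoxication"]])
  expect_equal(vary_term("the acute intoxication", lex)$rule,
               "determiner_drop")
  hit <- vary_term("carcinoma of the lung", lex)
  expect_equal(hit$rule, "of_inversion")
  expect_equal(hit$cuis, lex$term_index[["lung carcinoma"]])
  expect_equal(vary_term("metastatic lung carcinoma", lex)$rule,
               "premodifier_strip")
  expect_null(vary_term("completely unrelated phrase", lex))
})

test_that("boundary correction trims function words and punctuation only", {
  text <- "He noted the asthma, worsening."
  a <- analyze1(text)
  mk <- function(s, e) data.frame(
    doc_id = "D1", sentence_index = 1L, start = s, end = e,
    surface = substr(text, s + 1L, e), cui = "C1",
    semantic_group = "DISORDERS", provenance = "DICTIONARY",
    stringsAsFactors = FALSE)
  trimmed <- correct_boundaries(mk(9L, 19L), a)     # "the asthma"
  expect_equal(trimmed$surface, "asthma")
  expect_equal(trimmed$provenance, "BOUNDARY_ADJUSTED")
  trailing <- correct_boundaries(mk(13L, 20L), a)   # "asthma,"
  expect_equal(trailing$surface, "asthma")
  clean <- correct_boundaries(mk(13L, 19L), a)      # already clean
  expect_equal(clean$surface, "asthma")
  expect_equal(clean$provenance, "DICTIONARY")
  # trimming to nothing drops the mention
  expect_equal(nrow(correct_boundaries(mk(9L, 12L), a)), 0L)
})

test_that("concept filtering removes non-NP and listed mentions", {
  lex <- toy_lexicon(c("worsening" = "DIS", "asthma" = "DIS",
                       "acute pain" = "DIS"))
  text <- "Symptoms were worsening the asthma with acute pain."
  a <- analyze1(text)
  m <- match_mentions(sentence_row(text), lex)
  expect_setequal(m$surface, c("worsening", "asthma", "acute pain"))
  kept <- filter_concepts(m, a)
  # "worsening" is a verb-chunk token overlapping no NP
  expect_false("worsening" %in% kept$surface)
  expect_true(all(c("asthma", "acute pain") %in% kept$surface))
  # filter list removes by CUI and by normalized term
  fl <- concept_filter_list(cuis = lex$term_index[["asthma"]])
  expect_false("asthma" %in% filter_concepts(m, a, fl)$surface)
  fl2 <- concept_filter_list(terms = "Acute   Pain")
  expect_false("acute pain" %in% filter_concepts(m, a, fl2)$surface)
  # partial overlap with an NP suffices to keep a mention
  nps <- a$noun_phrases
  pain <- m[m$surface == "acute pain", ]
  expect_true(any(nps$start < pain$end & pain$start < nps$end))
})

test_that("filter list files parse CUIs and terms with comments", {
  fl <- read_concept_filter_list(c("# comment", "C0123", "drug rash  # x",
                                   ""))
  expect_equal(fl$cuis, "C0123")
  expect_equal(fl$terms, "drug rash")
})

test_that("the rule pipeline is idempotent and leaves gold untouched", {
  fx <- default_test_fixture(n_documents = 40L)
  gold_before <- fx$corpus$relations
  m0 <- recognize_corpus(fx$corpus, fx$res$lexicon)
  m1 <- apply_nlp_rules(m0, fx$corpus, fx$res$lexicon)
  m2 <- apply_nlp_rules(m1, fx$corpus, fx$res$lexicon)
  expect_equal(m2, m1)
  expect_identical(fx$corpus$relations, gold_before)
  # every surviving mention overlaps an NP or came from abbreviation
  analyses <- analyze_corpus(fx$corpus)
  for (i in seq_len(nrow(m1))) {
    a <- analyses[[paste(m1$doc_id[i], m1$sentence_index[i], sep = "\r")]]
    ok <- m1$provenance[i] == "ABBREVIATION" ||
      any(a$noun_phrases$start < m1$end[i] &
            m1$start[i] < a$noun_phrases$end)
    expect_true(ok, info = paste(m1$doc_id[i], m1$surface[i]))
  }
})

test_that("NLP rules strictly raise gold-entity recall over dictionary", {
  fx <- default_test_fixture(n_documents = 80L)
  gold <- fx$corpus$relations
  gold_keys <- unique(c(
    paste(gold$doc_id, gold$drug_start, gold$drug_end),
    paste(gold$doc_id, gold$effect_start, gold$effect_end)))
  m0 <- recognize_corpus(fx$corpus, fx$res$lexicon)
  m1 <- apply_nlp_rules(m0, fx$corpus, fx$res$lexicon)
  recall_of <- function(m) {
    mean(gold_keys %in% paste(m$doc_id, m$start, m$end))
  }
  expect_gt(recall_of(m1), recall_of(m0))
  expect_equal(recall_of(m1), 1.0)
})

test_that("false-positive mention counts can seed the concept filter", {
  lex <- toy_lexicon(c("aspirin" = "DRUG", "patient" = "DIS"))
  sents <- rbind(sentence_row("The patient received aspirin."),
                 sentence_row("Another patient improved.", start = 30L,
                              sentence_index = 2L))
  corpus <- ade_corpus(sents)
  m <- recognize_corpus(corpus, lex)
  fl <- derive_concept_filter(m, corpus, min_count = 2L)
  expect_equal(fl$cuis, lex$term_index[["patient"]])
})
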