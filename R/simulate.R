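#' Specification of a synthetic test fixture
#'
#' Describes a seeded toy world: a lexicon of drug and disorder terms, a
#' typed concept graph with planted structure, and a template-generated
#' annotated corpus. True drug--effect pairs are wired into the graph at a
#' short distance through clean relation types; "far" decoy pairs sit
#' beyond the distance threshold; "trap" decoy pairs sit at a short
#' distance but every one of their shortest paths carries the planted
#' noise relation type, so the trained relation-type filter -- and only
#' the filter -- can reject them.
#'
#' @param n_drugs,n_disorders concept counts per group.
#' @param n_background_concepts extra background concepts (pendant or
#'   isolated), beyond the dedicated path nodes.
#' @param true_pair_distance planted distance of true pairs (default 3,
#'   under the default threshold of 4).
#' @param decoy_pair_min_distance planted distance of far decoys (default
#'   6, beyond the default threshold); must exceed `true_pair_distance`.
#' @param noise_relation_type the relation-type label planted on every hop
#'   of every trap-decoy shortest path.
#' @param n_trap_decoys,n_far_decoys decoy pair counts.
#' @param n_documents number of abstracts to generate.
#' @param negative_sentence_fraction share of sentences without a gold
#'   relation (default 0.64, echoing the corpus composition this fixture
#'   emulates).
#' @param coordination_rate,abbreviation_rate probability that a positive
#'   sentence uses the coordinated-drug template, respectively that a pair
#'   of positive sentences uses the abbreviation define/use pattern.
#' @param seed integer seed; all generators are pure functions of the spec.
#' @return list of class `ade_fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 20L, n_disorders = 20L,
                         n_background_concepts = 10L,
                         true_pair_distance = 3L,
                         decoy_pair_min_distance = 6L,
                         noise_relation_type = "co-reported-with",
                         n_trap_decoys = 25L, n_far_decoys = 25L,
                         n_documents = 200L,
                         negative_sentence_fraction = 0.64,
                         coordination_rate = 0.15,
                         abbreviation_rate = 0.15,
                         seed = 20140304L) {
  spec <- list(n_drugs = as.integer(n_drugs),
               n_disorders = as.integer(n_disorders),
               n_background_concepts = as.integer(n_background_concepts),
               true_pair_distance = as.integer(true_pair_distance),
               decoy_pair_min_distance = as.integer(decoy_pair_min_distance),
               noise_relation_type = noise_relation_type,
               n_trap_decoys = as.integer(n_trap_decoys),
               n_far_decoys = as.integer(n_far_decoys),
               n_documents = as.integer(n_documents),
               negative_sentence_fraction = negative_sentence_fraction,
               coordination_rate = coordination_rate,
               abbreviation_rate = abbreviation_rate,
               seed = as.integer(seed))
  rates <- c(spec$negative_sentence_fraction, spec$coordination_rate,
             spec$abbreviation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (spec$decoy_pair_min_distance <= spec$true_pair_distance) {
    stop("decoy_pair_min_distance must exceed true_pair_distance")
  }
  if (spec$true_pair_distance < 1L) stop("true_pair_distance must be >= 1")
  if (spec$n_drugs < 4L || spec$n_disorders < 4L) {
    stop("need at least 4 drugs and 4 disorders")
  }
  structure(spec, class = "ade_fixture_spec")
}

clean_relation_types <- function() {
  c("cause-of", "is-a", "associated-with", "manifestation-of")
}

## term inventories ----------------------------------------------------------

fixture_drug_terms <- function(n, n_family_drugs) {
  syl <- c("zor", "vel", "tam", "bri", "cus", "dol", "fen", "gat", "hex",
           "lim", "mor", "nev", "pex", "quil", "ras", "sul", "tor", "vex",
           "cro", "dap", "elo", "fin", "gos", "hib")
  suf <- c("mab", "cillin", "pril", "azole", "idone", "arone", "statin",
           "micin")
  heads <- c("chloride", "sulfate", "citrate", "acetate")
  bases <- character(n)
  k <- 0L
  for (i in seq_along(syl)) {
    for (j in seq_along(suf)) {
      k <- k + 1L
      if (k > n) break
      bases[k] <- paste0(syl[i], syl[(i + j) %% length(syl) + 1L], suf[j])
    }
    if (k > n) break
  }
  if (any(!nzchar(bases))) stop("too many drugs requested for the term pool")
  terms <- bases
  # the first n_family_drugs come in shared-head families of two, e.g.
  # "zorveltamab chloride" / "brimorsulmab chloride", which the coordinated
  # template renders as "zorveltamab and brimorsulmab chloride"
  for (i in seq_len(n_family_drugs)) {
    terms[i] <- paste(bases[i], heads[(i - 1L) %/% 2L %% length(heads) + 1L])
  }
  terms
}

fixture_disorder_terms <- function(n, n_abbrev) {
  adjs <- c("renal", "hepatic", "acute", "toxic", "chronic", "severe",
            "refractory", "progressive", "fulminant", "hemolytic")
  nouns <- c("neuropathy", "toxicity", "anemia", "fibrosis", "colitis",
             "myopathy", "dermatitis", "nephritis", "pancreatitis",
             "vasculitis")
  tails <- c("syndrome", "reaction", "disorder")
  terms <- character(n)
  k <- 0L
  for (i in seq_along(adjs)) {
    for (j in seq_along(nouns)) {
      k <- k + 1L
      if (k > n) break
      terms[k] <- paste(adjs[i], nouns[(i + j - 2L) %% length(nouns) + 1L])
    }
    if (k > n) break
  }
  if (any(!nzchar(terms))) {
    stop("too many disorders requested for the term pool")
  }
  # the first n_abbrev disorders get a third word so their initials form a
  # 3-letter short form for the abbreviation define/use pattern
  sfs <- character(n)
  for (i in seq_len(n_abbrev)) {
    terms[i] <- paste(terms[i], tails[(i - 1L) %% length(tails) + 1L])
    sfs[i] <- toupper(paste(substr(strsplit(terms[i], " ")[[1L]], 1L, 1L),
                            collapse = ""))
  }
  # keep only short forms that are unique
  dup <- sfs[duplicated(sfs[nzchar(sfs)])]
  sfs[sfs %in% dup] <- ""
  list(terms = terms, short_forms = sfs)
}

## resources -----------------------------------------------------------------

#' Generate the fixture lexicon, concept graph, and planted truth table
#'
#' Builds drug and disorder inventories (including multiword and
#' shared-head terms), wires every planted true pair into the graph at
#' `true_pair_distance` through dedicated path nodes with clean relation
#' types, wires far decoys at `decoy_pair_min_distance`, and wires trap
#' decoys at distance 2 with the noise relation type on both hops (so
#' every shortest path of a trap pair is tainted). Path nodes are
#' dedicated per pair, which guarantees the planted distances exactly.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `ade_fixture_resources`: `lexicon`, `graph`,
#'   `truth` (data.frame `drug_cui`, `effect_cui`, `class` in
#'   `true`/`trap`/`far`, `planted_distance`), and `terms` (the term
#'   inventory with coordination/abbreviation bookkeeping).
#' @export
generate_fixture_resources <- function(spec) {
  stopifnot(inherits(spec, "ade_fixture_spec"))
  with_seed(spec$seed, {
    n_fam <- min(6L, 2L * (spec$n_drugs %/% 4L))  # family drugs, pairs of 2
    n_abbrev <- min(6L, spec$n_disorders %/% 3L)
    drug_terms <- fixture_drug_terms(spec$n_drugs, n_fam)
    dis <- fixture_disorder_terms(spec$n_disorders, n_abbrev)
    terms <- rbind(
      new_df(cui = sprintf("C1%04d", seq_len(spec$n_drugs)),
             term = drug_terms, semantic_group = "CHEMICALS_AND_DRUGS",
             family = c(rep(seq_len(n_fam %/% 2L), each = 2L),
                        rep(NA_integer_, spec$n_drugs - n_fam)),
             short_form = NA_character_),
      new_df(cui = sprintf("C2%04d", seq_len(spec$n_disorders)),
             term = dis$terms, semantic_group = "DISORDERS",
             family = NA_integer_,
             short_form = ifelse(nzchar(dis$short_forms),
                                 dis$short_forms, NA_character_)))
    drugs <- terms[terms$semantic_group == "CHEMICALS_AND_DRUGS", ]
    disorders <- terms[terms$semantic_group == "DISORDERS", ]

    # planted true pairs: family members share one effect (so coordinated
    # sentences yield two extractable gold relations); the rest map 1-1
    truth <- list()
    used_dis <- integer()
    for (f in unique(stats::na.omit(drugs$family))) {
      members <- which(drugs$family %in% f)
      di <- setdiff(seq_len(nrow(disorders)), used_dis)[1L]
      used_dis <- c(used_dis, di)
      for (m in members) {
        truth[[length(truth) + 1L]] <- new_df(
          drug_cui = drugs$cui[m], effect_cui = disorders$cui[di],
          class = "true", planted_distance = spec$true_pair_distance)
      }
    }
    solo <- which(is.na(drugs$family))
    for (m in solo) {
      pool <- setdiff(seq_len(nrow(disorders)), used_dis)
      di <- if (length(pool)) pool[1L] else
        sample.int(nrow(disorders), 1L)
      used_dis <- c(used_dis, di)
      truth[[length(truth) + 1L]] <- new_df(
        drug_cui = drugs$cui[m], effect_cui = disorders$cui[di],
        class = "true", planted_distance = spec$true_pair_distance)
    }
    truth <- rbind_df(truth)
    true_keys <- paste(truth$drug_cui, truth$effect_cui)

    # decoy pairs drawn from the non-true cross product
    all_pairs <- expand.grid(drug_cui = drugs$cui,
                             effect_cui = disorders$cui,
                             stringsAsFactors = FALSE)
    free <- all_pairs[!(paste(all_pairs$drug_cui, all_pairs$effect_cui) %in%
                          true_keys), ]
    need <- spec$n_trap_decoys + spec$n_far_decoys
    if (need > nrow(free)) {
      stop("infeasible fixture spec: ", need, " decoy pairs requested but ",
           "only ", nrow(free), " non-true pairs exist")
    }
    pick <- sample.int(nrow(free), need)
    traps <- free[pick[seq_len(spec$n_trap_decoys)], ]
    fars <- free[pick[spec$n_trap_decoys + seq_len(spec$n_far_decoys)], ]
    traps$class <- rep("trap", nrow(traps))
    traps$planted_distance <- rep(2L, nrow(traps))
    fars$class <- rep("far", nrow(fars))
    fars$planted_distance <- rep(spec$decoy_pair_min_distance, nrow(fars))
    truth <- rbind(truth, traps, fars)
    rownames(truth) <- NULL

    # wire the graph: dedicated chain nodes per pair keep the planted
    # distances exact (shared endpoints cannot create shortcuts: any
    # composite drug-to-disorder walk concatenates >= 3 planted segments)
    clean <- clean_relation_types()
    edges <- list()
    node_id <- 0L
    chain <- function(a, b, len, types) {
      nodes <- a
      if (len > 1L) {
        for (k in seq_len(len - 1L)) {
          node_id <<- node_id + 1L
          nodes <- c(nodes, sprintf("C9%05d", node_id))
        }
      }
      nodes <- c(nodes, b)
      for (k in seq_len(len)) {
        edges[[length(edges) + 1L]] <<- new_df(
          cui_a = nodes[k], cui_b = nodes[k + 1L],
          relation_type = types[(k - 1L) %% length(types) + 1L])
      }
    }
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      if (r$class == "trap") {
        chain(r$drug_cui, r$effect_cui, 2L, spec$noise_relation_type)
      } else {
        chain(r$drug_cui, r$effect_cui, r$planted_distance,
              sample(clean, max(2L, r$planted_distance), replace = TRUE))
      }
    }
    edges <- rbind_df(edges)
    # background concepts: half pendant on random chain nodes, half isolated
    extra <- sprintf("C8%04d", seq_len(spec$n_background_concepts))
    pendant <- extra[seq_len(spec$n_background_concepts %/% 2L)]
    anchors <- unique(c(edges$cui_a, edges$cui_b))
    for (p in pendant) {
      edges <- rbind(edges, new_df(
        cui_a = p, cui_b = anchors[sample.int(length(anchors), 1L)],
        relation_type = clean[sample.int(length(clean), 1L)]))
    }
    groups <- terms[, c("cui", "semantic_group")]
    lex <- lexicon(terms[, c("term", "cui")], groups)
    graph <- concept_graph(edges, concepts = extra,
                           term_tier = new_df(term = terms$term,
                                              cui = terms$cui),
                           type_tier = new_df(
                             cui = terms$cui,
                             semantic_type = terms$semantic_group))
    structure(list(lexicon = lex, graph = graph, truth = truth,
                   terms = terms, spec = spec),
              class = "ade_fixture_resources")
  })
}

## corpus --------------------------------------------------------------------

# assemble a sentence from parts; parts with a role become gold entities
render_parts <- function(parts) {
  text <- ""
  ents <- list()
  for (p in parts) {
    start <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.null(p$role)) {
      ents[[length(ents) + 1L]] <- list(role = p$role, start = start,
                                        end = nchar(text),
                                        surface = p$text)
    }
  }
  list(text = text, entities = ents)
}

txt <- function(x) list(text = x)
ent <- function(x, role) list(text = x, role = role)

# one planned sentence: rendered text plus gold (drug, effect) entity index
# pairs into the entity list
plan_simple <- function(drug_term, effect_term, variant = 1L,
                        hyphenate = FALSE) {
  if (hyphenate && grepl(" ", effect_term) &&
      length(strsplit(effect_term, " ")[[1L]]) == 2L) {
    effect_term <- sub(" ", "-", effect_term)
  }
  parts <- switch(
    variant,
    list(ent(effect_term, "ADVERSE_EFFECT"),
         txt(" as a complication of "), ent(drug_term, "DRUG"),
         txt(" treatment.")),
    list(ent(drug_term, "DRUG"), txt("-induced "),
         ent(effect_term, "ADVERSE_EFFECT"), txt(" was observed.")),
    list(txt("A patient developed "), ent(effect_term, "ADVERSE_EFFECT"),
         txt(" after "), ent(drug_term, "DRUG"), txt(" therapy.")))
  r <- render_parts(parts)
  r$relations <- list(c(drug = 1L, effect = 2L))
  # entity order differs per template: locate by role
  roles <- vapply(r$entities, `[[`, "", "role")
  r$relations <- list(c(drug = which(roles == "DRUG")[1L],
                        effect = which(roles == "ADVERSE_EFFECT")[1L]))
  r
}

plan_coordination <- function(term1, term2, effect_term) {
  w1 <- strsplit(term1, " ")[[1L]]
  w2 <- strsplit(term2, " ")[[1L]]
  stopifnot(length(w1) == 2L, length(w2) == 2L, w1[2L] == w2[2L])
  parts <- list(ent(w1[1L], "DRUG"), txt(" and "), ent(term2, "DRUG"),
                txt("-induced "), ent(effect_term, "ADVERSE_EFFECT"),
                txt(" was reported."))
  r <- render_parts(parts)
  r$relations <- list(c(drug = 1L, effect = 3L), c(drug = 2L, effect = 3L))
  r
}

plan_abbrev_define <- function(drug_term, effect_term, sf) {
  parts <- list(txt("Patients treated with "), ent(drug_term, "DRUG"),
                txt(" developed "), ent(effect_term, "ADVERSE_EFFECT"),
                txt(paste0(" (", sf, ").")))
  r <- render_parts(parts)
  r$relations <- list(c(drug = 1L, effect = 2L))
  r
}

plan_abbrev_use <- function(drug_term, sf) {
  parts <- list(txt("The "), ent(sf, "ADVERSE_EFFECT"),
                txt(" resolved after withdrawal of "),
                ent(drug_term, "DRUG"), txt("."))
  r <- render_parts(parts)
  r$relations <- list(c(drug = 2L, effect = 1L))
  r
}

plan_negative <- function(kind, drug_term = NULL, effect_term = NULL,
                          variant = 1L) {
  parts <- switch(
    kind,
    trap = list(ent(drug_term, "DRUG"), txt(" was administered for "),
                ent(effect_term, "ADVERSE_EFFECT"), txt(".")),
    far = list(ent(drug_term, "DRUG"), txt(" was given while "),
               ent(effect_term, "ADVERSE_EFFECT"), txt(" was monitored.")),
    plain = switch(
      variant,
      list(txt("No new safety signals were recorded during follow-up.")),
      list(ent(drug_term, "DRUG"),
           txt(" dose was tapered gradually over two weeks.")),
      list(ent(effect_term, "ADVERSE_EFFECT"),
           txt(" was noted in the family history."))))
  r <- render_parts(parts)
  r$relations <- list()
  r
}

#' Generate the fixture corpus with exact gold offsets
#'
#' Renders template sentences over the planted truth table: simple,
#' coordinated (`"<drug1> and <drug2>-induced <effect>"`), and
#' abbreviation define/use positive sentences, plus relation-free negative
#' sentences mentioning trap pairs, far pairs, or no pair at all. Gold
#' offsets are computed from the rendered strings and checked at emission;
#' within each document positive sentences precede negative ones. The
#' generator is a pure function of `(spec, seed)`.
#'
#' @param spec a [fixture_spec()].
#' @param resources output of [generate_fixture_resources()] for the same
#'   spec.
#' @return an [ade_corpus()].
#' @export
generate_fixture_corpus <- function(spec, resources) {
  stopifnot(inherits(resources, "ade_fixture_resources"))
  terms <- resources$terms
  truth <- resources$truth
  term_of <- function(cui) terms$term[match(cui, terms$cui)]
  sf_of <- function(cui) terms$short_form[match(cui, terms$cui)]
  true_pairs <- truth[truth$class == "true", ]
  trap_pairs <- truth[truth$class == "trap", ]
  far_pairs <- truth[truth$class == "far", ]
  # coordination-capable pairs: both family members of one family
  fam <- terms[!is.na(terms$family), ]
  coord_fams <- unique(fam$family)
  # abbreviation-capable true pairs: effect has a usable short form
  abbrev_pairs <- true_pairs[!is.na(sf_of(true_pairs$effect_cui)), ]
  simple_pairs <- true_pairs

  with_seed(spec$seed + 1L, {
    n_sent_per_doc <- sample(3:5, spec$n_documents, replace = TRUE)
    total <- sum(n_sent_per_doc)
    n_neg <- round(spec$negative_sentence_fraction * total)
    slot_is_neg <- sample(rep(c(TRUE, FALSE), c(n_neg, total - n_neg)))
    sent_rows <- list()
    rel_rows <- list()
    slot <- 0L
    for (doc in seq_len(spec$n_documents)) {
      doc_id <- sprintf("D%04d", doc)
      plans <- list()
      neg_plans <- list()
      n_here <- n_sent_per_doc[doc]
      flags <- slot_is_neg[slot + seq_len(n_here)]
      slot <- slot + n_here
      n_pos_here <- sum(!flags)
      seen_texts <- character()
      # within a document every sentence string must be unique: the ADE
      # serialization keys sentences on (doc_id, text), so duplicates would
      # not round-trip; re-draw on collision
      add_unique <- function(make_plan, tries = 20L) {
        for (a in seq_len(tries)) {
          pl <- make_plan()
          if (is.null(pl)) return(NULL)
          texts <- vapply(pl, `[[`, "", "text")
          if (!any(texts %in% seen_texts)) {
            seen_texts <<- c(seen_texts, texts)
            return(pl)
          }
        }
        NULL
      }
      i <- 1L
      while (i <= n_pos_here) {
        u <- stats::runif(1L)
        pl <- NULL
        if (u < spec$abbreviation_rate && i + 1L <= n_pos_here &&
            nrow(abbrev_pairs) > 0L) {
          pl <- add_unique(function() {
            p <- abbrev_pairs[sample.int(nrow(abbrev_pairs), 1L), ]
            list(plan_abbrev_define(term_of(p$drug_cui),
                                    term_of(p$effect_cui),
                                    sf_of(p$effect_cui)),
                 plan_abbrev_use(term_of(p$drug_cui), sf_of(p$effect_cui)))
          })
        } else if (u < spec$abbreviation_rate + spec$coordination_rate &&
                   length(coord_fams) > 0L) {
          pl <- add_unique(function() {
            f <- coord_fams[sample.int(length(coord_fams), 1L)]
            members <- fam$cui[fam$family == f]
            eff <- true_pairs$effect_cui[
              true_pairs$drug_cui == members[1L]][1L]
            list(plan_coordination(term_of(members[1L]),
                                   term_of(members[2L]), term_of(eff)))
          })
        }
        if (is.null(pl)) {
          pl <- add_unique(function() {
            p <- simple_pairs[sample.int(nrow(simple_pairs), 1L), ]
            list(plan_simple(term_of(p$drug_cui), term_of(p$effect_cui),
                             variant = sample.int(3L, 1L),
                             hyphenate = stats::runif(1L) < 0.1))
          })
        }
        if (is.null(pl)) break     # document exhausted its unique pool
        plans <- c(plans, pl)
        i <- i + length(pl)
      }
      for (j in seq_len(sum(flags))) {
        pl <- add_unique(function() {
          u <- stats::runif(1L)
          if (u < 0.4 && nrow(trap_pairs) > 0L) {
            p <- trap_pairs[sample.int(nrow(trap_pairs), 1L), ]
            list(plan_negative("trap", term_of(p$drug_cui),
                               term_of(p$effect_cui)))
          } else if (u < 0.7 && nrow(far_pairs) > 0L) {
            p <- far_pairs[sample.int(nrow(far_pairs), 1L), ]
            list(plan_negative("far", term_of(p$drug_cui),
                               term_of(p$effect_cui)))
          } else {
            v <- sample.int(3L, 1L)
            p <- truth[sample.int(nrow(truth), 1L), ]
            list(plan_negative("plain", term_of(p$drug_cui),
                               term_of(p$effect_cui), variant = v))
          }
        })
        if (!is.null(pl)) neg_plans <- c(neg_plans, pl)
      }
      plans <- c(plans, neg_plans)        # positives first within a doc
      pos0 <- 0L
      for (k in seq_along(plans)) {
        pl <- plans[[k]]
        sent_rows[[length(sent_rows) + 1L]] <- new_df(
          doc_id = doc_id, sentence_index = k, text = pl$text,
          start = pos0, end = pos0 + nchar(pl$text))
        for (rel in pl$relations) {
          de <- pl$entities[[rel[["drug"]]]]
          ee <- pl$entities[[rel[["effect"]]]]
          rel_rows[[length(rel_rows) + 1L]] <- new_df(
            doc_id = doc_id, sentence_index = k,
            drug_text = de$surface, drug_start = pos0 + de$start,
            drug_end = pos0 + de$end, effect_text = ee$surface,
            effect_start = pos0 + ee$start, effect_end = pos0 + ee$end)
        }
        pos0 <- pos0 + nchar(pl$text) + 1L   # single-space join
      }
    }
    ade_corpus(rbind_df(sent_rows, empty_sentences()),
               rbind_df(rel_rows, empty_relations()))
  })
}

#' Emit a fixture to disk as plain-text files
#'
#' Writes the lexicon TSV (`term`, `cui`), group table TSV, relation-table
#' TSV, ADE-format relation and negative-sentence files, and the planted
#' truth table as JSON into a directory.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture <- function(spec, dir) {
  res <- generate_fixture_resources(spec)
  corpus <- generate_fixture_corpus(spec, res)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(lexicon = file.path(dir, "lexicon.tsv"),
             groups = file.path(dir, "groups.tsv"),
             relations = file.path(dir, "graph_relations.tsv"),
             ade = file.path(dir, "corpus_relations.psv"),
             negatives = file.path(dir, "corpus_negatives.psv"),
             truth = file.path(dir, "truth.json"))
  ents <- res$lexicon$entries
  writeLines(paste(ents$preferred_term, ents$cui, sep = "\t"),
             paths["lexicon"])
  writeLines(paste(ents$cui, ents$semantic_group, sep = "\t"),
             paths["groups"])
  e <- res$graph$edges
  writeLines(paste(e$cui_a, e$cui_b, e$relation_type, sep = "\t"),
             paths["relations"])
  write_ade_corpus(corpus, paths["ade"], paths["negatives"])
  jsonlite::write_json(res$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
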