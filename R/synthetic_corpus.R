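#' Default planted phrase families
#'
#' Six disease-topic families and three filler families. Each family's
#' member phrases are built with the two variation operators the string
#' similarity must absorb — word-order permutation and numeral aliasing /
#' single-letter edits — plus one longer phrase containing the base phrase,
#' which is only reachable through context similarity. Members 3 and 4 of
#' every family form an exclusive pair: the generator never puts them in
#' the same document, so they are context-sharing but never co-mentioned
#' (the situation context similarity exists to absorb). Partner phrases
#' accompany the members in documents and provide the shared third-party
#' context.
#'
#' @return A list of family definitions (name, members, partners,
#'   exclusive pair indices, disease_topic flag).
#' @export
default_phrase_families <- function() {
  fam <- function(name, members, partners, disease_topic = TRUE)
    list(name = name, members = members, partners = partners,
         exclusive = c(3L, 4L), disease_topic = disease_topic)
  list(
    fam("glucose_homeostasis",
        c("glucose homeostasis", "homeostasis glucose",
          "glucose homeostasys", "impaired glucose homeostasis"),
        c("islet perifusion", "glycogen turnover", "hepatic output")),
    fam("insulin_resistance",
        c("insulin resistance", "resistance insulin",
          "insulin resistence", "severe insulin resistance"),
        c("euglycemic clamp", "adipocyte signalling", "muscle uptake")),
    fam("type_2_diabetes",
        c("type 2 diabetes", "diabetes type ii",
          "type ii diabetes", "type 2 diabetis"),
        c("sulfonylurea therapy", "incretin axis", "metformin response")),
    fam("beta_cell_function",
        c("beta cell function", "function beta cell",
          "beta cell functon", "pancreatic beta cell function"),
        c("granule exocytosis", "calcium oscillation", "apoptosis cascade")),
    fam("glucagon_secretion",
        c("glucagon secretion", "secretion glucagon",
          "glucagon secretoin", "basal glucagon secretion"),
        c("portal signalling", "somatostatin tone", "alpha granularity")),
    fam("lipid_oxidation",
        c("lipid oxidation", "oxidation lipid",
          "lipid oxidatoin", "hepatic lipid oxidation"),
        c("mitochondrial flux", "acyl shuttle", "ketone spillover")),
    fam("patient_survey",
        c("patient questionnaire", "questionnaire patient",
          "patient questionaire", "validated patient questionnaire"),
        c("clinic visits", "response scale"), disease_topic = FALSE),
    fam("hospital_admin",
        c("hospital readmission", "readmission hospital",
          "hospital readmision", "repeat hospital readmission"),
        c("billing codes", "ward census"), disease_topic = FALSE),
    fam("image_analysis",
        c("image segmentation", "segmentation image",
          "image segmentatoin", "automated image segmentation"),
        c("voxel grid", "contour fitting"), disease_topic = FALSE)
  )
}

#' Configuration of the synthetic corpus generator
#'
#' The generator emulates weekly batches of short abstracts: filler tokens
#' drawn from an arbitrary vocabulary, multi-word phrases drawn from latent
#' phrase families (with spelling and word-order variants), protein and
#' disease mentions at controlled rates, one weekly "hub" document loaded
#' with phrases from two families (mentioning a planted high-relevance
#' protein), and one "jumper" document at a chosen week that is loaded with
#' phrases from `boost` families and mentions a previously quiet protein.
#'
#' @param n_weeks Number of weekly batches (default 60).
#' @param docs_per_week Documents per week (default 50).
#' @param vocabulary_size Filler vocabulary size (default 500).
#' @param phrase_families As [default_phrase_families()].
#' @param n_core_proteins Disease-linked proteins appearing in topic
#'   documents (default 10).
#' @param n_background_proteins Background proteins (default 90).
#' @param p_topic_doc Probability a non-hub document is about a disease
#'   topic (default 0.35).
#' @param p_disease_in_topic,p_disease_in_filler Probability that a topic /
#'   filler document mentions the disease (defaults 0.6 and 0.03).
#' @param background_topic_rates Range of per-protein probabilities that a
#'   topic document additionally mentions a given background protein;
#'   log-spaced across proteins (default `c(0.001, 0.02)`).
#' @param filler_mention_rate Probability any document mentions a given
#'   protein as background noise (default 0.004).
#' @param p_filler_phrases Probability a filler document carries phrases of
#'   a (non-disease) filler family (default 0.35).
#' @param filler_len Range of filler token counts per document
#'   (default `c(20, 35)`).
#' @param jumper List `(protein_id, week, boost)`: the jumper protein, the
#'   week of its loaded abstract, and how many disease families that
#'   abstract draws phrases from (defaults `"PJUMP"`, `n_weeks - 10`, 6).
#' @param hub_protein Protein mentioned by the weekly hub document
#'   (default `"HUBP"`).
#' @param disease_id,disease_synonyms Disease identity for the dictionary.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_weeks = 60L, docs_per_week = 50L,
                             vocabulary_size = 500L,
                             phrase_families = default_phrase_families(),
                             n_core_proteins = 10L,
                             n_background_proteins = 90L,
                             p_topic_doc = 0.3,
                             p_disease_in_topic = 0.65,
                             p_disease_in_filler = 0.03,
                             background_topic_rates = c(0.001, 0.02),
                             filler_mention_rate = 0.004,
                             p_filler_phrases = 0.35,
                             filler_len = c(20L, 35L),
                             jumper = NULL,
                             hub_protein = "HUBP",
                             disease_id = "T2D",
                             disease_synonyms = c("t2d", "t2dm"),
                             seed = 1L) {
  if (is.null(jumper))
    jumper <- list(protein_id = "PJUMP",
                   week = as.integer(max(1L, n_weeks - 10L)), boost = 6L)
  cfg <- list(n_weeks = as.integer(n_weeks),
              docs_per_week = as.integer(docs_per_week),
              vocabulary_size = as.integer(vocabulary_size),
              phrase_families = phrase_families,
              n_core_proteins = as.integer(n_core_proteins),
              n_background_proteins = as.integer(n_background_proteins),
              p_topic_doc = p_topic_doc,
              p_disease_in_topic = p_disease_in_topic,
              p_disease_in_filler = p_disease_in_filler,
              background_topic_rates = background_topic_rates,
              filler_mention_rate = filler_mention_rate,
              p_filler_phrases = p_filler_phrases,
              filler_len = as.integer(filler_len),
              jumper = jumper, hub_protein = hub_protein,
              disease_id = disease_id, disease_synonyms = disease_synonyms,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, field) if (!isTRUE(cond)) bad <<- c(bad, field)
  chk(cfg$n_weeks >= 1L, "n_weeks")
  chk(cfg$docs_per_week >= 1L, "docs_per_week")
  chk(cfg$vocabulary_size >= 10L, "vocabulary_size")
  probs <- c(cfg$p_topic_doc, cfg$p_disease_in_topic, cfg$p_disease_in_filler,
             cfg$background_topic_rates, cfg$filler_mention_rate,
             cfg$p_filler_phrases)
  chk(all(probs >= 0 & probs <= 1), "probabilities")
  chk(length(cfg$filler_len) == 2L && cfg$filler_len[1] >= 1L &&
        cfg$filler_len[2] >= cfg$filler_len[1], "filler_len")
  chk(is.list(cfg$jumper) &&
        all(c("protein_id", "week", "boost") %in% names(cfg$jumper)),
      "jumper")
  if (is.list(cfg$jumper) && !is.null(cfg$jumper$week))
    chk(cfg$jumper$week >= 1L && cfg$jumper$week <= cfg$n_weeks,
        "jumper$week")
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed")
  if (length(bad))
    stop("invalid generator config field(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

# planted protein universe: core proteins with decreasing topic affinity,
# background proteins with log-spaced topic rates, plus hub and jumper
generator_proteins <- function(cfg) {
  nc <- cfg$n_core_proteins
  core <- data.table(
    protein_id = sprintf("CORE%02d", seq_len(nc)),
    class = "core",
    # all core proteins are strongly disease-linked (that is what makes
    # them core); affinities vary only 2-fold across the set
    affinity = 0.5 + 0.5 * rev(seq_len(nc)) / nc,
    topic_rate = NA_real_)
  nb <- cfg$n_background_proteins
  bg <- data.table(
    protein_id = sprintf("PROT%03d", seq_len(nb)),
    class = "background", affinity = 0,
    topic_rate = exp(seq(log(cfg$background_topic_rates[1]),
                         log(cfg$background_topic_rates[2]),
                         length.out = max(nb, 2L)))[seq_len(nb)])
  extra <- data.table(
    protein_id = c(cfg$hub_protein, cfg$jumper$protein_id),
    class = c("hub", "jumper"), affinity = 0, topic_rate = 0)
  rbindlist(list(core, bg, extra))
}

#' Entity dictionary implied by a generator configuration
#'
#' One synonym per protein (its lower-cased id) plus the disease synonyms.
#'
#' @param cfg A `generator_config`.
#' @return An `entity_dictionary`.
#' @export
generate_dictionary <- function(cfg) {
  prot <- generator_proteins(cfg)
  entity_dictionary(
    entity_id = c(prot$protein_id, rep(cfg$disease_id,
                                       length(cfg$disease_synonyms))),
    entity_class = c(rep("protein", nrow(prot)),
                     rep("disease", length(cfg$disease_synonyms))),
    synonym = c(tolower(prot$protein_id), cfg$disease_synonyms))
}

#' Planted ground truth of a generator configuration
#'
#' Everything the recovery tests need, derivable from the configuration
#' alone: phrase-family membership (members and partners, disease-topic
#' flag), the intended core proteins, the hub protein, and the jump event.
#'
#' @param cfg A `generator_config`.
#' @return A `ground_truth` list with elements `families`
#'   (`data.table(family, phrase, role, disease_topic)`), `core_proteins`,
#'   `hub_protein`, `jumper`, `disease_id`.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  fams <- rbindlist(lapply(cfg$phrase_families, function(f)
    data.table(family = f$name,
               phrase = c(f$members, f$partners),
               role = c(rep("member", length(f$members)),
                        rep("partner", length(f$partners))),
               disease_topic = f$disease_topic)))
  if (is.null(fams)) fams <- data.table(family = character(),
                                        phrase = character(),
                                        role = character(),
                                        disease_topic = logical())
  prot <- generator_proteins(cfg)
  structure(list(families = fams,
                 core_proteins = prot[class == "core", protein_id],
                 hub_protein = cfg$hub_protein,
                 jumper = cfg$jumper,
                 disease_id = cfg$disease_id),
            class = "ground_truth")
}

#' Write / read ground truth as a JSON sidecar
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return The truth object (read) or `path` invisibly (write).
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(families = as.data.frame(truth$families),
              core_proteins = truth$core_proteins,
              hub_protein = truth$hub_protein,
              jumper = truth$jumper,
              disease_id = truth$disease_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(families = as.data.table(obj$families),
                 core_proteins = obj$core_proteins,
                 hub_protein = obj$hub_protein,
                 jumper = obj$jumper,
                 disease_id = obj$disease_id),
            class = "ground_truth")
}

#' Generate a synthetic corpus with planted structure
#'
#' Samples `n_weeks * docs_per_week` documents. The first document of every
#' week is the hub document (phrases from two disease families plus the hub
#' protein); at the jumper week the last document is the loaded jumper
#' abstract. Every other document is a topic document with probability
#' `p_topic_doc` (two member phrases — never the family's exclusive pair
#' together — and two partner phrases of one disease family, core-protein
#' mentions, and a disease mention with probability `p_disease_in_topic`)
#' or otherwise a filler document (random tokens, possibly a filler-family
#' phrase pair, low-rate protein and disease mentions). All randomness is
#' governed by `cfg$seed`; the same configuration always yields an
#' identical corpus.
#'
#' @param cfg A `generator_config`.
#' @return List with `corpus` (a `lit_corpus`), `truth` (the
#'   [ground_truth()] plus a per-document composition table `docs`), and
#'   `dictionary` (the matching [generate_dictionary()]).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  vocab <- sprintf("w%03d", seq_len(cfg$vocabulary_size))
  prot <- generator_proteins(cfg)
  core <- prot[class == "core"]
  bg <- prot[class == "background"]
  dis_fams <- Filter(function(f) isTRUE(f$disease_topic), cfg$phrase_families)
  fil_fams <- Filter(function(f) !isTRUE(f$disease_topic), cfg$phrase_families)

  member_weights <- function(f) {
    w <- rev(seq_along(f$members)) + 1
    w / sum(w)
  }
  sample_members <- function(f, k = 2L) {
    k <- min(k, length(f$members))
    repeat {
      s <- sample(seq_along(f$members), k, prob = member_weights(f))
      if (length(f$exclusive) < 2L ||
          !all(f$exclusive[1:2] %in% s)) return(f$members[s])
    }
  }
  sample_partners <- function(f, k = 2L)
    f$partners[sample(seq_along(f$partners), min(k, length(f$partners)))]
  # topic documents carry a full phrase complement of one family; hub and
  # jumper documents take a single member + partner per family so that
  # spanning several families does not plant systematic cross-family
  # co-occurrence
  family_phrases <- function(f, n_members = 2L, n_partners = 2L)
    c(sample_members(f, n_members), sample_partners(f, n_partners))

  n_docs <- cfg$n_weeks * cfg$docs_per_week
  texts <- character(n_docs)
  weeks <- integer(n_docs)
  types <- character(n_docs)
  fam_of <- character(n_docs)
  has_dis <- logical(n_docs)
  prot_list <- vector("list", n_docs)

  idx <- 0L
  for (w in seq_len(cfg$n_weeks)) {
    for (d in seq_len(cfg$docs_per_week)) {
      idx <- idx + 1L
      weeks[idx] <- w
      is_hub <- d == 1L && length(dis_fams) > 0L
      is_jumper <- w == cfg$jumper$week && d == cfg$docs_per_week &&
        length(dis_fams) > 0L
      phrases <- character(0)
      mentions <- character(0)
      fam_name <- NA_character_
      if (is_jumper) {
        # the loaded abstract talks pure disease biology without naming the
        # disease: relevance must come through the concepts alone
        types[idx] <- "jumper"
        k <- min(cfg$jumper$boost, length(dis_fams))
        for (f in dis_fams[seq_len(k)])
          phrases <- c(phrases, family_phrases(f, 1L, 1L))
        mentions <- cfg$jumper$protein_id
        dis <- runif(1) < cfg$p_disease_in_filler
      } else if (is_hub) {
        types[idx] <- "hub"
        pick <- sample(seq_along(dis_fams), min(2L, length(dis_fams)))
        for (f in dis_fams[pick])
          phrases <- c(phrases, family_phrases(f, 1L, 1L))
        mentions <- cfg$hub_protein
        dis <- runif(1) < cfg$p_disease_in_filler
      } else if (length(dis_fams) > 0L && runif(1) < cfg$p_topic_doc) {
        types[idx] <- "topic"
        fi <- sample(seq_along(dis_fams), 1L)
        fam_name <- dis_fams[[fi]]$name
        phrases <- family_phrases(dis_fams[[fi]])
        n_core_men <- 1L + stats::rbinom(1L, 1L, 0.6)
        mentions <- sample(core$protein_id, min(n_core_men, nrow(core)),
                           prob = core$affinity)
        hits <- bg$protein_id[runif(nrow(bg)) < bg$topic_rate]
        mentions <- c(mentions, hits)
        dis <- runif(1) < cfg$p_disease_in_topic
      } else {
        types[idx] <- "filler"
        if (length(fil_fams) > 0L && runif(1) < cfg$p_filler_phrases) {
          fi <- sample(seq_along(fil_fams), 1L)
          fam_name <- fil_fams[[fi]]$name
          phrases <- c(sample_members(fil_fams[[fi]]),
                       sample_partners(fil_fams[[fi]], 1L))
        }
        dis <- runif(1) < cfg$p_disease_in_filler
      }
      noise <- prot$protein_id[runif(nrow(prot)) < cfg$filler_mention_rate]
      mentions <- unique(c(mentions, noise))
      fam_of[idx] <- fam_name
      has_dis[idx] <- dis
      prot_list[idx] <- list(mentions)
      dis_tok <- if (dis) sample(cfg$disease_synonyms, 1L) else character(0)
      len <- sample(cfg$filler_len[1]:cfg$filler_len[2], 1L)
      filler <- sample(vocab, len, replace = TRUE)
      inserts <- c(as.list(strsplit(phrases, " ", fixed = TRUE)),
                   as.list(tolower(mentions)), as.list(dis_tok))
      texts[idx] <- paste(interleave_tokens(filler, inserts), collapse = " ")
    }
  }
  doc_ids <- sprintf("D%05d", seq_len(n_docs))
  # single-token titles: a shared multi-word title would plant a
  # corpus-wide n-gram
  corpus <- as_corpus(doc_ids, weeks,
                      title = sprintf("t%05d", seq_len(n_docs)),
                      abstract = texts)
  truth <- ground_truth(cfg)
  truth$docs <- data.table(doc_id = doc_ids, week = weeks, doc_type = types,
                           family = fam_of, disease = has_dis,
                           proteins = prot_list)
  list(corpus = corpus, truth = truth, dictionary = generate_dictionary(cfg))
}

# insert token groups at random gaps of the filler stream, keeping each
# group contiguous
interleave_tokens <- function(filler, groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) == 0L) return(filler)
  gaps <- sample(0:length(filler), length(groups), replace = TRUE)
  ord <- order(gaps)
  gaps <- gaps[ord]; groups <- groups[ord]
  out <- vector("list", 2L * length(groups) + 1L)
  prev <- 0L
  for (k in seq_along(groups)) {
    out[[2L * k - 1L]] <- if (gaps[k] > prev) filler[(prev + 1L):gaps[k]]
                          else character(0)
    out[[2L * k]] <- groups[[k]]
    prev <- gaps[k]
  }
  out[[2L * length(groups) + 1L]] <-
    if (prev < length(filler)) filler[(prev + 1L):length(filler)]
    else character(0)
  unlist(out, use.names = FALSE)
}
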