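#' Pipeline configuration
#'
#' Collects every tunable of the staged pipeline with its default: core-set
#' size `K`, n-gram mining parameters, disease-filter thresholds, the two
#' similarity thresholds and their mixing weight, MCL inflation, the
#' relevance window (`W` weeks, top `M`), the jump-test level, and the
#' random seed (used only by the `simulate` stage). A serialized copy is
#' written next to every stage output for provenance.
#'
#' @param K Core-protein set size (default 100).
#' @param n_range N-gram lengths (default 2:6).
#' @param min_df Minimum n-gram document frequency (default 5).
#' @param min_co,min_ratio,alpha_ngram Disease over-representation filter
#'   (defaults 3, 2, 0.01).
#' @param string_threshold,context_threshold,lambda Similarity graph
#'   parameters (defaults 0.8, 0.5, 0.5).
#' @param inflation MCL inflation (default 2).
#' @param W,M Relevance window length and top count (defaults 260, 40).
#' @param alpha_jump Weekly high-jumper significance level (default 0.05).
#' @param burn_in Weeks of rank history required before jumps are tested
#'   (default 10).
#' @param corpus_path,corpus_format,dictionary_path Input locations for the
#'   `ingest` stage (unused when `simulate` provides them).
#' @param disease_id Disease entity id (default `"T2D"`).
#' @param generator Optional [generator_config()] for the `simulate` stage.
#' @param seed Seed forwarded to the generator.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(K = 100L, n_range = 2:6, min_df = 5L,
                            min_co = 3L, min_ratio = 2, alpha_ngram = 0.01,
                            string_threshold = 0.8, context_threshold = 0.5,
                            lambda = 0.5, inflation = 2,
                            W = 260L, M = 40L, alpha_jump = 0.05,
                            burn_in = 10L,
                            corpus_path = NULL,
                            corpus_format = "records_jsonl",
                            dictionary_path = NULL,
                            disease_id = "T2D",
                            generator = NULL, seed = 1L) {
  cfg <- list(K = as.integer(K), n_range = as.integer(n_range),
              min_df = as.integer(min_df), min_co = as.integer(min_co),
              min_ratio = min_ratio, alpha_ngram = alpha_ngram,
              string_threshold = string_threshold,
              context_threshold = context_threshold, lambda = lambda,
              inflation = inflation, W = as.integer(W), M = as.integer(M),
              alpha_jump = alpha_jump, burn_in = as.integer(burn_in),
              corpus_path = corpus_path, corpus_format = corpus_format,
              dictionary_path = dictionary_path, disease_id = disease_id,
              generator = generator, seed = as.integer(seed))
  stopifnot(cfg$K >= 1L, cfg$min_df >= 1L, cfg$W >= cfg$M,
            cfg$lambda >= 0, cfg$lambda <= 1, cfg$inflation > 1,
            cfg$alpha_jump > 0, cfg$alpha_jump <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return The configuration (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen <- obj$generator
  obj$generator <- NULL
  cfg <- do.call(pipeline_config, obj)
  if (!is.null(gen)) {
    gen$phrase_families <- NULL  # families are code-defined defaults
    cfg$generator <- do.call(generator_config, gen)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  obj <- unclass(cfg)
  if (!is.null(obj$generator)) {
    gen <- unclass(obj$generator)
    gen$phrase_families <- NULL
    obj$generator <- gen
  }
  obj <- obj[!vapply(obj, is.null, logical(1))]
  yaml::write_yaml(obj, path)
  invisible(path)
}

pipeline_stages <- c("simulate", "ingest", "core-proteins", "mine-ngrams",
                     "cluster-concepts", "weight-concepts", "score-articles",
                     "score-proteins", "detect-jumps", "evaluate-roc")

stage_requires <- list(
  "ingest" = character(0),
  "simulate" = character(0),
  "core-proteins" = c("corpus.rds", "mentions.rds"),
  "mine-ngrams" = c("corpus.rds", "mentions.rds"),
  "cluster-concepts" = "catalog.rds",
  "weight-concepts" = c("concepts.rds", "catalog.rds", "core.rds",
                        "mentions.rds", "corpus.rds"),
  "score-articles" = c("corpus.rds", "concepts.rds", "weights.rds"),
  "score-proteins" = c("article_scores.rds", "mentions.rds", "corpus.rds"),
  "detect-jumps" = c("series.rds", "weekly.rds"),
  "evaluate-roc" = c("series.rds", "truth.json")
)

stage_produced_by <- c(
  "corpus.rds" = "ingest (or simulate)", "mentions.rds" = "ingest",
  "catalog.rds" = "mine-ngrams", "core.rds" = "core-proteins",
  "concepts.rds" = "cluster-concepts", "weights.rds" = "weight-concepts",
  "article_scores.rds" = "score-articles", "series.rds" = "score-proteins",
  "weekly.rds" = "score-proteins", "truth.json" = "simulate")

#' Run one stage of the literature-relevance pipeline
#'
#' Stages communicate through cached intermediates in `out_dir`; each stage
#' reads its upstream artifacts, writes its own (both an `.rds` cache and
#' human-readable TSV reports), logs its funnel counts via `message()`, and
#' is idempotent given identical inputs and configuration. The
#' configuration is serialized to `config.yaml` next to the outputs.
#'
#' @param stage One of `r paste(pipeline_stages, collapse = ", ")`.
#' @param cfg A `pipeline_config`.
#' @param out_dir Artifact directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
run_stage <- function(stage, cfg, out_dir) {
  stage <- match.arg(stage, pipeline_stages)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (dep in stage_requires[[stage]]) {
    if (!file.exists(file.path(out_dir, dep)))
      stop("missing upstream artifact '", dep, "': run stage '",
           stage_produced_by[[dep]], "' first")
  }
  art <- function(name) file.path(out_dir, name)
  get_art <- function(name) readRDS(art(name))
  written <- character(0)
  put <- function(obj, name) {
    saveRDS(obj, art(name))
    written <<- c(written, art(name))
  }
  put_tsv <- function(dt, name) {
    fwrite(as.data.table(dt), art(name), sep = "\t")
    written <<- c(written, art(name))
  }

  if (stage == "simulate") {
    gen <- cfg$generator
    if (is.null(gen)) gen <- generator_config(seed = cfg$seed)
    sim <- generate_corpus(gen)
    put(sim$corpus, "corpus.rds")
    put(corpus_mentions(sim$corpus, sim$dictionary), "mentions.rds")
    write_ground_truth(sim$truth, art("truth.json"))
    written <- c(written, art("truth.json"))
    dict_tab <- sim$dictionary$entries[, .(entity_id, entity_class, synonym)]
    put_tsv(dict_tab, "dictionary.tsv")
    write_corpus_jsonl(sim$corpus, art("corpus.jsonl"))
    written <- c(written, art("corpus.jsonl"))
    message("simulate: ", nrow(sim$corpus), " documents over ",
            gen$n_weeks, " weeks")
  } else if (stage == "ingest") {
    if (is.null(cfg$corpus_path) || is.null(cfg$dictionary_path))
      stop("ingest requires corpus_path and dictionary_path in the config")
    corpus <- read_corpus(cfg$corpus_path, cfg$corpus_format)
    dict <- read_dictionary(cfg$dictionary_path)
    put(corpus, "corpus.rds")
    put(corpus_mentions(corpus, dict), "mentions.rds")
    message("ingest: ", nrow(corpus), " documents (",
            attr(corpus, "skipped") %||% 0L, " skipped)")
  } else if (stage == "core-proteins") {
    corpus <- get_art("corpus.rds"); mentions <- get_art("mentions.rds")
    core <- select_core_proteins(corpus, dict = NULL,
                                 disease_id = cfg$disease_id, K = cfg$K,
                                 mentions = mentions)
    put(core, "core.rds")
    put_tsv(core, "core_proteins.tsv")
    message("core-proteins: ", nrow(core), " selected (K = ", cfg$K, ")")
  } else if (stage == "mine-ngrams") {
    corpus <- get_art("corpus.rds"); mentions <- get_art("mentions.rds")
    catalog <- extract_ngrams(corpus, cfg$n_range, cfg$min_df)
    n_all <- nrow(catalog$ngrams)
    disease_docs <- unique(mentions[entity_id == cfg$disease_id, doc_id])
    catalog <- disease_overrepresented(catalog, disease_docs, cfg$min_co,
                                       cfg$min_ratio, cfg$alpha_ngram)
    put(catalog, "catalog.rds")
    put_tsv(catalog$ngrams, "ngrams.tsv")
    message("mine-ngrams: ", n_all, " frequent n-grams, ",
            nrow(catalog$ngrams), " disease over-represented")
  } else if (stage == "cluster-concepts") {
    catalog <- get_art("catalog.rds")
    graph <- build_similarity_graph(catalog, cfg$string_threshold,
                                    cfg$context_threshold, cfg$lambda)
    concepts <- mcl_cluster(graph, cfg$inflation)
    put(concepts, "concepts.rds")
    put_tsv(concepts$members, "concept_members.tsv")
    message("cluster-concepts: ", nrow(concepts$concepts), " concepts from ",
            nrow(graph$nodes), " n-grams (", nrow(graph$edges), " edges)")
  } else if (stage == "weight-concepts") {
    concepts <- get_art("concepts.rds"); catalog <- get_art("catalog.rds")
    core <- get_art("core.rds"); mentions <- get_art("mentions.rds")
    corpus <- get_art("corpus.rds")
    weights <- concept_weights(concepts, catalog, core, mentions,
                               D = nrow(corpus))
    put(weights, "weights.rds")
    put_tsv(concept_table(concepts, catalog, weights), "concept_table.tsv")
    message("weight-concepts: ", nrow(weights), " concepts weighted against ",
            nrow(core), " core proteins")
  } else if (stage == "score-articles") {
    corpus <- get_art("corpus.rds"); concepts <- get_art("concepts.rds")
    weights <- get_art("weights.rds")
    scores <- score_articles(corpus, concepts, weights)
    put(scores, "article_scores.rds")
    put_tsv(scores, "article_scores.tsv")
    put_tsv(attr(scores, "contributions"), "article_contributions.tsv")
    message("score-articles: ", nrow(scores), " articles scored, ",
            sum(scores$score > 0), " with a positive score")
  } else if (stage == "score-proteins") {
    scores <- get_art("article_scores.rds")
    mentions <- get_art("mentions.rds")
    weekly <- weekly_protein_scores(scores, mentions)
    proteins <- sort(unique(mentions[entity_class == "protein", entity_id]))
    series <- relevance_series(weekly, proteins, W = cfg$W, M = cfg$M)
    put(weekly, "weekly.rds")
    put(series, "series.rds")
    put_tsv(weekly, "weekly_protein_scores.tsv")
    put_tsv(series, "protein_ranks.tsv")
    message("score-proteins: ", length(proteins), " proteins over ",
            uniqueN(series$week), " weeks")
  } else if (stage == "detect-jumps") {
    series <- get_art("series.rds"); weekly <- get_art("weekly.rds")
    report <- detect_jumps(series, weekly, alpha = cfg$alpha_jump,
                           burn_in = cfg$burn_in)
    put(report, "jumps.rds")
    put_tsv(report, "high_jumpers.tsv")
    message("detect-jumps: ", nrow(report), " significant weekly jumps")
  } else if (stage == "evaluate-roc") {
    series <- get_art("series.rds")
    truth <- read_ground_truth(art("truth.json"))
    final <- series[week == max(week)]
    roc <- evaluate_roc(setNames(final$combined, final$protein_id),
                        truth$core_proteins)
    put_tsv(roc$points, "roc_points.tsv")
    put_tsv(data.table(benchmark = "planted_core", auc = roc$auc),
            "roc_auc.tsv")
    message("evaluate-roc: AUC ", round(roc$auc, 4),
            " against the planted core set")
  }
  write_pipeline_config(cfg, art("config.yaml"))
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan all weeks of a rank history for significant upward jumps
#'
#' For every week after the burn-in, builds the jump null from the history
#' strictly before that week and reports the proteins whose upward jump is
#' significant at `alpha`, together with the article that caused it.
#'
#' @param series Output of [relevance_series()].
#' @param weekly Output of [weekly_protein_scores()] (provides the
#'   triggering article ids).
#' @param alpha Significance level (default 0.05).
#' @param burn_in Number of initial weeks used only as history
#'   (default 10).
#' @return `data.table(week, protein_id, initial_rank, new_rank, jump,
#'   p_value, top_doc)`.
#' @export
detect_jumps <- function(series, weekly, alpha = 0.05, burn_in = 10L) {
  weeks <- sort(unique(series$week))
  if (length(weeks) <= burn_in + 1L)
    stop("insufficient rank history (", length(weeks), " weeks <= burn_in + 1);",
         " extend the corpus or lower burn_in")
  ranks <- series[, .(protein_id, week, rank)]
  out <- list()
  for (w in weeks[weeks > weeks[burn_in + 1L]]) {
    prev_w <- weeks[match(w, weeks) - 1L]
    if (prev_w != w - 1L) next
    dist <- build_jump_distribution(ranks, eval_week = w)
    prev <- ranks[week == prev_w]
    cur <- ranks[week == w]
    rep_w <- weekly_high_jumpers(setNames(prev$rank, prev$protein_id),
                                 setNames(cur$rank, cur$protein_id),
                                 dist, alpha = alpha,
                                 weekly = weekly[week == w])
    if (nrow(rep_w)) out[[as.character(w)]] <- cbind(week = w, rep_w)
  }
  if (length(out) == 0L) return(cbind(week = integer(0),
                                      empty_jumper_report()))
  rbindlist(out)
}
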