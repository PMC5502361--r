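#' Parameters of the synthetic triage benchmark
#'
#' The generator emulates the essential statistics of a triage
#' benchmark: for each (gene, axis) query a handful of relevant
#' abstracts carry many gene mentions and several distinct axis
#' concepts, while irrelevant abstracts mention the gene rarely and
#' carry background concepts sporadically. Relevance thus correlates
#' with both gene-mention density and distinct-concept density, which
#' is exactly the signal the fused ranking exploits.
#'
#' @param n_docs corpus size.
#' @param n_queries number of (gene, axis) queries.
#' @param relevant_per_query planted relevant documents per query;
#'   `relevant_per_query * n_queries` must not exceed `n_docs`.
#' @param filler_vocab_size size of the filler-token vocabulary.
#' @param gene_rate_relevant Poisson rate of extra gene mentions in a
#'   relevant document (the document always carries at least one).
#' @param gene_rate_irrelevant Poisson rate of gene mentions in
#'   documents not relevant to the query; must not exceed
#'   `gene_rate_relevant`.
#' @param concept_rate_relevant Poisson rate mu_c of extra distinct
#'   axis concepts in a relevant document (always at least one).
#' @param background_concept_prob probability in `[0, 1)` that any
#'   given axis concept appears in a non-relevant document.
#' @param doc_length mean document length in tokens.
#' @param year_range inclusive range publication years are drawn
#'   uniformly from, so the recency-ranked Boolean baseline is
#'   well-defined.
#' @param axis `"PPI"` or `"PTM"`.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_docs = 500L, n_queries = 20L,
                         relevant_per_query = 5L,
                         filler_vocab_size = 2000L,
                         gene_rate_relevant = 3,
                         gene_rate_irrelevant = 0.3,
                         concept_rate_relevant = 1.5,
                         background_concept_prob = 0.05,
                         doc_length = 120,
                         year_range = c(1990L, 2013L),
                         axis = c("PPI", "PTM"), seed = 1L) {
  axis <- match.arg(axis)
  n_docs <- as.integer(n_docs); n_queries <- as.integer(n_queries)
  relevant_per_query <- as.integer(relevant_per_query)
  if (n_docs < 1 || n_queries < 1 || relevant_per_query < 1)
    stop("n_docs, n_queries and relevant_per_query must be >= 1")
  if (relevant_per_query * n_queries > n_docs)
    stop("relevant_per_query * n_queries must not exceed n_docs")
  if (gene_rate_irrelevant < 0 || gene_rate_relevant < gene_rate_irrelevant)
    stop("need gene_rate_relevant >= gene_rate_irrelevant >= 0")
  if (background_concept_prob < 0 || background_concept_prob >= 1)
    stop("background_concept_prob must be in [0, 1)")
  if (doc_length <= 0 || filler_vocab_size < 10)
    stop("doc_length must be positive and filler_vocab_size >= 10")
  year_range <- as.integer(year_range)
  if (length(year_range) != 2 || year_range[1] > year_range[2])
    stop("year_range must be an increasing pair of years")
  structure(list(n_docs = n_docs, n_queries = n_queries,
                 relevant_per_query = relevant_per_query,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 gene_rate_relevant = gene_rate_relevant,
                 gene_rate_irrelevant = gene_rate_irrelevant,
                 concept_rate_relevant = concept_rate_relevant,
                 background_concept_prob = background_concept_prob,
                 doc_length = doc_length, year_range = year_range,
                 axis = axis, seed = as.integer(seed)),
            class = "synth_params")
}

# a random morphological variant of one thesaurus entry: phrase stems
# are rendered verbatim, single-token stems get a random inflection
# suffix (token soup -- the consumers only ever see tokens)
.render_concept <- function(stems) {
  st <- stems[[sample.int(length(stems), 1L)]]
  if (grepl(" ", st, fixed = TRUE)) st
  else paste0(st, c("e", "es", "ed", "ing", "ion")[sample.int(5L, 1L)])
}

#' Generate a synthetic corpus, queries and judgements
#'
#' Builds a deterministic (seeded) MEDLINE-like corpus in which, for
#' each query, `relevant_per_query` documents plant
#' `1 + Poisson(gene_rate_relevant)` gene mentions and
#' `1 + Poisson(concept_rate_relevant)` distinct axis concepts from the
#' thesaurus (each rendered in a random morphological variant), while
#' non-relevant documents mention each query's gene at rate
#' `gene_rate_irrelevant` and carry each concept independently with
#' probability `background_concept_prob`. Remaining space is filled
#' with uniform filler tokens; publication years are uniform over
#' `year_range`. The qrels mark exactly the planted-relevant documents.
#'
#' @param params a [synth_params()] object.
#' @param thesaurus thesaurus to plant concepts from; defaults to the
#'   bundled vocabulary of `params$axis`.
#' @return A list with elements `docs` (a [document_set()]), `queries`
#'   (list of [query_spec()]) and `qrels` (data frame).
#' @export
generate_corpus <- function(params, thesaurus = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (is.null(thesaurus)) thesaurus <- default_thesaurus(params$axis)
  set.seed(params$seed)
  nd <- params$n_docs; nq <- params$n_queries
  npq <- params$relevant_per_query
  genes <- sprintf("gn%03dx", seq_len(nq))
  vocab <- sprintf("w%04d", seq_len(params$filler_vocab_size))
  rel_query <- rep(NA_integer_, nd)
  rel_query[seq_len(nq * npq)] <- rep(seq_len(nq), each = npq)
  n_entries <- nrow(thesaurus)
  stems_list <- lapply(thesaurus$stems, .split_pipe)
  title <- character(nd); abstract <- character(nd)
  year <- integer(nd); month <- integer(nd)
  for (d in seq_len(nd)) {
    q <- rel_query[d]
    gene_counts <- rpois(nq, params$gene_rate_irrelevant)
    if (!is.na(q)) gene_counts[q] <- 1L + rpois(1, params$gene_rate_relevant)
    gene_toks <- rep(genes, gene_counts)
    cids <- if (!is.na(q)) {
      k <- min(1L + rpois(1, params$concept_rate_relevant), n_entries)
      sample.int(n_entries, k)
    } else {
      which(runif(n_entries) < params$background_concept_prob)
    }
    concept_surf <- vapply(cids, function(i) .render_concept(stems_list[[i]]),
                           character(1))
    planted <- c(gene_toks, concept_surf)
    n_planted <- length(gene_toks) +
      sum(lengths(strsplit(concept_surf, " ", fixed = TRUE)))
    n_fill <- max(6L, rpois(1, params$doc_length) - n_planted)
    fill <- sample(vocab, n_fill, replace = TRUE)
    title[d] <- paste(fill[1:5], collapse = " ")
    abstract[d] <- paste(sample(c(planted, fill[-(1:5)])), collapse = " ")
    year[d] <- sample(seq(params$year_range[1], params$year_range[2]), 1)
    month[d] <- sample.int(12L, 1L)
  }
  perm <- sample.int(nd)
  pmid <- 100000L + seq_len(nd)
  docs <- document_set(pmid = pmid, title = title[perm],
                       abstract = abstract[perm], year = year[perm],
                       month = month[perm])
  qid <- sprintf("q%03d", seq_len(nq))
  newrow <- match(seq_len(nd), perm)
  rel_docs <- which(!is.na(rel_query))
  qrels <- data.frame(query_id = qid[rel_query[rel_docs]],
                      pmid = pmid[newrow[rel_docs]], rel = 1L,
                      stringsAsFactors = FALSE)
  qrels <- qrels[order(qrels$query_id, qrels$pmid), , drop = FALSE]
  rownames(qrels) <- NULL
  queries <- lapply(seq_len(nq), function(q)
    query_spec(gene = genes[q], axis = params$axis, id = qid[q]))
  list(docs = docs, queries = queries, qrels = qrels)
}

#' Benchmark retrieval strategies on one corpus
#'
#' Evaluates the Boolean recency baseline, the engine-only BM25
#' ranking, and each supplied fusion configuration (applied as a
#' re-ranking of the engine run), reporting P@1, MRR and MAP per
#' system together with the relative P@1 improvement over the Boolean
#' baseline.
#'
#' @param docs a [document_set()].
#' @param queries list of [query_spec()] objects.
#' @param qrels judgements data frame.
#' @param configs named list of [fusion_config()] objects (possibly
#'   empty, in which case only the baseline and engine rows are
#'   reported).
#' @param thesaurus thesaurus used to build concept profiles; defaults
#'   to the bundled vocabulary of `axis`.
#' @param axis axis of the default thesaurus.
#' @return An object of class `triage_benchmark`: a data frame with
#'   columns `system`, `p_at_1`, `mrr`, `map` and
#'   `improvement_p_at_1` (percent versus the Boolean baseline, `NA`
#'   when the baseline P@1 is 0).
#' @export
run_benchmark <- function(docs, queries, qrels, configs = list(),
                          thesaurus = NULL, axis = c("PPI", "PTM")) {
  axis <- match.arg(axis)
  if (is.null(thesaurus)) thesaurus <- default_thesaurus(axis)
  if (length(configs) && is.null(names(configs)))
    names(configs) <- paste0("fused_", seq_along(configs))
  index <- build_index(docs)
  profiles <- corpus_profiles(docs, thesaurus)
  bool_run <- do.call(rbind, lapply(queries, function(q)
    boolean_search(index, q, mode = "OR")))
  eng_run <- do.call(rbind, lapply(queries, function(q)
    search_index(index, q)))
  reports <- list(boolean_recency = evaluate_run(bool_run, qrels),
                  engine = evaluate_run(eng_run, qrels))
  for (nm in names(configs))
    reports[[nm]] <- evaluate_run(rerank(eng_run, profiles, configs[[nm]]),
                                  qrels)
  p1 <- vapply(reports, `[[`, numeric(1), "p1")
  base <- p1[["boolean_recency"]]
  impr <- vapply(p1, function(v)
    if (base > 0) relative_improvement(v, base) else NA_real_, numeric(1))
  out <- data.frame(system = names(reports), p_at_1 = unname(p1),
                    mrr = vapply(reports, `[[`, numeric(1), "mrr"),
                    map = vapply(reports, `[[`, numeric(1), "map"),
                    improvement_p_at_1 = unname(impr),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("triage_benchmark", "data.frame")
  attr(out, "reports") <- reports
  out
}

#' @export
print.triage_benchmark <- function(x, digits = 4, ...) {
  cat("<triage_benchmark>\n")
  y <- as.data.frame(x)
  y$p_at_1 <- round(y$p_at_1, digits)
  y$mrr <- round(y$mrr, digits)
  y$map <- round(y$map, digits)
  y$improvement_p_at_1 <- ifelse(is.na(y$improvement_p_at_1), NA,
                                 sprintf("%+.1f%%", y$improvement_p_at_1))
  print(y)
  invisible(x)
}
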