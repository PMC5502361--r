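#' Specify a triage query
#'
#' A query names the gene of interest, optional synonyms, the curation
#' axis and whether axis-specific refinement keywords are appended at
#' search time (`binds`, `interacts`, `associates` for PPI;
#' `phosphorylates` for PTM).
#'
#' @param gene gene symbol (non-empty).
#' @param synonyms additional gene synonyms.
#' @param axis `"PPI"` or `"PTM"`.
#' @param refinement append the axis trigger keywords?
#' @param extra_keywords override the default refinement keywords.
#' @param top_k maximum number of documents returned (default 1000).
#' @param id query identifier used in run files; defaults to the gene.
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(gene, synonyms = character(),
                       axis = c("PPI", "PTM"), refinement = FALSE,
                       extra_keywords = NULL, top_k = 1000L, id = NULL) {
  axis <- match.arg(axis)
  if (!is.character(gene) || length(gene) != 1 || !nzchar(gene))
    stop("gene must be a non-empty string")
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) stop("top_k must be >= 1")
  if (is.null(extra_keywords))
    extra_keywords <- switch(axis,
                             PPI = c("binds", "interacts", "associates"),
                             PTM = "phosphorylates")
  structure(list(gene = gene, synonyms = as.character(synonyms),
                 axis = axis, refinement = isTRUE(refinement),
                 extra_keywords = as.character(extra_keywords),
                 top_k = top_k, id = id %||% gene),
            class = "query_spec")
}

#' Expand a query into engine terms
#'
#' Returns the gene plus synonyms (lowercased) and, when refinement is
#' on, the axis trigger keywords; duplicates are removed preserving
#' first occurrence. Refinement keywords enter the engine score only —
#' they are never counted as axis descriptors.
#'
#' @param query a [query_spec()].
#' @return A character vector of search terms.
#' @export
expand_query <- function(query) {
  stopifnot(inherits(query, "query_spec"))
  terms <- tolower(c(query$gene, query$synonyms))
  if (query$refinement) terms <- c(terms, tolower(query$extra_keywords))
  unique(terms[nzchar(terms)])
}

.index_tokens <- function(docs) {
  texts <- tolower(paste(docs$title, docs$abstract))
  toks <- strsplit(texts, "[^[:alnum:]]+")
  lapply(toks, function(x) x[nzchar(x)])
}

#' Build an inverted index over a corpus
#'
#' Terms are the lowercased alphanumeric tokens of title + abstract.
#' The index stores document frequencies, per-term postings (pmid, term
#' frequency), document lengths and the mean document length, plus the
#' publication-date keys needed by the Boolean recency baseline.
#'
#' @param docs a non-empty [document_set()].
#' @return An object of class `triage_index`.
#' @export
build_index <- function(docs) {
  stopifnot(inherits(docs, "document_set"))
  if (nrow(docs) == 0) stop("cannot index an empty corpus")
  if (anyDuplicated(docs$pmid)) stop("duplicate pmid in corpus")
  toks <- .index_tokens(docs)
  doc_len <- lengths(toks)
  n <- nrow(docs)
  term <- unlist(toks, use.names = FALSE)
  did <- rep.int(seq_len(n), doc_len)
  if (length(term)) {
    o <- order(term, did, method = "radix")
    term <- term[o]; did <- did[o]
    new <- c(TRUE, term[-1L] != term[-length(term)] |
                   did[-1L] != did[-length(did)])
    grp <- cumsum(new)
    tf <- tabulate(grp)
    uterm <- term[new]; udid <- did[new]
    sp <- split(seq_along(uterm), uterm)
    postings <- lapply(sp, function(ix)
      list(pmid = docs$pmid[udid[ix]], tf = tf[ix]))
    df <- lengths(sp)
  } else {
    postings <- list()
    df <- integer()
  }
  structure(list(N = n, df = df, postings = postings,
                 doc_len = stats::setNames(doc_len, docs$pmid),
                 avgdl = mean(doc_len), pmids = docs$pmid,
                 date_key = stats::setNames(.date_key(docs), docs$pmid)),
            class = "triage_index")
}

#' @export
print.triage_index <- function(x, ...) {
  cat("<triage_index> N=", x$N, ", terms=", length(x$df),
      ", avgdl=", round(x$avgdl, 1), "\n", sep = "")
  invisible(x)
}

.idf <- function(index, term) {
  dfq <- index$df[[term]]
  log(1 + (index$N - dfq + 0.5) / (dfq + 0.5))
}

#' Okapi BM25 score of one document for a term set
#'
#' Computes sum over distinct query terms of
#' `idf(t) * tf * (k1+1) / (tf + k1 * (1 - b + b * dl/avgdl))` with
#' `idf(t) = ln(1 + (N - df + 0.5)/(df + 0.5))`. The `ln(1 + ...)` form
#' keeps scores non-negative. Repeated query terms contribute once.
#'
#' @param index a [build_index()] object.
#' @param terms character vector of query terms (lowercased internally).
#' @param pmid a document identifier present in the index.
#' @param k1,b BM25 parameters (defaults 1.2 and 0.75).
#' @return A non-negative scalar; 0 when no query term occurs in the
#'   document.
#' @export
bm25_score <- function(index, terms, pmid, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(index, "triage_index"))
  if (!pmid %in% index$pmids) stop("unknown pmid: ", pmid)
  terms <- unique(tolower(terms))
  dl <- index$doc_len[[as.character(pmid)]]
  s <- 0
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    k <- match(pmid, p$pmid)
    if (is.na(k)) next
    tf <- p$tf[k]
    s <- s + .idf(index, t) * tf * (k1 + 1) /
      (tf + k1 * (1 - b + b * dl / index$avgdl))
  }
  s
}

.new_run <- function(query_id, pmid, score) {
  n <- length(pmid)
  data.frame(query_id = rep_len(as.character(query_id), n),
             pmid = as.integer(pmid), rank = seq_len(n),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Rank a corpus for a query with BM25
#'
#' Scores every document holding at least one query term, sorts by
#' score descending (ties broken by pmid descending) and truncates to
#' the query's `top_k`.
#'
#' @param index a [build_index()] object.
#' @param query a [query_spec()].
#' @param k1,b BM25 parameters.
#' @return A ranked run: data frame with columns `query_id`, `pmid`,
#'   `rank` (1..n without gaps) and `score` (non-increasing in rank).
#' @export
search_index <- function(index, query, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(index, "triage_index"), inherits(query, "query_spec"))
  terms <- expand_query(query)
  score <- numeric(index$N)
  names(score) <- as.character(index$pmids)
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    dl <- index$doc_len[as.character(p$pmid)]
    contrib <- .idf(index, t) * p$tf * (k1 + 1) /
      (p$tf + k1 * (1 - b + b * dl / index$avgdl))
    ids <- as.character(p$pmid)
    score[ids] <- score[ids] + contrib
  }
  keep <- score > 0
  pm <- index$pmids[keep]
  sc <- unname(score[keep])
  o <- order(-sc, -pm)
  o <- utils::head(o, query$top_k)
  .new_run(query$id, pm[o], sc[o])
}

#' Boolean search with recency ranking
#'
#' The baseline retrieval mode: documents matching the Boolean
#' condition over the query terms (`AND` or `OR`) are ranked by
#' publication date, most recent first (ties by pmid descending), and
#' truncated to `top_k`. Documents without a date sort last. The run's
#' score column carries the numeric date key so scores are
#' non-increasing in rank.
#'
#' @param index a [build_index()] object.
#' @param query a [query_spec()].
#' @param mode `"OR"` or `"AND"`.
#' @return A ranked run (see [search_index()]).
#' @export
boolean_search <- function(index, query, mode = c("OR", "AND")) {
  stopifnot(inherits(index, "triage_index"), inherits(query, "query_spec"))
  mode <- match.arg(mode)
  terms <- expand_query(query)
  sets <- lapply(terms, function(t) {
    p <- index$postings[[t]]
    if (is.null(p)) integer() else p$pmid
  })
  pm <- if (length(sets) == 0) integer() else
    Reduce(if (mode == "AND") intersect else union, sets)
  if (length(pm) == 0) return(.new_run(query$id, integer(), numeric()))
  key <- index$date_key[as.character(pm)]
  key[is.na(key)] <- 0
  o <- order(-key, -pm)
  o <- utils::head(o, query$top_k)
  .new_run(query$id, pm[o], unname(key[o]))
}

#' Write a ranked run in TREC format
#'
#' One line per document: `qid Q0 pmid rank score tag`.
#'
#' @param run a ranked run data frame.
#' @param path output path.
#' @param tag run tag recorded in the last column.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, tag = "litriage") {
  lines <- sprintf("%s Q0 %d %d %.6g %s", run$query_id, run$pmid,
                   run$rank, run$score, tag)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a ranked run in TREC format
#'
#' @param path path to a whitespace-separated `qid Q0 pmid rank score
#'   tag` file.
#' @return A ranked run data frame ordered by query and rank.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(.new_run(character(), integer(), numeric())[0, ])
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) < 6))
    stop("run lines must have 6 whitespace-separated fields")
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  run <- data.frame(query_id = m[, 1], pmid = as.integer(m[, 3]),
                    rank = as.integer(m[, 4]), score = as.numeric(m[, 5]),
                    stringsAsFactors = FALSE)
  run[order(run$query_id, run$rank), c("query_id", "pmid", "rank", "score")]
}
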