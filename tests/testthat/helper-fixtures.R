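# Fixtures and independent oracles shared across the test files. The
# oracles deliberately recompute everything from first principles
# (straight loops over token lists / run rows) so they stay independent
# of the indexed implementation they are checking.

medline_xml <- function(articles) {
  art <- vapply(articles, function(a) {
    abs_xml <- if (is.null(a$abstract)) "" else
      paste0("<Abstract>",
             paste0("<AbstractText>", a$abstract, "</AbstractText>",
                    collapse = ""),
             "</Abstract>")
    pt <- if (is.null(a$pub_types)) "" else
      paste0("<PublicationTypeList>",
             paste0("<PublicationType>", a$pub_types,
                    "</PublicationType>", collapse = ""),
             "</PublicationTypeList>")
    pmid <- if (is.null(a$pmid)) "" else paste0("<PMID>", a$pmid, "</PMID>")
    paste0("<PubmedArticle><MedlineCitation>", pmid,
           "<Article><ArticleTitle>", a$title, "</ArticleTitle>",
           "<Journal><JournalIssue><PubDate><Year>",
           a$year %||% 2000, "</Year></PubDate></JournalIssue></Journal>",
           abs_xml, "</Article>", pt,
           "</MedlineCitation></PubmedArticle>")
  }, character(1))
  paste0("<?xml version='1.0'?><PubmedArticleSet>",
         paste0(art, collapse = ""), "</PubmedArticleSet>")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_corpus <- function(n_docs, vocab_n = 30, len = 12,
                          years = 1990:2013) {
  vocab <- sprintf("t%02d", seq_len(vocab_n))
  document_set(
    pmid = seq_len(n_docs),
    title = vapply(seq_len(n_docs), function(i)
      paste(sample(vocab, 3, replace = TRUE), collapse = " "), ""),
    abstract = vapply(seq_len(n_docs), function(i)
      paste(sample(vocab, len, replace = TRUE), collapse = " "), ""),
    year = sample(years, n_docs, replace = TRUE))
}

corpus_token_lists <- function(docs) {
  texts <- tolower(paste(docs$title, docs$abstract))
  lapply(strsplit(texts, "[^[:alnum:]]+"), function(x) x[nzchar(x)])
}

# per-document BM25 computed directly from the token lists
brute_bm25 <- function(token_lists, terms, i, k1 = 1.2, b = 0.75) {
  N <- length(token_lists)
  dl <- lengths(token_lists)
  avgdl <- mean(dl)
  s <- 0
  for (t in unique(tolower(terms))) {
    tf <- sum(token_lists[[i]] == t)
    if (tf == 0) next
    df <- sum(vapply(token_lists, function(x) t %in% x, logical(1)))
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl[i] / avgdl))
  }
  s
}

# brute-force retrieval metrics: one explicit loop per query
brute_metrics <- function(run, qrels) {
  qids <- unique(qrels$query_id)
  p1 <- rr <- ap <- numeric(length(qids))
  for (j in seq_along(qids)) {
    q <- qids[j]
    rel <- qrels$pmid[qrels$query_id == q & qrels$rel == 1]
    g <- run[run$query_id == q, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    hits <- which(g$pmid %in% rel)
    p1[j] <- as.numeric(length(hits) > 0 && hits[1] == 1)
    rr[j] <- if (length(hits)) 1 / hits[1] else 0
    ap[j] <- if (length(rel) == 0 || length(hits) == 0) 0 else
      sum(seq_along(hits) / hits) / length(rel)
  }
  list(p1 = mean(p1), mrr = mean(rr), map = mean(ap))
}

# a random (run, qrels) instance for the metric oracle tests
random_run_qrels <- function(max_q = 10, max_docs = 20) {
  n_q <- sample.int(max_q, 1)
  qids <- sprintf("q%d", seq_len(n_q))
  runs <- lapply(qids, function(q) {
    n <- sample.int(max_docs, 1)
    pm <- sample.int(1000, n)
    data.frame(query_id = q, pmid = pm, rank = seq_len(n),
               score = sort(runif(n), decreasing = TRUE),
               stringsAsFactors = FALSE)
  })
  run <- do.call(rbind, runs)
  qrels <- do.call(rbind, lapply(qids, function(q) {
    pool <- union(run$pmid[run$query_id == q], sample.int(1000, 5))
    n <- sample.int(length(pool), 1)
    data.frame(query_id = q, pmid = sample(pool, n),
               rel = sample(0:1, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(run = run, qrels = qrels)
}
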