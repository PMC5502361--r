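#' Read TREC-style relevance judgements
#'
#' Qrels lines have four whitespace-separated fields:
#' `qid 0 pmid rel`, with binary relevance. Repeated (qid, pmid) pairs
#' keep the last judgement, with a warning; graded (non-binary)
#' judgements are rejected.
#'
#' @param path path to a qrels file.
#' @return A data frame with columns `query_id`, `pmid`, `rel`.
#' @export
read_qrels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty qrels file: ", path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) != 4))
    stop("qrels lines must have 4 whitespace-separated fields")
  m <- do.call(rbind, parts)
  if (!all(m[, 4] %in% c("0", "1")))
    stop("relevance must be binary (0/1)")
  qr <- data.frame(query_id = m[, 1], pmid = as.integer(m[, 3]),
                   rel = as.integer(m[, 4]), stringsAsFactors = FALSE)
  key <- paste(qr$query_id, qr$pmid)
  if (anyDuplicated(key)) {
    warning("repeated (query, pmid) judgements: last one wins")
    qr <- qr[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(qr) <- NULL
  }
  qr
}

#' Write TREC-style relevance judgements
#'
#' @param qrels a data frame with columns `query_id`, `pmid`, `rel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(qrels, path) {
  writeLines(sprintf("%s 0 %d %d", qrels$query_id, qrels$pmid, qrels$rel),
             path, useBytes = TRUE)
  invisible(path)
}

# per-query statistics shared by all metrics; queries present in the
# qrels but absent from the run score 0 (TREC convention)
.per_query_stats <- function(run, qrels, ks = integer()) {
  qids <- unique(qrels$query_id)
  extra <- setdiff(unique(run$query_id), qids)
  if (length(extra))
    warning("run queries without judgements ignored: ",
            paste(extra, collapse = ", "))
  rows <- lapply(qids, function(q) {
    rel_pm <- qrels$pmid[qrels$query_id == q & qrels$rel == 1]
    g <- run[run$query_id == q, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    isrel <- g$pmid %in% rel_pm
    p1 <- if (length(isrel) >= 1) as.numeric(isrel[1]) else 0
    frank <- which(isrel)[1]
    rr <- if (is.na(frank)) 0 else 1 / frank
    ap <- if (length(rel_pm) == 0 || !any(isrel)) 0 else {
      ranks <- which(isrel)
      sum(seq_along(ranks) / ranks) / length(rel_pm)
    }
    pk <- vapply(ks, function(k)
      sum(isrel[seq_len(min(k, length(isrel)))]) / k, numeric(1))
    names(pk) <- if (length(ks)) paste0("p_at_", ks) else character(0)
    c(p1 = p1, rr = rr, ap = ap, pk)
  })
  stats <- do.call(rbind, rows)
  data.frame(query_id = qids, stats, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Precision at rank k
#'
#' Mean over judged queries of the fraction of relevant documents among
#' the top k returned; a query with fewer than k (or no) results is
#' scored over k regardless.
#'
#' @param run a ranked run data frame.
#' @param qrels a qrels data frame (see [read_qrels()]).
#' @param k cut-off rank.
#' @return A value in `[0, 1]`.
#' @export
precision_at_k <- function(run, qrels, k) {
  mean(.per_query_stats(run, qrels, ks = k)[[paste0("p_at_", k)]])
}

#' Precision of the top-returned document (P@1)
#'
#' Mean over judged queries of the indicator that the top-ranked
#' document is relevant; an empty result list contributes 0.
#'
#' @inheritParams precision_at_k
#' @return A value in `[0, 1]`.
#' @export
precision_at_1 <- function(run, qrels) {
  mean(.per_query_stats(run, qrels)$p1)
}

#' Mean reciprocal rank
#'
#' Mean over judged queries of 1 / rank of the first relevant document
#' retrieved; 0 when none is. Always >= P@1.
#'
#' @inheritParams precision_at_k
#' @return A value in `[0, 1]`.
#' @export
mean_reciprocal_rank <- function(run, qrels) {
  mean(.per_query_stats(run, qrels)$rr)
}

#' Mean average precision
#'
#' Per query, average precision is the mean over relevant retrieved
#' documents of the precision at their ranks, divided by the total
#' number of relevant documents in the judgements; MAP averages this
#' over queries.
#'
#' @inheritParams precision_at_k
#' @return A value in `[0, 1]`.
#' @export
mean_average_precision <- function(run, qrels) {
  mean(.per_query_stats(run, qrels)$ap)
}

#' Relative improvement over a baseline, in percent
#'
#' @param value the metric of the system under test.
#' @param baseline the baseline metric; must be positive.
#' @return `100 * (value - baseline) / baseline`.
#' @examples
#' relative_improvement(0.2, 0.1) # +100
#' @export
relative_improvement <- function(value, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1 || baseline <= 0)
    stop("baseline must be a positive number")
  100 * (value - baseline) / baseline
}

#' Evaluate a ranked run against judgements
#'
#' Computes P@1, MRR, MAP and P@k for the requested cut-offs in one
#' pass, with a per-query breakdown.
#'
#' @inheritParams precision_at_k
#' @param ks cut-off ranks for P@k (default 5 and 10).
#' @return An object of class `metric_report`: a list with elements
#'   `p1`, `mrr`, `map`, `p_at_k` (named vector), `per_query` (data
#'   frame) and `n_queries`.
#' @export
evaluate_run <- function(run, qrels, ks = c(5L, 10L)) {
  pq <- .per_query_stats(run, qrels, ks = ks)
  pk <- vapply(paste0("p_at_", ks), function(cn) mean(pq[[cn]]), numeric(1))
  structure(list(p1 = mean(pq$p1), mrr = mean(pq$rr), map = mean(pq$ap),
                 p_at_k = pk, per_query = pq, n_queries = nrow(pq)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("<metric_report> ", x$n_queries, " quer",
      if (x$n_queries == 1) "y" else "ies", "\n", sep = "")
  vals <- c("P@1" = x$p1, MRR = x$mrr, MAP = x$map, x$p_at_k)
  names(vals) <- sub("^p_at_", "P@", names(vals))
  w <- max(nchar(names(vals)))
  for (i in seq_along(vals))
    cat(sprintf("  %-*s %.*f\n", w, names(vals)[i], digits, vals[i]))
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param report a `metric_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(
    list(n_queries = report$n_queries, p_at_1 = report$p1,
         mrr = report$mrr, map = report$map,
         p_at_k = as.list(report$p_at_k),
         per_query = report$per_query),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
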