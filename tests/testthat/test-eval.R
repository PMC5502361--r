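qrels_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".qrels",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("qrels parsing validates format and deduplicates", {
  qr <- read_qrels(qrels_file(c("q1 0 10 1", "q1 0 11 0", "q2 0 10 1")))
  expect_equal(length(unique(qr$query_id)), 2)
  expect_equal(nrow(qr), 3)
  expect_error(read_qrels(qrels_file(character())), "empty")
  expect_error(read_qrels(qrels_file("q1 0 10 2")), "binary")
  expect_warning(dup <- read_qrels(qrels_file(c("q1 0 10 1", "q1 0 10 0"))),
                 "last one wins")
  expect_equal(nrow(dup), 1)
  expect_equal(dup$rel, 0L)
})

run_of <- function(qid, pmids)
  data.frame(query_id = rep(qid, length(pmids)), pmid = pmids,
             rank = seq_along(pmids), score = rev(seq_along(pmids)),
             stringsAsFactors = FALSE)

test_that("P@1, MRR and MAP reproduce hand-computed values", {
  # 4 queries; only q1's top document is relevant -> P@1 = 0.25;
  # first relevant at ranks 1, 2, 4 and one query without a relevant
  # retrieved -> MRR = (1 + 1/2 + 1/4 + 0)/4
  run <- rbind(run_of("q1", c(1L, 2L)), run_of("q2", c(3L, 4L)),
               run_of("q3", c(5L, 6L, 7L, 8L)), run_of("q4", 9L))
  qrels <- data.frame(query_id = c("q1", "q2", "q3", "q4"),
                      pmid = c(1L, 4L, 8L, 99L), rel = 1L)
  expect_equal(precision_at_1(run, qrels), 0.25)
  expect_equal(mean_reciprocal_rank(run, qrels), (1 + 0.5 + 0.25 + 0) / 4)
  # AP: both relevant docs at ranks 1 and 2 of 2 -> 1.0
  r2 <- run_of("a", c(1L, 2L))
  q2 <- data.frame(query_id = "a", pmid = c(1L, 2L), rel = 1L)
  expect_equal(mean_average_precision(r2, q2), 1.0)
  # relevant at ranks 2 and 4 of 2 total -> (1/2 + 2/4)/2 = 0.5
  r3 <- run_of("a", c(9L, 1L, 8L, 2L))
  expect_equal(mean_average_precision(r3, q2), 0.5)
  # nothing relevant retrieved -> 0
  r4 <- run_of("a", c(7L, 8L))
  expect_equal(mean_average_precision(r4, q2), 0)
  # empty run scores 0 everywhere
  empty <- run_of("a", integer())
  expect_equal(precision_at_1(empty, q2), 0)
  expect_equal(mean_reciprocal_rank(empty, q2), 0)
})

test_that("queries judged but not retrieved count as zero in all means", {
  run <- run_of("q1", 1L)
  qrels <- data.frame(query_id = c("q1", "q2"), pmid = c(1L, 2L), rel = 1L)
  expect_equal(precision_at_1(run, qrels), 0.5)
  expect_equal(mean_average_precision(run, qrels), 0.5)
})

test_that("metrics agree with brute force and MRR dominates P@1", {
  for (i in 1:30) {
    set.seed(i)
    inst <- random_run_qrels()
    oracle <- brute_metrics(inst$run, inst$qrels)
    expect_equal(precision_at_1(inst$run, inst$qrels), oracle$p1)
    expect_equal(mean_reciprocal_rank(inst$run, inst$qrels), oracle$mrr)
    expect_equal(mean_average_precision(inst$run, inst$qrels), oracle$map)
    expect_gte(oracle$mrr, oracle$p1)
  }
})

test_that("metrics are invariant under query relabeling and die with truncation", {
  set.seed(99)
  inst <- random_run_qrels()
  relabel <- setNames(sprintf("Z%s", seq_along(unique(inst$qrels$query_id))),
                      unique(inst$qrels$query_id))
  run2 <- inst$run; run2$query_id <- unname(relabel[run2$query_id])
  qr2 <- inst$qrels; qr2$query_id <- unname(relabel[qr2$query_id])
  expect_equal(mean_average_precision(run2, qr2),
               mean_average_precision(inst$run, inst$qrels))
  expect_equal(precision_at_1(run2, qr2),
               precision_at_1(inst$run, inst$qrels))
  # truncating every ranking above its first relevant hit zeroes the metrics
  run3 <- do.call(rbind, lapply(split(inst$run, inst$run$query_id),
    function(g) {
      g <- g[order(g$rank), , drop = FALSE]
      rel <- inst$qrels$pmid[inst$qrels$query_id == g$query_id[1] &
                             inst$qrels$rel == 1]
      first <- which(g$pmid %in% rel)[1]
      if (is.na(first)) g else g[seq_len(first - 1), , drop = FALSE]
    }))
  expect_equal(precision_at_1(run3, inst$qrels), 0)
  expect_equal(mean_reciprocal_rank(run3, inst$qrels), 0)
  expect_equal(mean_average_precision(run3, inst$qrels), 0)
})

test_that("relative improvement follows the reporting convention", {
  expect_equal(relative_improvement(0.2, 0.1), 100)
  expect_equal(relative_improvement(0.1, 0.1), 0)
  # improvement computed from the rounded headline precisions
  expect_equal(relative_improvement(0.299, 0.103), 190.29126, tolerance = 1e-6)
  expect_error(relative_improvement(0.5, 0), "positive")
})

test_that("evaluate_run assembles a coherent report", {
  run <- rbind(run_of("q1", c(1L, 2L, 3L)), run_of("q2", c(4L, 5L)))
  qrels <- data.frame(query_id = c("q1", "q1", "q2"),
                      pmid = c(2L, 3L, 9L), rel = 1L)
  rep <- evaluate_run(run, qrels, ks = c(1L, 2L))
  expect_s3_class(rep, "metric_report")
  expect_equal(rep$n_queries, 2)
  expect_true(all(unlist(rep[c("p1", "mrr", "map")]) >= 0))
  expect_true(all(unlist(rep[c("p1", "mrr", "map")]) <= 1))
  expect_gte(rep$mrr, rep$p1)
  expect_equal(rep$p_at_k[["p_at_1"]], rep$p1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$map, rep$map)
})
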