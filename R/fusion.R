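#' Configure score fusion
#'
#' Score fusion re-scores a ranked list with a linear combination of
#' the engine score s and a concept-density statistic:
#' * `distinct_count`: `alpha * s + beta * D`, where D is the number of
#'   distinct axis concepts annotated in the document;
#' * `log_len_tf`: `alpha * s + beta * sum_c ln(1 + len_c * tf_c)` over
#'   annotated concepts c, where `len_c` is the descriptor label length
#'   in characters and `tf_c` its occurrence count.
#'
#' The logarithm is natural. Engine scores are used raw; an optional
#' min-max normalization switch exists but defaults off.
#'
#' @param variant `"distinct_count"` or `"log_len_tf"`.
#' @param alpha non-negative weight on the engine score.
#' @param beta non-negative weight on the density term.
#' @param normalize min-max normalize engine scores per query before
#'   fusing (default `FALSE`).
#' @return An object of class `fusion_config`.
#' @seealso [fusion_preset()] for the four named weight presets.
#' @export
fusion_config <- function(variant = c("distinct_count", "log_len_tf"),
                          alpha, beta, normalize = FALSE) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || alpha < 0 || !is.numeric(beta) || beta < 0)
    stop("alpha and beta must be non-negative")
  structure(list(variant = variant, alpha = as.numeric(alpha),
                 beta = as.numeric(beta), normalize = isTRUE(normalize)),
            class = "fusion_config")
}

.PRESETS <- list(
  PPI_base = list(variant = "distinct_count", alpha = 0.9, beta = 1.5),
  PTM_base = list(variant = "distinct_count", alpha = 0.9, beta = 1.7),
  PPI_refined = list(variant = "log_len_tf", alpha = 1.0, beta = 0.1),
  PTM_refined = list(variant = "distinct_count", alpha = 1.4, beta = 1.3)
)

#' Named fusion presets
#'
#' The four tuned weight combinations: `PPI_base`
#' (0.9 s + 1.5 D), `PTM_base` (0.9 s + 1.7 D), `PPI_refined`
#' (1.0 s + 0.1 sum ln(1 + len x tf)) and `PTM_refined`
#' (1.4 s + 1.3 D).
#'
#' @param name one of `"PPI_base"`, `"PTM_base"`, `"PPI_refined"`,
#'   `"PTM_refined"`.
#' @return A [fusion_config()].
#' @export
fusion_preset <- function(name) {
  p <- .PRESETS[[name]]
  if (is.null(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.PRESETS), collapse = ", "))
  fusion_config(p$variant, p$alpha, p$beta)
}

#' Fuse an engine score with a distinct-concept count
#'
#' @param s non-negative engine score(s).
#' @param D distinct-concept count(s).
#' @param config a `fusion_config` with variant `distinct_count`.
#' @return `alpha * s + beta * D`.
#' @export
fuse_distinct <- function(s, D, config) {
  stopifnot(inherits(config, "fusion_config"))
  if (config$variant != "distinct_count")
    stop("fuse_distinct requires variant 'distinct_count'")
  if (any(s < 0)) stop("engine scores must be non-negative")
  config$alpha * s + config$beta * D
}

#' Fuse an engine score with a log(length x TF) density term
#'
#' @param s non-negative engine score.
#' @param profile a [build_profile()] object (or `NULL` for an empty
#'   profile).
#' @param config a `fusion_config` with variant `log_len_tf`.
#' @return `alpha * s + beta * sum_c ln(1 + len_c * tf_c)`.
#' @export
fuse_logtf <- function(s, profile, config) {
  stopifnot(inherits(config, "fusion_config"))
  if (config$variant != "log_len_tf")
    stop("fuse_logtf requires variant 'log_len_tf'")
  if (any(s < 0)) stop("engine scores must be non-negative")
  if (is.null(profile) || profile$D == 0)
    return(config$alpha * s)
  if (any(profile$tf <= 0) || any(profile$desc_len <= 0))
    stop("profile term frequencies and descriptor lengths must be positive")
  dens <- sum(log1p(as.numeric(profile$desc_len) * as.numeric(profile$tf)))
  config$alpha * s + config$beta * dens
}

.fused_scores <- function(s, pmids, profiles, config) {
  if (config$normalize && length(s) > 1 && diff(range(s)) > 0)
    s <- (s - min(s)) / (max(s) - min(s))
  key <- as.character(pmids)
  if (config$variant == "distinct_count") {
    D <- vapply(key, function(k) {
      p <- profiles[[k]]
      if (is.null(p)) 0L else p$D
    }, integer(1), USE.NAMES = FALSE)
    fuse_distinct(s, D, config)
  } else {
    vapply(seq_along(s), function(i)
      fuse_logtf(s[i], profiles[[key[i]]], config), numeric(1))
  }
}

#' Re-score a ranked run with concept-density fusion
#'
#' Computes the fused score of every document in the run via the
#' configured variant and re-sorts each query's list by fused score
#' descending (ties by pmid descending). Documents without a profile
#' count as having no annotated concepts (D = 0); no document is ever
#' added or dropped.
#'
#' @param run a ranked run (see [search_index()]); engine scores must
#'   be non-negative.
#' @param profiles a named list (by pmid) of `concept_profile` objects,
#'   e.g. from [corpus_profiles()].
#' @param config a [fusion_config()] or preset.
#' @return The re-ranked run with `score` holding fused scores.
#' @export
rerank <- function(run, profiles, config) {
  stopifnot(inherits(config, "fusion_config"))
  qids <- unique(run$query_id)
  out <- lapply(qids, function(q) {
    g <- run[run$query_id == q, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    fused <- .fused_scores(g$score, g$pmid, profiles, config)
    o <- order(-fused, -g$pmid)
    .new_run(q, g$pmid[o], fused[o])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
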