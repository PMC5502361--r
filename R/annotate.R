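# Tokenization: maximal runs of alphanumerics; hyphens and slashes (and
# every other non-alphanumeric) separate tokens, digits stay inside
# tokens, so "ubiquitin-mediated" yields the matchable token "ubiquitin".
.tokenize_offsets <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1)
    return(data.frame(token = character(), start = integer(),
                      end = integer()))
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(token = tolower(substring(text, start1, start1 + len - 1L)),
             start = start1 - 1L, end = start1 + len - 1L,
             stringsAsFactors = FALSE)
}

.pattern_tokens <- function(p) {
  t <- strsplit(p, "[^[:alnum:]]+")[[1]]
  t[nzchar(t)]
}

# one row per match pattern: single-token patterns are word prefixes,
# multi-token patterns are exact phrases; multi-word labels are added as
# phrase patterns automatically
.compile_patterns <- function(thesaurus) {
  out <- list()
  for (i in seq_len(nrow(thesaurus))) {
    pats <- .split_pipe(thesaurus$stems[i])
    lab <- tolower(trimws(thesaurus$label[i]))
    if (length(.pattern_tokens(lab)) > 1L) pats <- unique(c(pats, lab))
    for (p in pats) {
      toks <- .pattern_tokens(p)
      if (length(toks) == 0) next
      out[[length(out) + 1L]] <- list(concept_id = thesaurus$concept_id[i],
                                      toks = toks, n = length(toks))
    }
  }
  out
}

#' Split text into sentence spans
#'
#' Sentence boundaries are placed after sentence-final punctuation
#' (`.`, `!` or `?`) followed by whitespace and an uppercase letter or a
#' digit. Spans are 0-based half-open character intervals, ordered,
#' non-overlapping, and together cover all non-whitespace text.
#'
#' @param text a single character string.
#' @return A data frame with columns `start` and `end`.
#' @examples
#' split_sentences("A binds B. C binds D.")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  bnd <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  ends1 <- if (bnd[1] == -1) integer() else as.integer(bnd)
  seg_start <- c(1L, ends1 + 1L)
  seg_end <- c(ends1, nchar(text))
  spans <- lapply(seq_along(seg_start), function(i) {
    seg <- substring(text, seg_start[i], seg_end[i])
    first <- regexpr("[^[:space:]]", seg)
    if (first == -1) return(NULL)
    last <- nchar(sub("[[:space:]]+$", "", seg))
    c(start = seg_start[i] + as.integer(first) - 2L,
      end = seg_start[i] + last - 1L)
  })
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) == 0) return(empty)
  m <- do.call(rbind, spans)
  data.frame(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]))
}

#' Annotate a document with thesaurus concepts
#'
#' Marks up every occurrence of an axis concept in the concatenated
#' title + single space + abstract text. A token matches an entry when
#' it begins with one of the entry's single-token stems; multi-word
#' labels (and stems containing spaces) match by exact lowercase phrase
#' equality over token windows. Matching is case-insensitive; matches
#' never overlap and the longest match wins; annotations are returned
#' sorted by character offset, with the containing sentence recorded.
#'
#' @param doc a one-row [document_set()] (or a list with `title` and
#'   `abstract` fields).
#' @param thesaurus a [load_thesaurus()] object.
#' @return A data frame with columns `concept_id`, `sentence_index`
#'   (0-based), `char_start`, `char_end` (0-based half-open offsets into
#'   the title+abstract text) and `surface` (the matched text slice).
#' @export
annotate_document <- function(doc, thesaurus) {
  if (inherits(doc, "document_set")) {
    if (nrow(doc) != 1L) stop("annotate_document expects a single document")
    doc <- as.list(doc)
  }
  stopifnot(inherits(thesaurus, "triage_thesaurus"))
  text <- paste(doc$title, doc$abstract)
  .annotate_text(text, .compile_patterns(thesaurus))
}

.annotate_text <- function(text, patterns) {
  empty <- data.frame(concept_id = character(), sentence_index = integer(),
                      char_start = integer(), char_end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  toks <- .tokenize_offsets(text)
  nt <- nrow(toks)
  if (nt == 0 || length(patterns) == 0) return(empty)
  cand_i <- integer(); cand_j <- integer(); cand_id <- character()
  for (p in patterns) {
    if (p$n == 1L) {
      hit <- which(startsWith(toks$token, p$toks))
      j <- hit
    } else {
      if (nt < p$n) next
      idx <- seq_len(nt - p$n + 1L)
      ok <- rep(TRUE, length(idx))
      for (k in seq_len(p$n))
        ok <- ok & toks$token[idx + k - 1L] == p$toks[k]
      hit <- idx[ok]
      j <- hit + p$n - 1L
    }
    if (length(hit)) {
      cand_i <- c(cand_i, hit)
      cand_j <- c(cand_j, j)
      cand_id <- c(cand_id, rep(p$concept_id, length(hit)))
    }
  }
  if (length(cand_i) == 0) return(empty)
  cs <- toks$start[cand_i]
  ce <- toks$end[cand_j]
  o <- order(cs, -(ce - cs))
  cand_i <- cand_i[o]; cand_j <- cand_j[o]
  cs <- cs[o]; ce <- ce[o]; cand_id <- cand_id[o]
  keep <- logical(length(cand_i))
  next_tok <- 1L
  for (k in seq_along(cand_i)) {
    if (cand_i[k] >= next_tok) {
      keep[k] <- TRUE
      next_tok <- cand_j[k] + 1L
    }
  }
  cs <- cs[keep]; ce <- ce[keep]; cand_id <- cand_id[keep]
  sent <- split_sentences(text)
  si <- if (nrow(sent)) findInterval(cs, sent$start) - 1L else
    rep(0L, length(cs))
  data.frame(concept_id = cand_id, sentence_index = si,
             char_start = cs, char_end = ce,
             surface = substring(text, cs + 1L, ce),
             stringsAsFactors = FALSE)
}

#' Concept-density profile of a document
#'
#' Summarises a document's annotations into the statistics consumed by
#' score fusion: the number of distinct concepts D, the per-concept
#' occurrence count (term frequency), and the canonical descriptor
#' length in characters (a proxy for descriptor specificity).
#'
#' @param annotations annotation data frame from [annotate_document()].
#' @param thesaurus the thesaurus the annotations were produced from.
#' @return An object of class `concept_profile`: a list with elements
#'   `D`, `tf` (named integer vector) and `desc_len` (named integer
#'   vector, label length excluding surrounding whitespace).
#' @export
build_profile <- function(annotations, thesaurus) {
  stopifnot(inherits(thesaurus, "triage_thesaurus"))
  ids <- as.character(annotations$concept_id)
  unknown <- setdiff(ids, thesaurus$concept_id)
  if (length(unknown))
    stop("annotation references unknown concept_id: ",
         paste(unknown, collapse = ", "))
  tf <- table(ids)
  tfv <- stats::setNames(as.integer(tf), names(tf))
  len <- nchar(trimws(thesaurus$label))[match(names(tfv),
                                              thesaurus$concept_id)]
  structure(list(D = length(tfv), tf = tfv,
                 desc_len = stats::setNames(as.integer(len), names(tfv))),
            class = "concept_profile")
}

#' @export
print.concept_profile <- function(x, ...) {
  cat("<concept_profile> D=", x$D, "\n", sep = "")
  if (x$D) print(data.frame(concept_id = names(x$tf), tf = unname(x$tf),
                            desc_len = unname(x$desc_len)))
  invisible(x)
}

#' Annotate a whole corpus and build per-document profiles
#'
#' @param docs a [document_set()].
#' @param thesaurus a `triage_thesaurus`.
#' @return A named list (by pmid) of `concept_profile` objects.
#' @export
corpus_profiles <- function(docs, thesaurus) {
  stopifnot(inherits(docs, "document_set"))
  pats <- .compile_patterns(thesaurus)
  profs <- lapply(seq_len(nrow(docs)), function(i) {
    ann <- .annotate_text(paste(docs$title[i], docs$abstract[i]), pats)
    build_profile(ann, thesaurus)
  })
  stats::setNames(profs, as.character(docs$pmid))
}

#' Write annotations as JSON lines
#'
#' One JSON object per annotation with fields `pmid`, `concept_id`,
#' `sentence_index`, `char_start`, `char_end` and `surface`.
#'
#' @param annotations annotation data frame from [annotate_document()].
#' @param pmid the document identifier recorded in each line.
#' @param path output file; opened in append mode when `append = TRUE`.
#' @param append whether to append to an existing file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, pmid, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(annotations))) {
    rec <- c(list(pmid = as.integer(pmid)),
             as.list(annotations[i, , drop = FALSE]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
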