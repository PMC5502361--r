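#' Construct a document set
#'
#' A document set is the in-memory corpus container: one row per abstract
#' record with identifier, text, publication date and publication-type
#' flags. It is the local stand-in for a record of a MEDLINE mirror.
#'
#' @param pmid positive integer identifiers, unique within the set.
#' @param title,abstract character vectors (abstract may be empty strings).
#' @param year integer publication year (>= 1800) or `NA`.
#' @param month,day optional integer date parts; `NA` when unknown.
#' @param pub_types publication-type labels per document, pipe-joined
#'   (e.g. `"Review|Retracted Publication"`); `""` for none.
#' @return An object of class `document_set` (a data frame).
#' @examples
#' document_set(pmid = 1:2, title = c("a", "b"), abstract = c("x", ""),
#'              year = c(2001L, NA))
#' @export
document_set <- function(pmid, title, abstract = "", year = NA_integer_,
                         month = NA_integer_, day = NA_integer_,
                         pub_types = "") {
  pmid <- as.integer(pmid)
  n <- length(pmid)
  if (n > 0 && (anyNA(pmid) || any(pmid <= 0L)))
    stop("pmid must be positive integers")
  if (anyDuplicated(pmid))
    stop("duplicate pmid in document set: ",
         paste(unique(pmid[duplicated(pmid)]), collapse = ", "))
  year <- as.integer(rep_len(year, n))
  if (any(!is.na(year) & year < 1800L))
    stop("publication year must be >= 1800")
  df <- data.frame(
    pmid = pmid,
    title = as.character(rep_len(title, n)),
    abstract = as.character(rep_len(abstract, n)),
    year = year,
    month = as.integer(rep_len(month, n)),
    day = as.integer(rep_len(day, n)),
    pub_types = as.character(rep_len(pub_types, n)),
    stringsAsFactors = FALSE
  )
  df$abstract[is.na(df$abstract)] <- ""
  df$pub_types[is.na(df$pub_types)] <- ""
  class(df) <- c("document_set", "data.frame")
  df
}

#' @export
print.document_set <- function(x, ...) {
  cat("<document_set> ", nrow(x), " document(s)\n", sep = "")
  if (nrow(x)) {
    yr <- range(x$year, na.rm = TRUE)
    if (all(is.finite(yr))) cat("  years: ", yr[1], "-", yr[2], "\n", sep = "")
  }
  invisible(x)
}

# numeric sortable key yyyymmdd; missing month/day completed as January/1st,
# missing year -> NA
.date_key <- function(docs) {
  m <- ifelse(is.na(docs$month), 1L, docs$month)
  d <- ifelse(is.na(docs$day), 1L, docs$day)
  ifelse(is.na(docs$year), NA_real_, docs$year * 10000 + m * 100 + d)
}

.as_key <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "Date"))
    return(as.numeric(format(x, "%Y")) * 10000 +
           as.numeric(format(x, "%m")) * 100 + as.numeric(format(x, "%d")))
  if (is.character(x)) {
    p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    if (length(p) < 1 || anyNA(p[1])) stop("unparseable date: ", x)
    if (length(p) < 2) p[2] <- 1L
    if (length(p) < 3) p[3] <- 1L
    return(p[1] * 10000 + p[2] * 100 + p[3])
  }
  stop("dates must be Date objects or 'YYYY-MM-DD' strings")
}

#' Specify corpus filters
#'
#' Captures the exclusion rules applied before evaluation: a temporal
#' window (e.g. discarding papers published after a benchmark's cut-off
#' date), publication types that curators do not use (reviews, retracted
#' publications) and explicitly excluded identifiers.
#'
#' @param date_after,date_before inclusive date bounds (`Date` or
#'   `"YYYY-MM-DD"` strings), or `NULL` for no bound.
#' @param exclude_pub_types publication-type labels to drop; matched
#'   case-insensitively.
#' @param excluded_pmids identifiers to drop unconditionally.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(date_after = NULL, date_before = NULL,
                        exclude_pub_types = character(),
                        excluded_pmids = integer()) {
  ka <- .as_key(date_after)
  kb <- .as_key(date_before)
  if (!is.null(ka) && !is.null(kb) && ka >= kb)
    stop("date_after must fall before date_before")
  structure(list(date_after = ka, date_before = kb,
                 exclude_pub_types = as.character(exclude_pub_types),
                 excluded_pmids = as.integer(excluded_pmids)),
            class = "filter_spec")
}

#' Filter a document set
#'
#' Applies a [filter_spec()] to a corpus: documents outside the date
#' window, carrying an excluded publication type, or explicitly excluded
#' by identifier are removed. Original order is preserved and the input
#' is never modified. Documents lacking any date are retained unless a
#' date filter is set, in which case they are dropped with a warning.
#'
#' @param docs a [document_set()].
#' @param spec a [filter_spec()].
#' @return The filtered `document_set`.
#' @export
apply_filters <- function(docs, spec = filter_spec()) {
  stopifnot(inherits(docs, "document_set"), inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(docs))
  has_date_filter <- !is.null(spec$date_after) || !is.null(spec$date_before)
  if (has_date_filter) {
    key <- .date_key(docs)
    undated <- is.na(key)
    if (any(undated)) {
      warning(sum(undated), " undated document(s) dropped by date filter")
      keep <- keep & !undated
    }
    if (!is.null(spec$date_after))
      keep <- keep & !is.na(key) & key >= spec$date_after
    if (!is.null(spec$date_before))
      keep <- keep & !is.na(key) & key <= spec$date_before
  }
  if (length(spec$exclude_pub_types)) {
    ex <- tolower(spec$exclude_pub_types)
    flagged <- vapply(docs$pub_types,
                      function(p) any(tolower(.split_pipe(p)) %in% ex),
                      logical(1), USE.NAMES = FALSE)
    keep <- keep & !flagged
  }
  if (length(spec$excluded_pmids))
    keep <- keep & !(docs$pmid %in% spec$excluded_pmids)
  out <- docs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("document_set", "data.frame")
  out
}

.MONTHS <- c(jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
             jul = 7L, aug = 8L, sep = 9L, oct = 10L, nov = 11L, dec = 12L)

.parse_month <- function(txt) {
  if (length(txt) == 0 || is.na(txt) || !nzchar(txt)) return(NA_integer_)
  if (grepl("^[0-9]+$", txt)) return(as.integer(txt))
  m <- .MONTHS[tolower(substr(txt, 1, 3))]
  if (is.na(m)) NA_integer_ else unname(m)
}

.xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
}

.parse_article <- function(art) {
  pmid_txt <- .xml_text1(art, ".//MedlineCitation/PMID")
  if (is.na(pmid_txt) || !grepl("^[0-9]+$", trimws(pmid_txt))) {
    warning("article without a numeric PMID skipped")
    return(NULL)
  }
  title <- .xml_text1(art, ".//Article/ArticleTitle")
  if (is.na(title)) title <- ""
  abs_nodes <- xml2::xml_find_all(art, ".//Article/Abstract/AbstractText")
  if (length(abs_nodes) == 0) {
    warning("PMID ", trimws(pmid_txt), " has no abstract")
    abstract <- ""
  } else {
    abstract <- paste(vapply(abs_nodes, xml2::xml_text, character(1)),
                      collapse = " ")
  }
  pd <- xml2::xml_find_first(art, ".//Article/Journal/JournalIssue/PubDate")
  year <- NA_integer_; month <- NA_integer_; day <- NA_integer_
  if (!inherits(pd, "xml_missing")) {
    ytxt <- .xml_text1(pd, "./Year")
    if (!is.na(ytxt) && grepl("^[0-9]{4}$", ytxt)) {
      year <- as.integer(ytxt)
    } else {
      # MedlineDate fallback such as "1998 Dec-1999 Jan": first 4-digit year
      md <- .xml_text1(pd, "./MedlineDate")
      if (!is.na(md)) {
        m <- regmatches(md, regexpr("[0-9]{4}", md))
        if (length(m)) year <- as.integer(m)
      }
    }
    month <- .parse_month(.xml_text1(pd, "./Month"))
    dtxt <- .xml_text1(pd, "./Day")
    if (!is.na(dtxt) && grepl("^[0-9]+$", dtxt)) day <- as.integer(dtxt)
  }
  pt <- xml2::xml_find_all(art, ".//PublicationTypeList/PublicationType")
  pub_types <- paste(vapply(pt, xml2::xml_text, character(1)), collapse = "|")
  list(pmid = as.integer(trimws(pmid_txt)), title = title,
       abstract = abstract, year = year, month = month, day = day,
       pub_types = pub_types)
}

#' Read a PubMed/MEDLINE XML corpus
#'
#' Parses the `PubmedArticleSet` dialect (PMID, ArticleTitle,
#' AbstractText, PubDate, PublicationTypeList). Articles without a PMID
#' are skipped with a warning; a missing Abstract element yields an
#' empty abstract with a warning; multiple AbstractText sections are
#' concatenated with single spaces in document order.
#'
#' @param path path to (or connection/URL of) a well-formed XML file.
#' @return A [document_set()].
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, "//PubmedArticle")
  recs <- Filter(Negate(is.null), lapply(arts, .parse_article))
  if (length(recs) == 0)
    return(document_set(pmid = integer(), title = character()))
  g <- function(f, what) vapply(recs, function(r) r[[f]], what)
  document_set(pmid = g("pmid", integer(1)),
               title = g("title", character(1)),
               abstract = g("abstract", character(1)),
               year = g("year", integer(1)),
               month = g("month", integer(1)),
               day = g("day", integer(1)),
               pub_types = g("pub_types", character(1)))
}

.TSV_COLS <- c("pmid", "title", "abstract", "year", "pub_types")

#' Read a corpus from the tab-separated dialect
#'
#' The TSV dialect carries columns `pmid`, `title`, `abstract`, `year`
#' and `pub_types` (pipe-separated labels), with a mandatory header.
#' Lines starting with `#` are comments.
#'
#' @param path path to a UTF-8 TSV file.
#' @return A [document_set()].
#' @seealso [write_tsv_corpus()] for the inverse operation.
#' @export
read_tsv_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty corpus file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .TSV_COLS))
    stop("corpus header must be: ", paste(.TSV_COLS, collapse = ", "))
  if (length(lines) == 1)
    return(document_set(pmid = integer(), title = character()))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < length(.TSV_COLS)) r <- c(r, rep("", 5 - length(r)))
    if (!grepl("^[0-9]+$", r[1]))
      stop("line ", lineno[i + 1L], ": non-integer pmid '", r[1], "'")
    rows[[i]] <- r[seq_along(.TSV_COLS)]
  }
  m <- do.call(rbind, rows)
  year <- suppressWarnings(as.integer(m[, 4]))
  document_set(pmid = as.integer(m[, 1]), title = m[, 2], abstract = m[, 3],
               year = year, pub_types = m[, 5])
}

#' Write a corpus in the tab-separated dialect
#'
#' @param docs a [document_set()].
#' @param path output path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_tsv_corpus <- function(docs, path) {
  stopifnot(inherits(docs, "document_set"))
  clean <- function(x) {
    bad <- grepl("[\t\n\r]", x)
    if (any(bad)) {
      warning("tabs/newlines in text fields replaced by spaces")
      x[bad] <- gsub("[\t\n\r]+", " ", x[bad])
    }
    x
  }
  lines <- c(paste(.TSV_COLS, collapse = "\t"),
             paste(docs$pmid, clean(docs$title), clean(docs$abstract),
                   ifelse(is.na(docs$year), "", docs$year),
                   clean(docs$pub_types), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
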