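.AXIS_CATEGORIES <- list(
  PPI = c("interaction_term", "experimental_method"),
  PTM = "ptm_type"
)

.THES_COLS <- c("concept_id", "label", "stems", "category")

#' Load an axis thesaurus
#'
#' A thesaurus is the controlled vocabulary of one curation axis: for
#' PPI, stemmed interaction terms plus experimental-method names; for
#' PTM, modification types. Each entry carries one or more lowercase
#' match stems; a stem containing spaces is matched as an exact token
#' phrase, a single-token stem by word-prefix (so `phosphorylat` covers
#' phosphorylated, phosphorylates, phosphorylating and phosphorylation).
#'
#' @param path TSV file with columns `concept_id`, `label`, `stems`
#'   (pipe-separated) and `category`; `#` lines are comments.
#' @param axis `"PPI"` or `"PTM"`; entry categories must be consistent
#'   with the axis (`interaction_term`/`experimental_method` for PPI,
#'   `ptm_type` for PTM).
#' @return An object of class `triage_thesaurus` (a data frame with an
#'   `axis` attribute).
#' @seealso [default_thesaurus()] for the bundled vocabularies.
#' @export
load_thesaurus <- function(path, axis = c("PPI", "PTM")) {
  axis <- match.arg(axis)
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (!all(.THES_COLS %in% names(tab)))
    stop("thesaurus must have columns: ", paste(.THES_COLS, collapse = ", "))
  tab <- tab[.THES_COLS]
  if (nrow(tab) == 0) {
    warning("empty thesaurus table: ", path)
  } else {
    if (anyDuplicated(tab$concept_id))
      stop("duplicate concept_id: ",
           paste(unique(tab$concept_id[duplicated(tab$concept_id)]),
                 collapse = ", "))
    bad_cat <- !(tab$category %in% .AXIS_CATEGORIES[[axis]])
    if (any(bad_cat))
      stop("category inconsistent with axis ", axis, ": ",
           paste(unique(tab$category[bad_cat]), collapse = ", "))
    for (i in seq_len(nrow(tab))) {
      st <- .split_pipe(tab$stems[i])
      if (length(st) == 0)
        stop("entry ", tab$concept_id[i], " has no stems")
      ok <- nzchar(st) & st == trimws(st) & st == tolower(st)
      if (!all(ok))
        stop("entry ", tab$concept_id[i],
             ": stems must be non-empty, lowercase, trimmed")
    }
  }
  structure(tab, class = c("triage_thesaurus", "data.frame"), axis = axis)
}

#' Bundled default thesauri
#'
#' Returns the packaged descriptor vocabulary for an axis. The PTM
#' vocabulary holds 16 modification types (phosphorylation, methylation,
#' dephosphorylation, glycosylation, nitrosylation, palmitoylation,
#' deubiquitination, polyADP-ribosylation, acetylation, desumoylation,
#' myristoylation, deacetylation, farnesylation, ubiquitination,
#' sumoylation, protein cleavage). The PPI vocabulary holds 23 entries:
#' 14 stemmed interaction terms plus 9 experimental-method names; it is
#' a reconstruction built from published exemplar terms (the original
#' curated list is not redistributable), and the bundled data file is
#' marked accordingly.
#'
#' @param axis `"PPI"` or `"PTM"`.
#' @return A `triage_thesaurus`.
#' @export
default_thesaurus <- function(axis = c("PPI", "PTM")) {
  axis <- match.arg(axis)
  file <- switch(axis,
                 PPI = "ppi_thesaurus_synthetic.tsv",
                 PTM = "ptm_thesaurus.tsv")
  load_thesaurus(system.file("extdata", file, package = "litriage",
                             mustWork = TRUE), axis)
}

#' @export
print.triage_thesaurus <- function(x, ...) {
  cat("<triage_thesaurus> axis=", attr(x, "axis"), ", ",
      nrow(x), " concept(s)\n", sep = "")
  if (nrow(x)) print(table(x$category))
  invisible(x)
}

#' Axis of a thesaurus
#' @param thesaurus a `triage_thesaurus`.
#' @return `"PPI"` or `"PTM"`.
#' @export
thesaurus_axis <- function(thesaurus) attr(thesaurus, "axis")
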