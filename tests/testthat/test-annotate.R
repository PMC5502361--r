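test_that("thesaurus loading validates identifiers, categories and stems", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("concept_id\tlabel\tstems\tcategory",
               "a\tbind\tbind\tinteraction_term",
               "a\tinteract\tinteract\tinteraction_term"), path)
  expect_error(load_thesaurus(path, "PPI"), "duplicate concept_id")
  writeLines(c("concept_id\tlabel\tstems\tcategory",
               "a\tbind\tbind\tptm_type"), path)
  expect_error(load_thesaurus(path, "PPI"), "inconsistent with axis")
  writeLines(c("concept_id\tlabel\tstems\tcategory",
               "a\tbind\tBind \tinteraction_term"), path)
  expect_error(load_thesaurus(path, "PPI"), "lowercase")
  writeLines("concept_id\tlabel\tstems\tcategory", path)
  expect_warning(empty <- load_thesaurus(path, "PTM"), "empty")
  expect_equal(nrow(empty), 0)
  expect_equal(thesaurus_axis(empty), "PTM")
})

test_that("sentence splitting follows the punctuation-whitespace-capital rule", {
  expect_equal(nrow(split_sentences("")), 0)
  two <- split_sentences("A binds B. C binds D.")
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(0L, 11L))
  expect_equal(two$end, c(10L, 21L))
  # digits also open a sentence, so the figure reference splits off
  fig <- split_sentences("Fig. 2 shows X. It binds Y.")
  expect_equal(fig$start, c(0L, 5L, 16L))
  expect_equal(fig$end, c(4L, 15L, 27L))
  # lowercase continuation does not split
  expect_equal(nrow(split_sentences("E. coli grows fast.")), 1)
})

test_that("sentence spans are ordered, non-overlapping and cover non-whitespace", {
  texts <- c("One. Two! Three? 4 ends.",
             "  padded   start. And end.  ",
             "No boundary here at all",
             "A. B. C. D. E.")
  for (tx in texts) {
    sp <- split_sentences(tx)
    expect_true(all(diff(sp$start) > 0))
    expect_true(all(sp$end > sp$start))
    expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
    covered <- unlist(mapply(seq, sp$start + 1, sp$end, SIMPLIFY = FALSE))
    chars <- strsplit(tx, "")[[1]]
    non_ws <- which(!grepl("[[:space:]]", chars))
    expect_true(all(non_ws %in% covered))
  }
})

test_that("stem annotation records exact offsets and surfaces", {
  ptm <- default_thesaurus("PTM")
  ann <- annotate_document(list(title = "BTK phosphorylated PLCG2 in vitro",
                                abstract = ""), ptm)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$surface, "phosphorylated")
  expect_equal(ann$char_start, 4L)
  expect_equal(ann$char_end, 18L)
  expect_equal(ann$concept_id, "PTM:phosphorylation")
  expect_equal(ann$sentence_index, 0L)
  # no thesaurus term present
  none <- annotate_document(list(title = "nothing relevant", abstract = ""),
                            ptm)
  expect_equal(nrow(none), 0)
})

test_that("a stem covers its morphological variants by prefix", {
  ptm <- default_thesaurus("PTM")
  txt <- "phosphorylated, phosphorylates, phosphorylating and phosphorylation"
  ann <- annotate_document(list(title = "", abstract = txt), ptm)
  expect_equal(nrow(ann), 4)
  expect_true(all(ann$concept_id == "PTM:phosphorylation"))
  # the de- prefixed modification is a different concept
  de <- annotate_document(list(title = "dephosphorylated", abstract = ""),
                          ptm)
  expect_equal(de$concept_id, "PTM:dephosphorylation")
})

test_that("multi-word phrases beat single-token matches (longest match wins)", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("concept_id\tlabel\tstems\tcategory",
               "m1\tpull\tpull\tinteraction_term",
               "m2\tpull down\tpulldown\texperimental_method"), path)
  thes <- load_thesaurus(path, "PPI")
  ann <- annotate_document(list(title = "pull down assay", abstract = ""),
                           thes)
  expect_equal(ann$concept_id, "m2")
  expect_equal(ann$surface, "pull down")
  # hyphenated variants tokenize into matchable words
  ann2 <- annotate_document(list(title = "a pull-down assay", abstract = ""),
                            thes)
  expect_equal(ann2$concept_id, "m2")
})

test_that("annotation is case-insensitive and surfaces slice the text", {
  ppi <- default_thesaurus("PPI")
  doc <- list(title = "GRB2 binds SOS and forms a complex",
              abstract = "Two hybrid and x-ray crystallography confirm binding.")
  ann <- annotate_document(doc, ppi)
  up <- annotate_document(lapply(doc, toupper), ppi)
  expect_equal(ann$concept_id, up$concept_id)
  expect_equal(ann$char_start, up$char_start)
  text <- paste(doc$title, doc$abstract)
  expect_equal(ann$surface,
               substring(text, ann$char_start + 1, ann$char_end))
  # matches never overlap
  if (nrow(ann) > 1)
    expect_true(all(ann$char_start[-1] >= ann$char_end[-nrow(ann)]))
  expect_true("PPI:two_hybrid" %in% ann$concept_id)
  expect_true("PPI:xray_crystallography" %in% ann$concept_id)
})

test_that("profiles summarise annotations and agree with the annotation set", {
  ppi <- default_thesaurus("PPI")
  empty <- build_profile(annotate_document(list(title = "x", abstract = ""),
                                           ppi), ppi)
  expect_equal(empty$D, 0)
  expect_length(empty$tf, 0)
  # {c1, c1, c2} -> D = 2, tf(c1) = 2, tf(c2) = 1
  ann <- data.frame(concept_id = c("PPI:bind", "PPI:bind", "PPI:complex"),
                    sentence_index = 0L, char_start = c(0L, 6L, 12L),
                    char_end = c(5L, 11L, 19L), surface = "s")
  p <- build_profile(ann, ppi)
  expect_equal(p$D, 2)
  expect_equal(unname(p$tf[["PPI:bind"]]), 2L)
  expect_equal(unname(p$tf[["PPI:complex"]]), 1L)
  expect_equal(unname(p$desc_len[["PPI:complex"]]), nchar("complex"))
  expect_error(build_profile(data.frame(concept_id = "nope"), ppi),
               "unknown concept_id")
})

test_that("profile D equals the distinct concepts annotated, and never exceeds the thesaurus", {
  ppi <- default_thesaurus("PPI")
  gen <- generate_corpus(synth_params(n_docs = 40, n_queries = 4, seed = 5))
  for (i in seq_len(20)) {
    doc <- gen$docs[i, , drop = FALSE]
    ann <- annotate_document(doc, ppi)
    prof <- build_profile(ann, ppi)
    expect_equal(prof$D, length(unique(ann$concept_id)))
    expect_lte(prof$D, nrow(ppi))
    if (nrow(ann) > 1)
      expect_true(all(ann$char_start[-1] >= ann$char_end[-nrow(ann)]))
    if (nrow(ann) > 0) {
      text <- paste(doc$title, doc$abstract)
      expect_equal(ann$surface,
                   substring(text, ann$char_start + 1, ann$char_end))
    }
  }
})
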