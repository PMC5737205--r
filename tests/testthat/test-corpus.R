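registry_fixture <- function() {
  schema_registry(list(
    pdbish = list(
      category = "Protein structure",
      fields = list(doc_id = "DocID", title = "TITLE",
                    description = "METADATA/description",
                    genes = "METADATA/genes/gene",
                    pmids = "METADATA/pmids/pmid")),
    plainish = list(
      category = "Unspecified",
      fields = list(doc_id = "DocID", title = "TITLE"))))
}

test_that("parse_record maps repository paths to canonical fields only", {
  reg <- registry_fixture()
  raw <- list(DocID = "d1", TITLE = "CheY structure",
              METADATA = list(description = "response regulator",
                              genes = list(gene = "cheY", gene = "cheA"),
                              pmids = list(pmid = "p2", pmid = "p1")))
  rec <- parse_record(raw, reg, "pdbish")
  expect_s3_class(rec, "dataset_record")
  expect_identical(rec$doc_id, "d1")
  expect_identical(rec$category, "Protein structure")
  expect_setequal(names(rec$fields), c("title", "description", "genes"))
  expect_identical(rec$fields$genes, c("cheY", "cheA"))
  expect_identical(sort(rec$pmids), c("p1", "p2"))
})

test_that("fields a repository does not provide are absent, not empty", {
  reg <- registry_fixture()
  rec <- parse_record(list(DocID = "d2", TITLE = "t",
                           METADATA = list(description = "ignored")),
                      reg, "plainish")
  expect_false("description" %in% names(rec$fields))
  expect_identical(names(rec$fields), "title")
})

test_that("parse_record error cases", {
  reg <- registry_fixture()
  expect_error(parse_record(list(DocID = "x"), reg, "nosuch"),
               "unknown repository")
  expect_error(parse_record(list(TITLE = "no id"), reg, "pdbish"),
               "missing DocID")
  expect_error(schema_registry(list(bad = list(category = "C",
                                               fields = list(title = "T")))),
               "doc_id")
  expect_error(schema_registry(list(bad = list(
    category = "C", fields = list(doc_id = "D", nonfield = "X")))),
    "non-canonical")
})

test_that("XML input parses identically to the equivalent JSON tree", {
  reg <- registry_fixture()
  xml <- xml2::read_xml(paste0(
    "<doc><DocID>d9</DocID><TITLE>CheY structure</TITLE>",
    "<METADATA><description>response regulator</description>",
    "<genes><gene>cheY</gene></genes></METADATA></doc>"))
  rec <- parse_record(xml, reg, "pdbish")
  expect_identical(rec$fields$title, "CheY structure")
  expect_identical(rec$fields$description, "response regulator")
  expect_identical(rec$fields$genes, "cheY")
})

test_that("article linkage concatenates in ascending PMID order and counts misses", {
  tab <- article_table(c("p1", "p2"), c("title one", "title two"),
                       c("abs one", "abs two"))
  recs <- list(
    dataset_record("a", "r", fields = list(title = "x"), pmids = c("p2", "p1")),
    dataset_record("b", "r", fields = list(title = "y"), pmids = "p9"),
    dataset_record("c", "r", fields = list(title = "z")))
  res <- link_articles(recs, tab)
  expect_identical(res$records[[1]]$fields$article_title, "title one title two")
  expect_identical(res$records[[1]]$fields$article_abstract, "abs one abs two")
  expect_false("article_title" %in% names(res$records[[2]]$fields))
  expect_identical(res$stats$linked, c(2L, 0L, 0L))
  expect_identical(res$stats$missing, c(0L, 1L, 0L))
})

test_that("canonical JSON-lines round-trips and rejects duplicate ids", {
  recs <- three_doc_records()
  recs[[1]]$fields$keywords <- c("two sign", "bacteria")
  recs[[1]]$pmids <- "p7"
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_collection(recs, path)
  back <- read_collection(path)
  expect_identical(back, recs)
  # byte determinism of the serialization
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_collection(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_collection(c(recs, recs[1]), path), "duplicate")
})

test_that("the field census reflects schema-driven presence patterns", {
  recs <- three_doc_records()
  cen <- field_census(recs)
  expect_identical(cen$n_present[cen$repository == "repoA" &
                                   cen$field == "title"], 2L)
  expect_identical(cen$n_present[cen$repository == "repoA" &
                                   cen$field == "description"], 0L)
})

test_that("record constructor enforces the closed field vocabulary", {
  expect_error(dataset_record("d", "r", fields = list(notafield = "x")),
               "unknown field")
  expect_error(dataset_record("", "r"), "non-empty")
  # empty placeholders are dropped rather than stored
  rec <- dataset_record("d", "r", fields = list(title = "", genes = "g"))
  expect_identical(names(rec$fields), "genes")
})
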