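test_that("creating a report writes front matter with title and authors", {
  d <- new_report_dir()
  rp <- create_report(file.path(d, "rnaseq_report"),
                      title = "RNA-seq Analysis Report",
                      authors = "Dario Righelli")
  expect_true(file.exists(file.path(d, "rnaseq_report.Rmd")))
  txt <- file_text(rp$path)
  expect_match(txt, 'title: "RNA-seq Analysis Report"', fixed = TRUE)
  expect_match(txt, 'name: "Dario Righelli"', fixed = TRUE)
  expect_match(txt, "^---", perl = TRUE)
  snap <- inspect_report(rp)
  expect_length(snap$authors, 1L)
  expect_null(snap$bibliography)
  expect_identical(snap$n_elements, 0L)
  expect_false(rp$chunk_open)
})

test_that("title and path are mandatory", {
  expect_error(create_report(file.path(new_report_dir(), "r"), title = ""),
               "mandatory")
  expect_error(create_report(file.path(new_report_dir(), "r"),
                             title = "   "), "mandatory")
  expect_error(create_report("", title = "t"), "mandatory")
})

test_that("creating over an existing report errors and leaves it untouched", {
  d <- new_report_dir()
  rp <- create_report(file.path(d, "r"), title = "first")
  before <- file_md5(rp$path)
  expect_error(create_report(file.path(d, "r"), title = "second"),
               "already exists")
  expect_identical(file_md5(rp$path), before)
  rp2 <- create_report(file.path(d, "r"), title = "second",
                       overwrite = TRUE)
  expect_match(file_text(rp2$path), 'title: "second"', fixed = TRUE)
})

test_that("parent directories are created and extensions respected", {
  d <- new_report_dir()
  rp <- create_report(file.path(d, "a", "b", "r"), title = "t")
  expect_true(file.exists(file.path(d, "a", "b", "r.Rmd")))
  rp2 <- create_report(file.path(d, "explicit.md"), title = "t")
  expect_identical(basename(rp2$path), "explicit.md")
})

test_that("inspect returns construction-time values plus resources", {
  d <- new_report_dir()
  rp <- create_report(file.path(d, "r"), title = "t",
                      bibliography = "refs.bib")
  expect_identical(inspect_report(rp)$bibliography, "refs.bib")
  add_resource(rp, "GEO", "raw counts", "https://example/GSE0000")
  add_resource(rp, "SRA", "fastq", "SRR000001")
  res <- inspect_report(rp)$resources
  expect_identical(nrow(res), 2L)
  expect_identical(res$source, c("GEO", "SRA"))  # insertion order
})

test_that("resources require a non-empty source", {
  rp <- tmp_report()
  before <- file_md5(rp$path)
  expect_error(add_resource(rp, "", "x", "y"), "non-empty")
  expect_identical(file_md5(rp$path), before)
})

test_that("authors round-trip through the front matter parser", {
  rp <- tmp_report(authors = list(
    author("Ada Lovelace", email = "ada@example.org",
           affiliation = "Analytical Engines", orcid = "0000-0000-0000-0001",
           affiliation_url = "https://example.org", url = "https://ada.dev"),
    author("Charles Babbage")))
  parsed <- parse_report(rp$path)
  expect_length(parsed$authors, 2L)
  expect_identical(parsed$authors[[1]]$email, "ada@example.org")
  expect_identical(parsed$authors[[1]]$orcid, "0000-0000-0000-0001")
  expect_identical(parsed$authors[[2]]$name, "Charles Babbage")
  expect_error(author(""), "mandatory")
})

test_that("global options validate and rewrite the options chunk", {
  rp <- tmp_report()
  expect_error(chunk_options(fig_width = 0), "positive")
  expect_error(chunk_options(fig_height = -1), "positive")
  expect_error(set_global_options(rp, list(eval = FALSE)), "chunk_options")
  set_global_options(rp, chunk_options(eval = FALSE, echo = FALSE))
  expect_match(file_text(rp$path), "eval=FALSE, echo=FALSE", fixed = TRUE)
  expect_false(inspect_report(rp)$global_options$eval)
})

test_that("the file always mirrors the in-memory serialization", {
  rp <- tmp_report()
  check_mirror <- function()
    expect_identical(provmark:::serialize_document(rp), file_text_nl(rp))
  file_text_nl <- function(doc)
    paste0(paste(readLines(doc$path, warn = FALSE), collapse = "\n"), "\n")
  add_title(rp, "Section", 2); check_mirror()
  add_text(rp, "Some *prose*."); check_mirror()
  open_chunk(rp); check_mirror()
  add_code(rp, "x <- 1"); check_mirror()
  close_chunk(rp); check_mirror()
  add_resource(rp, "db", "d", "l"); check_mirror()
})

test_that("failed operations leave the file byte-unchanged", {
  rp <- tmp_report()
  add_title(rp, "ok")
  before <- file_md5(rp$path)
  expect_error(add_title(rp, "x", 7))
  expect_error(add_title(rp, ""))
  expect_error(add_titled_text(rp, "x", 0, "body"))
  expect_error(close_chunk(rp))
  expect_error(add_code(rp, "x"))
  expect_identical(file_md5(rp$path), before)
})
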