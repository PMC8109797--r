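test_that("titles render as markdown headings at the requested level", {
  rp <- tmp_report()
  add_title(rp, "Loading Counts Data", 1)
  add_title(rp, "Recursive Tracing Function", 2)
  for (lvl in 3:6) add_title(rp, paste("level", lvl), lvl)
  lines <- readLines(rp$path, warn = FALSE)
  expect_true("# Loading Counts Data" %in% lines)
  expect_true("## Recursive Tracing Function" %in% lines)
  expect_true("###### level 6" %in% lines)
})

test_that("title levels outside 1..6 are rejected", {
  rp <- tmp_report()
  expect_error(add_title(rp, "x", 7), "between 1 and 6")
  expect_error(add_title(rp, "x", 0), "between 1 and 6")
  expect_error(add_title(rp, "x", 2.5), "between 1 and 6")
})

test_that("prose is written verbatim, markup preserved", {
  rp <- tmp_report()
  add_text(rp, "We now filter low counts.")
  add_text(rp, "Emphasis *stays* and `code spans` stay **exactly**.")
  lines <- readLines(rp$path, warn = FALSE)
  expect_true("We now filter low counts." %in% lines)
  expect_true("Emphasis *stays* and `code spans` stay **exactly**." %in% lines)
})

test_that("prose and titles are state errors inside an open chunk", {
  rp <- tmp_report()
  open_chunk(rp)
  expect_error(add_text(rp, "nope"), "add_code")
  expect_error(add_title(rp, "nope"), "open")
  expect_error(open_chunk(rp), "open")
  close_chunk(rp)
  expect_error(close_chunk(rp), "no code chunk is open")
  expect_error(add_code(rp, "x"), "no code chunk is open")
})

test_that("titled text equals title-then-text and fails atomically", {
  a <- tmp_report(); b <- tmp_report()
  add_titled_text(a, "Notes", 3, "comment")
  add_title(b, "Notes", 3); add_text(b, "comment")
  expect_identical(file_text(a$path), file_text(b$path))
  expect_match(file_text(a$path), "### Notes", fixed = TRUE)

  before <- file_md5(a$path)
  expect_error(add_titled_text(a, "x", 0, "body"))
  expect_identical(file_md5(a$path), before)
})

test_that("open_chunk emits loaders first and spells options per dialect", {
  rp <- tmp_report()
  open_chunk(rp, options = chunk_options(eval = FALSE),
             source_files = "script/importFunctions.R")
  add_code(rp, "head(geneCounts, 20)")
  close_chunk(rp)
  lines <- readLines(rp$path, warn = FALSE)
  open_line <- grep("^```\\{r chunk-1", lines, value = TRUE)
  expect_match(open_line, "eval=FALSE", fixed = TRUE)
  i <- grep("^```\\{r chunk-1", lines)
  expect_identical(lines[i + 1L], 'source("script/importFunctions.R")')
  expect_identical(lines[i + 2L], "head(geneCounts, 20)")
})

test_that("variable assignments use the dialect operator and show flag", {
  rp <- tmp_report()
  open_chunk(rp)
  add_variable_assignment(rp, "geneCounts", "as.matrix(importData(fn))",
                          show = FALSE)
  add_variable_assignment(rp, "tbl", "table(x)", show = TRUE)
  expect_error(add_variable_assignment(rp, "2x", "1"), "identifier")
  close_chunk(rp)
  lines <- readLines(rp$path, warn = FALSE)
  expect_true("geneCounts <- as.matrix(importData(fn))" %in% lines)
  expect_true("tbl <- table(x)" %in% lines)
  # show=TRUE adds a bare display line right after the assignment
  expect_identical(lines[which(lines == "tbl <- table(x)") + 1L], "tbl")
  expect_false("geneCounts" %in% lines)
})

test_that("include_source_files emits one loader per path, none for empty", {
  rp <- tmp_report()
  open_chunk(rp)
  include_source_files(rp, c("a.R", "b.R"))
  include_source_files(rp, character())
  close_chunk(rp)
  lines <- readLines(rp$path, warn = FALSE)
  expect_true(all(c('source("a.R")', 'source("b.R")') %in% lines))
  expect_identical(sum(grepl("^source\\(", lines)), 2L)
})

test_that("one-call chunks order heading, comment, fenced code", {
  rp <- tmp_report()
  add_complete_chunk(rp, code = list("a <- 1", "b <- a + 1"),
                     comment = "c", title = "Recursive Tracing Function",
                     level = 2)
  lines <- readLines(rp$path, warn = FALSE)
  i_title <- which(lines == "## Recursive Tracing Function")
  i_comment <- which(lines == "c")
  i_fence <- grep("^```\\{r chunk-1\\}", lines)
  expect_true(i_title < i_comment && i_comment < i_fence)
  expect_true(all(c("a <- 1", "b <- a + 1") %in%
                    lines[(i_fence + 1):(i_fence + 2)]))
})

test_that("auto labels count up and explicit labels must be unique", {
  rp <- tmp_report()
  add_complete_chunk(rp, "x <- 1")
  add_complete_chunk(rp, "y <- 2")
  lines <- readLines(rp$path, warn = FALSE)
  expect_true(any(grepl("^```\\{r chunk-1\\}", lines)))
  expect_true(any(grepl("^```\\{r chunk-2\\}", lines)))
  add_complete_chunk(rp, "z <- 3", label = "mine")
  expect_error(add_complete_chunk(rp, "w <- 4", label = "mine"),
               "already used")
  expect_error(add_complete_chunk(rp, "w <- 4", label = "global-options"),
               "already used")
})

test_that("open+close with no code equals a complete chunk with no code", {
  a <- tmp_report(); b <- tmp_report()
  open_chunk(a); close_chunk(a)
  add_complete_chunk(b, character())
  expect_identical(file_text(a$path), file_text(b$path))
})

test_that("step-by-step and one-call construction are byte-identical", {
  set.seed(421)
  for (i in 1:25) {
    tuple <- random_chunk_tuple()
    both <- build_both_ways(tuple)
    expect_identical(both$a, both$b, info = paste("tuple", i))
  }
})

test_that("headers carry only non-default options", {
  rp <- tmp_report()
  add_complete_chunk(rp, "x <- 1",
                     options = chunk_options(eval = TRUE, echo = TRUE))
  lines <- readLines(rp$path, warn = FALSE)
  # all-default chunk: header is dialect + label only
  expect_true(any(lines == "```{r chunk-1}"))
  set_global_options(rp, chunk_options(eval = FALSE))
  add_complete_chunk(rp, "y <- 2", options = chunk_options(eval = TRUE))
  lines <- readLines(rp$path, warn = FALSE)
  expect_true(any(lines == "```{r chunk-2, eval=TRUE}"))
})

test_that("fences stay balanced and the file grows monotonically", {
  rp <- tmp_report()
  len <- nchar(file_text(rp$path))
  set.seed(99)
  ops <- list(
    function() add_title(rp, paste("T", sample(1e6, 1)), sample(1:6, 1)),
    function() add_text(rp, paste("prose", sample(1e6, 1))),
    function() { open_chunk(rp); add_code(rp, "x <- 1"); close_chunk(rp) },
    function() add_complete_chunk(rp, "y <- 2 + 2")
  )
  for (i in 1:20) {
    ops[[sample(4, 1)]]()
    expect_identical(count_fences(rp$path) %% 2L, 0L)
    new_len <- nchar(file_text(rp$path))
    expect_gte(new_len, len)
    len <- new_len
  }
})
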