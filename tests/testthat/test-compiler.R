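test_that("parsing an emitted report reproduces it byte for byte", {
  rp <- tmp_report(title = "RNA-seq Analysis Report",
                   authors = "Dario Righelli")
  add_title(rp, "Loading Counts Data", 1)
  add_text(rp, "We now filter low counts.")
  add_complete_chunk(rp, c("x <- 1:10", "sum(x)"),
                     options = chunk_options(eval = FALSE, fig_width = 4),
                     comment = "A comment.", title = "Stage", level = 2)
  add_resource(rp, "GEO", "raw counts", "https://example/GSE0000")
  parsed <- parse_report(rp$path)
  expect_identical(provmark:::serialize_document(parsed), file_text_raw(rp))
  expect_identical(parsed$title, "RNA-seq Analysis Report")
  kinds <- vapply(parsed$elements, `[[`, character(1), "kind")
  expect_identical(kinds, c("title", "text", "title", "text", "chunk"))
  expect_identical(parsed$resources$source, "GEO")
  expect_identical(parsed$elements[[5]]$overrides$eval, FALSE)
  expect_identical(parsed$elements[[5]]$overrides$fig_width, 4)
})

test_that("randomized documents survive the parse/serialize round trip", {
  set.seed(1234)
  for (i in 1:10) {
    rp <- tmp_report()
    for (k in 1:sample(2:5, 1)) {
      tuple <- random_chunk_tuple()
      add_complete_chunk(rp, code = tuple$code, options = tuple$options,
                         source_files = tuple$source_files,
                         comment = tuple$comment, title = tuple$title,
                         level = tuple$level)
    }
    expect_identical(provmark:::serialize_document(parse_report(rp$path)),
                     file_text_raw(rp), info = paste("doc", i))
  }
})

test_that("malformed sources produce parse errors with line numbers", {
  d <- new_report_dir()
  p1 <- file.path(d, "nofm.Rmd")
  writeLines("# just a heading", p1)
  expect_error(parse_report(p1), "line 1")

  rp <- tmp_report()
  add_complete_chunk(rp, "x <- 1")
  lines <- readLines(rp$path, warn = FALSE)
  open_at <- grep("^```\\{r chunk-1\\}", lines)
  p2 <- file.path(d, "unclosed.Rmd")
  writeLines(lines[seq_len(open_at + 1L)], p2)  # drop the closing fence
  expect_error(parse_report(p2), paste("line", open_at))
  expect_error(parse_report(file.path(d, "missing.Rmd")), "no such file")
})

test_that("chunk execution captures output and threads state", {
  env <- new.env(parent = globalenv())
  r1 <- execute_chunk(c("x <- 40", 'print("ok")'), env, label = "a")
  expect_match(r1$stdout_text, "ok")
  expect_null(r1$error)
  r2 <- execute_chunk("x + 2", env, label = "b")
  expect_match(r2$stdout_text, "42", fixed = TRUE)
})

test_that("disabled evaluation runs nothing and touches nothing", {
  env <- new.env(parent = globalenv())
  res <- execute_chunk("x <- 99", env,
                       options = chunk_options(eval = FALSE))
  expect_identical(res$stdout_text, "")
  expect_length(res$figures, 0L)
  expect_false(exists("x", envir = env, inherits = FALSE))
})

test_that("a plotting chunk yields exactly one figure artifact", {
  env <- new.env(parent = globalenv())
  fig_dir <- tempfile("figs"); dir.create(fig_dir)
  res <- execute_chunk("plot(1:10)", env, label = "p", fig_dir = fig_dir)
  expect_length(res$figures, 1L)
  expect_true(file.exists(res$figures[1]))
})

test_that("session info reflects the live runtime and this package", {
  info <- collect_session_info()
  expect_identical(info$language_version, R.version.string)
  expect_true("provmark" %in% names(info$package_versions))
  expect_identical(unname(info$package_versions[["provmark"]]),
                   as.character(utils::packageVersion("provmark")))
  info2 <- collect_session_info()
  expect_identical(info$package_versions, info2$package_versions)
})

test_that("eval/echo/include combinations control visibility exactly", {
  for (ev in c(TRUE, FALSE)) for (ec in c(TRUE, FALSE))
    for (inc in c(TRUE, FALSE)) {
      rp <- tmp_report()
      add_complete_chunk(rp, 'print("MARKER_OUT")',
                         options = chunk_options(eval = ev, echo = ec,
                                                 include = inc))
      html <- file_text(compile_report(rp))
      code_shown <- grepl('print("MARKER_OUT")', html, fixed = TRUE)
      out_shown <- grepl('[1] "MARKER_OUT"', html, fixed = TRUE)
      info <- sprintf("eval=%s echo=%s include=%s", ev, ec, inc)
      expect_identical(code_shown, ec && inc, info = info)
      expect_identical(out_shown, ev && inc, info = info)
    }
})

test_that("an excluded chunk still executes for its side effects", {
  rp <- tmp_report()
  add_complete_chunk(rp, "hidden_val <- 7",
                     options = chunk_options(include = FALSE))
  add_complete_chunk(rp, "print(hidden_val * 6)")
  html <- file_text(compile_report(rp))
  expect_false(grepl("hidden_val &lt;- 7", html, fixed = TRUE))
  expect_true(grepl("[1] 42", html, fixed = TRUE))
})

test_that("warning and message flags gate their streams", {
  rp <- tmp_report()
  add_complete_chunk(rp, 'warning("W1"); message("M1")',
                     options = chunk_options(warning = FALSE,
                                             message = FALSE))
  add_complete_chunk(rp, 'warning("W2"); message("M2")')
  html <- file_text(compile_report(rp))
  expect_false(grepl('class="warning">Warning: W1', html, fixed = TRUE))
  expect_false(grepl('class="message">M1', html, fixed = TRUE))
  expect_true(grepl('class="warning">Warning: W2', html, fixed = TRUE))
  expect_true(grepl('class="message">M2', html, fixed = TRUE))
})

test_that("compiled output orders body, session info, references, resources", {
  d <- new_report_dir()
  write_bib(d)
  rp <- create_report(file.path(d, "r"), title = "Ordered",
                      bibliography = "refs.bib")
  add_title(rp, "First Section", 1)
  add_text(rp, "Cited by @smith2020 here.")
  add_complete_chunk(rp, 'print("body-output")')
  add_resource(rp, "GEO", "raw counts", "https://example/GSE0000")
  html <- file_text(compile_report(rp))

  pos <- c(body = regexpr("First Section", html, fixed = TRUE),
           output = regexpr("body-output", html, fixed = TRUE),
           session = regexpr("Session Information", html, fixed = TRUE),
           refs = regexpr("<h1>References</h1>", html, fixed = TRUE),
           resources = regexpr("Resources Availability", html, fixed = TRUE))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0))  # strict document order
  # exactly one session info section
  expect_identical(
    lengths(regmatches(html, gregexpr("Session Information", html))), 1L)
  # citation resolved and linked; resource row complete
  expect_match(html, 'href="#ref-smith2020"', fixed = TRUE)
  expect_match(html, "Smith, Ann", fixed = TRUE)
  expect_match(html, "<td>GEO</td><td>raw counts</td>", fixed = TRUE)
})

test_that("optional sections are omitted when their inputs are absent", {
  rp <- tmp_report()
  add_text(rp, "No citations, no resources.")
  html <- file_text(compile_report(rp))
  expect_false(grepl("<h1>References</h1>", html, fixed = TRUE))
  expect_false(grepl("Resources Availability", html, fixed = TRUE))
  expect_true(grepl("Session Information", html, fixed = TRUE))
})

test_that("citations without a findable bibliography are a compile error", {
  d <- new_report_dir()
  rp <- create_report(file.path(d, "r"), title = "t",
                      bibliography = "absent.bib")
  add_text(rp, "See @ghost2020.")
  expect_error(compile_report(rp), class = "provmark_compile_error")
})

test_that("unresolved keys render verbatim with a warning", {
  d <- new_report_dir()
  write_bib(d)
  rp <- create_report(file.path(d, "r"), title = "t",
                      bibliography = "refs.bib")
  add_text(rp, "Known @smith2020 and unknown @nokey9.")
  expect_warning(html <- file_text(compile_report(rp)), "nokey9")
  expect_match(html, "@nokey9", fixed = TRUE)
})

test_that("double compilation leaves the source unchanged and is stable", {
  rp <- tmp_report()
  add_complete_chunk(rp, c("set.seed(1)", "print(round(rnorm(3), 3))"))
  src_before <- file_md5(rp$path)
  h1 <- file_text(compile_report(rp))
  expect_identical(file_md5(rp$path), src_before)
  h2 <- file_text(compile_report(rp))
  expect_identical(file_md5(rp$path), src_before)
  strip_ts <- function(x) gsub("compiled: [^<]*", "compiled: X", x)
  expect_identical(strip_ts(h1), strip_ts(h2))
  expect_identical(
    lengths(regmatches(h2, gregexpr("Session Information", h2))), 1L)
})

test_that("halt policy names the failing chunk; continue renders it", {
  rp <- tmp_report()
  add_complete_chunk(rp, "good <- 1")
  add_complete_chunk(rp, 'stop("kaput")', label = "failing-stage")
  add_complete_chunk(rp, 'print("after")')
  err <- tryCatch(compile_report(rp), error = function(e) e)
  expect_s3_class(err, "provmark_compile_error")
  expect_identical(err$chunk_label, "failing-stage")
  expect_match(conditionMessage(err), "kaput")

  html <- file_text(compile_report(rp, on_error = "continue"))
  expect_match(html, "kaput", fixed = TRUE)
  expect_match(html, "after", fixed = TRUE)  # later chunks still ran
})

test_that("compiling an open-chunk document is a state error", {
  rp <- tmp_report()
  open_chunk(rp)
  expect_error(compile_report(rp), "open")
})

test_that("compile accepts a path and works from the file alone", {
  rp <- tmp_report()
  add_complete_chunk(rp, "print(6 * 7)")
  out <- compile_report(rp$path)
  expect_true(grepl("[1] 42", file_text(out), fixed = TRUE))
})
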