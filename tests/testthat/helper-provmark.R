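# shared fixtures: everything is generated in code, under tempdirs

new_report_dir <- function() {
  d <- tempfile("provmark-test-")
  dir.create(d)
  d
}

tmp_report <- function(..., title = "Test Report") {
  create_report(file.path(new_report_dir(), "report"), title = title, ...)
}

file_text <- function(path) {
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

# raw text with the trailing newline, for byte-identity comparisons
file_text_raw <- function(doc) {
  path <- if (is.character(doc)) doc else doc$path
  paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
}

file_md5 <- function(path) unname(tools::md5sum(path))

count_fences <- function(path) {
  sum(grepl("^```", readLines(path, warn = FALSE)))
}

# a small .bib fixture written on the fly
write_bib <- function(dir, keys = c("smith2020")) {
  path <- file.path(dir, "refs.bib")
  entries <- vapply(keys, function(k) paste0(
    "@article{", k, ",\n",
    "  author = {Smith, Ann and Jones, Bob},\n",
    "  title = {A study of ", k, "},\n",
    "  year = {2020},\n",
    "  journal = {Journal of Tests}\n}\n"), character(1))
  writeLines(entries, path)
  path
}

# randomized (code, options, comment, title) tuples for equivalence checks
random_chunk_tuple <- function() {
  opts_args <- list()
  for (f in c("eval", "echo", "include", "warning", "message", "cache"))
    if (runif(1) < 0.5) opts_args[[f]] <- runif(1) < 0.5
  if (runif(1) < 0.3) opts_args$fig_width <- sample(3:9, 1)
  if (runif(1) < 0.3) opts_args$fig_height <- sample(3:9, 1)
  n_stmt <- sample(1:4, 1)
  code <- replicate(n_stmt, sprintf("x%d <- %d + %d", sample(1:99, 1),
                                    sample(1:50, 1), sample(1:50, 1)))
  list(
    code = as.list(code),
    options = if (length(opts_args)) do.call(chunk_options, opts_args)
              else NULL,
    source_files = if (runif(1) < 0.3) "script/helpers.R" else NULL,
    comment = if (runif(1) < 0.6)
      paste("Randomized comment", sample(1:1e6, 1)) else NULL,
    title = if (runif(1) < 0.6)
      paste("Randomized title", sample(1:1e6, 1)) else NULL,
    level = sample(1:6, 1))
}

# build the same chunk step-by-step and in one call; return both file texts
build_both_ways <- function(tuple) {
  a <- tmp_report()
  if (!is.null(tuple$title)) add_title(a, tuple$title, tuple$level)
  if (!is.null(tuple$comment)) add_text(a, tuple$comment)
  open_chunk(a, options = tuple$options, source_files = tuple$source_files)
  for (stmt in tuple$code) add_code(a, stmt)
  close_chunk(a)

  b <- tmp_report()
  add_complete_chunk(b, code = tuple$code, options = tuple$options,
                     source_files = tuple$source_files,
                     comment = tuple$comment, title = tuple$title,
                     level = tuple$level)
  list(a = file_text(a$path), b = file_text(b$path))
}
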