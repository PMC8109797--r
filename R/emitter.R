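#' Insert a section title
#'
#' Reports support up to six levels of titles, rendered as markdown
#' headings.
#'
#' @param doc a `ReportDocument`.
#' @param text heading text (non-empty).
#' @param level heading level, 1 to 6.
#' @return the document, invisibly.
#' @examples
#' rp <- create_report(tempfile(), title = "t")
#' add_title(rp, "Loading Counts Data", 1)
#' @export
add_title <- function(doc, text, level = 1L) {
  check_doc(doc)
  check_no_open_chunk(doc, "add_title")
  validate_title(text, level, "add_title")
  doc$elements <- c(doc$elements,
                    list(list(kind = "title", level = as.integer(level),
                              text = text)))
  write_document(doc)
  invisible(doc)
}

validate_title <- function(text, level, op) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop(op, ": title text must be a non-empty string", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level != as.integer(level) || level < 1L || level > 6L)
    stop(op, ": title level must be an integer between 1 and 6", call. = FALSE)
  invisible(TRUE)
}

#' Append a prose paragraph
#'
#' The text is written verbatim (markdown markup is preserved, never
#' escaped) as a paragraph surrounded by blank lines. Inside an open code
#' chunk this is an error: use [add_code()] for code lines.
#'
#' @param doc a `ReportDocument`.
#' @param text paragraph text; may span several lines.
#' @return the document, invisibly.
#' @export
add_text <- function(doc, text) {
  check_doc(doc)
  check_no_open_chunk(doc, "add_text")
  if (!is.character(text) || length(text) < 1L)
    stop("add_text: 'text' must be character", call. = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (length(lines) == 0L) lines <- ""
  doc$elements <- c(doc$elements, list(list(kind = "text", text = lines)))
  write_document(doc)
  invisible(doc)
}

#' Append a title followed by a paragraph
#'
#' Equivalent to [add_title()] then [add_text()], but atomic: both
#' arguments are validated before anything is written, so a failure leaves
#' the file untouched.
#'
#' @inheritParams add_title
#' @param text paragraph text.
#' @return the document, invisibly.
#' @export
add_titled_text <- function(doc, title, level = 1L, text = "") {
  check_doc(doc)
  check_no_open_chunk(doc, "add_titled_text")
  validate_title(title, level, "add_titled_text")
  if (!is.character(text))
    stop("add_titled_text: 'text' must be character", call. = FALSE)
  add_title(doc, title, level)
  add_text(doc, text)
  invisible(doc)
}

#' Open a code chunk
#'
#' Starts the step-by-step chunk construction: an opening fence is written
#' (the file always keeps balanced fences; the chunk is completed in place
#' as code is added) and the document enters the chunk-open state, in
#' which only [add_code()], [add_variable_assignment()],
#' [include_source_files()] and [close_chunk()] are permitted.
#'
#' The fence header carries the dialect tag, the chunk label, and only the
#' options that differ from the document defaults.
#'
#' @param doc a `ReportDocument`.
#' @param options optional [chunk_options()] overriding document defaults.
#' @param source_files optional character vector of script paths; a loader
#'   statement per file is emitted as the first code lines. Paths are not
#'   checked for existence at emission time — a missing file surfaces as a
#'   chunk execution error at compile time.
#' @param label optional explicit chunk label (must be unique in the
#'   document); default an automatic `chunk-<n>`.
#' @return the document, invisibly.
#' @export
open_chunk <- function(doc, options = NULL, source_files = NULL,
                       label = NULL) {
  check_doc(doc)
  check_no_open_chunk(doc, "open_chunk")
  prep <- prepare_chunk(doc, options, label, "open_chunk")
  doc$open_label <- prep$label
  doc$open_overrides <- prep$overrides
  doc$open_lines <- source_loader_lines(source_files, doc$dialect)
  doc$chunk_open <- TRUE
  doc$labels_used <- c(doc$labels_used, prep$label)
  write_document(doc)
  invisible(doc)
}

prepare_chunk <- function(doc, options, label, op) {
  if (!is.null(options)) {
    validate_chunk_options(options, op)
    if (is.null(label)) label <- options$label
  }
  if (is.null(label)) {
    label <- paste0("chunk-", doc$chunk_counter + 1L)
  } else if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop(op, ": label must be a non-empty string", call. = FALSE)
  }
  if (label %in% doc$labels_used)
    stop(op, ": chunk label '", label, "' already used in this document",
         call. = FALSE)
  list(label = label,
       overrides = chunk_overrides(options, doc$global_options))
}

source_loader_lines <- function(source_files, dialect) {
  if (is.null(source_files) || length(source_files) == 0L) return(character())
  if (!is.character(source_files))
    stop("source_files must be a character vector of paths", call. = FALSE)
  vapply(source_files, function(p) {
    if (identical(dialect, "python"))
      sprintf("exec(open(%s).read())", format_literal(p, dialect))
    else
      sprintf("source(%s)", format_literal(p, dialect))
  }, character(1), USE.NAMES = FALSE)
}

#' Add code lines to the open chunk
#'
#' @param doc a `ReportDocument`.
#' @param code character; one string per statement, or a single string with
#'   embedded newlines. Appended inside the fence in order, never reflowed.
#' @return the document, invisibly.
#' @export
add_code <- function(doc, code) {
  check_doc(doc)
  check_open_chunk(doc, "add_code")
  if (!is.character(code))
    stop("add_code: 'code' must be character", call. = FALSE)
  lines <- unlist(strsplit(code, "\n", fixed = TRUE))
  doc$open_lines <- c(doc$open_lines, lines)
  write_document(doc)
  invisible(doc)
}

#' Record a variable assignment in the open chunk
#'
#' Emits one assignment statement in the chunk dialect; with `show = TRUE`
#' a second line displaying the bare variable follows, so the compiled
#' report prints the assigned value.
#'
#' @param doc a `ReportDocument`.
#' @param name target variable name (a valid identifier).
#' @param expression right-hand-side code, passed through verbatim.
#' @param show logical; also emit a display line. Default `FALSE`.
#' @return the document, invisibly.
#' @export
add_variable_assignment <- function(doc, name, expression, show = FALSE) {
  check_doc(doc)
  check_open_chunk(doc, "add_variable_assignment")
  check_identifier(name, doc$dialect, "add_variable_assignment")
  if (!is.character(expression) || length(expression) != 1L)
    stop("add_variable_assignment: 'expression' must be a single string",
         call. = FALSE)
  op <- if (identical(doc$dialect, "r")) " <- " else " = "
  stmt <- paste0(name, op, expression)
  lines <- unlist(strsplit(stmt, "\n", fixed = TRUE))
  if (isTRUE(show)) lines <- c(lines, name)
  doc$open_lines <- c(doc$open_lines, lines)
  write_document(doc)
  invisible(doc)
}

#' Emit loader statements for source files into the open chunk
#'
#' @param doc a `ReportDocument`.
#' @param paths character vector of script paths; one loader statement per
#'   path at the current position. An empty vector emits nothing.
#' @return the document, invisibly.
#' @export
include_source_files <- function(doc, paths) {
  check_doc(doc)
  check_open_chunk(doc, "include_source_files")
  lines <- source_loader_lines(paths, doc$dialect)
  if (length(lines)) {
    doc$open_lines <- c(doc$open_lines, lines)
    write_document(doc)
  }
  invisible(doc)
}

#' Close the open code chunk
#'
#' @param doc a `ReportDocument`.
#' @return the document, invisibly.
#' @export
close_chunk <- function(doc) {
  check_doc(doc)
  check_open_chunk(doc, "close_chunk")
  doc$elements <- c(doc$elements,
                    list(list(kind = "chunk", label = doc$open_label,
                              overrides = doc$open_overrides,
                              lines = doc$open_lines)))
  doc$chunk_open <- FALSE
  doc$open_label <- character()
  doc$open_overrides <- list()
  doc$open_lines <- character()
  doc$chunk_counter <- doc$chunk_counter + 1L
  write_document(doc)
  invisible(doc)
}

#' Append a complete code chunk in one call
#'
#' The one-call counterpart of the open/add/close sequence: emits an
#' optional heading, an optional comment paragraph, and the fenced chunk,
#' atomically (a validation failure writes nothing). For identical code,
#' options and source files the result is byte-identical to step-by-step
#' construction.
#'
#' @param doc a `ReportDocument`.
#' @param code character; a single string or a vector/list of statements,
#'   joined one statement per line.
#' @param options optional [chunk_options()].
#' @param source_files optional script paths loaded at the top of the chunk.
#' @param comment optional prose paragraph placed before the chunk.
#' @param title optional heading placed before the comment.
#' @param level heading level for `title`, default 2.
#' @param label optional explicit chunk label.
#' @return the document, invisibly.
#' @examples
#' rp <- create_report(tempfile(), title = "t")
#' add_complete_chunk(rp, "head(geneCounts, 20)",
#'                    options = chunk_options(eval = FALSE),
#'                    title = "Loading Counts Data", level = 2,
#'                    comment = "Raw counts are loaded from the package.")
#' @export
add_complete_chunk <- function(doc, code = character(), options = NULL,
                               source_files = NULL, comment = NULL,
                               title = NULL, level = 2L, label = NULL) {
  check_doc(doc)
  check_no_open_chunk(doc, "add_complete_chunk")
  if (!is.null(title)) validate_title(title, level, "add_complete_chunk")
  if (!is.null(comment) && !is.character(comment))
    stop("add_complete_chunk: 'comment' must be character", call. = FALSE)
  if (is.list(code)) {
    ok <- vapply(code, function(x) is.character(x) ||
                   inherits(x, "serialized_code"), logical(1))
    if (!all(ok))
      stop("add_complete_chunk: 'code' list elements must be character",
           call. = FALSE)
    code <- vapply(code, function(x)
      paste(as.character(x), collapse = "\n"), character(1))
  }
  if (inherits(code, "serialized_code")) code <- as.character(code)
  if (!is.character(code))
    stop("add_complete_chunk: 'code' must be character", call. = FALSE)
  prep <- prepare_chunk(doc, options, label, "add_complete_chunk")
  loader <- source_loader_lines(source_files, doc$dialect)
  body <- unlist(strsplit(code, "\n", fixed = TRUE))

  new_elements <- list()
  if (!is.null(title))
    new_elements <- c(new_elements,
                      list(list(kind = "title", level = as.integer(level),
                                text = title)))
  if (!is.null(comment)) {
    clines <- unlist(strsplit(paste(comment, collapse = "\n"), "\n",
                              fixed = TRUE))
    if (length(clines) == 0L) clines <- ""
    new_elements <- c(new_elements, list(list(kind = "text", text = clines)))
  }
  new_elements <- c(new_elements,
                    list(list(kind = "chunk", label = prep$label,
                              overrides = prep$overrides,
                              lines = c(loader, body))))
  doc$elements <- c(doc$elements, new_elements)
  doc$labels_used <- c(doc$labels_used, prep$label)
  doc$chunk_counter <- doc$chunk_counter + 1L
  write_document(doc)
  invisible(doc)
}
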