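#' Parse a report source file back into a document
#'
#' Reads a markdown file in the dialect this package emits — YAML front
#' matter, a global-options chunk, then headings, paragraphs and fenced
#' code chunks — and reconstructs the `ReportDocument`. Re-serializing the
#' returned document reproduces the input byte for byte, which is what
#' makes compilation, inspection and further appending of a previously
#' written report safe.
#'
#' @param path path to the report source.
#' @return a `ReportDocument` with no open chunk.
#' @export
parse_report <- function(path) {
  if (!file.exists(path))
    stop("parse_report: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || lines[1L] != "---")
    stop("parse error at line 1: report must begin with '---' front matter",
         call. = FALSE)
  fm_end <- which(lines == "---")[-1L]
  if (length(fm_end) == 0L)
    stop("parse error at line 1: unterminated front matter (no closing ---)",
         call. = FALSE)
  fm_end <- fm_end[1L]
  meta <- tryCatch(
    yaml::yaml.load(paste(lines[2:(fm_end - 1L)], collapse = "\n")),
    error = function(e)
      stop("parse error at line 2: malformed front matter: ",
           conditionMessage(e), call. = FALSE))
  if (is.null(meta$title))
    stop("parse error at line 2: front matter lacks a title", call. = FALSE)

  authors <- list()
  if (!is.null(meta$author)) {
    if (is.character(meta$author)) authors <- as_author_list(meta$author)
    else authors <- lapply(meta$author, function(a) do.call(author, a))
  }
  resources <- empty_resources()
  if (!is.null(meta$resources)) {
    for (r in meta$resources)
      resources <- rbind(resources, data.frame(
        source = r$source %||% "", description = r$description %||% "",
        locator = r$locator %||% "", stringsAsFactors = FALSE))
  }

  body <- parse_body(lines, fm_end + 1L)
  if (is.null(body$global_options))
    stop("parse error at line ", fm_end + 1L,
         ": missing global-options chunk after front matter", call. = FALSE)

  chunk_labels <- vapply(Filter(function(e) e$kind == "chunk", body$elements),
                         function(e) e$label, character(1))
  ReportDocument$new(
    path = path, title = meta$title, authors = authors,
    date = meta$date %||% format(Sys.Date(), "%Y-%m-%d"),
    document_type = meta$output %||% "html",
    dialect = meta$dialect %||% "r",
    bibliography = if (is.null(meta$bibliography)) character()
                   else meta$bibliography,
    global_options = body$global_options,
    resources = resources, elements = body$elements,
    chunk_open = FALSE, open_label = character(), open_overrides = list(),
    open_lines = character(), chunk_counter = length(chunk_labels),
    labels_used = c("global-options", chunk_labels))
}

is_fence_open <- function(line) grepl("^```\\{.*\\}\\s*$", line)
is_fence_close <- function(line) grepl("^```\\s*$", line)

parse_body <- function(lines, from) {
  elements <- list()
  global_options <- NULL
  i <- from
  n <- length(lines)
  text_buf <- character()
  flush_text <- function() {
    if (length(text_buf)) {
      elements[[length(elements) + 1L]] <<- list(kind = "text",
                                                 text = text_buf)
      text_buf <<- character()
    }
  }
  while (i <= n) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      flush_text()
      i <- i + 1L
      next
    }
    if (is_fence_open(line)) {
      flush_text()
      hdr <- parse_chunk_header(line, i)
      j <- i + 1L
      while (j <= n && !is_fence_close(lines[j])) {
        if (is_fence_open(lines[j]))
          stop("parse error at line ", j, ": nested code fence (chunk ",
               "opened at line ", i, " is unclosed)", call. = FALSE)
        j <- j + 1L
      }
      if (j > n)
        stop("parse error at line ", i, ": unclosed code fence", call. = FALSE)
      body <- if (j > i + 1L) lines[(i + 1L):(j - 1L)] else character()
      if (identical(hdr$label, "global-options") && is.null(global_options)) {
        opts <- chunk_options()
        for (f in names(hdr$overrides)) opts[[f]] <- hdr$overrides[[f]]
        global_options <- unclass_options(opts)
      } else {
        if (is.null(hdr$label))
          stop("parse error at line ", i, ": chunk without a label",
               call. = FALSE)
        elements[[length(elements) + 1L]] <-
          list(kind = "chunk", label = hdr$label,
               overrides = hdr$overrides, lines = body)
      }
      i <- j + 1L
      next
    }
    m <- regmatches(line, regexec("^(#{1,6}) (.+)$", line))[[1]]
    if (length(m) == 3L) {
      flush_text()
      elements[[length(elements) + 1L]] <-
        list(kind = "title", level = nchar(m[2]), text = m[3])
      i <- i + 1L
      next
    }
    text_buf <- c(text_buf, line)
    i <- i + 1L
  }
  flush_text()
  list(elements = elements, global_options = global_options)
}

# --- execution --------------------------------------------------------------

#' Execute one code chunk with output capture
#'
#' Runs chunk code in the given environment — the single environment a
#' compile run threads through every chunk, so bindings persist — and
#' captures printed output, warnings, messages, figures and errors. When
#' the chunk's `eval` option is off nothing runs and all capture fields
#' are empty.
#'
#' @param code character vector of code lines (or a single string).
#' @param env execution environment shared across the compile run.
#' @param options effective [chunk_options()] for the chunk.
#' @param label chunk label used in diagnostics.
#' @param fig_dir directory where figure files are written.
#' @return a list of class `provmark_execution` with `chunk_label`,
#'   `stdout_text` (all textual output), `value_displays` (the individual
#'   captured text items, in order), `figures` (PNG paths), `error`
#'   (`NULL`, or a list with `message` and `location`), and `outputs`, the
#'   ordered stream of captured items used by the renderer.
#' @export
execute_chunk <- function(code, env, options = chunk_options(),
                          label = "chunk", fig_dir = tempdir()) {
  empty <- list(chunk_label = label, stdout_text = "",
                value_displays = list(), figures = character(),
                error = NULL, outputs = list())
  class(empty) <- "provmark_execution"
  if (!isTRUE(options$eval)) return(empty)
  src <- paste(code, collapse = "\n")
  if (!nzchar(trimws(src))) return(empty)

  captured <- evaluate::evaluate(src, envir = env, new_device = TRUE,
                                 stop_on_error = 1L)
  res <- empty
  fig_i <- 0L
  fw <- options$fig_width %||% 7
  fh <- options$fig_height %||% 5
  for (item in captured) {
    if (inherits(item, "source")) next
    if (is.character(item)) {
      res$stdout_text <- paste0(res$stdout_text, item)
      res$value_displays <- c(res$value_displays, list(item))
      res$outputs <- c(res$outputs, list(list(type = "text",
                                              content = item)))
    } else if (inherits(item, "recordedplot")) {
      fig_i <- fig_i + 1L
      fig_path <- file.path(fig_dir, sprintf("%s-%d.png", label, fig_i))
      grDevices::png(fig_path, width = fw, height = fh, units = "in",
                     res = 96)
      tryCatch(grDevices::replayPlot(item),
               finally = grDevices::dev.off())
      res$figures <- c(res$figures, fig_path)
      res$outputs <- c(res$outputs, list(list(type = "figure",
                                              content = fig_path)))
    } else if (inherits(item, "warning")) {
      res$outputs <- c(res$outputs,
                       list(list(type = "warning",
                                 content = conditionMessage(item))))
    } else if (inherits(item, "message")) {
      res$outputs <- c(res$outputs,
                       list(list(type = "message",
                                 content = conditionMessage(item))))
    } else if (inherits(item, "error")) {
      res$error <- list(message = conditionMessage(item), location = label)
      res$outputs <- c(res$outputs,
                       list(list(type = "error",
                                 content = conditionMessage(item))))
    }
  }
  res
}

#' Capture the compile-time session information
#'
#' @return a list of class `provmark_session_info` with `language_version`
#'   (the interpreter's own version string), `platform`, `package_versions`
#'   (named character vector of loaded package versions, always including
#'   this package), and an ISO `timestamp`.
#' @export
collect_session_info <- function() {
  pkgs <- sort(setdiff(loadedNamespaces(), "base"))
  versions <- vapply(pkgs, function(p)
    as.character(utils::packageVersion(p)), character(1))
  versions <- c(versions, base = paste(R.version$major, R.version$minor,
                                       sep = "."))
  versions <- versions[order(names(versions))]
  structure(list(language_version = R.version.string,
                 platform = R.version$platform,
                 package_versions = versions,
                 timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
            class = "provmark_session_info")
}

#' @export
print.provmark_session_info <- function(x, ...) {
  cat(x$language_version, "\n", x$platform, "\n",
      length(x$package_versions), " packages loaded\n", sep = "")
  invisible(x)
}

# --- compilation ------------------------------------------------------------

#' Compile a report to its final rendered form
#'
#' Parses the report source from disk, executes its chunks in document
#' order within one fresh shared environment (working directory set to the
#' report's directory), and renders standalone HTML containing, in order:
#' the title block; every body element, with code shown iff `echo` and
#' `include`, and captured output and figures shown iff `eval` and
#' `include`; exactly one session-information section; a references
#' section iff a bibliography was set and at least one citation key
#' (`@key`) appears in the prose; and a "Resources Availability" table iff
#' resources were registered. The source file is never modified — in
#' particular, session information lives only in the rendered output, so
#' recompiling can never duplicate content.
#'
#' @param doc a `ReportDocument`, or the path of a report source file.
#' @param output_format `"html"` (default) or `"pdf"`; PDF delegates to an
#'   external `pandoc` converter when one is on the PATH.
#' @param on_error `"halt"` (default) aborts compilation at the first
#'   failing chunk with an error condition of class
#'   `provmark_compile_error` carrying the chunk label; `"continue"`
#'   renders the error message in place and keeps going.
#' @param output_file optional output path; default: source path with its
#'   extension replaced.
#' @param self_contained logical; embed figures as base64 data URIs
#'   (default). Otherwise PNGs are written beside the output under
#'   `<name>_files/`.
#' @return the output file path, invisibly.
#' @examples
#' rp <- create_report(tempfile(), title = "Demo")
#' add_complete_chunk(rp, 'print("ok")', title = "A step")
#' html <- compile_report(rp)
#' @export
compile_report <- function(doc, output_format = NULL,
                           on_error = c("halt", "continue"),
                           output_file = NULL, self_contained = TRUE) {
  on_error <- match.arg(on_error)
  if (is.character(doc)) doc <- parse_report(doc)
  check_doc(doc)
  check_no_open_chunk(doc, "compile_report")
  # compile what is on disk; the in-memory handle mirrors it by contract
  src <- parse_report(doc$path)
  fmt <- output_format %||% src$document_type
  if (!fmt %in% c("html", "pdf"))
    stop("compile_report: unsupported output format '", fmt, "'",
         call. = FALSE)

  report_dir <- dirname(normalizePath(src$path))
  stem <- tools::file_path_sans_ext(basename(src$path))
  out_html <- output_file %||% file.path(report_dir, paste0(stem, ".html"))
  if (identical(fmt, "pdf"))
    out_html <- file.path(report_dir, paste0(stem, ".html"))

  fig_dir <- if (self_contained) {
    file.path(tempfile("provmark-figs"))
  } else {
    file.path(report_dir, paste0(stem, "_files"))
  }
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

  # citations
  prose <- unlist(lapply(Filter(function(e) e$kind == "text", src$elements),
                         function(e) e$text))
  keys <- find_citation_keys(prose)
  bib <- list()
  if (length(src$bibliography) && length(keys)) {
    bib_path <- src$bibliography
    if (!file.exists(bib_path))
      bib_path <- file.path(report_dir, src$bibliography)
    if (!file.exists(bib_path))
      stop(errorCondition(
        paste0("compile_report: citations present but bibliography file '",
               src$bibliography, "' not found"),
        class = c("provmark_compile_error", "error")))
    bib <- read_bibtex(bib_path)
    unresolved <- setdiff(keys, names(bib))
    for (k in unresolved)
      warning("compile_report: unresolved citation key '@", k,
              "' rendered verbatim", call. = FALSE)
    keys <- intersect(keys, names(bib))
  } else {
    keys <- character()
  }

  env <- new.env(parent = globalenv())
  old_wd <- setwd(report_dir)
  on.exit(setwd(old_wd), add = TRUE)

  body_html <- character()
  for (el in src$elements) {
    if (el$kind == "title") {
      body_html <- c(body_html, sprintf("<h%d>%s</h%d>", el$level,
                                        html_escape(el$text), el$level))
    } else if (el$kind == "text") {
      md <- paste(el$text, collapse = "\n")
      md <- link_citations(md, keys)
      body_html <- c(body_html, commonmark::markdown_html(md))
    } else {
      opts <- effective_options(src$global_options, el$overrides)
      res <- execute_chunk(el$lines, env, options = opts, label = el$label,
                           fig_dir = fig_dir)
      if (!is.null(res$error) && on_error == "halt") {
        setwd(old_wd)
        stop(errorCondition(
          paste0("compile_report: error in chunk '", el$label, "': ",
                 res$error$message),
          class = c("provmark_compile_error", "error"),
          chunk_label = el$label))
      }
      body_html <- c(body_html,
                     render_chunk_html(el, opts, res, self_contained,
                                       report_dir))
    }
  }
  setwd(old_wd)

  info <- collect_session_info()
  tail_html <- c(render_session_info_html(info),
                 render_references_html(bib, keys),
                 render_resources_html(src$resources))

  html <- assemble_html(src, c(body_html, tail_html))
  con <- file(out_html, open = "wb")
  writeLines(enc2utf8(html), con, sep = "", useBytes = TRUE)
  close(con)

  if (identical(fmt, "pdf")) {
    pandoc <- Sys.which("pandoc")
    out_pdf <- output_file %||% file.path(report_dir, paste0(stem, ".pdf"))
    if (!nzchar(pandoc))
      stop("compile_report: pdf output needs an external 'pandoc' ",
           "converter on the PATH; the HTML rendering was written to ",
           out_html, call. = FALSE)
    status <- system2(pandoc, c(shQuote(out_html), "-o", shQuote(out_pdf)))
    if (status != 0L)
      stop("compile_report: pdf conversion failed (exit ", status, ")",
           call. = FALSE)
    return(invisible(out_pdf))
  }
  invisible(out_html)
}

# --- rendering helpers ------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

find_citation_keys <- function(lines) {
  if (!length(lines)) return(character())
  m <- gregexpr("(?<![A-Za-z0-9_@.])@([A-Za-z][A-Za-z0-9_:-]*[A-Za-z0-9])",
                paste(lines, collapse = "\n"), perl = TRUE)
  keys <- unlist(regmatches(paste(lines, collapse = "\n"), m))
  unique(sub("^@", "", keys))
}

link_citations <- function(md, resolved_keys) {
  for (k in resolved_keys) {
    md <- gsub(paste0("(?<![A-Za-z0-9_@.])@", k, "(?![A-Za-z0-9_:-])"),
               sprintf("[%s](#ref-%s)", k, k), md, perl = TRUE)
  }
  md
}

render_chunk_html <- function(el, opts, res, self_contained, report_dir) {
  if (!isTRUE(opts$include)) return(character())
  out <- sprintf('<div class="chunk" id="chunk-%s">', html_escape(el$label))
  if (isTRUE(opts$echo))
    out <- c(out, paste0('<pre class="code"><code>',
                         paste(html_escape(el$lines), collapse = "\n"),
                         "</code></pre>"))
  if (isTRUE(opts$eval)) {
    for (item in res$outputs) {
      if (item$type == "figure") {
        srcattr <- if (self_contained)
          base64enc::dataURI(file = item$content, mime = "image/png")
        else
          file.path(basename(dirname(item$content)), basename(item$content))
        out <- c(out, sprintf('<p><img src="%s" alt="%s"/></p>', srcattr,
                              html_escape(basename(item$content))))
      } else if (item$type == "warning") {
        if (isTRUE(opts$warning))
          out <- c(out, paste0('<pre class="warning">Warning: ',
                               html_escape(item$content), "</pre>"))
      } else if (item$type == "message") {
        if (isTRUE(opts$message))
          out <- c(out, paste0('<pre class="message">',
                               html_escape(item$content), "</pre>"))
      } else if (item$type == "error") {
        out <- c(out, paste0('<pre class="error">Error: ',
                             html_escape(item$content), "</pre>"))
      } else {
        out <- c(out, paste0('<pre class="output">',
                             html_escape(item$content), "</pre>"))
      }
    }
  }
  c(out, "</div>")
}

render_session_info_html <- function(info) {
  pkgs <- paste(sprintf("%s %s", names(info$package_versions),
                        info$package_versions), collapse = "\n")
  c('<section id="session-info">',
    "<h1>Session Information</h1>",
    paste0("<pre>", html_escape(paste(
      info$language_version,
      info$platform,
      paste0("compiled: ", info$timestamp),
      "", "Loaded packages:", pkgs, sep = "\n")), "</pre>"),
    "</section>")
}

render_references_html <- function(bib, keys) {
  if (!length(keys)) return(character())
  keys <- sort(keys)
  items <- vapply(keys, function(k) {
    entry_md <- format_bib_entry(bib[[k]])
    inner <- commonmark::markdown_html(entry_md)
    inner <- sub("^<p>", "", sub("</p>\\s*$", "", inner))
    sprintf('<p id="ref-%s">[%s] %s</p>', k, html_escape(k), inner)
  }, character(1))
  c('<section id="references">', "<h1>References</h1>", items, "</section>")
}

render_resources_html <- function(resources) {
  if (!nrow(resources)) return(character())
  rows <- vapply(seq_len(nrow(resources)), function(i) {
    loc <- resources$locator[i]
    loc_html <- if (grepl("^https?://", loc))
      sprintf('<a href="%s">%s</a>', loc, html_escape(loc))
    else html_escape(loc)
    sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
            html_escape(resources$source[i]),
            html_escape(resources$description[i]), loc_html)
  }, character(1))
  c('<section id="resources-availability">',
    "<h1>Resources Availability</h1>",
    "<table>",
    "<tr><th>Source</th><th>Description</th><th>Locator</th></tr>",
    rows, "</table>", "</section>")
}

assemble_html <- function(doc, body_html) {
  authors_html <- vapply(doc$authors, function(a) {
    bits <- html_escape(a$name)
    if (!is.null(a$email))
      bits <- paste0(bits, sprintf(' &lt;<a href="mailto:%s">%s</a>&gt;',
                                   a$email, html_escape(a$email)))
    if (!is.null(a$orcid))
      bits <- paste0(bits, sprintf(' <a href="https://orcid.org/%s">ORCID</a>',
                                   a$orcid))
    if (!is.null(a$affiliation)) {
      aff <- html_escape(a$affiliation)
      if (!is.null(a$affiliation_url))
        aff <- sprintf('<a href="%s">%s</a>', a$affiliation_url, aff)
      bits <- paste0(bits, " &mdash; ", aff)
    }
    if (!is.null(a$url))
      bits <- paste0(bits, sprintf(' (<a href="%s">site</a>)', a$url))
    paste0('<p class="author">', bits, "</p>")
  }, character(1))
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(doc$title), "</title>\n",
    "<style>\n", .provmark_css, "</style>\n</head>\n<body>\n",
    '<header>\n<h1 class="title">', html_escape(doc$title), "</h1>\n",
    paste(authors_html, collapse = "\n"),
    if (length(authors_html)) "\n" else "",
    '<p class="date">', html_escape(doc$date), "</p>\n</header>\n",
    paste(body_html, collapse = "\n"),
    "\n</body>\n</html>\n")
}

.provmark_css <- paste(
  "body { max-width: 50em; margin: 2em auto; padding: 0 1em;",
  "  font-family: sans-serif; line-height: 1.45; }",
  "pre { background: #f6f6f6; padding: .6em; overflow-x: auto; }",
  "pre.warning { background: #fff3e0; }",
  "pre.message { background: #eef4fb; }",
  "pre.error { background: #fdecea; }",
  "img { max-width: 100%; }",
  "table { border-collapse: collapse; }",
  "td, th { border: 1px solid #999; padding: .3em .6em; }",
  "h1.title { margin-bottom: .2em; }",
  "p.author, p.date { margin: .1em 0; color: #444; }",
  "", sep = "\n")
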