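#' Describe a report author
#'
#' Authors appear in the YAML front matter of the report source and in the
#' compiled document's title block. Only the name is mandatory; the other
#' fields mirror what a journal byline carries.
#'
#' @param name author name (non-empty).
#' @param email,affiliation,affiliation_url,orcid,url optional strings.
#' @return an object of class `report_author`.
#' @examples
#' author("Ada Lovelace", orcid = "0000-0000-0000-0000")
#' @export
author <- function(name, email = NULL, affiliation = NULL,
                   affiliation_url = NULL, orcid = NULL, url = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("author: 'name' is mandatory and must be a non-empty string",
         call. = FALSE)
  check_opt <- function(v, what) {
    if (!is.null(v) && (!is.character(v) || length(v) != 1L))
      stop("author: '", what, "' must be a single string or NULL",
           call. = FALSE)
    v
  }
  a <- list(name = name,
            email = check_opt(email, "email"),
            affiliation = check_opt(affiliation, "affiliation"),
            affiliation_url = check_opt(affiliation_url, "affiliation_url"),
            orcid = check_opt(orcid, "orcid"),
            url = check_opt(url, "url"))
  a <- a[!vapply(a, is.null, logical(1))]
  class(a) <- "report_author"
  a
}

.author_fields <- c("name", "email", "affiliation", "affiliation_url",
                    "orcid", "url")

as_author_list <- function(authors) {
  if (is.null(authors)) return(list())
  if (inherits(authors, "report_author")) return(list(authors))
  if (is.character(authors)) return(lapply(authors, author))
  if (is.list(authors)) {
    return(lapply(authors, function(a) {
      if (inherits(a, "report_author")) a
      else if (is.character(a) && length(a) == 1L) author(a)
      else if (is.list(a) && !is.null(a$name)) do.call(author, a)
      else stop("authors must be author() objects or character names",
                call. = FALSE)
    }))
  }
  stop("authors must be author() objects or character names", call. = FALSE)
}

# --- document class ---------------------------------------------------------

#' @importFrom methods new setRefClass
ReportDocument <- methods::setRefClass(
  "ReportDocument",
  fields = list(
    path = "character",          # on-disk markdown file (with extension)
    title = "character",
    authors = "list",
    date = "character",          # ISO creation date, kept for stable bytes
    document_type = "character", # html | pdf
    dialect = "character",       # chunk language tag, e.g. "r"
    bibliography = "character",  # length 0 when absent
    global_options = "list",     # full chunk_options
    resources = "data.frame",    # source / description / locator
    elements = "list",
    chunk_open = "logical",
    open_label = "character",
    open_overrides = "list",
    open_lines = "character",
    chunk_counter = "integer",
    labels_used = "character"
  ),
  methods = list(
    show = function() {
      cat("<provmark report> ", path, "\n", sep = "")
      cat("  title:    ", title, "\n", sep = "")
      cat("  authors:  ", length(authors), "\n", sep = "")
      cat("  elements: ", length(elements),
          if (chunk_open) "  (one chunk open)" else "", "\n", sep = "")
      cat("  chunks:   ", chunk_counter, "\n", sep = "")
    }
  )
)

empty_resources <- function() {
  data.frame(source = character(), description = character(),
             locator = character(), stringsAsFactors = FALSE)
}

# --- serialization ----------------------------------------------------------

yaml_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

front_matter_lines <- function(doc) {
  out <- c("---", paste0("title: ", yaml_quote(doc$title)))
  if (length(doc$authors)) {
    out <- c(out, "author:")
    for (a in doc$authors) {
      first <- TRUE
      for (f in .author_fields) {
        if (is.null(a[[f]])) next
        prefix <- if (first) "- " else "  "
        out <- c(out, paste0(prefix, f, ": ", yaml_quote(a[[f]])))
        first <- FALSE
      }
    }
  }
  out <- c(out, paste0("date: ", yaml_quote(doc$date)),
           paste0("output: ", yaml_quote(doc$document_type)),
           paste0("dialect: ", yaml_quote(doc$dialect)))
  if (length(doc$bibliography))
    out <- c(out, paste0("bibliography: ", yaml_quote(doc$bibliography)))
  if (nrow(doc$resources)) {
    out <- c(out, "resources:")
    for (i in seq_len(nrow(doc$resources))) {
      out <- c(out,
        paste0("- source: ", yaml_quote(doc$resources$source[i])),
        paste0("  description: ", yaml_quote(doc$resources$description[i])),
        paste0("  locator: ", yaml_quote(doc$resources$locator[i])))
    }
  }
  c(out, "---")
}

global_options_lines <- function(doc) {
  ov <- doc$global_options[.opt_flags]
  for (f in c("fig_width", "fig_height"))
    if (!is.null(doc$global_options[[f]])) ov[[f]] <- doc$global_options[[f]]
  c(render_chunk_header("global-options", ov, doc$dialect), "```")
}

element_lines <- function(el, doc) {
  switch(el$kind,
    title = paste0(strrep("#", el$level), " ", el$text),
    text  = el$text,
    chunk = c(render_chunk_header(el$label, el$overrides, doc$dialect),
              el$lines, "```"),
    stop("internal: unknown element kind ", el$kind)
  )
}

serialize_document <- function(doc) {
  blocks <- list(front_matter_lines(doc), global_options_lines(doc))
  for (el in doc$elements) blocks <- c(blocks, list(element_lines(el, doc)))
  if (doc$chunk_open) {
    open_el <- list(kind = "chunk", label = doc$open_label,
                    overrides = doc$open_overrides, lines = doc$open_lines)
    blocks <- c(blocks, list(element_lines(open_el, doc)))
  }
  lines <- unlist(lapply(blocks, function(b) c(b, "")))
  paste0(paste(lines, collapse = "\n"), "\n")
}

write_document <- function(doc) {
  con <- file(doc$path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(serialize_document(doc)), con, sep = "", useBytes = TRUE)
  invisible(doc)
}

# --- public operations ------------------------------------------------------

#' Create a new analysis report
#'
#' Creates the on-disk markdown source for a report — YAML front matter
#' (title, authors, creation date) followed by a chunk declaring the
#' document-wide execution options — and returns the document handle that
#' all other operations mutate in place. Parent directories are created
#' recursively; a markdown extension is appended when the path carries
#' none (`.Rmd` for the default R chunk dialect, `.md` otherwise).
#'
#' @param path report file path, with or without a markdown extension.
#' @param title report title (mandatory, non-empty).
#' @param authors a character vector of names, an [author()] object, or a
#'   list of them. May be empty.
#' @param bibliography optional path to a BibTeX `.bib` file, resolved
#'   relative to the report directory at compile time.
#' @param global_options optional [chunk_options()] used as document
#'   defaults for every chunk.
#' @param document_type output format, `"html"` (default) or `"pdf"`.
#' @param dialect language tag written in chunk headers; default `"r"`.
#' @param overwrite logical; replace an existing report file. Default
#'   `FALSE`: creating over an existing file is an error so an audit trail
#'   cannot be clobbered accidentally.
#' @return a `ReportDocument` handle (reference semantics).
#' @examples
#' rp <- create_report(file.path(tempdir(), "rnaseq_report"),
#'                     title = "RNA-seq Analysis Report",
#'                     authors = "Dario Righelli", overwrite = TRUE)
#' add_title(rp, "Loading Counts Data")
#' @seealso [add_title()], [add_complete_chunk()], [compile_report()]
#' @export
create_report <- function(path, title, authors = list(), bibliography = NULL,
                          global_options = NULL, document_type = "html",
                          dialect = "r", overwrite = FALSE) {
  if (missing(path) || !is.character(path) || length(path) != 1L ||
      !nzchar(trimws(path)) || missing(title) || !is.character(title) ||
      length(title) != 1L || !nzchar(trimws(title)))
    stop("create_report: filenamepath and title are mandatory parameters",
         call. = FALSE)
  if (!document_type %in% c("html", "pdf"))
    stop("create_report: document_type must be \"html\" or \"pdf\"",
         call. = FALSE)
  authors <- as_author_list(authors)
  if (is.null(global_options)) global_options <- chunk_options()
  validate_chunk_options(global_options, "create_report")
  if (!is.null(bibliography) &&
      (!is.character(bibliography) || length(bibliography) != 1L))
    stop("create_report: bibliography must be a single path", call. = FALSE)

  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("rmd", "md", "markdown"))
    path <- paste0(path, if (identical(dialect, "r")) ".Rmd" else ".md")
  if (file.exists(path) && !overwrite)
    stop("create_report: '", path, "' already exists; use overwrite = TRUE ",
         "to replace it", call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)

  doc <- ReportDocument$new(
    path = path, title = title, authors = authors,
    date = format(Sys.Date(), "%Y-%m-%d"),
    document_type = document_type, dialect = dialect,
    bibliography = if (is.null(bibliography)) character() else bibliography,
    global_options = unclass_options(global_options),
    resources = empty_resources(), elements = list(),
    chunk_open = FALSE, open_label = character(), open_overrides = list(),
    open_lines = character(), chunk_counter = 0L,
    labels_used = "global-options")
  write_document(doc)
  if (!file.exists(doc$path))
    stop("create_report: could not write '", doc$path, "'", call. = FALSE)
  invisible(doc)
}

# chunk_options carries an "explicit" attribute that must not leak into the
# stored document defaults (defaults are always fully specified)
unclass_options <- function(opts) {
  out <- unclass(opts)
  attr(out, "explicit") <- NULL
  out
}

#' Replace the document-wide chunk options
#'
#' Rewrites the global-options chunk at the top of the report source.
#' Chunks emitted afterwards inherit the new defaults unless they override
#' them locally; chunk headers already emitted are left as written.
#'
#' @param doc a `ReportDocument`.
#' @param options a [chunk_options()] object.
#' @return the document, invisibly.
#' @export
set_global_options <- function(doc, options) {
  check_doc(doc)
  validate_chunk_options(options, "set_global_options")
  doc$global_options <- unclass_options(options)
  write_document(doc)
  invisible(doc)
}

#' Snapshot a report's metadata
#'
#' @param doc a `ReportDocument`.
#' @return a list with `path`, `title`, `authors`, `bibliography` (NULL when
#'   unset), `document_type`, `dialect`, `global_options`, `resources` (a
#'   data frame in insertion order), `n_elements` and `n_chunks`.
#' @export
inspect_report <- function(doc) {
  check_doc(doc)
  list(path = doc$path, title = doc$title, authors = doc$authors,
       bibliography = if (length(doc$bibliography)) doc$bibliography else NULL,
       document_type = doc$document_type, dialect = doc$dialect,
       global_options = doc$global_options, resources = doc$resources,
       n_elements = length(doc$elements), n_chunks = doc$chunk_counter)
}

#' Register an external resource
#'
#' Resources (databases, archives, identifiers consulted during the
#' analysis) accumulate in insertion order and are rendered by
#' [compile_report()] as a three-column table under a trailing
#' "Resources Availability" section. The section is omitted entirely when
#' no resource was ever registered.
#'
#' @param doc a `ReportDocument`.
#' @param source resource origin, e.g. a database name (non-empty).
#' @param description free-text description.
#' @param locator URL or identifier.
#' @return the document, invisibly.
#' @examples
#' rp <- create_report(tempfile(), title = "t")
#' add_resource(rp, "GEO", "raw counts", "https://example.org/GSE0000")
#' @export
add_resource <- function(doc, source, description = "", locator = "") {
  check_doc(doc)
  if (!is.character(source) || length(source) != 1L || !nzchar(trimws(source)))
    stop("add_resource: 'source' must be a non-empty string", call. = FALSE)
  row <- data.frame(source = source, description = as.character(description),
                    locator = as.character(locator), stringsAsFactors = FALSE)
  doc$resources <- rbind(doc$resources, row)
  write_document(doc)
  invisible(doc)
}

check_doc <- function(doc) {
  if (!methods::is(doc, "ReportDocument"))
    stop("expected a ReportDocument created by create_report() or ",
         "parse_report()", call. = FALSE)
  invisible(doc)
}

check_no_open_chunk <- function(doc, op) {
  if (doc$chunk_open)
    stop(op, ": a code chunk is open; close it with close_chunk() first ",
         "(use add_code() to add code inside the open chunk)", call. = FALSE)
  invisible(doc)
}

check_open_chunk <- function(doc, op) {
  if (!doc$chunk_open)
    stop(op, ": no code chunk is open; call open_chunk() first",
         call. = FALSE)
  invisible(doc)
}
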