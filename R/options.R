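#' Per-chunk execution and rendering options
#'
#' Constructs the option set attached to a code chunk or, via
#' [set_global_options()], to a whole report. The flags mirror the ones a
#' literate-programming renderer understands: `eval` controls whether the
#' chunk is executed at compile time, `echo` whether its code is displayed,
#' `include` whether anything of the chunk (code or output) appears in the
#' compiled document at all, `warning`/`message` whether captured warnings
#' and messages are shown, and `cache` is accepted for dialect compatibility
#' but currently treated as a no-op by the compiler. Figure dimensions are
#' in inches.
#'
#' Only the options a caller names explicitly are treated as local
#' overrides; unnamed ones inherit the document defaults, and chunk headers
#' list only the overriding keys.
#'
#' @param label optional chunk label; must be unique within a document.
#'   When absent an automatic `chunk-<n>` label is assigned.
#' @param eval logical; execute the chunk when compiling. Default `TRUE`.
#' @param echo logical; show the chunk's code in the compiled report.
#'   Default `TRUE`.
#' @param include logical; include the chunk (code and output) in the
#'   compiled report. Default `TRUE`. An excluded chunk is still executed
#'   when `eval` is `TRUE`, so its side effects remain visible to later
#'   chunks.
#' @param warning,message logical; show captured warnings / messages.
#'   Both default `TRUE`.
#' @param cache logical; parsed and serialized but not acted upon.
#'   Default `FALSE`.
#' @param fig_width,fig_height optional positive figure dimensions in
#'   inches. Compile-time defaults are 7 by 5 inches when unset.
#' @return an object of class `chunk_options`.
#' @examples
#' chunk_options(eval = FALSE)
#' chunk_options(fig_width = 4, fig_height = 3)
#' @export
chunk_options <- function(label = NULL, eval = TRUE, echo = TRUE,
                          include = TRUE, warning = TRUE, message = TRUE,
                          cache = FALSE, fig_width = NULL, fig_height = NULL) {
  explicit <- names(match.call())[-1L]
  opts <- list(label = label, eval = eval, echo = echo, include = include,
               warning = warning, message = message, cache = cache,
               fig_width = fig_width, fig_height = fig_height)
  class(opts) <- "chunk_options"
  attr(opts, "explicit") <- intersect(explicit, .opt_fields)
  validate_chunk_options(opts)
  opts
}

# canonical field order; also the order keys appear in serialized headers
.opt_fields <- c("eval", "echo", "include", "warning", "message", "cache",
                 "fig_width", "fig_height")
.opt_flags <- c("eval", "echo", "include", "warning", "message", "cache")

# header key spelling in the R-compatible dialect
.opt_header_key <- c(eval = "eval", echo = "echo", include = "include",
                     warning = "warning", message = "message",
                     cache = "cache", fig_width = "fig.width",
                     fig_height = "fig.height")
.opt_field_for_key <- structure(names(.opt_header_key), names = .opt_header_key)

#' @export
print.chunk_options <- function(x, ...) {
  cat("<chunk_options>\n")
  for (f in .opt_fields) {
    v <- x[[f]]
    if (!is.null(v)) cat(" ", f, "=", format(v), "\n")
  }
  if (!is.null(x$label)) cat("  label =", x$label, "\n")
  invisible(x)
}

validate_chunk_options <- function(opts, context = "chunk_options") {
  if (!inherits(opts, "chunk_options"))
    stop(context, ": expected an object created by chunk_options()",
         call. = FALSE)
  known <- c("label", .opt_fields)
  extra <- setdiff(names(opts), known)
  if (length(extra))
    stop(context, ": unknown option key(s) ", paste(extra, collapse = ", "),
         "; supported keys are: ", paste(known, collapse = ", "),
         call. = FALSE)
  for (f in .opt_flags) {
    v <- opts[[f]]
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop(context, ": option '", f, "' must be TRUE or FALSE", call. = FALSE)
  }
  for (f in c("fig_width", "fig_height")) {
    v <- opts[[f]]
    if (!is.null(v)) {
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
        stop(context, ": option '", f, "' must be a positive number (inches)",
             call. = FALSE)
    }
  }
  if (!is.null(opts$label)) {
    if (!is.character(opts$label) || length(opts$label) != 1L ||
        !nzchar(opts$label))
      stop(context, ": 'label' must be a non-empty string", call. = FALSE)
    if (grepl("[,{}\\s]", opts$label, perl = TRUE))
      stop(context, ": 'label' must not contain spaces, commas or braces",
           call. = FALSE)
  }
  invisible(opts)
}

# fields the caller set explicitly (used for header minimality)
explicit_options <- function(opts) {
  ex <- attr(opts, "explicit")
  if (is.null(ex)) {
    # options reconstructed by the parser: every stored key is explicit
    ex <- .opt_fields[!vapply(opts[.opt_fields], is.null, logical(1))]
  }
  ex
}

# sparse override list (field -> value) for one chunk, given the document
# defaults: explicitly-set fields whose value differs from the default
chunk_overrides <- function(opts, global) {
  if (is.null(opts)) return(list())
  validate_chunk_options(opts)
  out <- list()
  for (f in intersect(explicit_options(opts), .opt_fields)) {
    v <- opts[[f]]
    g <- global[[f]]
    if (is.null(v)) next
    if (is.null(g) || !identical(as.vector(v), as.vector(g))) out[[f]] <- v
  }
  out
}

# merge document defaults with a sparse override list
effective_options <- function(global, overrides) {
  out <- global
  for (f in names(overrides)) out[[f]] <- overrides[[f]]
  out
}

format_option_value <- function(value, dialect) {
  if (is.logical(value)) {
    if (identical(dialect, "r")) {
      if (value) "TRUE" else "FALSE"
    } else {
      if (value) "true" else "false"
    }
  } else {
    # numeric figure dimension
    format(value, trim = TRUE, scientific = FALSE)
  }
}

parse_option_value <- function(field, text, line_no) {
  text <- trimws(text)
  if (field %in% .opt_flags) {
    if (text %in% c("TRUE", "true")) return(TRUE)
    if (text %in% c("FALSE", "false")) return(FALSE)
    stop("parse error at line ", line_no, ": option '", field,
         "' must be a boolean, got '", text, "'", call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(text))
  if (is.na(v))
    stop("parse error at line ", line_no, ": option '", field,
         "' must be numeric, got '", text, "'", call. = FALSE)
  v
}

# "```{r label, eval=FALSE, fig.width=5}" — canonical key order
render_chunk_header <- function(label, overrides, dialect) {
  parts <- paste(dialect, label)
  for (f in .opt_fields) {
    if (!is.null(overrides[[f]]))
      parts <- c(parts, paste0(.opt_header_key[[f]], "=",
                               format_option_value(overrides[[f]], dialect)))
  }
  paste0("```{", paste(parts, collapse = ", "), "}")
}

parse_chunk_header <- function(line, line_no) {
  inner <- sub("^```\\{", "", line)
  inner <- sub("\\}\\s*$", "", inner)
  parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
  head_words <- strsplit(parts[1L], "\\s+")[[1]]
  if (length(head_words) < 1L || !nzchar(head_words[1L]))
    stop("parse error at line ", line_no, ": empty chunk header", call. = FALSE)
  dialect <- head_words[1L]
  label <- if (length(head_words) >= 2L) head_words[2L] else NULL
  overrides <- list()
  for (kv in parts[-1L]) {
    if (!nzchar(kv)) next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stop("parse error at line ", line_no, ": malformed chunk option '",
           kv, "'", call. = FALSE)
    key <- trimws(substr(kv, 1L, eq - 1L))
    val <- substr(kv, eq + 1L, nchar(kv))
    field <- .opt_field_for_key[[key]]
    if (is.null(field))
      stop("parse error at line ", line_no, ": unknown chunk option '", key,
           "'; supported: ", paste(.opt_header_key, collapse = ", "),
           call. = FALSE)
    overrides[[field]] <- parse_option_value(field, val, line_no)
  }
  list(dialect = dialect, label = label, overrides = overrides)
}
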