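#' Make a function self-tracing
#'
#' Returns a wrapper around `target` bound to a report: every invocation
#' first records one complete, re-executable code chunk describing the
#' call (optionally preceded by a heading and a comment), then performs
#' the call and returns its value unchanged. This is the pattern that
#' gives point-and-click front-ends and package APIs a reproducible-
#' research audit trail: the interface calls the wrapper where it would
#' have called the target, and the report accumulates the exact calls with
#' the exact parameters.
#'
#' Scalar arguments (numbers, strings, flags, paths, flat vectors) are
#' serialized literally into the chunk. Data-bearing arguments must be
#' declared in `placeholder_names`: they are rendered as a bare variable
#' name, so the chunk references the object without inlining its value,
#' and re-executing the report reproduces the call wherever that name is
#' bound to equal data. An argument that is neither serializable nor
#' mapped to a placeholder raises a serialization error *before* anything
#' is written.
#'
#' The chunk is recorded before the target runs; if the target then
#' fails, the chunk remains — a failed attempt is part of the provenance —
#' and the error propagates to the caller.
#'
#' @param target the function to wrap.
#' @param doc the `ReportDocument` that accumulates the trace.
#' @param name function name to appear in the emitted code; default the
#'   expression `target` was passed as.
#' @param title optional heading written before each traced chunk.
#' @param level heading level for `title`, default 2.
#' @param comment optional prose written between the heading and the chunk.
#' @param placeholder_names named list or character vector mapping
#'   argument names to the variable names their values go by in the
#'   report's execution environment.
#' @param chunk_options optional [chunk_options()] for the traced chunks.
#' @param assign_to optional identifier; emitted chunks assign the call's
#'   result to this name.
#' @return a function of class `provmark_traced` with the same calling
#'   convention as `target`.
#' @examples
#' rp <- create_report(tempfile(), title = "trace demo")
#' sq <- make_traced(function(x) x^2, rp, name = "square")
#' sq(x = 3)  # returns 9 and appends one chunk: square(x=3)
#' @export
make_traced <- function(target, doc, name = NULL, title = NULL, level = 2L,
                        comment = NULL, placeholder_names = list(),
                        chunk_options = NULL, assign_to = NULL) {
  if (!is.function(target))
    stop("make_traced: 'target' must be a function", call. = FALSE)
  check_doc(doc)
  if (is.null(name)) name <- deparse(substitute(target))
  if (!is.character(name) || length(name) != 1L || grepl("[(){}]", name))
    stop("make_traced: supply 'name' explicitly when wrapping an anonymous ",
         "function", call. = FALSE)
  if (!is.null(title)) validate_title(title, level, "make_traced")
  placeholder_names <- as.list(placeholder_names)
  formal_names <- names(formals(target))

  traced <- function(...) {
    args <- list(...)
    nm <- names(args)
    if (is.null(nm)) nm <- rep("", length(args))
    # positional arguments take the target's formal names, in order
    pool <- setdiff(formal_names, nm[nzchar(nm)])
    pool <- setdiff(pool, "...")
    pos <- which(!nzchar(nm))
    if (length(pos) > length(pool))
      stop("traced '", name, "': too many positional arguments to name; ",
           "pass arguments by keyword", call. = FALSE)
    nm[pos] <- pool[seq_along(pos)]
    names(args) <- nm

    ser_args <- vector("list", length(args))
    names(ser_args) <- nm
    for (i in seq_along(args)) {
      ph <- placeholder_names[[nm[i]]]
      ser_args[[i]] <- if (!is.null(ph)) placeholder(ph) else args[[i]]
    }
    code <- serialize_call(name, ser_args, assign_to = assign_to,
                           dialect = doc$dialect)
    add_complete_chunk(doc, code = as.character(code),
                       options = chunk_options, comment = comment,
                       title = title, level = level)
    do.call(target, args)
  }
  class(traced) <- c("provmark_traced", "function")
  attr(traced, "target") <- target
  attr(traced, "doc") <- doc
  attr(traced, "name") <- name
  traced
}

#' @export
print.provmark_traced <- function(x, ...) {
  cat("<traced function> ", attr(x, "name"), " -> report ",
      attr(x, "doc")$path, "\n", sep = "")
  invisible(x)
}
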