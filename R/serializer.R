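#' Reference a variable by name inside serialized code
#'
#' A placeholder serializes as the bare variable name, never as the
#' argument's runtime value. This is how data-bearing arguments are traced:
#' the emitted chunk says `f(degList = degList)` and the compiled report
#' re-runs it against whatever `degList` is bound to in the execution
#' environment, instead of inlining a dump of the object.
#'
#' @param variable_name a valid identifier in the chunk dialect.
#' @return an object of class `provmark_placeholder`.
#' @examples
#' serialize_call("MAedgeRMAPlotEx", list(degList = placeholder("degList")))
#' @export
placeholder <- function(variable_name) {
  check_identifier(variable_name, "r", "placeholder")
  structure(list(variable_name = variable_name),
            class = "provmark_placeholder")
}

#' Pass raw code text through the serializer verbatim
#'
#' @param text code text, emitted without quoting or escaping.
#' @return an object of class `provmark_raw_code`.
#' @export
raw_code <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("raw_code: 'text' must be a single string", call. = FALSE)
  structure(list(text = text), class = "provmark_raw_code")
}

check_identifier <- function(name, dialect = "r", op = "serializer") {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop(op, ": identifier must be a single string", call. = FALSE)
  ok <- if (identical(dialect, "python"))
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)
  else
    grepl("^(\\.[A-Za-z._]|[A-Za-z])[A-Za-z0-9._]*$", name)
  if (!ok)
    stop(op, ": '", name, "' is not a valid ", dialect, " identifier",
         call. = FALSE)
  invisible(name)
}

#' Serialize a literal value to code text
#'
#' Returns code text that, evaluated in the chunk dialect, reconstructs a
#' value equal to the input. Supported kinds: `NULL` (absent-value marker),
#' logicals, integers, doubles (serialized with round-trip fidelity),
#' character strings (quote characters escaped), and flat unnamed vectors
#' of these. Anything else — nested lists, functions, model objects — is
#' a serialization error: reference such data through a [placeholder()]
#' instead.
#'
#' @param value the value to serialize.
#' @param dialect target dialect, default `"r"`.
#' @return a single code string.
#' @examples
#' format_literal(TRUE)
#' format_literal(c(1L, 2L, 3L))
#' format_literal("it's here")
#' @export
format_literal <- function(value, dialect = "r") {
  r <- identical(dialect, "r")
  if (is.null(value)) return(if (r) "NULL" else "None")
  if (inherits(value, "provmark_placeholder")) return(value$variable_name)
  if (inherits(value, "provmark_raw_code")) return(value$text)
  if (!is.atomic(value) || !is.null(dim(value)) ||
      !(is.null(names(value))))
    stop("format_literal: unsupported value of class '",
         paste(class(value), collapse = "/"),
         "'; pass large or structured data via placeholder()", call. = FALSE)
  if (!(is.logical(value) || is.numeric(value) || is.character(value)))
    stop("format_literal: unsupported atomic type '", typeof(value),
         "'; pass such data via placeholder()", call. = FALSE)
  one <- function(x) {
    if (is.na(x)) return(if (r) "NA" else "float('nan')")
    if (is.logical(x)) return(format_option_value(x, dialect))
    if (is.character(x)) return(quote_string(x, dialect))
    if (is.integer(x)) return(if (r) paste0(x, "L") else as.character(x))
    shortest_double(x)
  }
  parts <- vapply(seq_along(value), function(i) one(value[[i]]), character(1))
  if (length(parts) == 1L) return(parts)
  if (r) paste0("c(", paste(parts, collapse = ", "), ")")
  else paste0("[", paste(parts, collapse = ", "), "]")
}

quote_string <- function(x, dialect = "r") {
  esc <- gsub("\\\\", "\\\\\\\\", x)
  esc <- gsub('"', '\\\\"', esc)
  esc <- gsub("\n", "\\\\n", esc)
  esc <- gsub("\t", "\\\\t", esc)
  paste0('"', esc, '"')
}

# shortest decimal text that parses back to exactly the same double
shortest_double <- function(x) {
  if (is.nan(x)) return("NaN")
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  for (digits in 1:17) {
    txt <- trimws(formatC(x, digits = digits, format = "g"))
    if (identical(as.numeric(txt), x)) return(txt)
  }
  trimws(formatC(x, digits = 17, format = "g"))
}

#' Serialize a function call to one executable statement
#'
#' Builds `name(arg = value, ...)` code text with every argument rendered
#' by keyword: literals via [format_literal()], [placeholder()]s as bare
#' variable names, and [raw_code()] verbatim. Argument order is preserved.
#'
#' @param function_name function identifier (may be namespace-qualified,
#'   e.g. `"stats::rnorm"`).
#' @param arguments a named list of argument values. Unnamed entries are
#'   rejected: keyword rendering is deliberate, so the emitted call
#'   survives signature reordering.
#' @param assign_to optional identifier; prefixes the statement with an
#'   assignment in the dialect's operator.
#' @param dialect target dialect, default `"r"`.
#' @return an object of class `serialized_code`: a string with a
#'   `statement_count` attribute.
#' @examples
#' serialize_call("f", list(n = 3L, flag = TRUE))
#' serialize_call("plot", list(x = placeholder("pc")), assign_to = NULL)
#' @export
serialize_call <- function(function_name, arguments = list(),
                           assign_to = NULL, dialect = "r") {
  parts <- strsplit(function_name, "::", fixed = TRUE)[[1]]
  for (p in parts) check_identifier(p, dialect, "serialize_call")
  if (!is.list(arguments))
    stop("serialize_call: 'arguments' must be a (named) list", call. = FALSE)
  nm <- names(arguments)
  if (length(arguments) && (is.null(nm) || any(!nzchar(nm))))
    stop("serialize_call: every argument must be named (keyword rendering)",
         call. = FALSE)
  rendered <- character(length(arguments))
  for (i in seq_along(arguments)) {
    rendered[i] <- tryCatch(
      format_literal(arguments[[i]], dialect),
      error = function(e)
        stop("serialize_call: cannot serialize argument '", nm[i], "': ",
             conditionMessage(e), call. = FALSE))
    rendered[i] <- paste0(nm[i], "=", rendered[i])
  }
  text <- paste0(function_name, "(", paste(rendered, collapse = ", "), ")")
  if (!is.null(assign_to)) {
    check_identifier(assign_to, dialect, "serialize_call")
    op <- if (identical(dialect, "r")) " <- " else " = "
    text <- paste0(assign_to, op, text)
  }
  serialized_code(text, 1L)
}

serialized_code <- function(text, statement_count) {
  structure(text, statement_count = as.integer(statement_count),
            class = "serialized_code")
}

#' @export
print.serialized_code <- function(x, ...) {
  cat(unclass(x), "\n", sep = "")
  invisible(x)
}

#' Join serialized statements into one block
#'
#' @param statements a non-empty list of `serialized_code` objects or code
#'   strings.
#' @return a `serialized_code` whose text joins the inputs with newlines,
#'   in order, and whose `statement_count` is the sum.
#' @export
serialize_statements <- function(statements) {
  if (!is.list(statements) || length(statements) == 0L)
    stop("serialize_statements: 'statements' must be a non-empty list",
         call. = FALSE)
  counts <- vapply(statements, function(s) {
    sc <- attr(s, "statement_count")
    if (is.null(sc)) 1L else sc
  }, integer(1))
  texts <- vapply(statements, function(s)
    paste(as.character(s), collapse = "\n"), character(1))
  serialized_code(paste(texts, collapse = "\n"), sum(counts))
}
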