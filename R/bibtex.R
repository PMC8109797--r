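#' Read a BibTeX bibliography
#'
#' A small brace-aware reader covering the entry syntax the report
#' compiler needs for its reference list: `@type{key, field = value, ...}`
#' with values in braces, double quotes, or bare (numbers/macros).
#' Concatenation with `#`, `@string` macros and cross-references are not
#' supported.
#'
#' @param path path to a `.bib` file.
#' @return a named list (by citation key) of entries; each entry is a list
#'   with `type`, `key`, and lower-cased field values.
#' @export
read_bibtex <- function(path) {
  if (!file.exists(path))
    stop("read_bibtex: no such file: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  entries <- list()
  i <- 1L
  n <- nchar(txt)
  while (i <= n) {
    at <- regexpr("@", substr(txt, i, n), fixed = TRUE)
    if (at < 0) break
    i <- i + at - 1L
    m <- regexpr("^@\\s*([A-Za-z]+)\\s*\\{", substr(txt, i, n), perl = TRUE)
    if (m < 0) { i <- i + 1L; next }
    type <- tolower(gsub("^@\\s*|\\s*\\{$", "",
                         regmatches(substr(txt, i, n), m)))
    i <- i + attr(m, "match.length")
    if (type %in% c("comment", "preamble", "string")) {
      i <- skip_braced(txt, i - 1L) # skip the whole group
      next
    }
    comma <- regexpr(",", substr(txt, i, n), fixed = TRUE)
    if (comma < 0) stop("read_bibtex: malformed entry near offset ", i,
                        call. = FALSE)
    key <- trimws(substr(txt, i, i + comma - 2L))
    i <- i + comma
    entry <- list(type = type, key = key)
    repeat {
      while (i <= n && grepl("[\\s,]", substr(txt, i, i), perl = TRUE))
        i <- i + 1L
      if (i > n || substr(txt, i, i) == "}") { i <- i + 1L; break }
      eq <- regexpr("=", substr(txt, i, n), fixed = TRUE)
      if (eq < 0) stop("read_bibtex: malformed field in entry '", key, "'",
                       call. = FALSE)
      field <- tolower(trimws(substr(txt, i, i + eq - 2L)))
      i <- i + eq
      while (i <= n && grepl("\\s", substr(txt, i, i), perl = TRUE))
        i <- i + 1L
      ch <- substr(txt, i, i)
      if (ch == "{") {
        j <- match_brace(txt, i)
        value <- substr(txt, i + 1L, j - 1L)
        i <- j + 1L
      } else if (ch == '"') {
        j <- i + 1L
        while (j <= n && substr(txt, j, j) != '"') j <- j + 1L
        value <- substr(txt, i + 1L, j - 1L)
        i <- j + 1L
      } else {
        j <- i
        while (j <= n && !grepl("[,}]", substr(txt, j, j))) j <- j + 1L
        value <- trimws(substr(txt, i, j - 1L))
        i <- j
      }
      entry[[field]] <- clean_bib_value(value)
    }
    entries[[key]] <- entry
  }
  entries
}

match_brace <- function(txt, open_at) {
  depth <- 0L
  n <- nchar(txt)
  for (j in open_at:n) {
    ch <- substr(txt, j, j)
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") {
      depth <- depth - 1L
      if (depth == 0L) return(j)
    }
  }
  stop("read_bibtex: unbalanced braces", call. = FALSE)
}

skip_braced <- function(txt, at) {
  open_at <- at + regexpr("{", substr(txt, at, nchar(txt)), fixed = TRUE) - 1L
  match_brace(txt, open_at) + 1L
}

clean_bib_value <- function(x) {
  x <- gsub("[{}]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# "Author, A. and B. Author" -> "Author, A., B. Author"
format_bib_authors <- function(x) {
  paste(strsplit(x, "\\s+and\\s+")[[1]], collapse = ", ")
}

format_bib_entry <- function(e) {
  bits <- character()
  if (!is.null(e$author)) bits <- c(bits, format_bib_authors(e$author))
  if (!is.null(e$year)) bits <- c(bits, paste0("(", e$year, ")"))
  if (!is.null(e$title)) bits <- c(bits, paste0(e$title, "."))
  venue <- e$journal %||% e$booktitle %||% e$publisher
  if (!is.null(venue)) bits <- c(bits, paste0("*", venue, "*."))
  if (!is.null(e$volume)) bits <- c(bits, paste0(e$volume, "."))
  if (!is.null(e$doi)) bits <- c(bits, paste0("doi:", e$doi, "."))
  paste(bits, collapse = " ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
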