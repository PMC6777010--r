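# Assay panels (which genes a test evaluates) and the user's amplified-gene
# query, parsed exactly as pasted from a clinical report.

#' List built-in panel names
#'
#' Built-in panels ship with the package under `inst/extdata/` and are
#' addressed by lowercase name in [load_panel()]. The packaged panels are
#' synthetic subsets built for the bundled synthetic genome; real vendor
#' gene lists are supplied by the user as plain-text files.
#'
#' @return character vector of registered names.
#' @export
builtin_panels <- function() {
  dir <- system.file("extdata", package = "panelamp")
  files <- list.files(dir, pattern = "^panel_.*\\.txt$")
  sub("\\.txt$", "", sub("^panel_", "", files))
}

#' Load an assay panel
#'
#' @param source a registered built-in name (see [builtin_panels()]) or a
#'   path to a plain-text file with one gene symbol per line. Blank lines
#'   and `#` comments are ignored; duplicate symbols (case-insensitive)
#'   collapse to the first occurrence.
#' @param name label for the panel; defaults to the built-in name or the
#'   file name.
#' @return An object of class `panel`: list with `name` and `symbols`
#'   (deduplicated character vector).
#' @export
load_panel <- function(source, name = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && !file.exists(source)) {
    builtin <- builtin_panels()
    key <- tolower(source)
    if (key %in% builtin) {
      path <- system.file("extdata", paste0("panel_", key, ".txt"),
                          package = "panelamp")
      if (is.null(name)) name <- key
      source <- path
    } else {
      stop(sprintf(
        "'%s' is neither a readable file nor a built-in panel (available: %s)",
        source, paste(builtin, collapse = ", ")), call. = FALSE)
    }
  }
  lines <- read_source_lines(source)
  toks <- trimws(lines)
  toks <- toks[nzchar(toks) & !startsWith(toks, "#")]
  toks <- toks[!duplicated(toupper(toks))]
  if (length(toks) == 0L) stop("panel has no genes", call. = FALSE)
  if (is.null(name)) {
    name <- if (length(source) == 1L && file.exists(source)) {
      sub("\\.[^.]*$", "", basename(source))
    } else "custom"
  }
  structure(list(name = name, symbols = toks), class = "panel")
}

#' Create a panel from a symbol vector
#' @param symbols character vector of gene symbols.
#' @param name panel label.
#' @return a `panel`.
#' @export
panel <- function(symbols, name = "custom") {
  symbols <- trimws(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(toupper(symbols))]
  if (length(symbols) == 0L) stop("panel has no genes", call. = FALSE)
  structure(list(name = name, symbols = symbols), class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel '%s'> %d genes\n", x$name, length(x$symbols)))
  invisible(x)
}

#' Write a panel to a plain-text file
#' @param x a `panel`.
#' @param path output path (one symbol per line).
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) {
  stopifnot(inherits(x, "panel"))
  writeLines(x$symbols, path)
  invisible(path)
}

#' Parse a comma-delimited amplified-gene list
#'
#' The query is the list of genes a clinical report calls amplified, pasted
#' verbatim. Tokens are split on commas, trimmed, empty tokens dropped, and
#' duplicates removed case-insensitively keeping first-occurrence order.
#'
#' @param text raw query string, e.g. `"CCND1, FGF19 ,FGF4,FGF3"`.
#' @return An object of class `amplified_query`: list with `symbols`
#'   (ordered, deduplicated) and `raw_text`.
#' @export
parse_amplified_list <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  toks <- toks[nzchar(toks)]
  toks <- toks[!duplicated(toupper(toks))]
  if (length(toks) == 0L) stop("no gene names entered", call. = FALSE)
  structure(list(symbols = toks, raw_text = text), class = "amplified_query")
}

#' @export
print.amplified_query <- function(x, ...) {
  cat(sprintf("<amplified_query> %d gene(s): %s\n",
              length(x$symbols), paste(x$symbols, collapse = ", ")))
  invisible(x)
}

# Coerce a query argument: accepts an amplified_query, a raw comma-delimited
# string, or a character vector of symbols.
as_amplified_query <- function(query) {
  if (inherits(query, "amplified_query")) return(query)
  if (is.character(query) && length(query) == 1L) {
    return(parse_amplified_list(query))
  }
  if (is.character(query)) {
    return(parse_amplified_list(paste(query, collapse = ",")))
  }
  stop("query must be an amplified_query, a string, or a character vector",
       call. = FALSE)
}
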