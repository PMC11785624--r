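#' Construct a gene-set library
#'
#' @param sets Named list; each element a list with `description` (character
#'   scalar) and `members` (character vector). Members are deduplicated.
#' @return An object of class `GeneSetLibrary`.
#' @export
gene_set_library <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("gene-set library: set names must be unique and nonempty",
         call. = FALSE)
  sets <- lapply(sets, function(s) {
    m <- unique(as.character(s$members))
    if (length(m) == 0) stop("gene-set library: empty set", call. = FALSE)
    list(description = as.character(s$description %||% ""), members = m)
  })
  structure(list(sets = sets), class = "GeneSetLibrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.GeneSetLibrary <- function(x, ...) {
  cat(sprintf("GeneSetLibrary: %d sets\n", length(x$sets)))
  invisible(x)
}

#' @export
length.GeneSetLibrary <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A `GeneSetLibrary`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    sets[[fields[1]]] <- list(description = fields[2],
                              members = fields[-(1:2)])
  }
  gene_set_library(sets)
}

#' Write a GeneSetLibrary as GMT
#' @param library A `GeneSetLibrary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  ensure_parent_dir(path)
  lines <- vapply(names(library$sets), function(nm) {
    s <- library$sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
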