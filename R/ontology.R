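#' Ontology container
#'
#' A minimal in-memory representation of a term ontology: a term table
#' (`id`, `name`, `namespace`) and an `is_a` parent list. Each
#' namespace must form a single-rooted directed acyclic graph.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`.
#' @param parents named list: for each term ID, the character vector of
#'   its `is_a` parents (empty for roots).
#' @return an object of class `ontology` with a `roots` element naming
#'   the root term of each namespace.
#' @export
ontology <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            !anyDuplicated(terms$id))
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents[vapply(parents, is.null, TRUE)] <- list(character(0))
  unknown <- setdiff(unlist(parents), terms$id)
  if (length(unknown) > 0) stop("parent term(s) not in term table: ",
                                paste(unknown, collapse = ", "))
  roots <- vapply(split(terms$id, terms$namespace), function(ids) {
    r <- ids[lengths(parents[ids]) == 0]
    if (length(r) != 1) stop("namespace must have exactly one root")
    r
  }, character(1))
  obj <- structure(list(terms = terms, parents = parents, roots = roots),
                   class = "ontology")
  # cycle check: ancestor closure must terminate
  invisible(term_ancestors(obj))
  obj
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms in %d namespace(s): %s\n",
              nrow(x$terms), length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Ancestor sets of every term (inclusive of the term itself)
#'
#' @param ont an [ontology].
#' @return named list of character vectors.
#' @export
term_ancestors <- function(ont) {
  anc <- list()
  visiting <- character(0)
  walk <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% visiting) stop("cycle detected at term ", id)
    visiting <<- c(visiting, id)
    res <- unique(c(id, unlist(lapply(ont$parents[[id]], walk))))
    visiting <<- setdiff(visiting, id)
    anc[[id]] <<- res
    res
  }
  for (id in ont$terms$id) walk(id)
  anc[ont$terms$id]
}

#' Read / write a minimal OBO file
#'
#' Supports the `[Term]` stanzas with `id`, `name`, `namespace` and
#' `is_a` tags — the subset the pipeline consumes and emits.
#'
#' @param path OBO file path.
#' @return [read_obo()] returns an [ontology]; [write_obo()] returns
#'   `path` invisibly.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  if (length(idx) == 0) stop("no [Term] stanzas in ", path)
  bounds <- c(idx, length(lines) + 1)
  recs <- lapply(seq_along(idx), function(i) {
    chunk <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    tag_of <- sub(":.*$", "", chunk)
    val_of <- trimws(sub("^[^:]+: ?", "", chunk))
    list(id = val_of[tag_of == "id"][1],
         name = val_of[tag_of == "name"][1],
         namespace = val_of[tag_of == "namespace"][1],
         is_a = sub(" !.*$", "", val_of[tag_of == "is_a"]))
  })
  terms <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    name = vapply(recs, `[[`, character(1), "name"),
    namespace = vapply(recs, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE)
  parents <- lapply(recs, `[[`, "is_a")
  names(parents) <- terms$id
  ontology(terms, parents)
}

#' @rdname read_obo
#' @param ont an [ontology].
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ont$terms$name[i]),
                 paste0("namespace: ", ont$terms$namespace[i]),
                 if (length(ont$parents[[id]]) > 0)
                   paste0("is_a: ", ont$parents[[id]])), con)
  }
  invisible(path)
}

#' Read / write gene-term annotation tables
#'
#' Tab-separated with columns `gene`, `term`, `namespace`.
#'
#' @param path file path.
#' @export
read_annotations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param annotations data frame `gene`, `term`, `namespace`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
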