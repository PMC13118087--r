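#' Journal-to-discipline mappings
#'
#' Journal names are used as a proxy for the medical discipline a paper
#' addresses. Names are normalised before lookup: lowercased, trimmed, and
#' internal whitespace collapsed to single spaces. Journals absent from the
#' map fall into an explicit `"unmapped"` bucket. No default mapping is
#' bundled beyond a tiny example for tests: discipline taxonomies are
#' editorial choices the user must supply.
#'
#' @param x data.frame with columns `journal` and `discipline`, or a path
#'   handled by [read_discipline_map()].
#' @return A named character vector keyed by normalised journal name.
#' @export
as_discipline_map <- function(x) {
  stopifnot(is.data.frame(x), all(c("journal", "discipline") %in% names(x)))
  key <- normalize_journal(x$journal)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("journal mapped more than once (after normalisation): ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  setNames(as.character(x$discipline), key)
}

#' @rdname as_discipline_map
#' @param path Two-column TSV (`journal`, `discipline`).
#' @export
read_discipline_map <- function(path) {
  as_discipline_map(read.delim(path, stringsAsFactors = FALSE))
}

#' Normalise journal names for mapping
#'
#' @param journal Character vector.
#' @return Lowercased, trimmed names with internal whitespace collapsed.
#' @export
normalize_journal <- function(journal) {
  gsub("\\s+", " ", trimws(tolower(as.character(journal))))
}

#' Count keyword-bearing documents per medical discipline
#'
#' Selects the documents whose abstract matched at least one keyword of
#' `keyword_subset`, maps each document's journal to a discipline, and
#' tallies. Unmapped journals (including missing journal fields) are
#' reported under `"unmapped"`, so the counts always partition the
#' matching documents.
#'
#' @param matrix Annotation matrix (rows aligned with `corpus`).
#' @param corpus Corpus `data.frame` carrying the `journal` column.
#' @param map A discipline map (see [as_discipline_map()]).
#' @param keyword_subset Keyword labels to profile; default all columns.
#' @return `data.frame` with columns `discipline`, `n_documents`, sorted by
#'   descending count with `"unmapped"` last.
#' @export
profile_by_discipline <- function(matrix, corpus, map,
                                  keyword_subset = colnames(matrix)) {
  corpus <- as_document_corpus(corpus)
  stopifnot(nrow(corpus) == nrow(matrix))
  miss <- setdiff(keyword_subset, colnames(matrix))
  if (length(miss) > 0L) {
    stop("unknown keyword(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  hit <- Matrix::rowSums(matrix[, keyword_subset, drop = FALSE]) > 0
  journals <- normalize_journal(corpus$journal[hit])
  disc <- unname(map[journals])
  disc[is.na(disc)] <- "unmapped"
  counts <- table(disc)
  out <- data.frame(discipline = names(counts),
                    n_documents = as.integer(counts),
                    stringsAsFactors = FALSE)
  unmapped <- out$discipline == "unmapped"
  out <- rbind(out[!unmapped, , drop = FALSE][
                 order(-out$n_documents[!unmapped]), , drop = FALSE],
               out[unmapped, , drop = FALSE])
  rownames(out) <- NULL
  out
}
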