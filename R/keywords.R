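#' Keyword specification tables
#'
#' A keyword set is a `data.frame` with columns `label` (unique display
#' name), `pattern` (the search string; a trailing `*` marks a prefix
#' wildcard), `group` (concept group) and the derived `match_mode`
#' (`exact_token`, `prefix` or `phrase`). Patterns containing internal
#' whitespace or hyphens are phrases; the final word of a phrase may carry
#' the wildcard. A `surface` column gives one canonical textual realisation
#' of each keyword, used by the synthetic corpus generator.
#'
#' @param x data.frame with at least `label`, `pattern`, `group`.
#' @return Validated keyword set with `match_mode` (and, if absent, a
#'   `surface`) filled in.
#' @export
as_keyword_set <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("label", "pattern", "group")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0L) {
    stop("keyword set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(label = as.character(x$label),
                    pattern = as.character(x$pattern),
                    group = as.character(x$group),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$pattern))) stop("empty keyword pattern", call. = FALSE)
  if (anyDuplicated(out$label)) {
    stop("duplicate keyword labels: ",
         paste(unique(out$label[duplicated(out$label)]), collapse = ", "),
         call. = FALSE)
  }
  out$match_mode <- vapply(out$pattern, function(p) {
    parse_pattern(p)$match_mode
  }, character(1L), USE.NAMES = FALSE)
  out$surface <- if ("surface" %in% names(x)) as.character(x$surface) else
    vapply(out$pattern, default_surface, character(1L), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

# Split a pattern into lowercase words and classify its match mode.
# Words are separated by runs of whitespace/hyphens; "*" is legal only as
# the final character of the whole pattern.
parse_pattern <- function(pattern) {
  p <- tolower(trimws(pattern))
  if (!nzchar(p)) stop("empty keyword pattern", call. = FALSE)
  star <- gregexpr("\\*", p, fixed = FALSE)[[1L]]
  has_star <- star[1L] != -1L
  if (has_star && (length(star) > 1L || star[1L] != nchar(p))) {
    stop("wildcard '*' must be the final character of the pattern: '",
         pattern, "'", call. = FALSE)
  }
  stem <- sub("\\*$", "", p)
  words <- strsplit(stem, "[\\s-]+", perl = TRUE)[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L || !all(grepl("^[[:alpha:]]+$", words))) {
    stop("keyword pattern must consist of letter words separated by ",
         "spaces or hyphens: '", pattern, "'", call. = FALSE)
  }
  mode <- if (length(words) > 1L) "phrase" else
    if (has_star) "prefix" else "exact_token"
  list(words = words, prefix_last = has_star, match_mode = mode)
}

default_surface <- function(pattern) {
  parsed <- parse_pattern(pattern)
  words <- parsed$words
  if (parsed$prefix_last) {
    n <- length(words)
    # a plain, real-word completion of the stem
    words[n] <- switch(words[n],
                       elderl = "elderly", geriatr = "geriatric",
                       athlet = "athlete", paste0(words[n], "a"))
  }
  paste(words, collapse = " ")
}

#' The default keyword taxonomy
#'
#' Thirty-one curated search terms in six concept groups: fragility
#' fracture outcomes (`ofs_outcome`), their underlying pathologies
#' (`ofs_pathology`), old-age terms (`old_age`), high-energy/trauma control
#' terms negatively associated with fragility fractures
#' (`trauma_control`), and metabolic syndrome outcomes and pathologies
#' (`metabolic_outcome`, `metabolic_pathology`) serving as an established
#' reference syndrome. A trailing `*` denotes a prefix wildcard, e.g.
#' `geriatr*` matches geriatric, geriatrics and geriatrician.
#'
#' @return A keyword set `data.frame` (see [as_keyword_set()]).
#' @export
default_keyword_set <- function() {
  spec <- rbind(
    data.frame(pattern = c("hip fracture", "femur fracture",
                           "spine fracture", "fragility fracture",
                           "fracture", "fragility"),
               group = "ofs_outcome"),
    data.frame(pattern = c("osteoporosis", "sarcopenia", "malnutrition",
                           "gait", "fall", "frail", "cognitive impairment"),
               group = "ofs_pathology"),
    data.frame(pattern = c("older adult", "elderl*", "geriatr*"),
               group = "old_age"),
    data.frame(pattern = c("sport", "athlet*", "trauma", "young",
                           "high-energy"),
               group = "trauma_control"),
    data.frame(pattern = c("stroke", "infarction", "heart failure",
                           "heart attack"),
               group = "metabolic_outcome"),
    data.frame(pattern = c("insulin resistance", "obesity", "hypertension",
                           "diabetes"),
               group = "metabolic_pathology")
  )
  spec$label <- spec$pattern
  as_keyword_set(spec)
}

#' Concept group display order
#'
#' @return Character vector of the six group labels in reporting order.
#' @export
keyword_group_levels <- function() {
  c("ofs_outcome", "ofs_pathology", "old_age", "trauma_control",
    "metabolic_outcome", "metabolic_pathology")
}

#' Compile a keyword pattern into a matcher
#'
#' Matching is case-insensitive on word-token boundaries, where a token is
#' a maximal run of letters (digits, punctuation and hyphens delimit).
#' `exact_token` patterns match a whole token; `prefix` patterns match any
#' token beginning with the stem; `phrase` patterns match their word
#' sequence in order, words separated by a single run of whitespace and/or
#' hyphens. Thus `fall` does not fire on "falling", while `geriatr*` fires
#' on "Geriatrics", and `high-energy` matches both "high-energy" and
#' "high energy".
#'
#' @param pattern A single pattern string, or one-row keyword set.
#' @return A `keyword_matcher` object usable with [keyword_detect()].
#' @export
compile_matcher <- function(pattern) {
  if (is.data.frame(pattern)) {
    stopifnot(nrow(pattern) == 1L)
    pattern <- pattern$pattern
  }
  parsed <- parse_pattern(pattern)
  words <- parsed$words
  n <- length(words)
  piece <- character(n)
  for (k in seq_len(n)) {
    left <- "(?<![[:alpha:]])"
    right <- if (k == n && parsed$prefix_last) "" else "(?![[:alpha:]])"
    piece[k] <- paste0(if (k == 1L) left else "", words[k], right)
  }
  regex <- paste0("(?i)", paste(piece, collapse = "[\\s-]+"))
  structure(list(pattern = pattern, words = words,
                 match_mode = parsed$match_mode, regex = regex),
            class = "keyword_matcher")
}

#' Test texts against a compiled matcher
#'
#' @param matcher A [compile_matcher()] result.
#' @param text Character vector of texts.
#' @return Logical vector: does the keyword occur at least once?
#' @export
keyword_detect <- function(matcher, text) {
  stopifnot(inherits(matcher, "keyword_matcher"))
  grepl(matcher$regex, text, perl = TRUE)
}

#' Annotate a corpus with binary keyword presence
#'
#' Runs every keyword matcher over the document abstracts (titles are not
#' searched) and records presence/absence. Repeated occurrences of a
#' keyword in one abstract still yield a single 1.
#'
#' @param corpus A corpus `data.frame` (ideally cleaned).
#' @param keyword_set A keyword set; defaults to [default_keyword_set()].
#' @return A sparse binary `Matrix::dgCMatrix`, documents in rows (named by
#'   `doc_id`) and keywords in columns (named by `label`), with a
#'   `provenance` attribute recording the dimensions and keyword patterns.
#' @export
annotate <- function(corpus, keyword_set = default_keyword_set()) {
  corpus <- as_document_corpus(corpus)
  keyword_set <- as_keyword_set(keyword_set)
  hits <- lapply(seq_len(nrow(keyword_set)), function(k) {
    which(keyword_detect(compile_matcher(keyword_set$pattern[k]),
                         corpus$abstract))
  })
  i <- unlist(hits, use.names = FALSE)
  j <- rep.int(seq_len(nrow(keyword_set)),
               vapply(hits, length, integer(1L)))
  mat <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(corpus), nrow(keyword_set)),
    dimnames = list(corpus$doc_id, keyword_set$label))
  attr(mat, "provenance") <- list(
    n_documents = nrow(corpus),
    n_keywords = nrow(keyword_set),
    patterns = setNames(keyword_set$pattern, keyword_set$label))
  mat
}

#' Per-keyword document counts by concept group
#'
#' Column sums of an annotation matrix, grouped and ordered by concept
#' group for occurrence-count reporting.
#'
#' @param matrix Annotation matrix from [annotate()].
#' @param keyword_set Keyword set supplying group labels; defaults to
#'   [default_keyword_set()]. Keywords absent from the set are reported
#'   with group `NA`.
#' @return `data.frame` with columns `label`, `group`, `n_documents`.
#' @export
count_occurrences <- function(matrix, keyword_set = default_keyword_set()) {
  keyword_set <- as_keyword_set(keyword_set)
  counts <- Matrix::colSums(matrix)
  out <- data.frame(label = colnames(matrix),
                    group = keyword_set$group[match(colnames(matrix),
                                                    keyword_set$label)],
                    n_documents = as.integer(counts),
                    stringsAsFactors = FALSE)
  grp <- factor(out$group, levels = keyword_group_levels())
  out <- out[order(grp, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write keyword sets as TSV
#'
#' Tab-separated with columns `label`, `pattern`, `group` (and optionally
#' `surface`); `match_mode` is always derived from the pattern.
#'
#' @param path File path.
#' @param keyword_set A keyword set.
#' @return The reader returns a keyword set; the writer returns `path`
#'   invisibly.
#' @export
read_keyword_set <- function(path) {
  as_keyword_set(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_keyword_set
#' @export
write_keyword_set <- function(keyword_set, path) {
  keyword_set <- as_keyword_set(keyword_set)
  write.table(keyword_set[c("label", "pattern", "group", "surface")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
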