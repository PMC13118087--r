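#' Assemble and validate a document corpus
#'
#' A corpus is a plain `data.frame` with one row per bibliographic record
#' and columns `doc_id`, `title`, `abstract`, `year`, `journal`. This
#' constructor normalises types (missing abstracts become empty strings,
#' missing year/journal become `NA`) and enforces unique document ids.
#'
#' @param x data.frame with at least `doc_id`, `title`, `abstract`; `year`
#'   and `journal` are optional and filled with `NA` when absent.
#' @return A validated corpus `data.frame`.
#' @export
as_document_corpus <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("doc_id", "title", "abstract")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    doc_id   = as.character(x$doc_id),
    title    = as.character(x$title),
    abstract = as.character(x$abstract),
    year     = if ("year" %in% names(x)) suppressWarnings(as.integer(x$year))
               else NA_integer_,
    journal  = if ("journal" %in% names(x)) as.character(x$journal)
               else NA_character_,
    stringsAsFactors = FALSE
  )
  out$abstract[is.na(out$abstract)] <- ""
  out$title[is.na(out$title)] <- ""
  if (anyDuplicated(out$doc_id)) {
    dup <- unique(out$doc_id[duplicated(out$doc_id)])
    stop("duplicate doc_id in corpus: ",
         paste(head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a MEDLINE/PubMed citation XML file
#'
#' Parses a `PubmedArticleSet` document (optionally gzip-compressed, as in
#' the bulk baseline distribution) into a corpus. One record is produced per
#' citation. Structured abstracts are concatenated in document order with
#' single spaces; section labels (stored as XML attributes) are not part of
#' the text. Citations without an abstract yield an empty abstract and are
#' kept -- dropping them is the job of [clean_corpus()], not of the reader.
#' Citations without a PMID are skipped with a warning.
#'
#' @param path Path to a MEDLINE citation XML file (`.xml` or `.xml.gz`).
#' @return A corpus `data.frame` (see [as_document_corpus()]).
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("malformed XML in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  recs <- lapply(citations, function(cit) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("skipping citation without PMID", call. = FALSE)
      return(NULL)
    }
    art <- xml2::xml_find_first(cit, "./Article")
    title <- xml2::xml_text(xml2::xml_find_first(art, "./ArticleTitle"))
    parts <- xml2::xml_find_all(art, "./Abstract/AbstractText")
    abstract <- if (length(parts) == 0L) "" else
      paste(trimws(xml2::xml_text(parts)), collapse = " ")
    year <- xml2::xml_text(
      xml2::xml_find_first(art, "./Journal/JournalIssue/PubDate/Year"))
    if (is.na(year)) {
      # MedlineDate fallback, e.g. "1998 Mar-Apr": first 4-digit run
      md <- xml2::xml_text(xml2::xml_find_first(
        art, "./Journal/JournalIssue/PubDate/MedlineDate"))
      year <- regmatches(md, regexpr("[0-9]{4}", md))
      if (length(year) == 0L) year <- NA_character_
    }
    journal <- xml2::xml_text(xml2::xml_find_first(art, "./Journal/Title"))
    data.frame(doc_id = pmid,
               title = if (is.na(title)) "" else title,
               abstract = abstract,
               year = suppressWarnings(as.integer(year)),
               journal = journal,
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (length(recs) == 0L) {
    return(as_document_corpus(data.frame(
      doc_id = character(), title = character(), abstract = character(),
      year = integer(), journal = character(), stringsAsFactors = FALSE)))
  }
  as_document_corpus(do.call(rbind, recs))
}

#' Read and write corpora in line-delimited JSON
#'
#' Each line is one JSON object with fields `doc_id`, `title`, `abstract`,
#' `year`, `journal`. A missing `abstract` becomes the empty string; missing
#' `year`/`journal` become `NA`. Blank lines are ignored. An unparseable
#' line raises an error naming its line number.
#'
#' @param path File path.
#' @return For the reader, a corpus `data.frame`; the writer returns `path`
#'   invisibly.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  recs <- lapply(idx, function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("cannot parse line ", i, " of '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (is.null(obj$doc_id)) {
      stop("record on line ", i, " of '", path, "' has no doc_id",
           call. = FALSE)
    }
    scalar <- function(v, default) {
      if (is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v)))
        default else v[[1L]]
    }
    data.frame(
      doc_id   = as.character(obj$doc_id),
      title    = as.character(scalar(obj$title, "")),
      abstract = as.character(scalar(obj$abstract, "")),
      year     = suppressWarnings(as.integer(scalar(obj$year, NA))),
      journal  = as.character(scalar(obj$journal, NA_character_)),
      stringsAsFactors = FALSE)
  })
  if (length(recs) == 0L) {
    return(as_document_corpus(data.frame(
      doc_id = character(), title = character(), abstract = character(),
      year = integer(), journal = character(), stringsAsFactors = FALSE)))
  }
  as_document_corpus(do.call(rbind, recs))
}

#' @rdname read_corpus_jsonl
#' @param corpus A corpus `data.frame`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  corpus <- as_document_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(doc_id = corpus$doc_id[i], title = corpus$title[i],
                abstract = corpus$abstract[i])
    rec$year <- if (is.na(corpus$year[i])) NULL else corpus$year[i]
    rec$journal <- if (is.na(corpus$journal[i])) NULL else corpus$journal[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"))
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Cleaning configuration
#'
#' Parameters of the corpus cleaning filters: abstracts must be non-empty,
#' have a length (Unicode code points, after trimming surrounding
#' whitespace) inside `[min_chars, max_chars]`, and end in standard
#' sentence-terminal punctuation. The defaults are the conventional
#' 250--4000 character window with `.`, `?`, `!` terminators.
#'
#' @param min_chars,max_chars Inclusive abstract length bounds.
#' @param terminal_punctuation Character vector of admissible final
#'   characters.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_chars = 250L, max_chars = 4000L,
                            terminal_punctuation = c(".", "?", "!")) {
  min_chars <- as.integer(min_chars)
  max_chars <- as.integer(max_chars)
  stopifnot(length(min_chars) == 1L, length(max_chars) == 1L,
            min_chars > 0L, min_chars < max_chars,
            is.character(terminal_punctuation),
            all(nchar(terminal_punctuation) == 1L))
  structure(list(min_chars = min_chars, max_chars = max_chars,
                 terminal_punctuation = terminal_punctuation),
            class = "cleaning_config")
}

#' Apply the cleaning filters to a corpus
#'
#' Three rules, applied to the whitespace-trimmed abstract: (1) it must be
#' non-empty; (2) its length in characters must lie inside the configured
#' inclusive range; (3) its last character must be sentence-terminal
#' punctuation. Each excluded record is attributed to the *first* failing
#' rule, in the order missing, length, punctuation, so the report counts
#' form a partition of the input.
#'
#' @param corpus A corpus `data.frame`.
#' @param config A [cleaning_config()].
#' @return A list with elements `corpus` (the retained records, in input
#'   order) and `report` (class `cleaning_report`: `n_input`,
#'   `n_missing_abstract`, `n_length_excluded`, `n_punctuation_excluded`,
#'   `n_retained`).
#' @export
clean_corpus <- function(corpus, config = cleaning_config()) {
  corpus <- as_document_corpus(corpus)
  stopifnot(inherits(config, "cleaning_config"))
  ab <- trimws(corpus$abstract)
  n <- nchar(ab, type = "chars")
  missing_ab <- n == 0L
  bad_length <- !missing_ab & (n < config$min_chars | n > config$max_chars)
  last_char <- substring(ab, n, n)
  bad_punct <- !missing_ab & !bad_length &
    !(last_char %in% config$terminal_punctuation)
  keep <- !(missing_ab | bad_length | bad_punct)
  report <- structure(list(
    n_input = nrow(corpus),
    n_missing_abstract = sum(missing_ab),
    n_length_excluded = sum(bad_length),
    n_punctuation_excluded = sum(bad_punct),
    n_retained = sum(keep)
  ), class = "cleaning_report")
  retained <- corpus[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(corpus = retained, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Corpus cleaning report\n")
  cat("  input records:          ", x$n_input, "\n")
  cat("  missing abstract:       ", x$n_missing_abstract, "\n")
  cat("  length out of range:    ", x$n_length_excluded, "\n")
  cat("  bad terminal character: ", x$n_punctuation_excluded, "\n")
  cat("  retained:               ", x$n_retained, "\n")
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
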