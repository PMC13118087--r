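# Independent oracles and fixture builders shared across the suite.

# Brute-force token-window matcher: tokenize into maximal letter runs,
# record the raw separator between consecutive tokens, and scan every
# window. Deliberately naive and regex-free on the matching side.
oracle_tokens <- function(text) {
  t <- tolower(text)
  hit <- gregexpr("[[:alpha:]]+", t)[[1L]]
  if (hit[1L] == -1L) return(list(tokens = character(), gaps = character()))
  tokens <- regmatches(t, gregexpr("[[:alpha:]]+", t))[[1L]]
  starts <- as.integer(hit)
  ends <- starts + attr(hit, "match.length") - 1L
  gaps <- if (length(tokens) > 1L) {
    substring(t, head(ends, -1L) + 1L, tail(starts, -1L) - 1L)
  } else character()
  list(tokens = tokens, gaps = gaps)
}

oracle_match <- function(pattern, text) {
  p <- tolower(trimws(pattern))
  star <- grepl("\\*$", p)
  words <- strsplit(sub("\\*$", "", p), "[\\s-]+", perl = TRUE)[[1L]]
  tk <- oracle_tokens(text)
  n_tok <- length(tk$tokens)
  len <- length(words)
  if (n_tok < len) return(FALSE)
  sep_ok <- function(gap) grepl("^[\\s-]+$", gap, perl = TRUE)
  for (s in seq_len(n_tok - len + 1L)) {
    ok <- TRUE
    for (k in seq_len(len)) {
      tok <- tk$tokens[s + k - 1L]
      hit <- if (k == len && star) startsWith(tok, words[k])
             else tok == words[k]
      if (!hit || (k < len && !sep_ok(tk$gaps[s + k - 1L]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Two-sided Fisher p by explicit binomial-coefficient enumeration
# (lchoose route, independent of dhyper).
oracle_fisher <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  c0 <- n - c1
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) return(1)
  ks <- max(0L, r1 - c0):min(r1, c1)
  probs <- exp(lchoose(c1, ks) + lchoose(c0, r1 - ks) - lchoose(n, r1))
  obs <- probs[ks == n11]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Random 2x2 table with all margins positive.
random_table <- function(max_n = 200L) {
  repeat {
    cells <- as.integer(rmultinom(1L, sample(4:max_n, 1L),
                                  prob = runif(4, 0.05, 1)))
    tab <- contingency_table(cells[1L], cells[2L], cells[3L], cells[4L])
    if (min(tab$r1, tab$r0, tab$c1, tab$c0) > 0L) return(tab)
  }
}

# Random binary annotation fixture (plain matrix, named dims).
random_annotation <- function(n_docs, keywords, p = 0.3) {
  m <- matrix(rbinom(n_docs * length(keywords), 1L, p), nrow = n_docs,
              dimnames = list(sprintf("d%03d", seq_len(n_docs)), keywords))
  m
}

# Wrap abstracts into a minimal corpus data.frame.
make_corpus <- function(abstracts, journal = NA_character_) {
  n <- length(abstracts)
  data.frame(doc_id = sprintf("doc%03d", seq_len(n)),
             title = sprintf("title %d", seq_len(n)),
             abstract = abstracts,
             year = rep(2020L, n),
             journal = rep_len(if (n == 0L) character() else journal, n),
             stringsAsFactors = FALSE)
}

# An abstract of exactly `n` characters ending in `terminal`.
abstract_of_length <- function(n, terminal = ".") {
  stopifnot(n >= 1L)
  paste0(strrep("a", n - nchar(terminal)), terminal)
}

# Minimal MEDLINE XML writers for reader tests.
medline_citation <- function(pmid, title = "A title", abstract_xml = "",
                             year = "2020", journal = "Journal A") {
  paste0(
    "<PubmedArticle><MedlineCitation>",
    if (!is.null(pmid)) paste0("<PMID>", pmid, "</PMID>") else "",
    "<Article>",
    "<Journal><Title>", journal, "</Title>",
    "<JournalIssue><PubDate><Year>", year, "</Year></PubDate>",
    "</JournalIssue></Journal>",
    "<ArticleTitle>", title, "</ArticleTitle>",
    abstract_xml,
    "</Article></MedlineCitation></PubmedArticle>")
}

write_medline_fixture <- function(citations, path = tempfile(
                                    fileext = ".xml")) {
  writeLines(c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>",
               citations, "</PubmedArticleSet>"), path)
  path
}
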