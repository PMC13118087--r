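#' Define the query/background document split
#'
#' The corpus is partitioned (partially) into a query subset -- documents
#' whose abstracts contain both the query term and the anchor term -- and a
#' background subset -- documents containing the anchor term but not the
#' query term. With the defaults this contrasts fragility-fracture
#' abstracts ("fragility" and "fracture" both present) against abstracts on
#' other fractures ("fracture" without "fragility"). Documents containing
#' neither the anchor, or the query term alone, belong to neither subset.
#' The two rules are disjoint by construction.
#'
#' @param query_term Keyword label whose presence (with the anchor) defines
#'   the query subset.
#' @param anchor_term Keyword label required in both subsets.
#' @return An object of class `subset_definition`.
#' @export
subset_definition <- function(query_term = "fragility",
                              anchor_term = "fracture") {
  stopifnot(is.character(query_term), length(query_term) == 1L,
            is.character(anchor_term), length(anchor_term) == 1L,
            query_term != anchor_term)
  structure(list(query_term = query_term, anchor_term = anchor_term),
            class = "subset_definition")
}

#' Split an annotation matrix into query and background rows
#'
#' @param matrix Annotation matrix from [annotate()].
#' @param definition A [subset_definition()].
#' @return List with integer row indices `query` and `background`
#'   (disjoint).
#' @export
split_subsets <- function(matrix, definition = subset_definition()) {
  stopifnot(inherits(definition, "subset_definition"))
  need <- c(definition$query_term, definition$anchor_term)
  miss <- setdiff(need, colnames(matrix))
  if (length(miss) > 0L) {
    stop("annotation matrix lacks required keyword column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  q <- as.numeric(matrix[, definition$query_term]) > 0
  a <- as.numeric(matrix[, definition$anchor_term]) > 0
  list(query = which(a & q), background = which(a & !q))
}

#' Pooled two-proportion z-test
#'
#' Tests the null of equal proportions with the pooled-variance statistic
#' \deqn{z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' where \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}, with a two-sided normal
#' p-value and no continuity correction. When the pooled proportion is 0 or
#' 1 the variance vanishes; the difference is still reported but `z` is
#' undefined and `p_value` is 1, flagged as degenerate.
#'
#' @param x1,n1 Successes and size in the first sample.
#' @param x2,n2 Successes and size in the second sample.
#' @return List: `difference` (p1 - p2), `z`, `p_value`, `degenerate`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    return(list(difference = p1 - p2, z = NA_real_, p_value = 1,
                degenerate = TRUE))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(difference = p1 - p2, z = z, p_value = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Rank keywords by query-vs-background prevalence difference
#'
#' For every keyword, compares its prevalence between the query and
#' background subsets with [two_proportion_z()], Bonferroni-adjusts over
#' the keywords actually tested, and ranks by signed prevalence difference
#' (descending). The two subset-defining keywords are excluded by default:
#' their contrast is degenerate by construction (the query term has
#' prevalence 1 vs 0, the anchor term 1 vs 1).
#'
#' @param matrix Annotation matrix.
#' @param keyword_set Keyword set supplying concept groups (matched by
#'   column name).
#' @param definition A [subset_definition()].
#' @param alpha Familywise significance level for the adjusted flag.
#' @param exclude_defining Drop the query/anchor keywords from the table
#'   and the adjustment family?
#' @return `data.frame` with one row per keyword: `keyword`, `group`,
#'   `n_query`, `x_query`, `p_query`, `n_background`, `x_background`,
#'   `p_background`, `difference`, `z`, `p_raw`, `p_bonferroni`,
#'   `significant`; ranked by `difference`.
#' @export
contrast_keywords <- function(matrix, keyword_set = default_keyword_set(),
                              definition = subset_definition(),
                              alpha = 0.05, exclude_defining = TRUE) {
  keyword_set <- as_keyword_set(keyword_set)
  subsets <- split_subsets(matrix, definition)
  n1 <- length(subsets$query)
  n2 <- length(subsets$background)
  if (n1 == 0L || n2 == 0L) {
    stop("empty ", if (n1 == 0L) "query" else "background",
         " subset; the contrast is undefined", call. = FALSE)
  }
  labels <- colnames(matrix)
  if (exclude_defining) {
    labels <- setdiff(labels, c(definition$query_term,
                                definition$anchor_term))
  }
  dense <- as.matrix(matrix[, labels, drop = FALSE]) > 0
  x1 <- colSums(dense[subsets$query, , drop = FALSE])
  x2 <- colSums(dense[subsets$background, , drop = FALSE])
  tests <- lapply(seq_along(labels),
                  function(k) two_proportion_z(x1[k], n1, x2[k], n2))
  m <- length(labels)
  p_raw <- vapply(tests, `[[`, numeric(1L), "p_value")
  out <- data.frame(
    keyword = labels,
    group = keyword_set$group[match(labels, keyword_set$label)],
    n_query = n1, x_query = as.integer(x1), p_query = x1 / n1,
    n_background = n2, x_background = as.integer(x2),
    p_background = x2 / n2,
    difference = vapply(tests, `[[`, numeric(1L), "difference"),
    z = vapply(tests, `[[`, numeric(1L), "z"),
    p_raw = p_raw,
    p_bonferroni = pmin(1, m * p_raw),
    stringsAsFactors = FALSE)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(-out$difference), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contrast table as TSV
#'
#' @param contrast Result of [contrast_keywords()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  write.table(contrast, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
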