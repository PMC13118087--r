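#' 2x2 contingency tables for keyword pairs
#'
#' @param n11 Documents containing both keywords.
#' @param n10 Documents containing only the first.
#' @param n01 Documents containing only the second.
#' @param n00 Documents containing neither.
#' @return Object of class `contingency_2x2` with the four cells and the
#'   derived margins `r1`, `r0`, `c1`, `c0` and total `n`.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 r1 = n11 + n10, r0 = n01 + n00,
                 c1 = n11 + n01, c0 = n10 + n00,
                 n = n11 + n10 + n01 + n00),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2L, 2L,
              dimnames = list(first = c("present", "absent"),
                              second = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Tally the co-occurrence table of two keywords
#'
#' @param matrix Annotation matrix from [annotate()].
#' @param keyword_i,keyword_j Column names or indices; must differ.
#' @return A [contingency_table()] over all documents of the matrix.
#' @export
build_contingency <- function(matrix, keyword_i, keyword_j) {
  ci <- if (is.character(keyword_i)) match(keyword_i, colnames(matrix))
        else as.integer(keyword_i)
  cj <- if (is.character(keyword_j)) match(keyword_j, colnames(matrix))
        else as.integer(keyword_j)
  if (is.na(ci) || is.na(cj)) {
    stop("unknown keyword column: ",
         paste(c(keyword_i, keyword_j)[is.na(c(ci, cj))], collapse = ", "),
         call. = FALSE)
  }
  if (ci == cj) stop("self-pair: a keyword cannot be tabulated against ",
                     "itself", call. = FALSE)
  a <- as.numeric(matrix[, ci]) > 0
  b <- as.numeric(matrix[, cj]) > 0
  contingency_table(n11 = sum(a & b), n10 = sum(a & !b),
                    n01 = sum(!a & b), n00 = sum(!a & !b))
}

# Vectorised workhorses over parallel cell vectors. Degenerate entries
# (a zero margin) yield NA.
phi_from_cells <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; r0 <- n01 + n00; c1 <- n11 + n01; c0 <- n10 + n00
  denom <- sqrt(as.numeric(r1) * r0 * c1 * c0)
  out <- (as.numeric(n11) * n00 - as.numeric(n10) * n01) / denom
  out[denom == 0] <- NA_real_
  out
}

chisq_from_cells <- function(n11, n10, n01, n00) {
  n <- as.numeric(n11 + n10 + n01 + n00)
  r1 <- n11 + n10; r0 <- n01 + n00; c1 <- n11 + n01; c0 <- n10 + n00
  e11 <- as.numeric(r1) * c1 / n; e10 <- as.numeric(r1) * c0 / n
  e01 <- as.numeric(r0) * c1 / n; e00 <- as.numeric(r0) * c0 / n
  stat <- (n11 - e11)^2 / e11 + (n10 - e10)^2 / e10 +
    (n01 - e01)^2 / e01 + (n00 - e00)^2 / e00
  stat[r1 == 0 | r0 == 0 | c1 == 0 | c0 == 0] <- NA_real_
  stat
}

#' The phi coefficient of a 2x2 table
#'
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{r_1 r_0 c_1 c_0},}
#' the Pearson correlation of the two binary indicators, in \[-1, 1\].
#' When any margin is zero (one indicator is constant) the correlation is
#' undefined and `NA` is returned with a `degenerate_reason` attribute.
#'
#' @param table A [contingency_table()].
#' @return Numeric scalar, or `NA` for a degenerate table.
#' @export
phi_coefficient <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (min(table$r1, table$r0, table$c1, table$c0) == 0) {
    return(structure(NA_real_,
                     degenerate_reason = "zero margin: constant indicator"))
  }
  phi_from_cells(table$n11, table$n10, table$n01, table$n00)
}

#' Choose the independence test for a 2x2 table
#'
#' The Pearson chi-squared test is used when every cell holds at least
#' `min_cell` documents; otherwise Fisher's exact test, which remains valid
#' at small counts. Tables with a zero margin admit no test.
#'
#' @param table A [contingency_table()].
#' @param min_cell Minimum cell count for the chi-squared branch
#'   (default 5).
#' @return One of `"chi_squared"`, `"fisher_exact"`, `"degenerate"`.
#' @export
select_test <- function(table, min_cell = 5L) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (min(table$r1, table$r0, table$c1, table$c0) == 0) return("degenerate")
  if (min(table$n11, table$n10, table$n01, table$n00) >= min_cell)
    "chi_squared" else "fisher_exact"
}

#' Pearson chi-squared test of independence (2x2, no continuity correction)
#'
#' Computes \eqn{\sum (O-E)^2/E} over the four cells with expected counts
#' from the margins, and a p-value from the chi-squared distribution with
#' one degree of freedom. On a 2x2 table the statistic equals
#' \eqn{N \phi^2}.
#'
#' @param table A [contingency_table()].
#' @return List: `statistic`, `p_value`, `degenerate`.
#' @export
chi_squared_test <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  stat <- chisq_from_cells(table$n11, table$n10, table$n01, table$n00)
  if (is.na(stat)) {
    return(list(statistic = NA_real_, p_value = 1, degenerate = TRUE))
  }
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Fisher's exact test (two-sided, minimum-likelihood rule)
#'
#' With margins fixed, `n11` follows a hypergeometric law. The two-sided
#' p-value sums the point probabilities of every table whose probability
#' does not exceed that of the observed table, ties being accepted within
#' a relative tolerance of 1e-7 (different two-sided conventions exist;
#' this is the common minimum-likelihood one, as in `stats::fisher.test`).
#'
#' @param table A [contingency_table()].
#' @return List: `p_value`, `degenerate`.
#' @export
fisher_exact_test <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (min(table$r1, table$r0, table$c1, table$c0) == 0) {
    return(list(p_value = 1, degenerate = TRUE))
  }
  support <- max(0L, table$r1 - table$c0):min(table$r1, table$c1)
  probs <- dhyper(support, m = table$c1, n = table$c0, k = table$r1)
  obs <- probs[match(table$n11, support)]
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  list(p_value = min(1, p), degenerate = FALSE)
}

#' Holm step-down adjustment
#'
#' Sorts the m raw p-values ascending, multiplies the k-th smallest by
#' (m - k + 1), enforces monotonicity with a running maximum, caps at 1,
#' and maps the result back to the input order. Controls the familywise
#' error rate; uniformly no larger than the Bonferroni adjustment.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` entries are
#'   passed through and do not count towards m).
#' @return Adjusted values, same length and order as `p`.
#' @export
holm_adjust <- function(p) {
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(q)
  pv <- p[ok]
  ord <- order(pv)
  stepped <- pmin(1, cummax((m - seq_len(m) + 1) * pv[ord]))
  q[ok][ord] <- stepped
  q
}

#' All-pairs keyword association network
#'
#' Builds the 2x2 co-occurrence table of every unordered keyword pair over
#' the full annotation matrix, computes the phi coefficient, tests
#' independence with the chi-squared/Fisher selection rule, adjusts the raw
#' p-values over the family of all non-degenerate pairs, and masks cells
#' that fail the adjusted threshold. Keywords are ordered by concept group
#' so the phi matrix displays the panel block structure (outcomes,
#' pathologies, old age, trauma controls, metabolic terms).
#'
#' @param matrix Annotation matrix with at least two keyword columns.
#' @param keyword_set Keyword set supplying group order (matched by column
#'   name; unknown columns keep their position at the end).
#' @param alpha Significance threshold on the adjusted values.
#' @param correction `"holm"` (default), `"bh"` or `"bonferroni"`.
#' @param min_cell Cell-count threshold of [select_test()].
#' @param mask_on Mask cells on the adjusted `"q"` (default) or the raw
#'   `"p"` values.
#' @return Object of class `association_network`: `results` (long-form
#'   `data.frame`: `keyword_i`, `keyword_j`, cells, `phi`, `test_used`,
#'   `p_raw`, `q`, `significant`), symmetric matrices `phi`, `p`, `q`, the
#'   logical `mask` of significant cells, and the call parameters.
#' @export
association_network <- function(matrix, keyword_set = default_keyword_set(),
                                alpha = 0.05,
                                correction = c("holm", "bh", "bonferroni"),
                                min_cell = 5L,
                                mask_on = c("q", "p")) {
  correction <- match.arg(correction)
  mask_on <- match.arg(mask_on)
  keyword_set <- as_keyword_set(keyword_set)
  if (ncol(matrix) < 2L) stop("need at least two keywords", call. = FALSE)

  grp <- factor(keyword_set$group[match(colnames(matrix),
                                        keyword_set$label)],
                levels = keyword_group_levels())
  ord <- order(grp, seq_len(ncol(matrix)), na.last = TRUE)
  labels <- colnames(matrix)[ord]

  dense <- as.matrix(matrix[, ord, drop = FALSE]) > 0
  storage.mode(dense) <- "double"
  n_docs <- nrow(dense)
  co <- crossprod(dense)                     # n11 for every pair
  s <- diag(co)                              # per-keyword document counts

  k <- length(labels)
  pair <- which(upper.tri(co), arr.ind = TRUE)
  i <- pair[, 1L]; j <- pair[, 2L]
  n11 <- co[pair]
  n10 <- s[i] - n11
  n01 <- s[j] - n11
  n00 <- n_docs - n11 - n10 - n01

  phi <- phi_from_cells(n11, n10, n01, n00)
  r1 <- n11 + n10; r0 <- n01 + n00; c1 <- n11 + n01; c0 <- n10 + n00
  degenerate <- pmin(r1, r0, c1, c0) == 0
  min_c <- pmin(n11, n10, n01, n00)
  test_used <- ifelse(degenerate, "degenerate",
                      ifelse(min_c >= min_cell, "chi_squared",
                             "fisher_exact"))

  p_raw <- rep(NA_real_, length(n11))
  chi_idx <- which(test_used == "chi_squared")
  if (length(chi_idx) > 0L) {
    stat <- chisq_from_cells(n11[chi_idx], n10[chi_idx], n01[chi_idx],
                             n00[chi_idx])
    p_raw[chi_idx] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  for (idx in which(test_used == "fisher_exact")) {
    p_raw[idx] <- fisher_exact_test(
      contingency_table(n11[idx], n10[idx], n01[idx], n00[idx]))$p_value
  }

  q <- switch(correction,
              holm = holm_adjust(p_raw),
              bh = {
                out <- rep(NA_real_, length(p_raw))
                out[!is.na(p_raw)] <- p.adjust(p_raw[!is.na(p_raw)],
                                               method = "BH")
                out
              },
              bonferroni = pmin(1, sum(!is.na(p_raw)) * p_raw))
  crit <- if (mask_on == "q") q else p_raw
  significant <- !is.na(crit) & crit < alpha

  results <- data.frame(
    keyword_i = labels[i], keyword_j = labels[j],
    n11 = as.integer(n11), n10 = as.integer(n10),
    n01 = as.integer(n01), n00 = as.integer(n00),
    phi = phi, test_used = test_used, p_raw = p_raw, q = q,
    significant = significant, stringsAsFactors = FALSE)

  sym <- function(values, diag_value = NA_real_) {
    m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
    m[cbind(i, j)] <- values
    m[cbind(j, i)] <- values
    diag(m) <- diag_value
    m
  }
  mask <- sym(as.numeric(significant), diag_value = 0) > 0
  structure(list(results = results,
                 phi = sym(phi), p = sym(p_raw), q = sym(q),
                 mask = mask,
                 keywords = labels,
                 groups = as.character(grp)[ord],
                 n_documents = n_docs,
                 alpha = alpha, correction = correction,
                 min_cell = min_cell, mask_on = mask_on),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  n_pairs <- nrow(x$results)
  n_sig <- sum(x$results$significant)
  cat("Keyword association network\n")
  cat("  documents:", x$n_documents, " keywords:", length(x$keywords), "\n")
  cat("  pairs tested: ", sum(x$results$test_used != "degenerate"),
      " of ", n_pairs, "; significant (", x$correction, ", alpha ",
      x$alpha, "): ", n_sig, "\n", sep = "")
  invisible(x)
}

#' Significance-masked phi matrix
#'
#' Returns the symmetric phi matrix with non-significant cells set to `NA`
#' (rendered blank in heatmaps), in concept-group panel order.
#'
#' @param network An [association_network()] result.
#' @return Numeric matrix.
#' @export
masked_phi <- function(network) {
  stopifnot(inherits(network, "association_network"))
  out <- network$phi
  out[!network$mask] <- NA_real_
  diag(out) <- NA_real_
  out
}

#' Write association results to disk
#'
#' Writes the long-form pair table as TSV and, optionally, the square phi
#' and q matrices as CSV next to it.
#'
#' @param network An [association_network()] result.
#' @param prefix Output path prefix; files `<prefix>_pairs.tsv`,
#'   `<prefix>_phi.csv`, `<prefix>_q.csv` are produced.
#' @return Character vector of the paths written, invisibly.
#' @export
write_association <- function(network, prefix) {
  stopifnot(inherits(network, "association_network"))
  paths <- c(pairs = paste0(prefix, "_pairs.tsv"),
             phi = paste0(prefix, "_phi.csv"),
             q = paste0(prefix, "_q.csv"))
  write.table(network$results, paths[["pairs"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(network$phi, paths[["phi"]])
  write.csv(network$q, paths[["q"]])
  invisible(paths)
}
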