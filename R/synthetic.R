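#' Neutral filler vocabulary for synthetic abstracts
#'
#' Words used to pad generated abstracts to a valid length. The generator
#' verifies at configuration time that no filler word fires any keyword
#' matcher and that none equals a component word of any phrase pattern, so
#' keyword presence in a synthetic abstract is controlled solely by the
#' latent-class draws.
#'
#' @return Character vector of lowercase words.
#' @export
default_filler_vocabulary <- function() {
  c("the", "of", "in", "with", "for", "was", "were", "between",
    "cohort", "clinical", "registry", "baseline", "followup", "measurement",
    "evaluation", "assessment", "protocol", "sample", "method", "design",
    "result", "pattern", "estimate", "variance", "random", "signal",
    "model", "context", "factor", "survey", "population", "subjects",
    "groups", "levels", "values", "rates", "trends", "effects", "analysis",
    "screening")
}

# fixed scaffold words used to frame every generated abstract; validated
# against the matchers together with the filler vocabulary
generator_scaffold <- function() {
  c("this", "record", "reports", "routine", "observations", "among",
    "participants", "and")
}

#' Define one latent class of the corpus generator
#'
#' @param weight Mixture weight of the class.
#' @param theta Named numeric vector of per-keyword inclusion
#'   probabilities in \[0, 1\]; keywords not named get probability 0.
#' @return Object of class `latent_class`.
#' @export
latent_class <- function(weight, theta = numeric()) {
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0,
            is.numeric(theta), all(theta >= 0 & theta <= 1))
  if (length(theta) > 0L && is.null(names(theta))) {
    stop("theta must be named by keyword label", call. = FALSE)
  }
  structure(list(weight = weight, theta = theta), class = "latent_class")
}

#' Configure the latent-class corpus generator
#'
#' Each synthetic document first draws a hidden class from the mixture
#' weights, then includes each keyword independently with that class's
#' inclusion probability. Included keywords are realised once as their
#' canonical surface form, separated by neutral filler so that no
#' unintended phrase can assemble across insertions, and the abstract is
#' padded with filler words to a valid length ending in a period. Because
#' keywords are conditionally independent given the class, all marginal and
#' pairwise moments are available in closed form ([analytic_moments()]).
#'
#' @param classes List of [latent_class()] objects; weights must sum to 1.
#' @param n_documents Number of documents to generate.
#' @param seed Integer RNG seed (default 0); sampling is reproducible and
#'   leaves the caller's RNG state untouched.
#' @param length_range Inclusive abstract length bounds (characters);
#'   default `c(250, 4000)` matching the default cleaning filters.
#' @param filler_vocabulary Neutral padding words; checked against the
#'   keyword matchers.
#' @param keyword_set Keyword set the generator plants; default
#'   [default_keyword_set()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(classes, n_documents, seed = 0L,
                             length_range = c(250L, 4000L),
                             filler_vocabulary = default_filler_vocabulary(),
                             keyword_set = default_keyword_set()) {
  stopifnot(is.list(classes), length(classes) >= 1L,
            all(vapply(classes, inherits, logical(1L), "latent_class")),
            length(n_documents) == 1L, n_documents >= 0,
            length(length_range) == 2L, length_range[1L] > 0,
            length_range[1L] < length_range[2L])
  keyword_set <- as_keyword_set(keyword_set)
  weights <- vapply(classes, `[[`, numeric(1L), "weight")
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("class weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  }
  theta <- matrix(0, nrow = nrow(keyword_set), ncol = length(classes),
                  dimnames = list(keyword_set$label, NULL))
  for (c_idx in seq_along(classes)) {
    th <- classes[[c_idx]]$theta
    unknown <- setdiff(names(th), keyword_set$label)
    if (length(unknown) > 0L) {
      stop("theta names not in the keyword set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    theta[names(th), c_idx] <- th
  }

  # filler safety: no filler/scaffold word may fire a matcher or equal a
  # phrase component word (which could complete a phrase across junctions)
  vocab <- unique(c(tolower(filler_vocabulary), generator_scaffold()))
  matchers <- lapply(keyword_set$pattern, compile_matcher)
  components <- unique(unlist(lapply(matchers, `[[`, "words")))
  for (m in matchers) {
    bad <- vocab[keyword_detect(m, vocab)]
    if (length(bad) > 0L) {
      stop("filler word(s) collide with keyword '", m$pattern, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad <- intersect(vocab, components)
  if (length(bad) > 0L) {
    stop("filler word(s) equal phrase component words: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # worst case: every keyword surface in one abstract must still fit
  max_base <- nchar(paste(keyword_set$surface, collapse = " and ")) + 60L
  if (max_base > length_range[2L]) {
    stop("infeasible length constraints: all keyword surfaces together ",
         "need ~", max_base, " characters but max length is ",
         length_range[2L], call. = FALSE)
  }
  structure(list(classes = classes, weights = weights, theta = theta,
                 n_documents = as.integer(n_documents),
                 seed = as.integer(seed),
                 length_range = as.integer(length_range),
                 filler_vocabulary = tolower(filler_vocabulary),
                 keyword_set = keyword_set),
            class = "generator_config")
}

# run code under a fixed seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Closed-form moments of a generator configuration
#'
#' Under the latent-class law, the marginal prevalence of keyword k is
#' \eqn{p_k = \sum_c \pi_c \theta_{kc}}, the pairwise joint is
#' \eqn{p_{11}(i,j) = \sum_c \pi_c \theta_{ic} \theta_{jc}}, and the
#' population phi coefficient follows as
#' \eqn{(p_{11} - p_i p_j)/\sqrt{p_i(1-p_i)\,p_j(1-p_j)}}. With a single
#' class, keywords are independent and every analytic phi is exactly 0.
#' Keywords with prevalence 0 or 1 have undefined phi (`NA`).
#'
#' These are the moments of the planted indicator draws. Textual nesting
#' (e.g. the surface "hip fracture" also contains the token "fracture")
#' can push the *annotated* prevalence of a container keyword above its
#' planted marginal; the moments match annotation exactly when no keyword's
#' surface contains another keyword's pattern.
#'
#' @param config A [generator_config()].
#' @return Object of class `analytic_moments`: named vector `p`, symmetric
#'   matrices `p11` and `phi`.
#' @export
analytic_moments <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  theta <- config$theta
  w <- config$weights
  p <- as.vector(theta %*% w)
  names(p) <- rownames(theta)
  p11 <- theta %*% (w * t(theta))
  v <- p * (1 - p)
  phi <- (p11 - outer(p, p)) / sqrt(outer(v, v))
  phi[outer(v, v) == 0] <- NA_real_
  diag(phi) <- NA_real_
  structure(list(p = p, p11 = p11, phi = phi), class = "analytic_moments")
}

# draw latent classes and keyword inclusion indicators; shared by the two
# sampling fronts
draw_indicators <- function(config) {
  n <- config$n_documents
  k <- nrow(config$theta)
  z <- sample.int(length(config$weights), n, replace = TRUE,
                  prob = config$weights)
  u <- matrix(runif(n * k), nrow = n, ncol = k)
  inc <- u < t(config$theta)[z, , drop = FALSE]
  dimnames(inc) <- list(NULL, rownames(config$theta))
  list(z = z, inc = inc)
}

#' Sample a synthetic corpus
#'
#' Realises the generator configuration as full document records whose
#' abstracts contain exactly the planted keyword surfaces (plus neutral
#' filler), have lengths within the configured range, and end in a period
#' -- i.e. they pass [clean_corpus()] with matching settings by
#' construction. Two calls with the same configuration produce identical
#' corpora.
#'
#' @param config A [generator_config()].
#' @return A corpus `data.frame` with `doc_id` `"syn000001"` ... and a
#'   class-indexed synthetic journal name per document.
#' @export
sample_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    drawn <- draw_indicators(config)
    n <- config$n_documents
    surfaces <- config$keyword_set$surface
    min_len <- config$length_range[1L]
    max_len <- config$length_range[2L]

    # shared filler text, cut at word boundaries for per-document padding
    pad_words <- sample(config$filler_vocabulary, 2000L, replace = TRUE)
    pad_full <- paste(pad_words, collapse = " ")
    cut_points <- cumsum(nchar(pad_words) + 1L) - 1L  # word-end offsets

    jitter <- floor(runif(n, 0, min(200L, max_len - min_len)))
    years <- sample(1990:2025, n, replace = TRUE)

    abstracts <- vapply(seq_len(n), function(d) {
      kws <- surfaces[drawn$inc[d, ]]
      body <- if (length(kws) == 0L) "routine observations" else
        paste(kws, collapse = " and ")
      base <- paste("this record reports", body, "among participants")
      target <- min(min_len + jitter[d], max_len - 2L)
      deficit <- target - nchar(base) - 1L
      if (deficit > 0L) {
        idx <- findInterval(deficit - 1L, cut_points) + 1L
        base <- paste(base, substr(pad_full, 1L, cut_points[min(
          idx, length(cut_points))]))
      }
      paste0(base, ".")
    }, character(1L))

    too_long <- nchar(abstracts) > max_len
    if (any(too_long)) {
      stop("infeasible length constraints: ", sum(too_long),
           " generated abstract(s) exceed max length", call. = FALSE)
    }
    as_document_corpus(data.frame(
      doc_id = sprintf("syn%06d", seq_len(n)),
      title = sprintf("Synthetic record %d", seq_len(n)),
      abstract = abstracts,
      year = years,
      journal = paste("Synthetic Journal", LETTERS[drawn$z]),
      stringsAsFactors = FALSE))
  })
}

#' Sample keyword indicators directly (no text realisation)
#'
#' Draws the binary documents-by-keywords matrix straight from the
#' latent-class law, skipping abstract assembly and matching. For keyword
#' sets without textual nesting this is distributed identically to
#' `annotate(sample_corpus(config))` and is the fast path for large
#' simulation studies (e.g. null calibration over many replicate corpora).
#'
#' @param config A [generator_config()].
#' @return Sparse binary `Matrix::dgCMatrix` as returned by [annotate()].
#' @export
sample_annotation <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    drawn <- draw_indicators(config)
    mat <- Matrix::Matrix(drawn$inc * 1, sparse = TRUE)
    dimnames(mat) <- list(sprintf("syn%06d", seq_len(config$n_documents)),
                          rownames(config$theta))
    mat
  })
}

#' A packaged fragility-fracture study scenario
#'
#' Four latent classes emulating the qualitative structure of the
#' fracture literature: an orthogeriatric class (fragility and fracture
#' always present as separate tokens, osteoporosis planted at prevalence
#' 0.50, elevated OFS pathologies and old-age terms), a trauma class
#' (fracture always present without fragility, osteoporosis 0.10, elevated
#' sport/athlete/trauma terms), a metabolic-syndrome class, and a large
#' neutral background. Fracture-containing keywords are disabled outside
#' the two fracture classes so that query/background membership is decided
#' by the planted classes alone; the planted osteoporosis contrast is
#' therefore exactly 0.50 vs 0.10 between the fragility-fracture query set
#' and the other-fracture background set, and osteoporosis carries the
#' largest planted prevalence difference of any keyword.
#'
#' @param n_documents Corpus size.
#' @param seed RNG seed.
#' @return A [generator_config()].
#' @export
make_ofs_scenario <- function(n_documents, seed = 0L) {
  ofs <- latent_class(0.10, c(
    "fragility" = 1, "fracture" = 1, "fragility fracture" = 0.30,
    "hip fracture" = 0.35, "femur fracture" = 0.15, "spine fracture" = 0.20,
    "osteoporosis" = 0.50, "sarcopenia" = 0.25, "malnutrition" = 0.20,
    "gait" = 0.25, "fall" = 0.30, "frail" = 0.30,
    "cognitive impairment" = 0.20,
    "older adult" = 0.25, "elderl*" = 0.35, "geriatr*" = 0.30,
    "sport" = 0.02, "athlet*" = 0.02, "trauma" = 0.10, "young" = 0.05,
    "high-energy" = 0.02,
    "stroke" = 0.05, "infarction" = 0.05, "heart failure" = 0.05,
    "heart attack" = 0.05, "insulin resistance" = 0.05, "obesity" = 0.05,
    "hypertension" = 0.05, "diabetes" = 0.05))
  trauma <- latent_class(0.15, c(
    "fracture" = 1,
    "hip fracture" = 0.15, "femur fracture" = 0.10, "spine fracture" = 0.10,
    "osteoporosis" = 0.10, "sarcopenia" = 0.05, "malnutrition" = 0.05,
    "gait" = 0.05, "fall" = 0.05, "frail" = 0.05,
    "cognitive impairment" = 0.05,
    "older adult" = 0.05, "elderl*" = 0.05, "geriatr*" = 0.05,
    "sport" = 0.35, "athlet*" = 0.30, "trauma" = 0.60, "young" = 0.30,
    "high-energy" = 0.25,
    "stroke" = 0.05, "infarction" = 0.05, "heart failure" = 0.05,
    "heart attack" = 0.05, "insulin resistance" = 0.05, "obesity" = 0.05,
    "hypertension" = 0.05, "diabetes" = 0.05))
  metabolic <- latent_class(0.15, c(
    "sarcopenia" = 0.03, "malnutrition" = 0.03, "gait" = 0.03,
    "fall" = 0.03, "frail" = 0.03, "cognitive impairment" = 0.03,
    "osteoporosis" = 0.03,
    "older adult" = 0.08, "elderl*" = 0.08, "geriatr*" = 0.08,
    "sport" = 0.02, "athlet*" = 0.02, "trauma" = 0.02, "young" = 0.02,
    "high-energy" = 0.02,
    "stroke" = 0.35, "infarction" = 0.30, "heart failure" = 0.30,
    "heart attack" = 0.20, "insulin resistance" = 0.25, "obesity" = 0.40,
    "hypertension" = 0.45, "diabetes" = 0.50))
  nonfrac <- c("osteoporosis", "sarcopenia", "malnutrition", "gait",
               "fall", "frail", "cognitive impairment", "older adult",
               "elderl*", "geriatr*", "sport", "athlet*", "trauma",
               "young", "high-energy", "stroke", "infarction",
               "heart failure", "heart attack", "insulin resistance",
               "obesity", "hypertension", "diabetes")
  background <- latent_class(0.60, setNames(rep(0.02, length(nonfrac)),
                                            nonfrac))
  generator_config(classes = list(ofs, trauma, metabolic, background),
                   n_documents = n_documents, seed = seed)
}

#' Export analytic moments as a long table
#'
#' @param moments An [analytic_moments()] result.
#' @return `data.frame` with one row per unordered keyword pair:
#'   `keyword_i`, `keyword_j`, `p_i`, `p_j`, `p11`, `phi_analytic`.
#' @export
moments_table <- function(moments) {
  stopifnot(inherits(moments, "analytic_moments"))
  labels <- names(moments$p)
  pair <- which(upper.tri(moments$p11), arr.ind = TRUE)
  data.frame(keyword_i = labels[pair[, 1L]],
             keyword_j = labels[pair[, 2L]],
             p_i = moments$p[pair[, 1L]],
             p_j = moments$p[pair[, 2L]],
             p11 = moments$p11[pair],
             phi_analytic = moments$phi[pair],
             row.names = NULL, stringsAsFactors = FALSE)
}
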