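Package: litcooc
Title: Keyword Co-Occurrence Analysis of Bibliographic Abstract Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining binary keyword presence patterns in large
    collections of scientific abstracts. Reads MEDLINE/PubMed citation XML or
    line-delimited record files, applies standard corpus cleaning filters
    (missing abstracts, abstract length bounds, terminal sentence
    punctuation), annotates documents against a curated keyword taxonomy with
    exact-token, prefix-wildcard and phrase matching, and quantifies keyword
    structure two ways: prevalence contrasts between a query and a background
    document subset using pooled two-proportion z-tests with Bonferroni
    adjustment, and all-pairs binary association via the phi coefficient with
    Pearson chi-squared or Fisher's exact testing and Holm step-down
    adjustment. A latent-class synthetic corpus generator with closed-form
    marginal and pairwise moments provides ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
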