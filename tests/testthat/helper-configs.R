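# Two equi-weighted classes, two non-nested keywords at 0.9/0.1 inclusion:
# marginals 0.5, joint 0.41, analytic phi exactly 0.64.
two_class_config <- function(n, seed = 0L) {
  generator_config(
    classes = list(
      latent_class(0.5, c(osteoporosis = 0.9, sarcopenia = 0.9)),
      latent_class(0.5, c(osteoporosis = 0.1, sarcopenia = 0.1))),
    n_documents = n, seed = seed)
}

# Single class, independent keywords: every analytic phi is zero.
null_config <- function(n, seed = 0L, p = 0.2,
                        labels = default_keyword_set()$label) {
  generator_config(
    classes = list(latent_class(1, setNames(rep(p, length(labels)),
                                            labels))),
    n_documents = n, seed = seed)
}
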