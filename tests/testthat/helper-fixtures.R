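# Shared fixtures, all generated in code.

.fixture_env <- new.env(parent = emptyenv())

# Default 10-factor panel, generated once per test run.
test_panel <- function(gamma = 0.05) {
  key <- paste0("panel_", gamma)
  p <- .fixture_env[[key]]
  if (is.null(p)) {
    p <- generate_landscape_panel(n_tf = 10, gamma = gamma, seed = 42)
    .fixture_env[[key]] <- p
  }
  p
}

# A single small additive landscape (shape checks, conservation).
test_single_landscape <- function(n_binders = 300, epistasis_weight = 0.2,
                                  seed = 7) {
  params <- landscape_params(n_binders = n_binders,
                             epistasis_weight = epistasis_weight,
                             seed = seed)
  raw <- generate_raw_landscape(params)
  norm <- normalize(raw)
  list(raw = raw, norm = norm,
       table = specificity(norm, gamma = 0.05))
}

# Toy panel: n factors, all empty except named entries.
# binders: list indexed by factor giving a named kappa vector.
toy_panel <- function(n = 10, binders = list(), gamma = 0.05) {
  tabs <- lapply(seq_len(n), function(j) {
    k <- binders[[as.character(j)]]
    if (is.null(k)) k <- stats::setNames(numeric(0), character(0))
    specificity_from_binders(k, tf_id = paste0("TF", j), gamma = gamma)
  })
  panel_from_tables(tabs)
}

# Genotype with fully specified URRs and fixed metadata.
toy_genotype <- function(urrs, tf_signs = NULL, initial_state = NULL) {
  n <- length(urrs)
  if (is.null(tf_signs)) tf_signs <- rep(1L, n)
  if (is.null(initial_state)) initial_state <- rep(1, n)
  new_genotype(urrs, tf_signs, initial_state)
}

# G-only URR of length L (binder-free under toy panels that avoid Gs).
g_urr <- function(L) strrep("G", L)
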