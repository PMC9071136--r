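# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Six small, structurally varied molecules.
tiny_library <- function() {
  fixture("tiny_library", function() {
    suppressMessages(compound_set(
      c("benzene", "toluene", "ethanol", "aspirin", "pyridine", "butane"),
      c("c1ccccc1", "Cc1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O",
        "c1ccncc1", "CCCC")
    ))
  })
}

tiny_bundle <- function() {
  fixture("tiny_bundle", function() compute_fingerprints(tiny_library()))
}

tiny_descriptors <- function() {
  fixture("tiny_descriptors", function() compute_descriptors(tiny_library()))
}

# Small paper-like synthetic library (fast: 10 families x 4 members).
small_synth <- function() {
  fixture("small_synth", function() {
    cfg <- synth_config(n_families = 10, compounds_per_family = 4,
                        cross_family_target_prob = 0.02, seed = 42)
    suppressMessages(generate_library(cfg))
  })
}

# A labelled pair table for the small synthetic library.
small_synth_pairs <- function() {
  fixture("small_synth_pairs", function() {
    lib <- small_synth()
    suppressMessages(pair_feature_table(
      lib$compounds, enumerate_pairs(lib$compounds$id), targets = lib$targets))
  })
}

# Deterministic random Match/Nomatch matrix with a planted linear signal in
# the first column; used by learner tests.
planted_matrix <- function(n = 400, p = 6, beta = 3, prevalence = 0.3,
                           seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lin <- beta * X[, 1] + qlogis(prevalence)
  y <- ifelse(runif(n) < plogis(lin), "Match", "Nomatch")
  list(X = X, y = y)
}
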