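# Synthetic scaffold-family compound libraries with a planted target map.
#
# Each family is built from one of a small set of valid ring-system
# scaffold templates plus a family-specific core substituent; members of a
# family differ only in randomized peripheral decorations, so within-family
# pairs are structurally similar and share the family's protein targets.
# Cross-family target sharing is injected per family pair with a stated
# probability, which sets the Match prevalence of the paired dataset.

SCAFFOLD_TEMPLATES <- list(
  benzene        = "c1cc{A}cc{B}c1{C}",
  pyridine       = "c1cc{A}nc{B}c1{C}",
  pyrimidine     = "c1nc{A}nc{B}c1{C}",
  furan          = "c1cc{A}c{B}o1",
  thiophene      = "c1cc{A}c{B}s1",
  pyrrole        = "c1cc{A}c{B}[nH]1",
  cyclohexane    = "C1CC{A}CC{B}C1{C}",
  cyclopentane   = "C1CC{A}C{B}C1{C}",
  piperidine     = "C1CC{A}NC{B}C1{C}",
  oxolane        = "C1CC{A}C{B}O1",
  naphthalene    = "c1ccc2cc{A}cc{B}c2c1{C}",
  indole         = "c1ccc2[nH]c{A}c{B}c2c1{C}",
  benzofuran     = "c1ccc2oc{A}c{B}c2c1{C}",
  quinoline      = "c1ccc2nc{A}cc{B}c2c1{C}",
  morpholine     = "C1COC{A}CN1{C}",
  cyclohexene    = "C1=CC{A}CC{B}C1{C}"
)

CORE_SUBSTITUENTS <- c("(Cl)", "(Br)", "(F)", "(C(F)(F)F)", "(C#N)",
                       "(C(=O)O)", "(N)", "(O)", "(S)", "(CC)", "(C(C)C)",
                       "(OC)", "(C(=O)N)", "(CCO)", "(I)", "(C=C)",
                       "(CNC)", "(COC)", "(CCl)", "(C(=O)C)")
QUERY_CORE_SUBSTITUENTS <- c("(OCC)", "(NC(=O)C)", "(SC)", "(CBr)",
                             "(C(O)C)", "(CCC#N)", "(OC(=O)C)", "(CF)")
DECORATIONS <- c("", "(C)", "(CC)", "(O)", "(OC)", "(N)", "(F)", "(Cl)",
                 "(C(C)C)", "(CO)", "(C#N)", "(CCC)")

fill_scaffold <- function(template, a = "", b = "", core = "") {
  s <- gsub("{A}", a, template, fixed = TRUE)
  s <- gsub("{B}", b, s, fixed = TRUE)
  gsub("{C}", core, s, fixed = TRUE)
}

family_scaffold <- function(fam_idx) {
  tpl <- SCAFFOLD_TEMPLATES[[((fam_idx - 1) %% length(SCAFFOLD_TEMPLATES)) + 1]]
  core <- CORE_SUBSTITUENTS[((fam_idx - 1) %/% length(SCAFFOLD_TEMPLATES)) %%
                              length(CORE_SUBSTITUENTS) + 1]
  list(template = tpl, core = core,
       name = names(SCAFFOLD_TEMPLATES)[((fam_idx - 1) %% length(SCAFFOLD_TEMPLATES)) + 1])
}

decorate <- function(template, core, intensity) {
  slots <- list(a = "", b = "")
  n_slots <- min(intensity, 2L)
  if (n_slots >= 1) slots$a <- sample(DECORATIONS, 1)
  if (n_slots >= 2) slots$b <- sample(DECORATIONS, 1)
  fill_scaffold(template, slots$a, slots$b, core)
}

#' Synthetic library configuration
#'
#' Defaults emulate the classical drug-pair dataset's structure at desk
#' scale: 30 scaffold families of 5 compounds (150 compounds, 11,175
#' pairs) with a Match prevalence of about 0.03 — within-family pairs
#' supply `F * C(m, 2)` matches and cross-family target sharing at
#' probability 0.003 per family pair supplies the remainder (see
#' [expected_match_prevalence()]).
#'
#' @param n_families number of scaffold families.
#' @param compounds_per_family members per family.
#' @param targets_per_family targets carried by every family member.
#' @param cross_family_target_prob probability that a family pair shares
#'   an extra common target.
#' @param decoration_intensity substituent edits per compound (0-2).
#' @param seed integer seed; generation is fully deterministic.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_families = 30, compounds_per_family = 5,
                         targets_per_family = 2,
                         cross_family_target_prob = 0.003,
                         decoration_intensity = 2, seed = 1) {
  stopifnot(n_families >= 1, compounds_per_family >= 1,
            targets_per_family >= 1,
            cross_family_target_prob >= 0, cross_family_target_prob <= 1,
            decoration_intensity >= 0)
  structure(list(n_families = n_families,
                 compounds_per_family = compounds_per_family,
                 targets_per_family = targets_per_family,
                 cross_family_target_prob = cross_family_target_prob,
                 decoration_intensity = decoration_intensity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Expected Match prevalence of a synthetic configuration
#'
#' `[F * C(m,2) + p * C(F,2) * m^2] / C(F*m, 2)` with `F` families of `m`
#' compounds and cross-family sharing probability `p`.
#'
#' @param config a `synth_config`.
#' @return expected fraction of Match pairs.
#' @export
expected_match_prevalence <- function(config) {
  F_ <- config$n_families; m <- config$compounds_per_family
  p <- config$cross_family_target_prob
  n <- F_ * m
  within <- F_ * choose(m, 2)
  cross <- p * choose(F_, 2) * m^2
  (within + cross) / choose(n, 2)
}

#' Generate a synthetic compound library with a planted target map
#'
#' Builds `n_families` scaffold families, each from a distinct valid ring
#' system with randomized peripheral decorations; every member carries the
#' family's targets, and family pairs additionally share a target with
#' probability `cross_family_target_prob`. The truth table records each
#' compound's family so intended labels can be reconstructed exactly.
#'
#' @param config a [synth_config()].
#' @return list with `compounds` (a `compound_set` annotated with the
#'   scaffold `superclass`), `targets` (a `target_map`), and `truth`
#'   (data frame: id, family, scaffold).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    ids <- character(0); smiles <- character(0)
    fam <- integer(0); scaff <- character(0)
    for (f in seq_len(config$n_families)) {
      sc <- family_scaffold(f)
      for (m in seq_len(config$compounds_per_family)) {
        id <- sprintf("F%02dC%02d", f, m)
        smi <- NA_character_
        for (try in 1:20) {
          cand <- decorate(sc$template, sc$core, config$decoration_intensity)
          canon <- canonical_smiles(cand)
          if (!is.na(canon)) { smi <- canon; break }
          message("scaffold retry for ", id, " (attempt ", try, ")")
        }
        if (is.na(smi)) stop("could not construct a valid member for family ", f)
        ids <- c(ids, id); smiles <- c(smiles, smi)
        fam <- c(fam, f); scaff <- c(scaff, sc$name)
      }
    }
    compounds <- compound_set(ids, smiles,
                              annotations = data.frame(superclass = scaff))
    # family targets
    cid <- character(0); tid <- character(0)
    for (f in seq_len(config$n_families)) {
      fams_ids <- ids[fam == f]
      ts <- sprintf("T%02d_%s", f, letters[seq_len(config$targets_per_family)])
      cid <- c(cid, rep(fams_ids, each = length(ts)))
      tid <- c(tid, rep(ts, times = length(fams_ids)))
    }
    # cross-family shared targets
    if (config$n_families >= 2 && config$cross_family_target_prob > 0) {
      for (f in seq_len(config$n_families - 1)) {
        for (g in seq((f + 1), config$n_families)) {
          if (stats::runif(1) < config$cross_family_target_prob) {
            shared <- sprintf("X%02d_%02d", f, g)
            both <- ids[fam %in% c(f, g)]
            cid <- c(cid, both)
            tid <- c(tid, rep(shared, length(both)))
          }
        }
      }
    }
    targets <- target_map(cid, tid, compounds)
    truth <- data.frame(id = ids, family = fam, scaffold = scaff,
                        stringsAsFactors = FALSE)
    list(compounds = compounds, targets = targets, truth = truth)
  })
}

#' Generate a query library for screening against a reference
#'
#' A stated fraction of query compounds are fresh decorations of
#' reference-family scaffolds (planted positives sharing those families'
#' targets); the rest use query-only core substituents on the same ring
#' systems (planted negatives with no shared target). A few exact copies
#' of reference compounds are injected to exercise the near-duplicate
#' (> 0.9 Tanimoto) removal path.
#'
#' @param config the [synth_config()] used for the reference library.
#' @param reference the `generate_library()` output for that config.
#' @param n_query number of query compounds.
#' @param positive_fraction fraction decorated from reference scaffolds.
#' @param n_exact_copies exact reference copies to inject.
#' @return list with `compounds` (query `compound_set`) and `truth`
#'   (id, source_family (NA = novel), is_copy, copy_of).
#' @export
generate_screen_library <- function(config, reference, n_query = 40,
                                    positive_fraction = 0.3,
                                    n_exact_copies = 3) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 7919L, {
    n_pos <- round(n_query * positive_fraction)
    n_neg <- n_query - n_pos
    ids <- character(0); smiles <- character(0)
    src_fam <- integer(0); is_copy <- logical(0); copy_of <- character(0)
    for (q in seq_len(n_pos)) {
      f <- sample(config$n_families, 1)
      sc <- family_scaffold(f)
      smi <- NA_character_
      for (try in 1:20) {
        canon <- canonical_smiles(
          decorate(sc$template, sc$core, config$decoration_intensity))
        if (!is.na(canon)) { smi <- canon; break }
      }
      ids <- c(ids, sprintf("Q%03d", q)); smiles <- c(smiles, smi)
      src_fam <- c(src_fam, f); is_copy <- c(is_copy, FALSE)
      copy_of <- c(copy_of, NA_character_)
    }
    for (q in seq_len(n_neg)) {
      tpl_i <- sample(length(SCAFFOLD_TEMPLATES), 1)
      core <- sample(QUERY_CORE_SUBSTITUENTS, 1)
      smi <- NA_character_
      for (try in 1:20) {
        canon <- canonical_smiles(
          decorate(SCAFFOLD_TEMPLATES[[tpl_i]], core,
                   config$decoration_intensity))
        if (!is.na(canon)) { smi <- canon; break }
      }
      ids <- c(ids, sprintf("Q%03d", n_pos + q)); smiles <- c(smiles, smi)
      src_fam <- c(src_fam, NA_integer_); is_copy <- c(is_copy, FALSE)
      copy_of <- c(copy_of, NA_character_)
    }
    if (n_exact_copies > 0) {
      picks <- sample(reference$compounds$id, n_exact_copies)
      for (k in seq_len(n_exact_copies)) {
        rid <- picks[k]
        ids <- c(ids, sprintf("Q%03d", n_query + k))
        smiles <- c(smiles,
                    reference$compounds$smiles[reference$compounds$id == rid])
        src_fam <- c(src_fam,
                     reference$truth$family[reference$truth$id == rid])
        is_copy <- c(is_copy, TRUE)
        copy_of <- c(copy_of, rid)
      }
    }
    compounds <- compound_set(ids, smiles)
    truth <- data.frame(id = ids, source_family = src_fam,
                        is_copy = is_copy, copy_of = copy_of,
                        stringsAsFactors = FALSE)
    list(compounds = compounds, truth = truth)
  })
}
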