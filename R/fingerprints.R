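#' The seven fingerprint kinds
#'
#' Order matters: pair feature vectors carry one Tanimoto score per kind in
#' this order. `morgan` is the circular ECFP-like fingerprint (radius 2),
#' `featmorgan` its feature-typed FCFP-like variant, `atompair` the
#' topological atom-pair set, `path` a Daylight-like linear-path
#' fingerprint, `torsion` the topological-torsion fingerprint, `layered` a
#' multi-layer substructure path fingerprint, and `maccs` the 166-key
#' structural key set.
#'
#' @export
FP_KINDS <- c("morgan", "featmorgan", "atompair", "path", "torsion",
              "layered", "maccs")

FP_PARAMS <- list(
  morgan     = list(backend = "openbabel:ECFP4", radius = 2, nbits = 4096),
  featmorgan = list(backend = "native", radius = 2, nbits = 2048),
  atompair   = list(backend = "chemminer:ap", nbits = NA),
  path       = list(backend = "openbabel:FP2", max_path = 7, nbits = 1024),
  torsion    = list(backend = "native", path_atoms = 4, nbits = 2048),
  layered    = list(backend = "native", max_path = 5, layers = 4, nbits = 2048),
  maccs      = list(backend = "openbabel:MACCS", nbits = 256)
)

ob_fp_bits <- function(sdfset, name) {
  m <- ChemmineR::fingerprintOB(sdfset, name)@fpma
  lapply(seq_len(nrow(m)), function(i) which(m[i, ] != 0))
}

# --- native circular FCFP-like fingerprint ---------------------------------

# FCFP-style initial atom invariants: six pharmacophoric feature flags.
fcfp_invariants <- function(g) {
  hs <- implicit_h(g)
  don <- g$elem %in% c("N", "O", "S") & hs > 0
  acc <- g$elem %in% c("N", "O")
  halo <- g$elem %in% c("F", "Cl", "Br", "I")
  arom <- g$arom_atom
  # carboxylic/acidic oxygen: O bonded to a C that carries a double-bonded O
  acid <- rep(FALSE, g$n)
  basic <- rep(FALSE, g$n)
  if (nrow(g$bonds)) {
    for (a in seq_len(g$n)) {
      if (g$elem[a] == "O") {
        for (c_at in g$adj[[a]]) {
          if (g$elem[c_at] == "C") {
            dbl_o <- any(vapply(g$adj[[c_at]], function(x) {
              if (g$elem[x] != "O" || x == a) return(FALSE)
              k <- which((g$bonds[, 1] == c_at & g$bonds[, 2] == x) |
                           (g$bonds[, 2] == c_at & g$bonds[, 1] == x))
              length(k) > 0 && g$border[k[1]] == 2L
            }, logical(1)))
            if (dbl_o) acid[a] <- TRUE
          }
        }
      }
      if (g$elem[a] == "N" && !g$arom_atom[a]) {
        # basic N: aliphatic amine not adjacent to a carbonyl carbon
        amide <- any(vapply(g$adj[[a]], function(c_at) {
          g$elem[c_at] == "C" && any(vapply(g$adj[[c_at]], function(x) {
            k <- which((g$bonds[, 1] == c_at & g$bonds[, 2] == x) |
                         (g$bonds[, 2] == c_at & g$bonds[, 1] == x))
            g$elem[x] == "O" && length(k) > 0 && g$border[k[1]] == 2L
          }, logical(1)))
        }, logical(1)))
        basic[a] <- !amide
      }
    }
  }
  as.integer(don) * 32L + as.integer(acc) * 16L + as.integer(arom) * 8L +
    as.integer(halo) * 4L + as.integer(acid) * 2L + as.integer(basic)
}

# ECFP-style initial invariants used by the torsion/layered helpers.
atom_invariants <- function(g) {
  code <- match(g$elem, names(ATOMIC_MASS), nomatch = 0L)
  code * 64L + g$deg * 8L + as.integer(g$arom_atom) * 4L +
    pmin(implicit_h(g), 3L)
}

# Circular (Morgan-type) fingerprint over arbitrary initial invariants.
circular_bits <- function(g, inv, radius = 2, nbits = 2048) {
  feats <- inv
  cur <- inv
  if (radius > 0 && nrow(g$bonds)) {
    for (r in seq_len(radius)) {
      nxt <- integer(g$n)
      for (a in seq_len(g$n)) {
        nb <- g$adj[[a]]
        if (length(nb)) {
          ord <- vapply(nb, function(x) {
            k <- which((g$bonds[, 1] == a & g$bonds[, 2] == x) |
                         (g$bonds[, 2] == a & g$bonds[, 1] == x))
            g$border[k[1]]
          }, integer(1))
          env <- cbind(ord, cur[nb])
          env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
          nxt[a] <- hash_ints(c(r, cur[a], t(env)))
        } else {
          nxt[a] <- hash_ints(c(r, cur[a]))
        }
      }
      cur <- nxt
      feats <- c(feats, cur)
    }
  }
  sort(unique(feats %% nbits))
}

bond_order_between <- function(g, a, b) {
  k <- which((g$bonds[, 1] == a & g$bonds[, 2] == b) |
               (g$bonds[, 2] == a & g$bonds[, 1] == b))
  g$border[k[1]]
}

torsion_bits <- function(g, nbits = 2048) {
  inv <- atom_invariants(g)
  out <- integer(0)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      b <- g$bonds[k, 1]; c_at <- g$bonds[k, 2]
      for (a in setdiff(g$adj[[b]], c_at)) {
        for (d in setdiff(g$adj[[c_at]], b)) {
          if (a == d) next
          fwd <- c(inv[a], inv[b], inv[c_at], inv[d])
          rev <- rev(fwd)
          key <- if (paste(fwd, collapse = ",") <= paste(rev, collapse = ",")) fwd else rev
          out <- c(out, hash_ints(key))
        }
      }
    }
  }
  sort(unique(out %% nbits))
}

# Enumerate simple paths with up to max_len bonds starting at each atom.
simple_paths <- function(g, max_len = 5) {
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) >= 2 && path[1] < last) {
      paths[[length(paths) + 1]] <<- path
    }
    if (length(path) > max_len) return()
    for (w in g$adj[[last]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  for (s in seq_len(g$n)) walk(s)
  paths
}

layered_bits <- function(g, max_len = 5, nbits = 2048) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ecode <- match(g$elem, names(ATOMIC_MASS), nomatch = 0L)
  ring <- rep(FALSE, g$n)
  # ring atoms: those with degree >= 2 lying on a cycle; approximate with
  # aromatic flag OR membership in any SSSR ring via bond count heuristic
  ring <- g$arom_atom | vapply(seq_len(g$n), function(a) {
    length(g$adj[[a]]) >= 2 && g$ring_count > 0 && on_cycle(g, a)
  }, logical(1))
  out <- integer(0)
  for (p in simple_paths(g, max_len)) {
    orders <- vapply(seq_len(length(p) - 1),
                     function(i) bond_order_between(g, p[i], p[i + 1]),
                     integer(1))
    l1 <- hash_ints(c(1L, rbind(ecode[p], c(orders, 0L))))
    l2 <- hash_ints(c(2L, ecode[p]))
    l3 <- hash_ints(c(3L, g$deg[p] * 2L + as.integer(g$arom_atom[p])))
    l4 <- hash_ints(c(4L, rbind(as.integer(ring[p]), c(orders, 0L))))
    out <- c(out, l1, l2, l3, l4)
  }
  sort(unique(out %% nbits))
}

# Is atom a on a cycle? BFS from a neighbour back to a avoiding the direct edge.
on_cycle <- function(g, a) {
  for (b in g$adj[[a]]) {
    seen <- rep(FALSE, g$n); seen[a] <- TRUE
    queue <- setdiff(g$adj[[a]], b)
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v == b) return(TRUE)
      nb <- setdiff(g$adj[[v]], which(seen))
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (seen[b]) return(TRUE)
  }
  FALSE
}

#' Compute the seven-fingerprint bundle for a compound library
#'
#' Each compound receives all seven fingerprint kinds (see [FP_KINDS]); a
#' compound for which any kind fails is rejected with a reason rather than
#' carried with a partial bundle. Fingerprints are deterministic for a
#' fixed canonical structure and the pinned generation parameters.
#'
#' @param compounds a `compound_set`.
#' @param sdfset optional pre-parsed `SDFset` (computed if missing).
#' @return an `fp_bundle`: per kind, a named list of sorted integer
#'   feature-id vectors (set-of-bits representation); generation parameters
#'   in `attr(, "params")`; rejected compound ids in `attr(, "rejected")`.
#' @export
compute_fingerprints <- function(compounds, sdfset = NULL) {
  sdfset <- sdfset %||% as_sdfset(compounds)
  ids <- compounds$id
  graphs <- mol_graphs(compounds, sdfset)

  bundle <- list()
  bundle$morgan <- ob_fp_bits(sdfset, "ECFP4")
  bundle$path <- ob_fp_bits(sdfset, "FP2")
  bundle$maccs <- ob_fp_bits(sdfset, "MACCS")
  apset <- ChemmineR::sdf2ap(sdfset)
  bundle$atompair <- lapply(seq_along(ids), function(i) {
    sort(unique(as.numeric(ChemmineR::ap(apset[i])[[1]])))
  })

  native <- lapply(graphs, function(g) {
    tryCatch(list(
      featmorgan = circular_bits(g, fcfp_invariants(g),
                                 radius = FP_PARAMS$featmorgan$radius,
                                 nbits = FP_PARAMS$featmorgan$nbits),
      torsion = torsion_bits(g, nbits = FP_PARAMS$torsion$nbits),
      layered = layered_bits(g, max_len = FP_PARAMS$layered$max_path,
                             nbits = FP_PARAMS$layered$nbits)
    ), error = function(e) e)
  })
  failed <- vapply(native, inherits, logical(1), what = "error")
  if (any(failed)) {
    message(sum(failed), " compound(s) rejected during fingerprinting: ",
            paste(ids[failed], collapse = ", "))
  }
  keep <- which(!failed)
  bundle$featmorgan <- lapply(native[keep], `[[`, "featmorgan")
  bundle$torsion <- lapply(native[keep], `[[`, "torsion")
  bundle$layered <- lapply(native[keep], `[[`, "layered")
  for (k in c("morgan", "path", "maccs", "atompair")) {
    bundle[[k]] <- bundle[[k]][keep]
    names(bundle[[k]]) <- ids[keep]
  }
  for (k in c("featmorgan", "torsion", "layered")) names(bundle[[k]]) <- ids[keep]
  bundle <- bundle[FP_KINDS]
  structure(bundle, class = "fp_bundle", params = FP_PARAMS,
            ids = ids[keep], rejected = ids[failed])
}

#' @export
print.fp_bundle <- function(x, ...) {
  cat("<fp_bundle> ", length(attr(x, "ids")), " compounds x ",
      length(FP_KINDS), " fingerprint kinds\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two fingerprint sets
#'
#' `|A n B| / |A u B|` on the set-of-features representation. Defined as 0
#' (with a warning) when both sets are empty.
#'
#' @param fp_a,fp_b integer/numeric vectors of set feature ids, same
#'   fingerprint kind on both sides.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  inter <- length(intersect(fp_a, fp_b))
  uni <- length(fp_a) + length(fp_b) - inter
  if (uni == 0) {
    warning("Tanimoto of two empty fingerprints defined as 0")
    return(0)
  }
  inter / uni
}

#' Overlap coefficient of two feature sets
#'
#' `|A n B| / min(|A|, |B|)`; insensitive to size disparity. Defined as 0
#' (with a warning) when either set is empty.
#'
#' @inheritParams tanimoto
#' @return overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(fp_a, fp_b) {
  m <- min(length(fp_a), length(fp_b))
  if (m == 0) {
    warning("overlap coefficient with an empty fingerprint defined as 0")
    return(0)
  }
  length(intersect(fp_a, fp_b)) / m
}

# Pairwise Tanimoto matrix between two id sets for one kind, via dense
# incidence crossproduct (libraries are small enough for dense algebra).
tanimoto_matrix <- function(bundle, kind, ids_a, ids_b = ids_a) {
  stopifnot(kind %in% FP_KINDS)
  sets_a <- bundle[[kind]][ids_a]
  sets_b <- bundle[[kind]][ids_b]
  if (any(vapply(c(sets_a, sets_b), is.null, logical(1)))) {
    stop("fingerprints missing for some requested ids")
  }
  feats <- sort(unique(c(unlist(sets_a), unlist(sets_b))))
  inc <- function(sets) {
    m <- matrix(0L, length(sets), length(feats))
    for (i in seq_along(sets)) m[i, match(sets[[i]], feats)] <- 1L
    m
  }
  A <- inc(sets_a); B <- inc(sets_b)
  inter <- A %*% t(B)
  sa <- rowSums(A); sb <- rowSums(B)
  uni <- outer(sa, sb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(ids_a, ids_b)
  out
}
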