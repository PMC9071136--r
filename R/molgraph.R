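# Internal molecular-graph representation built from ChemmineR SDF objects.
# Heavy atoms only (OpenBabel 2D SDF output carries no explicit hydrogens).

#' Convert a compound set to an SDF set
#'
#' Parses each canonical SMILES through OpenBabel with 2D coordinate
#' generation. The result is deterministic for a fixed canonical structure.
#'
#' @param compounds a `compound_set`.
#' @return a `ChemmineR::SDFset` with one molecule per compound, named by id.
#' @export
as_sdfset <- function(compounds) {
  sms <- compounds$smiles
  names(sms) <- compounds$id
  sdf <- ChemmineR::smiles2sdf(sms)
  ChemmineR::cid(sdf) <- compounds$id
  sdf
}

PAULING_EN <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Se = 2.55,
                Br = 2.96, I = 2.66)
ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                 Cl = 35.45, Se = 78.971, Br = 79.904, I = 126.904)
STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                 Cl = 1, Se = 2, Br = 1, I = 1)

# Build one molecular graph from a single-molecule SDF.
mol_graph_one <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:2, drop = FALSE]

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }

  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  # Aromatic perception: atoms belonging to any SSSR ring flagged aromatic.
  arom_atom <- rep(FALSE, n)
  if (nrow(bonds) > 0 && n >= 3) {
    rg <- tryCatch(
      ChemmineR::rings(sdf1, type = "all", arom = TRUE, inner = FALSE),
      error = function(e) NULL
    )
    if (!is.null(rg) && length(rg$RINGS)) {
      for (ri in seq_along(rg$RINGS)) {
        if (isTRUE(rg$AROMATIC[[ri]])) {
          idx <- as.integer(sub("^[A-Za-z]+_", "", rg$RINGS[[ri]]))
          arom_atom[idx] <- TRUE
        }
      }
    }
  }
  # Bond aromatic if both ends aromatic and the bond lies in a ring.
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    deg <- lengths(adj)
    # a bond is a ring bond iff removing it keeps its ends connected;
    # cheap sufficient test: both atoms aromatic => aromatic ring bond here
    in_ring_bond <- arom_atom[bonds[, 1]] & arom_atom[bonds[, 2]]
  }
  border <- bonds[, 3, drop = TRUE]
  border[in_ring_bond] <- 4L  # aromatic order sentinel

  ring_count <- nrow(bonds) - n + n_components(adj, n)

  list(n = n, elem = elem, coords = coords, bonds = bonds,
       border = as.integer(border), adj = adj,
       arom_atom = arom_atom, deg = lengths(adj),
       ring_count = max(0L, as.integer(ring_count)))
}

n_components <- function(adj, n) {
  if (n == 0) return(0L)
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comp
}

# Named list of molecular graphs for a compound set.
mol_graphs <- function(compounds, sdfset = NULL) {
  sdfset <- sdfset %||% as_sdfset(compounds)
  out <- lapply(seq_along(compounds$id), function(i) mol_graph_one(sdfset[[i]]))
  names(out) <- compounds$id
  out
}

# All-pairs topological distance matrix (BFS per atom; molecules are small).
topo_dist <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in g$adj[[v]]) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

# Implicit hydrogen estimate: standard valence minus sum of bond orders
# (aromatic bonds count 1.5); clamped at zero.
implicit_h <- function(g) {
  bsum <- rep(0, g$n)
  if (nrow(g$bonds)) {
    ord <- ifelse(g$border == 4L, 1.5, g$border)
    for (k in seq_len(nrow(g$bonds))) {
      bsum[g$bonds[k, 1]] <- bsum[g$bonds[k, 1]] + ord[k]
      bsum[g$bonds[k, 2]] <- bsum[g$bonds[k, 2]] + ord[k]
    }
  }
  val <- STD_VALENCE[g$elem]
  val[is.na(val)] <- 0
  pmax(0, round(val - bsum))
}
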