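#' The pinned molecular-descriptor registry
#'
#' An ordered, versioned list of per-molecule numeric descriptors covering
#' the five classical categories: constitutional, topological, geometrical
#' (from generated 2D coordinates), electronic, and hybrid. The registry
#' order defines the descriptor-block column order of every feature matrix
#' in a run; `d = nrow(registry)` is a parameter throughout the package.
#'
#' @param categories optional subset of categories to retain.
#' @return data frame with columns `name`, `category`; attribute `version`.
#' @export
descriptor_registry <- function(categories = NULL) {
  reg <- rbind(
    data.frame(category = "constitutional", name = c(
      "n_heavy", "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur",
      "n_halogen", "n_hetero", "frac_hetero", "n_bonds", "n_single",
      "n_double", "n_triple", "n_aromatic_bonds", "n_aromatic_atoms", "mw")),
    data.frame(category = "topological", name = c(
      "n_rings", "wiener", "zagreb1", "zagreb2", "randic",
      "graph_diameter", "graph_radius", "petitjean", "mean_degree",
      "max_degree", "n_branch_atoms", "n_terminal_atoms",
      "eccentric_connectivity", "n_rotatable")),
    data.frame(category = "geometrical", name = c(
      "geom_span", "radius_gyration_2d", "bbox_area", "bbox_aspect",
      "mean_pair_dist", "geom_compactness", "centroid_spread",
      "mean_bond_length")),
    data.frame(category = "electronic", name = c(
      "tpsa", "hba1", "hba2", "hbd", "sum_en", "mean_en",
      "max_bond_en_diff", "polar_atom_frac")),
    data.frame(category = "hybrid", name = c(
      "logp", "mr", "logp_per_heavy", "ats_en_1", "ats_en_2", "ats_en_3",
      "ats_mass_1", "ats_mass_2", "ats_mass_3"))
  )
  if (!is.null(categories)) reg <- reg[reg$category %in% categories, ]
  rownames(reg) <- NULL
  structure(reg[, c("name", "category")], version = "1.0")
}

ats_autocorr <- function(D, w, lag) {
  sel <- which(D == lag, arr.ind = TRUE)
  sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
  if (!nrow(sel)) return(0)
  sum(w[sel[, 1]] * w[sel[, 2]])
}

descriptors_one <- function(g, prop) {
  elem <- g$elem
  n <- g$n
  deg <- g$deg
  nb <- nrow(g$bonds)
  arom_bond <- g$border == 4L
  halo <- elem %in% c("F", "Cl", "Br", "I")
  hetero <- !(elem %in% c("C", "H"))
  en <- PAULING_EN[elem]; en[is.na(en)] <- 2.2
  mass <- ATOMIC_MASS[elem]; mass[is.na(mass)] <- 12

  D <- topo_dist(g)
  finD <- D[is.finite(D) & upper.tri(D)]
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  diam <- if (length(ecc)) max(ecc) else 0
  radi <- if (length(ecc)) min(ecc) else 0

  # rotatable: acyclic single bonds between non-terminal heavy atoms
  rot <- 0L
  if (nb > 0) {
    ring_bond <- g$arom_atom[g$bonds[, 1]] & g$arom_atom[g$bonds[, 2]]
    for (k in seq_len(nb)) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
      if (g$border[k] == 1L && !ring_bond[k] && deg[i] > 1 && deg[j] > 1 &&
          !bond_on_cycle(g, k)) {
        rot <- rot + 1L
      }
    }
  }

  xy <- g$coords
  centroid <- colMeans(xy)
  dc <- sqrt(rowSums((xy - matrix(centroid, n, 2, byrow = TRUE))^2))
  pd <- if (n >= 2) as.vector(stats::dist(xy)) else 0
  bl <- if (nb > 0) {
    sqrt(rowSums((xy[g$bonds[, 1], , drop = FALSE] -
                    xy[g$bonds[, 2], , drop = FALSE])^2))
  } else 0
  bw <- diff(range(xy[, 1])); bh <- diff(range(xy[, 2]))

  en_diff <- if (nb > 0) {
    max(abs(en[g$bonds[, 1]] - en[g$bonds[, 2]]))
  } else 0

  c(
    n_heavy = n,
    n_carbon = sum(elem == "C"),
    n_nitrogen = sum(elem == "N"),
    n_oxygen = sum(elem == "O"),
    n_sulfur = sum(elem == "S"),
    n_halogen = sum(halo),
    n_hetero = sum(hetero),
    frac_hetero = sum(hetero) / n,
    n_bonds = nb,
    n_single = sum(g$border == 1L),
    n_double = sum(g$border == 2L),
    n_triple = sum(g$border == 3L),
    n_aromatic_bonds = sum(arom_bond),
    n_aromatic_atoms = sum(g$arom_atom),
    mw = prop[["MW"]],
    n_rings = g$ring_count,
    wiener = sum(finD),
    zagreb1 = sum(deg^2),
    zagreb2 = if (nb > 0) sum(deg[g$bonds[, 1]] * deg[g$bonds[, 2]]) else 0,
    randic = if (nb > 0) sum(1 / sqrt(deg[g$bonds[, 1]] * deg[g$bonds[, 2]])) else 0,
    graph_diameter = diam,
    graph_radius = radi,
    petitjean = if (diam > 0) (diam - radi) / diam else 0,
    mean_degree = mean(deg),
    max_degree = max(deg),
    n_branch_atoms = sum(deg >= 3),
    n_terminal_atoms = sum(deg == 1),
    eccentric_connectivity = sum(deg * ecc),
    n_rotatable = rot,
    geom_span = if (n >= 2) max(pd) else 0,
    radius_gyration_2d = sqrt(mean(dc^2)),
    bbox_area = bw * bh,
    bbox_aspect = if (min(bw, bh) > 0) max(bw, bh) / min(bw, bh) else 0,
    mean_pair_dist = mean(pd),
    geom_compactness = if (n > 0) (if (n >= 2) max(pd) else 0) / n else 0,
    centroid_spread = stats::sd(dc),
    mean_bond_length = mean(bl),
    tpsa = prop[["TPSA"]],
    hba1 = prop[["HBA1"]],
    hba2 = prop[["HBA2"]],
    hbd = prop[["HBD"]],
    sum_en = sum(en),
    mean_en = mean(en),
    max_bond_en_diff = en_diff,
    polar_atom_frac = sum(elem %in% c("N", "O", "S", "P") | halo) / n,
    logp = prop[["logP"]],
    mr = prop[["MR"]],
    logp_per_heavy = prop[["logP"]] / n,
    ats_en_1 = ats_autocorr(D, en, 1),
    ats_en_2 = ats_autocorr(D, en, 2),
    ats_en_3 = ats_autocorr(D, en, 3),
    ats_mass_1 = ats_autocorr(D, mass, 1) / 1000,
    ats_mass_2 = ats_autocorr(D, mass, 2) / 1000,
    ats_mass_3 = ats_autocorr(D, mass, 3) / 1000
  )
}

bond_on_cycle <- function(g, k) {
  i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
  # is j reachable from i without using bond k?
  seen <- rep(FALSE, g$n); seen[i] <- TRUE
  queue <- i
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in g$adj[[v]]) {
      if (v == i && w == j) next
      if (v == j && w == i) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  seen[j]
}

#' Compute molecular descriptors for a compound library
#'
#' Evaluates every descriptor of the pinned registry, in registry order,
#' for each compound. Failed or undefined descriptors become `NA` (flagged,
#' never silently zeroed); a compound with more than 10 percent non-finite
#' entries is rejected with a reason.
#'
#' @param compounds a `compound_set`.
#' @param registry a registry from [descriptor_registry()].
#' @param sdfset optional pre-parsed `SDFset`.
#' @return numeric matrix, one row per retained compound (rownames = ids),
#'   columns in registry order; rejected ids in `attr(, "rejected")`.
#' @export
compute_descriptors <- function(compounds, registry = descriptor_registry(),
                                sdfset = NULL) {
  sdfset <- sdfset %||% as_sdfset(compounds)
  graphs <- mol_graphs(compounds, sdfset)
  props <- ChemmineR::propOB(sdfset)
  full <- t(vapply(seq_along(graphs), function(i) {
    out <- tryCatch(descriptors_one(graphs[[i]], props[i, ]),
                    error = function(e) NULL)
    if (is.null(out)) {
      stats::setNames(rep(NA_real_, nrow(descriptor_registry())),
                      descriptor_registry()$name)
    } else out
  }, stats::setNames(numeric(nrow(descriptor_registry())),
                     descriptor_registry()$name)))
  rownames(full) <- compounds$id
  mat <- full[, registry$name, drop = FALSE]
  frac_bad <- rowMeans(!is.finite(mat))
  rejected <- rownames(mat)[frac_bad > 0.10]
  if (length(rejected)) {
    message(length(rejected),
            " compound(s) rejected (>10% non-finite descriptors): ",
            paste(rejected, collapse = ", "))
  }
  mat <- mat[frac_bad <= 0.10, , drop = FALSE]
  structure(mat, rejected = rejected,
            registry_version = attr(registry, "version"))
}
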