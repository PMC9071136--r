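#' Canonicalize SMILES strings
#'
#' Converts each input SMILES to the OpenBabel canonical form. The result is
#' idempotent: canonicalizing a canonical SMILES returns it unchanged.
#' Unparseable inputs yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(trimws(s), "\n"))),
      error = function(e) ""
    )
    out <- sub("[\t ].*$", "", sub("\n$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

inchi_to_smiles <- function(inchi) {
  vapply(inchi, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("INCHI", "CAN", paste0(trimws(s), "\n"))),
      error = function(e) ""
    )
    out <- sub("[\t ].*$", "", sub("\n$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Count heavy atoms of a single-fragment SMILES cheaply (parse via OB).
smiles_heavy_atoms <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NA_integer_)
  nrow(ChemmineR::atomblock(sdf[[1]]))
}

# Multi-fragment records (salts, counter-ions): keep the largest organic
# fragment. Fragments containing carbon are preferred; ties break to the
# first fragment in canonical order.
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(list(smiles = smiles, was_multi = FALSE))
  has_c <- grepl("(?i)(?<![a-z])c", frags, perl = TRUE) |
    grepl("\\[[0-9]*[Cc]", frags)
  pool <- if (any(has_c)) frags[has_c] else frags
  sizes <- vapply(pool, smiles_heavy_atoms, integer(1))
  keep <- pool[which.max(sizes)]
  list(smiles = canonical_smiles(keep), was_multi = TRUE)
}

new_compound_set <- function(df, rejects, fragment_events = character(0)) {
  stopifnot(all(c("id", "smiles") %in% names(df)))
  rownames(df) <- NULL
  structure(df,
            class = c("compound_set", "data.frame"),
            rejects = rejects,
            fragment_events = fragment_events)
}

empty_rejects <- function() {
  data.frame(id = character(0), input = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Load a compound library
#'
#' Reads compounds from a SMILES TSV, an InChI TSV, or an SDF (V2000) file,
#' canonicalizes every structure, and indexes them by identifier. TSV inputs
#' are UTF-8 with a header row; the structure column is named `smiles` or
#' `inchi` and the identifier column `id`. Any additional TSV columns are
#' carried along as free-text annotations (e.g. `superclass`, `atc`,
#' `food_source`). Multi-fragment records keep their largest organic
#' fragment, and the event is logged.
#'
#' Unparseable records are not silently dropped: they are counted, reported
#' via [compound_rejects()], and a message summarises them.
#'
#' @param path file path.
#' @param format one of `"smiles-tsv"`, `"inchi-tsv"`, `"sdf"`.
#' @return a `compound_set`: a data frame with columns `id`, `smiles`
#'   (canonical) and any annotation columns, with a rejection log attached.
#' @export
load_compounds <- function(path, format = c("smiles-tsv", "inchi-tsv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read compound file: ", path)

  if (format == "sdf") {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfset)
    raw <- vapply(seq_along(sdfset), function(i) {
      out <- tryCatch(
        suppressWarnings(ChemmineR::sdf2smiles(sdfset[i])),
        error = function(e) NULL
      )
      if (is.null(out)) NA_character_ else as.character(out)[1]
    }, character(1))
    tab <- data.frame(id = ids, structure = raw, stringsAsFactors = FALSE)
    extra <- NULL
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    names(tab) <- tolower(names(tab))
    if (!"id" %in% names(tab)) stop("input TSV must have an 'id' column")
    struct_col <- if (format == "smiles-tsv") "smiles" else "inchi"
    if (!struct_col %in% names(tab)) {
      stop("input TSV must have a '", struct_col, "' column for format ", format)
    }
    extra <- setdiff(names(tab), c("id", struct_col))
    tab$structure <- if (format == "inchi-tsv") {
      inchi_to_smiles(tab[[struct_col]])
    } else {
      tab[[struct_col]]
    }
    tab$id <- as.character(tab$id)
  }

  if (anyDuplicated(tab$id)) {
    stop("duplicate compound ids in input: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }

  canon <- canonical_smiles(tab$structure)
  frag_events <- character(0)
  multi <- !is.na(canon) & grepl(".", canon, fixed = TRUE)
  for (i in which(multi)) {
    res <- largest_organic_fragment(canon[i])
    canon[i] <- res$smiles
    frag_events <- c(frag_events, tab$id[i])
  }
  if (length(frag_events)) {
    message(length(frag_events), " multi-fragment record(s) reduced to largest organic fragment: ",
            paste(frag_events, collapse = ", "))
  }

  bad <- is.na(canon)
  rejects <- data.frame(id = tab$id[bad],
                        input = as.character(tab$structure[bad]),
                        reason = rep("unparseable structure", sum(bad)),
                        stringsAsFactors = FALSE)
  if (nrow(rejects)) {
    message(nrow(rejects), " record(s) rejected as unparseable: ",
            paste(rejects$id, collapse = ", "))
  }
  keep <- !bad
  if (!any(keep)) stop("no parseable compound records in ", path)

  df <- data.frame(id = tab$id[keep], smiles = canon[keep],
                   stringsAsFactors = FALSE)
  if (format != "sdf" && length(extra)) {
    for (col in extra) df[[col]] <- tab[[col]][keep]
  }
  new_compound_set(df, rejects, frag_events)
}

#' Build a compound set from an in-memory SMILES vector
#'
#' Convenience constructor used by the synthetic generator and in examples;
#' applies the same canonicalization and rejection logging as
#' [load_compounds()].
#'
#' @param id character vector of unique identifiers.
#' @param smiles character vector of SMILES strings.
#' @param annotations optional data frame of annotation columns.
#' @return a `compound_set`.
#' @export
compound_set <- function(id, smiles, annotations = NULL) {
  stopifnot(length(id) == length(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate compound ids")
  canon <- canonical_smiles(smiles)
  bad <- is.na(canon)
  rejects <- data.frame(id = id[bad], input = smiles[bad],
                        reason = rep("unparseable structure", sum(bad)),
                        stringsAsFactors = FALSE)
  if (nrow(rejects)) {
    message(nrow(rejects), " record(s) rejected as unparseable: ",
            paste(rejects$id, collapse = ", "))
  }
  if (all(bad)) stop("no parseable compound records")
  df <- data.frame(id = id[!bad], smiles = canon[!bad], stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == length(id))
    for (col in names(annotations)) df[[col]] <- annotations[[col]][!bad]
  }
  new_compound_set(df, rejects)
}

#' Rejection log of a compound set
#' @param x a `compound_set`.
#' @return data frame of rejected records (id, input, reason).
#' @export
compound_rejects <- function(x) attr(x, "rejects") %||% empty_rejects()

#' Write a compound set to a SMILES TSV
#'
#' Inverse of [load_compounds()] for the `smiles-tsv` format; a written file
#' reloads to an identical compound set.
#'
#' @param x a `compound_set`.
#' @param path output file path.
#' @export
write_compounds <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.compound_set <- function(x, ...) {
  cat("<compound_set> ", nrow(x), " compounds, ",
      nrow(compound_rejects(x)), " rejected record(s)\n", sep = "")
  ann <- setdiff(names(x), c("id", "smiles"))
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Load a compound-to-target map
#'
#' Reads a two-column TSV (`compound_id`, `target_id`), aggregates rows into
#' one target set per compound, and validates the result against a loaded
#' reference library. Rows whose compound id is absent from the library are
#' excluded with a warning and recorded in the exclusion report.
#'
#' @param path TSV file path (header row required).
#' @param compounds the `compound_set` the map refers to.
#' @return a `target_map`: a named list of character target-id vectors.
#' @export
load_target_map <- function(path, compounds) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2) stop("target map must be a two-column TSV")
  names(tab)[1:2] <- c("compound_id", "target_id")
  target_map(tab$compound_id, tab$target_id, compounds)
}

#' Build a target map from vectors
#'
#' @param compound_id,target_id parallel character vectors; duplicate rows
#'   collapse under set semantics.
#' @param compounds the reference `compound_set`.
#' @return a `target_map`.
#' @export
target_map <- function(compound_id, target_id, compounds) {
  compound_id <- as.character(compound_id)
  target_id <- as.character(target_id)
  ok <- nzchar(compound_id) & nzchar(target_id) &
    !is.na(compound_id) & !is.na(target_id)
  compound_id <- compound_id[ok]; target_id <- target_id[ok]
  known <- compound_id %in% compounds$id
  excluded <- unique(compound_id[!known])
  if (length(excluded)) {
    warning(length(excluded), " compound id(s) in target map absent from library, excluded: ",
            paste(utils::head(excluded, 10), collapse = ", "))
  }
  entries <- lapply(split(target_id[known], compound_id[known]),
                    function(v) sort(unique(v)))
  if (!length(entries)) stop("target map is empty after validation")
  structure(entries, class = "target_map", excluded = excluded)
}

#' @export
print.target_map <- function(x, ...) {
  sizes <- lengths(x)
  cat("<target_map> ", length(x), " compounds, ",
      length(unique(unlist(x))), " targets; fan-out ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}
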