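#' Parse a SMILES string into a molecule
#'
#' Parses a SMILES with OpenBabel (via ChemmineOB). Aromaticity is perceived
#' with OpenBabel's default aromaticity model (so e.g. the Kekule spelling
#' `C1=CC=CC=C1` and `c1ccccc1` give the same molecule); the molecule stays
#' on its implicit-hydrogen representation — no explicit H atoms are added —
#' which is the representation all SMARTS matching in this package runs on.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `"pofp_mol"`: a handle to the parsed molecule
#'   with components `smiles` (input), `formula` (Hill formula) and
#'   `canonical_smiles`.
#' @examples
#' mol <- parse_smiles("c1ccccc1")
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("invalid SMILES: empty or not a single string")
  }
  ob <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, identity),
    error = function(e) stop("invalid SMILES: ", smiles, call. = FALSE)
  )
  if (length(ob) != 1) stop("invalid SMILES: ", smiles, call. = FALSE)
  props <- tryCatch(ChemmineOB::prop_OB(ob), error = function(e) NULL)
  structure(list(smiles = smiles, ob = ob,
                 formula = if (is.null(props)) NA_character_ else props$formula,
                 canonical_smiles = if (is.null(props)) NA_character_ else
                   props$cansmi),
            class = "pofp_mol")
}

#' @export
print.pofp_mol <- function(x, ...) {
  cat("<molecule ", x$formula, "> ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Count distinct substructure matches of a SMARTS pattern
#'
#' Counts matches of `smarts` in a molecule, deduplicated by matched atom set:
#' two matches that map the pattern onto the same set of atoms in different
#' atom orders (as happens for every symmetric pattern, e.g. `[C]=[C]` across
#' a double bond) count once. This is the counting convention under which
#' tetraphenylethylene has exactly one carbon-carbon double-bond match.
#'
#' @param mol A molecule from [parse_smiles()].
#' @param smarts A SMARTS pattern string.
#' @return Non-negative integer match count.
#' @examples
#' tpe <- parse_smiles("C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1")
#' count_substructure(tpe, "[C]=[C]")  # 1
#' @export
count_substructure <- function(mol, smarts) {
  stopifnot(inherits(mol, "pofp_mol"))
  if (!.smarts_compiles(smarts)) {
    stop("SMARTS pattern failed to parse: ", smarts, call. = FALSE)
  }
  as.integer(ChemmineOB::smartsSearch_OB(mol$ob, smarts,
                                         uniqueMatches = TRUE)[[1]])
}

#' Count aromatic atoms in a molecule
#'
#' Counts atoms flagged aromatic under OpenBabel's default aromaticity
#' perception. This is fingerprint digit 46.
#'
#' @inheritParams count_substructure
#' @return Non-negative integer.
#' @examples
#' aromatic_atom_count(parse_smiles("c1ccccc1"))  # 6
#' @export
aromatic_atom_count <- function(mol) {
  count_substructure(mol, "[a]")
}

# elements representable by the fingerprint: the organic/main-group set plus
# the five metals of feature 38
.allowed_elements <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                       "Se", "Br", "I", "Au", "Bi", "Ir", "Ru", "Eu")

.mol_elements <- function(mol) {
  if (is.na(mol$formula)) return(character(0))
  unique(unlist(regmatches(mol$formula, gregexpr("[A-Z][a-z]?", mol$formula))))
}

#' Compute the photophysics-oriented fingerprint of one molecule
#'
#' Converts a SMILES string into the 46-digit POFP. Digits 1--45 are distinct
#' atom-set substructure counts of the SMARTS features from [pofp_features()]
#' (in `"num"` mode) or their presence indicators (in `"bit"` mode,
#' presence = count >= 1); digit 46 is the aromatic atom count in both modes.
#'
#' Molecules containing elements outside the representable set (organic and
#' main-group elements plus Au, Bi, Ir, Ru, Eu) are not silently zeroed: the
#' fingerprint is still computed and returned, with a warning and with the
#' offending elements recorded in the `"disallowed_elements"` attribute.
#' Use [clean_records()] to exclude such entries from a dataset.
#'
#' @param smiles A single SMILES string.
#' @param mode `"num"` (substructure counts; the default) or `"bit"`.
#' @return A named numeric vector of length 46 (names `s1`...`s46`) of class
#'   `"pofp"`, with attributes `mode`, `smiles` and `aromaticity_model`.
#' @examples
#' fp <- compute_pofp("C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1")
#' fp[fp > 0]  # s10 = 1, s46 = 24
#' @export
compute_pofp <- function(smiles, mode = c("num", "bit")) {
  mode <- match.arg(mode)
  mol <- parse_smiles(smiles)
  feats <- pofp_features()
  counts <- vapply(feats$smarts, function(p) count_substructure(mol, p),
                   integer(1), USE.NAMES = FALSE)
  if (mode == "bit") counts <- as.integer(counts > 0)
  values <- c(counts, aromatic_atom_count(mol))
  names(values) <- pofp_digit_names()
  bad <- setdiff(.mol_elements(mol), .allowed_elements)
  if (length(bad) > 0) {
    warning("SMILES contains element(s) not representable by the fingerprint: ",
            paste(bad, collapse = ", "), " (", smiles, ")")
  }
  structure(as.numeric(values), names = names(values), class = "pofp",
            mode = mode, smiles = smiles,
            aromaticity_model = "openbabel-default",
            disallowed_elements = if (length(bad)) bad else NULL)
}

#' @export
print.pofp <- function(x, ...) {
  cat("POFP(", attr(x, "mode"), ") of ", attr(x, "smiles"), "\n", sep = "")
  active <- which(x != 0)
  if (length(active) == 0) {
    cat("  all 46 digits are 0\n")
  } else {
    labs <- pofp_digit_labels()
    for (i in active) {
      cat(sprintf("  s%-2d (%s) = %g\n", i, labs[i], x[i]))
    }
  }
  invisible(x)
}

#' Fingerprint a list of SMILES into a matrix
#'
#' Computes the POFP for every parseable SMILES in `smiles_list`, batching the
#' SMARTS matching over all molecules for speed. Unparseable entries (and, if
#' `reject_disallowed = TRUE`, molecules with non-representable elements) are
#' skipped and reported, never fatal.
#'
#' @param smiles_list Character vector of SMILES.
#' @param mode `"num"` or `"bit"` (see [compute_pofp()]).
#' @param reject_disallowed If `TRUE`, molecules containing elements outside
#'   the representable set are rejected (reason `"disallowed_element"`)
#'   instead of fingerprinted. Default `FALSE`: they are fingerprinted and
#'   only invalid SMILES are rejected.
#' @return A list of class `"pofp_table"` with elements:
#'   \describe{
#'     \item{fingerprints}{`n_valid x 46` numeric matrix, columns `s1`...`s46`,
#'       rows in input order of the valid entries.}
#'     \item{smiles}{Character vector of the fingerprinted SMILES (row order).}
#'     \item{rejections}{data.frame with columns `index` (position in the
#'       input), `smiles`, `reason`.}
#'     \item{mode, aromaticity_model}{Provenance metadata.}
#'   }
#' @examples
#' ft <- fingerprint_table(c("c1ccccc1", "CCO"))
#' dim(ft$fingerprints)
#' @export
fingerprint_table <- function(smiles_list, mode = c("num", "bit"),
                              reject_disallowed = FALSE) {
  mode <- match.arg(mode)
  smiles_list <- as.character(smiles_list)
  n <- length(smiles_list)

  mols <- vector("list", n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    mol <- tryCatch(parse_smiles(smiles_list[i]), error = function(e) NULL)
    if (is.null(mol)) {
      reasons[i] <- "invalid_smiles"
      next
    }
    if (reject_disallowed &&
        length(setdiff(.mol_elements(mol), .allowed_elements)) > 0) {
      reasons[i] <- "disallowed_element"
      next
    }
    mols[[i]] <- mol$ob[[1]]
  }
  valid <- which(!nzchar(reasons))
  rejections <- data.frame(index = which(nzchar(reasons)),
                           smiles = smiles_list[nzchar(reasons)],
                           reason = reasons[nzchar(reasons)],
                           stringsAsFactors = FALSE)

  fp <- matrix(0, nrow = length(valid), ncol = 46,
               dimnames = list(NULL, pofp_digit_names()))
  if (length(valid) > 0) {
    obrefs <- mols[valid]
    feats <- pofp_features()
    for (j in seq_len(45)) {
      fp[, j] <- ChemmineOB::smartsSearch_OB(obrefs, feats$smarts[j],
                                             uniqueMatches = TRUE)
    }
    fp[, 46] <- ChemmineOB::smartsSearch_OB(obrefs, "[a]", uniqueMatches = TRUE)
    if (mode == "bit") fp[, 1:45] <- (fp[, 1:45] > 0) + 0
  }
  structure(list(fingerprints = fp, smiles = smiles_list[valid],
                 rejections = rejections, mode = mode,
                 aromaticity_model = "openbabel-default"),
            class = "pofp_table")
}

#' @export
print.pofp_table <- function(x, ...) {
  cat("POFP(", x$mode, ") table: ", nrow(x$fingerprints), " molecules, ",
      nrow(x$rejections), " rejected\n", sep = "")
  invisible(x)
}

#' Write a fingerprint table to CSV
#'
#' Output schema: `smiles, s1...s46, mode`, one row per fingerprinted
#' molecule.
#'
#' @param x A `"pofp_table"` from [fingerprint_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path) {
  stopifnot(inherits(x, "pofp_table"))
  df <- data.frame(smiles = x$smiles, x$fingerprints, mode = x$mode,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.smarts_compiles <- function(smarts) {
  probe <- .probe_mol()
  ok <- tryCatch({
    ChemmineOB::smartsSearch_OB(probe, smarts, uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# tiny cached probe molecule used only to exercise pattern compilation
.pkg_cache <- new.env(parent = emptyenv())
.probe_mol <- function() {
  if (is.null(.pkg_cache$probe)) {
    .pkg_cache$probe <- ChemmineOB::forEachMol("SMILES", "c1ccccc1", identity)
  }
  .pkg_cache$probe
}
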