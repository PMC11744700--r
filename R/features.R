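#' Feature definitions of the photophysics-oriented fingerprint
#'
#' The POFP encodes an organic luminophore as 46 non-negative integers:
#' digits 1--15 count electron donors and ESIPT (excited-state intramolecular
#' proton transfer) patterns, digits 16--38 count electron acceptors, digits
#' 39--45 count conjugation breakers (bulky or saturated substructures that
#' disrupt pi-conjugation or intermolecular packing), and digit 46 is the
#' total number of aromatic atoms. Digits 1--45 are defined by the SMARTS
#' patterns returned by [pofp_features()].
#'
#' A few patterns as originally published are not syntactically valid SMARTS
#' or cannot match the intended aromatic substructure; these are repaired
#' here and the published spelling is retained in the `smarts_printed`
#' column so every repair is auditable:
#'
#' * Unicode hyphens are normalized to ASCII `-`.
#' * Rows 8 and 9 (thiophene, furan) printed explicit single ring-closure
#'   bonds (`[s]-1[c][c][c][c]-1`), which can never match an aromatic ring
#'   bond; the dash is read as a typographic rendering of the ring-closure
#'   digit and dropped.
#' * Row 12 (naphthalene) printed a dangling ring closure; it is repaired to
#'   a fused-bicycle naphthalene pattern.
#' * Rows 42 and 43 use `[B-]` / `[P-]` (the printed minus was typographic).
#'
#' Rows 42/43 are named "BF4 cation"/"PF6 cation" in the source table even
#' though the depicted species are anions; the published names are kept.
#'
#' @return A data.frame with one row per fingerprint digit 1--45 and columns
#'   `index`, `category` (one of `"donor_esipt"`, `"acceptor"`, `"breaker"`),
#'   `name`, `smarts` (the pattern actually matched), and `smarts_printed`
#'   (the published spelling where it differs, otherwise equal to `smarts`).
#' @examples
#' feats <- pofp_features()
#' table(feats$category)
#' feats[feats$index == 10, ]
#' @export
pofp_features <- function() {
  df <- .pofp_feature_table
  # internal consistency: every pattern must compile in the matcher
  bad <- which(!vapply(df$smarts, .smarts_compiles, logical(1)))
  if (length(bad) > 0) {
    stop("POFP feature definition ", df$index[bad[1]], " (", df$name[bad[1]],
         "): SMARTS pattern fails to parse: ", df$smarts[bad[1]])
  }
  df
}

# One row per digit 1-45 in published table order. smarts_printed preserves the
# published spelling (ASCII-normalized) wherever the matched pattern differs.
.pofp_feature_table <- local({
  rows <- list(
    # -- donors and ESIPT patterns (1-15) --
    list(1L,  "donor_esipt", "dialkylamino",             "[c][N]([C])[C]", NA),
    list(2L,  "donor_esipt", "diphenylamine",            "[c][N]([c])[C]", NA),
    list(3L,  "donor_esipt", "triphenylamine",           "[c][N]([c])[c]", NA),
    list(4L,  "donor_esipt", "methoxy",                  "[c][O][C]", NA),
    list(5L,  "donor_esipt", "diphenyloxy",              "[c][O][c]", NA),
    list(6L,  "donor_esipt", "phenothiazine",            "[c][S][c][c][N][c]", NA),
    list(7L,  "donor_esipt", "phenoxazine",              "[c][O][c][c][N][c]", NA),
    list(8L,  "donor_esipt", "thiophene",                "[s]1[c][c][c][c]1",
         "[s]-1[c][c][c][c]-1"),
    list(9L,  "donor_esipt", "furan",                    "[o]1[c][c][c][c]1",
         "[o]-1-[c][c][c][c]-1"),
    list(10L, "donor_esipt", "carbon-carbon double bond", "[C]=[C]", NA),
    list(11L, "donor_esipt", "1,2-dihydroxy aromatic ring", "[O][c][c][O]", NA),
    list(12L, "donor_esipt", "naphthalene",              "[c]1[c][c][c]2[c]([c]1)[c][c][c][c]2",
         "[c]-1[c][c][c]([c][c]-1)[c][c][c][c]-2"),
    list(13L, "donor_esipt", "ESIPT: enol-imide",        "[N]=[C;H][c][c][O;H]", NA),
    list(14L, "donor_esipt", "ESIPT: enol-keto",         "[O]=[C;H][c][c][O;H]", NA),
    list(15L, "donor_esipt", "ESIPT: 5m ring",           "[c][C](=[O])[C](=[C])[O;H]", NA),
    # -- acceptors (16-38) --
    list(16L, "acceptor", "cyano",                       "[C]#[N]", NA),
    list(17L, "acceptor", "carbon-nitrogen double bond", "[C]=[N]", NA),
    list(18L, "acceptor", "aromatic positive nitrogen",  "[n+]", NA),
    list(19L, "acceptor", "aromatic positive oxygen",    "[o+]", NA),
    list(20L, "acceptor", "boron as acceptor",           "[c][B]", NA),
    list(21L, "acceptor", "BF2 bridge",                  "[O,N][B]([F])[F]", NA),
    list(22L, "acceptor", "benzothiazole",               "[C][c](s)[n]", NA),
    list(23L, "acceptor", "benzoxazole",                 "[C][c](o)[n]", NA),
    list(24L, "acceptor", "benzoimidazole",              "[C][c](n)[n]", NA),
    list(25L, "acceptor", "aromatic N-S-N",              "[n][s][n]", NA),
    list(26L, "acceptor", "N=S=N",                       "[c][N]=[S]=[N][c]", NA),
    list(27L, "acceptor", "aromatic N-Se-N",             "[n][se][n]", NA),
    list(28L, "acceptor", "TPA-BMO",                     "[C]=[C]([N])[C](=[O])[O]", NA),
    list(29L, "acceptor", "bisimide",                    "[c][C](=[O])[N][C](=[O])[c]", NA),
    list(30L, "acceptor", "aromatic nitrogen",           "[n]", NA),
    list(31L, "acceptor", "indanone",                    "[C]=[C]([C](=[O])[c])[C](=[O])[c]", NA),
    list(32L, "acceptor", "carboxy",                     "[C]=[O]", NA),
    list(33L, "acceptor", "carbon-carbon triple bond",   "[c][C]#[C]", NA),
    list(34L, "acceptor", "4-cyano-indanone",
         "[N]#[C][C]([C]#[N])=[C]([c])[C](=[C])[C](c)=[C]([C]#[N])[C]#[N]", NA),
    list(35L, "acceptor", "pyrazine-NBD",
         "[c][c][n][c][c]([c])[n,c][s][n,c][c]([c])[c][n][c][c]", NA),
    list(36L, "acceptor", "fluoride",                    "[C,c][F]", NA),
    list(37L, "acceptor", "flavone",                     "[O]=[C,c][c][c]([c])[S,s,O,o]", NA),
    list(38L, "acceptor", "heavy metal atoms",           "[Au,Bi,Ir,Ru,Eu]", NA),
    # -- conjugation breakers (39-45) --
    list(39L, "breaker", "spatial conflict of aromatic hydrogen", "[C][c][c]([c,C])[c]", NA),
    list(40L, "breaker", "BINAP core",
         "[c][c]([c])[c]([c])[c]([c])[c]([c])[c]", NA),
    list(41L, "breaker", "saturated aromatic bridge",    "[c][C]([c])-[C]", NA),
    list(42L, "breaker", "BF4 cation",                   "[F][B-]([F])([F])[F]", NA),
    list(43L, "breaker", "PF6 cation",                   "[F][P-]([F])([F])([F])([F])[F]", NA),
    list(44L, "breaker", "t-butyl",                      "[C]([C])([C])[C]", NA),
    list(45L, "breaker", "continual benzene rings",
         "[c]([c])[c]([c])[c]([c])[c]([c])[c]([c])[c]([c])[c]([c])[c]([c])", NA)
  )
  df <- data.frame(
    index          = vapply(rows, function(r) r[[1]], integer(1)),
    category       = vapply(rows, function(r) r[[2]], character(1)),
    name           = vapply(rows, function(r) r[[3]], character(1)),
    smarts         = vapply(rows, function(r) r[[4]], character(1)),
    smarts_printed = vapply(rows, function(r) {
      if (is.na(r[[5]])) r[[4]] else r[[5]]
    }, character(1)),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(df) == 45L, identical(df$index, 1:45))
  df
})

#' Names for all 46 fingerprint digits
#'
#' @return Character vector of length 46: `s1` ... `s46`.
#' @export
pofp_digit_names <- function() paste0("s", 1:46)

#' Human-readable labels for all 46 digits
#'
#' @return Character vector of length 46: the 45 feature names from
#'   [pofp_features()] followed by `"aromatic atoms"`.
#' @export
pofp_digit_labels <- function() c(.pofp_feature_table$name, "aromatic atoms")

#' Export the feature definitions as JSON
#'
#' Writes the 45 SMARTS feature definitions (index, category, name, smarts)
#' to a JSON file, e.g. for consumption by external tools.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pofp_features_json <- function(path) {
  df <- pofp_features()[, c("index", "category", "name", "smarts")]
  jsonlite::write_json(df, path, pretty = TRUE)
  invisible(path)
}

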