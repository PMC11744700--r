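#' @name dataset
#' @title Photophysics record tables
#'
#' @description
#' A dataset is an ordinary data.frame with one row per database entry and
#' columns `smiles`, `lambda_solid_nm`, `lambda_agg_nm` (emission peak
#' wavelengths in nm, solid state / nanoaggregate), `qy` (fluorescence quantum
#' yield, 0--1), `lifetime_ns`, `feature_class` (one of AIE, ACQ, TADF, AIDF,
#' RTP) and `mechanism` (one of ICT_TICT, ESIPT, NA, CL — "NA" here is the
#' *neutral aromaticity* class label, not a missing value). Any property or
#' label may be absent for a given record. The data.frame carries a
#' `"provenance"` attribute (e.g. `"synthetic:seed=42"` or the source path).
NULL

.feature_classes <- c("AIE", "ACQ", "TADF", "AIDF", "RTP")
.mechanisms <- c("ICT_TICT", "ESIPT", "NA", "CL")
.record_cols <- c("smiles", "lambda_solid_nm", "lambda_agg_nm", "qy",
                  "lifetime_ns", "feature_class", "mechanism")

.empty_records <- function() {
  data.frame(smiles = character(0), lambda_solid_nm = numeric(0),
             lambda_agg_nm = numeric(0), qy = numeric(0),
             lifetime_ns = numeric(0), feature_class = character(0),
             mechanism = character(0), stringsAsFactors = FALSE)
}

#' Read photophysics records from a CSV file
#'
#' Reads a table in the schema described in [dataset]. The header must name
#' at least `smiles`; any of the property/label columns may be missing (they
#' are filled with `NA`) and extra columns are ignored. Empty cells parse to
#' absent values, never 0. Rows whose fields violate the record invariants
#' (wavelengths outside (0, 10000) nm, quantum yield outside [0, 1],
#' non-positive lifetime, unknown labels, blank SMILES, or no property/label
#' at all) are rejected with a reason, never fatal. Because "NA" is a real
#' mechanism label (neutral aromaticity), label columns are parsed with empty
#' string — not the text "NA" — as the missing-value marker.
#'
#' @param path CSV file path (a JSON-lines file with the same fields is also
#'   accepted if `path` ends in `.jsonl`).
#' @return A list with `records` (the dataset data.frame, `provenance`
#'   attribute set to the path) and `rejections` (data.frame of `index`,
#'   `smiles`, `reason`).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- if (length(lines) == 0) .empty_records() else
      do.call(rbind, lapply(lines, function(l) {
        rec <- jsonlite::fromJSON(l)
        out <- .empty_records()[0, ]
        out[1, ] <- NA
        for (cn in intersect(names(rec), .record_cols)) out[[cn]][1] <- rec[[cn]]
        out
      }))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = "", check.names = FALSE)
  }
  if (!"smiles" %in% names(raw)) {
    stop("input file must have a 'smiles' column: ", path)
  }
  for (cn in setdiff(.record_cols, names(raw))) raw[[cn]] <- rep(NA, nrow(raw))
  raw <- raw[, .record_cols, drop = FALSE]
  for (cn in c("lambda_solid_nm", "lambda_agg_nm", "qy", "lifetime_ns")) {
    raw[[cn]] <- suppressWarnings(as.numeric(raw[[cn]]))
  }
  for (cn in c("smiles", "feature_class", "mechanism")) {
    raw[[cn]] <- as.character(raw[[cn]])
  }

  reason <- vapply(seq_len(nrow(raw)), function(i) .record_problem(raw[i, ]),
                   character(1))
  keep <- !nzchar(reason)
  rejections <- data.frame(index = which(!keep),
                           smiles = ifelse(is.na(raw$smiles[!keep]), "",
                                           raw$smiles[!keep]),
                           reason = reason[!keep], stringsAsFactors = FALSE)
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "provenance") <- paste0("file:", path)
  list(records = records, rejections = rejections)
}

.record_problem <- function(row) {
  if (is.na(row$smiles) || !nzchar(trimws(row$smiles))) return("blank_smiles")
  for (cn in c("lambda_solid_nm", "lambda_agg_nm")) {
    v <- row[[cn]]
    if (!is.na(v) && (v <= 0 || v >= 10000)) return("wavelength_out_of_range")
  }
  if (!is.na(row$qy) && (row$qy < 0 || row$qy > 1)) return("qy_out_of_range")
  if (!is.na(row$lifetime_ns) && row$lifetime_ns <= 0) return("bad_lifetime")
  if (!is.na(row$feature_class) && !row$feature_class %in% .feature_classes) {
    return("unknown_feature_class")
  }
  if (!is.na(row$mechanism) && !row$mechanism %in% .mechanisms) {
    return("unknown_mechanism")
  }
  has_any <- any(!is.na(unlist(row[c("lambda_solid_nm", "lambda_agg_nm", "qy",
                                     "lifetime_ns", "feature_class",
                                     "mechanism")])))
  if (!has_any) return("no_property_or_label")
  ""
}

#' Write photophysics records to CSV
#'
#' Inverse of [read_records()]: writes the standard column schema with empty
#' cells for absent values, so `read_records(write_records(ds, f))` is the
#' identity on all fields.
#'
#' @param records A dataset data.frame (see [dataset]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- records[, .record_cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Clean records: drop invalid SMILES and non-representable elements
#'
#' Applies the database cleaning rule: a record is retained iff its SMILES
#' parses and the molecule contains only elements the fingerprint can
#' represent (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I plus the heavy-metal
#' feature's Au, Bi, Ir, Ru, Eu). Everything else is rejected with reason
#' `invalid_smiles` or `disallowed_element`. Cleaning never throws on data
#' content, never mutates retained field values, and is idempotent.
#'
#' @param records A dataset data.frame.
#' @return A list with `records` (the retained rows, provenance preserved)
#'   and `rejections` (data.frame of `index`, `smiles`, `reason`).
#' @export
clean_records <- function(records) {
  n <- nrow(records)
  reason <- character(n)
  for (i in seq_len(n)) {
    mol <- tryCatch(parse_smiles(records$smiles[i]), error = function(e) NULL)
    if (is.null(mol)) {
      reason[i] <- "invalid_smiles"
    } else if (length(setdiff(.mol_elements(mol), .allowed_elements)) > 0) {
      reason[i] <- "disallowed_element"
    }
  }
  keep <- !nzchar(reason)
  rejections <- data.frame(index = which(!keep), smiles = records$smiles[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(records, "provenance")
  list(records = out, rejections = rejections)
}

#' Convert an emission wavelength to a transition energy
#'
#' Uses the approximate conversion E = 1240 / lambda with the constant 1240
#' exactly as conventionally printed (not 1239.84): a wavelength in nm maps
#' to an energy in eV. The function is its own inverse under exchange of the
#' two scales, so it also converts an energy in eV back to a wavelength in nm.
#'
#' @param lambda_nm Positive wavelength(s) in nm (or energies in eV for the
#'   inverse direction).
#' @return Energy in eV (or wavelength in nm), same length as the input.
#' @examples
#' wavelength_to_energy(1240)          # 1 eV
#' wavelength_to_energy(548)           # 2.263 eV
#' @export
wavelength_to_energy <- function(lambda_nm) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop("wavelength must be positive and finite")
  }
  1240 / lambda_nm
}

#' @rdname wavelength_to_energy
#' @param energy_ev Positive energy/energies in eV.
#' @export
energy_to_wavelength <- function(energy_ev) wavelength_to_energy(energy_ev)
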