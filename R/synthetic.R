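#' Default fragment library for synthetic chromophore assembly
#'
#' Fragments used by [assemble_molecule()] to build donor--acceptor
#' chromophores by string substitution into core templates. Cores are SMILES
#' templates containing `{R}` slots; each slot is either left unsubstituted
#' or replaced by an attachable fragment bonded through a single bond.
#' Every donor fragment activates at least one of fingerprint digits 1--15
#' when attached, every acceptor at least one of digits 16--38, and every
#' breaker at least one of digits 39--45.
#'
#' @return A list of class `"fragment_library"` with components `cores`,
#'   `donors`, `acceptors`, `breakers`; each is a named character vector of
#'   SMILES (templates for cores, attachable groups otherwise).
#' @export
default_fragment_library <- function() {
  structure(list(
    cores = c(
      benzene     = "c1c{R}c{R}c{R}c{R}c1",
      biphenyl    = "c1cc{R}ccc1c1ccc{R}cc1",
      naphthalene = "c1cc{R}c2cc{R}ccc2c1",
      pyrazine    = "c1nc{R}c{R}nc1{R}",
      ethylene    = "C{R}{R}=C{R}{R}"
    ),
    donors = c(
      dimethylamino   = "N(C)C",
      triphenylamine  = "N(c1ccccc1)c1ccccc1",
      methoxy         = "OC",
      thienyl         = "c1cccs1",
      vinyl           = "C=C",
      salicylaldimine = "N=Cc1ccccc1O"
    ),
    acceptors = c(
      cyano    = "C#N",
      aldehyde = "C=O",
      pyridyl  = "c1ccncc1",
      fluoro   = "F"
    ),
    breakers = c(
      tbutyl        = "C(C)(C)C",
      tamyl         = "C(C)(C)CC",
      phenylethyl   = "C(c1ccccc1)C"
    )
  ), class = "fragment_library")
}

#' Ground-truth structure-property law for synthetic data
#'
#' Parameters of the generative law used by [generate_dataset()]. With
#' D = sum of donor digits 1--15, A = sum of acceptor digits 16--38 and
#' s46 the aromatic atom count of a molecule's POFP(num), the synthetic
#' solid-state transition energy is
#'
#' `E = e0 - coef_donor*D - coef_acceptor*A - coef_synergy*min(D, A)
#'     - coef_aromatic*s46 + Normal(0, noise_sd)`
#'
#' clipped to `[1.1, 3.9]` eV (about 318--1127 nm, the span of curated
#' solid-state emission data). The functional form is an invention of this
#' package, chosen to encode the qualitative design rules of the field:
#' donors, acceptors and conjugation red-shift emission, and donor--acceptor
#' co-presence is synergistic.
#'
#' @param e0 Intercept energy in eV.
#' @param coef_donor,coef_acceptor,coef_synergy eV per fragment count.
#' @param coef_aromatic eV per aromatic atom.
#' @param noise_sd Gaussian noise standard deviation in eV.
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth_defaults <- function(e0 = 3.6, coef_donor = 0.12,
                                  coef_acceptor = 0.10, coef_synergy = 0.20,
                                  coef_aromatic = 0.010, noise_sd = 0.05) {
  stopifnot(noise_sd >= 0, is.finite(c(e0, coef_donor, coef_acceptor,
                                       coef_synergy, coef_aromatic)))
  structure(list(e0 = e0, coef_donor = coef_donor,
                 coef_acceptor = coef_acceptor, coef_synergy = coef_synergy,
                 coef_aromatic = coef_aromatic, noise_sd = noise_sd,
                 e_min = 1.1, e_max = 3.9), class = "ground_truth")
}

#' Assemble one random chromophore SMILES
#'
#' Draws a core uniformly from the library and substitutes randomly drawn
#' donors (0--3), acceptors (0--3) and breakers (0--2) into its open `{R}`
#' slots via single bonds; unused slots become hydrogens. Uses R's current
#' random-number stream, so a `set.seed()` call beforehand makes the sequence
#' of assemblies reproducible. Assembly retries (up to 5 times) if the
#' resulting SMILES fails to parse, then falls back to the bare core.
#'
#' @param library A `"fragment_library"`; see [default_fragment_library()].
#' @param p_donors,p_acceptors,p_breakers Categorical probabilities for the
#'   number of fragments of each kind (donors/acceptors over 0:3, breakers
#'   over 0:2).
#' @return A single valid SMILES string.
#' @export
assemble_molecule <- function(library = default_fragment_library(),
                              p_donors = c(0.2, 0.4, 0.25, 0.15),
                              p_acceptors = c(0.2, 0.4, 0.25, 0.15),
                              p_breakers = c(0.5, 0.3, 0.2)) {
  stopifnot(inherits(library, "fragment_library"))
  for (attempt in 1:5) {
    core <- sample(library$cores, 1)
    n_slots <- lengths(regmatches(core, gregexpr("\\{R\\}", core)))
    nd <- sample(0:3, 1, prob = p_donors)
    na <- sample(0:3, 1, prob = p_acceptors)
    nb <- sample(0:2, 1, prob = p_breakers)
    frags <- c(
      if (nd > 0) sample(library$donors, nd, replace = TRUE),
      if (na > 0) sample(library$acceptors, na, replace = TRUE),
      if (nb > 0) sample(library$breakers, nb, replace = TRUE)
    )
    # fill slots in random order; excess fragments are dropped
    frags <- if (length(frags) > 0) sample(frags) else character(0)
    smi <- .renumber_rings(core, frags, n_slots)
    ok <- tryCatch({parse_smiles(smi); TRUE}, error = function(e) FALSE)
    if (ok) return(smi)
  }
  sub_all <- gsub("\\{R\\}", "", sample(library$cores, 1))
  sub_all
}

# substitute fragments into the core, renumbering each fragment's ring
# closures (digits after aromatic/aliphatic atoms) into the %10+ range so
# they cannot collide with core ring numbers
.renumber_rings <- function(core, frags, n_slots) {
  counter <- 10L
  smi <- core
  for (k in seq_len(n_slots)) {
    if (k <= length(frags)) {
      f <- frags[k]
      # ring digits 1-9 in the fragment -> unique %nn labels
      for (d in unique(unlist(regmatches(f, gregexpr("[0-9]", f))))) {
        f <- gsub(d, paste0("%", counter), f, fixed = TRUE)
        counter <- counter + 1L
      }
      smi <- sub("\\{R\\}", paste0("(", f, ")"), smi)
    } else {
      smi <- sub("\\{R\\}", "", smi)
    }
  }
  smi
}

#' Ground-truth transition energy of a fingerprint
#'
#' Evaluates the generative law of [ground_truth_defaults()] on a POFP(num)
#' vector, adding Gaussian noise from R's current random-number stream (none
#' if `noise_sd = 0`).
#'
#' @param fp A numeric vector of length 46 (POFP in num mode).
#' @param gt A `"ground_truth"` parameter list.
#' @return Energy in eV, clipped to the ground truth's `[e_min, e_max]`.
#' @export
ground_truth_energy <- function(fp, gt = ground_truth_defaults()) {
  stopifnot(length(fp) == 46)
  D <- sum(fp[1:15]); A <- sum(fp[16:38]); s46 <- fp[46]
  e <- gt$e0 - gt$coef_donor * D - gt$coef_acceptor * A -
    gt$coef_synergy * min(D, A) - gt$coef_aromatic * s46
  if (gt$noise_sd > 0) e <- e + stats::rnorm(1, 0, gt$noise_sd)
  min(max(e, gt$e_min), gt$e_max)
}

#' Ground-truth aggregate-feature class of a fingerprint
#'
#' Deterministic-plus-tie rule encoding the "conjugation is a double-edged
#' sword" structure: a flexibility score `X = 2*s10 + 2*s17 +
#' sum(s39..s45) + sum(s13..s15)` is compared with a rigidity score
#' `Y = s46 / 6`. The label is `AIE` when `X > Y`, `ACQ` when `X <= Y - 1`
#' (boundary ties resolve to ACQ), and otherwise one of `TADF`, `AIDF`,
#' `RTP` drawn uniformly from R's current random-number stream.
#'
#' @inheritParams ground_truth_energy
#' @return One of `"AIE"`, `"ACQ"`, `"TADF"`, `"AIDF"`, `"RTP"`.
#' @export
ground_truth_class <- function(fp, gt = ground_truth_defaults()) {
  stopifnot(length(fp) == 46)
  X <- 2 * fp[10] + 2 * fp[17] + sum(fp[39:45]) + sum(fp[13:15])
  Y <- fp[46] / 6
  if (X > Y) return("AIE")
  if (X <= Y - 1) return("ACQ")
  sample(c("TADF", "AIDF", "RTP"), 1)
}

#' Ground-truth excited-state mechanism of a fingerprint
#'
#' Mechanisms track the presence of their representative functional groups:
#' `ESIPT` if any of the ESIPT digits 13--15 is active, else `ICT_TICT` if
#' both a donor (digits 1--15) and an acceptor (digits 16--38) are present,
#' else `CL` (clusterluminescence) if there is no aromatic system at all but
#' donor heteroatom substructures are present, else `NA` (neutral
#' aromaticity).
#'
#' @inheritParams ground_truth_energy
#' @return One of `"ESIPT"`, `"ICT_TICT"`, `"CL"`, `"NA"`.
#' @export
ground_truth_mechanism <- function(fp) {
  stopifnot(length(fp) == 46)
  D <- sum(fp[1:15]); A <- sum(fp[16:38])
  if (sum(fp[13:15]) > 0) return("ESIPT")
  if (D > 0 && A > 0) return("ICT_TICT")
  if (fp[46] == 0 && D > 0) return("CL")
  "NA"
}

#' Generate a synthetic photophysics dataset
#'
#' Assembles `n` chromophores from the fragment library, fingerprints them,
#' and labels each with a solid-state emission wavelength, feature class and
#' mechanism from the ground-truth law. Fully deterministic given `seed`.
#'
#' @param n Number of records.
#' @param seed Integer seed controlling assembly, noise and tie-breaking.
#' @param gt A `"ground_truth"` parameter list.
#' @param library A `"fragment_library"`.
#' @return A list with `records` (a dataset data.frame as in [dataset], with
#'   provenance tag `"synthetic:seed=<seed>"`) and `fingerprints` (the
#'   `n x 46` POFP(num) matrix of the generated molecules, so callers need
#'   not recompute it).
#' @examples
#' \donttest{
#' ds <- generate_dataset(20, seed = 1)
#' head(ds$records)
#' }
#' @export
generate_dataset <- function(n, seed = 42L, gt = ground_truth_defaults(),
                             library = default_fragment_library()) {
  stopifnot(n >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  smiles <- character(n)
  for (i in seq_len(n)) smiles[i] <- assemble_molecule(library)
  ft <- fingerprint_table(smiles, mode = "num")
  if (nrow(ft$rejections) > 0) {
    stop("internal error: assembled SMILES failed to fingerprint: ",
         paste(ft$rejections$smiles, collapse = ", "))
  }
  fp <- ft$fingerprints
  energy <- numeric(n); fclass <- character(n); mech <- character(n)
  for (i in seq_len(n)) {
    energy[i] <- ground_truth_energy(fp[i, ], gt)
    fclass[i] <- ground_truth_class(fp[i, ], gt)
    mech[i] <- ground_truth_mechanism(fp[i, ])
  }
  records <- data.frame(
    smiles = ft$smiles,
    lambda_solid_nm = if (n > 0) round(1240 / energy, 4) else numeric(0),
    lambda_agg_nm = rep(NA_real_, n),
    qy = rep(NA_real_, n),
    lifetime_ns = rep(NA_real_, n),
    feature_class = fclass,
    mechanism = mech,
    stringsAsFactors = FALSE
  )
  attr(records, "provenance") <- paste0("synthetic:seed=", as.integer(seed))
  list(records = records, fingerprints = fp)
}
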