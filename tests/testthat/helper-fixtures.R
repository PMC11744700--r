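# Shared fixtures: built in code, cached for the duration of the test run.

TPE_SMILES <- "C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1"

# 20 small molecules (<= 20 heavy atoms) spanning every feature category:
# donors, acceptors, ESIPT patterns, breakers, plain aromatics
fixture_panel <- function() {
  c(benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    naphthalene = "c1ccc2ccccc2c1",
    stilbene = "C(=Cc1ccccc1)c1ccccc1",
    benzonitrile = "N#Cc1ccccc1",
    aniline = "Nc1ccccc1",
    dimethylaniline = "CN(C)c1ccccc1",
    anisole = "COc1ccccc1",
    diphenylether = "c1ccc(Oc2ccccc2)cc1",
    thiophene = "c1ccsc1",
    furan = "c1ccoc1",
    pyridine = "c1ccncc1",
    pyrazine = "c1cnccn1",
    salicylaldehyde = "O=Cc1ccccc1O",
    salicylaldimine = "Oc1ccccc1C=Nc1ccccc1",
    tbutylbenzene = "CC(C)(C)c1ccccc1",
    oxylene = "Cc1ccccc1C",
    fluorotoluene = "Cc1ccc(F)cc1",
    benzophenone = "O=C(c1ccccc1)c1ccccc1",
    phenylacetylene = "C#Cc1ccccc1")
}

# independent brute-force match counter: enumerate every subgraph isomorphism
# with RDKit (a separate codebase from the OpenBabel matcher under test),
# deduplicate matches by atom-index set, count the distinct sets
oracle_counts <- function(molecules, patterns) {
  script <- system.file("oracle", "subgraph_count.py", package = "pofpr")
  stopifnot(nzchar(script))
  task <- jsonlite::toJSON(list(molecules = molecules, patterns = patterns),
                           auto_unbox = FALSE)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(task, f)
  res <- system2("python", script, stdin = f, stdout = TRUE, stderr = FALSE)
  out <- jsonlite::fromJSON(paste(res, collapse = ""))
  matrix(out, nrow = length(molecules), ncol = length(patterns))
}

# memoized synthetic study dataset (the paper-scale 700-record run) and
# models derived from it, so expensive fixtures are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

syn700 <- function() {
  if (is.null(.fixture_cache$syn700)) {
    .fixture_cache$syn700 <- generate_dataset(700, seed = 42)
  }
  .fixture_cache$syn700
}

syn700_reg_model <- function() {
  if (is.null(.fixture_cache$reg_model)) {
    ds <- syn700()
    .fixture_cache$reg_model <- fit_model(
      model_spec("fcnn", "regression", seed = 42),
      ds$fingerprints, wavelength_to_energy(ds$records$lambda_solid_nm))
  }
  .fixture_cache$reg_model
}

syn700_class_model <- function() {
  if (is.null(.fixture_cache$class_model)) {
    ds <- syn700()
    .fixture_cache$class_model <- fit_model(
      model_spec("fcnn", "classification", seed = 42),
      ds$fingerprints, ds$records$feature_class)
  }
  .fixture_cache$class_model
}

# small regression FCNN on random smooth data, for attribution tests
small_fcnn_regression <- function() {
  if (is.null(.fixture_cache$small_fcnn)) {
    set.seed(7)
    X <- matrix(rnorm(200 * 46), 200, 46)
    y <- as.numeric(X %*% rnorm(46, 0, 0.3)) + 0.5 * sin(X[, 1]) + rnorm(200, 0, 0.01)
    .fixture_cache$small_fcnn <- fit_model(
      model_spec("fcnn", "regression", list(epochs = 60), seed = 7), X, y)
  }
  .fixture_cache$small_fcnn
}
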