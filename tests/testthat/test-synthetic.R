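test_that("assembly is deterministic under seed and always parseable", {
  set.seed(11)
  a <- replicate(25, assemble_molecule())
  set.seed(11)
  b <- replicate(25, assemble_molecule())
  expect_identical(a, b)

  set.seed(12)
  many <- replicate(200, assemble_molecule())
  ft <- fingerprint_table(many, mode = "num")
  expect_equal(nrow(ft$rejections), 0)   # every assembly survives the pipeline
})

test_that("a degenerate library yields the bare core", {
  lib <- structure(list(cores = c(benzene = "c1c{R}c{R}c{R}c{R}c1"),
                        donors = c(x = "C"), acceptors = c(x = "C"),
                        breakers = c(x = "C")),
                   class = "fragment_library")
  set.seed(1)
  out <- replicate(5, assemble_molecule(lib, p_donors = c(1, 0, 0, 0),
                                        p_acceptors = c(1, 0, 0, 0),
                                        p_breakers = c(1, 0, 0)))
  expect_true(all(out == "c1ccccc1"))
})

test_that("library fragments activate the digits of their category", {
  lib <- default_fragment_library()
  core <- "c1ccccc1"
  attach_one <- function(frag) {
    f <- frag
    for (d in unique(unlist(regmatches(f, gregexpr("[0-9]", f))))) {
      f <- gsub(d, paste0("%1", d), f, fixed = TRUE)
    }
    as.numeric(compute_pofp(paste0("c1cc(", f, ")ccc1")))
  }
  for (nm in names(lib$donors)) {
    expect_gt(sum(attach_one(lib$donors[[nm]])[1:15]), 0, label = nm)
  }
  for (nm in names(lib$acceptors)) {
    expect_gt(sum(attach_one(lib$acceptors[[nm]])[16:38]), 0, label = nm)
  }
  for (nm in names(lib$breakers)) {
    expect_gt(sum(attach_one(lib$breakers[[nm]])[39:45]), 0, label = nm)
  }
})

test_that("ground-truth energy follows its stated closed form", {
  gt0 <- ground_truth_defaults(noise_sd = 0)
  benzene <- as.numeric(compute_pofp("c1ccccc1"))
  expect_equal(ground_truth_energy(benzene, gt0), 3.6 - 0.010 * 6)  # 3.54
  zero <- rep(0, 46)
  expect_equal(ground_truth_energy(zero, gt0), 3.6)  # e0, inside the clip
  # adding one acceptor to a donor-rich fingerprint costs
  # coef_acceptor + coef_synergy
  fp <- zero; fp[3] <- 2; fp[16] <- 0
  e_before <- ground_truth_energy(fp, gt0)
  fp[16] <- 1
  expect_equal(e_before - ground_truth_energy(fp, gt0), 0.10 + 0.20)
  # clipping floor
  big <- zero; big[3] <- 10; big[16] <- 10; big[46] <- 100
  expect_equal(ground_truth_energy(big, gt0), 1.1)
})

test_that("class rule orders flexibility against rigidity as stated", {
  tpe <- as.numeric(compute_pofp(TPE_SMILES))
  # X = 2, Y = 4: firmly in the ACQ region under the defaults
  expect_equal(ground_truth_class(tpe), "ACQ")
  benzene <- as.numeric(compute_pofp("c1ccccc1"))
  expect_equal(ground_truth_class(benzene), "ACQ")   # X=0 ties to ACQ
  flexible <- rep(0, 46); flexible[10] <- 2; flexible[46] <- 6
  expect_equal(ground_truth_class(flexible), "AIE")  # X=4 > Y=1
})

test_that("generated labels agree with the rule recomputed offline", {
  ds <- syn700()
  fp <- ds$fingerprints
  X <- 2 * fp[, 10] + 2 * fp[, 17] + rowSums(fp[, 39:45]) +
    rowSums(fp[, 13:15])
  Y <- fp[, 46] / 6
  cls <- ds$records$feature_class
  expect_true(all(cls[X > Y] == "AIE"))
  expect_true(all(cls[X <= Y - 1] == "ACQ"))
  mid <- X > Y - 1 & X <= Y
  expect_true(all(cls[mid] %in% c("TADF", "AIDF", "RTP")))
  # mechanisms track their functional groups deterministically
  mech <- ds$records$mechanism
  expect_true(all((rowSums(fp[, 13:15]) > 0) == (mech == "ESIPT")))
  D <- rowSums(fp[, 1:15]); A <- rowSums(fp[, 16:38])
  expect_true(all(mech[rowSums(fp[, 13:15]) == 0 & D > 0 & A > 0] ==
                    "ICT_TICT"))
})

test_that("the dataset embeds the qualitative design laws", {
  ds <- syn700()
  recs <- ds$records
  fp <- ds$fingerprints
  expect_true(all(recs$lambda_solid_nm >= 318 &
                    recs$lambda_solid_nm <= 1128))
  # (a) mean energy decreases with donor+acceptor count
  E <- wavelength_to_energy(recs$lambda_solid_nm)
  da <- rowSums(fp[, 1:38])
  grp <- cut(da, breaks = c(-0.5, 0.5, 2.5, 4.5, Inf))
  means <- tapply(E, grp, mean)
  expect_true(all(diff(means) < 0))
  # (b) AIE frequency decreases with aromatic count at fixed flexibility
  X <- 2 * fp[, 10] + 2 * fp[, 17] + rowSums(fp[, 39:45]) +
    rowSums(fp[, 13:15])
  sel <- X >= 1 & X <= 3
  aie <- recs$feature_class[sel] == "AIE"
  s46 <- fp[sel, 46]
  lo <- s46 <= stats::median(s46)
  expect_gt(mean(aie[lo]), mean(aie[!lo]))
})

test_that("generation is reproducible to the byte", {
  d1 <- generate_dataset(40, seed = 9)
  d2 <- generate_dataset(40, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_records(d1$records, f1)
  write_records(d2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  expect_equal(attr(d1$records, "provenance"), "synthetic:seed=9")
  d0 <- generate_dataset(0, seed = 1)
  expect_equal(nrow(d0$records), 0)
})
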