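#' Configuration of the conditional variational autoencoder
#'
#' The CVAE encodes a POFP(num) vector concatenated with the solid-state
#' emission energy `E = 1240/lambda` into a low-dimensional Gaussian latent
#' (two-layer ReLU encoder emitting a mean and a log-variance per latent
#' dimension), and decodes latent-plus-energy back to a 46-vector with a
#' two-layer ReLU decoder. The default latent dimension is 2, so the decoder
#' input (latent plus the energy condition) is 3-dimensional. Training
#' minimizes reconstruction MSE plus `kl_weight` times the KL divergence of
#' the latent posterior from N(0, I), via the reparameterization trick.
#' Fingerprint columns and the energy condition are standardized with
#' training-set statistics (stored with the model and inverted at
#' generation time).
#'
#' @param latent_dim Latent dimensionality (default 2).
#' @param encoder_hidden,decoder_hidden Two hidden-layer widths each.
#' @param kl_weight Weight of the KL term (>= 0, default 1).
#' @param epochs,batch,lr Training schedule (Adam).
#' @param seed Integer seed: weight init, shuffling and reparameterization
#'   noise all derive from it.
#' @return A list of class `"cvae_config"`.
#' @export
cvae_config <- function(latent_dim = 2L, encoder_hidden = c(64L, 32L),
                        decoder_hidden = c(32L, 64L), kl_weight = 1,
                        epochs = 200L, batch = 32L, lr = 1e-3, seed = 1L) {
  stopifnot(latent_dim >= 1, kl_weight >= 0, length(encoder_hidden) == 2,
            length(decoder_hidden) == 2)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 kl_weight = kl_weight, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, seed = as.integer(seed)),
            class = "cvae_config")
}

.cvae_init <- function(input_dim, config) {
  L <- config$latent_dim
  eh <- config$encoder_hidden; dh <- config$decoder_hidden
  dims_e <- c(input_dim + 1L, eh)
  dims_d <- c(L + 1L, dh, input_dim)
  he <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  list(
    We1 = he(dims_e[1], dims_e[2]), be1 = rep(0, dims_e[2]),
    We2 = he(dims_e[2], dims_e[3]), be2 = rep(0, dims_e[3]),
    Wmu = he(dims_e[3], L), bmu = rep(0, L),
    Wlv = matrix(0, dims_e[3], L), blv = rep(0, L),
    Wd1 = he(dims_d[1], dims_d[2]), bd1 = rep(0, dims_d[2]),
    Wd2 = he(dims_d[2], dims_d[3]), bd2 = rep(0, dims_d[3]),
    Wd3 = he(dims_d[3], dims_d[4]), bd3 = rep(0, dims_d[4])
  )
}

.cvae_encode <- function(p, Xe) {
  Z1 <- sweep(Xe %*% p$We1, 2, p$be1, "+"); A1 <- .relu(Z1)
  Z2 <- sweep(A1 %*% p$We2, 2, p$be2, "+"); A2 <- .relu(Z2)
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
       mu = sweep(A2 %*% p$Wmu, 2, p$bmu, "+"),
       lv = sweep(A2 %*% p$Wlv, 2, p$blv, "+"))
}

.cvae_decode <- function(p, Din) {
  Z3 <- sweep(Din %*% p$Wd1, 2, p$bd1, "+"); A3 <- .relu(Z3)
  Z4 <- sweep(A3 %*% p$Wd2, 2, p$bd2, "+"); A4 <- .relu(Z4)
  out <- sweep(A4 %*% p$Wd3, 2, p$bd3, "+")
  list(Z3 = Z3, A3 = A3, Z4 = Z4, A4 = A4, out = out)
}

#' Train the conditional variational autoencoder
#'
#' @param records A dataset data.frame (see [dataset]) with non-missing
#'   `lambda_solid_nm`; rows with a missing wavelength are dropped. The
#'   condition is `E = 1240/lambda` in eV.
#' @param config A [cvae_config()].
#' @param fingerprints Optional precomputed `n x 46` POFP(num) matrix
#'   matching `records` rows (e.g. from [generate_dataset()]); computed from
#'   `records$smiles` when `NULL`.
#' @return A list of class `"cvae_model"`: trained parameters, the
#'   fingerprint and energy scalers, `config`, and `trace` (a data.frame of
#'   per-epoch mean reconstruction MSE, mean KL and total loss).
#' @export
train_cvae <- function(records, config = cvae_config(), fingerprints = NULL) {
  keep <- !is.na(records$lambda_solid_nm)
  if (!any(keep)) stop("no records with solid-state wavelengths")
  lambda <- records$lambda_solid_nm[keep]
  if (is.null(fingerprints)) {
    ft <- fingerprint_table(records$smiles[keep], mode = "num")
    if (nrow(ft$rejections) > 0) {
      stop("unfingerprintable SMILES in training data; clean the records first")
    }
    fingerprints <- ft$fingerprints
  } else {
    fingerprints <- as.matrix(fingerprints)[keep, , drop = FALSE]
  }
  n <- nrow(fingerprints)
  stopifnot(n >= 2, length(lambda) == n)
  E <- wavelength_to_energy(lambda)

  fp_scaler <- .fit_scaler(fingerprints)
  Xs <- .apply_scaler(fp_scaler, fingerprints)
  e_scaler <- list(center = mean(E), scale = max(stats::sd(E), 1e-12))
  Es <- (E - e_scaler$center) / e_scaler$scale

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  p <- .cvae_init(ncol(Xs), config)
  L <- config$latent_dim
  klw <- config$kl_weight

  # Adam state
  m <- lapply(p, function(w) w * 0)
  v <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8; t_step <- 0
  trace <- data.frame(epoch = integer(0), recon_mse = numeric(0),
                      kl = numeric(0), loss = numeric(0))

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_rec <- ep_kl <- c()
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1, n)]
      nb <- length(idx)
      Xb <- Xs[idx, , drop = FALSE]
      Eb <- Es[idx]
      Xe <- cbind(Xb, Eb)
      enc <- .cvae_encode(p, Xe)
      epsn <- matrix(stats::rnorm(nb * L), nb, L)
      sd_z <- exp(0.5 * enc$lv)
      z <- enc$mu + epsn * sd_z
      Din <- cbind(z, Eb)
      dec <- .cvae_decode(p, Din)

      rec <- mean((dec$out - Xb)^2)
      kl <- mean(-0.5 * rowSums(1 + enc$lv - enc$mu^2 - exp(enc$lv)))
      ep_rec <- c(ep_rec, rec); ep_kl <- c(ep_kl, kl)

      # ---- backward ----
      g <- list()
      dout <- 2 * (dec$out - Xb) / (nb * ncol(Xb))
      g$Wd3 <- crossprod(dec$A4, dout); g$bd3 <- colSums(dout)
      dA4 <- dout %*% t(p$Wd3); dZ4 <- dA4 * (dec$Z4 > 0)
      g$Wd2 <- crossprod(dec$A3, dZ4); g$bd2 <- colSums(dZ4)
      dA3 <- dZ4 %*% t(p$Wd2); dZ3 <- dA3 * (dec$Z3 > 0)
      g$Wd1 <- crossprod(Din, dZ3); g$bd1 <- colSums(dZ3)
      dDin <- dZ3 %*% t(p$Wd1)
      dz <- dDin[, seq_len(L), drop = FALSE]
      dmu <- dz + klw * enc$mu / nb
      dlv <- dz * epsn * 0.5 * sd_z + klw * 0.5 * (exp(enc$lv) - 1) / nb
      g$Wmu <- crossprod(enc$A2, dmu); g$bmu <- colSums(dmu)
      g$Wlv <- crossprod(enc$A2, dlv); g$blv <- colSums(dlv)
      dA2 <- dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv)
      dZ2 <- dA2 * (enc$Z2 > 0)
      g$We2 <- crossprod(enc$A1, dZ2); g$be2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(p$We2); dZ1 <- dA1 * (enc$Z1 > 0)
      g$We1 <- crossprod(Xe, dZ1); g$be1 <- colSums(dZ1)

      t_step <- t_step + 1
      for (nm in names(p)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t_step)
        vhat <- v[[nm]] / (1 - beta2^t_step)
        p[[nm]] <- p[[nm]] - config$lr * mhat / (sqrt(vhat) + eps_adam)
      }
    }
    trace <- rbind(trace, data.frame(epoch = ep, recon_mse = mean(ep_rec),
                                     kl = mean(ep_kl),
                                     loss = mean(ep_rec) + klw * mean(ep_kl)))
  }
  structure(list(params = p, config = config, fp_scaler = fp_scaler,
                 e_scaler = e_scaler, trace = trace, input_dim = ncol(Xs)),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat("cvae_model: latent_dim =", x$config$latent_dim, ", final loss =",
      signif(utils::tail(x$trace$loss, 1), 5), "\n")
  invisible(x)
}

#' Encode records into the latent space
#'
#' Returns the posterior means and log-variances for each record, mainly for
#' diagnostics (e.g. checking that stronger KL regularization pulls the
#' posterior means toward 0).
#'
#' @param model A `"cvae_model"`.
#' @param fingerprints `n x 46` POFP(num) matrix.
#' @param lambda_nm Wavelengths (nm), length n.
#' @return A list with matrices `mu` and `logvar` (`n x latent_dim`).
#' @export
cvae_encode <- function(model, fingerprints, lambda_nm) {
  Xs <- .apply_scaler(model$fp_scaler, as.matrix(fingerprints))
  Es <- (wavelength_to_energy(lambda_nm) - model$e_scaler$center) /
    model$e_scaler$scale
  enc <- .cvae_encode(model$params, cbind(Xs, Es))
  list(mu = enc$mu, logvar = enc$lv)
}

#' Decode the mean fingerprint profile at a target wavelength
#'
#' Feeds the latent origin (z = 0, i.e. the prior mean, with no sampling
#' noise) plus the standardized target emission energy `E = 1240/lambda`
#' into the trained decoder. The output approximates the average POFP(num)
#' of training structures emitting at the target wavelength. Counts are
#' clipped at 0 at report time only (the decoder itself is linear-output).
#'
#' @param model A `"cvae_model"`.
#' @param lambda_target Target emission wavelength in nm (> 0).
#' @return Named numeric vector of length 46 (`s1`...`s46`), non-negative.
#' @export
generate_profile <- function(model, lambda_target) {
  stopifnot(lambda_target > 0)
  Es <- (wavelength_to_energy(lambda_target) - model$e_scaler$center) /
    model$e_scaler$scale
  Din <- matrix(c(rep(0, model$config$latent_dim), Es), nrow = 1)
  out <- .cvae_decode(model$params, Din)$out[1, ]
  raw <- out * model$fp_scaler$scale + model$fp_scaler$center
  raw <- pmax(raw, 0)
  names(raw) <- pofp_digit_names()
  raw
}

#' Mean fingerprint profiles across target wavelengths
#'
#' Decodes [generate_profile()] at each wavelength and summarizes, per
#' feature, the monotonic trend of the profile across wavelengths (Spearman
#' rank correlation of the feature value against wavelength; `NA` for
#' features that are constant across the sweep).
#'
#' @param model A `"cvae_model"`.
#' @param wavelengths Wavelengths in nm (default `c(400, 500, 600, 800,
#'   1000)`).
#' @return A list of class `"cvae_profile_report"`: `table` (data.frame,
#'   one row per wavelength: `lambda_nm`, `s1`...`s46`) and `trend` (named
#'   length-46 vector of Spearman rho).
#' @export
profile_report <- function(model, wavelengths = c(400, 500, 600, 800, 1000)) {
  profs <- t(vapply(wavelengths, function(w) generate_profile(model, w),
                    numeric(46)))
  tab <- data.frame(lambda_nm = wavelengths, profs, check.names = FALSE)
  trend <- apply(profs, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    suppressWarnings(stats::cor(wavelengths, col, method = "spearman"))
  })
  names(trend) <- pofp_digit_names()
  structure(list(table = tab, trend = trend), class = "cvae_profile_report")
}

#' @export
print.cvae_profile_report <- function(x, ...) {
  cat("cvae profile report:", nrow(x$table), "wavelengths\n")
  invisible(x)
}

#' Write a profile report to CSV
#'
#' @param report A `"cvae_profile_report"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(report, path) {
  stopifnot(inherits(report, "cvae_profile_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
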