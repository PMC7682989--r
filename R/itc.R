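## Independent identical-sites ITC binding model: closed-form equilibrium,
## forward simulation of a perfusion-cell titration with displacement
## dilution, and multi-start least-squares fitting of (n, K_D, dH, offset).

#' ITC titration experiment
#'
#' Titration design and (optionally) measured integrated heats. All
#' concentrations are molar, volumes in litres, heats in microcalories and
#' molar enthalpies in cal/mol of injectant (1 cal = 4.184 J).
#'
#' @param cell_conc macromolecule concentration in the cell, mol/L.
#' @param syringe_conc titrant concentration in the syringe, mol/L.
#' @param injection_volumes per-injection volumes, L.
#' @param cell_volume working cell volume, L (default 185 uL, a typical
#'   perfusion-cell calorimeter).
#' @param heats optional measured heats, ucal (same length as
#'   `injection_volumes`).
#' @param temperature bath temperature, degrees C.
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_conc, syringe_conc, injection_volumes,
                           cell_volume = 185e-6, heats = NULL,
                           temperature = 25) {
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0 ||
      any(injection_volumes <= 0))
    stop("concentrations and volumes must all be > 0")
  if (!is.null(heats) && length(heats) != length(injection_volumes))
    stop("heats and injection_volumes differ in length")
  if (sum(injection_volumes) >= cell_volume)
    stop("cumulative injected volume reaches the cell volume")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 heats = heats, temperature = temperature),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "itc_experiment: %.3g M cell / %.3g M syringe, %d injections, %.0f uL cell, %g C%s\n",
    x$cell_conc, x$syringe_conc, length(x$injection_volumes),
    x$cell_volume * 1e6, x$temperature,
    if (is.null(x$heats)) " (design only)" else ""))
  invisible(x)
}

#' Bound titrant at equilibrium (independent identical sites)
#'
#' Physical root of
#' `Xb^2 - Xb * (n*Mt + Xt + Kd) + n*Mt*Xt = 0`,
#' guaranteed in `[0, min(n*Mt, Xt)]`. Written in the numerically stable
#' form `2*n*Mt*Xt / (s + sqrt(s^2 - 4*n*Mt*Xt))` with
#' `s = n*Mt + Xt + Kd`.
#'
#' @param mt total macromolecule concentration, mol/L.
#' @param xt total titrant concentration, mol/L.
#' @param n sites per macromolecule.
#' @param kd dissociation constant, mol/L.
#' @return Bound titrant concentration, mol/L (vectorized over `xt`).
#' @export
bound_fraction <- function(mt, xt, n, kd) {
  if (any(mt <= 0) || any(n <= 0) || any(kd <= 0) || any(xt < 0))
    stop("mt, n, kd must be > 0 and xt >= 0")
  s <- n * mt + xt + kd
  disc <- pmax(0, s^2 - 4 * n * mt * xt)
  2 * n * mt * xt / (s + sqrt(disc))
}

#' Simulate an independent-sites titration isotherm
#'
#' Perfusion-cell accounting with displacement dilution: each injection of
#' volume `v` dilutes the existing cell contents by `(1 - v/V0)` before
#' adding `v/V0 * syringe_conc` of titrant. The heat of injection `i` is
#' `dh * V0 * (Xb_i - Xb_(i-1) * (1 - v_i/V0)) * 1e6 + q_offset` ucal, with
#' `Xb` from [bound_fraction()] at the post-injection totals.
#'
#' @param design an [itc_experiment] (heats ignored).
#' @param n sites per macromolecule.
#' @param kd dissociation constant, mol/L.
#' @param dh binding enthalpy, cal per mol of injectant.
#' @param q_offset heat-of-dilution baseline per injection, ucal.
#' @return Numeric vector of per-injection heats, ucal.
#' @export
simulate_isotherm <- function(design, n, kd, dh, q_offset = 0) {
  v0 <- design$cell_volume
  mt <- design$cell_conc
  xt <- 0
  xb_prev <- 0
  heats <- numeric(length(design$injection_volumes))
  for (i in seq_along(heats)) {
    v <- design$injection_volumes[i]
    f <- 1 - v / v0
    mt <- mt * f
    xt <- xt * f + (v / v0) * design$syringe_conc
    xb <- bound_fraction(mt, xt, n, kd)
    heats[i] <- dh * v0 * (xb - xb_prev * f) * 1e6 + q_offset
    xb_prev <- xb
  }
  heats
}

#' Fit an independent-sites binding isotherm
#'
#' Minimizes the sum of squared heat residuals over `(n, Kd, dH,
#' q_offset)`. `dH` and `q_offset` enter the model linearly and are
#' profiled out exactly; `(n, log10 Kd)` are optimized by Nelder-Mead from
#' a deterministic multi-start grid (log-spaced `Kd` over 1e-9..1e-3 M
#' crossed with `n` in 0.5/1/2) unless an initial guess is supplied.
#'
#' @param experiment an [itc_experiment] with at least 5 heats.
#' @param initial_guess optional `list(n=, kd=, dh=, q_offset=)`; when
#'   given, the multi-start is replaced by this single start.
#' @param exclude_first drop the first injection before fitting (common
#'   ITC practice; default `FALSE`).
#' @return Object of class `binding_fit`: `n`, `kd` (mol/L), `dh`
#'   (cal/mol), `q_offset` (ucal), `rss` (ucal^2), `converged`,
#'   `wiseman_c` (`n * cell_conc / kd`) and `n_poorly_determined` (flagged
#'   when `wiseman_c < 0.5`, where the isotherm carries almost no
#'   stoichiometry information).
#' @export
fit_isotherm <- function(experiment, initial_guess = NULL,
                         exclude_first = FALSE) {
  heats <- experiment$heats
  if (is.null(heats)) stop("experiment carries no measured heats")
  design <- experiment
  if (exclude_first) {
    if (length(heats) < 6) stop("too few heats to exclude the first")
    # first injection still changes the cell contents; only its heat is
    # dropped from the residuals
    drop1 <- TRUE
  } else drop1 <- FALSE
  if (length(heats) < 5) stop("need at least 5 heats to fit")
  resid_idx <- if (drop1) -1 else TRUE
  obj <- function(par) {
    nn <- par[1]
    kd <- 10^par[2]
    if (nn < 1e-3 || nn > 50 || kd < 1e-15 || kd > 1) return(1e30)
    prof <- itc_profile_linear(design, nn, kd, heats, resid_idx)
    prof$rss
  }
  starts <- if (!is.null(initial_guess)) {
    list(c(initial_guess$n, log10(initial_guess$kd)))
  } else {
    grid <- expand.grid(n = c(0.5, 1, 2),
                        lkd = seq(-9, -3, by = 1))
    lapply(seq_len(nrow(grid)), function(i) c(grid$n[i], grid$lkd[i]))
  }
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the best optimum
  best <- optim(best$par, obj, method = "Nelder-Mead",
                control = list(maxit = 1000, reltol = 1e-14))
  n_hat <- best$par[1]
  kd_hat <- 10^best$par[2]
  prof <- itc_profile_linear(design, n_hat, kd_hat, heats, resid_idx)
  h <- heats[resid_idx]
  rss_flat <- sum((h - mean(h))^2)
  # an essentially-zero residual counts as optimizer success even when
  # Nelder-Mead stops on maxit while polishing noise-floor digits
  optimizer_ok <- best$convergence == 0 ||
    prof$rss <= 1e-12 * sum(h^2)
  converged <- optimizer_ok && rss_flat > 0 &&
    prof$rss <= 0.5 * rss_flat
  c_par <- n_hat * experiment$cell_conc / kd_hat
  structure(list(n = n_hat, kd = kd_hat,
                 dh = as.numeric(prof$dh),
                 q_offset = as.numeric(prof$q_offset),
                 rss = prof$rss, converged = converged,
                 wiseman_c = c_par,
                 n_poorly_determined = c_par < 0.5),
            class = "binding_fit")
}

# profile the linear parameters (dh, q_offset) out of the fit: for fixed
# (n, kd) the model heats are dh * basis + q_offset with basis the
# per-injection bound-titrant increments
itc_profile_linear <- function(design, n, kd, heats, resid_idx) {
  basis <- simulate_isotherm(design, n, kd, dh = 1, q_offset = 0)
  X <- cbind(basis[resid_idx], 1)
  y <- heats[resid_idx]
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients)))
    return(list(dh = 0, q_offset = mean(y),
                rss = sum((y - mean(y))^2)))
  list(dh = fit$coefficients[1], q_offset = fit$coefficients[2],
       rss = sum(fit$residuals^2))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "binding_fit: n = %.3f, Kd = %.3g M, dH = %.1f cal/mol, offset = %.3g ucal\n",
    x$n, x$kd, x$dh, x$q_offset))
  cat(sprintf("  rss = %.3g ucal^2, c = %.1f, converged = %s%s\n",
              x$rss, x$wiseman_c, x$converged,
              if (x$n_poorly_determined)
                " (n poorly determined: c < 0.5)" else ""))
  invisible(x)
}

#' Read an ITC experiment from TSV
#'
#' Header block of `# key<TAB>value` lines (`cell_volume_uL`,
#' `cell_conc_uM`, `syringe_conc_uM`, `temperature_C`) followed by a
#' tab-separated table with columns `injection_volume_uL` and (optionally)
#' `heat_ucal`.
#'
#' @param path TSV file.
#' @return An [itc_experiment].
#' @export
read_itc <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, lapply(hdr_lines, function(l) {
    parts <- strsplit(sub("^#\\s*", "", l), "[\t:]+")[[1]]
    c(trimws(parts[1]), trimws(parts[2]))
  }))
  hdr <- setNames(as.numeric(kv[, 2]), kv[, 1])
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  itc_experiment(cell_conc = hdr[["cell_conc_uM"]] * 1e-6,
                 syringe_conc = hdr[["syringe_conc_uM"]] * 1e-6,
                 injection_volumes = tab$injection_volume_uL * 1e-6,
                 cell_volume = hdr[["cell_volume_uL"]] * 1e-6,
                 heats = if ("heat_ucal" %in% names(tab)) tab$heat_ucal,
                 temperature = hdr[["temperature_C"]])
}

#' Write an ITC experiment to TSV
#'
#' @param experiment an [itc_experiment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_itc <- function(experiment, path) {
  hdr <- c(sprintf("# cell_volume_uL\t%g", experiment$cell_volume * 1e6),
           sprintf("# cell_conc_uM\t%g", experiment$cell_conc * 1e6),
           sprintf("# syringe_conc_uM\t%g", experiment$syringe_conc * 1e6),
           sprintf("# temperature_C\t%g", experiment$temperature))
  df <- data.frame(injection_volume_uL = experiment$injection_volumes * 1e6)
  if (!is.null(experiment$heats)) df$heat_ucal <- experiment$heats
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Write a binding fit as JSON
#'
#' @param fit a `binding_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
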