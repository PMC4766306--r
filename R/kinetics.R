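# Michaelis-Menten and substrate-inhibition kinetics, catalytic
# efficiency, and the small assay computations (phenol-coupling mass
# bookkeeping, alkaloid molar ratios).

#' Kinetic parameters
#'
#' @param km Michaelis constant, uM (> 0).
#' @param kcat turnover number, 1/min (> 0).
#' @param ki uncompetitive substrate-inhibition constant, uM; `Inf` gives
#'   plain Michaelis-Menten behaviour.
#' @param enzyme_conc enzyme concentration, nM (> 0).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(km, kcat, ki = Inf, enzyme_conc) {
  if (km <= 0 || kcat <= 0 || ki <= 0 || enzyme_conc <= 0) {
    stop("km, kcat, ki and enzyme_conc must be positive", call. = FALSE)
  }
  structure(list(km = km, kcat = kcat, ki = ki, enzyme_conc = enzyme_conc),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: Km %.4g uM, kcat %.4g /min, Ki %s, [E] %g nM\n",
              x$km, x$kcat,
              if (is.finite(x$ki)) sprintf("%.4g uM", x$ki) else "Inf (MM)",
              x$enzyme_conc))
  invisible(x)
}

#' Reaction velocity under substrate inhibition
#'
#' The uncompetitive substrate-inhibition rate law
#' \deqn{v = \frac{k_{cat} [E] S}{K_m + S + S^2/K_i}}
#' which reduces to Michaelis-Menten when Ki is infinite. With `[E]` in nM
#' the velocity is in nM/min. Velocity peaks at S* = sqrt(Km * Ki) and
#' declines beyond it.
#'
#' @param S substrate concentration(s), uM (>= 0).
#' @param params a [kinetic_params()].
#' @return velocity vector, nM/min.
#' @export
#' @examples
#' p <- kinetic_params(km = 1.13, kcat = 15.0, ki = 64.3, enzyme_conc = 1)
#' enzyme_rate(10, p)  # ~11.8 nM/min
enzyme_rate <- function(S, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(S < 0)) stop("negative substrate concentration", call. = FALSE)
  inhib <- if (is.finite(params$ki)) S^2 / params$ki else 0
  params$kcat * params$enzyme_conc * S / (params$km + S + inhib)
}

#' Catalytic efficiency kcat/Km
#'
#' @param params a [kinetic_params()] or `kinetic_fit`.
#' @return kcat/Km in 1/(uM*min).
#' @export
catalytic_efficiency <- function(params) {
  if (inherits(params, "kinetic_fit")) params <- params$params
  stopifnot(inherits(params, "kinetic_params"))
  params$kcat / params$km
}

.fit_one <- function(data, model, enzyme_conc, start) {
  E <- enzyme_conc
  if (model == "substrate_inhibition") {
    form <- v ~ kcat * E * S / (km + S + S^2 / ki)
    lower <- c(km = 1e-8, kcat = 1e-8, ki = 1e-8)
  } else {
    form <- v ~ kcat * E * S / (km + S)
    start <- start[c("km", "kcat")]
    lower <- c(km = 1e-8, kcat = 1e-8)
  }
  minpack.lm::nlsLM(
    form, data = data, start = start, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                         ptol = 1e-10))
}

#' Fit a kinetic model to rate data
#'
#' Least-squares fit of the Michaelis-Menten or substrate-inhibition rate
#' law by damped (Levenberg-Marquardt) least squares. Starting values
#' follow a robust recipe for inhibition-shaped curves: Km from the
#' substrate concentration at half-maximal observed velocity, kcat from
#' the maximal velocity over `[E]`, Ki at ten times the largest tested
#' concentration. With `model = "auto"` both models are fitted and the
#' substrate-inhibition fit is reported only when it reduces the residual
#' sum of squares by at least 5% — otherwise Ki is not reported, mirroring
#' substrates for which no substrate inhibition is observed.
#'
#' @param data data.frame with substrate concentrations (`S_uM` or `S`,
#'   uM) and velocities (`v`, nM/min). Replicates are simply additional
#'   rows.
#' @param model `"substrate_inhibition"`, `"mm"`, or `"auto"`.
#' @param enzyme_conc enzyme concentration, nM.
#' @param start optional named list of starting values (`km`, `kcat`,
#'   `ki`).
#' @return object of class `kinetic_fit`: `params` ([kinetic_params()]),
#'   `std_errors`, `efficiency` (kcat/Km), `model`, `residual_ss`,
#'   `n_points`.
#' @export
fit_kinetics <- function(data,
                         model = c("substrate_inhibition", "mm", "auto"),
                         enzyme_conc, start = NULL) {
  model <- match.arg(model)
  S <- if ("S_uM" %in% names(data)) data$S_uM else data$S
  if (is.null(S)) stop("data needs an S_uM (or S) column", call. = FALSE)
  df <- data.frame(S = S, v = data$v)
  df <- df[is.finite(df$S) & is.finite(df$v), ]
  n_par <- if (model == "mm") 2L else 3L
  if (length(unique(df$S)) < n_par + 1L) {
    stop("need at least ", n_par + 1L, " distinct substrate concentrations",
         call. = FALSE)
  }
  if (is.null(start)) {
    v_max <- max(df$v)
    half <- df$S[which.min(abs(df$v - v_max / 2))]
    start <- list(km = max(half, min(df$S)), kcat = v_max / enzyme_conc,
                  ki = 10 * max(df$S))
  }
  if (model == "auto") {
    fit_mm <- .fit_one(df, "mm", enzyme_conc, start)
    fit_si <- tryCatch(
      .fit_one(df, "substrate_inhibition", enzyme_conc, start),
      error = function(e) NULL)
    ss_mm <- deviance(fit_mm)
    use_si <- !is.null(fit_si) &&
      (ss_mm - deviance(fit_si)) / ss_mm >= 0.05
    model <- if (use_si) "substrate_inhibition" else "mm"
    fit <- if (use_si) fit_si else fit_mm
  } else {
    fit <- .fit_one(df, model, enzyme_conc, start)
  }
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(co)),
                                              names(co)))
  ki <- if (model == "substrate_inhibition") unname(co["ki"]) else Inf
  params <- kinetic_params(km = unname(co["km"]), kcat = unname(co["kcat"]),
                           ki = ki, enzyme_conc = enzyme_conc)
  std_errors <- c(km = unname(se["km"]), kcat = unname(se["kcat"]),
                  ki = if (model == "substrate_inhibition")
                    unname(se["ki"]) else NA_real_)
  structure(list(params = params, std_errors = std_errors,
                 efficiency = params$kcat / params$km, model = model,
                 residual_ss = deviance(fit), n_points = nrow(df)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kinetic_fit (%s, n = %d points)\n", x$model, x$n_points))
  cat(sprintf("  Km   = %.4g +/- %.2g uM\n", x$params$km, x$std_errors["km"]))
  cat(sprintf("  kcat = %.4g +/- %.2g /min\n", x$params$kcat,
              x$std_errors["kcat"]))
  if (is.finite(x$params$ki)) {
    cat(sprintf("  Ki   = %.4g +/- %.2g uM\n", x$params$ki,
                x$std_errors["ki"]))
  } else {
    cat("  Ki   = not reported (no substrate inhibition)\n")
  }
  cat(sprintf("  kcat/Km = %.3g 1/(uM*min); residual SS = %.3g\n",
              x$efficiency, x$residual_ss))
  invisible(x)
}

#' Precursor m/z of a C-C phenol-coupled product
#'
#' Oxidative C-C phenol coupling removes two hydrogens, so the singly
#' charged product precursor ion is monitored 2 m/z below the substrate
#' precursor.
#'
#' @param substrate_mz substrate precursor m/z (> 2).
#' @return product precursor m/z.
#' @export
#' @examples
#' coupled_product_mz(274.30)  # 272.30
coupled_product_mz <- function(substrate_mz) {
  if (any(substrate_mz <= 2)) stop("substrate m/z must exceed 2",
                                   call. = FALSE)
  substrate_mz - 2
}

#' Molar ratio of two tissue constituents
#'
#' Converts mass contents (mg per g fresh weight) to molar amounts via the
#' molecular masses and returns their ratio.
#'
#' @param content_a,content_b contents, mg/g (> 0).
#' @param mw_a,mw_b molecular masses, g/mol (> 0).
#' @return fold ratio (moles of a per mole of b).
#' @export
#' @examples
#' # bulb haemanthamine vs galanthamine
#' molar_ratio(2.23, alkaloid_molar_masses["haemanthamine"],
#'             0.246, alkaloid_molar_masses["galanthamine"])
molar_ratio <- function(content_a, mw_a, content_b, mw_b) {
  if (any(c(content_a, mw_a, content_b, mw_b) <= 0)) {
    stop("contents and molecular masses must be positive", call. = FALSE)
  }
  unname((content_a / mw_a) / (content_b / mw_b))
}

#' Molecular masses of reference Amaryllidaceae alkaloids
#'
#' Standard monoisotopic-free average molecular masses (g/mol):
#' haemanthamine (C17H19NO4) and galanthamine (C17H21NO3).
#'
#' @format named numeric vector.
#' @export
alkaloid_molar_masses <- c(haemanthamine = 301.34, galanthamine = 287.35)

#' MRM transition settings for the assay substrates
#'
#' Packaged table of first-quadrupole precursor m/z settings used for the
#' substrate-specificity assays: substrate precursor m/z and the monitored
#' product precursor m/z per compound.
#'
#' @return data.frame with columns `compound`, `substrate_mz`,
#'   `product_mz`.
#' @export
mrm_transitions <- function() {
  utils::read.delim(.extdata("mrm_transitions.tsv"),
                    stringsAsFactors = FALSE)
}
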