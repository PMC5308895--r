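#' Depletion-corrected 1:1 binding isotherm
#'
#' Fraction of protein bound at total protein concentration P and total
#' ligand concentration L is the physical root of the mass-action
#' quadratic, evaluated in the numerically stable form
#' `theta = 2L / (b + sqrt(b^2 - 4PL))` with `b = P + L + Kd`, which tends
#' to the hyperbolic `L/(L+Kd)` as P tends to 0. The observed signal is
#' `f0 + (finf - f0) * theta`.
#'
#' @param kd dissociation constant (same units as the concentrations)
#' @param f0 signal at zero ligand
#' @param finf signal at saturation
#' @param protein_conc total protein (fluorophore) concentration
#' @param ligand_conc total ligand concentration(s), vectorized
#' @param depletion if `FALSE`, use the hyperbolic approximation
#'   `theta = L/(L+Kd)` (valid only when P << Kd)
#' @return predicted signal, same length as `ligand_conc`
#' @export
isotherm <- function(kd, f0, finf, protein_conc, ligand_conc,
                     depletion = TRUE) {
  if (kd <= 0 || protein_conc < 0 || any(ligand_conc < 0))
    stop("kd must be positive and concentrations non-negative")
  theta <- if (depletion) {
    b <- protein_conc + ligand_conc + kd
    2 * ligand_conc / (b + sqrt(b^2 - 4 * protein_conc * ligand_conc))
  } else {
    ligand_conc / (ligand_conc + kd)
  }
  f0 + (finf - f0) * theta
}

#' A fluorescence titration curve
#' @param ligand_concs strictly increasing positive concentrations (nM)
#' @param fluorescence observed signal, same length (>= 5 points)
#' @param protein_conc total protein concentration (nM)
#' @return a `titration_curve` (data.frame `ligand_nM`, `fluorescence` with
#'   a `protein_conc` attribute)
#' @export
titration_curve <- function(ligand_concs, fluorescence, protein_conc) {
  if (length(ligand_concs) != length(fluorescence) || length(ligand_concs) < 5L)
    stop("need >= 5 matched (concentration, fluorescence) points")
  if (any(ligand_concs <= 0) || any(diff(ligand_concs) <= 0))
    stop("ligand concentrations must be positive and strictly increasing")
  structure(data.frame(ligand_nM = ligand_concs, fluorescence = fluorescence),
            protein_conc = protein_conc, class = c("titration_curve",
                                                   "data.frame"))
}

#' Read a titration TSV (columns `ligand_nM`, `fluorescence`)
#' @param path TSV path
#' @param protein_conc total protein concentration (nM)
#' @export
read_titration <- function(path, protein_conc) {
  dt <- fread(path, header = TRUE, sep = "\t")
  titration_curve(dt$ligand_nM, dt$fluorescence, protein_conc)
}

fit_once <- function(conc, fl, P, kd0, f00, finf0, depletion) {
  tryCatch(
    minpack.lm::nlsLM(
      fl ~ isotherm(kd, f0, finf, P, conc, depletion),
      start = list(kd = kd0, f0 = f00, finf = finf0),
      lower = c(kd = 1e-9, f0 = -Inf, finf = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

#' Fit a dissociation constant to a titration curve
#'
#' Least-squares fit of the depletion-corrected isotherm over
#' `(kd, f0, finf)` with multi-start initialization (Kd starts log-spaced
#' across the titrated range), and an optional bootstrap confidence
#' interval for Kd from resampled residuals.
#'
#' @param curve a [titration_curve()]
#' @param n_boot bootstrap replicates for the Kd CI (0 skips it)
#' @param depletion fit the depletion-corrected model (default) or the
#'   hyperbolic approximation
#' @param conf CI level
#' @return a `binding_fit`: list with `kd`, `f0`, `finf`, `residual_sse`,
#'   `ci_kd` (or `NULL`), `boot_kd`, `protein_conc`, `fitted`
#' @export
fit_kd <- function(curve, n_boot = 0, depletion = TRUE, conf = 0.95) {
  conc <- curve$ligand_nM
  fl <- curve$fluorescence
  P <- attr(curve, "protein_conc", exact = TRUE)
  span <- diff(range(fl))
  if (span <= 1e-8 * max(abs(fl), 1))
    stop("titration signal is flat; no binding transition to fit")
  kd_starts <- exp(seq(log(min(conc) / 10), log(max(conc) * 10), length.out = 7))
  best <- NULL; best_sse <- Inf
  for (k0 in kd_starts) {
    fit <- fit_once(conc, fl, P, k0, fl[1L], fl[length(fl)], depletion)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (sse < best_sse) { best <- fit; best_sse <- sse }
  }
  if (is.null(best))
    stop(sprintf("Kd fit failed to converge from all starts (best SSE %g)",
                 best_sse))
  cf <- coef(best)
  if (abs(cf[["finf"]] - cf[["f0"]]) <= 1e-8 * max(abs(fl), 1))
    stop(sprintf("degenerate fit: no signal amplitude (best SSE %g)", best_sse))
  pred <- isotherm(cf[["kd"]], cf[["f0"]], cf[["finf"]], P, conc, depletion)
  res <- fl - pred
  boot_kd <- NULL
  if (n_boot > 0) {
    ## inflate residuals by sqrt(n/(n-p)): least squares absorbs p = 3
    ## degrees of freedom, so raw residuals understate the noise
    res_b <- res * sqrt(length(res) / (length(res) - 3))
    boot_kd <- vapply(seq_len(n_boot), function(b) {
      fl_b <- pred + sample(res_b, length(res), replace = TRUE)
      fit_b <- fit_once(conc, fl_b, P, cf[["kd"]], cf[["f0"]], cf[["finf"]],
                        depletion)
      if (is.null(fit_b)) NA_real_ else coef(fit_b)[["kd"]]
    }, 0)
    boot_kd <- boot_kd[!is.na(boot_kd)]
  }
  ci <- if (length(boot_kd)) {
    ## expanded percentile interval: widen the quantile levels with the
    ## small-sample t correction (Hesterberg), df = n - 3 fitted parameters
    n <- length(res)
    a <- stats::pnorm(-sqrt(n / (n - 1)) *
                        stats::qt(1 - (1 - conf) / 2, df = n - 3))
    quantile(boot_kd, c(a, 1 - a), names = FALSE)
  }
  structure(list(kd = cf[["kd"]], f0 = cf[["f0"]], finf = cf[["finf"]],
                 residual_sse = sum(res^2), ci_kd = ci, boot_kd = boot_kd,
                 protein_conc = P, fitted = pred),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit: Kd = %.4g nM (f0 = %.4g, finf = %.4g, SSE = %.3g)\n",
              x$kd, x$f0, x$finf, x$residual_sse))
  if (!is.null(x$ci_kd))
    cat(sprintf("  bootstrap 95%% CI: [%.4g, %.4g] nM (%d replicates)\n",
                x$ci_kd[1L], x$ci_kd[2L], length(x$boot_kd)))
  invisible(x)
}

#' Bootstrap comparison of two dissociation constants
#'
#' Two-sided bootstrap p-value for Kd_a != Kd_b: random pairs are drawn
#' from the two fits' bootstrap Kd distributions and the p-value is twice
#' the smaller tail probability of the paired differences (with +1
#' smoothing), capped at 1.
#'
#' @param fit_a,fit_b [fit_kd()] results with `boot_kd` populated
#' @param n_boot number of paired draws
#' @return p-value in (0, 1]
#' @export
compare_kds <- function(fit_a, fit_b, n_boot = 10000) {
  if (!length(fit_a$boot_kd) || !length(fit_b$boot_kd))
    stop("both fits need bootstrap Kd draws (fit_kd with n_boot > 0)")
  da <- sample(fit_a$boot_kd, n_boot, replace = TRUE)
  db <- sample(fit_b$boot_kd, n_boot, replace = TRUE)
  d <- da - db
  p <- 2 * (min(sum(d <= 0), sum(d >= 0)) + 1) / (n_boot + 1)
  min(p, 1)
}
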