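# Nucleotide-exchange kinetics: one-phase decay fits of fluorescent-GDP
# release traces, catalytic efficiency, fold changes with bootstrap CIs,
# and dose-response summaries.

#' Fit a one-phase exponential decay
#'
#' Least-squares fit of \code{Y(t) = (Y0 - plateau) exp(-kObs t) + plateau}
#' to a fluorescence trace (Levenberg-Marquardt). Start values: Y0 = first
#' point, plateau = last point, kObs = ln(2) divided by half the time range.
#' The decay fit is used instead of initial rates because traces recorded at
#' working enzyme concentrations are often already past the initial linear
#' phase of product release.
#'
#' The fit is flagged unreliable (value still returned) when it fails to
#' converge, when the amplitude is degenerate (|Y0 - plateau| below 1e-6 of
#' the signal scale), or when SE(kObs) exceeds kObs.
#'
#' @param time numeric vector, seconds, strictly increasing, length >= 8
#' @param signal fluorescence values, finite
#' @return a [KineticsFit-class]
#' @examples
#' t <- seq(0, 600, length.out = 60)
#' y <- 80 * exp(-0.01 * t) + 20
#' fitOnePhaseDecay(t, y)
#' @export
fitOnePhaseDecay <- function(time, signal) {
  stopifnot(length(time) == length(signal))
  if (length(time) < 8) stop("trace must have at least 8 points")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (!all(is.finite(time)) || !all(is.finite(signal)))
    stop("trace contains non-finite values")
  y0 <- signal[1]
  plateau <- signal[length(signal)]
  k0 <- log(2) / (diff(range(time)) / 2)
  scale <- max(abs(signal), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(signal ~ (y0 - pl) * exp(-k * time) + pl,
                      start = list(y0 = y0, pl = plateau, k = max(k0, 1e-9)),
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("KineticsFit", kObs = 0, y0 = y0, plateau = plateau,
               amplitude = y0 - plateau,
               se = c(y0 = NA_real_, plateau = NA_real_, kObs = NA_real_),
               rSquared = 0, reliable = FALSE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  resid <- stats::resid(fit)
  ssTot <- sum((signal - mean(signal))^2)
  r2 <- if (ssTot > 0) 1 - sum(resid^2) / ssTot else 0
  amplitude <- unname(cf["y0"] - cf["pl"])
  reliable <- is.finite(se[3]) && se[3] <= cf["k"] &&
    abs(amplitude) > 1e-6 * scale
  new("KineticsFit", kObs = unname(cf["k"]), y0 = unname(cf["y0"]),
      plateau = unname(cf["pl"]), amplitude = amplitude,
      se = stats::setNames(as.numeric(se), c("y0", "plateau", "kObs")),
      rSquared = r2, reliable = isTRUE(unname(reliable)))
}

#' Fit every trace of a long-form kinetics table
#'
#' @param traces data.frame with columns \code{time_s}, \code{signal},
#'   \code{condition}, \code{replicate} and optionally \code{enzyme_conc}
#'   (micromolar) and \code{additive}
#' @return data.frame with one row per (condition, replicate): \code{k_obs},
#'   \code{amplitude}, \code{plateau}, \code{r_squared}, \code{reliable},
#'   plus carried-through condition metadata
#' @export
fitKineticsTable <- function(traces) {
  need <- c("time_s", "signal", "condition", "replicate")
  missing <- setdiff(need, names(traces))
  if (length(missing))
    stop("kinetics table missing column(s): ", paste(missing, collapse = ", "))
  groups <- split(traces, interaction(traces$condition, traces$replicate,
                                      drop = TRUE))
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    f <- fitOnePhaseDecay(g$time_s, g$signal)
    meta <- g[1, setdiff(names(g), c("time_s", "signal")), drop = FALSE]
    data.frame(meta, k_obs = f@kObs, amplitude = f@amplitude,
               plateau = f@plateau, r_squared = f@rSquared,
               reliable = f@reliable)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Catalytic efficiency of a GEF
#'
#' \code{(kObs - kIntr) / enzymeConc}: the observed exchange rate corrected
#' for the intrinsic (uncatalysed) nucleotide release rate, per unit enzyme
#' concentration. Units are 1/(microM s) when \code{enzymeConc} is in
#' micromolar; negative values (sub-intrinsic observed rates) are permitted
#' with a warning.
#'
#' @param kObs observed rate constant(s), 1/s
#' @param kIntr intrinsic release rate, 1/s
#' @param enzymeConc enzyme concentration(s), micromolar, > 0
#' @return catalytic efficiency, 1/(microM s)
#' @export
catalyticEfficiency <- function(kObs, kIntr, enzymeConc) {
  if (any(enzymeConc <= 0)) stop("enzyme concentration must be positive")
  value <- (kObs - kIntr) / enzymeConc
  if (any(value < 0))
    warning("negative catalytic efficiency (observed rate below intrinsic)")
  value
}

#' Fold changes in catalytic efficiency with bootstrap CIs
#'
#' For each condition, the fold change is its mean efficiency over the mean
#' efficiency of the reference condition. Confidence intervals are
#' percentile bootstrap over replicates (both condition and reference
#' resampled).
#'
#' @param efficiencies data.frame with columns \code{condition},
#'   \code{replicate}, \code{efficiency}
#' @param reference reference condition name
#' @param nBoot bootstrap resamples (default 2000)
#' @param level confidence level (default 0.95)
#' @param seed bootstrap seed
#' @return data.frame: \code{condition}, \code{fold_change}, \code{ci_lo},
#'   \code{ci_hi}, \code{n}
#' @export
compareConditions <- function(efficiencies, reference, nBoot = 2000,
                              level = 0.95, seed = 1) {
  stopifnot(all(c("condition", "efficiency") %in% names(efficiencies)))
  if (!reference %in% efficiencies$condition)
    stop("reference condition '", reference, "' not present")
  refVals <- efficiencies$efficiency[efficiencies$condition == reference]
  if (mean(refVals) <= 0) stop("reference efficiency must be positive")
  set.seed(seed)
  conds <- unique(efficiencies$condition)
  out <- lapply(conds, function(cond) {
    vals <- efficiencies$efficiency[efficiencies$condition == cond]
    fc <- mean(vals) / mean(refVals)
    boots <- replicate(nBoot, {
      mean(sample(vals, replace = TRUE)) / mean(sample(refVals, replace = TRUE))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE)
    data.frame(condition = cond, fold_change = fc, ci_lo = unname(qs[1]),
               ci_hi = unname(qs[2]), n = length(vals))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dose-response monotonicity summary
#'
#' Reports the mean efficiency per dose level and the Spearman rank
#' correlation between efficiency and dose (a monotone, distribution-free
#' association measure). An all-tied series returns rho = 0.
#'
#' @param doses numeric vector of additive concentrations (micromolar)
#' @param efficiencies catalytic efficiencies, same length
#' @return \code{list(per_dose, rho)} where \code{per_dose} is a data.frame
#'   of mean efficiency per dose
#' @export
doseResponse <- function(doses, efficiencies) {
  stopifnot(length(doses) == length(efficiencies))
  if (length(unique(doses)) < 3) stop("need at least 3 dose levels")
  rho <- suppressWarnings(stats::cor(doses, efficiencies, method = "spearman"))
  if (is.na(rho)) rho <- 0  # constant series: no association
  perDose <- stats::aggregate(list(efficiency = efficiencies),
                              list(dose = doses), mean)
  list(per_dose = perDose[order(perDose$dose), ], rho = rho)
}
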