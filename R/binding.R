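## Equilibrium binding curves and 1:1 Langmuir fitting for SPR-style
## saturation data.

#' Twofold (or other) serial dilution series
#'
#' @param cMax top concentration (uM).
#' @param nPoints number of points (>= 1).
#' @param factor dilution factor (> 1), default 2.
#' @return concentrations `cMax / factor^(0:(nPoints-1))`, descending.
#' @examples
#' serialDilution(83, 4)    # 83, 41.5, 20.75, 10.375
#' serialDilution(3.4, 3)   # 3.4, 1.7, 0.85
#' @export
serialDilution <- function(cMax, nPoints, factor = 2) {
  stopifnot(nPoints >= 1, factor > 1)
  if (cMax <= 0) stop("top concentration must be > 0")
  cMax / factor^(0:(nPoints - 1))
}

#' Fit the 1:1 Langmuir adsorption model
#'
#' Nonlinear least squares on `B(C) = Bmax * C / (KD + C)`.  Positivity is
#' enforced by optimising log-parameters; standard errors come from the
#' curvature at the optimum (delta method back to the natural scale).
#' Replicate responses at the same concentration are averaged before fitting,
#' with their spread reported.
#'
#' @param curve data.frame with columns `conc` and `response` (e.g. from
#'   [simulateSaturation()]), or a two-column object coercible to one.
#' @param init optional starting values `c(KD, Bmax)`; default
#'   `Bmax = 1.1 * max(B)` and `KD` = the concentration whose response is
#'   nearest `Bmax/2`.
#' @param weights optional response weights (unweighted by default; pass
#'   `1/response` for relative weighting).
#' @return a [LangmuirFit-class].
#' @examples
#' fit <- fitLangmuir(simulateSaturation(300, 100, serialDilution(2400, 8)))
#' kd(fit)
#' @export
fitLangmuir <- function(curve, init = NULL, weights = NULL) {
  curve <- as.data.frame(curve)
  if (!all(c("conc", "response") %in% names(curve)))
    names(curve)[1:2] <- c("conc", "response")
  stopifnot(all(curve$conc > 0))
  spread <- NULL
  if (anyDuplicated(curve$conc)) {
    spread <- stats::aggregate(response ~ conc, curve, sd)
    curve <- stats::aggregate(response ~ conc, curve, mean)
  }
  curve <- curve[order(-curve$conc), ]
  if (length(unique(curve$conc)) < 3)
    stop("need >= 3 distinct concentrations to fit KD and Bmax")
  if (all(curve$response == 0))
    stop("all responses are zero: no binding signal to fit")
  if (is.null(init)) {
    bmax0 <- 1.1 * max(curve$response)
    kd0 <- curve$conc[which.min(abs(curve$response - bmax0 / 2))]
    init <- c(KD = kd0, Bmax = bmax0)
  }
  dat <- curve
  if (!is.null(weights)) dat$w <- weights else dat$w <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ exp(lBmax) * conc / (exp(lKD) + conc),
                      data = dat, weights = dat$w,
                      start = list(lKD = log(init[[1]]),
                                   lBmax = log(init[[2]])),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$convInfo$isConv) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit)
           else fit$convInfo$stopMessage
    warning("Langmuir fit did not converge: ", msg)
    return(new("LangmuirFit", KD = NA_real_, Bmax = NA_real_,
               se = c(NA_real_, NA_real_), rss = NA_real_,
               converged = FALSE, data = curve))
  }
  lc <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  kdHat <- exp(lc[["lKD"]]); bmaxHat <- exp(lc[["lBmax"]])
  se <- c(kdHat * sqrt(vc[1, 1]), bmaxHat * sqrt(vc[2, 2]))
  out <- new("LangmuirFit", KD = kdHat, Bmax = bmaxHat, se = se,
             rss = sum(stats::residuals(fit)^2), converged = TRUE,
             data = curve)
  if (!is.null(spread)) attr(out@data, "replicate_sd") <- spread
  out
}

#' Compare binding conditions by KD ratio
#'
#' Pairwise KD ratios between conditions (row / column order of listing) with
#' relative errors propagated in quadrature.  Failed fits are excluded with a
#' warning.
#'
#' @param fits named list of [LangmuirFit-class] objects.
#' @return data.frame `condition_a`, `condition_b`, `kd_a`, `kd_b`, `ratio`,
#'   `ratio_se`.
#' @examples
#' \dontrun{compareConditions(list(headgroup = fitA, nanodisc = fitB))}
#' @export
compareConditions <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f@converged), logical(1))
  if (any(!ok))
    warning("excluding failed fit(s): ",
            paste(names(fits)[!ok], collapse = ", "))
  fits <- fits[ok]
  if (length(fits) < 2)
    stop("need >= 2 successful fits to compare conditions")
  nm <- names(fits)
  rows <- list()
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i >= j) next
    ka <- kd(fits[[i]]); kb <- kd(fits[[j]])
    ra <- fits[[i]]@se[1] / ka; rb <- fits[[j]]@se[1] / kb
    ratio <- ka / kb
    rows[[length(rows) + 1]] <- data.frame(
      condition_a = nm[i], condition_b = nm[j], kd_a = ka, kd_b = kb,
      ratio = ratio, ratio_se = ratio * sqrt(ra^2 + rb^2))
  }
  do.call(rbind, rows)
}
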