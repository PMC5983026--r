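#' One- or two-classes-of-sites Michaelis-Menten model
#'
#' A steady-state ATPase model in which each class ("phase") of ATP-binding
#' sites contributes an independent Michaelis-Menten term:
#' `v(S) = sum_p sites_p * k_cat_p * S / (K_M_p + S)`, in per-complex units.
#' A biphasic saturation profile (two classes of sites, tight and weak) is
#' the two-phase case; by convention phase 1 is the tighter class
#' (`K_M1 <= K_M2`).
#'
#' @param K_M Michaelis constants, one per phase (uM).
#' @param k_cat Turnover numbers, one per phase (mol ATP hydrolysed per mol
#'   active sites per min).
#' @param sites Number of active sites per phase (default 8 per phase, the
#'   per-ring subunit count of a hexadecamer with two classes of sites).
#' @return A list of class `kinetic_model` with fields `phases`, `K_M`,
#'   `k_cat`, `sites`.
#' @examples
#' wt <- kinetic_model(K_M = c(15, 370), k_cat = c(2.15, 3.2))
#' model_rate(wt, c(15, 370, 1e5))
#' @export
kinetic_model <- function(K_M, k_cat, sites = rep(8L, length(K_M))) {
  stopifnot(length(K_M) == length(k_cat), length(K_M) %in% 1:2)
  if (length(sites) == 1) sites <- rep(sites, length(K_M))
  stopifnot(all(K_M > 0), all(k_cat >= 0), all(sites > 0))
  ord <- order(K_M)
  structure(
    list(
      phases = length(K_M),
      K_M = unname(K_M[ord]), k_cat = unname(k_cat[ord]), sites = unname(sites[ord])
    ),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Michaelis-Menten model with %d class(es) of sites\n", x$phases))
  for (p in seq_len(x$phases)) {
    cat(sprintf(
      "  phase %d: K_M = %g uM, k_cat = %g /min, %d sites\n",
      p, x$K_M[p], x$k_cat[p], x$sites[p]
    ))
  }
  invisible(x)
}

#' Model ATPase rate at given substrate concentrations
#'
#' @param model A [kinetic_model()].
#' @param S ATP concentrations (uM), `>= 0`.
#' @return Rates in per-complex units (mol ATP hydrolysed per mol complex
#'   per min), same length as `S`.
#' @export
model_rate <- function(model, S) {
  stopifnot(inherits(model, "kinetic_model"), all(S >= 0))
  Reduce(`+`, lapply(seq_len(model$phases), function(p) {
    model$sites[p] * model$k_cat[p] * S / (model$K_M[p] + S)
  }))
}

#' Blank-correct a rate dataset
#'
#' Subtracts the matched no-enzyme blank rate (spontaneous ATP hydrolysis at
#' assay temperature) from each measured rate. Negative corrected rates are
#' kept but flagged in a `flag_negative` column.
#'
#' @param data Tibble with columns `atp_uM`, `rate` and `blank_rate`.
#' @return The tibble with `rate` corrected, the original in `rate_raw`, and
#'   a `flag_negative` logical column.
#' @export
blank_correct <- function(data) {
  data <- as_tibble(data)
  if (!"blank_rate" %in% names(data) || anyNA(data$blank_rate)) {
    miss <- if ("blank_rate" %in% names(data)) {
      unique(data$atp_uM[is.na(data$blank_rate)])
    } else {
      unique(data$atp_uM)
    }
    abort(
      paste0(
        "Missing blank rates for ATP concentration(s): ",
        paste(signif(miss, 4), collapse = ", "), " uM."
      ),
      class = "thermoring_correction_error"
    )
  }
  data$rate_raw <- data$rate
  data$rate <- data$rate - data$blank_rate
  data$flag_negative <- data$rate < 0
  data
}

#' Fit a Michaelis-Menten model to rate data
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt with box bounds)
#' of the one- or two-classes-of-sites model to blank-corrected rate data.
#' Initialization: K_M starts from the concentration nearest the half-max
#' rate (for two phases, at 0.1x and 10x that value); each k_cat starts from
#' the maximum observed rate divided by the total site count. Bounds:
#' `K_M` in (0, 10 * max(S)], `k_cat >= 0`. Phases are reordered after the
#' fit so phase 1 is the tighter class; a two-phase fit whose Michaelis
#' constants lie within a factor 3 of each other is flagged as weakly
#' identifiable.
#'
#' @param data Tibble with columns `atp_uM` and `rate` (per-complex units).
#' @param phases 1 or 2 classes of sites.
#' @param sites Sites per phase (default 8).
#' @return An object of class `kinetic_fit`: list with `model` (a
#'   [kinetic_model()]), `se` (standard errors on `K_M` and `k_cat`),
#'   `fit` (the underlying `nls` object), `flags`, `data`, `phases`.
#' @export
fit_kinetics <- function(data, phases = 1, sites = 8L) {
  data <- as_tibble(data)
  stopifnot(all(c("atp_uM", "rate") %in% names(data)), phases %in% 1:2)
  df <- data[, c("atp_uM", "rate")]
  names(df) <- c("S", "v")
  df <- df[order(df$S), ]
  if (nrow(dplyr::distinct(df["S"])) < 2 * (2 * phases)) {
    abort(
      sprintf("A %d-phase fit needs at least %d distinct concentrations.", phases, 4 * phases),
      class = "thermoring_fit_error"
    )
  }
  vmax <- max(df$v)
  half_idx <- which.min(abs(df$v - vmax / 2))
  km0 <- max(df$S[half_idx], min(df$S[df$S > 0]))
  upper_km <- 10 * max(df$S)
  n_sites <- rep(sites, phases)
  if (phases == 1) {
    start <- list(Km1 = km0, kcat1 = vmax / n_sites[1])
    fit <- minpack.lm::nlsLM(
      v ~ s1 * kcat1 * S / (Km1 + S),
      data = cbind(df, s1 = n_sites[1]),
      start = start,
      lower = c(Km1 = 1e-9, kcat1 = 0),
      upper = c(Km1 = upper_km, kcat1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    est <- coef(fit)
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
      error = function(e) rep(NA_real_, 2)
    )
    K_M <- est[["Km1"]]
    k_cat <- est[["kcat1"]]
    se <- list(K_M = unname(ses[1]), k_cat = unname(ses[2]))
  } else {
    start <- list(
      Km1 = 0.1 * km0, Km2 = 10 * km0,
      kcat1 = vmax / sum(n_sites), kcat2 = vmax / sum(n_sites)
    )
    fit <- minpack.lm::nlsLM(
      v ~ s1 * kcat1 * S / (Km1 + S) + s2 * kcat2 * S / (Km2 + S),
      data = cbind(df, s1 = n_sites[1], s2 = n_sites[2]),
      start = start,
      lower = c(Km1 = 1e-9, Km2 = 1e-9, kcat1 = 0, kcat2 = 0),
      upper = c(Km1 = upper_km, Km2 = upper_km, kcat1 = Inf, kcat2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000)
    )
    est <- coef(fit)
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
      error = function(e) setNames(rep(NA_real_, 4), names(est))
    )
    K_M <- c(est[["Km1"]], est[["Km2"]])
    k_cat <- c(est[["kcat1"]], est[["kcat2"]])
    ord <- order(K_M)
    K_M <- K_M[ord]
    k_cat <- k_cat[ord]
    se <- list(
      K_M = unname(ses[c("Km1", "Km2")][ord]),
      k_cat = unname(ses[c("kcat1", "kcat2")][ord])
    )
  }
  if (!fit$convInfo$isConv) {
    abort(
      paste0(
        "Nonlinear fit did not converge; residual sum of squares = ",
        signif(sum(residuals(fit)^2), 4)
      ),
      class = "thermoring_fit_error"
    )
  }
  flags <- character(0)
  if (phases == 2 && max(K_M) / min(K_M) < 3) {
    flags <- c(flags, "phases_weakly_identifiable")
    warn("Two-phase fit: Michaelis constants within a factor 3; phases weakly identifiable.")
  }
  structure(
    list(
      model = kinetic_model(K_M = K_M, k_cat = k_cat, sites = n_sites),
      se = se, fit = fit, flags = flags, data = data, phases = phases
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (%d phase(s), unweighted least squares)\n", x$phases))
  print(x$model)
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_kinetics Tidy the fitted parameters: one row per
#'   parameter with `term`, `phase`, `estimate`, `std_error`, `unit`.
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  m <- x$model
  tibble(
    term = rep(c("K_M", "k_cat"), each = m$phases),
    phase = rep(seq_len(m$phases), times = 2),
    estimate = c(m$K_M, m$k_cat),
    std_error = c(x$se$K_M, x$se$k_cat),
    unit = rep(c("uM", "mol ATP/(mol active sites)/min"), each = m$phases)
  )
}

#' @describeIn fit_kinetics One-row model summary: residual standard error,
#'   residual sum of squares, number of observations, convergence, flags.
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  res <- residuals(x$fit)
  tibble(
    phases = x$phases,
    sigma = sqrt(sum(res^2) / max(1, length(res) - 2 * x$phases)),
    rss = sum(res^2),
    nobs = length(res),
    converged = isTRUE(x$fit$convInfo$isConv),
    flags = paste(x$flags, collapse = ";")
  )
}

#' @describeIn fit_kinetics Rate-vs-[ATP] plot of the data with the fitted
#'   saturation curve on a log concentration axis.
#' @param object A `kinetic_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  smax <- max(d$atp_uM)
  smin <- max(min(d$atp_uM[d$atp_uM > 0]), 1e-3)
  grid <- tibble(atp_uM = exp(seq(log(smin), log(smax), length.out = 200)))
  grid$rate <- model_rate(object$model, grid$atp_uM)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$atp_uM, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "[ATP] (uM)",
      y = "rate (mol ATP / mol complex / min)"
    ) +
    ggplot2::theme_minimal()
}

#' Linearity of maximum rate versus enzyme concentration
#'
#' Ordinary least-squares check that maximum hydrolytic rates scale linearly
#' with enzyme concentration — the diagnostic that rules out an equilibrium
#' between oligomeric states with different activities.
#'
#' @param data Tibble with columns `enzyme_conc` and `max_rate` (>= 3 rows).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `intercept_slope_ratio`.
#' @export
linearity_check <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("enzyme_conc", "max_rate") %in% names(data)))
  if (nrow(data) < 3) {
    abort("At least 3 enzyme concentrations are required.", class = "thermoring_input_error")
  }
  fit <- lm(max_rate ~ enzyme_conc, data = data)
  cf <- coef(fit)
  r2 <- summary(fit)$r.squared
  tibble(
    slope = unname(cf["enzyme_conc"]),
    intercept = unname(cf["(Intercept)"]),
    r_squared = r2,
    intercept_slope_ratio = unname(cf["(Intercept)"] / cf["enzyme_conc"])
  )
}

#' Refolding yield as percent recovery of native activity
#'
#' @param activity_refolded Activity measured after chaperonin-assisted
#'   refolding (rate units).
#' @param activity_native Activity of the native substrate (> 0).
#' @return Percent recovery, `100 * refolded / native`.
#' @examples
#' refolding_yield(0.13, 1) # spontaneous-refolding scale
#' @export
refolding_yield <- function(activity_refolded, activity_native) {
  if (any(activity_native <= 0)) {
    abort("Native activity must be positive.", class = "thermoring_input_error")
  }
  100 * activity_refolded / activity_native
}

#' Convert per-site turnover to per-complex maximal rate
#'
#' @param model A [kinetic_model()].
#' @return Saturating per-complex rate, `sum(sites * k_cat)`.
#' @export
per_complex_vmax <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sum(model$sites * model$k_cat)
}
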