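#' Four-parameter logistic
#'
#' \code{bottom + (top - bottom) / (1 + (c / ic50)^hill)}. With
#' \code{hill > 0} the response decreases from \code{top} toward
#' \code{bottom} as concentration rises (an inhibition curve).
#'
#' @param conc Concentration vector (positive).
#' @param bottom,top Lower and upper asymptotes.
#' @param ic50 Midpoint concentration.
#' @param hill Hill slope.
#' @return Response vector.
#' @export
four_pl <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Initial reaction velocity from a kinetic trace
#'
#' Ordinary least-squares slope of fluorescence versus time over the
#' requested window. The additive offset of the trace is irrelevant:
#' only the slope is returned.
#'
#' @param time_s,fluorescence Numeric vectors of equal length.
#' @param window Length-2 numeric, inclusive time window in seconds
#'   (default: the full trace).
#' @return Velocity in AU/s.
#' @export
compute_velocity <- function(time_s, fluorescence,
                             window = range(time_s)) {
  keep <- time_s >= window[1] & time_s <= window[2] &
    !is.na(fluorescence)
  if (sum(keep) < 3) {
    stop("need at least 3 samples in the window to fit a velocity",
         call. = FALSE)
  }
  t <- time_s[keep]
  y <- fluorescence[keep]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Per-well velocities for a whole plate
#'
#' @param plate Long data.frame (well, role, compound_id, time_s,
#'   fluorescence), e.g. from \code{\link{simulate_screen_plate}} or
#'   \code{read.csv} on a plate file.
#' @param window Passed to \code{\link{compute_velocity}}.
#' @return data.frame well, role, compound_id, velocity.
#' @export
plate_velocities <- function(plate, window = NULL) {
  parts <- split(plate, plate$well)
  rows <- lapply(parts, function(d) {
    w <- if (is.null(window)) range(d$time_s) else window
    data.frame(well = d$well[1], role = d$role[1],
               compound_id = d$compound_id[1],
               velocity = compute_velocity(d$time_s, d$fluorescence, w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Control-anchored screen hit calling
#'
#' A compound well is a hit when its velocity is at or below
#' \code{multiplier} times the mean velocity of the full-inhibition
#' (DEAB) control wells. Percent inhibition is reported on the
#' DMSO-to-DEAB scale, clipped to \verb{[0, 100]}.
#'
#' @param velocities data.frame from \code{\link{plate_velocities}}
#'   with roles \code{compound}, \code{DMSO}, \code{DEAB}.
#' @param multiplier Cutoff multiple of the mean DEAB velocity
#'   (default 2).
#' @return data.frame of compound wells: well, compound_id, velocity,
#'   percent_inhibition, hit; plus attributes \code{cutoff},
#'   \code{v_dmso}, \code{v_deab}.
#' @export
call_screen_hits <- function(velocities, multiplier = 2) {
  v_deab <- velocities$velocity[velocities$role == "DEAB"]
  v_dmso <- velocities$velocity[velocities$role == "DMSO"]
  if (length(v_deab) == 0 || length(v_dmso) == 0) {
    stop("plate needs at least one DEAB and one DMSO control well",
         call. = FALSE)
  }
  m_deab <- mean(v_deab)
  m_dmso <- mean(v_dmso)
  if (m_dmso <= m_deab) {
    stop("degenerate plate: mean DMSO velocity (", signif(m_dmso, 4),
         ") does not exceed mean DEAB velocity (", signif(m_deab, 4), ")",
         call. = FALSE)
  }
  cutoff <- multiplier * m_deab
  cmp <- velocities[velocities$role == "compound", , drop = FALSE]
  pct <- 100 * (1 - (cmp$velocity - m_deab) / (m_dmso - m_deab))
  out <- data.frame(well = cmp$well, compound_id = cmp$compound_id,
                    velocity = cmp$velocity,
                    percent_inhibition = pmin(pmax(pct, 0), 100),
                    hit = cmp$velocity <= cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, v_dmso = m_dmso, v_deab = m_deab)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt least squares on the 4PL, parameterized in
#' log(IC50) and fitted from several data-driven starts to escape the
#' well-known local minima. The Hill slope may take either sign but is
#' bounded to |hill| in [0.2, 10].
#'
#' @param conc Positive concentration vector (>= 4 distinct values).
#' @param response Response vector.
#' @return List of class \code{fit_4pl}: bottom, top, ic50, hill,
#'   residual_sse, converged, fitted (function of concentration).
#' @export
fit_4pl <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  ok <- !is.na(conc) & !is.na(response) & conc > 0
  conc <- conc[ok]
  response <- response[ok]
  if (length(unique(conc)) < 4) {
    stop("need >= 4 distinct positive concentrations", call. = FALSE)
  }
  df <- data.frame(lc = log(conc), y = response)
  rng <- range(response)
  spread <- diff(rng)
  if (spread == 0) spread <- max(abs(rng), 1)
  starts <- list()
  for (lic in stats::quantile(df$lc, c(0.25, 0.5, 0.75))) {
    for (h in c(1, -1)) {
      starts[[length(starts) + 1L]] <- c(bottom = rng[1], top = rng[2],
                                         lic50 = unname(lic), hill = h)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (lc - lic50))),
        data = df, start = as.list(st),
        lower = c(bottom = rng[1] - spread, top = rng[1] - spread,
                  lic50 = min(df$lc) - 10, hill = -10),
        upper = c(bottom = rng[2] + spread, top = rng[2] + spread,
                  lic50 = max(df$lc) + 10, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from any start; response range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  hill <- unname(cf["hill"])
  if (abs(hill) < 0.2) hill <- sign(hill + (hill == 0)) * 0.2
  bottom <- unname(cf["bottom"])
  top <- unname(cf["top"])
  ## report with top >= bottom; flipping asymptotes flips the slope sign
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp
    hill <- -hill
  }
  ic50 <- exp(unname(cf["lic50"]))
  structure(list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
                 residual_sse = best$sse, converged = TRUE,
                 fitted = function(c) four_pl(c, bottom, top, ic50, hill)),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL fit: bottom %.4g, top %.4g, IC50 %.4g, Hill %.3g (SSE %.3g)\n",
    x$bottom, x$top, x$ic50, x$hill, x$residual_sse))
  invisible(x)
}

#' Fit a 1:1 binding isotherm
#'
#' Least-squares fit of \code{ratio(L) = baseline + amplitude * L /
#' (L + kd)}, the hyperbolic single-site model used for
#' thermophoresis-ratio titrations.
#'
#' @param ligand_conc Positive titrant concentrations (>= 4 values).
#' @param ratio Measured signal (e.g. a 670 nm / 650 nm fluorescence
#'   ratio).
#' @return List of class \code{binding_fit}: kd, baseline, amplitude,
#'   residual_sse, identifiable (FALSE when the fitted amplitude is
#'   negligible against the residual noise, leaving kd unconstrained).
#' @export
fit_binding_isotherm <- function(ligand_conc, ratio) {
  stopifnot(length(ligand_conc) == length(ratio))
  ok <- !is.na(ligand_conc) & !is.na(ratio) & ligand_conc > 0
  ligand_conc <- ligand_conc[ok]
  ratio <- ratio[ok]
  if (length(unique(ligand_conc)) < 4) {
    stop("need >= 4 distinct positive ligand concentrations",
         call. = FALSE)
  }
  df <- data.frame(L = ligand_conc, y = ratio)
  amp0 <- ratio[which.max(ligand_conc)] - ratio[which.min(ligand_conc)]
  starts <- lapply(stats::quantile(ligand_conc, c(0.25, 0.5, 0.75)),
                   function(k) list(baseline = min(ratio),
                                    amplitude = amp0, lkd = log(k)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ baseline + amplitude * L / (L + exp(lkd)),
                        data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("isotherm fit failed to converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  amp <- unname(cf["amplitude"])
  noise <- sqrt(best$sse / max(1, nrow(df) - 3))
  structure(list(kd = exp(unname(cf["lkd"])),
                 baseline = unname(cf["baseline"]),
                 amplitude = amp, residual_sse = best$sse,
                 identifiable = abs(amp) > 5 * noise + 1e-12),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit: Kd %.4g, baseline %.4g, amplitude %.4g%s\n",
              x$kd, x$baseline, x$amplitude,
              if (x$identifiable) "" else " [kd not identifiable]"))
  invisible(x)
}

#' Michaelis-Menten fits and inhibition-mode classification
#'
#' For each inhibitor level, fits v = Vmax [S] / (Km + [S]) by
#' nonlinear least squares and the double-reciprocal (1/v vs 1/[S])
#' line. The mode is classified from the trends of the apparent
#' parameters relative to the zero-inhibitor level, with a relative
#' tolerance band: Vmax falling with Km constant is noncompetitive,
#' Km rising with Vmax constant is competitive, both falling by the
#' same factor (constant Vmax/Km) is uncompetitive, anything else with
#' both parameters moving is mixed.
#'
#' @param substrate Positive substrate concentrations (>= 3).
#' @param velocities Matrix or data.frame, one column per inhibitor
#'   level (ordered by increasing inhibitor), rows matching
#'   \code{substrate}. All velocities must be positive.
#' @param inhibitor Optional numeric inhibitor concentrations for
#'   labelling; defaults to the column index.
#' @param tolerance Relative band within which a parameter counts as
#'   unchanged (default 0.2).
#' @return List of class \code{kinetics_summary}: \code{table}
#'   (data.frame inhibitor, vmax, km, recip_slope, recip_intercept)
#'   and \code{mode}.
#' @export
reciprocal_kinetics <- function(substrate, velocities, inhibitor = NULL,
                                tolerance = 0.2) {
  velocities <- as.matrix(velocities)
  stopifnot(length(substrate) == nrow(velocities))
  if (length(substrate) < 3) {
    stop("need >= 3 substrate levels", call. = FALSE)
  }
  if (any(velocities <= 0) || any(substrate <= 0)) {
    stop("substrate concentrations and velocities must be positive",
         call. = FALSE)
  }
  if (is.null(inhibitor)) inhibitor <- seq_len(ncol(velocities)) - 1
  fits <- lapply(seq_len(ncol(velocities)), function(j) {
    v <- velocities[, j]
    S <- substrate
    lb <- stats::lm(I(1 / v) ~ I(1 / S))
    ## double-reciprocal line seeds the nonlinear fit:
    ## intercept = 1/Vmax, slope = Km/Vmax
    b <- unname(stats::coef(lb))
    start <- c(vmax = if (b[1] > 0) 1 / b[1] else max(v) * 1.2,
               km = if (b[1] > 0 && b[2] > 0) b[2] / b[1]
                    else stats::median(S))
    fit <- minpack.lm::nls.lm(
      par = start,
      fn = function(p) v - p[1] * S / (p[2] + S),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    c(vmax = unname(cf["vmax"]), km = unname(cf["km"]),
      recip_intercept = unname(stats::coef(lb)[1]),
      recip_slope = unname(stats::coef(lb)[2]))
  })
  tab <- cbind(data.frame(inhibitor = inhibitor),
               as.data.frame(do.call(rbind, fits)))
  mode <- classify_inhibition(tab$vmax, tab$km, tolerance)
  structure(list(table = tab, mode = mode), class = "kinetics_summary")
}

classify_inhibition <- function(vmax, km, tolerance = 0.2) {
  if (length(vmax) < 2) return(NA_character_)
  rv <- vmax[-1] / vmax[1]
  rk <- km[-1] / km[1]
  km_const <- all(abs(rk - 1) <= tolerance)
  vmax_const <- all(abs(rv - 1) <= tolerance)
  vmax_down <- any(rv < 1 - tolerance) && all(diff(c(1, rv)) <= tolerance)
  km_up <- any(rk > 1 + tolerance)
  ratio_const <- all(abs(rv / rk - 1) <= tolerance)
  if (vmax_down && km_const) return("noncompetitive")
  if (vmax_const && km_up) return("competitive")
  if (vmax_down && all(rk < 1 + tolerance) && ratio_const &&
      !km_const) return("uncompetitive")
  "mixed"
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("Inhibition mode:", x$mode, "\n")
  print(x$table, ...)
  invisible(x)
}
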