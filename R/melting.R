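#' Assemble per-curve data from a normalized table
#'
#' Reshapes a filtered, reference-normalized protein table into one
#' melting curve per (protein, condition, replicate), points sorted by
#' temperature. Curves with no surviving (non-missing) point — e.g.
#' those discarded by the missing-pattern filter — are omitted.
#'
#' @param table A \code{protein_table} at stage \code{"filtered"} (or
#'   \code{"reference_normalized"}).
#' @param manifest Manifest data.frame.
#' @return Long data.frame: protein_id, condition, replicate,
#'   temperature, abundance (missing points omitted), sorted by
#'   protein, condition, replicate, temperature.
#' @export
assemble_curves <- function(table, manifest) {
  stopifnot(inherits(table, "protein_table"))
  if (!attr(table, "stage") %in% c("filtered", "reference_normalized")) {
    stop("curves are assembled from reference-normalized or filtered ",
         "tables, not stage ", sQuote(attr(table, "stage")), call. = FALSE)
  }
  denat <- manifest[!manifest$is_reference, ]
  vals <- as.matrix(table[, denat$run_id, drop = FALSE])
  long <- data.frame(
    protein_id = rep(table$protein_id, times = nrow(denat)),
    condition = rep(denat$condition, each = nrow(table)),
    replicate = rep(denat$replicate, each = nrow(table)),
    temperature = rep(denat$temperature, each = nrow(table)),
    abundance = as.vector(vals),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$abundance), , drop = FALSE]
  long <- long[order(long$protein_id, long$condition, long$replicate,
                     long$temperature), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Estimate a melting temperature from one curve
#'
#' Three-branch procedure. Direct: if any measured point's relative
#' abundance lies within \code{tol} of 0.5, that point's temperature
#' is the Tm (when several qualify, the abundance closest to 0.5 wins;
#' remaining ties go to the lower temperature). Spline: otherwise a
#' natural cubic interpolating spline through the points is evaluated
#' on a 0.01 degree grid over the ladder range and the lowest grid
#' temperature where the spline crosses 0.5 from above is returned.
#' Fallback: when no such crossing exists (or fewer than 4 points are
#' available for the spline), the Tm is set to the ladder maximum.
#'
#' @param temperature,abundance Numeric vectors of equal length, the
#'   curve's non-missing points.
#' @param ladder_range Length-2 numeric, the full ladder span the
#'   spline is evaluated on (and the fallback maximum). Defaults to
#'   the range of \code{temperature}.
#' @param tol Half-width of the direct-detection abundance window
#'   around 0.5 (default 0.05).
#' @param grid_step Spline evaluation grid step, degrees C.
#' @return List with \code{tm} (degrees C) and \code{method}
#'   (\code{"direct"}, \code{"spline"} or \code{"fallback"}).
#' @export
estimate_tm <- function(temperature, abundance, ladder_range = NULL,
                        tol = 0.05, grid_step = 0.01) {
  keep <- !is.na(abundance) & !is.na(temperature)
  temperature <- temperature[keep]
  abundance <- abundance[keep]
  if (length(temperature) < 2) {
    stop("need at least 2 points to estimate a Tm", call. = FALSE)
  }
  ord <- order(temperature)
  temperature <- temperature[ord]
  abundance <- abundance[ord]
  if (is.null(ladder_range)) ladder_range <- range(temperature)

  ## direct detection: a measured point at 0.5 +/- tol
  near <- which(abs(abundance - 0.5) <= tol)
  if (length(near)) {
    d <- abs(abundance[near] - 0.5)
    best <- near[d == min(d)]
    return(list(tm = temperature[min(best)], method = "direct"))
  }

  ## spline interpolation, needs >= 4 points
  if (length(temperature) >= 4) {
    sf <- stats::splinefun(temperature, abundance, method = "natural")
    grid <- seq(ladder_range[1], ladder_range[2], by = grid_step)
    y <- sf(grid)
    cross <- which(y[-length(y)] >= 0.5 & y[-1] < 0.5)
    if (length(cross)) {
      return(list(tm = grid[cross[1] + 1L], method = "spline"))
    }
  }
  list(tm = ladder_range[2], method = "fallback")
}

#' Estimate Tm for every assembled curve
#'
#' @param curves Long data.frame from \code{\link{assemble_curves}}.
#' @param ladder Numeric temperature ladder (gives the spline range
#'   and the fallback maximum).
#' @param tol,grid_step Passed to \code{\link{estimate_tm}}.
#' @return data.frame protein_id, condition, replicate, tm, method.
#'   Curves with fewer than 2 points are skipped.
#' @export
estimate_tm_all <- function(curves, ladder, tol = 0.05,
                            grid_step = 0.01) {
  key <- interaction(curves$protein_id, curves$condition,
                     curves$replicate, drop = TRUE)
  parts <- split(curves, key)
  rows <- lapply(parts, function(d) {
    if (nrow(d) < 2) return(NULL)
    est <- estimate_tm(d$temperature, d$abundance,
                       ladder_range = range(ladder), tol = tol,
                       grid_step = grid_step)
    data.frame(protein_id = d$protein_id[1], condition = d$condition[1],
               replicate = d$replicate[1], tm = est$tm,
               method = est$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Melting shift between two sets of Tm estimates
#'
#' Difference of condition means, treated minus vehicle; positive
#' values indicate ligand stabilization.
#'
#' @param tms_treated,tms_vehicle Numeric vectors of per-replicate Tm
#'   estimates.
#' @return Delta-Tm in degrees C.
#' @export
compute_delta_tm <- function(tms_treated, tms_vehicle) {
  if (length(tms_treated) == 0 || length(tms_vehicle) == 0) {
    stop("need at least one Tm estimate per condition", call. = FALSE)
  }
  mean(tms_treated) - mean(tms_vehicle)
}

#' Replicate-level test for a melting shift
#'
#' Two-sided test that the mean Tm differs between conditions,
#' computed on the per-replicate Tm estimates. The default is a Welch
#' t-test; \code{method = "permutation"} uses the exact permutation
#' distribution of the mean difference (all assignments enumerated
#' when feasible, otherwise Monte Carlo).
#'
#' @param tms_treated,tms_vehicle Numeric vectors, length >= 2 each.
#' @param method \code{"welch"} or \code{"permutation"}.
#' @param n_perm Monte Carlo draws when enumeration exceeds this count.
#' @return Two-sided p-value. Degenerate input (zero variance on both
#'   sides) gives 1 when the means are equal and 0 otherwise for the
#'   Welch branch.
#' @export
shift_test <- function(tms_treated, tms_vehicle,
                       method = c("welch", "permutation"),
                       n_perm = 10000) {
  method <- match.arg(method)
  if (length(tms_treated) < 2 || length(tms_vehicle) < 2) {
    stop("need >= 2 replicate Tm values per condition", call. = FALSE)
  }
  if (method == "welch") {
    if (stats::sd(tms_treated) == 0 && stats::sd(tms_vehicle) == 0) {
      return(if (mean(tms_treated) == mean(tms_vehicle)) 1 else 0)
    }
    return(stats::t.test(tms_treated, tms_vehicle)$p.value)
  }
  pooled <- c(tms_treated, tms_vehicle)
  n1 <- length(tms_treated)
  obs <- abs(mean(tms_treated) - mean(tms_vehicle))
  combs <- utils::combn(length(pooled), n1)
  if (ncol(combs) <= n_perm) {
    stat <- apply(combs, 2, function(idx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])))
    mean(stat >= obs - 1e-12)
  } else {
    stat <- replicate(n_perm, {
      idx <- sample(length(pooled), n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    (sum(stat >= obs - 1e-12) + 1) / (n_perm + 1)
  }
}

#' Coefficient of variation of replicate Tm values
#' @param tms Numeric vector of replicate Tm estimates.
#' @return sd/mean (sample SD); 0 for identical replicates.
#' @export
tm_cv <- function(tms) {
  if (length(tms) < 2) return(NA_real_)
  stats::sd(tms) / mean(tms)
}

#' Call melting-shift hits between two conditions
#'
#' For every protein with at least \code{min_replicates} Tm estimates
#' in both conditions, computes the delta-Tm (treated minus vehicle),
#' a replicate-level p-value, and the per-condition coefficient of
#' variation of the Tm estimates. A protein is a \emph{hit} when
#' |delta-Tm| >= \code{shift_cutoff} and p < \code{alpha}; it is
#' additionally \emph{robust} when every condition CV is below
#' \code{cv_cutoff}, the filter used to discard irregular melting
#' curves.
#'
#' @param tm_estimates data.frame from \code{\link{estimate_tm_all}}.
#' @param treated,vehicle Condition labels to compare.
#' @param shift_cutoff Minimum |delta-Tm| in degrees C (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @param cv_cutoff CV threshold for the robust flag (default 0.1).
#' @param min_replicates Minimum Tm estimates per side (default 2).
#' @param test Passed to \code{\link{shift_test}}.
#' @param adjust_p If TRUE, Benjamini-Hochberg adjust the p-values
#'   before applying \code{alpha} (default FALSE: raw p-values).
#' @return data.frame protein_id, delta_tm, p_value, cv_treated,
#'   cv_vehicle, hit, robust; sorted by |delta_tm| decreasing.
#' @export
call_hits <- function(tm_estimates, treated, vehicle,
                      shift_cutoff = 1.5, alpha = 0.05, cv_cutoff = 0.1,
                      min_replicates = 2,
                      test = c("welch", "permutation"),
                      adjust_p = FALSE) {
  test <- match.arg(test)
  stopifnot(all(c(treated, vehicle) %in% tm_estimates$condition))
  tt <- tm_estimates[tm_estimates$condition == treated, ]
  vv <- tm_estimates[tm_estimates$condition == vehicle, ]
  ids <- intersect(unique(tt$protein_id), unique(vv$protein_id))
  rows <- lapply(ids, function(p) {
    a <- tt$tm[tt$protein_id == p]
    b <- vv$tm[vv$protein_id == p]
    if (length(a) < min_replicates || length(b) < min_replicates) {
      return(NULL)
    }
    data.frame(protein_id = p,
               delta_tm = compute_delta_tm(a, b),
               p_value = shift_test(a, b, method = test),
               cv_treated = tm_cv(a), cv_vehicle = tm_cv(b),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(protein_id = character(0), delta_tm = numeric(0),
                      p_value = numeric(0), cv_treated = numeric(0),
                      cv_vehicle = numeric(0), hit = logical(0),
                      robust = logical(0)))
  }
  p_eff <- if (adjust_p) stats::p.adjust(res$p_value, "BH") else res$p_value
  res$hit <- abs(res$delta_tm) >= shift_cutoff & p_eff < alpha
  res <- cv_filter(res, cv_cutoff = cv_cutoff)
  res <- res[order(-abs(res$delta_tm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag melting-shift results with reproducible Tm estimates
#'
#' Adds (or recomputes) the \code{robust} flag: TRUE when the
#' coefficient of variation of the replicate Tm estimates is below
#' \code{cv_cutoff} in every compared condition, the criterion used to
#' restrict attention to proteins with regular, reproducible melting
#' curves.
#'
#' @param results data.frame with \code{cv_} columns (one per
#'   condition), e.g. from \code{\link{call_hits}}.
#' @param cv_cutoff CV threshold (default 0.1).
#' @return \code{results} with a logical \code{robust} column.
#' @export
cv_filter <- function(results, cv_cutoff = 0.1) {
  cv_cols <- grep("^cv_", names(results), value = TRUE)
  stopifnot(length(cv_cols) >= 1)
  cvs <- as.matrix(results[, cv_cols, drop = FALSE])
  results$robust <- rowSums(cvs >= cv_cutoff | is.na(cvs)) == 0
  results
}
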