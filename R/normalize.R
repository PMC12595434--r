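#' Precursor-depth scaling factors
#'
#' For every condition, the mean identified-precursor count over that
#' condition's denaturation runs (all temperatures and replicates) is
#' computed; each run's factor is its own precursor count divided by
#' that mean. Reference runs are excluded from the mean and receive a
#' factor of 1. Within each condition the factors therefore average
#' to 1.
#'
#' Note the direction: runs with deeper sampling get factors above 1,
#' so their abundances are scaled \emph{up}. That is the procedure as
#' practiced in the source workflow; pass \code{invert = TRUE} for the
#' conventional depth correction (dividing by the factor).
#'
#' @param manifest Manifest data.frame (see
#'   \code{\link{read_run_manifest}}).
#' @param invert If TRUE, return reciprocal factors (deeper runs
#'   scaled down).
#' @return data.frame run_id, condition, factor.
#' @export
compute_scaling_factors <- function(manifest, invert = FALSE) {
  if (any(!manifest$is_reference & manifest$precursor_count <= 0)) {
    stop("non-reference run with zero precursor count", call. = FALSE)
  }
  fac <- rep(1, nrow(manifest))
  for (cond in unique(manifest$condition)) {
    idx <- which(manifest$condition == cond & !manifest$is_reference)
    m <- mean(manifest$precursor_count[idx])
    fac[idx] <- manifest$precursor_count[idx] / m
  }
  if (invert) fac <- 1 / fac
  data.frame(run_id = manifest$run_id, condition = manifest$condition,
             factor = fac, stringsAsFactors = FALSE)
}

#' Apply scaling factors to a protein table
#'
#' Multiplies every abundance in a run by that run's scaling factor.
#' Missing cells stay missing.
#'
#' @param table A \code{protein_table} at stage \code{"raw"}.
#' @param factors data.frame from \code{\link{compute_scaling_factors}}.
#' @return The table at stage \code{"scaled"}.
#' @export
apply_scaling <- function(table, factors) {
  check_stage(table, "raw")
  runs <- run_cols(table)
  absent <- setdiff(runs, factors$run_id)
  if (length(absent)) {
    stop("no scaling factor for run(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  f <- stats::setNames(factors$factor, factors$run_id)
  for (r in runs) table[[r]] <- table[[r]] * f[[r]]
  new_protein_table(as.data.frame(table), stage = "scaled")
}

#' Per-protein median normalization within condition
#'
#' For each protein and condition, the median of the protein's
#' non-missing abundances across that condition's denaturation runs is
#' computed, and every one of the protein's values in that condition
#' (denaturation and reference runs alike) is divided by it. After
#' this step each protein's denaturation values have median 1 within
#' each condition. Reference runs contribute nothing to the median but
#' are rescaled with it, so the subsequent reference normalization is
#' performed on commensurate values.
#'
#' @param table A \code{protein_table} at stage \code{"scaled"}.
#' @param manifest Manifest data.frame.
#' @return The table at stage \code{"median_normalized"}. Proteins
#'   with no non-missing denaturation value in a condition are left
#'   missing there and listed in the \code{"undefined_median"}
#'   attribute.
#' @export
median_normalize_by_protein <- function(table, manifest) {
  check_stage(table, "scaled")
  flagged <- character(0)
  for (cond in unique(manifest$condition)) {
    denat <- manifest$run_id[manifest$condition == cond &
                               !manifest$is_reference]
    all_runs <- manifest$run_id[manifest$condition == cond]
    vals <- as.matrix(table[, denat, drop = FALSE])
    med <- apply(vals, 1, stats::median, na.rm = TRUE)  # NaN if all NA
    undef <- !is.finite(med)
    if (any(undef)) {
      flagged <- union(flagged, table$protein_id[undef])
      med[undef] <- NA_real_
    }
    for (r in all_runs) table[[r]] <- table[[r]] / med
  }
  out <- new_protein_table(as.data.frame(table),
                           stage = "median_normalized")
  attr(out, "undefined_median") <- flagged
  out
}

#' Reference-sample normalization
#'
#' For each condition, the median of each protein's values across that
#' condition's non-denatured reference runs is the divisor for all of
#' the protein's values in the condition. Proteins with no usable
#' reference value fall back to the median, over proteins, of the
#' per-protein reference medians. After this step reference-run values
#' have per-protein median 1 and denaturation values are soluble
#' fractions relative to the unheated aliquot.
#'
#' @param table A \code{protein_table} at stage
#'   \code{"median_normalized"}.
#' @param manifest Manifest data.frame; every condition must have at
#'   least one reference run.
#' @return The table at stage \code{"reference_normalized"}, with an
#'   \code{"audit"} attribute recording fallback use per condition.
#' @export
reference_normalize <- function(table, manifest) {
  check_stage(table, "median_normalized")
  audit <- list()
  for (cond in unique(manifest$condition)) {
    refs <- manifest$run_id[manifest$condition == cond &
                              manifest$is_reference]
    if (length(refs) == 0) {
      stop("condition ", sQuote(cond), " has no reference run",
           call. = FALSE)
    }
    all_runs <- manifest$run_id[manifest$condition == cond]
    rv <- as.matrix(table[, refs, drop = FALSE])
    med <- apply(rv, 1, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- NA_real_
    fallback <- stats::median(med, na.rm = TRUE)
    n_fb <- sum(is.na(med))
    med[is.na(med)] <- fallback
    for (r in all_runs) table[[r]] <- table[[r]] / med
    audit[[cond]] <- list(n_reference_runs = length(refs),
                          n_fallback_proteins = n_fb,
                          fallback_divisor = fallback)
  }
  out <- new_protein_table(as.data.frame(table),
                           stage = "reference_normalized")
  attr(out, "audit") <- audit
  out
}

#' Missing-value pattern filter for melting curves
#'
#' A protein's curve for one replicate of one condition is discarded
#' when more than \code{max_missing} of its ladder temperatures are
#' missing, unless all of the \code{first_k} lowest temperatures are
#' present (a curve complete at the low end still anchors a melting
#' transition). Discarded curves have all their cells set to missing;
#' surviving values are untouched.
#'
#' @param table A \code{protein_table} at stage
#'   \code{"reference_normalized"}.
#' @param manifest Manifest data.frame.
#' @param max_missing Maximum tolerated missing temperatures per curve
#'   (default 3).
#' @param first_k Number of lowest ladder temperatures whose complete
#'   presence rescues a curve (default 5).
#' @return The table at stage \code{"filtered"}, with a
#'   \code{"dropped_curves"} attribute (data.frame protein_id,
#'   condition, replicate, n_missing).
#' @export
filter_missing_pattern <- function(table, manifest, max_missing = 3,
                                   first_k = 5) {
  check_stage(table, "reference_normalized")
  dropped <- list()
  for (cond in unique(manifest$condition)) {
    for (rep_i in unique(manifest$replicate[manifest$condition == cond])) {
      sel <- manifest$condition == cond & manifest$replicate == rep_i &
        !manifest$is_reference
      if (!any(sel)) next
      ord <- order(manifest$temperature[sel])
      runs <- manifest$run_id[sel][ord]
      low_runs <- runs[seq_len(min(first_k, length(runs)))]
      vals <- as.matrix(table[, runs, drop = FALSE])
      n_miss <- rowSums(is.na(vals))
      low_ok <- rowSums(is.na(
        as.matrix(table[, low_runs, drop = FALSE]))) == 0
      drop <- n_miss > max_missing & !low_ok
      if (any(drop)) {
        for (r in runs) table[[r]][drop] <- NA_real_
        dropped[[length(dropped) + 1L]] <- data.frame(
          protein_id = table$protein_id[drop], condition = cond,
          replicate = rep_i, n_missing = n_miss[drop],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- new_protein_table(as.data.frame(table), stage = "filtered")
  attr(out, "dropped_curves") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(protein_id = character(0), condition = character(0),
               replicate = integer(0), n_missing = integer(0))
  }
  out
}

#' Run the full normalization pipeline
#'
#' Convenience wrapper chaining depth scaling, per-protein median
#' normalization, reference normalization and the missing-pattern
#' filter in their required order.
#'
#' @inheritParams apply_scaling
#' @inheritParams filter_missing_pattern
#' @param invert_scaling Passed to
#'   \code{\link{compute_scaling_factors}}.
#' @return A \code{protein_table} at stage \code{"filtered"}.
#' @export
normalize_melt_table <- function(table, manifest, invert_scaling = FALSE,
                                 max_missing = 3, first_k = 5) {
  sf <- compute_scaling_factors(manifest, invert = invert_scaling)
  table |>
    apply_scaling(sf) |>
    median_normalize_by_protein(manifest) |>
    reference_normalize(manifest) |>
    filter_missing_pattern(manifest, max_missing = max_missing,
                           first_k = first_k)
}

check_stage <- function(table, expected) {
  stopifnot(inherits(table, "protein_table"))
  got <- attr(table, "stage")
  if (!identical(got, expected)) {
    stop("table is at stage ", sQuote(got), " but this step requires ",
         sQuote(expected), "; run the pipeline in order", call. = FALSE)
  }
  invisible(table)
}
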