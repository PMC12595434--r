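#' Pipeline configuration with study defaults
#'
#' Collects every tunable threshold of the pipeline. The defaults are
#' the values the analysis is designed around: peptide-count filter at
#' 2, missing-pattern filter at 3 of 10 temperatures with a 5-lowest
#' rescue, direct Tm window 0.5 +/- 0.05, shift cutoff 1.5 degrees C
#' at alpha 0.05, Tm CV cutoff 0.1, screen cutoff at 2x the DEAB mean,
#' and a 0.52 Tanimoto ceiling for diversity picking.
#'
#' @param ... Overrides for any default field.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_peptides = 2,
    max_missing = 3,
    first_k_required = 5,
    tm_tolerance = 0.05,
    shift_cutoff = 1.5,
    alpha = 0.05,
    cv_cutoff = 0.1,
    screen_multiplier = 2.0,
    sim_cutoff = 0.52,
    invert_scaling = FALSE,
    test = "welch",
    adjust_p = FALSE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  num <- c("min_peptides", "max_missing", "first_k_required",
           "tm_tolerance", "shift_cutoff", "alpha", "cv_cutoff",
           "screen_multiplier", "sim_cutoff")
  bad <- num[!vapply(cfg[num], function(x)
    is.numeric(x) && length(x) == 1 && x > 0, TRUE)]
  if (length(bad)) {
    stop("config field(s) must be positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys are \code{\link{pipeline_config}}
#'   fields.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

#' Run the TPP pipeline end to end
#'
#' ingest -> peptide/contaminant filters -> scaling -> per-protein
#' median normalization -> reference normalization -> missing-pattern
#' filter -> curve assembly -> Tm estimation -> shift hit calling.
#' Stage artifacts (Tm table, shift table, audit log) are written as
#' TSV when \code{out_dir} is given.
#'
#' @param manifest_path,report_path,contaminants_path Fixture paths
#'   (dialects of \code{\link{write_fixture_bundle}});
#'   \code{contaminants_path} may be NULL.
#' @param treated,vehicle Condition labels to compare.
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional output directory.
#' @return List: \code{tm_table}, \code{shift_table}, \code{audit}
#'   (named list of per-stage counts), \code{normalized} (the filtered
#'   \code{protein_table}).
#' @export
run_tpp <- function(manifest_path, report_path,
                    contaminants_path = NULL,
                    treated = "treated", vehicle = "vehicle",
                    config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_run_manifest(manifest_path)
  table <- read_protein_report(report_path, manifest)
  audit <- list(n_proteins_raw = nrow(table))

  table <- filter_low_peptide_proteins(table, config$min_peptides)
  audit$n_after_peptide_filter <- nrow(table)
  if (!is.null(contaminants_path)) {
    table <- remove_contaminants(table, read_contaminants(contaminants_path))
  }
  audit$n_after_contaminant_filter <- nrow(table)

  norm <- normalize_melt_table(table, manifest,
                               invert_scaling = config$invert_scaling,
                               max_missing = config$max_missing,
                               first_k = config$first_k_required)
  audit$n_curves_dropped_missing <- nrow(attr(norm, "dropped_curves"))

  ladder <- sort(unique(manifest$temperature[!manifest$is_reference]))
  curves <- assemble_curves(norm, manifest)
  tm_table <- estimate_tm_all(curves, ladder, tol = config$tm_tolerance)
  audit$n_curves_with_tm <- nrow(tm_table)

  shift_table <- call_hits(tm_table, treated = treated, vehicle = vehicle,
                           shift_cutoff = config$shift_cutoff,
                           alpha = config$alpha,
                           cv_cutoff = config$cv_cutoff,
                           test = config$test,
                           adjust_p = config$adjust_p)
  audit$n_proteins_tested <- nrow(shift_table)
  audit$n_hits <- sum(shift_table$hit)
  audit$n_robust_hits <- sum(shift_table$hit & shift_table$robust)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(tm_table, file.path(out_dir, "tm_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(shift_table, file.path(out_dir, "shift_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(audit), unlist(audit), sep = "\t"),
               file.path(out_dir, "audit.tsv"))
  }
  list(tm_table = tm_table, shift_table = shift_table, audit = audit,
       normalized = norm)
}

#' Run the biochemical screen analytics
#'
#' Computes per-well velocities from a kinetic plate CSV, calls hits
#' against the DEAB-anchored cutoff, and (optionally) fits 4PL curves
#' for each compound of a dose-titration CSV.
#'
#' @param plate_path Plate CSV (well, role, compound_id, time_s,
#'   fluorescence).
#' @param dose_path Optional dose CSV (compound_id, conc_nM,
#'   response).
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Optional output directory.
#' @return List: \code{hits} (from \code{\link{call_screen_hits}}),
#'   \code{fits} (data.frame compound, ic50_nM, hill, top, bottom,
#'   sse, converged; NULL without \code{dose_path}).
#' @export
run_screen <- function(plate_path, dose_path = NULL,
                       config = pipeline_config(), out_dir = NULL) {
  plate <- utils::read.csv(plate_path, stringsAsFactors = FALSE)
  vel <- plate_velocities(plate)
  hits <- call_screen_hits(vel, multiplier = config$screen_multiplier)

  fits <- NULL
  if (!is.null(dose_path)) {
    dose <- utils::read.csv(dose_path, stringsAsFactors = FALSE)
    fits <- do.call(rbind, lapply(split(dose, dose$compound_id),
      function(d) {
        f <- tryCatch(fit_4pl(d$conc_nM, d$response),
                      error = function(e) NULL)
        if (is.null(f)) {
          data.frame(compound = d$compound_id[1], ic50_nM = NA,
                     hill = NA, top = NA, bottom = NA, sse = NA,
                     converged = FALSE, stringsAsFactors = FALSE)
        } else {
          data.frame(compound = d$compound_id[1], ic50_nM = f$ic50,
                     hill = f$hill, top = f$top, bottom = f$bottom,
                     sse = f$residual_sse, converged = f$converged,
                     stringsAsFactors = FALSE)
        }
      }))
    rownames(fits) <- NULL
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(hits, file.path(out_dir, "screen_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fits)) {
      utils::write.table(fits, file.path(out_dir, "dose_fits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(hits = hits, fits = fits)
}

#' Run the virtual-screen triage
#'
#' Parses structures, computes descriptors, applies the
#' physicochemical windows, merges docking ranks into the combined
#' (minimum) rank, and selects a fingerprint-diversity subset by
#' sphere exclusion.
#'
#' @param structures_path SMILES or SDF library.
#' @param ranks_path Rank CSV (id, hybrid_rank, moe_rank).
#' @param config A \code{\link{pipeline_config}}.
#' @param windows Descriptor windows (default
#'   \code{\link{vhts_windows}()}).
#' @param max_picks Cap on the diversity subset size.
#' @param out_dir Optional output directory.
#' @return List: \code{descriptors} (full table), \code{pass},
#'   \code{fail}, \code{ranked}, \code{excluded}, \code{picked}
#'   (data.frame of the kept compounds in pick order).
#' @export
run_triage <- function(structures_path, ranks_path,
                       config = pipeline_config(),
                       windows = vhts_windows(), max_picks = Inf,
                       out_dir = NULL) {
  cs <- parse_structures(structures_path)
  cs <- compute_descriptors(cs)
  flt <- apply_physchem_filter(cs, windows)

  ranks <- read_rank_csv(ranks_path)
  ranks <- ranks[ranks$id %in% flt$pass$id, , drop = FALSE]
  missing_rank <- setdiff(flt$pass$id, ranks$id)
  cr <- combine_ranks(ranks)
  excluded <- cr$excluded
  if (length(missing_rank)) {
    excluded <- rbind(excluded,
                      data.frame(id = missing_rank, hybrid_rank = NA,
                                 moe_rank = NA, reason = "no rank record",
                                 stringsAsFactors = FALSE))
  }

  fps <- ecfp_fingerprints(cs)
  picked_ids <- diversity_pick(cr$ranked$id, fps,
                               sim_cutoff = config$sim_cutoff,
                               max_picks = max_picks)
  picked <- merge(data.frame(id = picked_ids,
                             pick_order = seq_along(picked_ids),
                             stringsAsFactors = FALSE),
                  merge(cs$table, cr$ranked[, c("id", "combined_rank")],
                        by = "id"),
                  by = "id")
  picked <- picked[order(picked$pick_order), , drop = FALSE]
  rownames(picked) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(cs$table, file.path(out_dir, "descriptors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flt$fail, file.path(out_dir, "filter_failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(picked$smiles, picked$id),
               file.path(out_dir, "picked_subset.smi"))
  }
  list(descriptors = cs$table, pass = flt$pass, fail = flt$fail,
       ranked = cr$ranked, excluded = excluded, picked = picked)
}
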