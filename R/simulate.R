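#' Simulation configuration for a synthetic melt dataset
#'
#' Bundles every knob of the synthetic thermal-denaturation experiment
#' into a validated list. Defaults describe the study design the
#' package targets: a 10-temperature ladder from 36.9 to 64 degrees C,
#' two conditions (vehicle and treated) with three replicates each,
#' non-denatured reference runs, multiplicative lognormal measurement
#' noise and a small set of ligand-stabilized ("spiked") proteins.
#'
#' @param n_proteins Number of simulated proteins (excluding
#'   contaminant entries).
#' @param n_spiked Number of proteins given a thermal shift in the
#'   treated condition(s).
#' @param ladder Strictly increasing vector of denaturation
#'   temperatures (degrees C).
#' @param conditions Character vector of condition labels; the first is
#'   the vehicle, all others receive the spike shift.
#' @param n_replicates Replicates per condition.
#' @param tm_range Interval the true vehicle Tm values are drawn from
#'   (uniform), degrees C.
#' @param shift_mean,shift_sd Mean and SD (degrees C) of the true
#'   stabilization shift of spiked proteins.
#' @param plateau_range Interval in \verb{[0, 1)} for the lower
#'   plateau of each melting curve.
#' @param slope_range Interval (degrees C) for the logistic transition
#'   width.
#' @param noise_sd Sigma of the multiplicative lognormal measurement
#'   noise; 0 gives noiseless data.
#' @param missing_rate Probability in \verb{[0, 1)} that any
#'   measurement cell is missing.
#' @param n_contaminants Number of contaminant entries (ids prefixed
#'   \code{CON__}) appended to the report.
#' @param low_peptide_rate Fraction of proteins whose reported peptide
#'   count is forced to 1, so the peptide filter has work to do.
#' @param seed Integer seed; every random draw derives from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 100,
                       n_spiked = 5,
                       ladder = c(36.9, 40.2, 43.9, 46.6, 48.6,
                                  52.7, 55.3, 58.8, 61.2, 64.0),
                       conditions = c("vehicle", "treated"),
                       n_replicates = 3,
                       tm_range = c(42, 58),
                       shift_mean = 4,
                       shift_sd = 0.5,
                       plateau_range = c(0, 0.2),
                       slope_range = c(1, 3),
                       noise_sd = 0.05,
                       missing_rate = 0.03,
                       n_contaminants = 3,
                       low_peptide_rate = 0.1,
                       seed = 1L) {
  stopifnot(
    n_proteins >= 0, n_spiked >= 0, n_spiked <= n_proteins,
    length(ladder) >= 2, all(diff(ladder) > 0),
    length(conditions) >= 1, !anyDuplicated(conditions),
    n_replicates >= 1,
    length(tm_range) == 2, tm_range[1] <= tm_range[2],
    shift_sd >= 0,
    length(plateau_range) == 2, plateau_range[1] >= 0, plateau_range[2] < 1,
    length(slope_range) == 2, slope_range[1] > 0,
    noise_sd >= 0,
    missing_rate >= 0, missing_rate < 1,
    n_contaminants >= 0,
    low_peptide_rate >= 0, low_peptide_rate <= 1
  )
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_spiked = as.integer(n_spiked),
         ladder = as.numeric(ladder),
         conditions = as.character(conditions),
         n_replicates = as.integer(n_replicates),
         tm_range = tm_range, shift_mean = shift_mean, shift_sd = shift_sd,
         plateau_range = plateau_range, slope_range = slope_range,
         noise_sd = noise_sd, missing_rate = missing_rate,
         n_contaminants = as.integer(n_contaminants),
         low_peptide_rate = low_peptide_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a thermal-proteome-profiling dataset
#'
#' Draws per-protein melting parameters, evaluates the logistic melt
#' model over the temperature ladder for every condition and
#' replicate, applies multiplicative lognormal noise and random
#' missingness, and assembles the run manifest (with per-run precursor
#' counts) and wide protein report the ingest module consumes. Spiked
#' proteins receive their shift only in non-vehicle conditions; each
#' condition gets one non-denatured reference run per replicate.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{melt_simulation} with elements
#'   \describe{
#'     \item{manifest}{data.frame: run_id, condition, replicate,
#'       temperature (NA for references), is_reference,
#'       precursor_count.}
#'     \item{report}{data.frame: protein_id, peptide_count, one
#'       abundance column per run_id (NA = missing).}
#'     \item{contaminants}{character vector of contaminant ids.}
#'     \item{truth}{data.frame: protein_id, one true-Tm column per
#'       condition, true_shift, spiked, contaminant, plateau, slope.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_melt_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  n_all <- cfg$n_proteins + cfg$n_contaminants
  protein_id <- c(sprintf("P%05d", seq_len(cfg$n_proteins)),
                  if (cfg$n_contaminants > 0)
                    sprintf("CON__%03d", seq_len(cfg$n_contaminants)))
  contaminant <- c(rep(FALSE, cfg$n_proteins), rep(TRUE, cfg$n_contaminants))

  ## manifest: denaturation runs then references, per condition
  rows <- list()
  for (cond in cfg$conditions) {
    for (rep_i in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_r%d_T%02d", cond, rep_i, seq_along(cfg$ladder)),
        condition = cond, replicate = rep_i,
        temperature = cfg$ladder, is_reference = FALSE,
        stringsAsFactors = FALSE)
    }
    for (rep_i in seq_len(cfg$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_r%d_REF", cond, rep_i),
        condition = cond, replicate = rep_i,
        temperature = NA_real_, is_reference = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  ## precursor depth varies a little run to run
  manifest$precursor_count <- as.integer(round(
    50000 * exp(stats::rnorm(nrow(manifest), 0, 0.05))))

  ## per-protein curve parameters
  tm_vehicle <- stats::runif(n_all, cfg$tm_range[1], cfg$tm_range[2])
  plateau <- stats::runif(n_all, cfg$plateau_range[1], cfg$plateau_range[2])
  slope <- stats::runif(n_all, cfg$slope_range[1], cfg$slope_range[2])
  base_abund <- exp(stats::rnorm(n_all, log(1e6), 1))

  spiked <- rep(FALSE, n_all)
  if (cfg$n_spiked > 0) {
    spiked[sample(seq_len(cfg$n_proteins), cfg$n_spiked)] <- TRUE
  }
  true_shift <- ifelse(
    spiked, stats::rnorm(n_all, cfg$shift_mean, cfg$shift_sd), 0)

  tm_by_cond <- matrix(tm_vehicle, nrow = n_all,
                       ncol = length(cfg$conditions))
  colnames(tm_by_cond) <- cfg$conditions
  if (length(cfg$conditions) > 1) {
    for (cond in cfg$conditions[-1]) {
      tm_by_cond[, cond] <- tm_vehicle + true_shift
    }
  }

  ## abundance matrix, proteins x runs
  abund <- matrix(NA_real_, nrow = n_all, ncol = nrow(manifest),
                  dimnames = list(protein_id, manifest$run_id))
  for (j in seq_len(nrow(manifest))) {
    cond <- manifest$condition[j]
    frac <- if (manifest$is_reference[j]) {
      rep(1, n_all)
    } else {
      melt_fraction(manifest$temperature[j], tm_by_cond[, cond],
                    slope, plateau)
    }
    noise <- if (cfg$noise_sd > 0) {
      exp(stats::rnorm(n_all, 0, cfg$noise_sd))
    } else rep(1, n_all)
    abund[, j] <- base_abund * frac * noise
  }
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(abund)) < cfg$missing_rate
    abund[miss] <- NA_real_
  }

  peptide_count <- stats::rpois(n_all, 8) + 2L
  if (cfg$low_peptide_rate > 0 && n_all > 0) {
    n_low <- round(cfg$low_peptide_rate * n_all)
    if (n_low > 0) peptide_count[sample(n_all, n_low)] <- 1L
  }

  report <- data.frame(protein_id = protein_id,
                       peptide_count = as.integer(peptide_count),
                       stringsAsFactors = FALSE)
  report <- cbind(report, as.data.frame(abund, optional = TRUE))
  rownames(report) <- NULL

  truth <- data.frame(protein_id = protein_id, stringsAsFactors = FALSE)
  for (cond in cfg$conditions) {
    truth[[paste0("tm_", cond)]] <- tm_by_cond[, cond]
  }
  truth$true_shift <- true_shift
  truth$spiked <- spiked
  truth$contaminant <- contaminant
  truth$plateau <- plateau
  truth$slope <- slope

  structure(list(manifest = manifest, report = report,
                 contaminants = protein_id[contaminant],
                 truth = truth, config = cfg),
            class = "melt_simulation")
}

## vectorized over proteins for a single temperature
melt_fraction <- function(temperature, tm, slope, plateau) {
  plateau + (1 - plateau) / (1 + exp((temperature - tm) / slope))
}

#' Simulate a kinetic screening plate
#'
#' Builds per-well kinetic fluorescence traces for a single-dose
#' biochemical screen with uniformly interspersed DMSO (full activity)
#' and DEAB (full inhibition) control wells. Compound wells are mostly
#' inactive (velocity near the DMSO level); a \code{hit_fraction}
#' subset are true inhibitors whose velocity is drawn below twice the
#' DEAB mean, the cutoff the hit caller applies.
#'
#' @param n_compounds Number of compound wells.
#' @param hit_fraction Fraction of compounds that are true inhibitors.
#' @param n_controls Number of DMSO wells (and of DEAB wells).
#' @param v_dmso,v_deab True uninhibited / fully inhibited velocities
#'   (AU/s).
#' @param n_timepoints Samples per kinetic trace over 600 s.
#' @param noise_sd SD of additive Gaussian read noise (AU).
#' @param seed Integer seed.
#' @return List of class \code{plate_simulation}: \code{plate}
#'   (data.frame well, role, compound_id, time_s, fluorescence) and
#'   \code{truth} (data.frame compound_id, true_velocity, is_hit).
#' @export
simulate_screen_plate <- function(n_compounds, hit_fraction = 0.02,
                                  n_controls = 8,
                                  v_dmso = 1.0, v_deab = 0.05,
                                  n_timepoints = 11, noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(n_compounds > 0, hit_fraction >= 0, hit_fraction <= 1,
            v_dmso > v_deab, v_deab >= 0)
  set.seed(as.integer(seed))
  times <- seq(0, 600, length.out = n_timepoints)
  cutoff <- 2 * v_deab   # hit caller uses 2 x mean DEAB velocity

  n_hits <- round(hit_fraction * n_compounds)
  is_hit <- rep(FALSE, n_compounds)
  if (n_hits > 0) is_hit[sample(n_compounds, n_hits)] <- TRUE
  true_v <- ifelse(is_hit,
                   stats::runif(n_compounds, v_deab, 0.9 * cutoff),
                   stats::runif(n_compounds, 1.2 * cutoff, 1.1 * v_dmso))

  wells <- data.frame(
    well = sprintf("W%03d", seq_len(n_compounds + 2 * n_controls)),
    role = c(rep("compound", n_compounds),
             rep("DMSO", n_controls), rep("DEAB", n_controls)),
    compound_id = c(sprintf("CMP%04d", seq_len(n_compounds)),
                    rep(NA_character_, 2 * n_controls)),
    velocity = c(true_v, rep(v_dmso, n_controls), rep(v_deab, n_controls)),
    stringsAsFactors = FALSE)

  trace <- function(v) {
    y <- 100 + v * times
    if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
    y
  }
  plate <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    data.frame(well = wells$well[i], role = wells$role[i],
               compound_id = wells$compound_id[i],
               time_s = times, fluorescence = trace(wells$velocity[i]),
               stringsAsFactors = FALSE)
  }))
  truth <- data.frame(compound_id = wells$compound_id[seq_len(n_compounds)],
                      true_velocity = true_v, is_hit = is_hit,
                      stringsAsFactors = FALSE)
  structure(list(plate = plate, truth = truth,
                 v_dmso = v_dmso, v_deab = v_deab, seed = seed),
            class = "plate_simulation")
}

#' Simulate dose-response data from a four-parameter logistic
#'
#' @param bottom,top Lower/upper response asymptotes.
#' @param ic50 Half-maximal inhibitory concentration (same units as
#'   \code{concentrations}); must be positive.
#' @param hill Hill slope.
#' @param concentrations Positive concentration vector.
#' @param noise_sd SD of additive Gaussian noise on the response.
#' @param seed Integer seed.
#' @return data.frame with columns \code{conc} and \code{response}.
#' @export
simulate_dose_response <- function(bottom = 0, top = 100, ic50 = 150,
                                   hill = 1,
                                   concentrations = 10^seq(0, 5, by = 0.5),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(ic50 > 0, all(concentrations > 0))
  set.seed(as.integer(seed))
  resp <- four_pl(concentrations, bottom, top, ic50, hill)
  if (noise_sd > 0) resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
  data.frame(conc = concentrations, response = resp)
}

#' Write a melt simulation as plain-text fixture files
#'
#' Emits exactly the dialects the ingest module reads:
#' \code{runs_manifest.tsv} (run_id, condition, replicate,
#' temperature_or_REF, precursor_count), \code{protein_report.tsv}
#' (protein_id, peptide_count, one column per run) and
#' \code{contaminants.txt} (one id per line).
#'
#' @param sim A \code{melt_simulation}.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written (named list).
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "melt_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- sim$manifest
  man_out <- data.frame(
    run_id = man$run_id, condition = man$condition,
    replicate = man$replicate,
    temperature_or_REF = ifelse(man$is_reference, "REF",
                                format(man$temperature, trim = TRUE)),
    precursor_count = man$precursor_count, stringsAsFactors = FALSE)
  paths <- list(
    manifest = file.path(dir, "runs_manifest.tsv"),
    report = file.path(dir, "protein_report.tsv"),
    contaminants = file.path(dir, "contaminants.txt"))
  utils::write.table(man_out, paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$report, paths$report, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  writeLines(sim$contaminants, paths$contaminants)
  invisible(paths)
}

#' Write a simulated plate as CSV
#' @param sim A \code{plate_simulation}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_plate_csv <- function(sim, path) {
  stopifnot(inherits(sim, "plate_simulation"))
  utils::write.csv(sim$plate, path, row.names = FALSE, na = "")
  invisible(path)
}
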