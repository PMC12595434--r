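#' Read a run manifest
#'
#' Parses the tab-separated run manifest describing every MS run of a
#' thermal-denaturation experiment: its condition, replicate,
#' temperature (or \code{REF} for a non-denatured reference aliquot)
#' and the run's identified-precursor count, the depth statistic the
#' scaling step consumes.
#'
#' @param path Path to a TSV with header columns \code{run_id},
#'   \code{condition}, \code{replicate}, \code{temperature_or_REF},
#'   \code{precursor_count}.
#' @param ladder Optional numeric ladder; when given, every
#'   non-reference temperature must match a ladder value.
#' @return data.frame with columns run_id, condition, replicate,
#'   temperature (NA for references), is_reference, precursor_count.
#' @export
read_run_manifest <- function(path, ladder = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("run_id", "condition", "replicate", "temperature_or_REF",
              "precursor_count")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  is_ref <- raw$temperature_or_REF == "REF"
  temp <- suppressWarnings(as.numeric(raw$temperature_or_REF))
  bad <- which(!is_ref & is.na(temp))
  if (length(bad)) {
    stop("unrecognized temperature token ",
         sQuote(raw$temperature_or_REF[bad[1]]),
         " at manifest line ", bad[1] + 1L, call. = FALSE)
  }
  if (!is.null(ladder)) {
    off <- which(!is_ref & !sapply(temp, function(t)
      any(abs(t - ladder) < 1e-6)))
    if (length(off)) {
      stop("temperature ", temp[off[1]], " at manifest line ", off[1] + 1L,
           " is not a ladder value", call. = FALSE)
    }
  }
  pc <- suppressWarnings(as.integer(raw$precursor_count))
  if (anyNA(pc) || any(pc < 0)) {
    stop("precursor_count must be a nonnegative integer", call. = FALSE)
  }
  data.frame(run_id = raw$run_id, condition = raw$condition,
             replicate = as.integer(raw$replicate),
             temperature = ifelse(is_ref, NA_real_, temp),
             is_reference = is_ref, precursor_count = pc,
             stringsAsFactors = FALSE)
}

#' Read a protein-level quant report
#'
#' Reads a wide search-engine-style protein report: one row per
#' protein, an identified-peptide count, and one abundance column per
#' run in the manifest. Empty cells and \code{NA} are kept as missing
#' values, never coerced to zero.
#'
#' @param path Path to the TSV report.
#' @param manifest Manifest data.frame from
#'   \code{\link{read_run_manifest}}; every \code{run_id} must have a
#'   column in the report.
#' @return A \code{protein_table}: data.frame with protein_id,
#'   peptide_count and one numeric column per run, stage attribute
#'   \code{"raw"}.
#' @export
read_protein_report <- function(path, manifest) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  if (!all(c("protein_id", "peptide_count") %in% names(raw))) {
    stop("report must have protein_id and peptide_count columns",
         call. = FALSE)
  }
  absent <- setdiff(manifest$run_id, names(raw))
  if (length(absent)) {
    stop("report is missing run column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tab <- raw[, c("protein_id", "peptide_count", manifest$run_id)]
  for (r in manifest$run_id) tab[[r]] <- as.numeric(tab[[r]])
  vals <- as.matrix(tab[, manifest$run_id, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative abundance in report", call. = FALSE)
  }
  new_protein_table(tab, stage = "raw")
}

new_protein_table <- function(df, stage) {
  stopifnot(stage %in% c("raw", "scaled", "median_normalized",
                         "reference_normalized", "filtered"))
  structure(df, stage = stage,
            class = c("protein_table", "data.frame"))
}

#' @export
print.protein_table <- function(x, ...) {
  cat("<protein_table> ", nrow(x), " proteins, ",
      ncol(x) - 2L, " runs, stage: ", attr(x, "stage"), "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Normalization stage of a protein table
#' @param x A \code{protein_table}.
#' @return One of \code{"raw"}, \code{"scaled"},
#'   \code{"median_normalized"}, \code{"reference_normalized"},
#'   \code{"filtered"}.
#' @export
table_stage <- function(x) attr(x, "stage")

run_cols <- function(table) setdiff(names(table),
                                    c("protein_id", "peptide_count"))

#' Discard proteins with too few identified peptides
#'
#' Proteins identified by fewer than \code{min_peptides} peptides are
#' removed before normalization; single-peptide identifications are
#' considered unreliable.
#'
#' @param table A \code{protein_table}.
#' @param min_peptides Minimum peptide count to retain (default 2).
#' @return The filtered table, row order preserved.
#' @export
filter_low_peptide_proteins <- function(table, min_peptides = 2) {
  stopifnot(inherits(table, "protein_table"))
  keep <- table$peptide_count >= min_peptides
  new_protein_table(table[keep, , drop = FALSE], attr(table, "stage"))
}

#' Remove contaminant proteins
#'
#' Drops rows whose id is in the contaminant list, matched exactly.
#' Ids carrying the common \code{CON__} database prefix also match
#' their unprefixed form.
#'
#' @param table A \code{protein_table}.
#' @param contaminant_ids Character vector of contaminant protein ids
#'   (possibly empty).
#' @return The filtered table.
#' @export
remove_contaminants <- function(table, contaminant_ids) {
  stopifnot(inherits(table, "protein_table"))
  if (length(contaminant_ids) == 0) return(table)
  bare <- sub("^CON__", "", contaminant_ids)
  bad <- table$protein_id %in% c(contaminant_ids, bare,
                                 paste0("CON__", bare))
  new_protein_table(table[!bad, , drop = FALSE], attr(table, "stage"))
}

#' Read a contaminant id list
#' @param path Text file, one protein id per line; blank lines and
#'   lines starting with \code{#} are skipped.
#' @return Character vector of ids.
#' @export
read_contaminants <- function(path) {
  if (!file.exists(path)) stop("contaminant list not found: ", path,
                               call. = FALSE)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
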