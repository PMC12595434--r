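## shared fixture builders; everything is generated in code

default_ladder <- c(36.9, 40.2, 43.9, 46.6, 48.6,
                    52.7, 55.3, 58.8, 61.2, 64.0)

## a minimal manifest for hand-built tables: conditions x replicates x
## ladder plus one reference per condition/replicate
make_manifest <- function(conditions = c("vehicle", "treated"),
                          n_replicates = 3, ladder = default_ladder,
                          precursor_count = 50000L) {
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_r%d_T%02d", cond, r, seq_along(ladder)),
        condition = cond, replicate = r, temperature = ladder,
        is_reference = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_r%d_REF", cond, r),
        condition = cond, replicate = r, temperature = NA_real_,
        is_reference = TRUE, stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  m$precursor_count <- precursor_count
  m
}

## wrap a plain data.frame as a raw protein_table
as_protein_table <- function(df, stage = "raw") {
  engagekit:::new_protein_table(df, stage)
}

## wide table with given abundance matrix (proteins x manifest runs)
make_table <- function(abund, manifest, peptide_count = 5L) {
  df <- data.frame(protein_id = rownames(abund),
                   peptide_count = peptide_count,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(abund, optional = TRUE))
  rownames(df) <- NULL
  as_protein_table(df)
}

run_ids_for <- function(manifest, cond, rep_i, refs = FALSE) {
  sel <- manifest$condition == cond & manifest$replicate == rep_i &
    manifest$is_reference == refs
  rid <- manifest$run_id[sel]
  if (!refs) rid[order(manifest$temperature[sel])] else rid
}
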