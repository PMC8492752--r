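# Readers and writers for the pipeline's plain-text interchange formats.
# All writers stamp a header comment with a short hash of the generating
# config; readers skip comment lines.

write_stamped_csv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  stamp <- if (is.null(cfg)) "" else paste0(" config=", config_hash(cfg))
  writeLines(paste0("# limnoch4", stamp), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read flux records CSV
#'
#' Columns: `trap_id, lake, zone, date, temp_C, flux_mg_m2_d`.
#'
#' @param records flux record data frame.
#' @param path file path.
#' @param cfg optional config whose hash is stamped in the header comment.
#' @return the path (writer) or the data frame (reader).
#' @export
write_flux_csv <- function(records, path, cfg = NULL) {
  write_stamped_csv(records, path, cfg)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  df$date <- as.Date(df$date)
  df
}

#' Write / read core chemistry CSV
#'
#' Columns: `sample, core, lake, zone, depth_cm, TOC_pct, d13C_TOC, CH4_uM,
#' DIC_uM, d13C_CH4, d13C_DIC, S_pct, TOC_TS` (plus any extras such as the
#' generator's `f_meth_true`).
#'
#' @inheritParams write_flux_csv
#' @param chem chemistry data frame.
#' @export
write_chem_csv <- function(chem, path, cfg = NULL) {
  write_stamped_csv(chem, path, cfg)
}

#' @rdname write_chem_csv
#' @export
read_chem_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write / read an OTU table TSV
#'
#' Layout: rows are OTUs, columns are samples, the final column is the
#' semicolon-delimited taxonomy string. Sample metadata travels in a
#' separate CSV (`write_sample_meta_csv()`).
#'
#' @param otu a `limnoch4_otu`.
#' @param path file path.
#' @export
write_otu_tsv <- function(otu, path) {
  df <- as.data.frame(t(otu$counts))
  df <- cbind(OTU_ID = rownames(df), df,
              taxonomy = unname(otu$taxonomy[rownames(df)]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @param meta_path optional metadata CSV (from
#'   `write_sample_meta_csv()`); if supplied the result is a full
#'   `limnoch4_otu`, otherwise a bare list without `meta`.
#' @export
read_otu_tsv <- function(path, meta_path = NULL) {
  df <- read.delim(path, check.names = FALSE)
  taxonomy <- setNames(df$taxonomy, df$OTU_ID)
  counts <- t(as.matrix(df[, setdiff(names(df), c("OTU_ID", "taxonomy")),
                           drop = FALSE]))
  colnames(counts) <- df$OTU_ID
  meta <- if (!is.null(meta_path)) read.csv(meta_path, comment.char = "#")
  structure(list(counts = counts, taxonomy = taxonomy, meta = meta),
            class = "limnoch4_otu")
}

#' @rdname write_otu_tsv
#' @export
write_sample_meta_csv <- function(otu, path) {
  write_stamped_csv(otu$meta, path)
}

#' Write / read a qPCR plate CSV pair
#'
#' Writes `<stem>_standards.csv` and `<stem>_samples.csv`.
#'
#' @param plate a `limnoch4_qpcr_plate`.
#' @param stem path stem (no extension).
#' @export
write_qpcr_csv <- function(plate, stem) {
  write_stamped_csv(plate$standards, paste0(stem, "_standards.csv"))
  write_stamped_csv(plate$samples, paste0(stem, "_samples.csv"))
  invisible(stem)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(stem) {
  structure(list(
    standards = read.csv(paste0(stem, "_standards.csv"),
                         comment.char = "#"),
    samples = read.csv(paste0(stem, "_samples.csv"), comment.char = "#"),
    elution_uL = 100, mass_g = 0.25
  ), class = "limnoch4_qpcr_plate")
}
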