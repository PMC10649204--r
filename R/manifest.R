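# Cohort manifests: CSV with header
#   lesion_id,class_label,af_path,g526_path,r663_path,ir964_path
# or, for synthetic cohorts, a `seed` column instead of the path columns.

.manifest_path_cols <- c("af_path", "g526_path", "r663_path", "ir964_path")

#' Load and validate a cohort manifest
#'
#' @param path CSV file with columns `lesion_id`, `class_label` and either
#'   the four per-band image path columns (`af_path`, `g526_path`,
#'   `r663_path`, `ir964_path`) or a `seed` column for synthetic cohorts.
#'   Lines starting with `#` are ignored.
#' @return Data frame of validated entries with a derived logical column
#'   `nf1_related` (`TRUE` for cafe-au-lait macules and neurofibromas).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    .nf_error(sprintf("manifest not found: %s", path), "nf_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_manifest(df)
}

#' Validate an in-memory manifest data frame
#'
#' @param df Data frame with manifest columns (see [load_manifest()]).
#' @return The validated data frame with an `nf1_related` column.
#' @export
validate_manifest <- function(df) {
  need <- c("lesion_id", "class_label")
  if (!all(need %in% names(df)))
    .nf_error(sprintf("manifest must contain columns: %s",
                      paste(need, collapse = ", ")), "nf_format_error")
  if (!("seed" %in% names(df)) && !all(.manifest_path_cols %in% names(df)))
    .nf_error("manifest needs either a 'seed' column or the four band path columns",
              "nf_format_error")
  bad <- setdiff(unique(df$class_label), lesion_classes())
  if (length(bad) > 0)
    .nf_error(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
              "nf_format_error")
  if (anyDuplicated(df$lesion_id))
    .nf_error("duplicate lesion_id in manifest", "nf_format_error")
  df$nf1_related <- df$class_label %in% nf1_classes()
  df
}

#' Write a cohort manifest CSV
#'
#' @param df Manifest data frame.
#' @param path Output CSV path.
#' @param provenance Optional named character vector written as `#`-prefixed
#'   header comment lines (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), provenance), con)
  }
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
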