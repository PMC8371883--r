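#' @include AllClasses.R correction.R
NULL

#' Read a community profile table
#'
#' Reads a CSV/TSV with one row per taxon: columns `taxon_id`, `freq`
#' (ribosomal gene frequency — relative frequencies, percentages or raw
#' counts; interpreted proportionally) and either `volume_um3` (cell
#' volume) or `bin_diameter_um` (an approximate spherical-equivalent
#' diameter, assigned to a size bin of `scheme`). Rows may mix the two:
#' `volume_um3` wins where both are present.
#'
#' @param path path to the table.
#' @param qpcrTotal optional sample-level total ribosomal gene copies
#'   \eqn{R_s} (copies per sample unit).
#' @param scheme [SizeBinScheme-class] used to resolve diameters.
#' @param dialect `"csv"` or `"tsv"` (default from extension).
#' @return a [CommunityProfile-class].
#' @seealso [correctProfile()], [writeCorrectedProfile()]
#' @export
readCommunityProfile <- function(path, qpcrTotal = NA_real_,
                                 scheme = sizeBinScheme(), dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          check.names = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "freq") %in% names(df)))
    stop("profile table needs 'taxon_id' and 'freq' columns")
  vol <- if ("volume_um3" %in% names(df)) as.numeric(df$volume_um3)
         else rep(NA_real_, nrow(df))
  dia <- if ("bin_diameter_um" %in% names(df))
    as.numeric(df$bin_diameter_um) else NULL
  communityProfile(taxon = df$taxon_id, freq = as.numeric(df$freq),
                   volume = vol, diameter = dia, qpcrTotal = qpcrTotal,
                   scheme = scheme)
}

#' Write a corrected profile table
#'
#' Emits one row per taxon with columns `taxon_id`, `rc`, `f_r`, `f_c`,
#' `f_v` and, when absolute abundances were computed, `r_abs`,
#' `cells_abs`, `biovol_abs_um3`.
#'
#' @param corrected a [CorrectedProfile-class].
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6;
#'   `NA` writes full precision).
#' @return `path`, invisibly.
#' @export
writeCorrectedProfile <- function(corrected, path, digits = 6) {
  stopifnot(is(corrected, "CorrectedProfile"))
  df <- as.data.frame(corrected)
  df <- df[, c("taxon_id", "rc", "f_r", "f_c", "f_v",
               intersect(c("r_abs", "cells_abs", "biovol_abs_um3"),
                         names(df)))]
  if (!is.na(digits))
    for (col in setdiff(names(df), "taxon_id"))
      df[[col]] <- signif(df[[col]], digits)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
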