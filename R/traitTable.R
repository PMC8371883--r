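#' @include geometry.R
NULL

## Canonical trait-table schema. dim1 = diameter, dim2 = length (um);
## genome sizes and DNA contents are in Mbp (per genome copy / per cell).
.traitColumns <- c("taxon_id", "domain", "shape", "dim1", "dim2", "dim3",
                   "volume_um3", "rrn_per_genome", "ploidy", "rrn_per_cell",
                   "genome_mbp", "dna_per_cell_mbp")
.traitNumericColumns <- setdiff(.traitColumns,
                                c("taxon_id", "domain", "shape"))
.traitDomains <- c("bacteria", "archaea", "eukaryote")

## Parse one table cell that may be a plain number or a "lo-hi" / "lo–hi"
## range (collapsed to the arithmetic mean). Errors name the offending
## row and column.
.parseTraitCell <- function(x, row, col) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v)) return(v)
  ## en-dash, em-dash or hyphen as range separator
  m <- regmatches(x, regexec(
    "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*[-–—]\\s*([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)$",
    x))[[1]]
  if (length(m) == 3L) {
    lo <- as.numeric(m[2])
    hi <- as.numeric(m[3])
    return((lo + hi) / 2)
  }
  stop(sprintf("row %d, column '%s': cannot parse numeric value '%s'",
               row, col, x), call. = FALSE)
}

.parseShapeCell <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") return(NA_character_)
  x
}

## Resolve the shape/dim columns of one row to a volume, or NA if the
## description is incomplete.
.shapeToVolume <- function(shape, dim1, dim2) {
  if (is.na(shape)) return(NA_real_)
  if (startsWith(shape, "{") || startsWith(shape, "[")) {
    spec <- jsonlite::fromJSON(shape, simplifyVector = FALSE)
    return(shapeVolume(spec))
  }
  shapeVolume(shape, d = dim1, l = dim2)
}

#' Ribosomal gene copies per cell from ploidy and operons per genome
#'
#' The cellular SSU rRNA gene dosage is the product of the ploidy level
#' `P` (genome copies per cell) and the ribosomal operon copy number per
#' genome `R_g`: \eqn{R_c = P \, R_g}.
#'
#' @param ploidy genomes per cell, > 0 (need not be integer: reported
#'   ploidies are often averages over a range).
#' @param rrnPerGenome ribosomal operons per genome, >= 1.
#' @return copies per cell (vectorized).
#' @examples
#' deriveRc(4, 2)       # 8
#' deriveRc(212.5, 2)   # 425
#' @seealso [derivePloidy()]
#' @export
deriveRc <- function(ploidy, rrnPerGenome) {
  if (any(!is.finite(ploidy)) || any(ploidy <= 0))
    stop("'ploidy' must be positive")
  if (any(!is.finite(rrnPerGenome)) || any(rrnPerGenome < 1))
    stop("'rrnPerGenome' must be at least 1")
  ploidy * rrnPerGenome
}

#' Ploidy from cellular DNA content and genome size
#'
#' When direct ploidy determinations are missing, the number of genome
#' copies per cell can be estimated as total cellular DNA divided by the
#' size of one genome copy (both in Mbp): \eqn{P = DNA_{cell} / G}.
#'
#' @param dnaPerCell total cellular DNA, Mbp-equivalents, > 0.
#' @param genomeSize size of one genome copy, Mbp, > 0.
#' @return genomes per cell (vectorized).
#' @examples
#' derivePloidy(8, 2)      # 4
#' derivePloidy(9.6, 3.2)  # 3
#' @seealso [deriveRc()], [fgToMbp()]
#' @export
derivePloidy <- function(dnaPerCell, genomeSize) {
  if (any(!is.finite(dnaPerCell)) || any(dnaPerCell <= 0))
    stop("'dnaPerCell' must be positive")
  if (any(!is.finite(genomeSize)) || any(genomeSize <= 0))
    stop("'genomeSize' must be positive")
  dnaPerCell / genomeSize
}

#' Convert a DNA mass to base pairs
#'
#' DNA quantities in the trait table are carried in Mbp-equivalents; this
#' helper converts masses reported in femtograms using the standard
#' average molecular weight of double-stranded DNA, 1 pg = 978 Mbp.
#'
#' @param fg DNA mass in femtograms.
#' @return Mbp-equivalents (`fg * 0.978`).
#' @examples
#' fgToMbp(1000)  # one picogram = 978 Mbp
#' @export
fgToMbp <- function(fg) fg * 0.978

#' Read and complete a microbial trait table
#'
#' Reads a CSV/TSV table of per-taxon traits (cell volume or shape and
#' dimensions, ribosomal operons per genome, ploidy, ribosomal gene
#' copies per cell, genome size, cellular DNA content), validates it,
#' and performs the derivations used to assemble such datasets from the
#' literature:
#'
#' * range-valued cells (`"lo-hi"`, hyphen or en-dash) collapse to their
#'   arithmetic mean;
#' * a missing `volume_um3` is computed from `shape` + `dim1`/`dim2`
#'   (see [shapeVolume()]; composite shapes as a JSON descriptor in the
#'   `shape` column);
#' * a missing `ploidy` is derived as `dna_per_cell_mbp / genome_mbp`
#'   when both are present ([derivePloidy()]);
#' * a missing `rrn_per_cell` is derived as `ploidy * rrn_per_genome`
#'   when both are present ([deriveRc()]).
#'
#' Nothing else is imputed: a record missing `rrn_per_cell` with only one
#' of ploidy / operon number stays incomplete and is simply excluded from
#' fits that need it (see [completeCases()]).
#'
#' Recognized columns: `taxon_id`, `domain` (bacteria / archaea /
#' eukaryote), `shape`, `dim1`..`dim3` (um), `volume_um3`,
#' `rrn_per_genome`, `ploidy`, `rrn_per_cell`, `genome_mbp`,
#' `dna_per_cell_mbp`. Unknown columns are dropped with a warning.
#'
#' @param path path to the table.
#' @param dialect `"csv"` or `"tsv"`; by default inferred from the file
#'   extension (`.tsv`/`.tab`/`.txt` read as TSV).
#' @return a `data.frame` with the full canonical column set (missing
#'   fields `NA`), one validated row per input row.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("taxon_id,domain,volume_um3,ploidy,rrn_per_genome",
#'              "t1,bacteria,10-20,4,2"), tf)
#' loadTraitTable(tf)  # volume 15, rrn_per_cell 8
#' @seealso [writeTraitTable()], [filterTraits()], [fitPowerLaw()]
#' @export
loadTraitTable <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  raw <- utils::read.table(path, header = TRUE,
                           sep = if (dialect == "csv") "," else "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  unknown <- setdiff(names(raw), .traitColumns)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  n <- nrow(raw)
  out <- data.frame(matrix(nrow = n, ncol = length(.traitColumns),
                           dimnames = list(NULL, .traitColumns)))
  for (col in .traitColumns) {
    if (col %in% c("taxon_id", "domain", "shape")) {
      out[[col]] <- if (col %in% names(raw))
        vapply(raw[[col]], .parseShapeCell, character(1), USE.NAMES = FALSE)
      else rep(NA_character_, n)
    } else {
      out[[col]] <- if (col %in% names(raw))
        vapply(seq_len(n), function(i)
          .parseTraitCell(raw[[col]][i], i, col), numeric(1))
      else rep(NA_real_, n)
    }
  }
  if (all(is.na(out$taxon_id)))
    out$taxon_id <- sprintf("taxon_%03d", seq_len(n))
  bad <- !is.na(out$domain) & !(out$domain %in% .traitDomains)
  if (any(bad))
    stop("unknown domain label(s): ",
         paste(unique(out$domain[bad]), collapse = ", "),
         " (expected bacteria, archaea or eukaryote)")
  completeTraitTable(out)
}

#' Apply the standard trait derivations to a table in memory
#'
#' The derivation/validation step of [loadTraitTable()], exposed for
#' tables constructed programmatically: fills `volume_um3` from shape
#' descriptors, `ploidy` from DNA content and genome size, and
#' `rrn_per_cell` from ploidy and operon number, then checks invariants
#' (positive volumes and dimensions, `rrn_per_cell` consistent with
#' `ploidy * rrn_per_genome` to 1% when all three are present,
#' `dna_per_cell_mbp >= genome_mbp`).
#'
#' @param traits a data.frame using the canonical trait columns (missing
#'   columns are added as `NA`).
#' @return the completed, validated data.frame.
#' @export
completeTraitTable <- function(traits) {
  for (col in setdiff(.traitColumns, names(traits))) {
    traits[[col]] <- if (col %in% .traitNumericColumns) NA_real_
                     else NA_character_
  }
  traits <- traits[, .traitColumns]
  n <- nrow(traits)
  for (i in seq_len(n)) {
    if (is.na(traits$volume_um3[i]) && !is.na(traits$shape[i]))
      traits$volume_um3[i] <- .shapeToVolume(traits$shape[i],
                                             traits$dim1[i], traits$dim2[i])
    if (is.na(traits$ploidy[i]) && !is.na(traits$dna_per_cell_mbp[i]) &&
        !is.na(traits$genome_mbp[i]))
      traits$ploidy[i] <- derivePloidy(traits$dna_per_cell_mbp[i],
                                       traits$genome_mbp[i])
    if (is.na(traits$rrn_per_cell[i]) && !is.na(traits$ploidy[i]) &&
        !is.na(traits$rrn_per_genome[i]))
      traits$rrn_per_cell[i] <- deriveRc(traits$ploidy[i],
                                         traits$rrn_per_genome[i])
  }
  .validateTraitTable(traits)
  traits
}

.validateTraitTable <- function(traits) {
  for (i in seq_len(nrow(traits))) {
    v <- traits$volume_um3[i]
    if (!is.na(v) && v <= 0)
      stop(sprintf("row %d: cell volume must be positive (got %g)", i, v),
           call. = FALSE)
    for (col in c("dim1", "dim2", "dim3")) {
      d <- traits[[col]][i]
      if (!is.na(d) && d < 0)
        stop(sprintf("row %d: dimension '%s' must be non-negative", i, col),
             call. = FALSE)
    }
    rc <- traits$rrn_per_cell[i]
    p <- traits$ploidy[i]
    rg <- traits$rrn_per_genome[i]
    if (!is.na(rc) && !is.na(p) && !is.na(rg) &&
        abs(rc - p * rg) > 0.01 * p * rg)
      stop(sprintf(
        "row %d: rrn_per_cell (%g) disagrees with ploidy * rrn_per_genome (%g) by more than 1%%",
        i, rc, p * rg), call. = FALSE)
    dna <- traits$dna_per_cell_mbp[i]
    g <- traits$genome_mbp[i]
    if (!is.na(dna) && !is.na(g) && dna < g * (1 - 1e-9))
      stop(sprintf(
        "row %d: dna_per_cell_mbp (%g) is smaller than genome_mbp (%g)",
        i, dna, g), call. = FALSE)
  }
  invisible(traits)
}

#' Write a trait table
#'
#' Emits the canonical schema read by [loadTraitTable()], at full
#' precision so that load -> write -> load round-trips exactly.
#'
#' @param traits a canonical trait data.frame.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"` (default inferred from extension).
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(traits, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv"))
  for (col in setdiff(.traitColumns, names(traits))) {
    traits[[col]] <- if (col %in% .traitNumericColumns) NA_real_
                     else NA_character_
  }
  out <- traits[, .traitColumns]
  for (col in .traitNumericColumns)
    out[[col]] <- vapply(out[[col]], function(x)
      if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE),
      character(1))
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     quote = TRUE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Rows usable for a given power-law fit
#'
#' @param traits a canonical trait data.frame.
#' @param x,y column names of the predictor and response.
#' @return the subset of rows where both are present and positive.
#' @export
completeCases <- function(traits, x = "volume_um3", y = "rrn_per_cell") {
  keep <- !is.na(traits[[x]]) & !is.na(traits[[y]]) &
    traits[[x]] > 0 & traits[[y]] > 0
  traits[keep, , drop = FALSE]
}
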