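# Readers and writers.  One flat CSV dialect (comma, UTF-8, header row)
# for all tables; units are documented in column-name suffixes (receptor
# surface levels ship as *_thousand_per_cell and are converted to
# molecules/cell on load).  Writers can stamp a config hash as a comment
# header; readers skip comment lines.

writeCsvWithHash <- function(df, path, hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

readCsvChecked <- function(path, required, numericCols = character(0),
                           sep = ",") {
  if (!file.exists(path)) ltStop("io", paste("no such file:", path))
  df <- try(read.delim(path, sep = sep, comment.char = "#",
                       check.names = FALSE, stringsAsFactors = FALSE),
            silent = TRUE)
  if (inherits(df, "try-error") || nrow(df) == 0)
    ltStop("schema", paste("empty or unreadable table:", path))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    hint <- if (ncol(df) == 1)
      " (single column parsed; wrong delimiter?)" else ""
    ltStop("schema", paste0("missing column(s): ",
                            paste(miss, collapse = ", "), hint))
  }
  for (cl in intersect(numericCols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !anyNA(df[[cl]])) {
      bad <- which(is.na(v))[1]
      ltStop("schema", sprintf(
        "non-numeric value in column '%s' at data row %d", cl, bad))
    }
    df[[cl]] <- v
  }
  df
}

#' Construct a cell line panel
#'
#' @param df data.frame with columns `cell_line`, `kras_mutant`,
#'   `pik3ca_mutant` and receptor columns `EGFR`, `HER2`, `ErbB3`, `Met`,
#'   `IGF1R` in molecules/cell.
#' @return a [CellLinePanel-class].
#' @export
cellLinePanel <- function(df) {
  obj <- new("CellLinePanel", data = as.data.frame(df))
  validObject(obj)
  obj
}

#' Load the packaged 58-cell-line panel
#'
#' Reads the packaged machine-learning panel (58 cancer cell lines with
#' KRAS/PIK3CA mutation annotations and qFACS-scale receptor surface
#' levels in thousands per cell, converted to molecules/cell on load).
#' The panel does not print an IGF1R column; it is imputed, by default as
#' a constant at the scale of the printed ErbB3/Met columns, and flagged
#' in the `igf1r_imputed` column.
#'
#' @param path optional path to a panel TSV (defaults to the packaged
#'   table).
#' @param igf1rThousand constant imputation value for IGF1R, in thousand
#'   receptors per cell.
#' @param map optional [LinearMap-class] plus `mrna` data.frame
#'   (`cell_line`, `IGF1R` TPM) to impute IGF1R from expression instead.
#' @param mrna see `map`.
#' @return a [CellLinePanel-class].
#' @examples
#' panel <- loadCellLinePanel()
#' nrow(panel@data)  # 58
#' @export
loadCellLinePanel <- function(path = NULL, igf1rThousand = 30,
                              map = NULL, mrna = NULL) {
  path <- path %||% system.file("extdata", "cell_line_panel.tsv",
                                package = "ligandtree")
  need <- c("cell_line", "kras_mutation", "pik3ca_mutation",
            "egfr_thousand_per_cell", "her2_thousand_per_cell",
            "erbb3_thousand_per_cell", "met_thousand_per_cell")
  df <- readCsvChecked(path, need, numericCols = need[4:7], sep = "\t")
  isWt <- function(x) tolower(trimws(x)) %in% c("wt", "")
  out <- data.frame(
    cell_line = df$cell_line,
    kras_mutant = !isWt(df$kras_mutation),
    pik3ca_mutant = !isWt(df$pik3ca_mutation),
    EGFR = df$egfr_thousand_per_cell * 1e3,
    HER2 = df$her2_thousand_per_cell * 1e3,
    ErbB3 = df$erbb3_thousand_per_cell * 1e3,
    Met = df$met_thousand_per_cell * 1e3,
    stringsAsFactors = FALSE)
  if (!is.null(map) && !is.null(mrna)) {
    tpm <- mrna$IGF1R[match(out$cell_line, mrna$cell_line)]
    out$IGF1R <- predictSurface(map, "IGF1R", tpm)
    out$igf1r_imputed <- "linear_map"
  } else {
    out$IGF1R <- igf1rThousand * 1e3
    out$igf1r_imputed <- "constant"
  }
  cellLinePanel(out)
}

#' @describeIn cellLinePanel cell line names of a panel.
#' @param object a [CellLinePanel-class].
#' @export
setMethod("cellLines", "CellLinePanel", function(object) {
  object@data$cell_line
})

#' Coerce a panel to data.frame
#' @param x a [CellLinePanel-class].
#' @param ... ignored.
#' @return the underlying data.frame.
#' @export
setMethod("as.data.frame", "CellLinePanel", function(x, ...) x@data)

setMethod("show", "CellLinePanel", function(object) {
  df <- object@data
  cat("CellLinePanel with", nrow(df), "cell lines\n")
  cat("  KRAS mutant:  ", sum(df$kras_mutant), "\n")
  cat("  PIK3CA mutant:", sum(df$pik3ca_mutant), "\n")
  rng <- range(as.matrix(df[, RECEPTORS]))
  cat(sprintf("  receptor surface levels: %.3g - %.3g molecules/cell\n",
              rng[1], rng[2]))
})

#' Read / write a measurement set
#'
#' Flat CSV with columns `cell_line`, `observable`, `condition`,
#' `time_min`, `replicate`, `value`, `sigma` plus one `dose_<ligand>`
#' column per ligand appearing in any condition.
#'
#' @param path file path.
#' @param mset a [MeasurementSet-class] (for writing).
#' @param hash optional config hash comment.
#' @return a [MeasurementSet-class] (read) or the path (write,
#'   invisibly).
#' @export
readMeasurementSet <- function(path) {
  need <- c("cell_line", "observable", "condition", "time_min",
            "replicate", "value", "sigma")
  df <- readCsvChecked(path, need,
                       numericCols = c("time_min", "replicate", "value",
                                       "sigma"))
  doseCols <- grep("^dose_", names(df), value = TRUE)
  for (cl in doseCols) df[[cl]] <- as.numeric(df[[cl]])
  conds <- list()
  for (cond in unique(df$condition)) {
    row <- df[df$condition == cond, , drop = FALSE][1, ]
    doses <- unlist(row[doseCols])
    names(doses) <- sub("^dose_", "", doseCols)
    conds[[cond]] <- doses[doses > 0]
  }
  measurementSet(df[need], conds)
}

#' @rdname readMeasurementSet
#' @export
writeMeasurementSet <- function(mset, path, hash = NULL) {
  df <- mset@data
  ligs <- unique(unlist(lapply(mset@conditions, names)))
  for (lg in ligs) {
    df[[paste0("dose_", lg)]] <- vapply(df$condition, function(cn) {
      d <- mset@conditions[[cn]]
      if (lg %in% names(d)) unname(d[lg]) else 0
    }, 0)
  }
  writeCsvWithHash(df, path, hash)
}

#' Construct a measurement set
#'
#' @param data data.frame of tidy measurement records.
#' @param conditions named list mapping condition labels to named dose
#'   vectors (nM).
#' @return a [MeasurementSet-class].
#' @export
measurementSet <- function(data, conditions) {
  obj <- new("MeasurementSet", data = as.data.frame(data),
             conditions = conditions)
  validObject(obj)
  obj
}

setMethod("show", "MeasurementSet", function(object) {
  df <- object@data
  cat("MeasurementSet:", nrow(df), "records\n")
  cat("  cell lines: ", paste(unique(df$cell_line), collapse = ", "),
      "\n")
  cat("  observables:", length(unique(df$observable)), "\n")
  cat("  conditions: ", length(object@conditions), "\n")
})

#' Read a viability screen table
#'
#' CSV with columns `cell_line`, `treatment`, `day`, `replicate`,
#' `value` (luminescence, positive).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readViabilityTable <- function(path) {
  df <- readCsvChecked(path, c("cell_line", "treatment", "day",
                               "replicate", "value"),
                       numericCols = c("day", "replicate", "value"))
  if (any(df$value <= 0))
    ltStop("schema", "viability values must be > 0")
  df
}

#' Read a cohort expression table
#'
#' CSV of samples x genes in transcripts-per-million; first column
#' `sample`.
#'
#' @param path file path.
#' @param requiredGenes genes that must be present.
#' @return numeric matrix (samples x genes) with sample rownames.
#' @export
readExpressionTable <- function(path,
                                requiredGenes = c("EGFR", "ERBB2",
                                                  "ERBB3", "MET",
                                                  "IGF1R")) {
  df <- readCsvChecked(path, "sample")
  genes <- setdiff(names(df), "sample")
  miss <- setdiff(requiredGenes, genes)
  if (length(miss))
    ltStop("schema", paste("missing gene column(s):",
                           paste(miss, collapse = ", ")))
  m <- as.matrix(df[genes])
  mode(m) <- "numeric"
  rownames(m) <- df$sample
  if (any(!is.finite(m)) || any(m < 0))
    ltStop("schema", "expression values must be finite and >= 0")
  m
}
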