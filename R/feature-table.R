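#' Sample-by-feature abundance table with design metadata
#'
#' The central container of the package: a numeric samples x features matrix of
#' non-negative (or missing) abundances together with the design metadata of
#' every sample and a provenance log of the filters that have been applied.
#' One row is one tissue-sample (a plant contributes one aboveground and one
#' belowground sample).
#'
#' @param abundance numeric matrix, samples in rows, features in columns.
#'   Column names are feature identifiers and must be unique. Values must be
#'   non-negative or `NA`.
#' @param meta data.frame with one row per sample and at least the columns
#'   `sample_id`, `plant_id`, `genotype`, `tissue`, `regime`, `replicate`.
#' @param log list of provenance records appended by the filtering functions.
#' @return an object of class `feature_table`.
#' @examples
#' m <- matrix(runif(12, 1, 2), 4, 3, dimnames = list(NULL, c("F1", "F2", "F3")))
#' meta <- data.frame(sample_id = paste0("s", 1:4), plant_id = paste0("p", 1:4),
#'                    genotype = "G01", tissue = "aboveground",
#'                    regime = rep(c("control", "drought"), 2), replicate = 1:4)
#' ft <- feature_table(m, meta)
#' @export
feature_table <- function(abundance, meta, log = list()) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) stop("abundance must be numeric")
  meta <- as.data.frame(meta)
  required <- c("sample_id", "plant_id", "genotype", "tissue", "regime", "replicate")
  miss <- setdiff(required, names(meta))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(abundance))
    stop("metadata rows (", nrow(meta), ") do not match abundance rows (", nrow(abundance), ")")
  for (col in required)
    if (anyNA(meta[[col]])) stop("metadata factor '", col, "' has missing entries")
  if (anyDuplicated(meta$sample_id)) stop("sample identifiers are not unique")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("F%04d", seq_len(ncol(abundance)))
  if (anyDuplicated(colnames(abundance))) stop("feature identifiers are not unique")
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundances are not allowed")
  rownames(abundance) <- meta$sample_id
  structure(list(abundance = abundance, meta = meta, log = log),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$abundance), " samples x ", ncol(x$abundance),
      " features\n", sep = "")
  cat("  genotypes: ", length(unique(x$meta$genotype)),
      " | tissues: ", paste(unique(x$meta$tissue), collapse = "/"),
      " | regimes: ", paste(unique(x$meta$regime), collapse = "/"), "\n", sep = "")
  na_frac <- mean(is.na(x$abundance))
  cat(sprintf("  missing: %.2f%% | filters applied: %d\n",
              100 * na_frac, length(x$log)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' Provenance log of a feature table
#'
#' @param table a [feature_table()].
#' @return list of filter records (step name, parameters, counts).
#' @export
filter_log <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$log
}

# Cell-factor id per sample: genotype x regime x tissue.
ft_cells <- function(table) {
  interaction(table$meta$genotype, table$meta$regime, table$meta$tissue, drop = TRUE)
}

ft_append_log <- function(table, record) {
  table$log <- c(table$log, list(record))
  table
}

#' Write / read the feature-table CSV dialect
#'
#' The on-disk dialect has the metadata columns `plant_id, genotype, tissue,
#' regime, replicate` first, then one column per feature; missing values are
#' written as empty cells. Blank samples use the same feature columns with a
#' single `blank_id` column in place of the metadata.
#'
#' @param table a [feature_table()].
#' @param path file path.
#' @return `write_feature_csv` returns `path` invisibly; `read_feature_csv`
#'   returns a [feature_table()].
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$meta[c("plant_id", "genotype", "tissue", "regime", "replicate")],
              as.data.frame(table$abundance))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  metacols <- c("plant_id", "genotype", "tissue", "regime", "replicate")
  miss <- setdiff(metacols, names(df))
  if (length(miss)) stop("feature CSV is missing columns: ", paste(miss, collapse = ", "))
  meta <- df[metacols]
  meta$sample_id <- paste(meta$plant_id, substr(meta$tissue, 1, 2), sep = "_")
  ab <- as.matrix(df[setdiff(names(df), metacols)])
  storage.mode(ab) <- "double"
  feature_table(ab, meta)
}

#' @rdname write_feature_csv
#' @param blanks numeric matrix of blank samples (rows) by features (columns).
#' @export
write_blank_csv <- function(blanks, path) {
  df <- data.frame(blank_id = rownames(blanks) %||% paste0("blank", seq_len(nrow(blanks))),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(blanks))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_blank_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"blank_id" %in% names(df)) stop("blank CSV is missing the blank_id column")
  m <- as.matrix(df[setdiff(names(df), "blank_id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$blank_id
  m
}

#' Write / read the per-plant biomass CSV dialect
#'
#' Columns: `plant_id, genotype, regime, shoot_dw_g, root_dw_g` (dry weights
#' in grams).
#'
#' @param biomass data.frame in the biomass dialect.
#' @param path file path.
#' @export
write_biomass_csv <- function(biomass, path) {
  cols <- c("plant_id", "genotype", "regime", "shoot_dw_g", "root_dw_g")
  stopifnot(all(cols %in% names(biomass)))
  utils::write.csv(biomass[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomass_csv
#' @export
read_biomass_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("plant_id", "genotype", "regime", "shoot_dw_g", "root_dw_g")
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("biomass CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
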