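# tGCN tables and pool summary statistics ----------------------------------

#' Validate or construct a tGCN table
#'
#' A tGCN (tRNA gene copy number) table is a species x anticodon matrix of
#' non-negative integer gene copy counts. Columns are the 61 sense
#' anticodons (RNA alphabet, 5'->3', first base = position 34); anticodons
#' absent from the input are filled with zero so every table has all 61
#' columns in sorted order.
#'
#' @param x a numeric matrix or data.frame with species as rows and
#'   anticodon columns; row names (or a `species` column) identify species.
#' @param strict reject unknown (non-sense) anticodon columns with an error;
#'   if FALSE they are dropped with a warning.
#' @return integer matrix with 61 columns, class `tgcn_table`.
#' @export
tgcn_table <- function(x, strict = TRUE) {
  if (is.data.frame(x)) {
    if ("species" %in% names(x)) {
      rn <- as.character(x$species)
      x <- x[, setdiff(names(x), "species"), drop = FALSE]
      rownames(x) <- rn
    }
    x <- as.matrix(x)
  }
  if (is.null(rownames(x))) stop("species identifiers (row names) required",
                                 call. = FALSE)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate species identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  colnames(x) <- as_rna(colnames(x))
  universe <- sense_anticodons()
  unknown <- setdiff(colnames(x), universe)
  if (length(unknown)) {
    msg <- paste0("columns outside the 61 sense-anticodon universe: ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " (dropped)", call. = FALSE)
    x <- x[, setdiff(colnames(x), unknown), drop = FALSE]
  }
  storage <- suppressWarnings(as.numeric(x))
  if (anyNA(storage)) stop("non-numeric counts in tGCN table", call. = FALSE)
  if (any(storage < 0)) stop("negative counts in tGCN table", call. = FALSE)
  if (any(storage != round(storage))) {
    stop("non-integer counts in tGCN table", call. = FALSE)
  }
  full <- matrix(0L, nrow(x), length(universe),
                 dimnames = list(rownames(x), universe))
  full[, colnames(x)] <- as.integer(x)
  class(full) <- c("tgcn_table", class(full))
  full
}

#' Read a tGCN table from TSV
#'
#' Expects a tab-separated file whose first column is `species` and whose
#' remaining columns are anticodons (RNA or DNA alphabet).
#'
#' @param path file path.
#' @inheritParams tgcn_table
#' @return a `tgcn_table` matrix.
#' @export
load_tgcn_table <- function(path, strict = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) {
    stop("tGCN TSV must have a 'species' first column", call. = FALSE)
  }
  tgcn_table(df, strict = strict)
}

#' Write a tGCN table to TSV
#' @param x a `tgcn_table`.
#' @param path output file path.
#' @export
write_tgcn_table <- function(x, path) {
  df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool summary statistics for one species
#'
#' `total_tgcn()` is the total number of tRNA genes (sum of copy counts over
#' anticodons). `trna_diversity()` is the number of distinct anticodons
#' represented (nonzero counts; at most 61).
#' `diversity_by_third_position()` splits the diversity by the third base of
#' each present anticodon's Watson-Crick codon: `gc_ending` counts
#' anticodons whose codon ends in G or C (equivalently anticodon position
#' 34 is C or G), `at_ending` the rest.
#'
#' @param row named numeric vector of counts (names = anticodons), e.g. one
#'   row of a `tgcn_table`.
#' @return `total_tgcn`, `trna_diversity`: a single integer;
#'   `diversity_by_third_position`: named integer vector
#'   `c(gc_ending = , at_ending = )`.
#' @export
total_tgcn <- function(row) as.integer(sum(row))

#' @rdname total_tgcn
#' @export
trna_diversity <- function(row) as.integer(sum(row > 0))

#' @rdname total_tgcn
#' @export
diversity_by_third_position <- function(row) {
  present <- names(row)[row > 0]
  gc34 <- substr(present, 1L, 1L) %in% c("C", "G")
  c(gc_ending = sum(gc34), at_ending = sum(!gc34))
}

#' Pool summaries for every species in a table
#'
#' @param tgcn a `tgcn_table`.
#' @return data.frame with columns `species`, `total_tgcn`, `diversity`,
#'   `gc_ending_diversity`, `at_ending_diversity`.
#' @export
pool_summary <- function(tgcn) {
  gc34 <- substr(colnames(tgcn), 1L, 1L) %in% c("C", "G")
  data.frame(
    species = rownames(tgcn),
    total_tgcn = as.integer(rowSums(tgcn)),
    diversity = as.integer(rowSums(tgcn > 0)),
    gc_ending_diversity = as.integer(rowSums(tgcn[, gc34, drop = FALSE] > 0)),
    at_ending_diversity = as.integer(rowSums(tgcn[, !gc34, drop = FALSE] > 0)),
    row.names = NULL
  )
}

#' Classify optimal growth temperature into thermal classes
#'
#' Psychrophiles prefer temperatures below 15 degrees C, thermophiles above
#' 45 degrees C, and mesophiles the interval between; the boundaries 15 and
#' 45 are assigned to mesophile.
#'
#' @param temp numeric vector of optimal growth temperatures (degrees C).
#' @return character vector in
#'   `{"psychrophile", "mesophile", "thermophile"}`.
#' @export
classify_temperature <- function(temp) {
  if (any(!is.finite(temp))) {
    stop("non-finite optimal growth temperature", call. = FALSE)
  }
  ifelse(temp < 15, "psychrophile",
         ifelse(temp > 45, "thermophile", "mesophile"))
}

TEMP_CLASSES <- c("mesophile", "psychrophile", "thermophile")

#' Read species metadata from TSV
#'
#' Expects columns `species`, `gc` and at least one of
#' `optimal_growth_temp`, `temp_class`. GC values are fractions in `[0, 1]`;
#' percent-scale inputs (values above 1.5) are detected and rescaled with a
#' warning. Missing `temp_class` values are derived from
#' `optimal_growth_temp` via [classify_temperature()].
#'
#' @param path file path.
#' @return data.frame with columns `species`, `gc`, `optimal_growth_temp`
#'   (possibly NA) and `temp_class`.
#' @export
load_species_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  species_metadata(df)
}

#' @rdname load_species_metadata
#' @param df data.frame with the columns described above.
#' @export
species_metadata <- function(df) {
  if (!all(c("species", "gc") %in% names(df))) {
    stop("metadata requires 'species' and 'gc' columns", call. = FALSE)
  }
  if (anyDuplicated(df$species)) stop("duplicate species in metadata",
                                      call. = FALSE)
  gc <- as.numeric(df$gc)
  if (any(gc > 1.5, na.rm = TRUE)) {
    warning("gc appears to be on a percent scale; dividing by 100",
            call. = FALSE)
    gc <- gc / 100
  }
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
    stop("gc must be a fraction in [0, 1]", call. = FALSE)
  }
  df$gc <- gc
  if (!"optimal_growth_temp" %in% names(df)) df$optimal_growth_temp <- NA_real_
  if (!"temp_class" %in% names(df)) df$temp_class <- NA_character_
  need <- is.na(df$temp_class) | df$temp_class == ""
  if (any(need)) {
    if (any(is.na(df$optimal_growth_temp[need]))) {
      stop("species without temp_class or optimal_growth_temp: ",
           paste(utils::head(df$species[need & is.na(df$optimal_growth_temp)],
                             5L), collapse = ", "), call. = FALSE)
    }
    df$temp_class[need] <- classify_temperature(df$optimal_growth_temp[need])
  }
  bad <- !df$temp_class %in% TEMP_CLASSES
  if (any(bad)) {
    stop("unknown temp_class label(s): ",
         paste(unique(df$temp_class[bad]), collapse = ", "), call. = FALSE)
  }
  df[, c("species", "gc", "optimal_growth_temp", "temp_class")]
}
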