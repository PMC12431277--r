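#' Read and validate a long-format phenotype table
#'
#' Reads a CSV of mineral phenotypes in long format — one row per
#' (genotype, generation, female parent, male parent, year, replicate,
#' trait, value) — validates it against the Design II contract, and returns
#' a normalised tibble. Columns may be renamed through `schema`, a named
#' character vector mapping the canonical names to the names found in the
#' file, e.g. `c(genotype = "ID", value = "conc")`.
#'
#' Validation enforces: the nine-mineral trait vocabulary (see
#' [mineral_traits()]); hybrids carry both parent ids and every named parent
#' exists as a `parent` row; parents carry no parent ids; the
#' (genotype, year, rep, trait) key is unique; values are finite and
#' nonnegative.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`genotype`, `generation`, `female`, `male`, `year`, `rep`,
#'   `trait`, `value`) to the column names used in the file.
#' @return A validated tibble with the canonical columns.
#' @export
read_phenotype_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_phenotype_table(raw, schema = schema)
}

#' Read a phenotype table from a spreadsheet sheet
#'
#' Ingestion path for supplementary-style XLSX files: reads one sheet and
#' passes it through the same column-map normalisation and validation as
#' [read_phenotype_table()]. Requires the `readxl` package.
#'
#' @inheritParams read_phenotype_table
#' @param sheet Sheet name or index passed to `readxl::read_excel()`.
#' @export
read_phenotype_xlsx <- function(path, schema = NULL, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("the 'readxl' package is required for xlsx input", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readxl::read_excel(path, sheet = sheet)
  as_phenotype_table(raw, schema = schema)
}

#' Coerce a data frame to a validated phenotype table
#'
#' @param data A data frame with the phenotype columns (possibly under
#'   different names, see `schema`).
#' @inheritParams read_phenotype_table
#' @return A validated tibble with columns `genotype`, `generation`,
#'   `female`, `male`, `year`, `rep`, `trait`, `value`.
#' @export
as_phenotype_table <- function(data, schema = NULL) {
  canonical <- c("genotype", "generation", "female", "male", "year", "rep",
                 "trait", "value")
  data <- tibble::as_tibble(data)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || !all(names(schema) %in% canonical)) {
      stop("`schema` must be a named vector keyed by canonical column names",
           call. = FALSE)
    }
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(data)) {
        stop("schema error: column '", src, "' not found in input",
             call. = FALSE)
      }
      names(data)[names(data) == src] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[canonical]
  if (!is.numeric(data$value)) {
    val <- suppressWarnings(as.numeric(data$value))
    bad <- which(is.na(val) & !is.na(data$value))
    if (length(bad)) {
      stop("parse error: non-numeric value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    data$value <- val
  }
  data$genotype <- as.character(data$genotype)
  data$generation <- as.character(data$generation)
  data$female <- as.character(data$female)
  data$male <- as.character(data$male)
  data$trait <- as.character(data$trait)
  validate_phenotype_table(data)
}

#' Validate the phenotype-table invariants
#'
#' @param data A tibble with the canonical phenotype columns.
#' @return `data`, invisibly unchanged, if all invariants hold; otherwise an
#'   error describing the first violation.
#' @export
validate_phenotype_table <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(data$generation %in% c("parent", "hybrid"))) {
    stop("generation must be 'parent' or 'hybrid'", call. = FALSE)
  }
  bad_trait <- setdiff(unique(data$trait), .trait_vocab)
  if (length(bad_trait)) {
    stop("unknown trait(s): ", paste(bad_trait, collapse = ", "),
         "; expected one of ", paste(.trait_vocab, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    stop("values must be finite (no missing values)", call. = FALSE)
  }
  if (any(data$value < 0)) {
    stop("domain error: negative concentration value(s)", call. = FALSE)
  }
  hyb <- data[data$generation == "hybrid", ]
  par <- data[data$generation == "parent", ]
  if (any(is.na(hyb$female) | is.na(hyb$male))) {
    stop("hybrids must have both parents recorded", call. = FALSE)
  }
  if (any(!is.na(par$female) | !is.na(par$male))) {
    stop("parents must have empty parent fields", call. = FALSE)
  }
  if (nrow(par)) {
    # referential integrity only checkable when parent rows are present;
    # hybrid-only tables (combining-ability fits) skip it
    unknown <- setdiff(unique(c(hyb$female, hyb$male)), unique(par$genotype))
    if (length(unknown)) {
      stop("referential error: hybrid parent(s) not in the parent set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(data$genotype, data$year, data$rep, data$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, year, rep, trait) key(s)", call. = FALSE)
  }
  data
}

#' Write a phenotype table to CSV
#'
#' Inverse of [read_phenotype_table()]; the written file round-trips through
#' the reader bit-identically on normalised tables.
#'
#' @param data A validated phenotype table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(data, path) {
  data <- validate_phenotype_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Infer the mating design from hybrid parentage
#'
#' Reads the female and male parent sets and the realised cross subset off a
#' validated phenotype table. A line appearing both as a female and as a
#' male parent violates the Design II factorial structure and is an error.
#'
#' @param data A validated phenotype table containing hybrid rows.
#' @return An object of class `mating_design`: a list with `females`,
#'   `males` (character vectors) and `crosses` (tibble with columns
#'   `female`, `male`), plus per-parent cross counts in `counts`.
#' @export
validate_design <- function(data) {
  data <- validate_phenotype_table(data)
  hyb <- dplyr::distinct(
    data[data$generation == "hybrid", ], .data$female, .data$male
  )
  if (!nrow(hyb)) stop("no hybrid rows: cannot infer a design", call. = FALSE)
  females <- sort(unique(hyb$female))
  males <- sort(unique(hyb$male))
  both <- intersect(females, males)
  if (length(both)) {
    stop("design error: line(s) used as both female and male: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  new_mating_design(females, males, hyb[order(hyb$female, hyb$male), ])
}

new_mating_design <- function(females, males, crosses) {
  crosses <- tibble::as_tibble(crosses)[c("female", "male")]
  if (anyDuplicated(paste(crosses$female, crosses$male))) {
    stop("duplicate cross in design", call. = FALSE)
  }
  counts <- dplyr::bind_rows(
    dplyr::count(crosses, parent = .data$female, name = "n_crosses"),
    dplyr::count(crosses, parent = .data$male, name = "n_crosses")
  )
  structure(
    list(females = females, males = males, crosses = crosses, counts = counts),
    class = "mating_design"
  )
}

#' @export
print.mating_design <- function(x, ...) {
  cat(sprintf(
    "North Carolina Design II: %d females x %d males, %d of %d crosses realised\n",
    length(x$females), length(x$males), nrow(x$crosses),
    length(x$females) * length(x$males)
  ))
  invisible(x)
}
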