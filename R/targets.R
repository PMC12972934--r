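#' Read a target gene list from disk
#'
#' Ingests a drug- or disease-target gene list as exported by hand from a
#' target-prediction or disease-gene database. Plain-text files are read one
#' symbol per line; CSV/TSV files require `column` naming the symbol column.
#' Symbols are whitespace-trimmed and uppercased, empty lines and
#' `#`-prefixed comment lines are skipped, and duplicates are removed, so the
#' result is a clean set of unique gene symbols.
#'
#' @param path Path to the list file (`.txt`, `.csv` or `.tsv`/`.tab`).
#' @param source_name Short label for the list's origin, e.g. `"SDSS"` or
#'   `"GeneCards"`. Defaults to the file name without extension.
#' @param column For CSV/TSV input, the name of the column holding gene
#'   symbols. Ignored for plain-text input.
#' @return A `target_list` object: a list with `source_name`, `symbols`
#'   (character vector, unique, uppercase), `n_raw` (rows/lines read before
#'   cleaning) and `n_unique`.
#' @export
read_target_list <- function(path, source_name = NULL, column = NULL) {
  if (!file.exists(path)) {
    stop("target list file not found: ", path, call. = FALSE)
  }
  if (is.null(source_name)) {
    source_name <- tools::file_path_sans_ext(basename(path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "tab", "txt") && !is.null(column)) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "#",
                            check.names = FALSE, quote = "\"")
    if (!column %in% names(df)) {
      stop("column '", column, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")",
           call. = FALSE)
    }
    raw <- as.character(df[[column]])
  } else {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[!grepl("^\\s*#", raw)]
  }
  n_raw <- length(raw)
  symbols <- normalize_symbols(raw)
  if (length(symbols) == 0L) {
    stop("no usable symbols in ", path, " after cleaning", call. = FALSE)
  }
  new_target_list(source_name, symbols, n_raw = n_raw)
}

#' Construct a target list from a character vector of symbols
#'
#' @param symbols Character vector of gene symbols (any case, possibly
#'   duplicated or padded with whitespace).
#' @param source_name Label for the list.
#' @return A `target_list` object.
#' @export
target_list <- function(symbols, source_name = "unnamed") {
  n_raw <- length(symbols)
  symbols <- normalize_symbols(symbols)
  new_target_list(source_name, symbols, n_raw = n_raw)
}

normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[nzchar(x)]
  sort(unique(x))
}

new_target_list <- function(source_name, symbols, n_raw = length(symbols)) {
  structure(
    list(source_name = source_name, symbols = symbols,
         n_raw = n_raw, n_unique = length(symbols)),
    class = "target_list"
  )
}

#' @export
print.target_list <- function(x, ...) {
  cat("<target_list> ", x$source_name, ": ", x$n_unique,
      " unique symbols (", x$n_raw, " raw entries)\n", sep = "")
  invisible(x)
}

#' Union of target lists
#'
#' Pools two or more target lists into one deduplicated list, the way
#' disease-target lists from several databases are merged before
#' intersection with a drug-target list.
#'
#' @param ... `target_list` objects, or a single list of them.
#' @return A `target_list` whose symbol set is the union and whose
#'   `source_name` concatenates the inputs with `"+"`.
#' @export
union_targets <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && !inherits(lists[[1]], "target_list")) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0L) stop("no target lists supplied", call. = FALSE)
  stopifnot(all(vapply(lists, inherits, logical(1), "target_list")))
  symbols <- sort(unique(unlist(lapply(lists, `[[`, "symbols"))))
  name <- paste(vapply(lists, `[[`, character(1), "source_name"),
                collapse = "+")
  new_target_list(name, symbols, n_raw = sum(vapply(lists, `[[`,
                                                    numeric(1), "n_raw")))
}

#' Intersect drug and disease target lists
#'
#' The Venn stage of the pipeline: the shared symbols between a compound's
#' predicted targets and a disease's associated genes are the candidate
#' targets carried into network analysis.
#'
#' @param drug,disease `target_list` objects.
#' @return An `intersection_result`: list with `drug_count`, `disease_count`,
#'   `shared` (sorted character vector), `shared_count`, and the two source
#'   names.
#' @export
intersect_targets <- function(drug, disease) {
  stopifnot(inherits(drug, "target_list"), inherits(disease, "target_list"))
  if (drug$n_unique == 0L || disease$n_unique == 0L) {
    stop("both target lists must be non-empty", call. = FALSE)
  }
  shared <- sort(intersect(drug$symbols, disease$symbols))
  structure(
    list(drug_source = drug$source_name, disease_source = disease$source_name,
         drug_count = drug$n_unique, disease_count = disease$n_unique,
         shared = shared, shared_count = length(shared)),
    class = "intersection_result"
  )
}

#' @export
print.intersection_result <- function(x, ...) {
  cat("<intersection_result> ", x$drug_source, " (", x$drug_count, ") x ",
      x$disease_source, " (", x$disease_count, "): ",
      x$shared_count, " shared targets\n", sep = "")
  invisible(x)
}

#' Write a Venn summary of an intersection
#'
#' Writes a one-row-per-set CSV with total, exclusive and shared counts,
#' plus the shared-target list as plain text next to it.
#'
#' @param result An `intersection_result`.
#' @param path Output CSV path. The shared-symbol list is written alongside
#'   with suffix `_shared.txt`.
#' @return Invisibly, the summary data frame.
#' @export
write_venn_summary <- function(result, path) {
  stopifnot(inherits(result, "intersection_result"))
  df <- data.frame(
    set = c(result$drug_source, result$disease_source),
    size = c(result$drug_count, result$disease_count),
    exclusive = c(result$drug_count - result$shared_count,
                  result$disease_count - result$shared_count),
    shared = result$shared_count,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  shared_path <- sub("\\.csv$", "_shared.txt", path)
  if (identical(shared_path, path)) shared_path <- paste0(path, "_shared.txt")
  writeLines(result$shared, shared_path)
  invisible(df)
}
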