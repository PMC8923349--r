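#' Construct and validate a species trait table
#'
#' A trait table is a `data.frame` (class `trait_table`) with one row per
#' species carrying the optimal growth temperature and per-genome defence
#' abundance counts. It is the x/y material of every downstream analysis.
#'
#' Required columns: `species_id` (unique), `topt_c` (numeric, within
#' `topt_range`) and at least one abundance measure among
#' `arrays`, `spacers`, `cas_genes`, `cas_clusters`, `rm_genes`
#' (non-negative integers; `NA` allowed and distinguished from an annotated
#' zero). Optional columns: `domain` (`"Bacteria"`/`"Archaea"`),
#' `isolation_sources` (semicolon-separated labels), `topt_raw` (pre-rounding
#' provenance, written by [round_topt()]).
#'
#' @param df data.frame with the columns above.
#' @param topt_range numeric length-2; declared validity range for `topt_c`
#'   in degrees Celsius. Default `c(0, 110)`.
#' @return `df` with class `trait_table` and attributes `measures` (the
#'   abundance columns present) and `topt_range`.
#' @examples
#' tt <- trait_table(data.frame(
#'   species_id = c("a", "b"), topt_c = c(30, 55), arrays = c(0L, 4L)))
#' attr(tt, "measures")
#' @export
trait_table <- function(df, topt_range = c(0, 110)) {
  if (!is.data.frame(df)) stop_ct("trait table input must be a data.frame")
  need <- c("species_id", "topt_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ct("missing required column(s): %s", paste(miss, collapse = ", "))
  measures <- intersect(MEASURE_COLS, names(df))
  if (!length(measures)) {
    stop_ct("no abundance column found (expected one of: %s)",
            paste(MEASURE_COLS, collapse = ", "))
  }
  df$species_id <- as.character(df$species_id)
  dup <- unique(df$species_id[duplicated(df$species_id)])
  if (length(dup)) stop_ct("duplicate species_id: %s", paste(dup, collapse = ", "))
  if (!is.numeric(df$topt_c)) stop_ct("topt_c must be numeric")
  bad <- which(!is.na(df$topt_c) &
                 (df$topt_c < topt_range[1] | df$topt_c > topt_range[2]))
  if (length(bad)) {
    stop_ct("topt_c outside validity range [%g, %g] for: %s", topt_range[1],
            topt_range[2], paste(df$species_id[bad], collapse = ", "))
  }
  for (m in measures) {
    v <- df[[m]]
    if (!is.numeric(v)) stop_ct("abundance column '%s' must be numeric", m)
    ok <- is.na(v) | (v >= 0 & v == floor(v))
    if (!all(ok)) {
      stop_ct("abundance column '%s' has negative or non-integral values (rows %s)",
              m, paste(which(!ok), collapse = ", "))
    }
  }
  if ("domain" %in% names(df)) {
    df$domain <- as.character(df$domain)
    okd <- is.na(df$domain) | df$domain %in% c("Bacteria", "Archaea")
    if (!all(okd)) stop_ct("domain must be 'Bacteria' or 'Archaea'")
  }
  structure(df, class = c("trait_table", "data.frame"),
            measures = measures, topt_range = topt_range)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d species; measures: %s\n", nrow(x),
              paste(attr(x, "measures"), collapse = ", ")))
  if (nrow(x)) {
    cat(sprintf("  Topt range: %g-%g degC\n", min(x$topt_c, na.rm = TRUE),
                max(x$topt_c, na.rm = TRUE)))
  }
  NextMethod()
}

# re-validate after row subsetting while keeping attributes
restore_trait_table <- function(df, template) {
  trait_table(as.data.frame(df), topt_range = attr(template, "topt_range") %||% c(0, 110))
}

#' Read a trait table from delimited text
#'
#' Reads a TSV (default) or CSV file with a header row, renames columns to
#' the canonical schema through `column_map`, and validates the result.
#' Rows whose Topt is missing or unparseable, and rows where every abundance
#' column is missing, are dropped; the counts are reported in a message and
#' attached as attribute `dropped`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`species_id`, `topt_c`, `arrays`, ...) to the file's column names.
#'   Unmapped canonical names are taken verbatim when present in the file.
#' @param sep field separator; `NULL` (default) chooses `","` for `.csv`
#'   paths and tab otherwise.
#' @param topt_range passed to [trait_table()].
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, column_map = NULL, sep = NULL,
                             topt_range = c(0, 110)) {
  if (!file.exists(path)) stop_ct("file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop_ct("column_map must be a fully named character vector")
    }
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) stop_ct("mapped column '%s' (for '%s') absent from %s",
                                        src, canon, path)
      names(raw)[names(raw) == src] <- canon
    }
  }
  need <- c("species_id", "topt_c")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_ct("missing required column(s): %s", paste(miss, collapse = ", "))

  topt_num <- suppressWarnings(as.numeric(raw$topt_c))
  n_parse <- sum(is.na(topt_num) & !is.na(raw$topt_c) &
                   !(trimws(as.character(raw$topt_c)) %in% c("", "NA")))
  raw$topt_c <- topt_num
  measures <- intersect(MEASURE_COLS, names(raw))
  if (!length(measures)) {
    stop_ct("no abundance column found in %s (expected one of: %s)", path,
            paste(MEASURE_COLS, collapse = ", "))
  }
  for (m in measures) raw[[m]] <- suppressWarnings(as.numeric(raw[[m]]))

  no_topt <- is.na(raw$topt_c)
  no_abund <- rowSums(!is.na(as.matrix(raw[measures]))) == 0
  drop <- no_topt | no_abund
  if (any(drop)) {
    message(sprintf("read_trait_table: dropped %d row(s) (%d missing/unparseable Topt, %d with all abundances missing)",
                    sum(drop), sum(no_topt), sum(no_abund & !no_topt)))
  }
  tt <- trait_table(raw[!drop, , drop = FALSE], topt_range = topt_range)
  attr(tt, "dropped") <- list(n = sum(drop), missing_topt = sum(no_topt),
                              parse_errors = n_parse,
                              all_abundance_missing = sum(no_abund & !no_topt))
  tt
}

#' Write a trait table as TSV
#'
#' @param table a [trait_table()].
#' @param path output file path.
#' @export
write_trait_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Round optimal growth temperatures to integers
#'
#' Replaces `topt_c` by its nearest integer, rounding half-values away from
#' zero (so 36.5 becomes 37). The unrounded values are kept in a `topt_raw`
#' column so the choice is auditable; if `topt_raw` already exists the call
#' is a no-op on it (rounding is idempotent).
#'
#' @param table a [trait_table()].
#' @return the table with integer `topt_c` and provenance `topt_raw`.
#' @export
round_topt <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  if (!"topt_raw" %in% names(table)) table$topt_raw <- table$topt_c
  table$topt_c <- round_half_away(table$topt_c)
  restore_trait_table(table, table)
}
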