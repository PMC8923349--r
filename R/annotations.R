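#' Reduce CRISPR annotation records to per-species abundances
#'
#' Array annotations come with an evidence level from 1 (weak) to 4 (strong).
#' Only levels 3 and 4 are trusted: a species' array abundance is the number
#' of its level-3/4 records and its spacer abundance the sum of their spacer
#' counts. Level-1/2 records contribute zero, so a species whose records are
#' all low-evidence gets abundance 0 (not `NA`).
#'
#' @param records data.frame with columns `species_id`, `evidence_level`
#'   (integer 1-4) and optionally `spacer_count` (non-negative integer;
#'   required for the spacer abundance).
#' @return data.frame with one row per species present in `records`:
#'   `species_id`, `arrays`, `spacers`, sorted by `species_id`.
#' @examples
#' rec <- data.frame(species_id = "s1", evidence_level = c(1, 2, 3, 4, 4),
#'                   spacer_count = c(9, 9, 10, 5, 5))
#' abundance_from_annotations(rec)  # arrays 3, spacers 20
#' @export
abundance_from_annotations <- function(records) {
  if (!is.data.frame(records)) stop_ct("records must be a data.frame")
  need <- c("species_id", "evidence_level")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_ct("records missing column(s): %s", paste(miss, collapse = ", "))
  if (!"spacer_count" %in% names(records)) records$spacer_count <- 0
  ev <- records$evidence_level
  if (length(ev) && (any(is.na(ev)) || any(!ev %in% 1:4))) {
    stop_ct("evidence_level must be in 1..4")
  }
  sc <- records$spacer_count
  if (length(sc) && (any(is.na(sc)) || any(sc < 0))) {
    stop_ct("spacer_count must be non-negative")
  }
  sp <- sort(unique(as.character(records$species_id)))
  keep <- ev %in% c(3, 4)
  arrays <- vapply(sp, function(s)
    sum(keep & records$species_id == s), integer(1))
  spacers <- vapply(sp, function(s)
    as.integer(sum(sc[keep & records$species_id == s])), integer(1))
  data.frame(species_id = sp, arrays = unname(arrays), spacers = unname(spacers),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read annotation records from TSV
#'
#' Expects columns `species_id`, `evidence_level`, `spacer_count`.
#'
#' @param path file path.
#' @return validated data.frame of annotation records.
#' @export
read_annotation_records <- function(path) {
  rec <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("species_id", "evidence_level", "spacer_count")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop_ct("annotation file missing column(s): %s",
                            paste(miss, collapse = ", "))
  if (any(!rec$evidence_level %in% 1:4)) stop_ct("evidence_level must be in 1..4")
  rec
}

#' Merge optimal-growth-temperature sources by precedence
#'
#' Temperature records come from several databases of unequal reliability.
#' Each source carries an integer rank (1 = most trusted); for a species
#' present in several sources the value from the best-ranked source wins.
#' Species absent from every source are absent from the output.
#'
#' @param sources list of sources, each a list with elements `source_name`
#'   (string), `rank` (integer, unique across `sources`) and `records`
#'   (named numeric vector, names are species ids, values Topt in degC).
#' @return named numeric vector of Topt keyed by species id, together with
#'   attribute `source` giving the winning source name per species.
#' @export
merge_topt_sources <- function(sources) {
  if (!length(sources)) stop_ct("no Topt sources supplied")
  ranks <- vapply(sources, function(s) as.integer(s$rank), integer(1))
  if (anyDuplicated(ranks)) stop_ct("source ranks must be unique")
  ord <- order(ranks)
  out <- numeric(0)
  src <- character(0)
  for (s in sources[ord]) {
    rec <- s$records
    if (is.null(names(rec))) stop_ct("source '%s' has unnamed records", s$source_name)
    new <- setdiff(names(rec), names(out))
    out[new] <- rec[new]
    src[new] <- s$source_name %||% paste0("rank", s$rank)
  }
  attr(out, "source") <- src
  out
}
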