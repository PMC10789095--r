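# Typed TSV ingestion behind named schemas.

SCHEMAS <- list(
  dosage = list(
    gene_id = "c", pli = "d", loeuf = "d", phaplo = "d", ptriplo = "d"),
  variants = list(
    gene_id = "c", transcript_id = "c", cdna_pos = "i", ref = "c", alt = "c",
    consequence = "c", clinical_significance = "c", review_stars = "i",
    has_conflicts = "l"),
  cnv = list(
    gene_id = "c", consequence = "c", clinical_significance = "c",
    review_stars = "i", has_conflicts = "l"),
  regions = list(
    protein_id = "c", start = "i", end = "i", label = "c", source = "c"),
  protein_labels = list(id = "c", class = "c", split = "c"),
  scores = list(id = "c", score = "d")
)

#' Table schemas known to the toolkit
#'
#' @param name One of `"dosage"`, `"variants"`, `"cnv"`, `"regions"`,
#'   `"protein_labels"`, `"scores"`.
#' @return A schema object (name plus required columns and their types).
#' @export
ps_schema <- function(name) {
  if (!name %in% names(SCHEMAS)) {
    abort_ps(sprintf("unknown schema '%s' (known: %s)", name,
                     paste(names(SCHEMAS), collapse = ", ")),
             "psdosage_validation_error")
  }
  structure(list(name = name, columns = SCHEMAS[[name]]),
            class = "ps_schema")
}

#' Read a tab-separated table against a schema
#'
#' Required columns are type-checked and coerced; absent required columns
#' raise a schema error listing every missing name. Extra columns are
#' preserved verbatim. Missing numeric cells (`NA`, empty) stay `NA` - they
#' are never silently turned into zeros.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema A [ps_schema()] object or schema name.
#' @return Tibble with required columns typed per the schema.
#' @export
read_ps_tsv <- function(path, schema) {
  if (is.character(schema)) schema <- ps_schema(schema)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(names(schema$columns), names(raw))
  if (length(missing_cols) > 0) {
    abort_ps(sprintf("table %s does not match schema '%s': missing column(s) %s",
                     path, schema$name, paste(missing_cols, collapse = ", ")),
             "psdosage_schema_error")
  }
  for (col in names(schema$columns)) {
    raw[[col]] <- suppressWarnings(switch(schema$columns[[col]],
      c = raw[[col]],
      i = as.integer(raw[[col]]),
      d = as.numeric(ifelse(raw[[col]] %in% c("NA", ""), NA, raw[[col]])),
      l = as.logical(ifelse(toupper(raw[[col]]) %in% c("TRUE", "T", "1"), TRUE,
                     ifelse(toupper(raw[[col]]) %in% c("FALSE", "F", "0"),
                            FALSE, NA)))
    ))
  }
  raw
}

#' Write a tibble as TSV (atomically)
#'
#' @param data Data frame.
#' @param path Output path.
#' @export
write_ps_tsv <- function(data, path) {
  write_atomic(path, function(tmp) {
    readr::write_tsv(data, tmp, progress = FALSE)
  })
}
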