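# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even). Tables in
# reports are displayed with this rule.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent format error: file, row (optional), reason.
format_error <- function(path, reason, row = NULL) {
  where <- if (is.null(row)) basename(path) else sprintf("%s, row %d", basename(path), row)
  stop(sprintf("format error in %s: %s", where, reason), call. = FALSE)
}

# Collapse a character vector to a stable comma string ("" when empty).
collapse_csv <- function(x) {
  if (length(x) == 0) "" else paste(sort(unique(x)), collapse = ",")
}

split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

# Empty DomainHit table: the common record type all domain evidence is
# normalized to. Coordinates are 1-based inclusive throughout the package.
empty_domain_hits <- function() {
  data.frame(
    protein_id = character(0), source = character(0),
    domain_accession = character(0), domain_name = character(0),
    evalue = numeric(0), score = numeric(0),
    ali_start = integer(0), ali_end = integer(0),
    significant = logical(0), evalue_missing = logical(0),
    relaxed = logical(0),
    stringsAsFactors = FALSE
  )
}

as_domain_hits <- function(df) {
  n <- nrow(df)
  defaults <- list(score = NA_real_, significant = FALSE,
                   evalue_missing = FALSE, relaxed = FALSE)
  for (col in names(defaults)) {
    if (is.null(df[[col]])) df[[col]] <- rep(defaults[[col]], n)
  }
  rownames(df) <- NULL
  df[, names(empty_domain_hits()), drop = FALSE]
}
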