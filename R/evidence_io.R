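# Readers and writers for the evidence file formats the pipeline consumes.
# All coordinates are 1-based inclusive, matching both the BLAST tabular and
# the profile-HMM per-domain dialects; no other module converts coordinates.

#' Read a predicted proteome from FASTA
#'
#' Parses an amino-acid FASTA file into one record per header. The protein
#' id is the first whitespace-delimited token of the header line. Duplicate
#' ids are a hard error because every downstream join keys on `protein_id`.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `protein_id`, `sequence` and `length`
#'   (residue count), one row per record. An empty file yields zero rows.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKTAYIAK", ">p2", "MSHAQKYF"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  empty <- data.frame(protein_id = character(0), sequence = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) return(empty)
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    format_error(path, "expected a FASTA header line starting with '>'", row = first)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    format_error(path, "empty FASTA header")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    format_error(path, paste0("duplicate protein id(s): ", paste(dup, collapse = ", ")))
  }
  seq_chr <- as.character(seqs)
  if (any(nchar(seq_chr) == 0)) {
    format_error(path, paste0("zero-length sequence for: ",
                              paste(ids[nchar(seq_chr) == 0], collapse = ", ")))
  }
  data.frame(protein_id = ids, sequence = unname(seq_chr),
             length = unname(nchar(seq_chr)), stringsAsFactors = FALSE)
}

#' Read BLAST tabular output (12-column format)
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (`-outfmt 6`): query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score. Row order is preserved.
#'
#' @param path Path to a tab-separated BLAST result file.
#' @return A data.frame of BLAST hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST file not found: ", path, call. = FALSE)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore")
  empty <- as.data.frame(setNames(
    list(character(0), character(0), numeric(0), integer(0), integer(0),
         integer(0), integer(0), integer(0), integer(0), integer(0),
         numeric(0), numeric(0)), cols), stringsAsFactors = FALSE)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) return(empty)
  bad <- which(nf != 12)
  if (length(bad) > 0) {
    format_error(path, sprintf("expected 12 tab-separated columns, found %d", nf[bad[1]]),
                 row = bad[1])
  }
  df <- read.table(path, sep = "\t", quote = "", comment.char = "",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric", "integer",
                                  "integer", "integer", "integer", "integer",
                                  "integer", "integer", "numeric", "numeric"))
  names(df) <- cols
  if (any(df$q_start > df$q_end)) {
    format_error(path, "q_start > q_end", row = which(df$q_start > df$q_end)[1])
  }
  if (any(df$evalue < 0)) {
    format_error(path, "negative e-value", row = which(df$evalue < 0)[1])
  }
  if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
    format_error(path, "percent identity outside [0, 100]",
                 row = which(df$percent_identity < 0 | df$percent_identity > 100)[1])
  }
  df
}

#' Read a profile-HMM per-domain table (domtblout)
#'
#' Parses the per-domain tabular output of `hmmscan` (one row per domain
#' instance; comment lines start with `#`). The per-domain *independent*
#' e-value (column 13) becomes the hit's `evalue` and the per-domain bit
#' score (column 14) its `score`, because filtering and copy-number rules
#' operate on individual domain instances, not whole-sequence statistics.
#' Alignment coordinates (`ali from`/`ali to`, columns 18-19) map to
#' `ali_start`/`ali_end`.
#'
#' @param path Path to a domtblout file.
#' @return A data.frame of domain hits (see [read_interproscan_tsv()] for
#'   the shared column layout) with `source = "hmmer_custom"`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (length(keep) == 0) return(empty_domain_hits())
  rows <- lapply(seq_along(keep), function(i) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 22) {
      format_error(path, sprintf("expected >= 22 whitespace-delimited fields, found %d",
                                 length(f)), row = ln)
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 18, 19)]))
    if (anyNA(num)) {
      format_error(path, "non-numeric i-Evalue, score or alignment coordinate", row = ln)
    }
    if (num[1] < 0) format_error(path, "negative e-value", row = ln)
    if (num[4] < num[3]) format_error(path, "ali_end < ali_start", row = ln)
    data.frame(protein_id = f[4], source = "hmmer_custom",
               domain_accession = f[2], domain_name = f[1],
               evalue = num[1], score = num[2],
               ali_start = as.integer(num[3]), ali_end = as.integer(num[4]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  # Profiles distributed without a Pfam-style accession print "-" there;
  # fall back to the profile name so rules can still reference them.
  noacc <- hits$domain_accession == "-"
  hits$domain_accession[noacc] <- hits$domain_name[noacc]
  as_domain_hits(hits)
}

#' Read InterProScan tab-separated annotation
#'
#' Parses the TSV annotation dialect: protein id, sequence MD5, sequence
#' length, member database, signature accession, signature description,
#' start, stop, score (an e-value for most member databases), status, date,
#' and optional InterPro columns. Only the first nine columns are required.
#' Rows whose score field is non-numeric (a dash, as emitted by member
#' databases that do not report e-values) carry a missing e-value and are
#' flagged via `evalue_missing`.
#'
#' @param path Path to an InterProScan `.tsv` file.
#' @return A data.frame of domain hits with
#'   `source = "interproscan:<member db>"`.
#' @export
read_interproscan_tsv <- function(path) {
  if (!file.exists(path)) stop("InterProScan file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(empty_domain_hits())
  rows <- lapply(keep, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      format_error(path, sprintf(
        "expected >= 9 tab-separated columns (protein, md5, length, db, accession, description, start, stop, score), found %d",
        length(f)), row = ln)
    }
    se <- suppressWarnings(as.integer(f[7:8]))
    if (anyNA(se)) format_error(path, "non-numeric start/stop", row = ln)
    if (se[2] < se[1]) format_error(path, "stop < start", row = ln)
    ev <- suppressWarnings(as.numeric(f[9]))
    if (!is.na(ev) && ev < 0) format_error(path, "negative e-value", row = ln)
    data.frame(protein_id = f[1], source = paste0("interproscan:", f[4]),
               domain_accession = f[5], domain_name = f[6],
               evalue = ev, score = NA_real_,
               ali_start = se[1], ali_end = se[2],
               evalue_missing = is.na(ev),
               stringsAsFactors = FALSE)
  })
  as_domain_hits(do.call(rbind, rows))
}

#' Write family assignments to TSV
#'
#' Writes one row per assignment with stable protein-id ordering, so the
#' same assignments always produce a byte-identical file regardless of
#' input order. Columns: `protein_id`, `family`, `subfamily`, `label`,
#' `supporting_accessions`, `all_dbd_types`, `evidence_sources`,
#' `curation_flags`.
#'
#' @param path Output path.
#' @param assignments Assignment data.frame from [classify_proteome()].
#' @return `path`, invisibly.
#' @seealso [read_assignments()]
#' @export
write_assignments <- function(path, assignments) {
  cols <- c("protein_id", "family", "subfamily", "label",
            "supporting_accessions", "all_dbd_types", "evidence_sources",
            "curation_flags")
  if (nrow(assignments) > 0) {
    missing <- setdiff(cols, names(assignments))
    if (length(missing) > 0) {
      stop("assignments lack column(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    assignments <- assignments[order(assignments$protein_id), cols, drop = FALSE]
  } else {
    assignments <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                                 stringsAsFactors = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(assignments) > 0) {
    body <- apply(assignments, 1, function(r) paste(ifelse(is.na(r), "", r), collapse = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read family assignments written by [write_assignments()]
#'
#' @param path Path to an assignments TSV.
#' @return Assignment data.frame; `write_assignments()` then
#'   `read_assignments()` is the identity on assignment content.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop("assignments file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  expected <- c("protein_id", "family", "subfamily", "label",
                "supporting_accessions", "all_dbd_types", "evidence_sources",
                "curation_flags")
  if (!identical(names(df), expected)) {
    format_error(path, "unexpected assignment columns")
  }
  df
}
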