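# False-positive filtering of the three evidence channels and merging of
# survivors into one evidence bundle per protein.

#' Filtering thresholds for the evidence channels
#'
#' Default values are the pipeline's calibrated operating point: BLAST hits
#' must have e-value <= 1e-10, percent identity >= 35 and alignment length
#' >= 100 residues; InterProScan annotations must have e-value <= 1e-3;
#' profile-HMM hits are judged per profile against curated score cutoffs
#' (gathering thresholds), falling back to a fixed e-value cutoff for
#' profiles without one. All comparisons are inclusive.
#'
#' @param blast_max_evalue Maximum BLAST e-value (default `1e-10`).
#' @param blast_min_identity Minimum percent identity (default `35`).
#' @param blast_min_alnlen Minimum alignment length in residues (default `100`).
#' @param ipr_max_evalue Maximum InterProScan e-value (default `1e-3`).
#' @param hmmer_policy `"per_profile_threshold"` (score >= the profile's
#'   cutoff, with the fixed e-value as fallback for profiles lacking one) or
#'   `"fixed_evalue"` (e-value <= `hmmer_fixed_evalue` for every profile).
#' @param hmmer_fixed_evalue Fallback/fixed e-value cutoff (default `1e-5`).
#' @return A validated list of class `tf_filter_thresholds`.
#' @export
filter_thresholds <- function(blast_max_evalue = 1e-10,
                              blast_min_identity = 35,
                              blast_min_alnlen = 100,
                              ipr_max_evalue = 1e-3,
                              hmmer_policy = c("per_profile_threshold", "fixed_evalue"),
                              hmmer_fixed_evalue = 1e-5) {
  hmmer_policy <- match.arg(hmmer_policy)
  num <- c(blast_max_evalue = blast_max_evalue,
           blast_min_identity = blast_min_identity,
           blast_min_alnlen = blast_min_alnlen,
           ipr_max_evalue = ipr_max_evalue,
           hmmer_fixed_evalue = hmmer_fixed_evalue)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all thresholds must be finite and > 0", call. = FALSE)
  }
  if (blast_min_identity > 100) stop("blast_min_identity must be <= 100", call. = FALSE)
  structure(list(blast_max_evalue = blast_max_evalue,
                 blast_min_identity = blast_min_identity,
                 blast_min_alnlen = blast_min_alnlen,
                 ipr_max_evalue = ipr_max_evalue,
                 hmmer_policy = hmmer_policy,
                 hmmer_fixed_evalue = hmmer_fixed_evalue),
            class = "tf_filter_thresholds")
}

#' Filter BLAST hits and keep the best hit per query
#'
#' Keeps hits with `evalue <= blast_max_evalue`, `percent_identity >=
#' blast_min_identity` and `alignment_length >= blast_min_alnlen`
#' (inclusive), then reduces each surviving query to a single best hit:
#' highest bit score, ties broken by lowest e-value, then lexicographically
#' smallest subject id, so runs are reproducible.
#'
#' @param hits BLAST hit data.frame from [read_blast_tab()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A data.frame with exactly one row per surviving `query_id`.
#' @export
filter_blast <- function(hits, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "tf_filter_thresholds"))
  keep <- hits$evalue <= thresholds$blast_max_evalue &
    hits$percent_identity >= thresholds$blast_min_identity &
    hits$alignment_length >= thresholds$blast_min_alnlen
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter InterProScan annotations down to significant TF DBDs
#'
#' Keeps hits whose accession belongs to the DBD catalog (the union of
#' accessions referenced by the family rules) and whose e-value is at most
#' `ipr_max_evalue`. Hits with a missing e-value fail the e-value test.
#' Accessions listed in `relaxed_accessions` (by default the MYB domain
#' accessions, whose e-value validation generated false negatives during
#' calibration) bypass the e-value cut entirely; hits kept only through
#' that bypass are marked `relaxed = TRUE` so classification can flag the
#' relaxed path. Survivors are marked `significant = TRUE`.
#'
#' @param hits Domain hit data.frame from [read_interproscan_tsv()].
#' @param thresholds A [filter_thresholds()] object.
#' @param dbd_catalog Character vector of accessions considered TF DBDs,
#'   e.g. `ruleset$dbd_catalog` from [load_rules()].
#' @param relaxed_accessions Accessions exempt from the e-value cut
#'   (default none).
#' @return The surviving hits, marked significant.
#' @export
filter_interpro <- function(hits, thresholds = filter_thresholds(), dbd_catalog,
                            relaxed_accessions = character(0)) {
  stopifnot(inherits(thresholds, "tf_filter_thresholds"))
  hits <- as_domain_hits(hits)
  in_catalog <- hits$domain_accession %in% dbd_catalog
  pass_e <- !is.na(hits$evalue) & hits$evalue <= thresholds$ipr_max_evalue
  relaxed <- hits$domain_accession %in% relaxed_accessions
  keep <- in_catalog & (pass_e | relaxed)
  out <- hits[keep, , drop = FALSE]
  out$significant <- TRUE
  out$relaxed <- !pass_e[keep] & relaxed[keep]
  rownames(out) <- NULL
  out
}

#' Filter profile-HMM hits by per-profile significance
#'
#' Under the `per_profile_threshold` policy a hit is significant when its
#' per-domain bit score is at least the profile's curated cutoff; profiles
#' without a cutoff fall back to the fixed e-value test. Under the
#' `fixed_evalue` policy every hit is judged by `evalue <=
#' hmmer_fixed_evalue`. Survivors are marked `significant = TRUE`.
#'
#' @param hits Domain hit data.frame from [read_domtblout()].
#' @param thresholds A [filter_thresholds()] object.
#' @param profile_thresholds Named numeric vector mapping profile accession
#'   to its score cutoff; may be empty. See [default_profile_thresholds()].
#' @return The surviving hits, marked significant.
#' @export
filter_hmmer <- function(hits, thresholds = filter_thresholds(),
                         profile_thresholds = default_profile_thresholds()) {
  stopifnot(inherits(thresholds, "tf_filter_thresholds"))
  hits <- as_domain_hits(hits)
  if (nrow(hits) == 0) return(hits)
  pass_e <- !is.na(hits$evalue) & hits$evalue <= thresholds$hmmer_fixed_evalue
  if (thresholds$hmmer_policy == "fixed_evalue" || length(profile_thresholds) == 0) {
    keep <- pass_e
  } else {
    cutoff <- unname(profile_thresholds[hits$domain_accession])
    keep <- ifelse(is.na(cutoff), pass_e, !is.na(hits$score) & hits$score >= cutoff)
  }
  out <- hits[keep, , drop = FALSE]
  out$significant <- TRUE
  rownames(out) <- NULL
  out
}

#' Per-profile score cutoffs for the custom DBD profiles
#'
#' Reads the bundled table of curated score cutoffs (gathering thresholds)
#' for the custom profile-HMM channel, which covers DBDs not represented in
#' the member-database consortium (e.g. G2-like, NF-YB, NF-YC, VARL).
#'
#' @param path Optional path to a two-column TSV (`accession`, `cutoff`);
#'   defaults to the bundled table.
#' @return Named numeric vector of score cutoffs.
#' @export
default_profile_thresholds <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hmm_profile_thresholds.tsv",
                                package = "phycotf", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df$cutoff, df$accession)
}

#' Merge surviving evidence into one bundle per protein
#'
#' Combines the filtered results of all channels into a single evidence
#' bundle per protein: the best BLAST hit (if any), all significant domain
#' hits, and the set of channels that contributed. Proteins with no
#' surviving evidence are absent from the result. Evidence referencing a
#' protein id not present in the proteome is a consistency error.
#'
#' @param proteome Proteome data.frame from [read_fasta()].
#' @param blast_best Output of [filter_blast()] (may have zero rows).
#' @param ipr_hits Output of [filter_interpro()].
#' @param hmmer_hits Output of [filter_hmmer()].
#' @return A named list (sorted by protein id) of bundles; each bundle is a
#'   list with `protein_id`, `best_blast` (one-row data.frame or `NULL`),
#'   `domain_hits` (significant hits) and `channels` (subset of
#'   `c("blast", "hmmer", "interproscan")`).
#' @export
merge_evidence <- function(proteome, blast_best = NULL, ipr_hits = NULL,
                           hmmer_hits = NULL) {
  ids <- proteome$protein_id
  blast_best <- blast_best %||% data.frame(query_id = character(0))
  ipr_hits <- as_domain_hits(ipr_hits %||% empty_domain_hits())
  hmmer_hits <- as_domain_hits(hmmer_hits %||% empty_domain_hits())
  evidenced <- c(blast_best$query_id, ipr_hits$protein_id, hmmer_hits$protein_id)
  unknown <- setdiff(unique(evidenced), ids)
  if (length(unknown) > 0) {
    stop("evidence references protein id(s) absent from the proteome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  domain_hits <- rbind(ipr_hits, hmmer_hits)
  targets <- sort(unique(evidenced))
  bundles <- lapply(targets, function(id) {
    bb <- blast_best[blast_best$query_id == id, , drop = FALSE]
    dh <- domain_hits[domain_hits$protein_id == id, , drop = FALSE]
    rownames(dh) <- NULL
    channels <- c(
      if (nrow(bb) > 0) "blast",
      if (any(dh$source == "hmmer_custom")) "hmmer",
      if (any(startsWith(dh$source, "interproscan"))) "interproscan"
    )
    structure(list(protein_id = id,
                   best_blast = if (nrow(bb) > 0) bb[1, , drop = FALSE] else NULL,
                   domain_hits = dh,
                   channels = channels),
              class = "tf_evidence_bundle")
  })
  names(bundles) <- targets
  bundles
}
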