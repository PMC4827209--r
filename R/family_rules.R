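# Rule-based family classification: declarative DBD assignment rules plus
# the automated curation heuristics (MYB repeat classes, SHAQKYF motif,
# G2-like cross-annotation, copy-number verification).

#' Load a family-assignment rule set
#'
#' Reads a declarative rules file: one record per family (or subfamily)
#' with its required DBD accession sets, minimum copy numbers, forbidden
#' accessions, a unique integer priority for conflict resolution, a flag
#' marking accessions exempt from the InterProScan e-value validation
#' (the MYB relaxed path) and an optional protein motif regex (used for
#' SHAQKYF detection). The bundled default covers the algal TF families of
#' the comparative layer, the plant families used for benchmarking and the
#' cyanobacterial families (arsR, Bac_DNA_binding, BolA, GerE, LysR, SfsA,
#' Crp, GntR, FUR) plus Fungal TRF (Zn-cluster).
#'
#' The exact accession content is data, not algorithm: the bundled file is
#' a curated reconstruction using representative Pfam-style accessions and
#' `CUST_*` accessions for the custom profile-HMM channel, and can be
#' replaced wholesale by the user.
#'
#' File format (tab-separated, `#` comments allowed): columns `label`
#' (unique display name, e.g. `"MYB (2R)"`), `family`, `subfamily` (may be
#' empty), `required` (accession sets separated by `&`, alternates within a
#' set separated by `,`; a protein must hit at least one accession from
#' every set), `min_copies` (`&`-separated integers aligned with the sets;
#' empty means 1 for each), `forbidden` (comma-separated accessions, none
#' of which may be hit), `priority` (unique integer; higher wins among
#' matching rules), `relax` (0/1), `motif` (regex or empty).
#'
#' @param path Path to a rules file; `NULL` loads the bundled default.
#' @return A list of class `tf_ruleset` with elements `rules` (list of
#'   parsed rules, sorted by decreasing priority), `labels`, `dbd_catalog`
#'   (all referenced accessions), `relaxed_accessions`, `myb_accessions`,
#'   `g2like_accessions` and `shaqkyf_motif`.
#' @export
load_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "family_rules.tsv",
                                package = "phycotf", mustWork = TRUE)
  if (!file.exists(path)) stop("rules file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = "character")
  needed <- c("label", "family", "subfamily", "required", "min_copies",
              "forbidden", "priority", "relax", "motif")
  if (!all(needed %in% names(df))) {
    stop("rules file lacks column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  dup <- unique(df$label[duplicated(df$label)])
  if (length(dup) > 0) problems <- c(problems, paste0("duplicate family label(s): ",
                                                      paste(dup, collapse = ", ")))
  pri <- suppressWarnings(as.integer(df$priority))
  if (anyNA(pri)) problems <- c(problems, "non-integer priority")
  pdup <- unique(pri[duplicated(pri)])
  if (length(pdup) > 0) problems <- c(problems, paste0("priority tie(s) at: ",
                                                       paste(pdup, collapse = ", ")))
  rules <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sets <- strsplit(df$required[i], "&", fixed = TRUE)[[1]]
    sets <- lapply(sets, function(s) split_csv(s))
    if (length(sets) == 0 || any(vapply(sets, length, 1L) == 0)) {
      problems <- c(problems, paste0("rule '", df$label[i], "' has an empty required set"))
      sets <- list()
    }
    mc <- if (nzchar(df$min_copies[i])) {
      suppressWarnings(as.integer(strsplit(df$min_copies[i], "&", fixed = TRUE)[[1]]))
    } else rep(1L, length(sets))
    if (anyNA(mc) || length(mc) != length(sets) || any(mc < 1)) {
      problems <- c(problems, paste0("rule '", df$label[i],
                                     "' has invalid min_copies (must be >= 1, one per required set)"))
    }
    rules[[i]] <- list(
      label = df$label[i], family = df$family[i],
      subfamily = if (nzchar(df$subfamily[i])) df$subfamily[i] else NA_character_,
      required = sets, min_copies = mc,
      forbidden = split_csv(df$forbidden[i]),
      priority = pri[i],
      relax = df$relax[i] %in% c("1", "TRUE", "true"),
      motif = if (nzchar(df$motif[i])) df$motif[i] else NA_character_
    )
  }
  if (length(problems) > 0) {
    stop("invalid rules file: ", paste(problems, collapse = "; "), call. = FALSE)
  }
  rules <- rules[order(-pri)]
  catalog <- sort(unique(unlist(lapply(rules, function(r) c(unlist(r$required), r$forbidden)))))
  relaxed <- sort(unique(unlist(lapply(rules[vapply(rules, `[[`, TRUE, "relax")],
                                       function(r) unlist(r$required)))))
  myb <- sort(unique(unlist(lapply(rules, function(r) {
    if (r$family == "MYB") unlist(r$required) else NULL
  }))))
  g2 <- sort(unique(unlist(lapply(rules, function(r) {
    if (identical(r$label, "GARP-G2-like")) unlist(r$required) else NULL
  }))))
  motif <- NA_character_
  for (r in rules) if (identical(r$label, "MYB-SHAQKYF") && !is.na(r$motif)) motif <- r$motif
  if (is.na(motif)) motif <- "SH[AL]QK[YF]"
  structure(list(rules = rules,
                 labels = vapply(rules, `[[`, character(1), "label"),
                 dbd_catalog = catalog,
                 relaxed_accessions = relaxed,
                 myb_accessions = myb,
                 g2like_accessions = g2,
                 shaqkyf_motif = motif),
            class = "tf_ruleset")
}

#' Look up a rule by its display label
#' @param ruleset A `tf_ruleset`.
#' @param label Rule label, e.g. `"bZIP"`.
#' @return The rule (a list), or `NULL` if absent.
#' @export
rule_by_label <- function(ruleset, label) {
  for (r in ruleset$rules) if (identical(r$label, label)) return(r)
  NULL
}

# Greedy selection of non-overlapping domain instances: ascending
# ali_start; an instance overlapping a previously selected one by more
# than 50% of the shorter alignment is not counted.
select_copies <- function(hits, accession_set) {
  h <- hits[hits$domain_accession %in% accession_set, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h <- h[order(h$ali_start, h$ali_end), , drop = FALSE]
  sel <- integer(0)
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in sel) {
      ov <- min(h$ali_end[i], h$ali_end[j]) - max(h$ali_start[i], h$ali_start[j]) + 1
      shorter <- min(h$ali_end[i] - h$ali_start[i], h$ali_end[j] - h$ali_start[j]) + 1
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  h[sel, , drop = FALSE]
}

#' Count non-overlapping domain copies
#'
#' Counts instances from `accession_set` whose alignment intervals are
#' mutually non-overlapping, by greedy selection in ascending `ali_start`
#' order; an instance overlapping an already selected one by more than 50%
#' of the shorter alignment length is not counted. This is the copy-number
#' primitive behind the multi-domain families (e.g. two or more AP2 or
#' B-box domains) and the MYB repeat classes.
#'
#' @param hits Domain hits of one protein.
#' @param accession_set Character vector of accessions to count.
#' @return Integer copy count.
#' @export
count_copies <- function(hits, accession_set) {
  nrow(select_copies(hits, accession_set))
}

rule_matches <- function(rule, hits) {
  if (length(rule$required) == 0) return(FALSE)
  if (length(rule$forbidden) > 0 && any(hits$domain_accession %in% rule$forbidden)) {
    return(FALSE)
  }
  for (k in seq_along(rule$required)) {
    if (count_copies(hits, rule$required[[k]]) < rule$min_copies[k]) return(FALSE)
  }
  TRUE
}

assignment_row <- function(protein_id, family, subfamily, label,
                           supporting, all_dbd, channels, flags) {
  data.frame(protein_id = protein_id, family = family,
             subfamily = subfamily, label = label,
             supporting_accessions = collapse_csv(supporting),
             all_dbd_types = collapse_csv(all_dbd),
             evidence_sources = collapse_csv(channels),
             curation_flags = collapse_csv(flags),
             stringsAsFactors = FALSE)
}

unclassified_row <- function(bundle, ruleset) {
  assignment_row(bundle$protein_id, "unclassified", NA_character_, "unclassified",
                 character(0),
                 intersect(bundle$domain_hits$domain_accession, ruleset$dbd_catalog),
                 bundle$channels, character(0))
}

#' Classify one evidenced protein into a TF family
#'
#' Evaluates every rule of the rule set against the protein's significant
#' domain hits. A rule matches when each of its required accession sets is
#' hit with at least its minimum copy number (counted over non-overlapping
#' instances) and no forbidden accession is hit. Among matching rules the
#' one with the highest priority is assigned. A protein whose only
#' surviving evidence is a best BLAST hit (no DBD) inherits the family of
#' the matched database subject — the reference database encodes the
#' subject's family label as the id prefix before the first `|` — unless
#' `require_dbd = TRUE`. When no rule matches, the protein is labelled
#' `"unclassified"` (retained, never silently dropped).
#'
#' @param bundle A `tf_evidence_bundle` from [merge_evidence()].
#' @param ruleset A `tf_ruleset` from [load_rules()].
#' @param require_dbd Disable the BLAST-only inheritance path.
#' @return A one-row assignment data.frame with columns `protein_id`,
#'   `family`, `subfamily`, `label`, `supporting_accessions`,
#'   `all_dbd_types`, `evidence_sources` and `curation_flags`.
#' @export
classify_protein <- function(bundle, ruleset, require_dbd = FALSE) {
  hits <- bundle$domain_hits
  if (nrow(hits) > 0) {
    all_dbd <- intersect(hits$domain_accession, ruleset$dbd_catalog)
    for (rule in ruleset$rules) {   # already sorted by decreasing priority
      if (rule_matches(rule, hits)) {
        supporting <- intersect(hits$domain_accession, unlist(rule$required))
        flags <- if (any(rule$min_copies > 1)) "copy_number_checked" else character(0)
        return(assignment_row(bundle$protein_id, rule$family, rule$subfamily,
                              rule$label, supporting, all_dbd, bundle$channels, flags))
      }
    }
    return(unclassified_row(bundle, ruleset))
  }
  if (!require_dbd && !is.null(bundle$best_blast)) {
    subject_label <- sub("\\|.*$", "", bundle$best_blast$subject_id[1])
    rule <- rule_by_label(ruleset, subject_label)
    if (!is.null(rule)) {
      return(assignment_row(bundle$protein_id, rule$family, rule$subfamily,
                            rule$label, character(0), character(0),
                            bundle$channels, character(0)))
    }
  }
  unclassified_row(bundle, ruleset)
}

#' Classify a MYB-evidenced protein by repeat count and SHAQKYF motif
#'
#' MYB candidates follow the standard protocol except that their
#' InterProScan e-value validation is bypassed (e-value filtration of MYB
#' domains generated false negatives during calibration); evidence retained
#' only through that bypass raises the `myb_relaxed_path` flag. The number
#' of non-overlapping MYB repeats `r` decides the class: `r >= 3` is
#' `"MYB (3R)"`, `r == 2` is `"MYB (2R)"` and `r == 1` is `"MYB-rel"`.
#' Single-repeat proteins are then scanned for the SHAQKYF signature
#' (default pattern `S-H-[AL]-Q-K-[YF]`, configurable in the rules file)
#' within the repeat's aligned subsequence; a match reclassifies the
#' protein to `"MYB-SHAQKYF"` and raises the `shaqkyf_motif` flag.
#'
#' @param bundle A `tf_evidence_bundle` containing at least one MYB domain
#'   hit.
#' @param ruleset A `tf_ruleset`.
#' @param sequence Optional amino-acid sequence of the protein; without it
#'   the motif scan is skipped and single-repeat proteins stay `"MYB-rel"`.
#' @return A one-row assignment data.frame.
#' @export
classify_myb <- function(bundle, ruleset, sequence = NULL) {
  hits <- bundle$domain_hits
  myb <- select_copies(hits, ruleset$myb_accessions)
  if (nrow(myb) == 0) return(classify_protein(bundle, ruleset))
  r <- nrow(myb)
  flags <- character(0)
  all_myb <- hits[hits$domain_accession %in% ruleset$myb_accessions, , drop = FALSE]
  if (any(all_myb$relaxed)) flags <- c(flags, "myb_relaxed_path")
  label <- if (r >= 3) "MYB (3R)" else if (r == 2) "MYB (2R)" else "MYB-rel"
  if (r == 1 && !is.null(sequence)) {
    repeat_seq <- substr(sequence, myb$ali_start[1],
                         min(myb$ali_end[1], nchar(sequence)))
    if (grepl(ruleset$shaqkyf_motif, repeat_seq, perl = TRUE)) {
      label <- "MYB-SHAQKYF"
      flags <- c(flags, "shaqkyf_motif")
    }
  }
  rule <- rule_by_label(ruleset, label)
  assignment_row(bundle$protein_id,
                 rule$family %||% "MYB", rule$subfamily %||% NA_character_, label,
                 unique(myb$domain_accession),
                 intersect(hits$domain_accession, ruleset$dbd_catalog),
                 bundle$channels, flags)
}

#' Resolve G2-like / MYB-SHAQKYF cross-annotation
#'
#' The G2-like DBD (absent from the member-database consortium, detected
#' through the custom profile channel) is closely similar to the
#' MYB-SHAQKYF domain. Every protein carrying both a G2-like profile hit
#' and a SHAQKYF call is re-scored: the signal with the higher profile bit
#' score wins, and the `g2like_crosscheck` flag is set on every protein
#' examined. Proteins with only one of the two signals are unchanged.
#'
#' @param assignments Assignment data.frame from classification.
#' @param bundles The evidence bundles the assignments were computed from.
#' @param ruleset A `tf_ruleset`.
#' @return The (possibly re-assigned) assignment data.frame.
#' @export
crosscheck_g2like <- function(assignments, bundles, ruleset) {
  if (nrow(assignments) == 0) return(assignments)
  for (i in seq_len(nrow(assignments))) {
    if (!identical(assignments$label[i], "MYB-SHAQKYF")) next
    bundle <- bundles[[assignments$protein_id[i]]]
    if (is.null(bundle)) next
    hits <- bundle$domain_hits
    g2 <- hits[hits$domain_accession %in% ruleset$g2like_accessions, , drop = FALSE]
    if (nrow(g2) == 0) next
    myb <- hits[hits$domain_accession %in% ruleset$myb_accessions, , drop = FALSE]
    g2_score <- suppressWarnings(max(g2$score, na.rm = TRUE))
    myb_score <- suppressWarnings(max(myb$score, na.rm = TRUE))
    flags <- union(split_csv(assignments$curation_flags[i]), "g2like_crosscheck")
    assignments$curation_flags[i] <- collapse_csv(flags)
    if (is.finite(g2_score) && (!is.finite(myb_score) || g2_score > myb_score)) {
      rule <- rule_by_label(ruleset, "GARP-G2-like")
      assignments$family[i] <- rule$family
      assignments$subfamily[i] <- rule$subfamily
      assignments$label[i] <- rule$label
      assignments$supporting_accessions[i] <- collapse_csv(unique(g2$domain_accession))
    }
  }
  assignments
}

#' Classify every evidenced protein of a proteome
#'
#' Applies [classify_protein()] to each evidence bundle, routing bundles
#' with MYB domain evidence through [classify_myb()], then resolves
#' G2-like/MYB-SHAQKYF cross-annotation with [crosscheck_g2like()].
#' Classification is a pure function of the bundles and the rule set:
#' output is sorted by protein id and independent of input order.
#' `"unclassified"` records are retained (and excluded from TF counts by
#' [count_table()]).
#'
#' @param bundles Named list of bundles from [merge_evidence()].
#' @param ruleset A `tf_ruleset`.
#' @param proteome Optional proteome data.frame (from [read_fasta()]);
#'   required for the SHAQKYF motif scan.
#' @param require_dbd Disable BLAST-only family inheritance.
#' @return Assignment data.frame, one row per bundle.
#' @export
classify_proteome <- function(bundles, ruleset, proteome = NULL,
                              require_dbd = FALSE) {
  if (length(bundles) == 0) {
    cols <- c("protein_id", "family", "subfamily", "label",
              "supporting_accessions", "all_dbd_types", "evidence_sources",
              "curation_flags")
    return(as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE))
  }
  sequences <- if (!is.null(proteome)) {
    setNames(proteome$sequence, proteome$protein_id)
  } else NULL
  get_seq <- function(id) {
    if (!is.null(sequences) && id %in% names(sequences)) sequences[[id]] else NULL
  }
  bundles <- bundles[order(names(bundles))]
  rows <- lapply(bundles, function(bundle) {
    has_myb <- any(bundle$domain_hits$domain_accession %in% ruleset$myb_accessions)
    if (has_myb) {
      classify_myb(bundle, ruleset, sequence = get_seq(bundle$protein_id))
    } else {
      classify_protein(bundle, ruleset, require_dbd = require_dbd)
    }
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  crosscheck_g2like(assignments, bundles, ruleset)
}
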