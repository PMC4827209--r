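# Synthetic proteomes and matched evidence files with planted truth labels
# and controlled noise. Evidence is written to real files in the standard
# dialects so the readers are exercised by every integration test.

#' Default family panel for synthetic fixtures
#'
#' Twelve families chosen to cover every classification mechanism: plain
#' single-DBD rules, alternate accessions, copy-number rules (AP2 vs ERF,
#' Double B-box), all MYB repeat classes including the SHAQKYF motif path,
#' and the custom profile-HMM channel (G2-like).
#'
#' @return Character vector of 12 family labels.
#' @export
synthetic_family_panel <- function() {
  c("bZIP", "HSF", "WRKY", "AP2", "ERF", "DBB", "C2C2-GATA", "GARP-G2-like",
    "MYB (3R)", "MYB (2R)", "MYB-rel", "MYB-SHAQKYF")
}

# Amino-acid alphabet; domain placeholders exclude H so the SHAQKYF
# pattern can only occur where it is planted.
aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic placeholder peptide for an accession: recognizable, fixed,
# independent of the RNG state.
dom_peptide <- function(accession, len) {
  alph <- setdiff(aa_alphabet(), "H")
  x <- utf8ToInt(accession)
  idx <- (cumsum(rep(x, length.out = len)) + 7L * seq_len(len)) %% length(alph) + 1L
  paste(alph[idx], collapse = "")
}

#' Noise model for synthetic evidence
#'
#' @param fn_rate Probability (0-1) that a planted domain instance is
#'   omitted from the evidence files.
#' @param fp_rate Expected number of spurious significant domain hits per
#'   background protein (Poisson).
#' @param seed Integer seed; identical seeds give identical files.
#' @param sig_evalue E-value given to significant (planted or spurious)
#'   hits.
#' @param junk_evalue E-value given to planted non-significant decoy hits
#'   (above the filtering threshold, so they must be removed by the
#'   filter engine).
#' @return A list of class `tf_noise_model`.
#' @export
noise_model <- function(fn_rate = 0, fp_rate = 0, seed = 1,
                        sig_evalue = 1e-9, junk_evalue = 0.5) {
  if (fn_rate < 0 || fn_rate > 1) stop("fn_rate must be in [0, 1]", call. = FALSE)
  if (fp_rate < 0) stop("fp_rate must be >= 0", call. = FALSE)
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate, seed = as.integer(seed),
                 sig_evalue = sig_evalue, junk_evalue = junk_evalue),
            class = "tf_noise_model")
}

#' Generate a synthetic proteome with planted TF architectures
#'
#' For each requested family, `n_per_family` proteins are built: a uniform
#' random amino-acid background with fixed recognizable domain placeholder
#' subsequences at the planted coordinates. Architectures follow the
#' family's rule (each required accession set contributes its minimum copy
#' number of disjoint instances); SHAQKYF-class proteins carry the motif
#' string inside their MYB repeat, other placeholders cannot contain it by
#' construction. Optional background (non-TF) proteins carry no planted
#' domains and serve as false-positive targets for [generate_evidence()].
#' Deterministic for a given seed.
#'
#' @param n_per_family Proteins per family.
#' @param families Family labels to plant; default [synthetic_family_panel()].
#' @param ruleset A `tf_ruleset`; families absent from it are an error.
#' @param seed Integer seed.
#' @param n_background Number of background proteins (default 0).
#' @param fasta Optional path; when given, the proteome is also written as
#'   FASTA.
#' @return A list of class `tf_synthetic_proteome`: `proteome` (data.frame
#'   as from [read_fasta()]), `truth` (protein_id, family, subfamily,
#'   label), `architecture` (protein_id, accession, start, end, channel)
#'   and `families`.
#' @export
generate_proteome <- function(n_per_family = 5, families = synthetic_family_panel(),
                              ruleset = load_rules(), seed = 1,
                              n_background = 0, fasta = NULL) {
  missing <- setdiff(families, ruleset$labels)
  if (length(missing) > 0) {
    stop("family label(s) absent from the rule set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  alph <- aa_alphabet()
  dom_len <- 50L
  gap <- 20L
  records <- truth <- arch <- list()
  for (fam in families) {
    rule <- rule_by_label(ruleset, fam)
    slug <- gsub("[^A-Za-z0-9]", "", fam)
    for (j in seq_len(n_per_family)) {
      id <- sprintf("%s_p%02d", slug, j)
      accs <- integer(0)
      plan <- list()
      pos <- 10L
      for (k in seq_along(rule$required)) {
        acc <- rule$required[[k]][1]
        for (copy in seq_len(rule$min_copies[k])) {
          plan[[length(plan) + 1]] <- list(accession = acc, start = pos,
                                           end = pos + dom_len - 1L)
          pos <- pos + dom_len + gap
        }
      }
      len <- pos + 10L
      seq_chars <- sample(alph, len, replace = TRUE)
      for (p in plan) {
        pep <- dom_peptide(p$accession, dom_len)
        if (identical(fam, "MYB-SHAQKYF")) {
          substr(pep, 21, 26) <- "SHAQKY"
        }
        seq_chars[p$start:p$end] <- strsplit(pep, "")[[1]]
      }
      records[[id]] <- paste(seq_chars, collapse = "")
      truth[[id]] <- data.frame(protein_id = id, family = rule$family,
                                subfamily = rule$subfamily, label = fam,
                                stringsAsFactors = FALSE)
      arch[[id]] <- do.call(rbind, lapply(plan, function(p) {
        data.frame(protein_id = id, accession = p$accession,
                   start = p$start, end = p$end,
                   channel = if (startsWith(p$accession, "CUST")) "hmmer" else "interproscan",
                   stringsAsFactors = FALSE)
      }))
    }
  }
  for (j in seq_len(n_background)) {
    id <- sprintf("bg_p%02d", j)
    records[[id]] <- paste(sample(alph, 180, replace = TRUE), collapse = "")
  }
  proteome <- data.frame(protein_id = names(records),
                         sequence = unlist(records, use.names = FALSE),
                         stringsAsFactors = FALSE)
  proteome$length <- nchar(proteome$sequence)
  out <- structure(list(proteome = proteome,
                        truth = do.call(rbind, unname(truth)),
                        architecture = do.call(rbind, unname(arch)),
                        families = families),
                   class = "tf_synthetic_proteome")
  if (!is.null(fasta)) {
    writeLines(paste0(">", proteome$protein_id, "\n", proteome$sequence), fasta)
  }
  out
}

# Accession pool for spurious significant hits: single-copy families only,
# so each spurious hit maps to one predictable family label.
fp_accession_pool <- function() {
  c("bZIP" = "PF00170", "HSF" = "PF00447", "WRKY" = "PF03106",
    "C2H2" = "PF00096", "C3H" = "PF00642", "CSD" = "PF00313")
}

write_domtblout_file <- function(path, rows) {
  header <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(rows) > 0) {
    lines <- sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
      rows$domain_name, rows$accession, 60L, rows$protein_id, "-", rows$qlen,
      rows$evalue, rows$score + 1, 0.1, 1L, 1L, rows$evalue, rows$evalue,
      rows$score, 0.1, 1L, 50L, rows$start, rows$end,
      pmax(rows$start - 2L, 1L), rows$end + 2L, 0.95, "synthetic profile")
    writeLines(lines, con)
  }
  invisible(path)
}

write_interpro_file <- function(path, rows) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(rows) > 0) {
    lines <- sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%d\t%d\t%s\tT\t2016-04-11\t-\t-",
                     rows$protein_id, "d41d8cd98f00b204e9800998ecf8427e",
                     rows$qlen, rows$db, rows$accession, rows$name,
                     rows$start, rows$end, rows$evalue_chr)
    writeLines(lines, con)
  }
  invisible(path)
}

write_blast_file <- function(path, rows) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(rows) > 0) {
    lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     rows$query_id, rows$subject_id, rows$pident, rows$len,
                     rows$mism, 0L, 1L, rows$len, 1L, rows$len,
                     rows$evalue_chr, rows$bitscore)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Generate evidence files for a synthetic proteome
#'
#' Writes the three evidence files (12-column BLAST tabular, profile-HMM
#' per-domain table, InterProScan TSV) for a synthetic proteome. Each
#' planted domain appears in its channel with a significant e-value unless
#' omitted as a false negative; spurious significant hits are injected on
#' background proteins as false positives. Every planted protein receives
#' a best BLAST hit to a subject named after its true family
#' (`"<label>|ref1"`) passing all thresholds plus a decoy hit below the
#' identity threshold; background proteins receive only decoy hits.
#' Deterministic sub-threshold junk domain rows are always included so the
#' filter engine is exercised even at zero noise.
#'
#' Randomness is consumed in a documented order so tests can recompute the
#' planted noise independently: after `set.seed(noise$seed)`, the first
#' `nrow(architecture)` uniform draws decide the false-negative drops (in
#' architecture row order), then one Poisson draw per background protein
#' decides the spurious hit counts, then one uniform draw per spurious hit
#' selects its accession from [fp_accession_pool()].
#'
#' @param synth A `tf_synthetic_proteome` from [generate_proteome()].
#' @param noise A [noise_model()].
#' @param dir Output directory (created if needed).
#' @return A list of class `tf_synthetic_evidence`: `files` (paths named
#'   `blast`, `domtblout`, `interpro`), `dropped` (architecture rows
#'   omitted as false negatives), `fp` (data.frame `protein_id`, `label` of
#'   injected false positives) and `noise`.
#' @export
generate_evidence <- function(synth, noise = noise_model(), dir = tempfile("evid")) {
  stopifnot(inherits(synth, "tf_synthetic_proteome"),
            inherits(noise, "tf_noise_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(noise$seed)
  arch <- synth$architecture
  lens <- setNames(synth$proteome$length, synth$proteome$protein_id)
  drop <- if (nrow(arch) > 0) runif(nrow(arch)) < noise$fn_rate else logical(0)
  kept <- arch[!drop, , drop = FALSE]
  dropped <- arch[drop, , drop = FALSE]

  bg_ids <- setdiff(synth$proteome$protein_id, synth$truth$protein_id)
  pool <- fp_accession_pool()
  fp_rows <- list()
  if (length(bg_ids) > 0 && noise$fp_rate > 0) {
    k <- rpois(length(bg_ids), noise$fp_rate)
    for (i in seq_along(bg_ids)) {
      if (k[i] == 0) next
      acc_i <- ceiling(runif(1) * length(pool))
      acc <- pool[[acc_i]]
      n_copies <- min(k[i], 2L)  # background proteins fit two disjoint domains
      fp_rows[[bg_ids[i]]] <- data.frame(
        protein_id = bg_ids[i], accession = acc,
        start = 10L + (seq_len(n_copies) - 1L) * 70L,
        end = 10L + (seq_len(n_copies) - 1L) * 70L + 49L,
        channel = "interproscan", label = names(pool)[acc_i],
        stringsAsFactors = FALSE)
    }
  }
  fp_arch <- do.call(rbind, unname(fp_rows)) %||%
    data.frame(protein_id = character(0), accession = character(0),
               start = integer(0), end = integer(0), channel = character(0),
               label = character(0), stringsAsFactors = FALSE)

  ev_chr <- function(e) formatC(e, format = "e", digits = 1)

  # InterProScan channel: planted + spurious + deterministic junk rows.
  ipr <- rbind(kept[kept$channel == "interproscan", c("protein_id", "accession", "start", "end")],
               fp_arch[, c("protein_id", "accession", "start", "end")])
  ipr_rows <- data.frame(
    protein_id = ipr$protein_id, qlen = unname(lens[ipr$protein_id]),
    db = rep("PFAM", nrow(ipr)), accession = ipr$accession, name = ipr$accession,
    start = ipr$start, end = ipr$end,
    evalue_chr = rep(ev_chr(noise$sig_evalue), nrow(ipr)),
    stringsAsFactors = FALSE)
  planted_ids <- unique(synth$truth$protein_id)
  junk_ids <- planted_ids[seq_along(planted_ids) %% 7 == 0]
  if (length(junk_ids) > 0) {
    junk <- rbind(
      data.frame(protein_id = junk_ids, qlen = unname(lens[junk_ids]),
                 db = "PFAM", accession = "PF99999", name = "not_a_dbd",
                 start = 1L, end = 30L, evalue_chr = ev_chr(noise$sig_evalue),
                 stringsAsFactors = FALSE),
      data.frame(protein_id = junk_ids, qlen = unname(lens[junk_ids]),
                 db = "PFAM", accession = "PF00313", name = "CSD",
                 start = 1L, end = 30L, evalue_chr = ev_chr(noise$junk_evalue),
                 stringsAsFactors = FALSE))
    ipr_rows <- rbind(ipr_rows, junk)
  }
  ipr_rows <- ipr_rows[order(ipr_rows$protein_id, ipr_rows$start, ipr_rows$accession), ]

  # Custom profile-HMM channel.
  hm <- kept[kept$channel == "hmmer", , drop = FALSE]
  hm_rows <- data.frame(
    domain_name = sub("^CUST_", "", hm$accession), accession = hm$accession,
    protein_id = hm$protein_id, qlen = unname(lens[hm$protein_id]),
    evalue = rep(noise$sig_evalue, nrow(hm)), score = rep(30, nrow(hm)),
    start = hm$start, end = hm$end, stringsAsFactors = FALSE)
  hm_rows <- hm_rows[order(hm_rows$protein_id, hm_rows$start), ]

  # BLAST channel: one passing best hit per planted protein (subject named
  # after the true family) plus sub-threshold decoys for every protein.
  labels <- setNames(synth$truth$label, synth$truth$protein_id)
  all_ids <- synth$proteome$protein_id
  bl_best <- data.frame(
    query_id = planted_ids,
    subject_id = paste0(unname(labels[planted_ids]), "|ref1"),
    pident = 62.5, len = 180L, mism = 60L,
    evalue_chr = "1e-80", bitscore = 250, stringsAsFactors = FALSE)
  bl_decoy <- data.frame(
    query_id = all_ids, subject_id = "DECOY|low_identity",
    pident = 20, len = 180L, mism = 140L,
    evalue_chr = "1e-30", bitscore = 80, stringsAsFactors = FALSE)
  bl_rows <- rbind(bl_best, bl_decoy)
  bl_rows <- bl_rows[order(bl_rows$query_id, bl_rows$subject_id), ]

  files <- list(blast = file.path(dir, "blast.tsv"),
                domtblout = file.path(dir, "hits.domtblout"),
                interpro = file.path(dir, "interproscan.tsv"))
  write_blast_file(files$blast, bl_rows)
  write_domtblout_file(files$domtblout, hm_rows)
  write_interpro_file(files$interpro, ipr_rows)

  fp <- unique(fp_arch[, c("protein_id", "label")])
  rownames(fp) <- NULL
  rownames(dropped) <- NULL
  structure(list(files = files, dropped = dropped, fp = fp, noise = noise),
            class = "tf_synthetic_evidence")
}
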