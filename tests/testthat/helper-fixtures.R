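# Shared fixtures: all evidence is built in code, no stored binary data.

# The bundled rule set, loaded once per test run.
RS <- load_rules()

# Construct a domain-hit table from parallel vectors.
make_hits <- function(protein_id, accession, start, end,
                      evalue = 1e-9, score = 30, source = "interproscan:PFAM",
                      significant = TRUE, relaxed = FALSE) {
  n <- length(accession)
  phycotf_hits <- data.frame(
    protein_id = rep_len(protein_id, n), source = rep_len(source, n),
    domain_accession = accession, domain_name = accession,
    evalue = rep_len(evalue, n), score = rep_len(score, n),
    ali_start = as.integer(start), ali_end = as.integer(end),
    significant = rep_len(significant, n),
    evalue_missing = rep_len(FALSE, n), relaxed = rep_len(relaxed, n),
    stringsAsFactors = FALSE)
  phycotf_hits
}

# Construct an evidence bundle directly (bypassing the filter engine).
make_bundle <- function(protein_id, hits = NULL, best_blast = NULL) {
  hits <- if (is.null(hits)) {
    make_hits(protein_id, character(0), integer(0), integer(0))
  } else hits
  channels <- c(
    if (!is.null(best_blast)) "blast",
    if (any(hits$source == "hmmer_custom")) "hmmer",
    if (any(startsWith(hits$source, "interproscan"))) "interproscan")
  structure(list(protein_id = protein_id, best_blast = best_blast,
                 domain_hits = hits, channels = channels),
            class = "tf_evidence_bundle")
}

make_blast_row <- function(query_id, subject_id, pident = 60,
                           alnlen = 150, evalue = 1e-50, bitscore = 200) {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = pident, alignment_length = alnlen,
             mismatches = 10L, gap_opens = 0L, q_start = 1L, q_end = alnlen,
             s_start = 1L, s_end = alnlen, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

# Brute-force maximum set of mutually compatible domain instances
# (pairwise overlap <= 50% of the shorter alignment): the independent
# oracle for copy counting.
brute_force_copies <- function(start, end) {
  n <- length(start)
  if (n == 0) return(0L)
  compatible <- function(i, j) {
    ov <- min(end[i], end[j]) - max(start[i], start[j]) + 1
    shorter <- min(end[i] - start[i], end[j] - start[j]) + 1
    ov <= 0.5 * shorter
  }
  best <- 0L
  for (k in n:1) {
    for (sel in utils::combn(n, k, simplify = FALSE)) {
      pairs_ok <- TRUE
      if (k > 1) {
        for (a in 1:(k - 1)) for (b in (a + 1):k) {
          if (!compatible(sel[a], sel[b])) { pairs_ok <- FALSE; break }
        }
      }
      if (pairs_ok) return(k)
    }
  }
  best
}

# The 41 family/subfamily labels of the seven-algae comparison table.
algal_family_labels <- function() {
  c("ABI3/VP1", "AP2", "ERF", "bHLH", "bZIP", "C2C2-CO-like", "C2C2-Dof",
    "C2C2-GATA", "C2C2-LSD", "C2H2", "C3H", "CCAAT", "CPP", "CSD", "DBB",
    "E2F/DP", "Fungal TRF", "GARP-G2-like", "GARP-ARR-B", "HB-other",
    "TALE", "HSF", "LIM", "M-type", "mTERF", "MYB (3R)", "MYB (2R)",
    "MYB-rel", "MYB-SHAQKYF", "NF-X1", "NF-YA", "NF-YB", "NF-YC",
    "Nin-like", "S1Fa-like", "SBP", "Sigma-70", "TUB", "VARL", "Whirly",
    "WRKY")
}

# Run the full pipeline on generated evidence files (in-memory variant of
# run_classify, used where tests need intermediate objects).
run_synthetic_pipeline <- function(synth, ev, ruleset = RS, blast = TRUE,
                                   require_dbd = FALSE) {
  thr <- filter_thresholds()
  blast_best <- if (blast) filter_blast(read_blast_tab(ev$files$blast), thr) else NULL
  ipr <- filter_interpro(read_interproscan_tsv(ev$files$interpro), thr,
                         ruleset$dbd_catalog,
                         relaxed_accessions = ruleset$relaxed_accessions)
  hmm <- filter_hmmer(read_domtblout(ev$files$domtblout), thr)
  bundles <- merge_evidence(synth$proteome, blast_best, ipr, hmm)
  classify_proteome(bundles, ruleset, proteome = synth$proteome,
                    require_dbd = require_dbd)
}

truth_labels <- function(synth) setNames(synth$truth$label, synth$truth$protein_id)

# Independent half-up display rounding (positive values).
half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

# Independent two-decimal truncation (the published accuracy tables'
# display convention: a ratio below 1 never prints as 1).
trunc2 <- function(x) floor(x * 100) / 100
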