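# Rule loading, copy counting and family classification.

test_that("bundled rule set covers the comparative and cyanobacterial families", {
  expect_true(all(algal_family_labels() %in% RS$labels))       # 41 rows
  cyano <- c("arsR", "Bac_DNA_binding", "BolA", "GerE", "LysR", "SfsA",
             "Crp", "GntR", "FUR")
  expect_true(all(cyano %in% RS$labels))
  expect_true("Fungal TRF" %in% RS$labels)
  expect_true(all(vapply(RS$rules, function(r) length(r$required) > 0, TRUE)))
  pri <- vapply(RS$rules, `[[`, integer(1), "priority")
  expect_false(any(duplicated(pri)))
})

test_that("rules file validation rejects duplicates, empty sets and priority ties", {
  header <- "label\tfamily\tsubfamily\trequired\tmin_copies\tforbidden\tpriority\trelax\tmotif"
  write_rules <- function(rows) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(header, rows), f)
    f
  }
  dup <- write_rules(c("bZIP\tbZIP\t\tPF00170\t\t\t10\t0\t",
                       "bZIP\tbZIP\t\tPF07716\t\t\t11\t0\t"))
  expect_error(load_rules(dup), "duplicate family label")

  noreq <- write_rules("bZIP\tbZIP\t\t\t\t\t10\t0\t")
  expect_error(load_rules(noreq), "empty required set")

  ties <- write_rules(c("bZIP\tbZIP\t\tPF00170\t\t\t10\t0\t",
                        "HSF\tHSF\t\tPF00447\t\t\t10\t0\t"))
  expect_error(load_rules(ties), "priority tie")
})

test_that("count_copies counts non-overlapping instances and matches brute force", {
  h <- function(s, e) make_hits("p", rep("PF00847", length(s)), s, e)
  expect_equal(count_copies(h(c(10, 100), c(60, 150)), "PF00847"), 2L)
  expect_equal(count_copies(h(c(10, 15), c(60, 65)), "PF00847"), 1L)

  chain <- h(c(10, 55, 120), c(60, 110, 170))
  expect_equal(count_copies(chain, "PF00847"),
               brute_force_copies(c(10, 55, 120), c(60, 110, 170)))

  # random architectures: greedy never exceeds the brute-force optimum and
  # adding a disjoint instance never decreases the count
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    s <- sort(sample(1:300, n))
    e <- s + sample(20:80, n, replace = TRUE)
    cc <- count_copies(h(s, e), "PF00847")
    expect_lte(cc, brute_force_copies(s, e))
    expect_gte(cc, 1L)
    far <- max(e) + 100
    expect_gte(count_copies(h(c(s, far), c(e, far + 50)), "PF00847"), cc)
  }
})

test_that("copy-number rules separate AP2 from ERF and gate DBB", {
  two_ap2 <- make_bundle("t1", make_hits("t1", c("PF00847", "PF00847"),
                                         c(10, 100), c(60, 150)))
  a <- classify_protein(two_ap2, RS)
  expect_equal(a$family, "AP2/ERF")
  expect_equal(a$subfamily, "AP2")
  expect_match(a$curation_flags, "copy_number_checked")

  one_ap2 <- make_bundle("t2", make_hits("t2", "PF00847", 10, 60))
  expect_equal(classify_protein(one_ap2, RS)$label, "ERF")

  one_bbox <- make_bundle("t3", make_hits("t3", "PF00643", 10, 60))
  expect_false(identical(classify_protein(one_bbox, RS)$label, "DBB"))
  two_bbox <- make_bundle("t4", make_hits("t4", c("PF00643", "PF00643"),
                                          c(10, 100), c(60, 150)))
  expect_equal(classify_protein(two_bbox, RS)$label, "DBB")
})

test_that("NF-Y subunit assignments are mutually exclusive", {
  nfyb <- make_bundle("n1", make_hits("n1", "CUST_NFYB", 10, 60,
                                      source = "hmmer_custom"))
  nfyc <- make_bundle("n2", make_hits("n2", "CUST_NFYC", 10, 60,
                                      source = "hmmer_custom"))
  both <- make_bundle("n3", make_hits("n3", c("CUST_NFYB", "CUST_NFYC"),
                                      c(10, 100), c(60, 150),
                                      source = "hmmer_custom"))
  labels <- vapply(list(nfyb, nfyc, both),
                   function(b) classify_protein(b, RS)$label, character(1))
  expect_equal(labels[1:2], c("NF-YB", "NF-YC"))
  expect_false(labels[3] %in% c("NF-YB", "NF-YC"))   # contradictory evidence
})

test_that("MYB repeat count decides the class; SHAQKYF motif reclassifies", {
  reps3 <- make_bundle("m1", make_hits("m1", rep("PF00249", 3),
                                       c(10, 80, 150), c(60, 130, 200)))
  expect_equal(classify_myb(reps3, RS)$label, "MYB (3R)")
  expect_equal(classify_myb(make_bundle("m2", make_hits("m2", rep("PF00249", 2),
                                                        c(10, 80), c(60, 130))),
                            RS)$label, "MYB (2R)")

  one <- make_bundle("m3", make_hits("m3", "PF00249", 10, 60))
  plain_seq <- strrep("A", 100)
  expect_equal(classify_myb(one, RS, sequence = plain_seq)$label, "MYB-rel")

  motif_seq <- paste0(strrep("A", 20), "SHAQKY", strrep("A", 74))
  a <- classify_myb(one, RS, sequence = motif_seq)
  expect_equal(a$label, "MYB-SHAQKYF")
  expect_match(a$curation_flags, "shaqkyf_motif")
  # independent check: the motif really is inside the repeat subsequence
  expect_true(grepl("SH[AL]QK[YF]", substr(motif_seq, 10, 60), perl = TRUE))
  expect_false(grepl("SH[AL]QK[YF]", substr(plain_seq, 10, 60), perl = TRUE))

  # relaxed-path flag propagates from filtering
  relaxed <- make_bundle("m4", make_hits("m4", "PF00249", 10, 60,
                                         evalue = 0.5, relaxed = TRUE))
  expect_match(classify_myb(relaxed, RS, sequence = plain_seq)$curation_flags,
               "myb_relaxed_path")
})

test_that("G2-like cross-annotation is resolved by the higher profile score", {
  seq_motif <- paste0(strrep("A", 20), "SHAQKY", strrep("A", 200))
  mk <- function(id, g2_score, myb_score) {
    hits <- rbind(
      make_hits(id, "PF00249", 21, 80, score = myb_score),
      make_hits(id, "CUST_G2LIKE", 100, 150, score = g2_score,
                source = "hmmer_custom"))
    make_bundle(id, hits)
  }
  b1 <- mk("g1", 40, 25); b2 <- mk("g2", 25, 40)
  bundles <- list(g1 = b1, g2 = b2)
  proteome <- data.frame(protein_id = c("g1", "g2"), sequence = seq_motif,
                         length = nchar(seq_motif))
  a <- classify_proteome(bundles, RS, proteome = proteome)
  expect_equal(a$label[a$protein_id == "g1"], "GARP-G2-like")
  expect_equal(a$label[a$protein_id == "g2"], "MYB-SHAQKYF")
  expect_true(all(grepl("g2like_crosscheck", a$curation_flags)))

  # only one of the two signals present: assignment unchanged, no flag
  only_myb <- make_bundle("g3", make_hits("g3", "PF00249", 21, 80, score = 25))
  a3 <- classify_proteome(list(g3 = only_myb), RS,
                          proteome = data.frame(protein_id = "g3",
                                                sequence = seq_motif,
                                                length = nchar(seq_motif)))
  expect_equal(a3$label, "MYB-SHAQKYF")
  expect_false(grepl("g2like_crosscheck", a3$curation_flags))
})

test_that("BLAST-only candidates inherit the subject family unless strict", {
  b <- make_bundle("b1", best_blast = make_blast_row("b1", "bZIP|ref1"))
  expect_equal(classify_protein(b, RS)$label, "bZIP")
  expect_equal(classify_protein(b, RS, require_dbd = TRUE)$label, "unclassified")
  unknown <- make_bundle("b2", best_blast = make_blast_row("b2", "NOFAM|x"))
  expect_equal(classify_protein(unknown, RS)$label, "unclassified")
})

test_that("proteome classification is exhaustive, pure and order-independent", {
  synth <- generate_proteome(n_per_family = 2, seed = 17)
  ev <- generate_evidence(synth, noise_model(seed = 17))
  ipr <- filter_interpro(read_interproscan_tsv(ev$files$interpro),
                         filter_thresholds(), RS$dbd_catalog,
                         relaxed_accessions = RS$relaxed_accessions)
  hmm <- filter_hmmer(read_domtblout(ev$files$domtblout), filter_thresholds())
  bundles <- merge_evidence(synth$proteome, NULL, ipr, hmm)
  a1 <- classify_proteome(bundles, RS, proteome = synth$proteome)
  expect_equal(nrow(a1), length(bundles))       # exactly one row per bundle
  a2 <- classify_proteome(rev(bundles), RS, proteome = synth$proteome)
  expect_identical(a1, a2)
  expect_identical(a1, classify_proteome(bundles, RS, proteome = synth$proteome))

  expect_equal(nrow(classify_proteome(list(), RS)), 0L)
})
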