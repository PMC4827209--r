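# Count/proportion tables, presence/absence dendrogram, family clustering
# and the MYB-SHAQKYF ratio.

test_that("count_table counts assignments per species and excludes unclassified", {
  a <- data.frame(protein_id = c("a", "b", "c", "d"),
                  label = c("bZIP", "bZIP", "HSF", "unclassified"))
  tab <- count_table(list(spX = a))
  expect_equal(tab$counts["spX", "bZIP"], 2)
  expect_equal(tab$counts["spX", "HSF"], 1)
  expect_equal(unname(tab$totals["spX"]), 3)

  empty <- count_table(list(spX = a[0, ]))
  expect_equal(sum(empty$counts), 0)

  bad <- data.frame(protein_id = "a", label = "NotAFamily")
  expect_error(count_table(list(spX = bad), ruleset = RS), "NotAFamily")
})

test_that("bundled seven-algae table carries the published counts and totals", {
  tab <- algal_tf_counts()
  expect_equal(length(tab$species), 7L)
  expect_equal(length(tab$families), 41L)
  expect_equal(unname(tab$totals["Phaeodactylum tricornutum"]), 196)
  expect_equal(unname(tab$totals["Tisochrysis lutea"]), 155)
  expect_equal(tab$counts["Emiliania huxleyi", "ERF"], 99)
})

test_that("proportions reproduce the published percentages", {
  tab <- algal_tf_counts()
  prop <- proportions(tab)
  expect_equal(prop$display["Tisochrysis lutea", "Fungal TRF"], 9.03)
  expect_equal(prop$display["Phaeodactylum tricornutum", "HSF"], 34.18)
  expect_equal(half_up(prop$values["Phaeodactylum tricornutum", "HSF"], 1), 34.2)
  expect_equal(half_up(prop$values["Porphyridium purpureum", "C2H2"], 1), 30.2)
  expect_equal(half_up(prop$values["Phaeodactylum tricornutum", "bZIP"], 1), 12.8)
  # a zero count is exactly 0
  expect_equal(prop$display["Chlamydomonas reinhardtii", "Fungal TRF"], 0)
})

test_that("per-species proportions sum to 100 when totals are the row sums", {
  a <- data.frame(protein_id = sprintf("p%d", 1:7),
                  label = c("bZIP", "bZIP", "HSF", "WRKY", "WRKY", "WRKY", "ERF"))
  prop <- proportions(count_table(list(s1 = a)))
  expect_equal(unname(rowSums(prop$values)), 100)
  expect_lt(abs(sum(prop$display) - 100), 0.5)

  zero <- tf_count_table(matrix(0, 1, 2, dimnames = list("s0", c("A", "B"))))
  expect_error(proportions(zero), "s0")
})

test_that("combined percentages behave as weighted unions", {
  tab <- algal_tf_counts()
  ehux_ap2erf <- combined_percentage(tab, "Emiliania huxleyi", c("AP2", "ERF"))
  expect_equal(half_up(ehux_ap2erf, 1), 32.8)
  expect_equal(half_up(ehux_ap2erf, 0), 33)
  expect_equal(combined_percentage(tab, "Tisochrysis lutea", tab$families), 100)
  prop <- proportions(tab)
  expect_equal(combined_percentage(tab, "Tisochrysis lutea", "HSF"),
               prop$values["Tisochrysis lutea", "HSF"])
  expect_error(combined_percentage(tab, "Tisochrysis lutea", character(0)),
               "non-empty")
})

test_that("SHAQKYF ratio uses the union denominator", {
  tab <- algal_tf_counts()
  expect_equal(half_up(shaqkyf_ratio(tab, "Porphyridium purpureum"), 1), 69.6)
  expect_equal(half_up(shaqkyf_ratio(tab, "Nannochloropsis gaditana"), 1), 53.3)
  expect_equal(shaqkyf_ratio(tab, "Phaeodactylum tricornutum"), 50)

  m <- matrix(c(0, 0, 5, 0), 2, 2,
              dimnames = list(c("s1", "s2"), c("MYB-SHAQKYF", "MYB-rel")))
  small <- tf_count_table(m)
  expect_equal(shaqkyf_ratio(small, "s1"), 0)       # no SHAQKYF, some MYB-rel
  expect_true(is.na(shaqkyf_ratio(small, "s2")))    # both absent: undefined
})

test_that("presence/absence is an indicator and order-invariant", {
  m <- matrix(c(0, 3, 1), 1, 3, dimnames = list("s", c("A", "B", "C")))
  expect_equal(unname(unclass(presence_absence(tf_count_table(m)))[1, ]), c(0, 1, 1))

  tab <- algal_tf_counts()
  pres <- presence_absence(tab)
  # 38 nonzero family rows for the chlorophyte; 37 distinct families once
  # the two AP2/ERF subfamily rows are collapsed to their superfamily
  crei <- unclass(pres)["Chlamydomonas reinhardtii", ]
  expect_equal(sum(crei), 38)
  expect_equal(sum(crei) - (crei[["AP2"]] & crei[["ERF"]]), 37)

  a <- data.frame(protein_id = c("a", "b", "c"), label = c("bZIP", "HSF", "bZIP"))
  p1 <- presence_absence(count_table(list(s = a)))
  p2 <- presence_absence(count_table(list(s = a[c(3, 1, 2), ])))
  expect_identical(p1, p2)
})

test_that("dendrogram reproduces the lineage topology of the seven algae", {
  tab <- algal_tf_counts()
  dend <- tf_dendrogram(presence_absence(tab))
  phy <- dend$phylo
  expect_setequal(phy$tip.label, gsub(" ", "_", tab$species))
  # the two coccolithophore-line haptophytes are sisters...
  expect_true(ape::is.monophyletic(phy, c("Tisochrysis_lutea", "Emiliania_huxleyi")))
  # ...within a clade of the three haptophytes
  expect_true(ape::is.monophyletic(
    phy, c("Tisochrysis_lutea", "Emiliania_huxleyi", "Pavlova_sp.")))
  # the chlorophyte splits off first: all other species form one clade
  expect_true(ape::is.monophyletic(
    phy, setdiff(gsub(" ", "_", tab$species), "Chlamydomonas_reinhardtii")))
  # ultrametric merge heights never decrease toward the root
  expect_true(all(diff(dend$hclust$height) >= 0))

  two <- tf_count_table(matrix(c(1, 1, 0, 0), 2, 2,
                               dimnames = list(c("x", "y"), c("A", "B"))))
  d2 <- tf_dendrogram(presence_absence(two))
  expect_equal(max(d2$hclust$height), 0)            # identical rows merge at 0
  expect_error(tf_dendrogram(matrix(1, 1, 2, dimnames = list("only", c("A", "B")))),
               "at least 2")
})

test_that("family clustering co-clusters the green-lineage families at k = 4", {
  prop <- proportions(algal_tf_counts())
  cl <- family_clusters(prop, k = 4)
  green <- c("SBP", "VARL", "Whirly", "WRKY", "S1Fa-like", "NF-X1",
             "C2C2-CO-like", "C2C2-Dof", "GARP-ARR-B")
  expect_equal(length(unique(cl[green])), 1L)

  # degenerate cuts
  expect_equal(length(unique(family_clusters(prop, k = length(prop$families)))),
               length(prop$families))
  m <- matrix(c(10, 10, 50, 90, 90, 50), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  p2 <- proportions(tf_count_table(m))
  cl2 <- family_clusters(p2, k = 2)
  expect_equal(cl2[["A"]], cl2[["B"]])              # identical proportion vectors
  expect_error(family_clusters(p2, k = 5), "exceeds")
})
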