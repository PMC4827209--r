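# Comparative layer: species x family count/proportion tables,
# presence/absence dendrograms, proportion-based family clustering and
# MYB-SHAQKYF ratios.

#' Construct a species x family TF count table
#'
#' @param counts Non-negative integer matrix, species in rows, families in
#'   columns, with dimnames.
#' @param totals Optional named per-species totals. By default totals are
#'   the row sums; published tables occasionally print a total that
#'   differs from the sum of the printed per-family counts (e.g. by a
#'   single-cell typo), and an explicit `totals` keeps the published
#'   denominators in that case.
#' @return An object of class `tf_count_table` with elements `species`,
#'   `families`, `counts` and `totals`.
#' @export
tf_count_table <- function(counts, totals = NULL) {
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have species row names and family column names", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  computed <- rowSums(counts)
  if (is.null(totals)) {
    totals <- computed
  } else {
    totals <- totals[rownames(counts)]
    if (anyNA(totals)) stop("totals must name every species", call. = FALSE)
  }
  structure(list(species = rownames(counts), families = colnames(counts),
                 counts = counts, totals = totals),
            class = "tf_count_table")
}

#' @export
print.tf_count_table <- function(x, ...) {
  cat(sprintf("TF count table: %d species x %d families; totals: %s\n",
              length(x$species), length(x$families),
              paste(sprintf("%s=%d", x$species, x$totals), collapse = ", ")))
  invisible(x)
}

#' Build a TF count table from per-species assignments
#'
#' Counts proteins per family label and species. `"unclassified"` records
#' are excluded from counts and totals. When a rule set is supplied, any
#' assignment label not present in it is an error.
#'
#' @param assignments_by_species Named list of assignment data.frames
#'   (one per species), as produced by [classify_proteome()].
#' @param ruleset Optional `tf_ruleset` used to validate labels and order
#'   the family columns.
#' @return A `tf_count_table`.
#' @export
count_table <- function(assignments_by_species, ruleset = NULL) {
  if (is.null(names(assignments_by_species)) ||
      any(!nzchar(names(assignments_by_species)))) {
    stop("assignments_by_species must be a named list (names are species)", call. = FALSE)
  }
  labs <- lapply(assignments_by_species, function(a) {
    l <- a$label %||% a$family
    l[l != "unclassified"]
  })
  fams <- sort(unique(unlist(labs)))
  if (!is.null(ruleset)) {
    unknown <- setdiff(fams, ruleset$labels)
    if (length(unknown) > 0) {
      stop("unknown family label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    fams <- intersect(ruleset$labels, fams)
  }
  counts <- matrix(0, nrow = length(labs), ncol = length(fams),
                   dimnames = list(names(labs), fams))
  for (s in names(labs)) {
    tab <- table(factor(labs[[s]], levels = fams))
    counts[s, ] <- as.numeric(tab)
  }
  tf_count_table(counts)
}

check_species <- function(table, species) {
  if (!species %in% table$species) {
    stop("unknown species: ", species, call. = FALSE)
  }
}

#' Per-species family proportions (percent)
#'
#' Converts counts to percentages of each species' TF complement:
#' `100 * count / total`. Raw values are retained; a display copy is
#' rounded half-up to `decimals` places. Per-species proportions sum to
#' 100 within rounding tolerance.
#'
#' @param table A `tf_count_table`.
#' @param decimals Display rounding (default 2).
#' @return An object of class `tf_proportion_table` with elements
#'   `species`, `families`, `values` (raw), `display` (rounded) and
#'   `totals`.
#' @export
proportions <- function(table, decimals = 2) {
  stopifnot(inherits(table, "tf_count_table"))
  if (any(table$totals <= 0)) {
    stop("zero TF total for species: ",
         paste(table$species[table$totals <= 0], collapse = ", "), call. = FALSE)
  }
  values <- 100 * sweep(table$counts, 1, table$totals, "/")
  structure(list(species = table$species, families = table$families,
                 values = values, display = round_half_up(values, decimals),
                 totals = table$totals),
            class = "tf_proportion_table")
}

#' Combined percentage of a family group
#'
#' Percentage of a species' TF complement contributed by a set of family
#' columns together, e.g. the two subfamilies of a superfamily.
#'
#' @param table A `tf_count_table`.
#' @param species Species name.
#' @param family_group Non-empty character vector of family columns.
#' @return `100 * sum(counts[species, family_group]) / total[species]`.
#' @export
combined_percentage <- function(table, species, family_group) {
  stopifnot(inherits(table, "tf_count_table"))
  check_species(table, species)
  if (length(family_group) == 0) stop("family_group must be non-empty", call. = FALSE)
  unknown <- setdiff(family_group, table$families)
  if (length(unknown) > 0) {
    stop("unknown family name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (table$totals[[species]] <= 0) stop("zero TF total for species: ", species, call. = FALSE)
  100 * sum(table$counts[species, family_group]) / table$totals[[species]]
}

#' MYB-SHAQKYF share of the MYB-related complement
#'
#' Percentage of MYB-SHAQKYF among MYB-related TFs, using the union
#' denominator: `100 * SHAQKYF / (SHAQKYF + MYB-rel)`. Undefined (both
#' counts zero) is `NA`.
#'
#' @param table A `tf_count_table` containing `MYB-rel` and `MYB-SHAQKYF`
#'   columns.
#' @param species Species name.
#' @param shaqkyf,myb_rel Column names of the two classes.
#' @return Percentage, or `NA` when both counts are zero.
#' @export
shaqkyf_ratio <- function(table, species, shaqkyf = "MYB-SHAQKYF",
                          myb_rel = "MYB-rel") {
  stopifnot(inherits(table, "tf_count_table"))
  check_species(table, species)
  missing <- setdiff(c(shaqkyf, myb_rel), table$families)
  if (length(missing) > 0) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  s <- table$counts[species, shaqkyf]
  r <- table$counts[species, myb_rel]
  if (s + r == 0) return(NA_real_)
  100 * s / (s + r)
}

#' Presence/absence matrix of TF families
#'
#' Binary indicator of `count > 0` per species and family row. Rows of the
#' count table are taken at the (sub)family level at which the table was
#' built.
#'
#' @param table A `tf_count_table`.
#' @return A binary matrix (class `tf_presence_matrix`), species in rows.
#' @export
presence_absence <- function(table) {
  stopifnot(inherits(table, "tf_count_table"))
  m <- (table$counts > 0) * 1
  class(m) <- c("tf_presence_matrix", class(m))
  m
}

#' Hierarchical dendrogram of species from family presence/absence
#'
#' Agglomerative clustering of species rows of a presence/absence matrix
#' under a configurable distance and linkage (defaults: Euclidean distance
#' on the 0/1 rows, complete linkage). Deterministic given its inputs. The
#' tree is also exported as a Newick string with branch lengths derived
#' from merge heights.
#'
#' @param presence A `tf_presence_matrix` (or any numeric matrix with >= 2
#'   rows and species row names).
#' @param metric Distance measure passed to [stats::dist()] (e.g.
#'   `"euclidean"`, `"binary"` for Jaccard).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list of class `tf_dendrogram` with elements `hclust`, `phylo`
#'   (an [ape::as.phylo()] tree) and `newick`.
#' @export
tf_dendrogram <- function(presence, metric = "euclidean", linkage = "complete") {
  m <- unclass(presence)
  if (nrow(m) < 2) stop("dendrogram requires at least 2 species", call. = FALSE)
  hc <- hclust(dist(m, method = metric), method = linkage)
  phy <- ape::as.phylo(hc)
  # spaces are not legal in unquoted Newick labels; normalize once so the
  # phylo object and the Newick string agree
  phy$tip.label <- gsub(" ", "_", phy$tip.label)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)),
            class = "tf_dendrogram")
}

#' @export
print.tf_dendrogram <- function(x, ...) {
  cat("TF presence/absence dendrogram:\n", x$newick, "\n")
  invisible(x)
}

#' Cluster TF families by their cross-species proportions
#'
#' Hierarchical clustering of family rows of a proportion table, cut at
#' `k` clusters. Defaults follow the dendrogram conventions (Euclidean
#' distance on raw proportion vectors, complete linkage); rows can be
#' standardized first with `scale_rows = TRUE`.
#'
#' @param proportion_table A `tf_proportion_table` from [proportions()].
#' @param k Number of clusters (>= 2, at most the number of families).
#' @param metric,linkage Distance and agglomeration method.
#' @param scale_rows Standardize each family row to zero mean / unit
#'   variance before clustering.
#' @return Named integer vector mapping family to cluster id (1..k).
#' @export
family_clusters <- function(proportion_table, k = 4, metric = "euclidean",
                            linkage = "complete", scale_rows = FALSE) {
  stopifnot(inherits(proportion_table, "tf_proportion_table"))
  m <- t(proportion_table$values)   # families in rows
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(m)) stop("k exceeds the number of families", call. = FALSE)
  if (scale_rows) {
    m <- t(scale(t(m)))
    m[!is.finite(m)] <- 0
  }
  hc <- hclust(dist(m, method = metric), method = linkage)
  cutree(hc, k = k)
}

#' Published TF counts for seven microalgae
#'
#' Loads the bundled species x family TF count table for seven microalgae
#' (three haptophytes, two stramenopiles, one rhodophyte, one
#' chlorophyte), the substrate of the comparative operations. Totals are
#' the published per-species totals: for *Porphyridium purpureum* the
#' printed per-family counts sum to 198 while the published total (against
#' which every printed percentage back-computes) is 199, so the published
#' totals are carried explicitly.
#'
#' @return A `tf_count_table` of 7 species x 41 family rows.
#' @export
algal_tf_counts <- function() {
  path <- system.file("extdata", "algal_tf_counts.tsv", package = "phycotf",
                      mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fams <- df[[1]][df[[1]] != "Total"]
  m <- as.matrix(df[df[[1]] != "Total", -1, drop = FALSE])
  rownames(m) <- fams
  totals <- unlist(df[df[[1]] == "Total", -1, drop = TRUE])
  tf_count_table(t(m), totals = totals)
}
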