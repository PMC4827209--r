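# Accuracy evaluation against a gold standard: per-family confusion
# counts, sensitivity and positive predictive value.

normalize_labels <- function(x, what) {
  if (is.data.frame(x)) {
    fam_col <- intersect(c("label", "family"), names(x))[1]
    if (is.na(fam_col) || is.null(x$protein_id)) {
      stop(what, " must have columns protein_id and label/family", call. = FALSE)
    }
    out <- setNames(as.character(x[[fam_col]]), x$protein_id)
  } else {
    out <- x
  }
  if (length(out) == 0) return(setNames(character(0), character(0)))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop(what, " must be a named vector protein_id -> family", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop(what, " labels each protein id at most once", call. = FALSE)
  }
  out[out != "unclassified"]
}

#' Read a gold-standard label table
#'
#' Two-column TSV (`protein_id`, `family`), each protein labeled at most
#' once.
#'
#' @param path Path to the TSV (header required).
#' @return Named character vector protein_id -> family.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("gold standard file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  normalize_labels(df, "gold standard")
}

#' Per-family confusion counts
#'
#' For one family: true positives are ids assigned to the family in both
#' prediction and gold standard; false positives are assigned but not gold;
#' false negatives are gold but not assigned.
#'
#' @param predicted,gold Assignment data.frames (columns `protein_id` and
#'   `label`/`family`) or named character vectors protein_id -> family.
#'   `"unclassified"` records are ignored.
#' @param family Family name to evaluate.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusion_counts <- function(predicted, gold, family) {
  p <- normalize_labels(predicted, "predicted")
  g <- normalize_labels(gold, "gold")
  pset <- names(p)[p == family]
  gset <- names(g)[g == family]
  c(tp = length(intersect(pset, gset)),
    fp = length(setdiff(pset, gset)),
    fn = length(setdiff(gset, pset)))
}

#' Sensitivity: TP / (TP + FN)
#'
#' The fraction of gold-standard members recovered. A value below one
#' means false negatives were included. Undefined (no gold members) is
#' reported as `NA`, never 0 or 1.
#'
#' @param tp,fn Non-negative counts.
#' @return `tp / (tp + fn)`, or `NA` when `tp + fn == 0`.
#' @export
sensitivity <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be non-negative", call. = FALSE)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Positive predictive value: TP / (TP + FP)
#'
#' The fraction of predictions that are correct. A value below one means
#' false positives were included. Undefined (no predictions) is reported
#' as `NA`.
#'
#' @param tp,fp Non-negative counts.
#' @return `tp / (tp + fp)`, or `NA` when `tp + fp == 0`.
#' @export
ppv <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative", call. = FALSE)
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Per-family accuracy report
#'
#' One row per requested family with confusion counts, raw sensitivity and
#' PPV, and display columns: the `tp/total` fractions and the ratios shown
#' to two decimals, truncated toward zero. Truncation (rather than
#' rounding to nearest) keeps the display faithful to the ratios'
#' semantics: a sensitivity or PPV below one flags included false
#' negatives/positives, so 224/225 must display as 0.99, never as 1. Raw
#' ratios are retained in the machine-readable columns.
#'
#' @inheritParams confusion_counts
#' @param families Families to evaluate; defaults to the union of gold and
#'   predicted family names (sorted).
#' @return A data.frame with columns `family`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `sensitivity_fraction`, `ppv_fraction`,
#'   `sensitivity_display`, `ppv_display`.
#' @export
benchmark_report <- function(predicted, gold, families = NULL) {
  p <- normalize_labels(predicted, "predicted")
  g <- normalize_labels(gold, "gold")
  families <- families %||% sort(union(unique(p), unique(g)))
  rows <- lapply(families, function(fam) {
    cc <- confusion_counts(p, g, fam)
    sens <- sensitivity(cc[["tp"]], cc[["fn"]])
    prec <- ppv(cc[["tp"]], cc[["fp"]])
    data.frame(
      family = fam, tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]],
      sensitivity = sens, ppv = prec,
      sensitivity_fraction = sprintf("%d/%d", cc[["tp"]], cc[["tp"]] + cc[["fn"]]),
      ppv_fraction = sprintf("%d/%d", cc[["tp"]], cc[["tp"]] + cc[["fp"]]),
      sensitivity_display = ifelse(is.na(sens), "NA",
                                   format(floor(sens * 100) / 100, nsmall = 0)),
      ppv_display = ifelse(is.na(prec), "NA",
                           format(floor(prec * 100) / 100, nsmall = 0)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows) %||%
    data.frame(family = character(0), tp = integer(0), fp = integer(0),
               fn = integer(0), sensitivity = numeric(0), ppv = numeric(0),
               sensitivity_fraction = character(0), ppv_fraction = character(0),
               sensitivity_display = character(0), ppv_display = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a benchmark report as TSV
#' @param path Output path.
#' @param report Data.frame from [benchmark_report()].
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(path, report) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
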