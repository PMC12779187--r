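# FeatureTable construction and accessors. Rows are features tagged with
# their modality group (IOS / AE / Land); columns are subjects with binary
# extraction labels.

#' Assemble a FeatureTable from per-group feature matrices
#'
#' @param ios,ae,land optional subjects x features matrices (equal row
#'   counts; rownames, when present, must agree).
#' @param labels integer 0/1 vector, one per subject (1 = extraction).
#' @param subject_ids optional ids; defaults to matrix rownames or S0001-style
#'   ids.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(ios = NULL, ae = NULL, land = NULL, labels,
                         subject_ids = NULL) {
  blocks <- list(IOS = ios, AE = ae, Land = land)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0) .stopf("at least one feature group is required")
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) .stopf("feature groups have differing subject counts")
  if (length(labels) != n) .stopf("labels length (%d) != subjects (%d)",
                                  length(labels), n)
  if (is.null(subject_ids)) {
    rn <- lapply(blocks, rownames)
    rn <- rn[!vapply(rn, is.null, logical(1))]
    subject_ids <- if (length(rn)) rn[[1]] else sprintf("S%04d", seq_len(n))
  }
  mats <- lapply(names(blocks), function(g) {
    m <- t(as.matrix(blocks[[g]]))
    rownames(m) <- paste0(g, ".", if (!is.null(colnames(blocks[[g]])))
      colnames(blocks[[g]]) else seq_len(nrow(m)))
    m
  })
  assay <- do.call(rbind, mats)
  colnames(assay) <- subject_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    rowData = S4Vectors::DataFrame(
      group = rep(names(blocks), vapply(mats, nrow, integer(1)))),
    colData = S4Vectors::DataFrame(label = as.integer(labels),
                                   row.names = subject_ids))
  new("FeatureTable", se)
}

#' @describeIn featureTable feature-group tag of every feature row.
#' @param x a `FeatureTable`.
#' @export
featureGroups <- function(x) SummarizedExperiment::rowData(x)$group

#' @describeIn featureTable binary subject labels, named by subject id.
#' @export
subjectLabels <- function(x)
  stats::setNames(SummarizedExperiment::colData(x)$label, colnames(x))

#' @describeIn featureTable subjects x features matrix for selected groups.
#' @param groups feature groups to keep (default: all present).
#' @export
featureMatrix <- function(x, groups = unique(featureGroups(x))) {
  keep <- featureGroups(x) %in% groups
  if (!any(keep)) .stopf("no features in groups {%s}",
                         paste(groups, collapse = ", "))
  t(SummarizedExperiment::assay(x)[keep, , drop = FALSE])
}
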