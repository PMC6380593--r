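#' Construct and validate an expression compendium
#'
#' An `ExpressionCompendium` bundles a samples-by-genes expression matrix
#' with per-sample annotation: the study each sample came from, its survival
#' time in years, the event indicator, and the derived dichotomous outcome.
#' It is the substrate of all pair scoring, network inference and
#' classification in this package.
#'
#' The outcome label dichotomizes survival at a threshold (5 years by
#' default): `"poor"` if the event occurred before the threshold, `"good"`
#' if the sample survived past it, and `"excluded"` if it was censored
#' before the threshold (its 5-year status is unknowable). Excluded samples
#' are dropped from training and from AUC evaluation.
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   complete dimnames. No missing values.
#' @param samples data.frame with columns `sample_id`, `study`,
#'   `survival_time` (years), `event` (1 = occurred, 0 = censored), and
#'   optionally `rfs_time`/`rfs_event` (recurrence-free survival, preferred
#'   for labelling when present).
#' @param outcome_threshold years at which survival is dichotomized.
#' @return an object of class `ExpressionCompendium`.
#' @export
new_compendium <- function(values, samples, outcome_threshold = 5) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids as rownames and gene symbols as colnames")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', gene '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene symbols in expression matrix")
  req <- c("sample_id", "study", "survival_time", "event")
  if (!all(req %in% names(samples)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in annotation")
  missing_ann <- setdiff(rownames(values), samples$sample_id)
  if (length(missing_ann))
    stop("samples missing from annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$study <- as.character(samples$study)
  if (any(samples$survival_time < 0)) stop("negative survival time")

  # recurrence-free survival takes precedence for labelling when available
  has_rfs <- all(c("rfs_time", "rfs_event") %in% names(samples)) &&
    !anyNA(samples$rfs_time) && !anyNA(samples$rfs_event)
  lab_time  <- if (has_rfs) samples$rfs_time  else samples$survival_time
  lab_event <- if (has_rfs) samples$rfs_event else samples$event
  samples$outcome <- derive_outcome(lab_time, lab_event, outcome_threshold)

  structure(list(values = values, samples = samples,
                 outcome_threshold = outcome_threshold),
            class = "ExpressionCompendium")
}

#' @export
print.ExpressionCompendium <- function(x, ...) {
  cat(sprintf("ExpressionCompendium: %d samples x %d genes, %d studies\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$study))))
  cat("outcome: ", paste(sprintf("%s=%d", names(table(x$samples$outcome)),
                                 as.integer(table(x$samples$outcome))),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dichotomize survival at a year threshold
#'
#' @param time non-negative survival times in years.
#' @param event 1 if the event occurred, 0 if censored (logical also
#'   accepted).
#' @param threshold dichotomization point in years (default 5).
#' @return character vector in `{"good", "poor", "excluded"}`: `poor` if the
#'   event occurred before the threshold, `good` if follow-up (event or
#'   censoring) reached the threshold, `excluded` if censored before it.
#' @export
derive_outcome <- function(time, event, threshold = 5) {
  if (any(time < 0)) stop("negative survival time")
  event <- as.integer(event)
  out <- ifelse(time >= threshold, "good",
                ifelse(event == 1L, "poor", "excluded"))
  out
}

#' Genes of a compendium
#' @param c an ExpressionCompendium.
#' @return character vector of gene symbols, in matrix column order.
#' @export
compendium_genes <- function(c) colnames(c$values)

#' Usable (non-excluded) sample indices
#' @param c an ExpressionCompendium.
#' @return integer indices of samples whose outcome is good or poor.
#' @export
usable_samples <- function(c) which(c$samples$outcome != "excluded")

#' Subset a compendium by sample index or by study
#'
#' @param c an ExpressionCompendium.
#' @param samples integer or logical sample index, or NULL.
#' @param studies character vector of study labels to keep, or NULL.
#' @return a new ExpressionCompendium.
#' @export
subset_compendium <- function(c, samples = NULL, studies = NULL) {
  idx <- seq_len(nrow(c$values))
  if (!is.null(samples)) idx <- idx[samples]
  if (!is.null(studies)) idx <- idx[c$samples$study[idx] %in% studies]
  out <- c
  out$values <- c$values[idx, , drop = FALSE]
  out$samples <- c$samples[idx, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' Read an expression compendium from TSV files
#'
#' Expression format: tab-separated, samples in rows, genes in columns, a
#' header row of gene symbols and a first column `sample_id`. Annotation
#' format: tab-separated with columns `sample_id`, `study`, `survival_time`
#' (years), `event` (1 occurred / 0 censored) and optionally
#' `rfs_time`/`rfs_event`.
#'
#' @param expr_path path to the expression TSV.
#' @param annot_path path to the annotation TSV.
#' @param outcome_threshold years at which survival is dichotomized.
#' @return an ExpressionCompendium.
#' @export
read_compendium <- function(expr_path, annot_path, outcome_threshold = 5) {
  expr <- data.table::fread(expr_path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  if (names(expr)[1] != "sample_id")
    stop("expression file must have first column 'sample_id'")
  sample_ids <- as.character(expr$sample_id)
  vals <- expr[, -1, drop = FALSE]
  nonnum <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(nonnum)) {
    j <- nonnum[1]
    i <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
    stop(sprintf("non-numeric expression value at row %d (sample '%s'), column '%s'",
                 i, sample_ids[i], names(vals)[j]))
  }
  values <- as.matrix(vals)
  rownames(values) <- sample_ids
  annot <- data.table::fread(annot_path, sep = "\t", header = TRUE,
                             data.table = FALSE)
  annot$sample_id <- as.character(annot$sample_id)
  new_compendium(values, annot, outcome_threshold)
}

#' Write an expression compendium to TSV files
#'
#' Inverse of [read_compendium()]: `read_compendium(write_compendium(c))`
#' reproduces the compendium.
#'
#' @param c an ExpressionCompendium.
#' @param expr_path,annot_path output paths.
#' @return invisibly, the paths written.
#' @export
write_compendium <- function(c, expr_path, annot_path) {
  expr <- data.frame(sample_id = rownames(c$values), c$values,
                     check.names = FALSE)
  data.table::fwrite(expr, expr_path, sep = "\t")
  ann <- c$samples[, setdiff(names(c$samples), "outcome"), drop = FALSE]
  data.table::fwrite(ann, annot_path, sep = "\t")
  invisible(c(expr_path, annot_path))
}

#' Quantile-normalize expression within each study
#'
#' Within every study, each sample's expression distribution is mapped onto
#' the study's mean quantile vector, so that all samples of a study share an
#' identical sorted value vector. Studies do not influence each other.
#' Single-sample studies are passed through unchanged with a warning (there
#' is no cross-sample distribution to equalize).
#'
#' @param c an ExpressionCompendium.
#' @return a new ExpressionCompendium with normalized values.
#' @export
quantile_normalize_per_study <- function(c) {
  out <- c
  for (st in unique(c$samples$study)) {
    idx <- which(c$samples$study == st)
    if (length(idx) < 2) {
      warning(sprintf("study '%s' has a single sample; left unchanged", st))
      next
    }
    # limma normalizes columns; our samples are rows. ties = FALSE maps
    # every sample's sorted vector exactly onto the study's mean quantile
    # vector (rank ties broken by position), which makes the operation
    # idempotent.
    out$values[idx, ] <- t(limma::normalizeQuantiles(
      t(c$values[idx, , drop = FALSE]), ties = FALSE))
  }
  out
}
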