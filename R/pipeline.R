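#' Construct a count matrix container
#'
#' @param counts Features-by-samples matrix of non-negative integer
#'   counts with feature and sample names.
#' @param total_reads Per-sample total reads; defaults to the column sums.
#' @return A list of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, total_reads = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers", call. = FALSE)
  }
  if (length(total_reads) != ncol(counts) || any(total_reads <= 0)) {
    stop("total reads must be positive, one per sample", call. = FALSE)
  }
  if (any(apply(counts, 2, max) > total_reads)) {
    stop("a feature count exceeds its sample's total reads", call. = FALSE)
  }
  structure(list(counts = counts, total_reads = total_reads),
            class = "count_matrix")
}

#' Read a feature-by-sample count table from TSV
#'
#' Expects features as rows and samples as columns (the common OTU-table
#' orientation; set `samples_as_rows = TRUE` for the transpose), with the
#' first column holding feature identifiers. A row whose identifier equals
#' `totals_id` supplies the per-sample total reads; when absent, totals
#' default to the per-sample column sums and a message is emitted.
#'
#' @param path TSV file path.
#' @param samples_as_rows Set when the file stores samples as rows.
#' @param totals_id Identifier of the optional total-reads row.
#' @return A list of class `"count_matrix"` with `counts` (integer matrix,
#'   features x samples) and `total_reads` (named per-sample vector).
#' @export
read_count_table <- function(path, samples_as_rows = FALSE,
                             totals_id = "total_reads") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (samples_as_rows) mat <- t(mat)

  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at feature '%s', sample '%s': %s",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]],
      format(mat[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicated feature identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicated sample identifiers", call. = FALSE)
  }

  if (totals_id %in% rownames(mat)) {
    total_reads <- mat[totals_id, ]
    mat <- mat[rownames(mat) != totals_id, , drop = FALSE]
  } else {
    total_reads <- colSums(mat)
    message("no total-reads row found; using per-sample column sums")
  }
  if (any(total_reads <= 0)) {
    stop("total reads must be strictly positive for every sample",
         call. = FALSE)
  }
  over <- apply(mat, 2, max) > total_reads
  if (any(over)) {
    stop(sprintf("sample '%s' has a feature count exceeding its total reads",
                 colnames(mat)[which(over)[1]]), call. = FALSE)
  }
  structure(list(counts = mat, total_reads = total_reads),
            class = "count_matrix")
}

#' Read sample metadata from TSV
#'
#' The first column must hold sample identifiers; remaining columns are
#' host factors and grouping variables. Character columns are converted to
#' factors (reference level first in sort order).
#'
#' @param path TSV file path.
#' @return A data frame with sample identifiers as row names.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  ids <- as.character(meta[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample identifiers in metadata", call. = FALSE)
  }
  meta <- meta[, -1, drop = FALSE]
  rownames(meta) <- ids
  for (j in seq_along(meta)) {
    if (is.character(meta[[j]])) meta[[j]] <- factor(meta[[j]])
  }
  meta
}

#' Screen every feature for association with host factors
#'
#' Fits the requested models feature by feature, each with the log total
#' reads as offset and (for the mixed models) a random intercept for the
#' grouping variable, and collects effect estimates and p-values for the
#' first host-factor coefficient into a tidy results table. Categorical
#' host factors are expanded to treatment-coded columns with the first
#' level (by sort order) as reference. Degenerate features — all zeros,
#' fewer than two positive counts, or below the prevalence filter — are
#' kept in the table with a `status` explaining the skip.
#'
#' @param counts A `"count_matrix"` from [read_count_table()], or a
#'   features-by-samples matrix (totals then default to column sums).
#' @param meta Data frame of sample metadata with sample identifiers as
#'   row names (see [read_sample_metadata()]).
#' @param fixed Character vector of metadata column names used as fixed
#'   effects; the first coefficient of the first variable is the one
#'   tested and reported.
#' @param random Metadata column name of the grouping variable (random
#'   intercept) for the mixed models.
#' @param methods Subset of `"NBMM"`, `"NB"`, `"LMM_log"`,
#'   `"LMM_arcsine"`, `"LM"`.
#' @param alpha Significance threshold for the `significant` flag (raw
#'   p-values; a Benjamini-Hochberg adjusted column is also provided).
#' @param min_prevalence Minimum fraction of samples with a nonzero count
#'   for a feature to be tested (default 0, i.e. off).
#' @param control [nbmm_control()] settings for the count models.
#' @return A data frame of class `"nbmm_results"`, one row per feature x
#'   method, with columns `feature`, `method`, `beta_hat`, `se`,
#'   `p_value`, `p_adjust` (BH within method), `significant`, `converged`,
#'   `theta_hat`, `tau2_hat`, `status`. The `alpha`, `fixed`, `random` and
#'   reference-level information are attached as attributes.
#' @export
screen_features <- function(counts, meta, fixed, random,
                            methods = c("NBMM", "LMM_arcsine"),
                            alpha = 0.05, min_prevalence = 0,
                            control = nbmm_control()) {
  if (is.matrix(counts)) counts <- count_matrix(counts)
  stopifnot(inherits(counts, "count_matrix"))
  methods <- match.arg(methods,
                       c("NBMM", "NB", "LMM_log", "LMM_arcsine", "LM"),
                       several.ok = TRUE)
  samples <- colnames(counts$counts)
  missing <- setdiff(samples, rownames(meta))
  if (length(missing) > 0) {
    stop(sprintf("metadata is missing sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  meta <- meta[samples, , drop = FALSE]
  absent <- setdiff(c(fixed, random), colnames(meta))
  if (length(absent) > 0) {
    stop(sprintf("metadata lacks column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  group <- factor(meta[[random]])
  if (nlevels(group) < 2) {
    stop("grouping variable must have at least two levels", call. = FALSE)
  }
  X <- stats::model.matrix(
    stats::reformulate(fixed), data = meta)
  offset <- log(counts$total_reads)

  rows <- list()
  for (f in rownames(counts$counts)) {
    y <- as.integer(counts$counts[f, ])
    status <- "ok"
    if (all(y == 0)) {
      status <- "skipped: degenerate (all zeros)"
    } else if (sum(y > 0) < 2) {
      status <- "skipped: degenerate (single positive count)"
    } else if (mean(y > 0) < min_prevalence) {
      status <- sprintf("skipped: prevalence below %g", min_prevalence)
    }
    for (m in methods) {
      row <- data.frame(feature = f, method = m, beta_hat = NA_real_,
                        se = NA_real_, p_value = NA_real_,
                        converged = NA, theta_hat = NA_real_,
                        tau2_hat = NA_real_, status = status)
      if (status == "ok") {
        res <- tryCatch(switch(m,
          NBMM = {
            fit <- fit_nbmm(y, X, group, offset = offset,
                            control = control)
            data.frame(beta_hat = unname(fit$beta[2]),
                       se = unname(fit$se[2]),
                       p_value = fit$wald$p_value[2],
                       converged = fit$converged,
                       theta_hat = fit$theta, tau2_hat = fit$tau2)
          },
          NB = {
            fit <- fit_nb_glm(y, X, offset = offset, control = control)
            data.frame(beta_hat = fit$beta_hat, se = fit$se,
                       p_value = fit$p_value, converged = fit$converged,
                       theta_hat = fit$theta, tau2_hat = NA_real_)
          },
          LMM_log = ,
          LMM_arcsine = {
            fit <- fit_lmm_transformed(
              y, X, group, counts$total_reads,
              transform = if (m == "LMM_log") "log" else "arcsine")
            data.frame(beta_hat = fit$beta_hat, se = fit$se,
                       p_value = fit$p_value, converged = fit$converged,
                       theta_hat = NA_real_, tau2_hat = fit$tau2)
          },
          LM = {
            fit <- fit_lm_arcsine(y, X, counts$total_reads)
            data.frame(beta_hat = fit$beta_hat, se = fit$se,
                       p_value = fit$p_value, converged = fit$converged,
                       theta_hat = NA_real_, tau2_hat = NA_real_)
          }), error = function(e) NULL)
        if (is.null(res)) {
          row$status <- "failed: fit error"
        } else {
          row[names(res)] <- res
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- NA_real_
  for (m in methods) {
    idx <- out$method == m & !is.na(out$p_value)
    out$p_adjust[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  attr(out, "alpha") <- alpha
  attr(out, "fixed") <- fixed
  attr(out, "random") <- random
  attr(out, "methods") <- methods
  class(out) <- c("nbmm_results", "data.frame")
  out
}

#' Write a screening results table as TSV with a provenance header
#'
#' The header records the package version, significance threshold, model
#' terms and methods as `#`-prefixed comment lines, followed by the tidy
#' table (one row per feature x method, stable column order).
#'
#' @param results An `"nbmm_results"` data frame from [screen_features()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(inherits(results, "nbmm_results"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# nbmm results, package version %s",
            as.character(utils::packageVersion("nbmm"))),
    sprintf("# alpha: %g", attr(results, "alpha")),
    sprintf("# fixed: %s", paste(attr(results, "fixed"), collapse = ",")),
    sprintf("# random: %s", attr(results, "random")),
    sprintf("# methods: %s",
            paste(attr(results, "methods"), collapse = ","))), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path File written by [write_results()].
#' @return A data frame; the `alpha` header value is attached as an
#'   attribute.
#' @export
read_results <- function(path) {
  header <- grep("^#", readLines(path, n = 20), value = TRUE)
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  alpha_line <- grep("^# alpha:", header, value = TRUE)
  if (length(alpha_line) == 1) {
    attr(out, "alpha") <- as.numeric(sub("^# alpha:\\s*", "", alpha_line))
  }
  out
}
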