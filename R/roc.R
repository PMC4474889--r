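#' Subject-level biomarker scores
#'
#' Reduces each subject's connectivity output to one scalar. The default
#' metric mirrors the discriminatory analysis the package targets: the mean
#' over nodes of the clustering coefficient of the proportionally-thresholded
#' PDC graph in the beta band.
#'
#' @param measure registry name of the connectivity measure (see
#'   [measure_registry()]).
#' @param band band name (must exist in the band-aggregated results).
#' @param statistic `"clustering"` (node-mean clustering coefficient),
#'   `"degree"` (node-mean degree) or `"assortativity"`.
#' @param fraction proportional threshold fraction (default 0.2).
#' @return object of class `score_spec`.
#' @export
score_spec <- function(measure = "pdc", band = "beta",
                       statistic = c("clustering", "degree", "assortativity"),
                       fraction = 0.2) {
  statistic <- match.arg(statistic)
  structure(list(measure = measure, band = band, statistic = statistic,
                 fraction = fraction), class = "score_spec")
}

#' @rdname score_spec
#' @param subject_results a named list (one element per subject) of named
#'   lists of band-aggregated [new_connectivity_result()] objects, as
#'   produced by the pipeline.
#' @param spec a `score_spec`.
#' @return `subject_score()`: tibble with columns `subject_id`, `score`.
#' @export
subject_score <- function(subject_results, spec = score_spec()) {
  missing <- names(subject_results)[!vapply(subject_results, function(r) {
    spec$measure %in% names(r)
  }, logical(1))]
  if (length(missing) > 0) {
    stop("measure ", spec$measure, " not computed for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- vapply(subject_results, function(r) {
    g <- threshold_top_fraction(r[[spec$measure]], band = spec$band,
                                fraction = spec$fraction)
    switch(spec$statistic,
           clustering = mean(clustering_coefficient(g)),
           degree = mean(graph_degree(g)),
           assortativity = assortativity_degree(g))
  }, numeric(1))
  tibble::tibble(subject_id = names(subject_results) %||%
                   sprintf("S%02d", seq_along(scores)),
                 score = unname(scores))
}

#' Empirical ROC curve with Youden-optimal operating point
#'
#' Subjects with scores at or above a threshold are classified as patients.
#' The curve sweeps all distinct scores (plus an all-negative endpoint), AUC
#' is computed by the trapezoid rule (equal to the normalized Mann-Whitney U
#' statistic), and the reported optimum maximizes Youden's
#' `J = sensitivity + specificity - 1`, ties resolved toward higher
#' specificity.
#'
#' @param scores numeric vector of subject scores.
#' @param labels logical or 0/1 vector; `TRUE`/1 = patient (positive class).
#' @return object of class `roc_analysis`: list with `curve` (tibble:
#'   threshold, sensitivity, specificity), `auc`, `optimal` (one-row tibble),
#'   `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  curve <- tibble::tibble(threshold = thr, sensitivity = sens,
                          specificity = spec)
  curve <- dplyr::arrange(curve, .data$threshold)
  # trapezoid over (FPR, TPR), sweeping threshold high -> low
  fpr <- rev(1 - curve$specificity); tpr <- rev(curve$sensitivity)
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(curve$specificity[best])]
  structure(list(curve = curve, auc = auc, optimal = curve[best, ],
                 scores = scores, labels = labels),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("<roc_analysis> AUC %.3f; optimum: sens %.0f%% / spec %.0f%% at %.4g\n",
              x$auc, 100 * x$optimal$sensitivity, 100 * x$optimal$specificity,
              x$optimal$threshold))
  invisible(x)
}

#' @export
tidy.roc_analysis <- function(x, ...) x$curve

#' @export
glance.roc_analysis <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 optimal_threshold = x$optimal$threshold,
                 sensitivity = x$optimal$sensitivity,
                 specificity = x$optimal$specificity,
                 n_patients = sum(x$labels), n_controls = sum(!x$labels))
}

#' Group distribution summaries (median / IQR / range) with a test
#'
#' Quartiles use the linear-interpolation convention (R type 7); the p-value
#' comes from a classic pooled-variance unpaired t-test by default.
#'
#' @param scores numeric vector of subject scores.
#' @param labels logical or 0/1; `TRUE` = patient.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return object of class `distribution_summary`: tibble with one row per
#'   group (`group`, `n`, `median`, `q1`, `q3`, `min`, `max`) and attribute
#'   `p_value`.
#' @export
summarize_groups <- function(scores, labels, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  sm <- function(v, g) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(group = g, n = length(v), median = q[2],
                   q1 = q[1], q3 = q[3], min = min(v), max = max(v))
  }
  out <- dplyr::bind_rows(sm(scores[labels], "patient"),
                          sm(scores[!labels], "control"))
  p <- if (test == "t") {
    if (sum(labels) >= 2 && sum(!labels) >= 2) {
      stats::t.test(scores[labels], scores[!labels],
                    var.equal = TRUE)$p.value
    } else NA_real_
  } else {
    stats::wilcox.test(scores[labels], scores[!labels], exact = FALSE)$p.value
  }
  structure(out, p_value = p,
            class = c("distribution_summary", class(out)))
}
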