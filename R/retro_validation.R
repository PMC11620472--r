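# Decoy-based retrospective validation: Tanimoto similarity scoring,
# ROC/AUC, enrichment factors and the active-vs-decoy distribution test.

#' Tanimoto coefficient between binary fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 0 when both bitsets are
#' empty.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in \eqn{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints have different widths (", length(a), " vs ",
         length(b), ")")
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L | b == 1L)
  if (uni == 0L) 0 else inter / uni
}

#' Score a fingerprint set by similarity to a control
#'
#' Computes the Tanimoto similarity of every query fingerprint to a
#' reference control fingerprint, attaching labels for downstream
#' ROC/enrichment statistics.
#'
#' @param fps 0/1 matrix, one fingerprint per row.
#' @param control 0/1 vector of the same width.
#' @param labels optional \code{"active"}/\code{"decoy"} label per row.
#' @return data.frame with \code{id}, \code{label}, \code{score}.
#' @export
similarity_to_control <- function(fps, control, labels = NULL) {
  if (ncol(fps) != length(control))
    stop("fingerprint width ", ncol(fps), " does not match control width ",
         length(control))
  ids <- rownames(fps) %||% as.character(seq_len(nrow(fps)))
  sc <- apply(fps, 1L, tanimoto, b = control)
  data.frame(id = ids,
             label = labels %||% rep(NA_character_, nrow(fps)),
             score = unname(sc), stringsAsFactors = FALSE)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps 0/1 matrix, one fingerprint per row.
#' @return symmetric matrix \eqn{M_{ij} = T(fp_i, fp_j)} with unit
#'   diagonal for non-empty fingerprints.
#' @export
pairwise_tanimoto <- function(fps) {
  stopifnot(nrow(fps) >= 1)
  fps <- matrix(as.numeric(fps), nrow(fps), ncol(fps),
                dimnames = dimnames(fps))
  common <- tcrossprod(fps)               # |a & b| for 0/1 rows
  ones <- rowSums(fps)
  uni <- outer(ones, ones, "+") - common  # |a | b|
  M <- ifelse(uni == 0, 0, common / uni)
  dimnames(M) <- list(rownames(fps), rownames(fps))
  M
}

#' ROC curve and AUC for active/decoy scores
#'
#' Sweeps the score threshold from high to low, recording the true- and
#' false-positive rates, and computes the area under the curve by the
#' trapezoid rule. Tied scores are handled by the midrank convention, so
#' the AUC equals the concordance probability
#' \eqn{P(s_{active} > s_{decoy}) + \frac12 P(s_{active} = s_{decoy})}.
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels \code{"active"}/\code{"decoy"} per score.
#' @return object of class \code{roc_result}: list with \code{fpr},
#'   \code{tpr} (threshold sweep, including the (0,0) and (1,1)
#'   endpoints) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  act <- labels == "active"
  if (!any(act) || all(act))
    stop("ROC needs at least one active and one decoy")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[act] >= t), 0))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!act] >= t), 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Enrichment factor at a top fraction
#'
#' Takes the top \eqn{n = \lceil f N \rceil} compounds of the
#' descending-score ranking and reports
#' \eqn{EF = (x/n) / (A/N)} where \eqn{x} is the number of actives in
#' the slice, \eqn{A} the total actives and \eqn{N} the library size.
#' Ties at the slice boundary are broken by stable id order, and the
#' boundary ids are recorded.
#'
#' @param scores numeric scores (higher = better; negate docking scores
#'   first).
#' @param labels \code{"active"}/\code{"decoy"} per score.
#' @param fraction top fraction in (0, 1]; default 0.01.
#' @param ids compound identifiers for tie bookkeeping.
#' @return object of class \code{ef_result}: list with \code{fraction},
#'   \code{slice_size}, \code{actives_in_slice}, \code{total_actives},
#'   \code{total}, \code{ef}, \code{tied_at_boundary}.
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01, ids = NULL) {
  stopifnot(length(scores) == length(labels),
            fraction > 0, fraction <= 1)
  act <- labels == "active"
  if (!any(act) || all(act))
    stop("enrichment factor needs both actives and decoys")
  N <- length(scores)
  A <- sum(act)
  n <- ceiling(fraction * N)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  ord <- order(-scores, ids, method = "radix")  # stable id tie-break
  slice <- ord[seq_len(n)]
  x <- sum(act[slice])
  boundary <- scores[ord[n]]
  tied <- ids[scores == boundary & !(seq_len(N) %in% slice)]
  structure(list(fraction = fraction, slice_size = n,
                 actives_in_slice = x, total_actives = A, total = N,
                 ef = (x / n) / (A / N), tied_at_boundary = tied),
            class = "ef_result")
}

#' @export
print.ef_result <- function(x, ...) {
  cat(sprintf(
    "EF@%g%%: %.2f  (%d of %d in top slice active; %d/%d actives overall)\n",
    100 * x$fraction, x$ef, x$actives_in_slice, x$slice_size,
    x$total_actives, x$total))
  invisible(x)
}

#' Rank-sum test for active vs decoy score distributions
#'
#' Mann-Whitney U test that active similarity scores are distributed
#' differently from decoy scores. Small samples without ties use the
#' exact null distribution; otherwise the normal approximation with tie
#' correction is used. The reported U counts pairs where an active
#' outranks a decoy (ties count one half).
#'
#' @param active_scores,decoy_scores numeric score vectors.
#' @return list with \code{U}, \code{p_value}, \code{n_active},
#'   \code{n_decoy}.
#' @export
rank_sum_test <- function(active_scores, decoy_scores) {
  stopifnot(length(active_scores) >= 1, length(decoy_scores) >= 1)
  wt <- suppressWarnings(
    stats::wilcox.test(active_scores, decoy_scores,
                       alternative = "two.sided",
                       exact = NULL, correct = FALSE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # every observation tied: no evidence
  list(U = unname(wt$statistic), p_value = min(1, p),
       n_active = length(active_scores), n_decoy = length(decoy_scores))
}
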