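#' Multiclass evaluation report: macro F1, per-class metrics, confusion matrix
#'
#' Per-class precision, recall and F1 are computed from the confusion counts;
#' classes with an undefined ratio (empty denominator) score 0. Macro F1 is
#' the unweighted mean of per-class F1 over the full label set. The confusion
#' matrix is row-normalized (rows of absent classes are left at zero) and,
#' when per-fly \code{sex} and \code{size} covariates are supplied, its rows
#' and columns are ordered by sex (males first) then ascending body size —
#' the presentation convention for re-identification confusion matrices.
#'
#' @param truth,pred vectors of true and predicted class labels.
#' @param levels optional label set; default: sorted union of both vectors.
#' @param sex optional named vector mapping each label to "M"/"F".
#' @param size optional named numeric vector mapping each label to a body
#'   size used for ordering.
#' @return object of class \code{eval_report}: \code{macro_f1},
#'   \code{per_class} (data.frame), \code{confusion} (row-normalized),
#'   \code{counts}, and \code{sex_f1} when \code{sex} is given.
#' @export
eval_report <- function(truth, pred, levels = NULL, sex = NULL, size = NULL) {
  if (length(truth) == 0L) stop("empty test set")
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (is.null(levels)) levels <- sort(unique(c(truth, pred)))
  tr <- factor(truth, levels = levels)
  pr <- factor(pred, levels = levels)
  counts <- table(truth = tr, pred = pr)
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  tp <- diag(counts)
  p_den <- colSums(counts); r_den <- rowSums(counts)
  precision <- ifelse(p_den > 0, tp / p_den, 0)
  recall <- ifelse(r_den > 0, tp / r_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = levels, precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          support = unname(r_den), stringsAsFactors = FALSE)
  conf <- counts
  rs <- rowSums(conf)
  conf[rs > 0, ] <- conf[rs > 0, , drop = FALSE] / rs[rs > 0]

  ord <- seq_along(levels)
  if (!is.null(sex) && !is.null(size)) {
    key <- as.character(levels)
    ord <- order(match(sex[key], c("M", "F")), size[key])
    conf <- conf[ord, ord, drop = FALSE]
    counts <- counts[ord, ord, drop = FALSE]
  }
  rep <- list(macro_f1 = mean(f1), per_class = per_class,
              confusion = conf, counts = counts)
  if (!is.null(sex)) rep$sex_f1 <- collapse_by_sex(truth, pred, sex)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> macro F1 = ", sprintf("%.4f", x$macro_f1), sep = "")
  if (!is.null(x$sex_f1)) cat(", sex-collapsed F1 = ",
                              sprintf("%.4f", x$sex_f1), sep = "")
  cat("\n  per-class F1: ",
      paste(sprintf("%.2f", x$per_class$f1), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Macro F1 score
#'
#' Unweighted mean over classes of the harmonic mean of precision and recall.
#'
#' @inheritParams eval_report
#' @export
macro_f1 <- function(truth, pred, levels = NULL) {
  eval_report(truth, pred, levels = levels)$macro_f1
}

#' F1 after collapsing identities to sex
#'
#' Maps every true and predicted identity to its sex and scores macro F1 over
#' \{M, F\}. Identities that are only ever confused within their own sex
#' collapse to a perfect score.
#'
#' @param truth,pred identity label vectors.
#' @param sex_map named vector mapping each identity to "M" or "F".
#' @export
collapse_by_sex <- function(truth, pred, sex_map) {
  ids <- unique(as.character(c(truth, pred)))
  missing <- setdiff(ids, names(sex_map))
  if (length(missing))
    stop("no sex mapping for identit(y/ies): ", paste(missing, collapse = ", "))
  macro_f1(unname(sex_map[as.character(truth)]),
           unname(sex_map[as.character(pred)]),
           levels = c("M", "F"))
}
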