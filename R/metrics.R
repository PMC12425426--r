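#' Confusion matrix from labels
#'
#' Tallies predictions into a k x k count matrix with true classes as rows
#' and predicted classes as columns, in the order given by `classes`. For
#' the binary task the convention throughout the package is that class 1
#' (the condition group) is the positive class.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class values fixing the matrix order; defaults to the
#'   sorted union of observed labels.
#' @return A `confusion_matrix` (integer matrix with dimnames).
#' @export
confusion <- function(y_true, y_pred, classes = sort(unique(c(y_true, y_pred)))) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(!c(y_true, y_pred) %in% classes)) {
    stop_actidep("label outside the declared class set",
                 class = "actidep_validation_error")
  }
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  out <- matrix(as.integer(cm), length(classes), length(classes),
                dimnames = list(true = as.character(classes),
                                predicted = as.character(classes)))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Classification metric suite from a confusion matrix
#'
#' Computes accuracy, precision, recall (sensitivity), specificity,
#' F1-score and the Matthews correlation coefficient. Binary: the standard
#' cell formulas with the second class positive — precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Multiclass:
#' per-class one-vs-rest precision/recall/specificity/F1 combined by
#' support-weighted (or macro) average, and the generalized multiclass MCC
#' computed on the full k x k matrix. Zero-denominator cells yield 0 with a
#' warning.
#'
#' @param cm A `confusion_matrix` (or plain square count matrix).
#' @param averaging `"binary"` (2x2 only), `"weighted"` or `"macro"`.
#' @return A `metric_report`: named list with `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`, `mcc`, and `averaging`.
#' @export
metric_suite <- function(cm, averaging = c("binary", "weighted", "macro")) {
  averaging <- match.arg(averaging)
  cm <- unclass(cm)
  total <- sum(cm)
  stopifnot(total > 0, nrow(cm) == ncol(cm))
  k <- nrow(cm)
  safe_div <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in metric; returning 0")
      return(0)
    }
    num / den
  }
  if (averaging == "binary") {
    stopifnot(k == 2)
    tp <- cm[2, 2]; fp <- cm[1, 2]; fn <- cm[2, 1]; tn <- cm[1, 1]
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    specificity <- safe_div(tn, tn + fp)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (mcc_den == 0) 0 else ((tp * tn) - (fp * fn)) / mcc_den
    out <- list(accuracy = (tp + tn) / total, precision = precision,
                recall = recall, specificity = specificity, f1 = f1,
                mcc = mcc, averaging = averaging)
  } else {
    support <- rowSums(cm)
    w <- if (averaging == "weighted") support / total else rep(1 / k, k)
    per <- vapply(seq_len(k), function(i) {
      tp <- cm[i, i]
      fp <- sum(cm[-i, i])
      fn <- sum(cm[i, -i])
      tn <- total - tp - fp - fn
      p <- safe_div(tp, tp + fp)
      r <- safe_div(tp, tp + fn)
      s <- safe_div(tn, tn + fp)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p, r, s, f)
    }, numeric(4))
    # generalized multiclass MCC on the full matrix
    s <- total
    c_tr <- sum(diag(cm))
    t_k <- rowSums(cm)   # true counts
    p_k <- colSums(cm)   # predicted counts
    den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
    mcc <- if (den == 0) 0 else (c_tr * s - sum(p_k * t_k)) / den
    out <- list(accuracy = c_tr / total,
                precision = sum(w * per[1, ]),
                recall = sum(w * per[2, ]),
                specificity = sum(w * per[3, ]),
                f1 = sum(w * per[4, ]),
                mcc = mcc, averaging = averaging)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> (%s averaging)\n", x$averaging))
  for (m in c("accuracy", "precision", "recall", "specificity", "f1", "mcc")) {
    cat(sprintf("  %-11s %.4f\n", m, x[[m]]))
  }
  invisible(x)
}
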