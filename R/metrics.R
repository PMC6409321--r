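# Pair-level evaluation.  Predictions and references are compared as sets
# of exact (i, j) base pairs; whether pairs cross is irrelevant, which is
# what makes pseudoknotted and pseudoknot-free predictions comparable.

pair_keys <- function(structure) {
  p <- structure$pairs
  sprintf("%d-%d", p[, 1L], p[, 2L])
}

#' Base-pair confusion counts
#'
#' `TP` is the number of pairs present in both prediction and reference,
#' `FP` the number predicted but absent from the reference, `FN` the number
#' of reference pairs missed.
#'
#' @param pred,ref [secondary_structure()] objects of equal length.
#' @return Named list with `TP`, `FP`, `FN`.
#' @export
confusion <- function(pred, ref) {
  if (pred$length != ref$length) {
    stop("confusion: structures have different lengths (",
         pred$length, " vs ", ref$length, ")")
  }
  pk <- pair_keys(pred)
  rk <- pair_keys(ref)
  tp <- sum(pk %in% rk)
  list(TP = tp, FP = length(pk) - tp, FN = length(rk) - tp)
}

#' F-score: harmonic mean of sensitivity and PPV
#'
#' `2 * sen * ppv / (sen + ppv)`, defined as 0 when both arguments are 0.
#' The printed form of the formula in the source literature,
#' `2 * ((sen + ppv) / (sen * ppv))`, is not a harmonic mean and exceeds 1;
#' `printed = TRUE` reproduces it for debugging comparisons only.
#'
#' @param sen,ppv Sensitivity and positive predictive value in `[0, 1]`.
#' @param printed Reproduce the literal (misprinted) formula.
#' @return F-score; equals 1 iff both arguments are 1 (default mode).
#' @export
f_score <- function(sen, ppv, printed = FALSE) {
  stopifnot(sen >= 0, sen <= 1, ppv >= 0, ppv <= 1)
  if (printed) {
    if (sen * ppv == 0) return(Inf)
    return(2 * ((sen + ppv) / (sen * ppv)))
  }
  if (sen + ppv == 0) return(0)
  2 * sen * ppv / (sen + ppv)
}

#' Pair-level metrics for one prediction
#'
#' Sensitivity `TP/(TP+FN)` measures the ability to find true pairs; PPV
#' `TP/(TP+FP)` the ability not to predict false ones; F is their harmonic
#' mean.  When a denominator is 0 the convention is: an empty prediction of
#' an empty reference is perfect (all three metrics 1), otherwise the
#' undefined metric is 0 — so a correctly predicted unstructured RNA
#' scores 1.
#'
#' @param pred,ref [secondary_structure()] objects of equal length.
#' @return One-row [tibble::tibble()] with `TP`, `FP`, `FN`, `SEN`, `PPV`,
#'   `F`.
#' @export
pair_metrics <- function(pred, ref) {
  cf <- confusion(pred, ref)
  both_empty <- nrow(pred$pairs) == 0L && nrow(ref$pairs) == 0L
  sen <- if (cf$TP + cf$FN == 0L) {
    if (both_empty) 1 else 0
  } else cf$TP / (cf$TP + cf$FN)
  ppv <- if (cf$TP + cf$FP == 0L) {
    if (both_empty) 1 else 0
  } else cf$TP / (cf$TP + cf$FP)
  tibble::tibble(
    TP = cf$TP, FP = cf$FP, FN = cf$FN,
    SEN = sen, PPV = ppv, F = f_score(sen, ppv)
  )
}

#' Select the candidate structure closest to a reference
#'
#' Returns the candidate with the highest F-score against the reference;
#' ties break to the earlier candidate (candidate rank).
#'
#' @param candidates Non-empty list of [secondary_structure()] objects.
#' @param ref Reference [secondary_structure()].
#' @return List with `index`, `structure` and `metrics` (a one-row tibble).
#' @export
select_best <- function(candidates, ref) {
  if (length(candidates) == 0L) {
    stop("select_best: no candidates supplied")
  }
  reports <- lapply(candidates, pair_metrics, ref = ref)
  fs <- vapply(reports, function(r) r$F, 0)
  i <- which.max(fs)
  list(index = i, structure = candidates[[i]], metrics = reports[[i]])
}

#' Evaluate a set of predictions against references
#'
#' @param preds,refs Named (or parallel) lists of [secondary_structure()]
#'   objects; ids are taken from `ids` or names.
#' @param ids Optional character vector of record ids.
#' @param family Optional character vector of family labels for per-family
#'   aggregation.
#' @return Tibble with one row per record (`id`, `family`, `TP`, `FP`,
#'   `FN`, `SEN`, `PPV`, `F`).
#' @export
evaluate_structures <- function(preds, refs, ids = NULL, family = NULL) {
  stopifnot(length(preds) == length(refs))
  if (is.null(ids)) ids <- names(preds) %||% sprintf("seq%03d", seq_along(preds))
  if (is.null(family)) family <- rep(NA_character_, length(preds))
  rows <- lapply(seq_along(preds), function(k) {
    m <- pair_metrics(preds[[k]], refs[[k]])
    tibble::tibble(id = ids[k], family = family[k], m)
  })
  do.call(rbind, rows)
}

#' Aggregate per-record metrics by family
#'
#' @param per_record Tibble from [evaluate_structures()].
#' @return Tibble with `family`, `n`, and mean `SEN`, `PPV`, `F`.
#' @export
aggregate_by_family <- function(per_record) {
  fam <- per_record$family
  fam[is.na(fam)] <- "all"
  sp <- split(per_record, fam)
  res <- do.call(rbind, lapply(names(sp), function(f) {
    d <- sp[[f]]
    tibble::tibble(family = f, n = nrow(d),
                   SEN = mean(d$SEN), PPV = mean(d$PPV), F = mean(d$F))
  }))
  res[order(res$family), ]
}
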