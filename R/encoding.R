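# Fixed one-hot encodings.  The base alphabet uses 8-bit vectors, the
# structural alphabet 7-bit vectors; padding (`N`) maps to all-zeros in both
# so it can be masked out of losses and accuracies.

BASE_ONEHOT <- rbind(
  A = c(1, 0, 0, 0, 0, 0, 1, 0),
  U = c(0, 0, 1, 0, 1, 0, 0, 0),
  G = c(0, 1, 0, 0, 0, 0, 1, 0),
  C = c(0, 0, 1, 0, 0, 1, 0, 0),
  N = c(0, 0, 0, 0, 0, 0, 0, 0)
)

SYMBOL_ONEHOT <- rbind(
  "(" = c(1, 0, 0, 0, 0, 0, 0),
  ")" = c(0, 0, 0, 0, 0, 0, 1),
  "." = c(0, 0, 0, 1, 0, 0, 0),
  "[" = c(0, 1, 0, 0, 0, 0, 0),
  "]" = c(0, 0, 0, 0, 0, 1, 0),
  "{" = c(0, 0, 1, 0, 0, 0, 0),
  "}" = c(0, 0, 0, 0, 1, 0, 0),
  N   = c(0, 0, 0, 0, 0, 0, 0)
)

# Class index (argmax slot) of each non-padding symbol, in SYMBOL_ONEHOT
# column order: ( [ { . } ] )
SYMBOL_BY_SLOT <- c("(", "[", "{", ".", "}", "]", ")")

#' One-hot encode bases
#'
#' Each base maps to a fixed 8-bit vector; the padding base `N` maps to
#' all-zeros.
#'
#' @param bases Character vector of single bases, or a single sequence
#'   string (which is split).
#' @return Numeric matrix with one 8-entry row per base.
#' @examples
#' encode_base("A")  # 1 0 0 0 0 0 1 0
#' @export
encode_base <- function(bases) {
  if (length(bases) == 1L && nchar(bases) > 1L) {
    bases <- strsplit(bases, "")[[1]]
  }
  bad <- setdiff(unique(bases), rownames(BASE_ONEHOT))
  if (length(bad) > 0) {
    stop("encode_base: no encoding for character '", bad[1L], "'")
  }
  m <- BASE_ONEHOT[bases, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' One-hot encode dot-bracket symbols
#'
#' @param symbols Character vector of symbols from `( ) [ ] { } .` plus the
#'   padding symbol `N`, or a single string.
#' @return Numeric matrix with one 7-entry row per symbol.
#' @export
encode_symbol <- function(symbols) {
  if (length(symbols) == 1L && nchar(symbols) > 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  bad <- setdiff(unique(symbols), rownames(SYMBOL_ONEHOT))
  if (length(bad) > 0) {
    stop("encode_symbol: no encoding for character '", bad[1L], "'")
  }
  m <- SYMBOL_ONEHOT[symbols, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Decode symbol score rows to dot-bracket symbols
#'
#' Takes the argmax of each 7-entry score row (the hardening rule applied to
#' the decoder's output layer) and maps it to its symbol.  An all-zero row
#' decodes to the padding symbol `N`.  Ties break to the lowest slot index,
#' deterministically.
#'
#' @param scores Numeric matrix with 7 columns (or a single 7-vector).
#' @return Character vector of symbols, one per row.
#' @export
decode_symbol <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  stopifnot(ncol(scores) == 7L)
  apply(scores, 1L, function(row) {
    if (all(row == 0)) return("N")
    SYMBOL_BY_SLOT[which.max(row)]
  })
}

#' Split a sequence into fixed-length overlapping windows
#'
#' Sequences no longer than `width` become a single window padded with `N`
#' to `width`.  Longer sequences are cut into windows of `width` bases
#' anchored at position 1 with consecutive windows overlapping by `overlap`
#' bases (step `width - overlap`); the last window is padded if short.
#' Every position is covered by at least one window.
#'
#' @param seq Sequence string.
#' @param width Window width (default 300).
#' @param overlap Overlap between consecutive windows (default 200).
#' @return List of windows, each a list with `start`, `end` (1-based,
#'   closed, in original coordinates) and `padded` (the `width`-character
#'   padded subsequence).
#' @export
window_sequence <- function(seq, width = 300L, overlap = 200L) {
  stopifnot(nzchar(seq), width > overlap, overlap >= 0L)
  n <- nchar(seq)
  step <- width - overlap
  starts <- 1L
  while (starts[length(starts)] + width - 1L < n) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  lapply(starts, function(s) {
    e <- min(s + width - 1L, n)
    sub <- substr(seq, s, e)
    pad <- width - (e - s + 1L)
    list(
      start = s, end = e,
      padded = paste0(sub, strrep("N", pad))
    )
  })
}

#' Merge per-window symbol predictions into a full-length string
#'
#' Padding positions are dropped.  Where windows overlap, each position
#' takes the symbol from the window whose midpoint (in original
#' coordinates, using the nominal padded width) is nearest; ties go to the
#' earlier window.  Central context is richest for a bidirectional encoder,
#' which motivates the midpoint rule.
#'
#' @param windows List of windows from [window_sequence()].
#' @param predictions Character vector of per-window symbol strings, each of
#'   the nominal window width.
#' @param n Original sequence length.
#' @param width Window width used (default 300).
#' @return Symbol string of length `n`.
#' @export
merge_window_predictions <- function(windows, predictions, n,
                                     width = 300L) {
  if (length(windows) != length(predictions)) {
    stop("merge_window_predictions: ", length(windows), " windows but ",
         length(predictions), " prediction strings")
  }
  for (k in seq_along(predictions)) {
    if (nchar(predictions[k]) != width) {
      stop("merge_window_predictions: prediction ", k, " has length ",
           nchar(predictions[k]), ", expected ", width)
    }
  }
  out <- character(n)
  best_dist <- rep(Inf, n)
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    centre <- w$start + (width - 1) / 2
    pos <- w$start:w$end
    d <- abs(pos - centre)
    take <- d < best_dist[pos]  # strict: ties keep the earlier window
    if (any(take)) {
      sym <- strsplit(predictions[k], "")[[1]]
      out[pos[take]] <- sym[(pos - w$start + 1L)[take]]
      best_dist[pos[take]] <- d[take]
    }
  }
  paste(out, collapse = "")
}
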