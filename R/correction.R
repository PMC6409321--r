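# Correction unit: turn a (noisy) 7-symbol labelling plus the sequence into
# an optimal set of mutually compatible stems per bracket class, then merge
# the up-to-three pseudoknot-free substructures into one pseudoknotted
# structure.  Scoring is base-pair count only; no thermodynamics.

#' Correction-unit configuration
#'
#' @param min_stem_len Minimum stem length (stacked pairs) a candidate stem
#'   must have.  Default 2: single-pair "stems" explode the candidate space
#'   and are sterically dubious.
#' @param min_loop Minimum number of unpaired bases enclosed by a hairpin
#'   (so a pair `(i, j)` requires `j - i >= min_loop + 1`).  Default 3, the
#'   standard steric minimum.
#' @param cap Maximum number of tree nodes kept per priority layer in the
#'   stem-combination search; pruning is deterministic (score, then
#'   lexicographic order).
#' @param literal_compat Use the literal printed compatibility inequalities
#'   instead of the strict base-disjoint + non-crossing predicate (see
#'   [stems_compatible()]).
#' @param k_keep Number of optimal combinations kept per bracket class when
#'   combining substructures.
#' @param rate_step1,rate_step2,rate_step3 Usage-rate acceptance thresholds
#'   of the three selection steps: step 1 accepts a group when its combined
#'   rate equals `rate_step1`, step 2 when a single side's rate equals
#'   `rate_step2`, step 3 when the rate strictly exceeds `rate_step3`.
#' @return A list of class `correction_config`.
#' @export
correction_config <- function(min_stem_len = 2L, min_loop = 3L, cap = 50L,
                              literal_compat = FALSE, k_keep = 3L,
                              rate_step1 = 1, rate_step2 = 1,
                              rate_step3 = 0.6) {
  stopifnot(min_stem_len >= 1L, min_loop >= 0L, cap >= 1L, k_keep >= 1L)
  structure(
    list(
      min_stem_len = as.integer(min_stem_len),
      min_loop = as.integer(min_loop),
      cap = as.integer(cap),
      literal_compat = isTRUE(literal_compat),
      k_keep = as.integer(k_keep),
      rate_step1 = rate_step1, rate_step2 = rate_step2,
      rate_step3 = rate_step3
    ),
    class = "correction_config"
  )
}

# ---- pair matrix and stems --------------------------------------------------

# The three admissible pairings: Watson-Crick A-U and G-C plus the G-U wobble.
can_pair_bases <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

# Empty stem matrix with the canonical columns.
empty_stems <- function() {
  matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("S", "E", "L")))
}

as_stems <- function(m) {
  if (is.null(m) || NROW(m) == 0L) return(empty_stems())
  m <- matrix(as.integer(m), ncol = 3L)
  dimnames(m) <- list(NULL, c("S", "E", "L"))
  m
}

# Canonical ordering and string key for a stem set (used for deterministic
# tie-breaks and deduplication).
sort_stems <- function(m) {
  m <- as_stems(m)
  if (nrow(m) <= 1L) return(m)
  m[order(m[, "S"], m[, "E"], m[, "L"]), , drop = FALSE]
}

stems_key <- function(m) {
  m <- sort_stems(m)
  paste(sprintf("%d.%d.%d", m[, "S"], m[, "E"], m[, "L"]), collapse = "|")
}

stems_score <- function(m) sum(as_stems(m)[, "L"])

#' Bases occupied by a stem set
#'
#' @param stems Stem matrix with columns `S`, `E`, `L`.
#' @param side `"both"`, `"5"` (rows `S..S+L-1`) or `"3"` (`E-L+1..E`).
#' @return Sorted integer vector of occupied positions.
#' @export
stem_bases <- function(stems, side = c("both", "5", "3")) {
  side <- match.arg(side)
  stems <- as_stems(stems)
  out <- integer(0)
  for (r in seq_len(nrow(stems))) {
    s <- stems[r, ]
    if (side != "3") out <- c(out, s["S"]:(s["S"] + s["L"] - 1L))
    if (side != "5") out <- c(out, (s["E"] - s["L"] + 1L):s["E"])
  }
  sort(unique(as.integer(out)))
}

# Pairs (i, j) implied by a stem set, as a 2-column matrix.
stems_to_pairs <- function(stems) {
  stems <- as_stems(stems)
  if (nrow(stems) == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, lapply(seq_len(nrow(stems)), function(r) {
    k <- 0:(stems[r, "L"] - 1L)
    cbind(stems[r, "S"] + k, stems[r, "E"] - k)
  }))
}

#' Build the base-pairing matrix of a sequence
#'
#' An upper-triangular boolean matrix marks every position pair `(i, j)`
#' that could form a base pair (A-U, G-C or G-U, with `j - i` at least
#' `min_loop + 1`).  Every maximal diagonal run of marks is a maximal stem;
#' those of length at least `min_stem_len` are indexed for the search, while
#' the raw matrix is retained for stem extension.
#'
#' @param sequence Sequence string (normalised; `N` never pairs).
#' @param min_stem_len,min_loop See [correction_config()].
#' @return An object of class `pair_matrix` with fields `n`, `can`
#'   (logical matrix), `stems` (maximal stems of sufficient length),
#'   `min_stem_len`, `min_loop`.
#' @export
build_pair_matrix <- function(sequence, min_stem_len = 2L, min_loop = 3L) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  n <- length(bases)
  can <- matrix(FALSE, n, n)
  if (n >= 2L) {
    comp <- outer(bases, bases, can_pair_bases)
    dist_ok <- outer(seq_len(n), seq_len(n), function(i, j) j - i >= min_loop + 1L)
    can <- comp & dist_ok
  }
  stems <- list()
  for (s in seq_len(2L * n)[-1L]) {       # anti-diagonal i + j = s
    i_lo <- max(1L, s - n)
    i_hi <- (s - 1L) %/% 2L
    if (i_hi < i_lo) next
    ii <- i_lo:i_hi
    vals <- can[cbind(ii, s - ii)]
    r <- rle(vals)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    for (k in which(r$values)) {
      L <- r$lengths[k]
      S <- ii[start_at[k]]
      stems[[length(stems) + 1L]] <- c(S, s - S, L)
    }
  }
  stems <- if (length(stems)) do.call(rbind, stems) else empty_stems()
  stems <- as_stems(stems)
  stems <- sort_stems(stems[stems[, "L"] >= min_stem_len, , drop = FALSE])
  structure(
    list(n = n, can = can, stems = stems,
         min_stem_len = as.integer(min_stem_len),
         min_loop = as.integer(min_loop)),
    class = "pair_matrix"
  )
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> n = %d, %d maximal stems (L >= %d)\n",
              x$n, nrow(x$stems), x$min_stem_len))
  invisible(x)
}

# ---- compatibility ----------------------------------------------------------

# Vectorised pairwise compatibility between two stem sets; returns an
# nrow(a) x nrow(b) logical matrix.
stem_compat_matrix <- function(a, b, literal = FALSE) {
  a <- as_stems(a); b <- as_stems(b)
  S1 <- a[, "S"]; E1 <- a[, "E"]; L1 <- a[, "L"]
  S2 <- b[, "S"]; E2 <- b[, "E"]; L2 <- b[, "L"]
  sep <- outer(E1, S2, `<`) | outer(S1, E2, `>`)
  if (literal) {
    c3 <- outer(S1 + L1 - 1L, S2, `<`) & outer(E1, E2 - L2 + 1L, `>`)
    c4 <- outer(S1, S2 + L2 - 1L, `>`) & outer(E1 - L1 + 1L, E2, `<`)
  } else {
    # strict: the second stem entirely inside the first stem's loop, or
    # vice versa (base-disjoint and non-crossing)
    c3 <- outer(S1 + L1 - 1L, S2, `<`) & outer(E1 - L1 + 1L, E2, `>`)
    c4 <- outer(S1, S2 + L2 - 1L, `>`) & outer(E1, E2 - L2 + 1L, `<`)
  }
  sep | c3 | c4
}

#' Are two stems compatible?
#'
#' In the default strict mode two stems are compatible when their occupied
#' bases are disjoint and their pair sets do not cross, i.e. the stems are
#' either fully separated or one lies entirely inside the other's loop.
#' `literal = TRUE` instead evaluates the looser printed inequalities
#' `(E1 < S2) | (E2 < S1) | (S1+L1-1 < S2 & E2-L2+1 < E1) |
#' (S2+L2-1 < S1 & E1-L1+1 < E2)`, which admit combinations whose 3' regions
#' share bases (e.g. `(1,20,3)` vs `(5,19,2)`); that mode exists only for
#' comparison, since shared bases violate the one-pair-per-base output
#' invariant.
#'
#' @param stm1,stm2 Stems as `(S, E, L)` triples.
#' @param literal Use the literal printed inequalities.
#' @return Logical scalar; symmetric in its arguments.
#' @export
stems_compatible <- function(stm1, stm2, literal = FALSE) {
  as.vector(stem_compat_matrix(rbind(stm1), rbind(stm2), literal))
}

# Is a stem set pairwise compatible?
stem_set_ok <- function(stems, literal = FALSE) {
  stems <- as_stems(stems)
  m <- nrow(stems)
  if (m < 2L) return(TRUE)
  cm <- stem_compat_matrix(stems, stems, literal)
  all(cm[upper.tri(cm)])
}

# ---- PCR extraction ---------------------------------------------------------

#' Extract prediction complementary regions from a symbol string
#'
#' A PCR is a maximal run of one bracket symbol in the labelling.  Runs of
#' the opening symbol of a class are 5' PCRs, runs of the closing symbol
#' 3' PCRs; dots (and padding symbols) separate runs and are ignored.
#'
#' @param symbols Symbol string over the 7-symbol alphabet.
#' @return List of three elements (one per bracket class), each a data frame
#'   with columns `start`, `end`, `side` (`"5"` or `"3"`), sorted by
#'   `start`.
#' @export
extract_pcrs <- function(symbols) {
  sym <- strsplit(symbols, "")[[1]]
  bad <- setdiff(unique(sym), c(DB_ALPHABET, "N"))
  if (length(bad) > 0) {
    stop("extract_pcrs: illegal symbol '", bad[1L], "'")
  }
  r <- rle(sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(1:3, function(cls) {
    keep <- r$values %in% c(DB_OPEN[cls], DB_CLOSE[cls])
    df <- data.frame(
      start = starts[keep], end = ends[keep],
      side = ifelse(r$values[keep] == DB_OPEN[cls], "5", "3"),
      stringsAsFactors = FALSE
    )
    df[order(df$start), , drop = FALSE]
  })
}

# ---- candidate stem collection ----------------------------------------------

#' Collect candidate stems between 5' and 3' PCR areas
#'
#' For every 5' PCR spanning rows `i..j` and every 3' PCR spanning columns
#' `p..q` with `i < j < p < q` (wholly ordered, else the pair contributes
#' nothing), all maximal diagonal runs of pairable positions clipped to the
#' rectangle and at least `min_stem_len` long are collected.
#'
#' @param pm A [build_pair_matrix()] result.
#' @param five,three Data frames with `start`/`end` columns (5' and 3' PCRs).
#' @return Stem matrix (columns `S`, `E`, `L`), deduplicated and sorted.
#' @export
collect_stems <- function(pm, five, three) {
  out <- list()
  for (f in seq_len(NROW(five))) {
    for (t in seq_len(NROW(three))) {
      i <- five$start[f]; j <- five$end[f]
      p <- three$start[t]; q <- three$end[t]
      if (!(i <= j && j < p && p <= q)) next
      for (s in (i + p):(j + q)) {
        a_lo <- max(i, s - q)
        a_hi <- min(j, s - p)
        if (a_hi < a_lo) next
        ii <- a_lo:a_hi
        vals <- pm$can[cbind(ii, s - ii)]
        r <- rle(vals)
        stop_at <- cumsum(r$lengths)
        start_at <- stop_at - r$lengths + 1L
        for (k in which(r$values)) {
          if (r$lengths[k] >= pm$min_stem_len) {
            out[[length(out) + 1L]] <- c(ii[start_at[k]],
                                         s - ii[start_at[k]],
                                         r$lengths[k])
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(empty_stems())
  m <- sort_stems(do.call(rbind, out))
  m[!duplicated(m), , drop = FALSE]
}

# ---- CSCP: priority-tree search for optimal compatible combinations --------

# Deterministic ordering of a list of stem sets: score descending, then
# lexicographic key.
order_stem_sets <- function(sets) {
  if (length(sets) == 0L) return(sets)
  sets <- lapply(sets, sort_stems)
  keys <- vapply(sets, stems_key, "")
  scores <- vapply(sets, stems_score, 0)
  sets[order(-scores, keys)]
}

dedupe_stem_sets <- function(sets) {
  keys <- vapply(sets, stems_key, "")
  sets[!duplicated(keys)]
}

#' Candidate-stem combination search (priority tree)
#'
#' Longer stems have higher priority.  Starting from the root combination
#' `initialC`, stems are added layer by layer in order of decreasing length:
#' at each layer, for each current node, the largest subsets of that
#' length's stems that are pairwise compatible and compatible with every
#' stem already in the node are found (all ties kept) and appended as child
#' nodes; a node with no compatible stem of the layer's length passes down
#' unchanged.  The leaf combinations of the lowest layer are returned,
#' sorted by total stem length (descending) then lexicographically.  Every
#' returned set is pairwise compatible, contains `initialC`, and is maximal
#' (no unused candidate can join without a conflict).
#'
#' The per-layer "largest compatible subset" problem is solved as a maximum
#' clique search on the compatibility graph (via igraph); the number of
#' nodes kept per layer is bounded by `cap` with deterministic pruning.
#'
#' @param candidates Candidate stem matrix (columns `S`, `E`, `L`).
#' @param initialC Initial combination; must itself be pairwise compatible.
#' @param cap Maximum nodes retained per layer; `Inf` disables pruning.
#' @param literal Compatibility mode, see [stems_compatible()].
#' @return List of stem matrices (the optimal combinations).
#' @export
cscp <- function(candidates, initialC = empty_stems(), cap = 50L,
                 literal = FALSE) {
  candidates <- sort_stems(candidates)
  candidates <- candidates[!duplicated(candidates), , drop = FALSE]
  initialC <- sort_stems(initialC)
  if (!stem_set_ok(initialC, literal)) {
    stop("cscp: initialC is not pairwise compatible")
  }
  nodes <- list(initialC)
  for (len in sort(unique(candidates[, "L"]), decreasing = TRUE)) {
    P <- candidates[candidates[, "L"] == len, , drop = FALSE]
    children <- list()
    for (node in nodes) {
      if (nrow(node) == 0L) {
        elig <- seq_len(nrow(P))
      } else {
        cm <- stem_compat_matrix(P, node, literal)
        elig <- which(rowSums(cm) == nrow(node))
      }
      if (length(elig) == 0L) {
        children[[length(children) + 1L]] <- node
        next
      }
      E <- P[elig, , drop = FALSE]
      if (length(elig) == 1L) {
        cliques <- list(1L)
      } else {
        adj <- stem_compat_matrix(E, E, literal)
        diag(adj) <- FALSE
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        cliques <- lapply(igraph::largest_cliques(g), as.integer)
      }
      for (cl in cliques) {
        children[[length(children) + 1L]] <-
          sort_stems(rbind(node, E[cl, , drop = FALSE]))
      }
    }
    nodes <- order_stem_sets(dedupe_stem_sets(children))
    if (is.finite(cap) && length(nodes) > cap) nodes <- nodes[seq_len(cap)]
  }
  order_stem_sets(dedupe_stem_sets(nodes))
}

#' Unpruned brute-force reference for the combination search
#'
#' Implements the identical priority semantics by recursive enumeration of
#' every subset at every priority layer (via [utils::combn()]), with no
#' clique search, no deduplication shortcuts and no width cap.  Serves as
#' the independent oracle for [cscp()] on small candidate sets.
#'
#' @inheritParams cscp
#' @return List of stem matrices, ordered as [cscp()].
#' @export
cscp_brute <- function(candidates, initialC = empty_stems(),
                       literal = FALSE) {
  candidates <- sort_stems(candidates)
  candidates <- candidates[!duplicated(candidates), , drop = FALSE]
  initialC <- sort_stems(initialC)
  if (!stem_set_ok(initialC, literal)) {
    stop("cscp_brute: initialC is not pairwise compatible")
  }
  recurse <- function(cands, C) {
    if (nrow(cands) == 0L) return(list(C))
    len <- max(cands[, "L"])
    P <- cands[cands[, "L"] == len, , drop = FALSE]
    rest <- cands[cands[, "L"] < len, , drop = FALSE]
    valid <- list()
    for (sz in seq_len(nrow(P))) {
      for (pick in as.data.frame(utils::combn(nrow(P), sz))) {
        sub <- P[pick, , drop = FALSE]
        union <- rbind(C, sub)
        if (stem_set_ok(union, literal)) {
          valid[[length(valid) + 1L]] <- sub
        }
      }
    }
    if (length(valid) == 0L) {
      children <- list(C)
    } else {
      sizes <- vapply(valid, nrow, 0L)
      best <- valid[sizes == max(sizes)]
      children <- lapply(best, function(sub) sort_stems(rbind(C, sub)))
    }
    out <- list()
    for (child in children) out <- c(out, recurse(rest, child))
    out
  }
  order_stem_sets(dedupe_stem_sets(recurse(candidates, initialC)))
}

# ---- usage rates ------------------------------------------------------------

#' Usage rate of a stem combination over its PCR group
#'
#' `H` and `G` count the bases of the group's 5' and 3' PCRs; `h` and `g`
#' count the combination's 5'-side and 3'-side bases lying inside those
#' PCRs.  The rates are `h/H`, `g/G` and their mean.
#'
#' @param five,three PCR data frames (`start`, `end`).
#' @param combination Stem matrix.
#' @return List with `H`, `G`, `h`, `g`, `rate5`, `rate3`, `rate`.
#' @export
compute_rate <- function(five, three, combination) {
  expand <- function(df) {
    if (NROW(df) == 0L) return(integer(0))
    unlist(lapply(seq_len(nrow(df)), function(k) df$start[k]:df$end[k]))
  }
  F5 <- expand(five); F3 <- expand(three)
  H <- length(F5); G <- length(F3)
  if (H == 0L || G == 0L) {
    stop("compute_rate: degenerate PCR group (H or G is zero)")
  }
  combination <- as_stems(combination)
  if (nrow(combination) == 0L) {
    h <- 0L; g <- 0L
  } else {
    h <- sum(stem_bases(combination, "5") %in% F5)
    g <- sum(stem_bases(combination, "3") %in% F3)
  }
  rate5 <- h / H; rate3 <- g / G
  list(H = H, G = G, h = h, g = g,
       rate5 = rate5, rate3 = rate3, rate = (rate5 + rate3) / 2)
}

# ---- the three selection steps ----------------------------------------------

# Candidate stems between one 5' PCR and one 3' PCR, cached per class run.
pair_stem_cache <- function(pm) {
  cache <- new.env(parent = emptyenv())
  function(f, t) {
    key <- sprintf("%d-%d:%d-%d", f$start, f$end, t$start, t$end)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- collect_stems(pm,
                         data.frame(start = f$start, end = f$end),
                         data.frame(start = t$start, end = t$end))
    cache[[key]] <- val
    val
  }
}

# Enumerate and evaluate PCR groups of size `size`; returns pooled accepted
# stems and the removal bookkeeping.  `accept` is one of "rate1" (step 1),
# "side1" (step 2), "gt" (step 3, threshold `thr`).
process_pcr_groups <- function(pcrs, size, pm, get_stems, accept, thr,
                               cap, literal) {
  pooled <- empty_stems()
  accepted_groups <- list()
  m <- nrow(pcrs)
  if (m < size || !any(pcrs$side == "5") || !any(pcrs$side == "3")) {
    return(list(pooled = pooled, accepted = accepted_groups))
  }
  combos <- utils::combn(m, size)
  for (col in seq_len(ncol(combos))) {
    idx <- combos[, col]
    grp <- pcrs[idx, , drop = FALSE]      # pcrs sorted by start
    # groups whose extreme PCRs cannot form stems are discarded
    if (grp$side[1L] != "5" || grp$side[nrow(grp)] != "3") next
    five <- grp[grp$side == "5", , drop = FALSE]
    three <- grp[grp$side == "3", , drop = FALSE]
    cand <- list()
    cover5 <- integer(0); cover3 <- integer(0)
    for (f in seq_len(nrow(five))) {
      for (t in seq_len(nrow(three))) {
        if (five$end[f] >= three$start[t]) next
        st <- get_stems(five[f, ], three[t, ])
        if (nrow(st) > 0L) {
          cand[[length(cand) + 1L]] <- st
          cover5 <- c(cover5, stem_bases(st, "5"))
          cover3 <- c(cover3, stem_bases(st, "3"))
        }
      }
    }
    if (length(cand) == 0L) next
    F5 <- unlist(lapply(seq_len(nrow(five)),
                        function(k) five$start[k]:five$end[k]))
    F3 <- unlist(lapply(seq_len(nrow(three)),
                        function(k) three$start[k]:three$end[k]))
    cov5 <- sum(F5 %in% cover5) / length(F5)
    cov3 <- sum(F3 %in% cover3) / length(F3)
    # necessary coverage bounds: h <= |cover5 ∩ F5|, g <= |cover3 ∩ F3|
    feasible <- switch(accept,
      rate1 = cov5 >= 1 && cov3 >= 1,
      side1 = cov5 >= 1 || cov3 >= 1,
      gt    = (cov5 + cov3) / 2 > thr
    )
    if (!feasible) next
    cand <- do.call(rbind, cand)
    leaves <- cscp(cand, empty_stems(), cap = cap, literal = literal)
    best <- leaves[[1L]]                   # highest score, lexicographic tie
    rate <- compute_rate(five, three, best)
    ok <- switch(accept,
      rate1 = rate$rate == thr,
      side1 = rate$rate5 == thr || rate$rate3 == thr,
      gt    = rate$rate > thr
    )
    if (ok) {
      pooled <- rbind(pooled, best)
      accepted_groups[[length(accepted_groups) + 1L]] <-
        list(idx = idx, rate = rate)
    }
  }
  pooled <- sort_stems(pooled)
  pooled <- pooled[!duplicated(pooled), , drop = FALSE]
  list(pooled = pooled, accepted = accepted_groups)
}

#' Run one selection step over a class's PCRs
#'
#' Step 1 examines PCR groups of sizes 2, 3 then 4 and accepts a group's
#' best first-kind combination only at full usage (`rate == 1`), removing
#' every PCR that contributed a base to the updated optimal set after each
#' group size.  Step 2 examines pairs and accepts when a single side is
#' fully used (`rate5 == 1` or `rate3 == 1`), removing the fully-used
#' sides.  Step 3 examines pairs and accepts when `rate > 0.6` (strict);
#' no PCRs are removed afterwards.  After the groups of a size are
#' processed, the pooled accepted stems are re-combined with the running
#' optimal set as the initial combination (the second-kind combination).
#'
#' @param step 1, 2 or 3.
#' @param pcrs PCR data frame for one class, sorted by `start`.
#' @param pm A [build_pair_matrix()] result.
#' @param optimal_set Running optimal stem combination.
#' @param config A [correction_config()].
#' @return List with `optimal_set`, `leaves` (combinations of the last
#'   second-kind search), and `pcrs` (survivors).
#' @export
run_step <- function(step, pcrs, pm, optimal_set = empty_stems(),
                     config = correction_config()) {
  stopifnot(step %in% 1:3)
  get_stems <- pair_stem_cache(pm)
  leaves <- list(sort_stems(optimal_set))
  sizes <- if (step == 1L) 2:4 else 2L
  accept <- c("rate1", "side1", "gt")[step]
  thr <- switch(step, config$rate_step1, config$rate_step2, config$rate_step3)
  for (size in sizes) {
    res <- process_pcr_groups(pcrs, size, pm, get_stems, accept, thr,
                              config$cap, config$literal_compat)
    if (nrow(res$pooled) > 0L) {
      leaves <- cscp(res$pooled, initialC = optimal_set, cap = config$cap,
                     literal = config$literal_compat)
      optimal_set <- leaves[[1L]]
    }
    if (step == 1L) {
      used <- stem_bases(optimal_set)
      if (length(used) > 0L && nrow(pcrs) > 0L) {
        hit <- vapply(seq_len(nrow(pcrs)), function(k) {
          any(seq(pcrs$start[k], pcrs$end[k]) %in% used)
        }, TRUE)
        pcrs <- pcrs[!hit, , drop = FALSE]
      }
    } else if (step == 2L) {
      drop <- integer(0)
      for (acc in res$accepted) {
        grp <- pcrs[acc$idx, , drop = FALSE]
        if (acc$rate$rate5 == thr) drop <- c(drop, acc$idx[grp$side == "5"])
        if (acc$rate$rate3 == thr) drop <- c(drop, acc$idx[grp$side == "3"])
      }
      if (length(drop) > 0L) pcrs <- pcrs[-unique(drop), , drop = FALSE]
    }
  }
  list(optimal_set = sort_stems(optimal_set), leaves = leaves, pcrs = pcrs)
}

# Run steps 1-3 for one bracket class; returns up to k_keep optimal
# combinations (leaves of the final search), best first.
class_fold <- function(pcrs, pm, config) {
  optimal <- empty_stems()
  leaves <- list(optimal)
  if (nrow(pcrs) > 0L) {
    for (step in 1:3) {
      res <- run_step(step, pcrs, pm, optimal, config)
      optimal <- res$optimal_set
      leaves <- res$leaves
      pcrs <- res$pcrs
    }
  }
  leaves <- order_stem_sets(dedupe_stem_sets(leaves))
  leaves[seq_len(min(config$k_keep, length(leaves)))]
}

# ---- extension --------------------------------------------------------------

#' Extend a stem combination along the pairing matrix
#'
#' Each stem is grown along its maximal diagonal, one pair at a time,
#' alternating the outer end (`(S-1, E+1)`) and the inner end
#' (`(S+L, E-L)`), stopping in a direction as soon as the next pair is not
#' pairable or would touch a base already used by any stem (original or
#' extended).  Stems are processed longest-first, then by `S` ascending.
#' The result stays pairwise compatible, extension never lowers the score,
#' and the operation is idempotent.
#'
#' @param combination Stem matrix.
#' @param pm A [build_pair_matrix()] result.
#' @param used Optional logical vector of length `pm$n` marking bases that
#'   extensions must additionally avoid (e.g. bases of other classes).
#' @return The extended stem matrix; input row order is preserved.
#' @export
extend_stems <- function(combination, pm, used = NULL) {
  stems <- as_stems(combination)
  if (is.null(used)) used <- logical(pm$n)
  if (nrow(stems) == 0L) return(stems)
  ord <- order(-stems[, "L"], stems[, "S"])
  for (b in stem_bases(stems)) used[b] <- TRUE
  for (r in ord) {
    S <- stems[r, "S"]; E <- stems[r, "E"]; L <- stems[r, "L"]
    outer_ok <- TRUE; inner_ok <- TRUE
    repeat {
      grew <- FALSE
      if (outer_ok) {
        a <- S - 1L; b <- E + 1L
        if (a >= 1L && b <= pm$n && pm$can[a, b] && !used[a] && !used[b]) {
          S <- a; E <- b; L <- L + 1L
          used[a] <- TRUE; used[b] <- TRUE
          grew <- TRUE
        } else {
          outer_ok <- FALSE
        }
      }
      if (inner_ok) {
        a <- S + L; b <- E - L
        if (a < b && pm$can[a, b] && !used[a] && !used[b]) {
          L <- L + 1L
          used[a] <- TRUE; used[b] <- TRUE
          grew <- TRUE
        } else {
          inner_ok <- FALSE
        }
      }
      if (!grew) break
    }
    stems[r, ] <- c(S, E, L)
  }
  stems
}

# ---- combination across classes ---------------------------------------------

#' Combine per-class substructures into pseudoknotted structures
#'
#' Takes up to `k_keep` optimal combinations per bracket class, forms the
#' cross product (one substructure per class), resolves cross-class base
#' conflicts in favour of the class whose combination scores higher (the
#' losing stem is trimmed from its conflicting end and dropped below
#' `min_stem_len`), extends every surviving stem, and ranks the resulting
#' structures by total paired bases (deterministic lexicographic
#' tie-break).  Crossings *between* classes are retained: they are the
#' pseudoknots.
#'
#' @param per_class List of three lists of stem matrices.
#' @param pm A [build_pair_matrix()] result.
#' @param config A [correction_config()].
#' @return List of candidate results, each with `structure`
#'   ([secondary_structure()]), `stems` (data frame with a `class` column),
#'   `db` (dot-bracket string) and `score`; best first.
#' @export
combine_substructures <- function(per_class, pm, config = correction_config()) {
  per_class <- lapply(per_class, function(x) {
    if (length(x) == 0L) list(empty_stems()) else x
  })
  results <- list()
  for (a in seq_along(per_class[[1L]])) {
    for (b in seq_along(per_class[[2L]])) {
      for (cc in seq_along(per_class[[3L]])) {
        pick <- list(per_class[[1L]][[a]], per_class[[2L]][[b]],
                     per_class[[3L]][[cc]])
        results[[length(results) + 1L]] <- assemble_one(pick, pm, config)
      }
    }
  }
  keys <- vapply(results, function(r) r$key, "")
  results <- results[!duplicated(keys)]
  scores <- vapply(results, function(r) r$score, 0)
  keys <- vapply(results, function(r) r$key, "")
  results[order(-scores, keys)]
}

# Assemble one cross-product choice: conflict resolution, extension,
# structure construction.
assemble_one <- function(pick, pm, config) {
  class_scores <- vapply(pick, stems_score, 0)
  class_order <- order(-class_scores, 1:3)
  used <- logical(pm$n)
  kept <- list()
  for (cls in class_order) {
    stems <- as_stems(pick[[cls]])
    if (nrow(stems) == 0L) next
    stems <- stems[order(-stems[, "L"], stems[, "S"]), , drop = FALSE]
    for (r in seq_len(nrow(stems))) {
      st <- trim_conflicts(stems[r, ], used, config$min_stem_len)
      if (is.null(st)) next
      for (bb in stem_bases(rbind(st))) used[bb] <- TRUE
      kept[[length(kept) + 1L]] <- c(st, cls)
    }
  }
  if (length(kept) == 0L) {
    structure0 <- secondary_structure(pm$n)
    return(list(structure = structure0,
                stems = data.frame(S = integer(0), E = integer(0),
                                   L = integer(0), class = integer(0)),
                db = pairs_to_dotbracket(structure0),
                score = 0, key = ""))
  }
  km <- do.call(rbind, kept)
  colnames(km) <- c("S", "E", "L", "class")
  # extension preserves row order, so class labels stay aligned
  km[, 1:3] <- extend_stems(km[, 1:3, drop = FALSE], pm)
  layers <- lapply(1:3, function(cls) {
    stems_to_pairs(km[km[, "class"] == cls, 1:3, drop = FALSE])
  })
  pairs <- do.call(rbind, layers)
  st <- secondary_structure(pm$n, pairs)
  db <- pairs_to_dotbracket(st, lapply(layers, function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    dimnames(m) <- list(NULL, c("i", "j"))
    m
  }))
  list(
    structure = st,
    stems = data.frame(S = km[, "S"], E = km[, "E"], L = km[, "L"],
                       class = km[, "class"]),
    db = db,
    score = nrow(st$pairs),
    key = paste(sprintf("%d.%d", st$pairs[, 1L], st$pairs[, 2L]),
                collapse = "|")
  )
}

# Trim a stem (S,E,L triple) so it touches no used base: repeatedly drop
# the conflicting end pair (outer first), giving up below min_len.
trim_conflicts <- function(st, used, min_len) {
  S <- st[[1L]]; E <- st[[2L]]; L <- st[[3L]]
  repeat {
    if (L < min_len) return(NULL)
    k <- 0:(L - 1L)
    conflict <- used[S + k] | used[E - k]
    if (!any(conflict)) return(c(S = S, E = E, L = L))
    if (conflict[1L]) {
      S <- S + 1L; E <- E - 1L; L <- L - 1L
    } else {
      L <- L - 1L
    }
  }
}

# ---- the full correction pipeline -------------------------------------------

#' Correct a symbol labelling into a pseudoknotted structure
#'
#' The full correction pipeline: extract PCRs per bracket class, run the
#' three usage-rate selection steps for each class to obtain its optimal
#' compatible stem combinations, combine one substructure per class into
#' pseudoknotted candidates, extend, and rank by total paired bases.  When
#' a reference structure is supplied (benchmark mode) the candidate with
#' the highest F-score against it is selected; otherwise the top-ranked
#' candidate is.
#'
#' @param record An [rna_record()].
#' @param symbols Predicted symbol string, same length as the sequence.
#' @param config A [correction_config()].
#' @param reference Optional [secondary_structure()] for best-by-F
#'   selection.
#' @return List with `best` (selected candidate: `structure`, `stems`,
#'   `db`, `score`), `candidates` (ranked list) and `db` (dot-bracket of
#'   the selection).
#' @examples
#' rec <- rna_record("hp", "GGGGAAAACCCC")
#' fold <- ibpmp_fold(rec, "((((....))))")
#' fold$db
#' @export
ibpmp_fold <- function(record, symbols, config = correction_config(),
                       reference = NULL) {
  n <- nchar(record$sequence)
  if (nchar(symbols) != n) {
    stop("ibpmp_fold: symbol string length ", nchar(symbols),
         " != sequence length ", n)
  }
  pm <- build_pair_matrix(record$sequence, config$min_stem_len,
                          config$min_loop)
  pcrs <- extract_pcrs(symbols)
  per_class <- lapply(pcrs, class_fold, pm = pm, config = config)
  candidates <- combine_substructures(per_class, pm, config)
  if (!is.null(reference)) {
    fs <- vapply(candidates, function(cand) {
      pair_metrics(cand$structure, reference)$F
    }, 0)
    best <- candidates[[which.max(fs)]]   # ties keep the earlier rank
  } else {
    best <- candidates[[1L]]
  }
  list(best = best, candidates = candidates, db = best$db)
}

#' Read a labelling naively as a structure (no correction)
#'
#' Baseline for measuring what the correction stage adds: each bracket
#' class is matched with a stack, unmatched closings and leftover openings
#' are treated as unpaired, and no pairing or stem constraint is checked.
#'
#' @param symbols Symbol string over the 7-symbol alphabet.
#' @return A [secondary_structure()].
#' @export
naive_pairs_from_symbols <- function(symbols) {
  sym <- strsplit(symbols, "")[[1]]
  pairs <- list()
  for (l in 1:3) {
    stack <- integer(0)
    for (pos in seq_along(sym)) {
      if (sym[pos] == DB_OPEN[l]) {
        stack <- c(stack, pos)
      } else if (sym[pos] == DB_CLOSE[l] && length(stack) > 0L) {
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], pos)
        stack <- stack[-length(stack)]
      }
    }
  }
  secondary_structure(length(sym), do.call(rbind, pairs))
}
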