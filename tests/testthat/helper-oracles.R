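# Independent oracles and generators shared across tests.  These
# deliberately re-derive quantities by brute force / first principles and
# never call the implementation paths they are used to check.

# Pair-set-level compatibility: expand both stems to explicit pair sets and
# check base disjointness plus absence of crossings.
oracle_stems_compatible <- function(s1, s2) {
  expand <- function(s) {
    k <- 0:(s[3] - 1)
    cbind(s[1] + k, s[2] - k)
  }
  p1 <- expand(s1)
  p2 <- expand(s2)
  bases1 <- c(p1[, 1], p1[, 2])
  bases2 <- c(p2[, 1], p2[, 2])
  if (length(intersect(bases1, bases2)) > 0) return(FALSE)
  for (a in seq_len(nrow(p1))) {
    for (b in seq_len(nrow(p2))) {
      i1 <- p1[a, 1]; j1 <- p1[a, 2]; i2 <- p2[b, 1]; j2 <- p2[b, 2]
      if ((i1 < i2 && i2 < j1 && j1 < j2) ||
          (i2 < i1 && i1 < j2 && j2 < j1)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Random plausible stem within [1, n] honouring the loop constraint.
random_stem <- function(n, min_loop = 3) {
  repeat {
    L <- sample(1:4, 1)
    span_min <- 2 * L + min_loop + 1
    if (span_min > n) next
    S <- sample(n - span_min + 1, 1)
    e_range <- (S + span_min - 1):n
    E <- e_range[sample.int(length(e_range), 1)]
    return(c(S, E, L))
  }
}

# Brute-force enumeration of all maximal complementary diagonal runs of a
# sequence (direct definition: every run of pairable (i, j), (i+1, j-1), ...
# inextensible at both ends), independent of build_pair_matrix.
oracle_maximal_stems <- function(seq, min_stem_len = 2, min_loop = 3) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  ok <- function(i, j) {
    if (i < 1 || j > n || j - i < min_loop + 1) return(FALSE)
    pair <- paste0(bases[i], bases[j])
    pair %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  found <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!ok(i, j)) next
      if (ok(i - 1, j + 1)) next          # not a run start
      L <- 0
      while (ok(i + L, j - L)) L <- L + 1
      if (L >= min_stem_len) found[[length(found) + 1]] <- c(i, j, L)
    }
  }
  if (length(found) == 0) {
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("S", "E", "L"))))
  }
  m <- do.call(rbind, found)
  colnames(m) <- c("S", "E", "L")
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  m[!duplicated(m), , drop = FALSE]
}

# Brute-force stems clipped to a rectangle rows i..j, cols p..q (maximal
# within the area), independent of collect_stems.
oracle_area_stems <- function(seq, i, j, p, q, min_stem_len = 2,
                              min_loop = 3) {
  bases <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    if (a < i || a > j || b < p || b > q || b - a < min_loop + 1) return(FALSE)
    paste0(bases[a], bases[b]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  found <- list()
  for (a in i:j) {
    for (b in p:q) {
      if (!ok(a, b)) next
      if (ok(a - 1, b + 1)) next
      L <- 0
      while (ok(a + L, b - L)) L <- L + 1
      if (L >= min_stem_len) found[[length(found) + 1]] <- c(a, b, L)
    }
  }
  if (length(found) == 0) {
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("S", "E", "L"))))
  }
  m <- do.call(rbind, found)
  colnames(m) <- c("S", "E", "L")
  m[!duplicated(m), , drop = FALSE]
}

# Canonical string key of a list of stem sets, for comparing cscp outputs
# as sets.
stem_set_keys <- function(sets) {
  sort(vapply(sets, function(m) {
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    paste(sprintf("%d.%d.%d", m[, 1], m[, 2], m[, 3]), collapse = "|")
  }, ""))
}

# O(n^2) crossing check over an explicit pair matrix.
oracle_any_crossing <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2) return(FALSE)
  for (a in 1:(m - 1)) {
    for (b in (a + 1):m) {
      i1 <- pairs[a, 1]; j1 <- pairs[a, 2]
      i2 <- pairs[b, 1]; j2 <- pairs[b, 2]
      if ((i1 < i2 && i2 < j1 && j1 < j2) ||
          (i2 < i1 && i1 < j2 && j2 < j1)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Unambiguous instance batch used by several tests; pseudoknot share
# guaranteed by construction.
make_unambiguous_batch <- function(n_plain, n_pk, seed) {
  plain <- generate_dataset(n_plain, gen_config(
    length_range = c(70, 130), n_stems_range = c(1, 3),
    stem_len_range = c(3, 6), pk_prob = 0, unambiguous = TRUE, seed = seed
  ))
  pk <- generate_dataset(n_pk, gen_config(
    length_range = c(70, 130), n_stems_range = c(2, 3),
    stem_len_range = c(3, 6), pk_prob = 1, unambiguous = TRUE,
    seed = seed + 7919
  ))
  c(plain$instances, pk$instances)
}
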