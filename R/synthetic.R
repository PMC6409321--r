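# Synthetic instances: sequences with planted (optionally pseudoknotted)
# stems obeying A-U/G-C/G-U pairing, plus a labeller-noise model, so every
# stage of the pipeline is testable without external data.

# Run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample1 <- function(range) {
  if (range[1L] == range[2L]) return(as.integer(range[1L]))
  sample(range[1L]:range[2L], 1L)
}

#' Synthetic-instance generator configuration
#'
#' Defaults emulate short structured RNAs: lengths 70-150 nt, 2-4 planted
#' stems of 3-6 stacked pairs, pseudoknots in 30% of instances, 10% wobble
#' pairs.
#'
#' @param length_range Sequence length range (nt).
#' @param n_stems_range Number of planted stems.
#' @param stem_len_range Stacked pairs per stem.
#' @param pk_prob Probability an instance is forced to be pseudoknotted
#'   (requires at least two stems).
#' @param unambiguous Certify (by exhaustive stem enumeration) that within
#'   every PCR area the planted stem is the strict maximum and that the
#'   planted combination is inextensible, so a perfect labelling must be
#'   recovered exactly.
#' @param gu_fraction Fraction of planted pairs drawn as G-U wobbles.
#' @param min_stem_len,min_loop Constraints of the consuming correction
#'   config; planted stems honour them.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(length_range = c(70L, 150L),
                       n_stems_range = c(2L, 4L),
                       stem_len_range = c(3L, 6L),
                       pk_prob = 0.3,
                       unambiguous = FALSE,
                       gu_fraction = 0.1,
                       min_stem_len = 2L, min_loop = 3L,
                       seed = NULL) {
  stopifnot(length_range[1L] <= length_range[2L],
            n_stems_range[1L] <= n_stems_range[2L],
            stem_len_range[1L] >= min_stem_len,
            pk_prob >= 0, pk_prob <= 1,
            gu_fraction >= 0, gu_fraction <= 1)
  structure(
    list(length_range = as.integer(length_range),
         n_stems_range = as.integer(n_stems_range),
         stem_len_range = as.integer(stem_len_range),
         pk_prob = pk_prob, unambiguous = isTRUE(unambiguous),
         gu_fraction = gu_fraction,
         min_stem_len = as.integer(min_stem_len),
         min_loop = as.integer(min_loop),
         seed = seed),
    class = "gen_config"
  )
}

#' Noise model configuration
#'
#' `substitution` corrupts each symbol independently with probability
#' `epsilon`, replacing it with a uniformly chosen different symbol.
#' `boundary` instead shifts the boundaries of bracket runs by 1-2
#' positions (extending or shrinking runs), calibrated so the expected
#' fraction of changed symbols is about `epsilon`; run-boundary errors are
#' the characteristic labeller failure mode the usage-rate thresholds are
#' designed around.
#'
#' @param epsilon Per-symbol corruption probability in `[0, 1]`.
#' @param mode `"substitution"` or `"boundary"`.
#' @param seed Optional integer seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(epsilon, mode = c("substitution", "boundary"),
                         seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  structure(list(epsilon = epsilon, mode = match.arg(mode), seed = seed),
            class = "noise_config")
}

# Sample one placement of `k` stems in a length-`n` sequence.  Side
# intervals are kept >= 1 base apart (so each PCR is exactly one stem
# side) and the innermost pair honours the loop constraint.  Returns a
# stem matrix or NULL.
place_stems <- function(n, lens, min_loop, want_pk) {
  k <- length(lens)
  placed <- empty_stems()
  occupied <- logical(n)
  for (L in lens) {
    ok <- FALSE
    for (try in 1:60) {
      span_min <- 2L * L + min_loop + 1L
      if (n < span_min) break
      S <- sample.int(n - span_min + 1L, 1L)
      e_min <- S + span_min - 1L
      E <- if (e_min >= n) e_min else {
        e_min + sample.int(n - e_min + 1L, 1L) - 1L
      }
      five <- S:(S + L - 1L)
      three <- (E - L + 1L):E
      guard <- unique(pmax(1L, pmin(n, c(five, three,
                                         min(five) - 1L, max(five) + 1L,
                                         min(three) - 1L, max(three) + 1L))))
      if (any(occupied[guard])) next
      placed <- rbind(placed, c(S, E, L))
      occupied[c(five, three)] <- TRUE
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  placed <- as_stems(placed)
  st <- secondary_structure(n, stems_to_pairs(placed))
  pk <- is_pseudoknotted(st)
  if (want_pk != pk) return(NULL)
  layers <- tryCatch(decompose_to_layers(st), error = function(e) NULL)
  if (is.null(layers)) return(NULL)
  placed
}

# Assign bases: random unpaired positions, planted pairs drawn from
# {A-U, G-C, G-U} with the configured wobble fraction.
assign_bases <- function(n, stems, gu_fraction) {
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  pairs <- stems_to_pairs(stems)
  for (r in seq_len(nrow(pairs))) {
    type <- if (stats::runif(1) < gu_fraction) {
      c("G", "U")
    } else if (stats::runif(1) < 0.5) c("A", "U") else c("G", "C")
    if (stats::runif(1) < 0.5) type <- rev(type)
    bases[pairs[r, 1L]] <- type[1L]
    bases[pairs[r, 2L]] <- type[2L]
  }
  bases
}

# Planted stems annotated with the bracket class they render to in `db`.
planted_with_class <- function(stems, db) {
  sym <- strsplit(db, "")[[1]]
  cls <- vapply(seq_len(nrow(stems)), function(r) {
    match(sym[stems[r, "S"]], DB_OPEN)
  }, 0L)
  cbind(stems, class = cls)
}

# Certify an unambiguous instance: in every ordered PCR-area rectangle of
# every class, each non-planted candidate stem is strictly shorter than
# both parent planted stems, and the planted combination cannot be
# extended.
certify_unambiguous <- function(sequence, stems, db, min_stem_len, min_loop) {
  pm <- build_pair_matrix(sequence, min_stem_len, min_loop)
  ext <- extend_stems(stems, pm)
  if (!identical(sort_stems(ext), sort_stems(stems))) return(FALSE)
  pw <- planted_with_class(stems, db)
  pcrs <- extract_pcrs(db)
  planted_keys <- sprintf("%d.%d.%d", stems[, "S"], stems[, "E"], stems[, "L"])
  for (cls in 1:3) {
    p <- pcrs[[cls]]
    five <- p[p$side == "5", , drop = FALSE]
    three <- p[p$side == "3", , drop = FALSE]
    if (nrow(five) == 0L || nrow(three) == 0L) next
    # parent planted stem of each PCR (sides coincide exactly with PCRs)
    parent_of <- function(df, side) {
      vapply(seq_len(nrow(df)), function(k) {
        hit <- if (side == "5") {
          which(pw[, "S"] == df$start[k] &
                  pw[, "S"] + pw[, "L"] - 1L == df$end[k])
        } else {
          which(pw[, "E"] == df$end[k] &
                  pw[, "E"] - pw[, "L"] + 1L == df$start[k])
        }
        if (length(hit) != 1L) NA_integer_ else hit
      }, 0L)
    }
    par5 <- parent_of(five, "5")
    par3 <- parent_of(three, "3")
    if (anyNA(par5) || anyNA(par3)) return(FALSE)
    for (f in seq_len(nrow(five))) {
      for (t in seq_len(nrow(three))) {
        if (five$end[f] >= three$start[t]) next
        area <- collect_stems(pm, five[f, ], three[t, ])
        if (nrow(area) == 0L) next
        lim <- min(stems[par5[f], "L"], stems[par3[t], "L"])
        keys <- sprintf("%d.%d.%d", area[, "S"], area[, "E"], area[, "L"])
        alien <- !(keys %in% planted_keys)
        if (any(area[alien, "L"] >= lim)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Generate one synthetic instance
#'
#' Plants stems at random positions (with at least one unpaired base
#' between any two stem sides, so each PCR of a perfect labelling is
#' exactly one stem side), draws paired bases from the admissible pairings
#' and unpaired bases uniformly, and renders the true extended dot-bracket.
#' In unambiguous mode, instances failing certification have their
#' unpaired bases resampled (then are regenerated) until certification
#' passes.
#'
#' @param config A [gen_config()].
#' @return List with `record` ([rna_record()]), `structure`
#'   ([secondary_structure()]), `db` (true dot-bracket) and `stems`
#'   (planted stems with a `class` column).
#' @export
generate_instance <- function(config = gen_config()) {
  with_seed(config$seed, {
    result <- NULL
    for (attempt in 1:400) {
      n <- sample1(config$length_range)
      k <- sample1(config$n_stems_range)
      if (k == 0L) {
        bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
        rec <- rna_record(sprintf("syn_%06d", sample.int(1e6, 1L)),
                          paste(bases, collapse = ""))
        st <- secondary_structure(n)
        result <- list(record = rec, structure = st,
                       db = pairs_to_dotbracket(st),
                       stems = planted_with_class(empty_stems(),
                                                  strrep(".", n)))
        break
      }
      want_pk <- k >= 2L && stats::runif(1) < config$pk_prob
      lens <- vapply(seq_len(k), function(i) sample1(config$stem_len_range), 0L)
      stems <- place_stems(n, lens, config$min_loop, want_pk)
      if (is.null(stems)) next
      st <- secondary_structure(n, stems_to_pairs(stems))
      db <- pairs_to_dotbracket(st)
      for (base_try in 1:40) {
        bases <- assign_bases(n, stems, config$gu_fraction)
        seqc <- paste(bases, collapse = "")
        if (!config$unambiguous ||
            certify_unambiguous(seqc, stems, db,
                                config$min_stem_len, config$min_loop)) {
          rec <- rna_record(sprintf("syn_%06d", sample.int(1e6, 1L)), seqc)
          result <- list(record = rec, structure = st, db = db,
                         stems = planted_with_class(stems, db))
          break
        }
      }
      if (!is.null(result)) break
      # certification kept failing: fall through and replace the layout
    }
    if (is.null(result)) {
      stop("generate_instance: could not satisfy the configuration after ",
           "bounded retries")
    }
    result
  })
}

#' Corrupt a dot-bracket labelling
#'
#' @param db True dot-bracket string.
#' @param config A [noise_config()].
#' @return Corrupted symbol string of the same length.
#' @export
corrupt_symbols <- function(db, config) {
  with_seed(config$seed, {
    sym <- strsplit(db, "")[[1]]
    n <- length(sym)
    if (config$epsilon == 0 || n == 0L) {
      db
    } else if (config$mode == "substitution") {
      hit <- which(stats::runif(n) < config$epsilon)
      for (pos in hit) {
        sym[pos] <- sample(setdiff(DB_ALPHABET, sym[pos]), 1L)
      }
      paste(sym, collapse = "")
    } else {
      # boundary mode: shift run edges of bracket runs
      r <- rle(sym)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bracket_runs <- which(r$values != DB_DOT & r$values != "N")
      n_bound <- 2L * length(bracket_runs)
      if (n_bound == 0L) {
        db
      } else {
        q <- min(1, config$epsilon * n / (1.5 * n_bound))
        out <- sym
        for (k in bracket_runs) {
          val <- r$values[k]
          len <- r$lengths[k]
          for (edge in c("left", "right")) {
            if (stats::runif(1) >= q) next
            delta <- sample(1:2, 1L)
            if (stats::runif(1) < 0.5) {      # extend the run outwards
              tgt <- if (edge == "left") {
                (starts[k] - delta):(starts[k] - 1L)
              } else {
                (ends[k] + 1L):(ends[k] + delta)
              }
              tgt <- tgt[tgt >= 1L & tgt <= n]
              out[tgt] <- val
            } else {                          # shrink the run inwards
              delta <- min(delta, len - 1L)
              if (delta < 1L) next
              tgt <- if (edge == "left") {
                starts[k]:(starts[k] + delta - 1L)
              } else {
                (ends[k] - delta + 1L):ends[k]
              }
              out[tgt] <- DB_DOT
            }
          }
        }
        paste(out, collapse = "")
      }
    }
  })
}

#' Generate a dataset of synthetic instances
#'
#' Per-instance seeds are derived deterministically from the master seed,
#' so any instance can be replayed in isolation from the manifest.
#'
#' @param n Number of instances (>= 1).
#' @param config A [gen_config()]; its `seed` is the master seed.
#' @return List with `instances` and `manifest` (a tibble with id, length,
#'   stem count, pseudoknot flag and per-instance seed).
#' @export
generate_dataset <- function(n, config = gen_config()) {
  stopifnot(n >= 1L)
  master <- config$seed %||% 1L
  seeds <- (as.integer(master) + 1000L * seq_len(n)) %% 2147483587L
  instances <- lapply(seq_len(n), function(k) {
    cfg <- config
    cfg$seed <- seeds[k]
    inst <- generate_instance(cfg)
    inst$record$id <- sprintf("syn_%04d", k)
    inst
  })
  manifest <- do.call(rbind, lapply(seq_len(n), function(k) {
    inst <- instances[[k]]
    tibble::tibble(
      id = inst$record$id,
      length = inst$structure$length,
      n_stems = nrow(inst$stems),
      pseudoknotted = is_pseudoknotted(inst$structure),
      seed = seeds[k]
    )
  }))
  list(instances = instances, manifest = manifest)
}
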