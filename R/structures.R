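#' @keywords internal
"_PACKAGE"

# Extended dot-bracket alphabet: three bracket classes + unpaired dot.
DB_OPEN  <- c("(", "[", "{")
DB_CLOSE <- c(")", "]", "}")
DB_DOT   <- "."
DB_ALPHABET <- c("(", ")", "[", "]", "{", "}", ".")

#' RNA sequence record
#'
#' A single named RNA sequence over the alphabet `A, C, G, U, N`.
#' Input is normalised: `T` becomes `U` and lowercase becomes uppercase.
#' `N` marks an unknown (or padding) base; it is legal in a sequence but can
#' never form a base pair.
#'
#' @param id Record identifier (non-empty string).
#' @param sequence Base string; normalised on construction.
#' @return An object of class `rna_record` with fields `id` and `sequence`.
#' @examples
#' rna_record("toy", "ggtAA")$sequence  # "GGUAA"
#' @export
rna_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (!nzchar(seq)) {
    stop("rna_record: empty sequence for record '", id, "'")
  }
  bad <- regmatches(seq, regexpr("[^ACGUN]", seq))
  if (length(bad) > 0 && nzchar(bad)) {
    stop(
      "rna_record: sequence of '", id, "' contains character '", bad,
      "' outside {A,C,G,U,N}"
    )
  }
  structure(list(id = id, sequence = seq), class = "rna_record")
}

#' @export
print.rna_record <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<rna_record> %s (%d nt)\n", x$id, n))
  cat(substr(x$sequence, 1, 60), if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Has a record any unknown bases?
#'
#' Records whose sequence contains `N` cannot be fully folded and are
#' typically dropped during data cleaning.
#'
#' @param record An [rna_record()].
#' @return Logical scalar.
#' @export
has_unknown_bases <- function(record) {
  grepl("N", record$sequence, fixed = TRUE)
}

#' Secondary structure as a set of base pairs
#'
#' Stores a structure of length `length` as a two-column integer matrix of
#' 1-based pairs `(i, j)` with `i < j`.  Pairs may cross (pseudoknots are
#' legal here); each position may participate in at most one pair.
#'
#' @param length Sequence length the structure annotates.
#' @param pairs Two-column matrix (or data frame) of positions, or `NULL`
#'   for an unpaired structure.  Rows are normalised to `i < j` and sorted.
#' @return An object of class `secondary_structure`.
#' @examples
#' secondary_structure(10, cbind(c(1, 2), c(10, 9)))
#' @export
secondary_structure <- function(length, pairs = NULL) {
  stopifnot(is.numeric(length), length >= 1)
  length <- as.integer(length)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    stopifnot(ncol(pairs) == 2L)
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, 2:1]
    if (any(pairs[, 1L] == pairs[, 2L])) {
      stop("secondary_structure: a base cannot pair with itself")
    }
    if (any(pairs < 1L) || any(pairs > length)) {
      stop("secondary_structure: pair positions outside [1, ", length, "]")
    }
    pos <- as.vector(pairs)
    if (anyDuplicated(pos)) {
      stop(
        "secondary_structure: position ",
        pos[duplicated(pos)][1L], " participates in more than one pair"
      )
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(length = length, pairs = pairs),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf(
    "<secondary_structure> length %d, %d pairs%s\n",
    x$length, nrow(x$pairs),
    if (is_pseudoknotted(x)) " (pseudoknotted)" else ""
  ))
  invisible(x)
}

# Do pairs (i1,j1) and (i2,j2) cross (i1 < i2 < j1 < j2 in either order)?
pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

#' Does a structure contain crossing pairs?
#'
#' @param structure A [secondary_structure()].
#' @return `TRUE` if any two pairs cross, i.e. the structure is pseudoknotted.
#' @export
is_pseudoknotted <- function(structure) {
  p <- structure$pairs
  m <- nrow(p)
  if (m < 2L) return(FALSE)
  for (a in seq_len(m - 1L)) {
    b <- (a + 1L):m
    if (any(pairs_cross(p[a, 1L], p[a, 2L], p[b, 1L], p[b, 2L]))) return(TRUE)
  }
  FALSE
}

#' Decompose a structure into up to three non-crossing layers
#'
#' Pseudoknotted structures cannot be written with a single bracket class;
#' they are split into pseudoknot-free substructures (layers), one bracket
#' class each.  The assignment is greedy first-fit: pairs are sorted by
#' `(i` ascending, `j` descending`)` and each pair is placed in the
#' lowest-index layer where it crosses nothing already placed.  Structures
#' needing more than three layers are rejected.
#'
#' @param structure A [secondary_structure()].
#' @return List of three two-column pair matrices (some possibly empty).
#' @export
decompose_to_layers <- function(structure) {
  p <- structure$pairs
  layers <- rep(list(matrix(integer(0), ncol = 2L)), 3L)
  if (nrow(p) == 0L) return(layers)
  ord <- order(p[, 1L], -p[, 2L])
  p <- p[ord, , drop = FALSE]
  assign <- integer(nrow(p))
  for (k in seq_len(nrow(p))) {
    placed <- FALSE
    for (l in 1:3) {
      prev <- p[which(assign == l), , drop = FALSE]
      if (nrow(prev) == 0L ||
          !any(pairs_cross(p[k, 1L], p[k, 2L], prev[, 1L], prev[, 2L]))) {
        assign[k] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "decompose_to_layers: pair (%d,%d) requires a fourth layer; only three bracket classes are supported",
        p[k, 1L], p[k, 2L]
      ))
    }
  }
  for (l in 1:3) {
    lp <- p[assign == l, , drop = FALSE]
    lp <- lp[order(lp[, 1L]), , drop = FALSE]
    dimnames(lp) <- list(NULL, c("i", "j"))
    layers[[l]] <- lp
  }
  layers
}

#' Convert a pair set to extended dot-bracket notation
#'
#' Layer 1 is written with `()`, layer 2 with `[]`, layer 3 with `{}`;
#' unpaired positions are dots.  A precomputed layer assignment can be
#' supplied (e.g. when the caller already knows which substructure each pair
#' belongs to); otherwise [decompose_to_layers()] is used.
#'
#' @param structure A [secondary_structure()].
#' @param layers Optional list of three pair matrices partitioning
#'   `structure$pairs`.
#' @return Dot-bracket string of length `structure$length`.
#' @examples
#' pairs_to_dotbracket(secondary_structure(10, cbind(c(1, 2), c(10, 9))))
#' @export
pairs_to_dotbracket <- function(structure, layers = NULL) {
  if (is.null(layers)) layers <- decompose_to_layers(structure)
  out <- rep(DB_DOT, structure$length)
  for (l in seq_along(layers)) {
    lp <- layers[[l]]
    if (NROW(lp) == 0L) next
    out[lp[, 1L]] <- DB_OPEN[l]
    out[lp[, 2L]] <- DB_CLOSE[l]
  }
  paste(out, collapse = "")
}

#' Parse extended dot-bracket notation into a pair set
#'
#' Each bracket class is matched independently with a stack, so crossings
#' *between* classes (pseudoknots) are legal while crossings within a class
#' are impossible by construction.
#'
#' @param db Dot-bracket string over `( ) [ ] { } .`.
#' @return A [secondary_structure()] of the same length.
#' @export
dotbracket_to_pairs <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  sym <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(sym), DB_ALPHABET)
  if (length(bad) > 0) {
    stop("dotbracket_to_pairs: illegal symbol '", bad[1L], "'")
  }
  pairs <- list()
  for (l in 1:3) {
    stack <- integer(0)
    for (pos in seq_along(sym)) {
      if (sym[pos] == DB_OPEN[l]) {
        stack <- c(stack, pos)
      } else if (sym[pos] == DB_CLOSE[l]) {
        if (length(stack) == 0L) {
          stop(sprintf(
            "dotbracket_to_pairs: unmatched '%s' at position %d",
            DB_CLOSE[l], pos
          ))
        }
        pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], pos)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) {
      stop(sprintf(
        "dotbracket_to_pairs: unmatched '%s' at position %d",
        DB_OPEN[l], stack[length(stack)]
      ))
    }
  }
  secondary_structure(length(sym), do.call(rbind, pairs))
}

# ---- file formats -----------------------------------------------------------

#' Read a FASTA file of RNA sequences
#'
#' Sequences may span multiple lines; they are normalised (T to U,
#' uppercase) on construction.
#'
#' @param path Path to a FASTA file.
#' @return List of [rna_record()] in file order (empty list for empty file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0]
  records <- list()
  id <- NULL
  seq_parts <- character(0)
  flush <- function(line_no) {
    if (is.null(id)) return(invisible())
    if (length(seq_parts) == 0L) {
      stop("read_fasta: header '", id, "' has no sequence (line ",
           line_no, ")")
    }
    records[[length(records) + 1L]] <<-
      rna_record(id, paste(seq_parts, collapse = ""))
    invisible()
  }
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush(k)
      id <- trimws(sub("^>", "", line))
      if (!nzchar(id)) stop("read_fasta: empty header at line ", k)
      seq_parts <- character(0)
    } else {
      if (is.null(id)) {
        stop("read_fasta: sequence before any header at line ", k)
      }
      seq_parts <- c(seq_parts, line)
    }
  }
  flush(length(lines) + 1L)
  records
}

#' Write records to a FASTA file
#'
#' @param records List of [rna_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$sequence)))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read reciprocal pairing columns shared by CT and BPSEQ: `idx` position
# column, `pair` partner column (0 = unpaired).  Returns an i<j pair matrix.
reciprocal_pairs <- function(idx, pair, what) {
  n <- length(idx)
  if (!identical(idx, seq_len(n))) {
    dup <- idx[duplicated(idx)]
    if (length(dup) > 0) {
      stop(what, ": duplicate position index ", dup[1L])
    }
    stop(what, ": position column must run 1..", n)
  }
  if (any(pair < 0L | pair > n)) {
    stop(what, ": pairing partner outside [0, ", n, "]")
  }
  if (any(pair == idx)) stop(what, ": base paired with itself")
  paired <- which(pair > 0L)
  for (i in paired) {
    if (pair[pair[i]] != i) {
      stop(sprintf(
        "%s: non-reciprocal pairing, row %d names %d but row %d names %d",
        what, i, pair[i], pair[i], pair[pair[i]]
      ))
    }
  }
  sel <- paired[idx[paired] < pair[paired]]
  cbind(idx[sel], pair[sel])
}

#' Read a CT (connectivity table) file
#'
#' Standard 6-column CT: header line `n title`, then one row per base with
#' index, base, previous, next, pairing partner (0 = unpaired) and natural
#' numbering.  Pairing must be reciprocal.  CT imposes no non-crossing
#' restriction, so pseudoknots survive a round trip.
#'
#' @param path Path to a CT file.
#' @return List with elements `record` ([rna_record()]) and `structure`
#'   ([secondary_structure()]).
#' @export
read_ct <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("read_ct: empty file ", path)
  head_fields <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_fields[1L]))
  if (is.na(n) || n < 1L) {
    stop("read_ct: header line must start with the sequence length (line 1)")
  }
  id <- if (length(head_fields) > 1L) {
    paste(head_fields[-1L], collapse = " ")
  } else {
    basename(path)
  }
  body <- lines[-1L]
  if (length(body) != n) {
    stop("read_ct: expected ", n, " body rows, found ", length(body))
  }
  mat <- do.call(rbind, lapply(seq_along(body), function(k) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(f) < 6L) {
      stop("read_ct: row at line ", k + 1L, " has fewer than 6 columns")
    }
    f[1:6]
  }))
  idx <- as.integer(mat[, 1L])
  pair <- as.integer(mat[, 5L])
  record <- rna_record(id, paste(mat[, 2L], collapse = ""))
  pairs <- reciprocal_pairs(idx, pair, "read_ct")
  list(record = record, structure = secondary_structure(n, pairs))
}

#' Write a CT file
#'
#' @param record An [rna_record()].
#' @param structure A [secondary_structure()] with
#'   `length == nchar(record$sequence)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct <- function(record, structure, path) {
  n <- nchar(record$sequence)
  if (structure$length != n) {
    stop("write_ct: structure length ", structure$length,
         " != sequence length ", n)
  }
  partner <- integer(n)
  partner[structure$pairs[, 1L]] <- structure$pairs[, 2L]
  partner[structure$pairs[, 2L]] <- structure$pairs[, 1L]
  bases <- strsplit(record$sequence, "")[[1]]
  lines <- c(
    sprintf("%d %s", n, record$id),
    sprintf("%d %s %d %d %d %d", seq_len(n), bases,
            seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a BPSEQ file
#'
#' 3-column format: position, base, pairing partner (0 = unpaired).
#'
#' @param path Path to a BPSEQ file.
#' @param id Record id; defaults to the file name.
#' @return List with elements `record` and `structure`, as [read_ct()].
#' @export
read_bpseq <- function(path, id = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) < 1L) stop("read_bpseq: empty file ", path)
  mat <- do.call(rbind, lapply(seq_along(lines), function(k) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) != 3L) {
      stop("read_bpseq: row at line ", k, " does not have 3 columns")
    }
    f
  }))
  idx <- as.integer(mat[, 1L])
  pair <- as.integer(mat[, 3L])
  record <- rna_record(id, paste(mat[, 2L], collapse = ""))
  pairs <- reciprocal_pairs(idx, pair, "read_bpseq")
  list(record = record, structure = secondary_structure(length(idx), pairs))
}

#' Write a BPSEQ file
#'
#' @inheritParams write_ct
#' @return Invisibly, `path`.
#' @export
write_bpseq <- function(record, structure, path) {
  n <- nchar(record$sequence)
  if (structure$length != n) {
    stop("write_bpseq: structure length ", structure$length,
         " != sequence length ", n)
  }
  partner <- integer(n)
  partner[structure$pairs[, 1L]] <- structure$pairs[, 2L]
  partner[structure$pairs[, 2L]] <- structure$pairs[, 1L]
  bases <- strsplit(record$sequence, "")[[1]]
  writeLines(sprintf("%d %s %d", seq_len(n), bases, partner), path)
  invisible(path)
}

#' Read an extended dot-bracket file
#'
#' Simple three-line-per-record text format: `>id`, sequence line, structure
#' line (over the 7-symbol alphabet).
#'
#' @param path Path to the file.
#' @return List of lists with elements `record` and `db` (dot-bracket
#'   string).
#' @export
read_dotbracket <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    if (!startsWith(lines[k], ">")) {
      stop("read_dotbracket: expected '>' header at line ", k)
    }
    if (k + 2L > length(lines)) {
      stop("read_dotbracket: truncated record at line ", k)
    }
    rec <- rna_record(trimws(sub("^>", "", lines[k])), trimws(lines[k + 1L]))
    db <- trimws(lines[k + 2L])
    if (nchar(db) != nchar(rec$sequence)) {
      stop("read_dotbracket: structure length != sequence length for '",
           rec$id, "' (line ", k + 2L, ")")
    }
    out[[length(out) + 1L]] <- list(record = rec, db = db)
    k <- k + 3L
  }
  out
}

#' Write an extended dot-bracket file
#'
#' @param entries List of lists with elements `record` and `db`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dotbracket <- function(entries, path) {
  lines <- unlist(lapply(entries, function(e) {
    c(paste0(">", e$record$id), e$record$sequence, e$db)
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}
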