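test_that("pair matrix marks admissible pairs and indexes maximal stems", {
  pm <- build_pair_matrix("GGGAAACCC", min_stem_len = 2, min_loop = 3)
  # brute-force enumeration agrees
  expect_equal(unname(pm$stems), unname(oracle_maximal_stems("GGGAAACCC")))
  # the full-length stem is present and is the longest
  expect_true(any(pm$stems[, "S"] == 1 & pm$stems[, "E"] == 9 &
                    pm$stems[, "L"] == 3))
  expect_equal(max(pm$stems[, "L"]), 3)

  expect_equal(nrow(build_pair_matrix("AAAA")$stems), 0)
  # loop constraint: adjacent complementary bases cannot pair
  pm2 <- build_pair_matrix("GC")
  expect_equal(nrow(pm2$stems), 0)
  expect_false(any(pm2$can))

  # randomized agreement with the brute-force enumeration
  set.seed(33)
  for (k in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "U"), sample(8:16, 1),
                        replace = TRUE), collapse = "")
    expect_equal(unname(build_pair_matrix(seq)$stems),
                 unname(oracle_maximal_stems(seq)),
                 info = seq)
  }
})

test_that("PCR extraction finds maximal runs per class and side", {
  p <- extract_pcrs("((..))")
  expect_equal(p[[1]]$start, c(1L, 5L))
  expect_equal(p[[1]]$side, c("5", "3"))
  expect_equal(nrow(p[[2]]), 0)
  expect_equal(nrow(p[[3]]), 0)

  p <- extract_pcrs("((.[[.)).]]")
  expect_equal(p[[1]], data.frame(start = c(1L, 7L), end = c(2L, 8L),
                                  side = c("5", "3")),
               ignore_attr = TRUE)
  expect_equal(p[[2]], data.frame(start = c(4L, 10L), end = c(5L, 11L),
                                  side = c("5", "3")),
               ignore_attr = TRUE)

  p <- extract_pcrs("......")
  expect_true(all(vapply(p, nrow, 0L) == 0))
})

test_that("compatibility matches the printed examples and diverges as documented", {
  expect_true(stems_compatible(c(1, 20, 3), c(25, 40, 2)))   # separated
  expect_true(stems_compatible(c(1, 30, 3), c(6, 25, 4)))    # nested
  expect_false(stems_compatible(c(1, 20, 3), c(10, 30, 3)))  # crossing
  # symmetry
  expect_true(stems_compatible(c(25, 40, 2), c(1, 20, 3)))
  # the printed inequalities admit a base-overlapping pair that the strict
  # predicate rejects: stems (1,20,3) and (5,19,2) share bases 18-19
  expect_false(stems_compatible(c(1, 20, 3), c(5, 19, 2)))
  expect_true(stems_compatible(c(1, 20, 3), c(5, 19, 2), literal = TRUE))
  expect_false(oracle_stems_compatible(c(1, 20, 3), c(5, 19, 2)))
})

test_that("strict compatibility equals the pair-set-level checker on random stems", {
  set.seed(77)
  for (k in 1:2000) {
    s1 <- random_stem(40)
    s2 <- random_stem(40)
    expect_equal(stems_compatible(s1, s2), oracle_stems_compatible(s1, s2),
                 info = paste(c(s1, s2), collapse = ","))
  }
})

test_that("candidate stems are collected only from ordered PCR areas", {
  pm <- build_pair_matrix("GGGAAACCC")
  five <- data.frame(start = 1L, end = 3L)
  three <- data.frame(start = 7L, end = 9L)
  got <- collect_stems(pm, five, three)
  expect_equal(unname(got), unname(oracle_area_stems("GGGAAACCC", 1, 3, 7, 9)))
  expect_true(any(got[, "S"] == 1 & got[, "E"] == 9 & got[, "L"] == 3))

  # order violated: the 5' area must precede the 3' area
  expect_equal(nrow(collect_stems(pm, three, five)), 0)
  # no complementary diagonal in the area
  pm2 <- build_pair_matrix("GGGAAAGGG")
  expect_equal(nrow(collect_stems(pm2, five, three)), 0)
})

test_that("cscp handles the base cases", {
  init <- rbind(c(1, 30, 2))
  out <- cscp(matrix(integer(0), ncol = 3), initialC = init)
  expect_length(out, 1)
  expect_equal(unname(out[[1]]), unname(knotfold:::as_stems(init)))

  # two incompatible stems: the longer has priority, the shorter cannot join
  cands <- rbind(c(1, 40, 5), c(3, 38, 3))  # base-overlapping
  out <- cscp(cands)
  expect_length(out, 1)
  expect_equal(unname(out[[1]]), unname(knotfold:::as_stems(rbind(c(1, 40, 5)))))

  expect_error(cscp(cands, initialC = cands), "not pairwise compatible")
})

test_that("cscp extends a parent combination with the largest compatible subset", {
  # parent C = {S1, S2, S3} (telescoped nesting); candidates of one lower
  # priority {S4, S5, S6} where S5 conflicts with S3 and S4: the child set
  # gains exactly {S4, S6}
  S1 <- c(1, 200, 3); S2 <- c(10, 180, 3); S3 <- c(20, 160, 3)
  S4 <- c(30, 150, 2); S5 <- c(21, 150, 2); S6 <- c(40, 140, 2)
  expect_false(stems_compatible(S5, S3))
  expect_false(stems_compatible(S5, S4))
  out <- cscp(rbind(S4, S5, S6), initialC = rbind(S1, S2, S3))
  expect_length(out, 1)
  expect_equal(stem_set_keys(out),
               stem_set_keys(list(knotfold:::sort_stems(
                 rbind(S1, S2, S3, S4, S6)))))
})

test_that("cscp equals the unpruned brute-force reference on random instances", {
  set.seed(2024)
  for (k in 1:60) {
    n_c <- sample(2:10, 1)
    cands <- unique(t(replicate(n_c, random_stem(50))))
    got <- cscp(cands, cap = Inf)
    want <- cscp_brute(cands)
    expect_equal(stem_set_keys(got), stem_set_keys(want),
                 info = paste("instance", k))
    # structural invariants of every returned set
    for (set in got) {
      expect_true(knotfold:::stem_set_ok(set))
      unused <- cands[!(apply(cands, 1, paste, collapse = ".") %in%
                          apply(set, 1, paste, collapse = ".")), ,
                      drop = FALSE]
      for (r in seq_len(nrow(unused))) {
        compat_all <- all(apply(set, 1, function(s) {
          stems_compatible(unused[r, ], s)
        }))
        expect_false(compat_all)  # maximality
      }
    }
  }
})

test_that("usage rates follow the printed formulas", {
  five <- data.frame(start = 1L, end = 5L)
  three <- data.frame(start = 11L, end = 15L)
  r <- compute_rate(five, three, rbind(c(1, 15, 5)))
  expect_equal(r$rate5, 1)
  expect_equal(r$rate3, 1)
  expect_equal(r$rate, 1)

  # h = 3 of H = 5, g = 4 of G = 5 -> (0.6 + 0.8) / 2 = 0.7
  r <- compute_rate(five, three, rbind(c(1, 14, 3), c(6, 15, 1)))
  expect_equal(r$h, 3)
  expect_equal(r$g, 4)
  expect_equal(r$rate, 0.7)

  r <- compute_rate(five, three, NULL)
  expect_equal(r$rate, 0)

  expect_error(compute_rate(data.frame(start = integer(0), end = integer(0)),
                            three, NULL), "degenerate")
})

test_that("step 1 accepts perfectly tiled PCR pairs and removes them", {
  # perfect hairpin: the true stem exactly tiles both PCRs -> rate 1
  pm <- build_pair_matrix("GGGGAAAACCCC")
  pcrs <- extract_pcrs("((((....))))")[[1]]
  res <- run_step(1, pcrs, pm)
  expect_equal(unname(res$optimal_set), unname(knotfold:::as_stems(
    rbind(c(1, 12, 4)))))
  expect_equal(nrow(res$pcrs), 0)
})

test_that("a 75%-covered PCR pair is rejected by steps 1-2 and accepted by step 3", {
  # stem (1,12,3) but the labelling claims 4 bases per side: usage 0.75
  pm <- build_pair_matrix("GGGAAAAAACCC")
  pcrs <- extract_pcrs("((((....))))")[[1]]
  s1 <- run_step(1, pcrs, pm)
  expect_equal(nrow(s1$optimal_set), 0)
  expect_equal(nrow(s1$pcrs), 2)  # survives step 1
  s2 <- run_step(2, s1$pcrs, pm, s1$optimal_set)
  expect_equal(nrow(s2$optimal_set), 0)
  s3 <- run_step(3, s2$pcrs, pm, s2$optimal_set)
  expect_equal(unname(s3$optimal_set),
               unname(knotfold:::as_stems(rbind(c(1, 12, 3)))))
})

test_that("no PCRs leaves the optimal set unchanged", {
  pm <- build_pair_matrix("GGGGAAAACCCC")
  none <- extract_pcrs("............")[[1]]
  init <- rbind(c(1, 12, 2))
  res <- run_step(1, none, pm, init)
  expect_equal(unname(res$optimal_set),
               unname(knotfold:::as_stems(init)))
})

test_that("stem extension grows to the maximal diagonal and is idempotent", {
  pm <- build_pair_matrix("GGGAAACCC")
  ext <- extend_stems(rbind(c(2, 8, 2)), pm)
  expect_equal(unname(ext), unname(knotfold:::as_stems(rbind(c(1, 9, 3)))))
  # already maximal: unchanged, idempotent
  expect_equal(unname(extend_stems(ext, pm)), unname(ext))

  # two stems on one diagonal: the later-extended stem stops at the first
  # contested base
  pm2 <- build_pair_matrix("GGGGGGAAAACCCCCC")
  ext2 <- extend_stems(rbind(c(1, 16, 2), c(4, 13, 2)), pm2)
  expect_equal(unname(ext2),
               unname(knotfold:::as_stems(rbind(c(1, 16, 3), c(4, 13, 3)))))
  # score never decreases, result pairwise compatible
  expect_gte(knotfold:::stems_score(ext2), 4)
  expect_true(knotfold:::stem_set_ok(ext2))
})

test_that("extension never lowers the score on random combinations", {
  set.seed(91)
  for (k in 1:30) {
    inst <- generate_instance(gen_config(length_range = c(40, 80),
                                         n_stems_range = c(1, 3),
                                         pk_prob = 0.3, seed = 400 + k))
    pm <- build_pair_matrix(inst$record$sequence)
    all_used <- logical(pm$n)
    all_used[stem_bases(inst$stems[, c("S", "E", "L"), drop = FALSE])] <- TRUE
    for (cls in 1:3) {
      # per bracket class the planted combination is pairwise compatible;
      # other classes' bases are off limits, as in the full pipeline
      stems <- inst$stems[inst$stems[, "class"] == cls, c("S", "E", "L"),
                          drop = FALSE]
      if (nrow(stems) == 0) next
      used <- all_used
      used[stem_bases(stems)] <- FALSE
      ext <- extend_stems(stems, pm, used = used)
      expect_gte(knotfold:::stems_score(ext), knotfold:::stems_score(stems))
      expect_true(knotfold:::stem_set_ok(ext))
      expect_equal(unname(extend_stems(ext, pm, used = used)), unname(ext))
    }
  }
})

test_that("substructure combination keeps cross-class crossings and resolves conflicts", {
  # base-disjoint classes: the union survives
  inst <- generate_instance(gen_config(length_range = c(60, 90),
                                       n_stems_range = c(2, 2), pk_prob = 1,
                                       unambiguous = TRUE, seed = 1234))
  pm <- build_pair_matrix(inst$record$sequence)
  per_class <- lapply(1:3, function(cls) {
    s <- inst$stems[inst$stems[, "class"] == cls, c("S", "E", "L"),
                    drop = FALSE]
    if (nrow(s) == 0) list() else list(s)
  })
  combos <- combine_substructures(per_class, pm)
  top <- combos[[1]]
  expect_true(is_pseudoknotted(top$structure))
  expect_identical(top$structure$pairs, inst$structure$pairs)

  # two classes proposing the same base: the lower-scoring stem is trimmed
  pmx <- build_pair_matrix("GGGGGAAAACCCCC")  # rich in G-C diagonals
  big <- rbind(c(1, 14, 4))   # class 1, score 4
  small <- rbind(c(4, 11, 2)) # class 2, overlaps base 4 and 11
  combos <- combine_substructures(list(list(big), list(small), list()), pmx)
  top <- combos[[1]]
  pos <- as.vector(top$structure$pairs)
  expect_equal(anyDuplicated(pos), 0)
  cls1 <- top$stems[top$stems$class == 1, ]
  expect_equal(cls1$L, 5)  # winner extends along its diagonal
})

test_that("folding a perfect labelling recovers planted structures exactly", {
  # unambiguous hairpin
  inst <- generate_instance(gen_config(length_range = c(70, 100),
                                       n_stems_range = c(1, 1), pk_prob = 0,
                                       unambiguous = TRUE, seed = 5150))
  fold <- ibpmp_fold(inst$record, inst$db)
  expect_equal(pair_metrics(fold$best$structure, inst$structure)$F, 1)

  # unambiguous H-type pseudoknot: both stems recovered, two bracket classes
  instpk <- generate_instance(gen_config(length_range = c(70, 100),
                                         n_stems_range = c(2, 2), pk_prob = 1,
                                         unambiguous = TRUE, seed = 5151))
  fold <- ibpmp_fold(instpk$record, instpk$db)
  expect_equal(pair_metrics(fold$best$structure, instpk$structure)$F, 1)
  expect_true(is_pseudoknotted(fold$best$structure))
  expect_setequal(unique(fold$best$stems$class)[1:2], c(1, 2))

  # all-dots labelling folds to the empty structure
  rec <- rna_record("dots", "GGGGAAAACCCC")
  fold <- ibpmp_fold(rec, "............")
  expect_equal(nrow(fold$best$structure$pairs), 0)

  expect_error(ibpmp_fold(rec, "..."), "length")
})

test_that("folded structures never assign one base to two pairs", {
  set.seed(314)
  for (k in 1:15) {
    inst <- generate_instance(gen_config(length_range = c(60, 110),
                                         n_stems_range = c(1, 3),
                                         pk_prob = 0.4, seed = 8800 + k))
    noisy <- corrupt_symbols(inst$db, noise_config(0.1, seed = 8900 + k))
    fold <- ibpmp_fold(inst$record, noisy)
    pos <- as.vector(fold$best$structure$pairs)
    expect_equal(anyDuplicated(pos), 0)
  }
})

test_that("benchmark mode selects the candidate closest to the reference", {
  inst <- generate_instance(gen_config(length_range = c(70, 100),
                                       n_stems_range = c(2, 2), pk_prob = 0,
                                       unambiguous = TRUE, seed = 929))
  noisy <- corrupt_symbols(inst$db, noise_config(0.05, seed = 930))
  fold_ref <- ibpmp_fold(inst$record, noisy, reference = inst$structure)
  fold_top <- ibpmp_fold(inst$record, noisy)
  f_ref <- pair_metrics(fold_ref$best$structure, inst$structure)$F
  f_top <- pair_metrics(fold_top$best$structure, inst$structure)$F
  expect_gte(f_ref, f_top)
})

test_that("naive symbol reading matches brackets leniently", {
  st <- naive_pairs_from_symbols("((..))")
  expect_equal(unname(st$pairs), cbind(c(1L, 2L), c(6L, 5L)))
  # unmatched closings and leftovers become unpaired
  expect_equal(nrow(naive_pairs_from_symbols(")(..(")$pairs), 0)
  # crossing classes both matched
  st <- naive_pairs_from_symbols("((..[[..))..]]")
  expect_equal(nrow(st$pairs), 4)
})
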