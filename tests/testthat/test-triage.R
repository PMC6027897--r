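test_that("the 19 screened pre-hit wells partition correctly under 2-of-3", {
  ph <- call_prehits(prehit_zscore_table())
  # exactly two compounds exceeded Z > 2 in all three replicates
  triple <- ph$substance[ph$n_reps_above == 3]
  expect_setequal(triple, c("CRUSTECDYSONE", "PICEID"))
  # both thioguanine library wells fail the replicate rule
  thio <- ph[grepl("THIOGUANINE", ph$substance), ]
  expect_equal(nrow(thio), 2)
  expect_true(all(!thio$is_prehit))
  expect_true(all(thio$n_reps_above == 1))
})

test_that("the threshold is strict: Z equal to 2 never qualifies", {
  zt <- merge_replicates(list(
    data.frame(compound_id = "X", z = 2.0),
    data.frame(compound_id = "X", z = 2.0),
    data.frame(compound_id = "X", z = 2.0)))
  ph <- call_prehits(zt)
  expect_false(ph$is_prehit)
  expect_equal(ph$n_reps_above, 0)
})

test_that("triple-qualifiers land in all three pair rows (the 22 vs 18 arithmetic)", {
  ph <- call_prehits(prehit_zscore_table())
  pair_total <- sum(ph$qual_12) + sum(ph$qual_13) + sum(ph$qual_23)
  n_unique_prehits <- sum(ph$is_prehit)
  n_triples <- sum(ph$n_reps_above == 3)
  # each triple contributes two extra pair-row entries
  expect_equal(pair_total, n_unique_prehits + 2 * n_triples)
})

test_that("missing replicates restrict evaluation to available pairs", {
  zt <- merge_replicates(list(
    data.frame(compound_id = c("A", "B"), z = c(3, 3)),
    data.frame(compound_id = c("A", "B"), z = c(3, NA)),
    data.frame(compound_id = c("A", "B"), z = c(0.5, 3))))
  expect_message(ph <- call_prehits(zt), "missing a replicate")
  expect_true(ph$is_prehit[ph$compound_id == "A"])   # reps 1 and 2
  expect_true(ph$is_prehit[ph$compound_id == "B"])   # reps 1 and 3
  expect_false(ph$qual_12[ph$compound_id == "B"])
})

test_that("artifact filtering does subtractive bookkeeping per pair row", {
  mk_rep <- function(z, bg, ld)
    data.frame(compound_id = sprintf("C%02d", seq_along(z)), z = z,
               flag_high_bg = bg, flag_low_dmso = ld)
  # C01: clean pre-hit in reps 1&2; C02: pre-hit 1&2 but bg-flagged in 2;
  # C03: pre-hit 2&3, low-dmso in 3; C04: pre-hit 1&3 flagged both ways
  # (high background wins the category); C05: not a pre-hit though flagged
  zt <- merge_replicates(list(
    mk_rep(c(3, 3, 0, 3, 0), c(F, F, F, T, T), c(F, F, F, F, F)),
    mk_rep(c(3, 3, 3, 0, 0), c(F, T, F, F, F), c(F, F, F, F, F)),
    mk_rep(c(0, 0, 3, 3, 0), c(F, F, F, F, F), c(F, F, T, T, F))))
  rep <- apply_artifact_filters(call_prehits(zt))
  expect_s3_class(rep, "triage_report")
  r12 <- rep[rep$pair == "1&2", ]
  expect_equal(unlist(r12[, -1]), c(n_prehit = 2, n_high_bg = 1,
                                    n_low_dmso = 0, n_clean = 1))
  r23 <- rep[rep$pair == "2&3", ]
  expect_equal(unlist(r23[, -1]), c(n_prehit = 1, n_high_bg = 0,
                                    n_low_dmso = 1, n_clean = 0))
  r13 <- rep[rep$pair == "1&3", ]
  expect_equal(unlist(r13[, -1]), c(n_prehit = 1, n_high_bg = 1,
                                    n_low_dmso = 0, n_clean = 0))
  tot <- rep[rep$pair == "total", ]
  expect_equal(tot$n_prehit, sum(rep$n_prehit[rep$pair != "total"]))
  expect_equal(attr(rep, "clean_ids"), "C01")
  # additivity invariant on every row
  expect_true(all(rep$n_clean ==
                    rep$n_prehit - rep$n_high_bg - rep$n_low_dmso))
})

test_that("zero pre-hits give an all-zero report", {
  zt <- merge_replicates(list(
    data.frame(compound_id = "A", z = 0, flag_high_bg = TRUE,
               flag_low_dmso = FALSE),
    data.frame(compound_id = "A", z = 0, flag_high_bg = FALSE,
               flag_low_dmso = FALSE),
    data.frame(compound_id = "A", z = 0, flag_high_bg = FALSE,
               flag_low_dmso = FALSE)))
  rep <- apply_artifact_filters(call_prehits(zt))
  expect_true(all(rep[, c("n_prehit", "n_high_bg", "n_low_dmso",
                          "n_clean")] == 0))
})

test_that("published per-pair counts reproduce the clean and total columns", {
  rep <- triage_from_counts(triage_count_table())
  expect_equal(rep$n_clean[rep$pair == "1&3"], 11)   # 44 - 30 - 3
  expect_equal(rep$n_clean[rep$pair == "1&2"], 25)   # 42 - 12 - 5
  expect_equal(rep$n_clean[rep$pair == "2&3"], 9)    # 76 - 64 - 3
  tot <- rep[rep$pair == "total", ]
  expect_equal(tot$n_prehit, 162)
  expect_equal(tot$n_high_bg, 106)
  expect_equal(tot$n_low_dmso, 11)
  expect_equal(tot$n_clean, 45)
  expect_error(triage_from_counts(data.frame(pair = "1&2", n_prehit = 5,
                                             n_high_bg = 4, n_low_dmso = 2)),
               "exceed")
})

test_that("substance deduplication is case-insensitive and order-preserving", {
  tab <- prehit_zscore_table()
  u <- unique_substances(tab$substance)
  expect_equal(u$n, 18)
  expect_equal(unique_substances("x")$n, 1)
  expect_equal(unique_substances(c("Ecdysone", " ECDYSONE "))$n, 1)
  expect_equal(unique_substances(character(0))$n, 0)
})

test_that("hit rate is a rounded percentage with a guarded denominator", {
  expect_identical(hit_rate(1, 2532), 0.04)
  expect_identical(hit_rate(0, 2532), 0)
  expect_identical(hit_rate(2532, 2532), 100)
  expect_error(hit_rate(1, 0), "positive")
})

test_that("planted strong hits are recalled and filtering raises precision", {
  recall <- numeric(20)
  tp_before <- fp_before <- tp_after <- fp_after <- 0
  for (s in 1:20) {
    scr <- sim_hit_screen(seed = 400 + s, n_plates = 8, hit_every = 45)
    zt <- screen_ztable(scr$areas)
    ph <- call_prehits(zt)
    rescues <- scr$cfg$hit_rescues
    strong <- scr$hits[rescues >= 0.8]
    called <- ph$compound_id[ph$is_prehit]
    recall[s] <- mean(strong %in% called)
    rep <- apply_artifact_filters(ph)
    clean <- attr(rep, "clean_ids")
    tp_before <- tp_before + sum(called %in% scr$hits)
    fp_before <- fp_before + sum(!called %in% scr$hits)
    tp_after <- tp_after + sum(clean %in% scr$hits)
    fp_after <- fp_after + sum(!clean %in% scr$hits)
  }
  expect_gte(mean(recall), 0.90)
  prec_before <- tp_before / (tp_before + fp_before)
  prec_after <- tp_after / (tp_after + fp_after)
  expect_gt(prec_after, prec_before)
})
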