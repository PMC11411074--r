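cand <- function(spacer, prom = "P1", on = 0.5, hsu = 90, dang = 0, cfd = 0.5,
                 polyT = FALSE, gc = FALSE, dist = -100, pos = NA) {
  data.frame(spacer = spacer, promoter_id = prom, position = pos,
             on_target = on, off_target_agg = hsu, dangerous_in_genome = dang,
             cfd_max_ot = cfd, polyT_flag = polyT, gc_flag = gc,
             tss_distance = dist, stringsAsFactors = FALSE)
}

test_that("TSS distances are signed, strand-oriented, and CAGE-referenced", {
  proms <- data.frame(promoter_id = c("P1", "P2"), chrom = "chr1",
                      tss = c(10000, 20000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  cands <- rbind(
    cand("GAAAAAAAAAAAAAAAAAAA", "P1", pos = 10000, dist = NA),
    cand("GCCCCCCCCCCCCCCCCCCC", "P1", pos = 9880, dist = NA),
    cand("GTTTTTTTTTTTTTTTTTTT", "P2", pos = 20120, dist = NA)
  )
  # no CAGE peaks: fall back to the annotated TSS
  a <- annotate_tss_distance(cands, proms)
  expect_equal(a$tss_distance, c(0, -120, -120))  # minus strand flips the sign

  # strongest peak within +/-500 bp becomes the reference
  cage <- data.frame(chrom = "chr1", position = c(10100, 9700, 25000),
                     signal = c(5, 9, 100), stringsAsFactors = FALSE)
  b <- annotate_tss_distance(cands, proms, cage)
  expect_equal(b$tss_distance[1], 10000 - 9700)
  # equal-signal peaks: the one closest to the annotated TSS wins
  cage_tie <- data.frame(chrom = "chr1", position = c(10300, 10050),
                         signal = c(7, 7), stringsAsFactors = FALSE)
  d <- annotate_tss_distance(cands, proms, cage_tie)
  expect_equal(d$tss_distance[1], -50)
  expect_error(annotate_tss_distance(cand("GAAAAAAAAAAAAAAAAAAA", "P9"), proms),
               "unknown promoters")
})

test_that("the printed round criteria force pass/fail outcomes", {
  rounds <- default_selection_rounds()
  # all four Round-1 constraints satisfied
  r1 <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", on = 0.5, hsu = 90,
                           dang = 0, dist = -100))
  expect_equal(r1$selected$round, 1L)
  # distance outside [-150, -75] but inside [-400, -50]: admitted in Round 2
  r2 <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", dist = -300))
  expect_equal(r2$selected$round, 2L)
  # off-target aggregate 60 fails Rounds 1-2 (needs > 80), passes Round 3
  r3 <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", dist = -300, hsu = 60))
  expect_equal(r3$selected$round, 3L)
  # dangerous = 2 additionally fails Round 3 (needs <= 1)
  r4 <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", dist = -300, hsu = 60, dang = 2))
  expect_equal(r4$selected$round, 4L)
  # only Round 5 drops the distance requirement; CFD ceiling applies there
  r5 <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", dist = 500, hsu = 60, dang = 2))
  expect_equal(r5$selected$round, 5L)
  bad_cfd <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", dist = 500, cfd = 0.95))
  expect_equal(nrow(bad_cfd$selected), 0L)
  expect_equal(bad_cfd$shortfall$n_selected, 0L)
  # on-target below 0.2 never passes any round
  never <- select_guides(cand("GAAAAAAAAAAAAAAAAAAA", on = 0.1))
  expect_equal(nrow(never$selected), 0L)
})

test_that("flagged candidates are excluded regardless of scores", {
  perfect <- cand("GAAAAAAAAAAAAAAAAAAA", on = 1, hsu = 100, dang = 0, dist = -100)
  perfect$polyT_flag <- TRUE
  expect_equal(nrow(select_guides(perfect)$selected), 0L)
  perfect$polyT_flag <- FALSE
  perfect$gc_flag <- TRUE
  expect_equal(nrow(select_guides(perfect)$selected), 0L)
})

test_that("top-k ranking within a round follows on-target then distance", {
  six <- do.call(rbind, lapply(1:6, function(i) {
    cand(sprintf("G%019d", i), on = (10 - i) / 10, dist = -100)
  }))
  out <- select_guides(six, k = 4)
  expect_equal(nrow(out$selected), 4L)
  expect_equal(out$selected$on_target, c(0.9, 0.8, 0.7, 0.6))
  expect_true(all(out$selected$round == 1L))
  # on-target tie broken by |tss_distance|
  tie <- rbind(cand("GAAAAAAAAAAAAAAAAAAA", on = 0.5, dist = -140),
               cand("GCCCCCCCCCCCCCCCCCCC", on = 0.5, dist = -80))
  sel_tie <- select_guides(tie, k = 1)
  expect_equal(sel_tie$selected$spacer, "GCCCCCCCCCCCCCCCCCCC")
})

test_that("rounds 1-4 are successive relaxations", {
  rounds <- default_selection_rounds()
  set.seed(9)
  rand <- do.call(rbind, lapply(1:300, function(i) {
    cand(sprintf("G%019d", i), on = runif(1), hsu = runif(1, 0, 100),
         dang = sample(0:3, 1), cfd = runif(1),
         dist = round(runif(1, -600, 200)))
  }))
  for (r in 1:3) {
    pass_r <- crisprascreen:::round_pass(rand, rounds[r, ])
    pass_next <- crisprascreen:::round_pass(rand, rounds[r + 1, ])
    expect_true(all(pass_next[pass_r]), label = paste("round", r, "to", r + 1))
  }
})

test_that("selection is deterministic and order-invariant", {
  set.seed(10)
  rand <- do.call(rbind, lapply(1:60, function(i) {
    cand(sprintf("G%019d", i), prom = sample(c("P1", "P2", "P3"), 1),
         on = round(runif(1), 2), hsu = round(runif(1, 40, 100)),
         dang = sample(0:2, 1), cfd = runif(1),
         dist = round(runif(1, -500, 0)),
         polyT = runif(1) < 0.1, gc = runif(1) < 0.1)
  }))
  a <- select_guides(rand)
  b <- select_guides(rand[sample(nrow(rand)), ])
  key <- function(s) s[order(s$promoter_id, s$spacer),
                       c("promoter_id", "spacer", "round")]
  expect_equal(key(a$selected), key(b$selected), ignore_attr = TRUE)
  expect_true(all(table(a$selected$promoter_id) <= 4))
  expect_false(any(a$selected$polyT_flag | a$selected$gc_flag))
  # shortfall reporting
  one <- cand("GAAAAAAAAAAAAAAAAAAA")
  sh <- select_guides(one, k = 4)$shortfall
  expect_equal(sh$n_selected, 1L)
})
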