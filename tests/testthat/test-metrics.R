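hits_df <- function(evalue, bitscore, species = NULL, taxid = NULL) {
  n <- length(evalue)
  data.frame(query_id = "q", subject_id = paste0("s", seq_len(n)),
             evalue = evalue, bitscore = bitscore,
             subject_taxid = if (is.null(taxid)) seq_len(n) + 2000L else taxid,
             subject_species = if (is.null(species)) NA_character_ else species,
             stringsAsFactors = FALSE)
}

test_that("alien index matches direct log-ratio evaluation", {
  eps <- 1e-200
  h <- hits_df(c(1e-5, 1e-40), c(80, 200))
  aff <- c("INGROUP", "DONOR")
  expect_equal(alien_index(h, aff, eps),
               log(1e-5 + eps) - log(1e-40 + eps))
  # symmetric best e-values give 0
  expect_equal(alien_index(hits_df(c(1e-30, 1e-30), c(100, 100)), aff), 0)
  # missing ingroup side enters at e-value 1
  h2 <- hits_df(1e-40, 200)
  expect_equal(alien_index(h2, "DONOR", eps), log(1 + eps) - log(1e-40 + eps))
  # no usable hits: undefined
  expect_true(is.na(alien_index(h, c("EXCLUDED", "QUERY"))))
  # best hit = lowest e-value wins even with a higher-bitscore runner-up
  h3 <- hits_df(c(1e-10, 1e-8), c(50, 500))
  expect_equal(alien_index(h3, c("DONOR", "INGROUP"), eps),
               log(1e-8 + eps) - log(1e-10 + eps))
})

test_that("hgt index is the bitscore difference with 0 for missing sides", {
  h <- hits_df(c(1e-40, 1e-20), c(250, 180))
  expect_equal(hgt_index(h, c("DONOR", "INGROUP")), 70)
  expect_equal(hgt_index(h, c("DONOR", "DONOR")), 250)
  expect_equal(hgt_index(hits_df(1e-10, 100), "INGROUP"), -100)
  expect_equal(hgt_index(hits_df(c(1e-5, 1e-5), c(90, 90)),
                         c("DONOR", "INGROUP")), 0)
})

test_that("outg_pct counts distinct donor species among the top hits", {
  # 10 hits from 10 distinct bacterial species
  h <- hits_df(rep(1e-30, 10), 100:91, species = paste0("sp", 1:10))
  expect_equal(outg_pct(h, rep("DONOR", 10), top_n = 10), 100)
  # half donor, half ingroup
  h2 <- hits_df(rep(1e-30, 10), 100:91, species = paste0("sp", 1:10))
  expect_equal(outg_pct(h2, rep(c("DONOR", "INGROUP"), 5), top_n = 10), 50)
  # one species, many HSPs
  h3 <- hits_df(rep(1e-30, 10), 100:91, species = rep("onesp", 10))
  expect_equal(outg_pct(h3, rep("DONOR", 10), top_n = 10), 10)
  # fewer hits than top_n: denominator shrinks to the actual count
  h4 <- hits_df(rep(1e-30, 4), 100:97, species = paste0("sp", 1:4))
  expect_equal(outg_pct(h4, rep("DONOR", 4), top_n = 10), 100)
  expect_equal(outg_pct(h4[0, ], character(0)), 0)
})

test_that("normalized bitscore matches direct exponential evaluation", {
  expect_equal(normalized_bitscore(200, 200), 200)
  expect_equal(normalized_bitscore(50, 100), 50 * exp(-10))
  expect_equal(normalized_bitscore(90, 100), 90 * exp(-10 / 9))
  expect_error(normalized_bitscore(101, 100), "exceeds")
  expect_error(normalized_bitscore(0, 100), "positive")
  # alternative-denominator switch
  expect_equal(normalized_bitscore(50, 100, alt_denominator = TRUE),
               50 * exp(-10 * 50 / 100))
  # strictly increasing in bitscore for fixed hbitscore
  b <- seq(1, 300, length.out = 100)
  expect_true(all(diff(normalized_bitscore(b, 300)) > 0))
})

test_that("AHS agrees with an independent direct-evaluation oracle", {
  # frozen hand-computable case: one donor at HBitscore, one weak ingroup
  h <- hits_df(c(1e-40, 1e-5), c(100, 50))
  expect_equal(ahs(h, c("DONOR", "INGROUP")), 100 - 50 * exp(-10))
  expect_equal(ahs(h[0, ], character(0)), 0)
  # mirrored multisets cancel
  h2 <- hits_df(rep(1e-20, 6), c(100, 80, 60, 100, 80, 60))
  expect_equal(ahs(h2, rep(c("DONOR", "INGROUP"), each = 3)), 0)

  # 1000 random (bitscore, hbitscore) pairs vs direct evaluation
  set.seed(101)
  b <- runif(1000, 1, 500)
  hb <- b + runif(1000, 0, 200)
  oracle <- b * exp(-10 * (hb - b) / b)
  expect_equal(normalized_bitscore(b, hb), oracle, tolerance = 1e-12)

  # label-swap antisymmetry and permutation invariance on random tables
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:12, 1)
    h <- hits_df(10^runif(n, -80, -5), runif(n, 30, 400))
    aff <- sample(c("DONOR", "INGROUP"), n, replace = TRUE)
    swapped <- c(DONOR = "INGROUP", INGROUP = "DONOR")[aff]
    expect_equal(ahs(h, swapped), -ahs(h, aff))
    p <- sample(n)
    expect_equal(ahs(h[p, ], aff[p]), ahs(h, aff))
  }
})

test_that("stronger donor hits never decrease AI", {
  set.seed(7)
  for (i in 1:20) {
    e_in <- 10^runif(1, -60, -5)
    e_don <- sort(10^runif(2, -120, -5))
    h_weak <- hits_df(c(e_in, e_don[2]), c(100, 100))
    h_strong <- hits_df(c(e_in, e_don[1]), c(100, 100))
    aff <- c("INGROUP", "DONOR")
    expect_gte(alien_index(h_strong, aff), alien_index(h_weak, aff))
  }
})

test_that("candidate selection honours arbitrary metric predicates", {
  rows <- data.frame(query_id = c("a", "b", "c"),
                     AI = c(5, -2, -1), AHS = c(-3, 8, -1),
                     outg_pct = c(90, 10, 0))
  expect_equal(select_candidates(rows), c("a", "b"))  # AI>0 | AHS>0
  expect_equal(select_candidates(rows, AI > 0 & AHS > 0), character(0))
  expect_equal(select_candidates(rows, outg_pct >= 90), "a")
  # strict inequality at the boundary
  expect_equal(select_candidates(data.frame(query_id = "x", AI = 30, AHS = 0),
                                 AI > 30), character(0))
  expect_equal(select_candidates(rows[0, ]), character(0))
  # NA metrics are never selected
  rows$AI[1] <- NA
  expect_equal(select_candidates(rows, AI > 0), character(0))
})

test_that("F1 scan satisfies the 2PR/(P+R) identity and monotonicity", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    rows <- data.frame(query_id = paste0("q", seq_len(n)),
                       AI = round(runif(n, -20, 40), 2))
    pos <- rows$query_id[rows$AI > 0]
    if (length(pos) < 2) next
    confirmed <- sample(pos, sample(seq_along(pos), 1))
    grid <- sort(unique(c(0, runif(6, 0, 40))))
    scan <- f1_threshold_scan(rows, confirmed, grid)
    # Eq identity against an independently coded precision/recall form
    P <- scan$hgt_above / scan$genes_above
    R <- scan$hgt_above / scan$hgt_total
    both <- !is.na(P) & (P + R) > 0
    expect_equal(scan$F1[both], (2 * P * R / (P + R))[both], tolerance = 1e-12)
    # counts are non-increasing in N
    expect_true(all(diff(scan$genes_above) <= 0))
    expect_true(all(diff(scan$hgt_above) <= 0))
  }
})

test_that("F1 scan finds a separating threshold and handles degenerate input", {
  rows <- data.frame(query_id = paste0("q", 1:10),
                     AI = c(rep(25, 4), rep(5, 6)))
  confirmed <- paste0("q", 1:4)
  scan <- f1_threshold_scan(rows, confirmed, n_grid = 0:30)
  best <- attr(scan, "best_N")
  expect_gte(best, 5); expect_lt(best, 25)
  expect_equal(max(scan$F1), 1)
  # N = 0 closed form
  expect_equal(scan$F1[scan$N == 0], 2 * 4 / (4 + 10))
  # confirmed set must have AI > 0
  expect_error(f1_threshold_scan(rows, c("q1", "nope")), "AI > 0")
})

test_that("per-query metric rows separate a planted scenario and flag gaps", {
  ht <- make_hit_table(planted_scenario(seed = 5, n_queries = 10))
  m <- compute_metrics(ht$table, ht$taxonomy$spec, ht$taxonomy$tax)
  expect_equal(nrow(m), 10)
  hgt <- ht$truth[m$query_id] == "HGT"
  expect_true(all(m$AI[hgt] > 0 & m$AHS[hgt] > 0 & m$h[hgt] > 0))
  expect_true(all(m$AI[!hgt] < 0 & m$AHS[!hgt] < 0 & m$h[!hgt] < 0))
  expect_true(all(m$HBitscore >= m$best_donor_bitscore, na.rm = TRUE))
  # a query whose hits are all excluded is flagged undefined
  spec_ex <- ingroup_spec("NoSuchClade", 999L,
                          excluded_names = c("Metazoa", "Bacteria"))
  m2 <- compute_metrics(ht$table, spec_ex, ht$taxonomy$tax)
  expect_true(all(m2$flag == "undefined"))
  expect_true(all(is.na(m2$AI)))
  expect_true(all(m2$AHS == 0))
})
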