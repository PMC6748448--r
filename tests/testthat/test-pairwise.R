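test_that("accumulation matches hand counts on simple read sets", {
  rs <- read_set(c("a", "b", "c"), list(1L, 1L, 1L), list(4L, 4L, 4L),
                 list(c(1L, 3L), 1L, integer(0)),
                 rep(list(integer(0)), 3), 4L)
  acc <- accumulate_pairs(rs)
  expect_equal(unname(contingency_table(acc, 1, 3)), c(1L, 1L, 0L, 1L))
  expect_equal(pair_depth(acc, 1, 3), 3L)
  expect_equal(unname(contingency_table(acc, 2, 4)), c(0L, 0L, 0L, 3L))
})

test_that("mate gaps contribute only pairs with both positions covered", {
  rs <- read_set("pair", list(c(1L, 500L)), list(c(100L, 600L)),
                 list(integer(0)), list(integer(0)), 700L)
  acc <- accumulate_pairs(rs)
  expect_equal(pair_depth(acc, 50, 550), 1L)
  expect_equal(pair_depth(acc, 150, 550), 0L)  # 150 in the mate gap
  expect_equal(pair_depth(acc, 50, 90), 1L)    # within-mate pair
})

test_that("an empty read stream yields all-zero tables and no rings", {
  rs <- read_set(character(0), list(), list(), list(), list(), 10L)
  acc <- accumulate_pairs(rs)
  expect_true(all(acc$N == 0L))
  rings <- detect_rings(acc, depth_min = 1)
  expect_equal(nrow(rings), 0L)
})

test_that("pair accessors reject masked, reversed and out-of-range queries", {
  rs <- read_set("a", list(1L), list(10L), list(integer(0)),
                 list(integer(0)), 10L)
  acc <- accumulate_pairs(rs, mask = position_mask(5L))
  expect_error(pair_depth(acc, 3, 5), "masked")
  expect_error(pair_depth(acc, 7, 3), "i < j")
  expect_error(pair_depth(acc, 3, 11), "i < j")
  # masked position contributes to no table
  expect_equal(pair_depth(acc, 4, 6), 1L)
  expect_equal(unname(contingency_table(acc, 4, 6)), c(0L, 0L, 0L, 1L))
})

test_that("Yates chi-squared matches the continuity-corrected reference", {
  expect_equal(yates_chi2(10, 90, 90, 810), 0)  # proportional table
  expect_equal(yates_chi2(5, 95, 95, 9805), 12.4987246199, tolerance = 1e-9)
  expect_equal(yates_chi2(30, 370, 370, 19230), 60.1637338609, tolerance = 1e-9)
  # zero marginal and all-zero table are no evidence, not errors
  expect_equal(yates_chi2(0, 0, 5, 5), 0)
  expect_equal(yates_chi2(0, 0, 0, 0), 0)
})

test_that("phi coefficient is signed and matches the closed form", {
  expect_equal(phi_coeff(10, 90, 90, 810), 0)
  expect_equal(phi_coeff(5, 95, 95, 9805), 0.040404040404, tolerance = 1e-9)
  expect_equal(phi_coeff(0, 100, 100, 9800), -0.010101010101, tolerance = 1e-9)
  expect_true(is.na(phi_coeff(0, 0, 5, 5)))
})

test_that("chi2 and phi are invariant under transposition of the table", {
  set.seed(11)
  for (rep in 1:50) {
    tb <- rbinom(4, 500, 0.3)
    expect_equal(yates_chi2(tb[1], tb[2], tb[3], tb[4]),
                 yates_chi2(tb[1], tb[3], tb[2], tb[4]))
    expect_equal(phi_coeff(tb[1], tb[2], tb[3], tb[4]),
                 phi_coeff(tb[1], tb[3], tb[2], tb[4]))
  }
})

test_that("ring detection applies a strict threshold and depth floor", {
  # craft reads giving one strongly correlated pair at known depth
  n <- 400L
  both <- rep(list(c(1L, 5L)), 60)
  none <- rep(list(integer(0)), n - 60L)
  rs <- read_set(sprintf("r%03d", 1:n), rep(list(1L), n),
                 rep(list(6L), n), c(both, none),
                 rep(list(integer(0)), n), 6L)
  acc <- accumulate_pairs(rs)
  chi2_15 <- yates_chi2(60, 0, 0, 340)
  rings <- detect_rings(acc, chi2_min = 20, depth_min = 100)
  expect_true(nrow(rings) >= 1L)
  expect_true(all(rings$chi2 > 20))
  hit <- rings[rings$i == 1 & rings$j == 5, ]
  expect_equal(hit$chi2, chi2_15)
  expect_equal(hit$depth, n)
  # strictly "above": a pair exactly at the criterion is excluded
  expect_false(any(detect_rings(acc, chi2_min = chi2_15,
                                depth_min = 100)$i == 1))
  # depth floor excludes everything when set above the read count
  expect_equal(nrow(detect_rings(acc, depth_min = n + 1L)), 0L)
})

test_that("streaming accumulation equals the brute-force recount", {
  set.seed(101)
  for (rep in 1:20) {
    rs <- random_read_set(L = 25L, n = 40L)
    mask <- if (rep %% 3 == 0) c(5L, 17L) else integer(0)
    acc <- accumulate_pairs(rs, mask = mask)
    arr <- brute_force_tables(rs, mask = mask)
    expect_matches_brute_force(acc, arr, mask)
  }
})

test_that("pairwise depth equals the number of quality-passing reads covering both", {
  set.seed(55)
  rs <- random_read_set(L = 20L, n = 35L)
  acc <- accumulate_pairs(rs)
  q <- apply_quality_rule(rs)
  for (i in c(1L, 4L, 9L)) for (j in c(12L, 19L)) {
    n_cover <- sum(vapply(seq_along(q$id), function(r) {
      cov <- unlist(mapply(seq, q$starts[[r]], q$ends[[r]],
                           SIMPLIFY = FALSE))
      (i %in% cov) && (j %in% cov)
    }, TRUE))
    expect_equal(pair_depth(acc, i, j), n_cover)
    expect_equal(sum(contingency_table(acc, i, j)), n_cover)
  }
})

test_that("min_separation excludes short-range pairs only", {
  rs <- read_set("a", list(1L), list(10L), list(c(2L, 3L, 8L)),
                 list(integer(0)), 10L)
  acc <- accumulate_pairs(rs, min_separation = 5L)
  expect_error(pair_depth(acc, 2, 3), "min_separation")
  expect_equal(pair_depth(acc, 2, 8), 1L)
  arr <- brute_force_tables(rs, min_sep = 5L)
  expect_equal(unname(contingency_table(acc, 3, 8)),
               as.integer(arr[3, 8, ]))
})

test_that("replicate merging keeps sign-consistent pairs present in both", {
  a <- mk_rings(i = c(100L, 200L, 300L), j = c(550L, 600L, 700L),
                phi = c(0.04, 0.04, 0.04), L = 800L,
                chi2 = c(25, 30, 40), depth = 20000L)
  b <- mk_rings(i = c(100L, 300L), j = c(550L, 700L),
                phi = c(0.06, -0.04), L = 800L, chi2 = c(35, 22),
                depth = 30000L)
  m <- merge_replicates(a, b)
  # (200,600) only in a; (300,700) flips sign; (100,550) kept
  expect_equal(nrow(m), 1L)
  expect_equal(m$i, 100L)
  expect_equal(m$phi, 0.05)
  expect_equal(m$chi2, 25)            # min of replicates
  expect_equal(m$depth, 50000L)       # sum of replicates
  # output keys are a subset of both inputs
  expect_true(all(paste(m$i, m$j) %in% paste(a$i, a$j)))
  expect_true(all(paste(m$i, m$j) %in% paste(b$i, b$j)))
  # mismatched reference length is an error
  attr(b, "L") <- 900L
  expect_error(merge_replicates(a, b), "reference length")
})

test_that("merging is order-independent", {
  a <- mk_rings(c(1L, 2L), c(10L, 20L), c(0.04, -0.03), L = 30L,
                chi2 = c(25, 30))
  b <- mk_rings(c(1L, 2L), c(10L, 20L), c(0.08, -0.05), L = 30L,
                chi2 = c(40, 21))
  m1 <- merge_replicates(a, b)
  m2 <- merge_replicates(b, a)
  expect_equal(m1$phi, m2$phi)
  expect_equal(m1$chi2, m2$chi2)
  expect_equal(m1$depth, m2$depth)
})

test_that("detection interval equals a brute-force scan over all pairs", {
  set.seed(9)
  L <- 60L
  s <- simulation_scenario(paste(rep("A", L), collapse = ""),
                           rep(0.01, L), numeric(L), integer(L),
                           p_occ = numeric(0), seq_error = 0,
                           lowq_frac = 0, insert_min = 20L,
                           insert_max = 40L, mate_length = 8L,
                           n_fragments = 3000L, label = "geom")
  acc <- accumulate_pairs(simulate_reads(s, seed = 4))
  di <- detection_interval(acc, depth_required = 200)
  # brute force over contingency tables
  best <- 0L
  for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
    if (pair_depth(acc, i, j) >= 200 && (j - i) > best) best <- j - i
  }
  expect_equal(di$max_separation, best)
  expect_gt(best, 0L)
  expect_equal(di$depth_required, 200)
  # per-separation medians are medians of the actual depths
  sep5 <- di$by_separation[di$by_separation$separation == 5L, ]
  depths5 <- vapply(seq_len(L - 5L), function(i) pair_depth(acc, i, i + 5L),
                    1L)
  expect_equal(sep5$median_depth, median(depths5[depths5 > 0]))
  # empty case
  expect_equal(detection_interval(acc, depth_required = 1e9)$max_separation,
               0L)
})

test_that("ring TSV output round trips with thresholds and order", {
  a <- mk_rings(c(5L, 2L, 2L), c(9L, 30L, 8L), c(0.04, -0.03, 0.2),
                L = 40L, chi2 = c(25, 30, 45))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_rings(a, p)
  back <- read_rings(p)
  expect_equal(back$i, c(2L, 2L, 5L))  # deterministic order: i then j
  expect_equal(back$j, c(8L, 30L, 9L))
  expect_equal(attr(back, "L"), 40L)
  expect_equal(attr(back, "chi2_min"), 20)
  expect_equal(back$phi[order(back$i, back$j)],
               a$phi[order(a$i, a$j)], tolerance = 1e-5)
  # empty set round trips too
  e <- mk_rings(integer(0), integer(0), numeric(0), L = 40L)
  write_rings(e, p)
  expect_equal(nrow(read_rings(p)), 0L)
})
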