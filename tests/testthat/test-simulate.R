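test_that("scenario invariants are validated", {
  L <- 20L
  seqs <- paste(rep("A", L), collapse = "")
  ok <- simulation_scenario(seqs, rep(0.02, L), rep(0.3, L),
                            rep(1L, L), p_occ = 0.5, insert_min = 10L,
                            insert_max = 20L, mate_length = 5L,
                            n_fragments = 10L)
  expect_s3_class(ok, "sim_scenario")
  expect_error(simulation_scenario(seqs, rep(0.02, L), rep(0.99, L),
                                   rep(1L, L), p_occ = 0.5,
                                   insert_min = 10L, insert_max = 20L,
                                   mate_length = 5L, n_fragments = 10L),
               "base_rate \\+ d < 1")
  expect_error(simulation_scenario(seqs, rep(0.02, L), rep(0.3, L),
                                   rep(1L, L), p_occ = 0.5,
                                   insert_min = 10L, insert_max = 30L,
                                   mate_length = 5L, n_fragments = 10L),
               "insert")
  # members must be reactive
  gu <- paste(rep("G", L), collapse = "")
  expect_error(simulation_scenario(gu, rep(0.02, L), rep(0.3, L),
                                   rep(1L, L), p_occ = 0.5,
                                   insert_min = 10L, insert_max = 20L,
                                   mate_length = 5L, n_fragments = 10L),
               "reactive")
  # infeasible coupling
  s <- small_two_block_scenario()
  expect_error(simulation_scenario(s$sequence, s$base_rate, s$d, s$block,
                                   s$p_occ, insert_min = s$insert_min,
                                   insert_max = s$insert_max,
                                   mate_length = s$mate_length,
                                   n_fragments = 10L,
                                   couple = c(1L, 2L), couple_rho = 1.5),
               "infeasible")
})

test_that("simulation is deterministic: same seed, byte-identical MRF", {
  s <- small_two_block_scenario(n_fragments = 500L)
  p1 <- withr::local_tempfile(fileext = ".mrf")
  p2 <- withr::local_tempfile(fileext = ".mrf")
  write_mrf(simulate_reads(s, seed = 77), p1)
  write_mrf(simulate_reads(s, seed = 77), p2)
  expect_identical(readLines(p1), readLines(p2))
  write_mrf(simulate_reads(s, seed = 78), p2)
  expect_false(identical(readLines(p1), readLines(p2)))
})

test_that("fragment geometry respects insert bounds and mate gaps", {
  L <- 800L
  s <- simulation_scenario(paste(rep("A", L), collapse = ""),
                           rep(0.02, L), numeric(L), integer(L),
                           p_occ = numeric(0), seq_error = 0,
                           lowq_frac = 0, insert_min = 500L,
                           insert_max = 700L, mate_length = 150L,
                           n_fragments = 2000L, label = "geom")
  rs <- simulate_reads(s, seed = 5)
  frag_len <- vapply(seq_along(rs$id), function(r)
    rs$ends[[r]][length(rs$ends[[r]])] - rs$starts[[r]][1] + 1L, 1L)
  expect_true(all(frag_len >= 500L & frag_len <= 700L))
  expect_true(all(unlist(rs$ends) <= L) && all(unlist(rs$starts) >= 1L))
  # insert > 2 * mate_length always leaves a two-interval gap here
  expect_true(all(lengths(rs$starts) == 2L))
  mate_sizes <- vapply(seq_along(rs$id), function(r)
    all(rs$ends[[r]] - rs$starts[[r]] + 1L == 150L), TRUE)
  expect_true(all(mate_sizes))
  # fully merged mates when the insert cannot exceed twice the mate length
  s2 <- small_two_block_scenario(n_fragments = 50L)
  rs2 <- simulate_reads(s2, seed = 1)
  expect_true(all(lengths(rs2$starts) == 1L))
})

test_that("empirical marginal rates match the analytic expectation", {
  s <- small_two_block_scenario(n_fragments = 10000L)
  rs <- simulate_reads(s, seed = 9)
  prof <- compute_profile(rs)
  expect_rate <- expected_rate(s)
  se <- sqrt(expect_rate * (1 - expect_rate) / prof$depth)
  z <- abs(prof$rate - expect_rate) / se
  # 3-sigma calibration: ~99.7% expected inside; demand at least 95%
  expect_gte(mean(z <= 3), 0.95)
  expect_lt(max(z), 6)
})

test_that("expected phi follows the closed form", {
  s <- small_two_block_scenario()
  # p = 0.5, d = 0.3, b = 0.02, e = 0: phi = 0.0225 / 0.1411 = 0.1595
  s0 <- s; s0$seq_error <- 0
  expect_equal(expected_phi(s0, 1L, 2L), 0.159461374911, tolerance = 1e-9)
  # same-block pairs at the default error rate are slightly attenuated
  expect_lt(expected_phi(s, 1L, 2L), 0.159461374911)
  # cross-block pairs are uncorrelated without coupling
  expect_equal(expected_phi(s, 1L, 30L), 0)
  # zero increment on either side kills the correlation
  s1 <- s; s1$d[2] <- 0
  expect_equal(expected_phi(s1, 1L, 2L), 0)
  # coupled blocks have positive cross-block phi
  sc <- small_two_block_scenario(couple = c(1L, 2L), couple_rho = 0.8)
  expect_gt(expected_phi(sc, 1L, 30L), 0)
  expect_equal(expected_phi(sc, 1L, 30L),
               0.8 * expected_phi(sc, 1L, 2L), tolerance = 1e-12)
})

test_that("pipeline phi estimates agree with the analytic oracle", {
  s <- small_two_block_scenario(n_fragments = 30000L)
  acc <- accumulate_pairs(simulate_reads(s, seed = 17))
  tr <- ground_truth(s)
  ok <- 0L
  for (r in seq_len(nrow(tr$pairs))) {
    tb <- contingency_table(acc, tr$pairs$i[r], tr$pairs$j[r])
    phi_hat <- phi_coeff(tb[1], tb[2], tb[3], tb[4])
    n <- sum(tb)
    if (abs(phi_hat - tr$pairs$expected_phi[r]) <= 4 / sqrt(n))
      ok <- ok + 1L
  }
  expect_gte(ok / nrow(tr$pairs), 0.95)
})

test_that("coupled occupancy factors reproduce the requested correlation", {
  sc <- small_two_block_scenario(n_fragments = 30000L,
                                 couple = c(1L, 2L), couple_rho = 0.8)
  acc <- accumulate_pairs(simulate_reads(sc, seed = 23))
  # average empirical phi across cross-block pairs tracks the analytic
  # coupled value (individual pairs fluctuate)
  cross <- expand.grid(i = 1:10, j = 31:40)
  phis <- mapply(function(i, j) {
    tb <- contingency_table(acc, i, j)
    phi_coeff(tb[1], tb[2], tb[3], tb[4])
  }, cross$i, cross$j)
  expect_equal(mean(phis), expected_phi(sc, 1L, 31L), tolerance = 0.01)
  # without coupling the same average is near zero
  s0 <- small_two_block_scenario(n_fragments = 30000L)
  acc0 <- accumulate_pairs(simulate_reads(s0, seed = 23))
  phis0 <- mapply(function(i, j) {
    tb <- contingency_table(acc0, i, j)
    phi_coeff(tb[1], tb[2], tb[3], tb[4])
  }, cross$i, cross$j)
  expect_lt(abs(mean(phis0)), 0.01)
})

test_that("null scenarios produce no significant pairs at moderate depth", {
  s <- null_calibration_scenario(L = 40L, n_fragments = 20000L)
  acc <- accumulate_pairs(simulate_reads(s, seed = 19))
  rings <- detect_rings(acc, chi2_min = 20, depth_min = 1)
  expect_lte(nrow(rings), 1L)
  # |phi| stays within sampling noise of zero
  phis <- mapply(function(i, j) {
    tb <- contingency_table(acc, i, j)
    phi_coeff(tb[1], tb[2], tb[3], tb[4])
  }, c(1, 5, 10), c(20, 25, 40))
  expect_true(all(abs(phis) < 4 / sqrt(20000)))
})

test_that("the default domain scenario is a constant with the stated layout", {
  s1 <- default_domain_scenario(n_fragments = 100L)
  s2 <- default_domain_scenario(n_fragments = 100L)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$block, s2$block)
  expect_identical(s1$base_rate, s2$base_rate)
  expect_equal(s1$L, 1542L)
  expect_equal(length(s1$p_occ), 4L)
  expect_equal(tabulate(s1$block, 4L), c(40L, 40L, 40L, 40L))
  expect_equal(s1$insert_min, 500L)
  expect_equal(s1$insert_max, 700L)
  # members are reactive and blocks live in their stated windows
  bases <- strsplit(s1$sequence, "")[[1]]
  expect_true(all(bases[s1$block > 0L] %in% c("A", "C")))
  expect_true(all(which(s1$block == 1L) <= 560L))
  expect_true(all(which(s1$block == 2L) >= 561L &
                    which(s1$block == 2L) <= 890L))
  # the inner-head + spine block spans long-range pairs
  b4 <- which(s1$block == 4L)
  expect_gt(max(b4) - min(b4), 400L)
  expect_gt(max(b4), 1396L)
})

test_that("the ligand scenario plants a footprint and couples head domains", {
  s <- ligand_scenario(n_fragments = 100L)
  d <- default_domain_scenario(n_fragments = 100L)
  focal <- s$protect_pos
  expect_equal(s$block[focal], 3L)
  # modification probability scales by 0.25 before error folding:
  # unfold the observed rate r' = r + e(1-r) back to r = (r'-e)/(1-e)
  expect_equal((expected_rate(s, focal) - 0.001) / (1 - 0.001),
               0.25 * (expected_rate(d, focal) - 0.001) / (1 - 0.001),
               tolerance = 1e-12)
  # all other positions keep their rates
  others <- setdiff(seq_len(s$L), focal)
  expect_equal(expected_rate(s, others), expected_rate(d, others))
  # coupling creates positive cross-block phi absent in the apo scenario
  i3 <- which(s$block == 3L)[2]; i4 <- which(s$block == 4L)[1]
  expect_gt(expected_phi(s, i3, i4), 0)
  expect_equal(expected_phi(d, i3, i4), 0)
})
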