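# Independent oracles and fixture builders shared across tests.

# Naive per-read, per-pair recount of all contingency tables: enumerates
# every covered pair of every read explicitly. Deliberately quadratic and
# independent of the package's difference-array accumulator.
brute_force_tables <- function(rs, mask = integer(0), min_sep = 1L) {
  rs <- apply_quality_rule(rs)
  L <- rs$L
  arr <- array(0L, c(L, L, 4L),
               dimnames = list(NULL, NULL, c("n11", "n10", "n01", "n00")))
  for (r in seq_along(rs$id)) {
    cov <- unlist(mapply(seq, rs$starts[[r]], rs$ends[[r]],
                         SIMPLIFY = FALSE))
    cov <- setdiff(cov, mask)
    mut <- setdiff(rs$muts[[r]], mask)
    if (length(cov) < 2L) next
    for (i in cov) for (j in cov) {
      if (i < j && (j - i) >= min_sep) {
        cell <- if (i %in% mut && j %in% mut) 1L
                else if (i %in% mut) 2L
                else if (j %in% mut) 3L else 4L
        arr[i, j, cell] <- arr[i, j, cell] + 1L
      }
    }
  }
  arr
}

# compare an accumulator against the brute-force array, cell by cell
expect_matches_brute_force <- function(acc, arr, mask = integer(0)) {
  L <- acc$L
  got <- exp_tab <- NULL
  for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
    if (i %in% mask || j %in% mask) next
    got <- rbind(got, unname(contingency_table(acc, i, j)))
    exp_tab <- rbind(exp_tab, as.integer(arr[i, j, ]))
  }
  expect_identical(got, exp_tab)
}

# random small read set over L positions (1-2 disjoint intervals per read)
random_read_set <- function(L = 30L, n = 50L, mut_p = 0.15, lowq_p = 0.08) {
  mk <- function() {
    n_iv <- sample(1:2, 1)
    iv <- sort(sample.int(L, 2L * n_iv))
    s <- iv[seq(1, 2 * n_iv, 2)]; e <- iv[seq(2, 2 * n_iv, 2)]
    cov <- unlist(mapply(seq, s, e, SIMPLIFY = FALSE))
    muts <- cov[runif(length(cov)) < mut_p]
    lowq <- cov[runif(length(cov)) < lowq_p]
    list(s = s, e = e, m = muts, q = lowq)
  }
  rec <- replicate(n, mk(), simplify = FALSE)
  read_set(sprintf("r%04d", seq_len(n)),
           lapply(rec, `[[`, "s"), lapply(rec, `[[`, "e"),
           lapply(rec, `[[`, "m"), lapply(rec, `[[`, "q"), L)
}

# iterative-peeling k-core oracle on an edge list (data frame i, j)
peel_kcore <- function(edges, k) {
  repeat {
    if (nrow(edges) == 0L)
      return(list(nodes = integer(0), edges = edges))
    deg <- table(c(edges$i, edges$j))
    keep_nodes <- as.integer(names(deg)[deg >= k])
    keep <- edges$i %in% keep_nodes & edges$j %in% keep_nodes
    if (all(keep)) return(list(nodes = sort(keep_nodes), edges = edges))
    edges <- edges[keep, , drop = FALSE]
  }
}

# ring set builder for network-level tests (cells are placeholders)
mk_rings <- function(i, j, phi, L = max(j), chi2 = 30, depth = 20000L) {
  n <- length(i)
  df <- data.frame(i = as.integer(i), j = as.integer(j),
                   n11 = integer(n), n10 = integer(n), n01 = integer(n),
                   n00 = integer(n),
                   depth = rep_len(as.integer(depth), n),
                   chi2 = rep_len(chi2, n), phi = phi)
  ringmapr:::new_ring_set(df, L, 20, 0, 1L, "test")
}

# small two-block scenario for fast end-to-end tests: every fragment spans
# the whole reference, so all pairs share the full read depth
small_two_block_scenario <- function(L = 40L, n_fragments = 20000L,
                                     d = 0.3, couple = NULL,
                                     couple_rho = 0) {
  bases <- rep(c("A", "C"), length.out = L)
  block <- rep(c(1L, 2L), each = L / 2L)
  simulation_scenario(paste(bases, collapse = ""),
                      base_rate = rep(0.02, L),
                      d = rep(d, L), block = block,
                      p_occ = c(0.5, 0.5), seq_error = 0.001,
                      lowq_frac = 0.01, insert_min = L, insert_max = L,
                      mate_length = as.integer(L / 2L),
                      n_fragments = n_fragments,
                      couple = couple, couple_rho = couple_rho,
                      label = "small_two_block")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
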