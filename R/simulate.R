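#' Define a read-simulation scenario
#'
#' The generative model behind all synthetic data: each molecule draws one
#' binary occupancy factor per block of nucleotides (an "ensemble state"),
#' and a reactive position i belonging to block k is chemically modified
#' with probability `base_rate[i] + f_k * d[i]`, or `base_rate[i]` outside
#' any block. A per-position protection multiplier models ligand
#' footprints. The observed mutation is the modification OR-folded with a
#' symmetric sequencing error; each covered base is independently flagged
#' low-quality with probability `lowq_frac`. Read geometry emulates random
#' priming with paired-end sequencing: fragment start uniform over the
#' valid range, insert length uniform on `[insert_min, insert_max]`
#' (truncated at L), two mates of `mate_length` at the fragment ends, with
#' a coverage gap whenever the insert exceeds twice the mate length.
#' Two blocks may be coupled (correlated occupancy factors), which plants
#' positive cross-block correlations without changing any marginal rate.
#'
#' @param sequence reference bases (string over A/C/G/U/T/N); A and C are
#'   the DMS-reactive nucleotides.
#' @param base_rate per-position baseline modification probability
#'   (0 for unreactive bases).
#' @param d per-position occupancy-driven rate increment (0 outside
#'   blocks).
#' @param block per-position block id (0 = none); a position belongs to at
#'   most one block.
#' @param p_occ per-block occupancy probability in (0, 1).
#' @param seq_error background sequencing/RT error rate per covered base.
#' @param lowq_frac probability a covered base is flagged low-quality.
#' @param insert_min,insert_max insert-size bounds (nt).
#' @param mate_length mate read length (nt).
#' @param n_fragments number of molecules per simulated replicate.
#' @param protect_pos optional focal position whose modification
#'   probability is multiplied by `protect_factor` (ligand footprint).
#' @param protect_factor protection multiplier in (0, 1].
#' @param couple optional pair of block ids with correlated occupancy.
#' @param couple_rho occupancy correlation for the coupled pair.
#' @param seed default RNG seed used by [simulate_reads()].
#' @param label scenario name.
#' @return a validated `sim_scenario`.
#' @export
simulation_scenario <- function(sequence, base_rate, d, block, p_occ,
                                seq_error = 0.001, lowq_frac = 0,
                                insert_min, insert_max, mate_length,
                                n_fragments, protect_pos = NULL,
                                protect_factor = 1, couple = NULL,
                                couple_rho = 0, seed = 1L,
                                label = "scenario") {
  L <- nchar(sequence)
  s <- structure(
    list(L = as.integer(L), sequence = toupper(sequence),
         base_rate = as.numeric(base_rate), d = as.numeric(d),
         block = as.integer(block), p_occ = as.numeric(p_occ),
         seq_error = seq_error, lowq_frac = lowq_frac,
         insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         mate_length = as.integer(mate_length),
         n_fragments = as.integer(n_fragments),
         protect_pos = if (is.null(protect_pos)) NULL
                       else as.integer(protect_pos),
         protect_factor = protect_factor,
         couple = if (is.null(couple)) NULL else as.integer(couple),
         couple_rho = couple_rho, seed = as.integer(seed), label = label),
    class = "sim_scenario")
  validate_scenario(s)
}

validate_scenario <- function(s) {
  L <- s$L
  if (L < 1L) stop("empty reference", call. = FALSE)
  if (length(s$base_rate) != L || length(s$d) != L ||
      length(s$block) != L)
    stop("base_rate, d and block must have one entry per position",
         call. = FALSE)
  if (any(s$base_rate < 0) || any(s$base_rate + s$d >= 1))
    stop("need 0 <= base_rate and base_rate + d < 1", call. = FALSE)
  K <- length(s$p_occ)
  if (any(s$block < 0L) || any(s$block > K))
    stop("block ids must be in 0..", K, call. = FALSE)
  if (K && (any(s$p_occ <= 0) || any(s$p_occ >= 1)))
    stop("occupancies must lie in (0, 1)", call. = FALSE)
  memb <- s$block > 0L
  if (any(memb & s$base_rate <= 0))
    stop("block members need a positive base rate", call. = FALSE)
  bases <- strsplit(s$sequence, "")[[1]]
  if (any(memb & !bases %in% c("A", "C")))
    stop("block members must be reactive (A/C) nucleotides",
         call. = FALSE)
  if (!(s$insert_min >= 1 && s$insert_min <= s$insert_max &&
        s$insert_max <= L))
    stop("need 1 <= insert_min <= insert_max <= L", call. = FALSE)
  if (s$mate_length < 1L) stop("mate_length must be >= 1", call. = FALSE)
  if (s$seq_error < 0 || s$seq_error >= 1 || s$lowq_frac < 0 ||
      s$lowq_frac >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)
  if (!is.null(s$protect_pos) &&
      (s$protect_pos < 1L || s$protect_pos > L))
    stop("protect_pos outside reference", call. = FALSE)
  if (s$protect_factor <= 0 || s$protect_factor > 1)
    stop("protect_factor must be in (0, 1]", call. = FALSE)
  if (!is.null(s$couple)) {
    if (length(s$couple) != 2L || s$couple[1] >= s$couple[2] ||
        any(s$couple < 1L) || any(s$couple > K))
      stop("couple must name two distinct block ids (a < b)",
           call. = FALSE)
    pa <- s$p_occ[s$couple[1]]; pb <- s$p_occ[s$couple[2]]
    p11 <- pa * pb + s$couple_rho * sqrt(pa * (1 - pa) * pb * (1 - pb))
    if (p11 < max(0, pa + pb - 1) - 1e-12 || p11 > min(pa, pb) + 1e-12)
      stop("couple_rho infeasible for the given occupancies",
           call. = FALSE)
  }
  s
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> '%s': L=%d, %d blocks (%s members), %d fragments, insert %d-%d, mates %d nt\n",
    x$label, x$L, length(x$p_occ),
    paste(tabulate(x$block, length(x$p_occ)), collapse = "/"),
    x$n_fragments, x$insert_min, x$insert_max, x$mate_length))
  invisible(x)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

protection_vec <- function(s) {
  prot <- rep(1, s$L)
  if (!is.null(s$protect_pos)) prot[s$protect_pos] <- s$protect_factor
  prot
}

#' Simulate randomly primed paired-end MaP reads
#'
#' Draws `n_fragments` molecules under the scenario's latent-state model
#' (see [simulation_scenario()]) and returns them as a `read_set`. Fully
#' reproducible: the same seed yields byte-identical MRF output.
#'
#' @param s a `sim_scenario`.
#' @param seed RNG seed (defaults to the scenario's).
#' @param prefix read-id prefix.
#' @return a `read_set`.
#' @export
simulate_reads <- function(s, seed = s$seed, prefix = "sim") {
  stopifnot(inherits(s, "sim_scenario"))
  set.seed(seed)
  couple <- s$couple %||% c(0L, 0L)
  r <- simulate_cpp(s$L, s$n_fragments, s$insert_min, s$insert_max,
                    s$mate_length, s$base_rate, s$d, s$block, s$p_occ,
                    s$seq_error, s$lowq_frac, protection_vec(s),
                    couple[1], couple[2], s$couple_rho)
  read_set(sprintf("%s%07d", prefix, seq_len(s$n_fragments)),
           r$starts, r$ends, r$muts, r$lowq, s$L, validate = FALSE)
}

#' Analytic expected marginal mutation rate
#'
#' For position i with protection multiplier m, block occupancy p and
#' increment d, the modification rate is `m * (base + p * d)`; folding
#' the symmetric sequencing error e into a rate x gives the observed rate
#' `x + e * (1 - x)`.
#'
#' @param s a `sim_scenario`.
#' @param positions positions to evaluate (default: all).
#' @return numeric vector of expected observed mutation rates.
#' @export
expected_rate <- function(s, positions = seq_len(s$L)) {
  prot <- protection_vec(s)
  p <- ifelse(s$block > 0L, s$p_occ[pmax(s$block, 1L)], 0)
  r <- prot * (s$base_rate + p * s$d)
  (r + s$seq_error * (1 - r))[positions]
}

block_cov <- function(s, i, j) {
  bi <- s$block[i]; bj <- s$block[j]
  if (bi == 0L || bj == 0L) return(0)
  if (bi == bj) {
    p <- s$p_occ[bi]
    return(p * (1 - p))
  }
  if (!is.null(s$couple) && all(sort(c(bi, bj)) == s$couple)) {
    pa <- s$p_occ[bi]; pb <- s$p_occ[bj]
    return(s$couple_rho * sqrt(pa * (1 - pa) * pb * (1 - pb)))
  }
  0
}

#' Analytic expected phi between two positions
#'
#' Closed-form oracle for parameter-recovery testing. For same-block
#' positions the modification covariance is `p(1-p) * d_i * d_j`
#' (occupancy variance times increments; protection scales the effective
#' increment); for coupled blocks `p(1-p)` is replaced by the occupancy
#' covariance; uncoupled cross-block pairs have phi 0. Sequencing error
#' attenuates the covariance by `(1-e)^2` and inflates the marginals,
#' giving `phi = cov * (1-e)^2 / sqrt(r'_i (1-r'_i) r'_j (1-r'_j))` with
#' r' the observed marginal rates.
#'
#' @param s a `sim_scenario`.
#' @param i,j 1-based positions.
#' @return expected phi (vectorized over i, j pairs).
#' @export
expected_phi <- function(s, i, j) {
  stopifnot(length(i) == length(j))
  prot <- protection_vec(s)
  covf <- mapply(block_cov, i, j, MoreArgs = list(s = s))
  covv <- covf * (prot[i] * s$d[i]) * (prot[j] * s$d[j]) *
    (1 - s$seq_error)^2
  ri <- expected_rate(s, i); rj <- expected_rate(s, j)
  den <- sqrt(ri * (1 - ri) * rj * (1 - rj))
  ifelse(den > 0, covv / den, 0)
}

#' Planted ground truth for a scenario
#'
#' Enumerates every same-block pair plus (when blocks are coupled) every
#' coupled cross-block pair, with the analytic expected phi, and returns
#' the planted block membership and expected per-position rates.
#'
#' @param s a `sim_scenario`.
#' @return list with `pairs` (i, j, block_i, block_j, expected_phi),
#'   `membership` (position, block for members), `rates` (position,
#'   expected_rate).
#' @export
ground_truth <- function(s) {
  memb <- which(s$block > 0L)
  pairs <- data.frame(i = integer(0), j = integer(0),
                      block_i = integer(0), block_j = integer(0))
  if (length(memb) >= 2L) {
    cmb <- t(utils::combn(memb, 2L))
    bi <- s$block[cmb[, 1]]; bj <- s$block[cmb[, 2]]
    same <- bi == bj
    coupled <- if (is.null(s$couple)) rep(FALSE, nrow(cmb)) else
      (pmin(bi, bj) == s$couple[1] & pmax(bi, bj) == s$couple[2])
    keep <- same | coupled
    pairs <- data.frame(i = cmb[keep, 1], j = cmb[keep, 2],
                        block_i = bi[keep], block_j = bj[keep])
  }
  pairs$expected_phi <- if (nrow(pairs)) expected_phi(s, pairs$i, pairs$j)
                        else numeric(0)
  list(pairs = pairs,
       membership = data.frame(position = memb, block = s$block[memb]),
       rates = data.frame(position = seq_len(s$L),
                          expected_rate = expected_rate(s)))
}

#' Write ground-truth pairs as TSV
#' @param truth result of [ground_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$pairs
  df$expected_phi <- formatC(df$expected_phi, digits = 6, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#ringmapr\tground_truth\tv1", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Echo a scenario as a flat key:value config
#' @param s a `sim_scenario`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path) {
  kv <- c(
    label = s$label, L = s$L, seed = s$seed,
    n_fragments = s$n_fragments, insert_min = s$insert_min,
    insert_max = s$insert_max, mate_length = s$mate_length,
    seq_error = s$seq_error, lowq_frac = s$lowq_frac,
    p_occ = paste(s$p_occ, collapse = ","),
    protect_pos = s$protect_pos %||% "-",
    protect_factor = s$protect_factor,
    couple = if (is.null(s$couple)) "-"
             else paste(s$couple, collapse = ","),
    couple_rho = s$couple_rho,
    sequence = s$sequence,
    base_rate = paste(formatC(s$base_rate, format = "g"), collapse = ","),
    d = paste(formatC(s$d, format = "g"), collapse = ","),
    block = paste(s$block, collapse = ","))
  writeLines(paste0(names(kv), ": ", kv), path)
  invisible(path)
}

# deterministic selection of n roughly evenly spaced elements
pick_spread <- function(v, n) {
  if (length(v) < n) stop("window too sparse in reactive bases")
  v[unique(round(seq(1, length(v), length.out = n)))]
}

#' Default four-domain simulation scenario
#'
#' A desk-scale stand-in for a long structured RNA the size of the E. coli
#' 16S rRNA (L = 1542) whose correlation network resolves into four
#' communities. Four latent blocks mimic the domain layout: body (within
#' 1-560), platform (561-890), outer head (a subset of 930-1380) and
#' inner head + spine (a second, interleaved subset of 930-1380 plus
#' members in 1397-1535, exercising long-range pairs). Each block has ~40
#' reactive (A/C) member positions with occupancy 0.5 and rate increment
#' 0.3 over baselines in 0.01-0.05; sequencing error 1e-3, low-quality
#' fraction 2e-3, inserts 500-700 nt, 150-nt mates, 200,000 fragments per
#' replicate. The reference sequence, member positions and baseline rates
#' are generated from a fixed internal RNG stream, so the scenario is a
#' constant.
#'
#' @param n_fragments fragments per replicate (default 200000).
#' @return a `sim_scenario`.
#' @export
default_domain_scenario <- function(n_fragments = 200000L) {
  L <- 1542L
  with_local_seed(161542L, {
    bases <- sample(c("A", "C", "G", "U"), L, replace = TRUE,
                    prob = c(0.25, 0.23, 0.31, 0.21))
    ac <- which(bases %in% c("A", "C"))
    base_rate <- numeric(L)
    base_rate[ac] <- runif(length(ac), 0.01, 0.05)
    in_win <- function(a, b) ac[ac >= a & ac <= b]
    body <- pick_spread(in_win(1, 560), 40L)
    platform <- pick_spread(in_win(561, 890), 40L)
    head <- pick_spread(in_win(930, 1380), 70L)
    outer <- head[c(seq(1, 59, 2), 61:70)]     # 40 members
    inner <- head[seq(2, 60, 2)]               # 30, interleaved with outer
    spine <- pick_spread(in_win(1397, 1535), 10L)
    block <- integer(L)
    block[body] <- 1L; block[platform] <- 2L
    block[outer] <- 3L; block[c(inner, spine)] <- 4L
    d <- numeric(L)
    d[block > 0L] <- 0.3
    simulation_scenario(paste(bases, collapse = ""), base_rate, d, block,
                        p_occ = rep(0.5, 4), seq_error = 0.001,
                        lowq_frac = 0.002, insert_min = 500L,
                        insert_max = 700L, mate_length = 150L,
                        n_fragments = n_fragments,
                        label = "default_domain")
  })
}

#' Ligand-bound variant of the default scenario
#'
#' The default four-domain scenario plus the two signatures of a
#' spectinomycin-like ligand: (i) a single-site footprint - the focal
#' position (the first outer-head member) has its modification probability
#' multiplied by 0.25 - and (ii) overstabilized long-range contacts -
#' the outer-head and inner-head+spine occupancy factors are coupled with
#' correlation 0.8, planting positive cross-block correlations without
#' changing marginal rates.
#'
#' @inheritParams default_domain_scenario
#' @return a `sim_scenario`.
#' @export
ligand_scenario <- function(n_fragments = 200000L) {
  s <- default_domain_scenario(n_fragments)
  s$protect_pos <- which(s$block == 3L)[1]
  s$protect_factor <- 0.25
  s$couple <- c(3L, 4L)
  s$couple_rho <- 0.8
  s$label <- "ligand"
  validate_scenario(s)
}

#' Null-model scenario for significance-criterion calibration
#'
#' No latent blocks: every position mutates independently at its baseline
#' rate, so every pairwise correlation is a false positive by
#' construction. Defaults give a short all-reactive reference fully
#' covered by every fragment, so each of the L(L-1)/2 pairs is observed
#' exactly `n_fragments` times.
#'
#' @param L reference length (default 60).
#' @param n_fragments fragments (default 1e5, i.e. per-pair depth 1e5).
#' @param base_rate common baseline modification rate.
#' @return a `sim_scenario`.
#' @export
null_calibration_scenario <- function(L = 60L, n_fragments = 100000L,
                                      base_rate = 0.02) {
  simulation_scenario(
    paste(rep(c("A", "C"), length.out = L), collapse = ""),
    rep(base_rate, L), numeric(L), integer(L), p_occ = numeric(0),
    seq_error = 0.001, lowq_frac = 0, insert_min = L, insert_max = L,
    mate_length = as.integer(ceiling(L / 2)), n_fragments = n_fragments,
    label = "null_calibration")
}
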