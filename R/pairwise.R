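#' Accumulate pairwise contingency tables over a read set
#'
#' Core of the correlated-probing analysis for long, randomly primed RNAs:
#' rather than keeping reads in memory, every read updates an
#' upper-triangular store holding one 2x2 contingency table per nucleotide
#' pair (i < j). For each read and each pair of covered positions, exactly
#' one cell is incremented according to whether i and/or j carried a
#' mutation; reads whose mates leave a gap contribute only pairs where both
#' positions are covered, so memory depends on the RNA length only, never
#' on read count. Per-read work uses difference-array (rectangle) updates
#' for the coverage-dominated cells and explicit counting only for
#' mutation-mutation pairs, and is exactly equal to a naive per-pair
#' recount.
#'
#' The per-base quality rule ([apply_quality_rule()]) is applied first, and
#' masked positions are excised from coverage, so they contribute to no
#' table.
#'
#' @param reads a `read_set`.
#' @param mask optional `position_mask` (or integer vector) of excluded
#'   positions.
#' @param min_separation smallest pair separation `j - i` retained
#'   (default 1: all i < j pairs are tested).
#' @return a `pair_accumulator` with count matrices and bookkeeping.
#' @export
accumulate_pairs <- function(reads, mask = NULL, min_separation = 1L) {
  stopifnot(inherits(reads, "read_set"), min_separation >= 1L)
  reads <- apply_quality_rule(reads)
  reads <- drop_masked_positions(reads, mask)
  m <- accumulate_cpp(reads$starts, reads$ends, reads$muts, reads$L)
  structure(
    list(L = reads$L, N = m$N, A = m$A, B = m$B, n11 = m$n11,
         mask = as.integer(mask %||% integer(0)),
         min_separation = as.integer(min_separation),
         n_reads = length(reads)),
    class = "pair_accumulator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pair_accumulator <- function(x, ...) {
  cat(sprintf(
    "<pair_accumulator> L=%d, %d reads, %d masked positions, min_sep=%d\n",
    x$L, x$n_reads, length(x$mask), x$min_separation))
  invisible(x)
}

check_pair <- function(acc, i, j) {
  if (!(i >= 1 && j <= acc$L && i < j))
    stop(sprintf("need 1 <= i < j <= %d (got i=%s, j=%s)", acc$L, i, j),
         call. = FALSE)
  if (i %in% acc$mask || j %in% acc$mask)
    stop(sprintf("pair (%d, %d) touches a masked position", i, j),
         call. = FALSE)
  if (j - i < acc$min_separation)
    stop(sprintf("pair (%d, %d) below min_separation %d", i, j,
                 acc$min_separation), call. = FALSE)
}

#' Extract one pair's 2x2 contingency table
#'
#' Cell layout over reads covering both positions: `n11` both mutated,
#' `n10` only i, `n01` only j, `n00` neither.
#'
#' @param acc a `pair_accumulator`.
#' @param i,j 1-based positions, `i < j`, neither masked.
#' @return named integer vector `c(n11, n10, n01, n00)`.
#' @export
contingency_table <- function(acc, i, j) {
  check_pair(acc, i, j)
  n11 <- acc$n11[i, j]
  c(n11 = n11,
    n10 = acc$A[i, j] - n11,
    n01 = acc$B[i, j] - n11,
    n00 = acc$N[i, j] - acc$A[i, j] - acc$B[i, j] + n11)
}

#' Pairwise read depth
#'
#' The total number of times nucleotides i and j were read together
#' (N_ij), i.e. the sum of the four contingency-table cells.
#'
#' @inheritParams contingency_table
#' @return integer depth.
#' @export
pair_depth <- function(acc, i, j) {
  check_pair(acc, i, j)
  acc$N[i, j]
}

#' Yates continuity-corrected chi-squared for 2x2 tables
#'
#' `N * (max(0, |n11*n00 - n10*n01| - N/2))^2 / (R1*R2*C1*C2)` with row and
#' column marginals R and C. The correction term is clamped at zero so
#' near-independent tables cannot produce a spurious positive statistic.
#' Returns 0 when any marginal is 0 (the statistic is undefined; treated as
#' no evidence). Vectorized over cells.
#'
#' @param n11,n10,n01,n00 contingency cell counts (vectors recycle).
#' @return chi-squared statistic(s), `>= 0`.
#' @export
yates_chi2 <- function(n11, n10, n01, n00) {
  n11 <- as.numeric(n11); n10 <- as.numeric(n10)
  n01 <- as.numeric(n01); n00 <- as.numeric(n00)
  N <- n11 + n10 + n01 + n00
  den <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  num <- pmax(0, abs(n11 * n00 - n10 * n01) - N / 2)
  out <- ifelse(den > 0, N * num^2 / den, 0)
  out[N == 0] <- 0
  out
}

#' Phi coefficient (signed 2x2 correlation)
#'
#' Pearson correlation of the two binary outcomes:
#' `(n11*n00 - n10*n01) / sqrt(R1*R2*C1*C2)`. Positive phi means
#' co-modification on the same molecules; negative phi means mutual
#' exclusion. `NA` when a marginal is zero (undefined). Vectorized.
#'
#' @inheritParams yates_chi2
#' @return phi in `[-1, 1]`, or `NA` where undefined.
#' @export
phi_coeff <- function(n11, n10, n01, n00) {
  n11 <- as.numeric(n11); n10 <- as.numeric(n10)
  n01 <- as.numeric(n01); n00 <- as.numeric(n00)
  den <- (n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00)
  ifelse(den > 0, (n11 * n00 - n10 * n01) / sqrt(den), NA_real_)
}

new_ring_set <- function(df, L, chi2_min, depth_min, min_separation,
                         provenance) {
  rownames(df) <- NULL
  structure(df, class = c("ring_set", "data.frame"), L = as.integer(L),
            chi2_min = chi2_min, depth_min = depth_min,
            min_separation = as.integer(min_separation),
            provenance = provenance)
}

#' Detect significant correlated modifications (RINGs)
#'
#' Tests every i < j pair in the accumulator and returns those with
#' pairwise depth `N_ij >= depth_min` and Yates chi-squared strictly above
#' `chi2_min` ("above 20": a pair at exactly the criterion is excluded).
#' Each ring carries its contingency table, depth, chi-squared and signed
#' phi.
#'
#' @param acc a `pair_accumulator`.
#' @param chi2_min significance criterion on the Yates statistic
#'   (default 20, upper-tail probability 7.7e-6 on 1 df).
#' @param depth_min minimum pairwise depth for a pair to be tested
#'   (default 10000; the chi-squared criterion is unreliable at low N).
#' @param sample provenance label recorded in the result.
#' @return a `ring_set` data frame (columns i, j, n11, n10, n01, n00,
#'   depth, chi2, phi), ordered by i then j.
#' @export
detect_rings <- function(acc, chi2_min = 20, depth_min = 10000,
                         sample = "sample") {
  stopifnot(inherits(acc, "pair_accumulator"))
  L <- acc$L
  idx <- which(acc$N >= depth_min)
  ri <- (idx - 1L) %% L + 1L
  rj <- (idx - 1L) %/% L + 1L
  keep <- (rj - ri) >= acc$min_separation
  idx <- idx[keep]; ri <- ri[keep]; rj <- rj[keep]
  n11 <- acc$n11[idx]
  a <- acc$A[idx]; b <- acc$B[idx]; N <- acc$N[idx]
  n10 <- a - n11; n01 <- b - n11; n00 <- N - a - b + n11
  chi2 <- yates_chi2(n11, n10, n01, n00)
  sig <- chi2 > chi2_min
  phi <- phi_coeff(n11[sig], n10[sig], n01[sig], n00[sig])
  df <- data.frame(i = ri[sig], j = rj[sig], n11 = n11[sig],
                   n10 = n10[sig], n01 = n01[sig], n00 = n00[sig],
                   depth = N[sig], chi2 = chi2[sig], phi = phi)
  df <- df[order(df$i, df$j), , drop = FALSE]
  new_ring_set(df, L, chi2_min, depth_min, acc$min_separation, sample)
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf(
    "<ring_set> %d rings (L=%d; chi2 > %g, depth >= %g; %s)\n",
    nrow(x), attr(x, "L"), attr(x, "chi2_min"), attr(x, "depth_min"),
    paste(attr(x, "provenance"), collapse = " + ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Merge replicate ring sets by intersection
#'
#' A correlation pair is kept only when it occurs in both replicates, and
#' only when its phi has the same sign in both (a pair flipping between
#' co-modification and mutual exclusion is discarded as irreproducible).
#' Merged statistics are conservative, order-independent combiners: phi is
#' the arithmetic mean, chi-squared the minimum, depth and cell counts the
#' sums.
#'
#' @param a,b `ring_set` objects from the same reference.
#' @return merged `ring_set`.
#' @export
merge_replicates <- function(a, b) {
  stopifnot(inherits(a, "ring_set"), inherits(b, "ring_set"))
  if (attr(a, "L") != attr(b, "L"))
    stop("replicates disagree on reference length", call. = FALSE)
  ka <- paste(a$i, a$j); kb <- paste(b$i, b$j)
  ia <- match(intersect(ka, kb), ka)
  ib <- match(ka[ia], kb)
  same_sign <- sign(a$phi[ia]) == sign(b$phi[ib])
  ia <- ia[same_sign]; ib <- ib[same_sign]
  df <- data.frame(
    i = a$i[ia], j = a$j[ia],
    n11 = a$n11[ia] + b$n11[ib], n10 = a$n10[ia] + b$n10[ib],
    n01 = a$n01[ia] + b$n01[ib], n00 = a$n00[ia] + b$n00[ib],
    depth = a$depth[ia] + b$depth[ib],
    chi2 = pmin(a$chi2[ia], b$chi2[ib]),
    phi = (a$phi[ia] + b$phi[ib]) / 2)
  df <- df[order(df$i, df$j), , drop = FALSE]
  new_ring_set(df, attr(a, "L"),
               max(attr(a, "chi2_min"), attr(b, "chi2_min")),
               max(attr(a, "depth_min"), attr(b, "depth_min")),
               max(attr(a, "min_separation"), attr(b, "min_separation")),
               c(attr(a, "provenance"), attr(b, "provenance")))
}

#' Effective maximum detection interval
#'
#' Correlated interactions can only be detected reliably between positions
#' read together often enough; with random priming and a finite insert
#' size the pairwise depth decays with separation. Returns the largest
#' separation `j - i` whose depth reaches `depth_required` (roughly 50,000
#' reads between two locations in the original protocol), plus a
#' per-separation summary of depths.
#'
#' @param acc a `pair_accumulator`.
#' @param depth_required pairwise depth needed for reliable detection
#'   (default 50000).
#' @return list with `max_separation` (0 when no pair qualifies),
#'   `depth_required`, and `by_separation` (data frame: separation,
#'   n_pairs, median_depth, max_depth).
#' @export
detection_interval <- function(acc, depth_required = 50000) {
  stopifnot(inherits(acc, "pair_accumulator"))
  L <- acc$L
  idx <- which(acc$N > 0)
  ri <- (idx - 1L) %% L + 1L
  rj <- (idx - 1L) %/% L + 1L
  keep <- (rj - ri) >= acc$min_separation
  sep <- (rj - ri)[keep]
  dep <- acc$N[idx][keep]
  if (length(sep) == 0L)
    return(list(max_separation = 0L, depth_required = depth_required,
                by_separation = data.frame(separation = integer(0),
                                           n_pairs = integer(0),
                                           median_depth = numeric(0),
                                           max_depth = numeric(0))))
  o <- order(sep)
  sep <- sep[o]; dep <- dep[o]
  g <- factor(sep)
  by_sep <- data.frame(
    separation = as.integer(levels(g)),
    n_pairs = as.integer(table(g)),
    median_depth = as.numeric(tapply(dep, g, stats::median)),
    max_depth = as.numeric(tapply(dep, g, max)))
  ok <- dep >= depth_required
  list(max_separation = if (any(ok)) max(sep[ok]) else 0L,
       depth_required = depth_required,
       by_separation = by_sep)
}

#' Write a ring set as TSV
#'
#' One row per ring, deterministic order (ascending i, then j), floats at 6
#' significant digits; thresholds and provenance are recorded in `#` header
#' lines so every number is recomputable.
#'
#' @param rings a `ring_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rings <- function(rings, path) {
  stopifnot(inherits(rings, "ring_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#ringmapr\trings\tv1",
    sprintf("#length\t%d", attr(rings, "L")),
    sprintf("#chi2_min\t%.10g", attr(rings, "chi2_min")),
    sprintf("#depth_min\t%.10g", attr(rings, "depth_min")),
    sprintf("#min_separation\t%d", attr(rings, "min_separation")),
    sprintf("#provenance\t%s",
            paste(attr(rings, "provenance"), collapse = ";")),
    paste(c("i", "j", "n11", "n10", "n01", "n00", "depth", "chi2", "phi"),
          collapse = "\t")), con)
  if (nrow(rings)) {
    df <- as.data.frame(rings)
    df <- df[order(df$i, df$j), , drop = FALSE]
    lines <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                     df$i, df$j, df$n11, df$n10, df$n01, df$n00, df$depth,
                     formatC(df$chi2, digits = 6, format = "g"),
                     formatC(df$phi, digits = 6, format = "g"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a ring set written by [write_rings()]
#' @param path TSV path.
#' @return a `ring_set`.
#' @export
read_rings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key, default = NA) {
    h <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(h) == 0L) return(default)
    strsplit(h[1], "\t", fixed = TRUE)[[1]][2]
  }
  body <- lines[!startsWith(lines, "#")]
  df <- if (length(body) > 1L) {
    read.delim(text = paste(body, collapse = "\n"), sep = "\t",
               stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), n11 = integer(0),
               n10 = integer(0), n01 = integer(0), n00 = integer(0),
               depth = integer(0), chi2 = numeric(0), phi = numeric(0))
  }
  new_ring_set(df, as.integer(get("length")),
               as.numeric(get("chi2_min", 20)),
               as.numeric(get("depth_min", 0)),
               as.integer(as.numeric(get("min_separation", 1))),
               strsplit(get("provenance", "unknown"), ";",
                        fixed = TRUE)[[1]])
}
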