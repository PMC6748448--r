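#' Per-nucleotide mutation-rate profile
#'
#' The conventional chemical-probing readout: for every reference position,
#' the effective depth (number of quality-passing reads covering it), the
#' number of reads carrying a mutation there, and the mutation rate
#' count/depth. Low-quality bases are excluded from both depth and count;
#' masked positions carry `NA` rates.
#'
#' @param reads a `read_set`.
#' @param mask optional `position_mask` of excluded positions.
#' @param reference optional reference (list from [read_reference()] or a
#'   bases string) used to attach base identities.
#' @param sample provenance label.
#' @return a `reactivity_profile` data frame: position, base, depth,
#'   mut_count, rate, masked.
#' @export
compute_profile <- function(reads, mask = NULL, reference = NULL,
                            sample = "sample") {
  stopifnot(inherits(reads, "read_set"))
  reads <- apply_quality_rule(reads)
  L <- reads$L
  cv <- coverage_cpp(reads$starts, reads$ends, reads$muts, L)
  masked <- logical(L)
  masked[as.integer(mask %||% integer(0))] <- TRUE
  base <- rep(NA_character_, L)
  if (!is.null(reference)) {
    bases <- if (is.list(reference)) reference$bases else reference
    stopifnot(nchar(bases) == L)
    base <- strsplit(toupper(bases), "")[[1]]
  }
  rate <- ifelse(cv$depth > 0, cv$count / cv$depth, NA_real_)
  rate[masked] <- NA_real_
  structure(
    data.frame(position = seq_len(L), base = base, depth = cv$depth,
               mut_count = cv$count, rate = rate, masked = masked),
    class = c("reactivity_profile", "data.frame"), sample = sample)
}

#' Flag high-background positions from an untreated control
#'
#' Positions whose mutation rate in a no-reagent control exceeds
#' `rate_cut` at adequate depth are returned as a mask. Such residues
#' (typically sequence polymorphisms relative to the reference) would
#' otherwise contaminate both reactivity profiles and pairwise
#' correlations.
#'
#' @param untreated a `reactivity_profile` from an untreated sample.
#' @param rate_cut background rate threshold (default 0.03).
#' @param depth_min minimum depth for a position to be assessable
#'   (default 100).
#' @return a `position_mask`.
#' @export
flag_high_background <- function(untreated, rate_cut = 0.03,
                                 depth_min = 100) {
  stopifnot(inherits(untreated, "reactivity_profile"))
  hit <- !is.na(untreated$rate) & untreated$rate > rate_cut &
    untreated$depth >= depth_min
  position_mask(untreated$position[hit], nrow(untreated))
}

#' Differential footprint calls between two conditions
#'
#' Ligand binding shows up as a localized change in per-nucleotide
#' reactivity. For each position the rate difference
#' `delta = rate_a - rate_b` is standardized with a Poisson approximation,
#' `z = delta / sqrt(rate_a/depth_a + rate_b/depth_b)`; a position is
#' called `protected` when `z <= -z_min` and `delta <= -delta_min`,
#' `enhanced` for the mirror image, else `unchanged`. Positions masked or
#' rate-less in either profile are never called.
#'
#' @param a,b `reactivity_profile` objects on the same reference (a is the
#'   condition of interest, e.g. +ligand; b the baseline).
#' @param z_min standardized-difference threshold (default 5).
#' @param delta_min absolute rate-difference threshold (default 0.01).
#' @param full return all positions (including `unchanged`) instead of
#'   calls only.
#' @return a `footprint_calls` data frame: position, rate_a, rate_b,
#'   delta, z, verdict; thresholds stored as attributes.
#' @export
differential_footprint <- function(a, b, z_min = 5, delta_min = 0.01,
                                   full = FALSE) {
  stopifnot(inherits(a, "reactivity_profile"),
            inherits(b, "reactivity_profile"))
  if (nrow(a) != nrow(b))
    stop("profiles disagree on reference length", call. = FALSE)
  ok <- !is.na(a$rate) & !is.na(b$rate) & a$depth > 0 & b$depth > 0
  delta <- a$rate - b$rate
  se <- sqrt(a$rate / a$depth + b$rate / b$depth)
  z <- ifelse(ok & se > 0, delta / se, ifelse(ok & delta == 0, 0, NA))
  verdict <- rep("unchanged", nrow(a))
  verdict[ok & !is.na(z) & z <= -z_min & delta <= -delta_min] <- "protected"
  verdict[ok & !is.na(z) & z >= z_min & delta >= delta_min] <- "enhanced"
  df <- data.frame(position = a$position, rate_a = a$rate, rate_b = b$rate,
                   delta = delta, z = z, verdict = verdict)
  if (!full) df <- df[df$verdict != "unchanged", , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("footprint_calls", "data.frame"),
            z_min = z_min, delta_min = delta_min,
            samples = c(attr(a, "sample"), attr(b, "sample")))
}

#' Write a reactivity profile as TSV
#' @param profile a `reactivity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reactivity_profile"))
  df <- as.data.frame(profile)
  df$rate <- ifelse(is.na(df$rate), "NA",
                    formatC(df$rate, digits = 6, format = "g"))
  df$masked <- as.integer(df$masked)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ringmapr\tprofile\tv1\t%s", attr(profile, "sample")),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path TSV path.
#' @return a `reactivity_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sample <- "sample"
  if (startsWith(lines[1], "#ringmapr")) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 4) sample <- f[4]
  }
  df <- read.delim(text = paste(lines[!startsWith(lines, "#")],
                                collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  df$rate <- suppressWarnings(as.numeric(df$rate))
  df$masked <- as.logical(df$masked)
  structure(df, class = c("reactivity_profile", "data.frame"),
            sample = sample)
}

#' Write differential footprint calls as TSV
#' @param calls a `footprint_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_footprint <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ringmapr\tfootprint\tv1\tz_min=%g\tdelta_min=%g",
                     attr(calls, "z_min"), attr(calls, "delta_min")), con)
  df <- as.data.frame(calls)
  for (cl in c("rate_a", "rate_b", "delta", "z"))
    df[[cl]] <- formatC(df[[cl]], digits = 6, format = "g")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
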