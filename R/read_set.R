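#' Construct a set of per-read mutation records
#'
#' A `read_set` is the in-memory form of MRF (mutation read format) data:
#' for each sequenced molecule it stores the reference intervals the read
#' pair covers, the positions where a mutation (chemical-adduct signature)
#' was called, and the positions whose base quality fell below the phred
#' cutoff. Coordinates are 1-based, intervals closed, matching rRNA residue
#' numbering. Mates of a pair are pre-merged: intervals are non-overlapping
#' and sorted, and a mutation seen in both mates counts once.
#'
#' @param id character vector of read identifiers.
#' @param starts,ends lists of integer vectors: per-read interval bounds.
#' @param muts list of integer vectors: per-read mutated positions.
#' @param lowq list of integer vectors: per-read low-quality positions.
#' @param length reference length L; all positions must lie in `[1, L]`.
#' @param validate check the structural invariants (intervals sorted and
#'   disjoint, mutations and lowq inside coverage, positions in range).
#'   Skipped for internally generated sets that are correct by construction.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, starts, ends, muts, lowq, length,
                     validate = TRUE) {
  n <- base::length(id)
  stopifnot(base::length(starts) == n, base::length(ends) == n,
            base::length(muts) == n, base::length(lowq) == n,
            is.numeric(length), length >= 1)
  x <- structure(
    list(id = as.character(id),
         starts = lapply(starts, as.integer),
         ends = lapply(ends, as.integer),
         muts = lapply(muts, function(v) as.integer(sort(v))),
         lowq = lapply(lowq, function(v) as.integer(sort(v))),
         L = as.integer(length)),
    class = "read_set")
  if (validate) validate_read_set(x)
  x
}

validate_read_set <- function(x) {
  bad <- check_reads_cpp(x$starts, x$ends, x$muts, x$lowq, x$L)
  if (bad[1] != 0L) {
    msg <- switch(bad[2],
                  "intervals not sorted, disjoint and non-empty",
                  sprintf("position outside [1, %d]", x$L),
                  "mutation outside covered intervals",
                  "low-quality position outside covered intervals")
    stop(sprintf("read %d ('%s'): %s", bad[1], x$id[bad[1]], msg),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
length.read_set <- function(x) base::length(x$id)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads over reference of length %d\n",
              length(x), x$L))
  cov <- sum(unlist(x$ends, use.names = FALSE)) -
    sum(unlist(x$starts, use.names = FALSE)) + sum(lengths(x$starts))
  cat(sprintf("  covered bases: %.4g; mutations: %d; lowq: %d\n",
              cov, sum(lengths(x$muts)), sum(lengths(x$lowq))))
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i) {
  read_set(x$id[i], x$starts[i], x$ends[i], x$muts[i], x$lowq[i], x$L,
           validate = FALSE)
}

#' Total number of quality-unfiltered covered bases
#' @param x a `read_set`.
#' @return integer count of covered reference bases summed over reads.
#' @export
covered_bases <- function(x) {
  sum(unlist(x$ends, use.names = FALSE)) -
    sum(unlist(x$starts, use.names = FALSE)) + sum(lengths(x$starts))
}

#' Apply the per-base quality rule
#'
#' Only nucleotides with a phred score above the cutoff are counted: every
#' position flagged low-quality is removed from the read's coverage (so it
#' contributes to no contingency table and no reactivity depth), and any
#' mutation called at such a position is discarded. The returned records
#' carry empty lowq sets; the operation is idempotent.
#'
#' @param reads a `read_set`.
#' @return a `read_set` with lowq positions excised from coverage.
#' @export
apply_quality_rule <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (sum(lengths(reads$lowq)) == 0L) return(reads)
  f <- filter_reads_cpp(reads$starts, reads$ends, reads$muts, reads$lowq,
                        logical(0), TRUE)
  read_set(reads$id, f$starts, f$ends, f$muts,
           rep(list(integer(0)), length(reads)), reads$L, validate = FALSE)
}

drop_masked_positions <- function(reads, mask) {
  if (is.null(mask) || length(mask) == 0L) return(reads)
  drop <- logical(reads$L)
  drop[mask] <- TRUE
  f <- filter_reads_cpp(reads$starts, reads$ends, reads$muts, reads$lowq,
                        drop, FALSE)
  read_set(reads$id, f$starts, f$ends, f$muts,
           rep(list(integer(0)), length(reads)), reads$L, validate = FALSE)
}

fmt_poslist <- function(v) {
  vapply(v, function(p)
    if (length(p) == 0L) "-" else paste(p, collapse = ","), "")
}

#' Write per-read mutation records in MRF
#'
#' MRF (mutation read format) is a tab-separated UTF-8 text format: header
#' lines `#MRF<TAB>v1` and `#length<TAB>L`, then one read per line:
#' `read_id TAB cov=start-end[,start-end...] TAB mut=pos[,pos...]|- TAB
#' lowq=pos[,pos...]|-`, intervals 1-based inclusive.
#'
#' @param reads a `read_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrf <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  cov <- mapply(function(s, e) paste(sprintf("%d-%d", s, e), collapse = ","),
                reads$starts, reads$ends)
  lines <- c(sprintf("#MRF\tv1"),
             sprintf("#length\t%d", reads$L),
             paste(reads$id, paste0("cov=", cov),
                   paste0("mut=", fmt_poslist(reads$muts)),
                   paste0("lowq=", fmt_poslist(reads$lowq)), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_poslist <- function(tok, field, lineno) {
  pref <- paste0(field, "=")
  ok <- startsWith(tok, pref)
  if (!all(ok))
    stop(sprintf("MRF line %d: expected '%s' field, got '%s'",
                 lineno[!ok][1], field, tok[!ok][1]), call. = FALSE)
  body <- substring(tok, nchar(pref) + 1L)
  out <- vector("list", length(body))
  empty <- body == "-"
  out[empty] <- list(integer(0))
  if (any(!empty)) {
    sp <- strsplit(body[!empty], ",", fixed = TRUE)
    val <- lapply(sp, function(v) suppressWarnings(as.integer(v)))
    bad <- vapply(val, function(v) anyNA(v) || length(v) == 0L, TRUE)
    if (any(bad))
      stop(sprintf("MRF line %d: non-integer %s list '%s'",
                   lineno[!empty][bad][1], field, body[!empty][bad][1]),
           call. = FALSE)
    out[!empty] <- val
  }
  out
}

#' Parse an MRF file into a read_set
#'
#' Reads and validates a mutation read format file (see [write_mrf()] for
#' the grammar). Malformed lines are rejected with their line number;
#' positions outside `[1, L]` or mutations outside the covered intervals
#' are format errors.
#'
#' @param path MRF file path.
#' @param reference_length expected reference length; must equal the file's
#'   `#length` header when both are given. If `NULL`, taken from the header.
#' @return a validated `read_set` in file order.
#' @export
parse_mrf <- function(path, reference_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], "#MRF"))
    stop("not an MRF file (missing '#MRF' header): ", path, call. = FALSE)
  hdr <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2L || hdr[1] != "#length")
    stop("MRF line 2: expected '#length<TAB>L' header", call. = FALSE)
  L <- suppressWarnings(as.integer(hdr[2]))
  if (is.na(L) || L < 1L)
    stop("MRF line 2: bad reference length '", hdr[2], "'", call. = FALSE)
  if (!is.null(reference_length) && L != as.integer(reference_length))
    stop(sprintf("MRF header length %d != expected reference length %d",
                 L, as.integer(reference_length)), call. = FALSE)
  body <- lines[-(1:2)]
  lineno <- seq_along(body) + 2L
  keep <- nzchar(body) & !startsWith(body, "#")
  body <- body[keep]; lineno <- lineno[keep]
  if (length(body) == 0L)
    return(read_set(character(0), list(), list(), list(), list(), L,
                    validate = FALSE))
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 4L))
    stop(sprintf("MRF line %d: expected 4 tab-separated fields, got %d",
                 lineno[nf != 4L][1], nf[nf != 4L][1]), call. = FALSE)
  fm <- matrix(unlist(f, use.names = FALSE), nrow = 4L)
  cov <- fm[2, ]
  ok <- startsWith(cov, "cov=")
  if (!all(ok))
    stop(sprintf("MRF line %d: expected 'cov=' field, got '%s'",
                 lineno[!ok][1], cov[!ok][1]), call. = FALSE)
  iv <- strsplit(substring(cov, 5L), ",", fixed = TRUE)
  starts <- vector("list", length(iv)); ends <- starts
  for (r in seq_along(iv)) {
    m <- regmatches(iv[[r]], regexec("^([0-9]+)-([0-9]+)$", iv[[r]]))
    if (any(lengths(m) != 3L))
      stop(sprintf("MRF line %d: bad interval '%s'", lineno[r],
                   iv[[r]][lengths(m) != 3L][1]), call. = FALSE)
    mm <- matrix(unlist(m, use.names = FALSE), nrow = 3L)
    starts[[r]] <- as.integer(mm[2, ]); ends[[r]] <- as.integer(mm[3, ])
  }
  muts <- parse_poslist(fm[3, ], "mut", lineno)
  lowq <- parse_poslist(fm[4, ], "lowq", lineno)
  x <- try(read_set(fm[1, ], starts, ends, muts, lowq, L, validate = TRUE),
           silent = TRUE)
  if (inherits(x, "try-error")) {
    # re-run validation to translate the failing record into a line number
    tmp <- read_set(fm[1, ], starts, ends, muts, lowq, L, validate = FALSE)
    bad <- check_reads_cpp(tmp$starts, tmp$ends, tmp$muts, tmp$lowq, L)
    stop(sprintf("MRF line %d: %s", lineno[bad[1]],
                 sub("^.*: ", "", attr(x, "condition")$message)),
         call. = FALSE)
  }
  x
}

#' Load a position mask
#'
#' A mask file lists one 1-based position per line; `#` comment lines and
#' blank lines are ignored. Masked positions (for example residues with a
#' high background mutation rate in an untreated control, typically rRNA
#' sequence polymorphisms) are excluded from all counting.
#'
#' @param path mask file path.
#' @param reference_length optional length for range validation.
#' @return sorted integer vector of class `position_mask`.
#' @export
load_mask <- function(path, reference_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  tok <- trimws(lines[keep])
  val <- suppressWarnings(as.integer(tok))
  if (anyNA(val))
    stop("mask file: non-integer token '", tok[is.na(val)][1], "'",
         call. = FALSE)
  position_mask(val, reference_length)
}

#' @rdname load_mask
#' @param positions integer vector of 1-based positions to exclude.
#' @export
position_mask <- function(positions, reference_length = NULL) {
  v <- sort(unique(as.integer(positions)))
  if (length(v) && v[1] < 1L)
    stop("mask positions must be >= 1", call. = FALSE)
  if (!is.null(reference_length) && length(v) &&
      v[length(v)] > reference_length)
    stop("mask position beyond reference length", call. = FALSE)
  structure(v, class = "position_mask")
}

#' Write a position mask file
#' @param mask integer vector of positions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  writeLines(as.character(as.integer(mask)), path)
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' Returns the first (or named) record as a list with `name` and `bases`
#' (uppercase, 1-based indexing convention). Uses Biostrings when
#' available, otherwise a minimal single-record reader.
#'
#' @param path FASTA file path.
#' @return list with elements `name`, `bases`, `length`.
#' @export
read_reference <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss)[1])
    bases <- toupper(as.character(ss[[1]]))
  } else {
    lines <- readLines(path, warn = FALSE)
    hd <- which(startsWith(lines, ">"))
    if (length(hd) == 0L) stop("not a FASTA file: ", path, call. = FALSE)
    to <- if (length(hd) > 1L) hd[2] - 1L else length(lines)
    nm <- sub("\\s.*$", "", substring(lines[hd[1]], 2L))
    bases <- toupper(paste(lines[(hd[1] + 1L):to], collapse = ""))
  }
  list(name = nm, bases = bases, length = nchar(bases))
}

#' Write a reference sequence as FASTA
#' @param name sequence name.
#' @param bases sequence string.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(name, bases, path, width = 70L) {
  n <- nchar(bases)
  at <- seq(1L, n, by = width)
  writeLines(c(paste0(">", name),
               substring(bases, at, pmin(at + width - 1L, n))), path)
  invisible(path)
}
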