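#' Default pipeline configuration
#'
#' Thresholds mirror the published analysis: chi-squared criterion 20,
#' edge strength above 0.015, k-core 3, Louvain resolution 1.0; the
#' remaining keys are this package's operational defaults.
#'
#' @return named list of configuration keys.
#' @export
default_config <- function() {
  list(chi2_min = 20, depth_min = 10000, min_separation = 1,
       weight_min = 0.015, kcore_k = 3, resolution = 1.0,
       z_min = 5, delta_min = 0.01, edge_delta_min = 0.01,
       rate_cut = 0.03, bg_depth_min = 100, seed = 1L)
}

#' Read a flat key:value configuration file
#'
#' One `key: value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys are kept verbatim; known keys override
#' [default_config()].
#'
#' @param path config file path.
#' @return named list (defaults merged with the file's keys).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("bad config line: '", ln, "'", call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a configuration as flat key:value text
#' @param cfg named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(format(v, scientific = FALSE),
                                                  collapse = ","), "")),
             path)
  invisible(path)
}

write_manifest <- function(path, command, inputs, params) {
  jsonlite::write_json(
    list(tool = "ringmapr",
         version = as.character(packageVersion("ringmapr")),
         command = command, inputs = inputs, params = params),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

as_read_set <- function(x) {
  if (inherits(x, "read_set")) x else parse_mrf(x)
}

as_mask <- function(x, L = NULL) {
  if (is.null(x)) NULL
  else if (inherits(x, "position_mask")) x
  else if (is.numeric(x)) position_mask(x, L)
  else load_mask(x, L)
}

as_ring_set <- function(x) {
  if (inherits(x, "ring_set")) x else read_rings(x)
}

log_msg <- function(...) message("[ringmapr] ", sprintf(...))

#' Detect rings from an MRF input (pipeline stage)
#'
#' parse -> quality rule -> accumulate -> detect, with logging and
#' optional TSV + manifest output.
#'
#' @param reads MRF path or `read_set`.
#' @param mask mask path, `position_mask`, or `NULL`.
#' @param out optional output TSV path (a `.manifest.json` sidecar is
#'   written next to it).
#' @param chi2_min,depth_min,min_separation see [detect_rings()] and
#'   [accumulate_pairs()].
#' @param sample provenance label.
#' @return the `ring_set`, invisibly when `out` is given.
#' @export
run_detect <- function(reads, mask = NULL, out = NULL, chi2_min = 20,
                       depth_min = 10000, min_separation = 1,
                       sample = "sample") {
  rs <- as_read_set(reads)
  msk <- as_mask(mask, rs$L)
  log_msg("detect: %d reads, L=%d, %d masked positions", length(rs),
          rs$L, length(msk %||% integer(0)))
  acc <- accumulate_pairs(rs, msk, min_separation)
  rings <- detect_rings(acc, chi2_min = chi2_min, depth_min = depth_min,
                        sample = sample)
  log_msg("detect: %d pairs at depth >= %g tested, %d rings (chi2 > %g)",
          sum(acc$N >= depth_min & upper.tri(acc$N)), depth_min,
          nrow(rings), chi2_min)
  if (!is.null(out)) {
    write_rings(rings, out)
    write_manifest(paste0(out, ".manifest.json"), "detect",
                   list(reads = if (is.character(reads)) reads
                                else "<in-memory>",
                        mask = if (is.character(mask)) mask
                               else length(msk %||% integer(0))),
                   list(chi2_min = chi2_min, depth_min = depth_min,
                        min_separation = min_separation))
    return(invisible(rings))
  }
  rings
}

#' Merge two replicate ring sets (pipeline stage)
#'
#' @param a,b ring TSV paths or `ring_set` objects.
#' @param out optional output TSV path.
#' @return merged `ring_set`.
#' @export
run_merge <- function(a, b, out = NULL) {
  ra <- as_ring_set(a); rb <- as_ring_set(b)
  merged <- merge_replicates(ra, rb)
  log_msg("merge: %d + %d rings -> %d in both replicates (same sign)",
          nrow(ra), nrow(rb), nrow(merged))
  if (!is.null(out)) {
    write_rings(merged, out)
    write_manifest(paste0(out, ".manifest.json"), "merge",
                   list(a = if (is.character(a)) a else "<in-memory>",
                        b = if (is.character(b)) b else "<in-memory>"),
                   list())
    return(invisible(merged))
  }
  merged
}

#' Build, filter and partition the correlation network (pipeline stage)
#'
#' @param rings merged ring TSV path or `ring_set`.
#' @param out_prefix optional output prefix; writes
#'   `<prefix>.graphml`, `<prefix>.communities.tsv`,
#'   `<prefix>.nodes.tsv`, `<prefix>.edges.tsv` and a manifest.
#' @param weight_min,kcore_k see [filter_graph()].
#' @param resolution,seed see [detect_communities()].
#' @return list with `network`, `partition` (NULL when the filtered graph
#'   is empty), `nodes`, `edges`.
#' @export
run_network <- function(rings, out_prefix = NULL, weight_min = 0.015,
                        kcore_k = 3, resolution = 1.0, seed = 1L) {
  rs <- as_ring_set(rings)
  g <- filter_graph(build_graph(rs), weight_min, kcore_k)
  if (igraph::vcount(g$graph) == 0L) {
    warning("network is empty after filtering", call. = FALSE)
    part <- NULL; nodes <- NULL; edges <- NULL
  } else {
    part <- detect_communities(g, resolution, seed)
    nodes <- node_strengths(g)
    edges <- edge_categories(g)
    log_msg("network: %d nodes, %d edges, %d communities, modularity %.3f",
            igraph::vcount(g$graph), igraph::ecount(g$graph),
            length(unique(part$community)), attr(part, "modularity"))
  }
  if (!is.null(out_prefix)) {
    if (!is.null(part)) {
      export_graphml(g, part, paste0(out_prefix, ".graphml"))
      write_communities(part, paste0(out_prefix, ".communities.tsv"))
      write.table(nodes, paste0(out_prefix, ".nodes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(edges, paste0(out_prefix, ".edges.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    } else {
      for (suf in c(".graphml", ".communities.tsv", ".nodes.tsv",
                    ".edges.tsv"))
        writeLines(character(0), paste0(out_prefix, suf))
    }
    write_manifest(paste0(out_prefix, ".manifest.json"), "network",
                   list(rings = if (is.character(rings)) rings
                                else "<in-memory>"),
                   list(weight_min = weight_min, kcore_k = kcore_k,
                        resolution = resolution, seed = seed))
  }
  list(network = g, partition = part, nodes = nodes, edges = edges)
}

#' Per-nucleotide profile (pipeline stage)
#'
#' @inheritParams run_detect
#' @param reference optional FASTA path or reference list.
#' @return a `reactivity_profile`.
#' @export
run_profile <- function(reads, mask = NULL, reference = NULL, out = NULL,
                        sample = "sample") {
  rs <- as_read_set(reads)
  ref <- if (is.character(reference)) read_reference(reference)
         else reference
  prof <- compute_profile(rs, as_mask(mask, rs$L), ref, sample)
  log_msg("profile: %d positions, median depth %g", nrow(prof),
          stats::median(prof$depth))
  if (!is.null(out)) {
    write_profile(prof, out)
    return(invisible(prof))
  }
  prof
}

#' Differential footprint (pipeline stage)
#'
#' @param a,b profile TSV paths or `reactivity_profile` objects
#'   (a = condition of interest, b = baseline).
#' @param z_min,delta_min see [differential_footprint()].
#' @param out optional output TSV path.
#' @return `footprint_calls`.
#' @export
run_footprint <- function(a, b, z_min = 5, delta_min = 0.01, out = NULL) {
  pa <- if (is.character(a)) read_profile(a) else a
  pb <- if (is.character(b)) read_profile(b) else b
  calls <- differential_footprint(pa, pb, z_min, delta_min)
  log_msg("footprint: %d positions called (%d protected, %d enhanced)",
          nrow(calls), sum(calls$verdict == "protected"),
          sum(calls$verdict == "enhanced"))
  if (!is.null(out)) {
    write_footprint(calls, out)
    return(invisible(calls))
  }
  calls
}

#' Differential network edges between conditions (pipeline stage)
#'
#' @param a,b merged ring TSV paths or `ring_set` objects (a = baseline,
#'   b = comparison).
#' @param weight_min,kcore_k network filter applied to each condition.
#' @param edge_delta_min classification threshold.
#' @param out optional output TSV path.
#' @return an `edge_deltas` data frame.
#' @export
run_diffnet <- function(a, b, weight_min = 0.015, kcore_k = 3,
                        edge_delta_min = 0.01, out = NULL) {
  ga <- filter_graph(build_graph(as_ring_set(a)), weight_min, kcore_k)
  gb <- filter_graph(build_graph(as_ring_set(b)), weight_min, kcore_k)
  deltas <- differential_edges(ga, gb, edge_delta_min)
  log_msg("diffnet: %d strengthened, %d weakened of %d union edges",
          sum(deltas$class == "strengthened"),
          sum(deltas$class == "weakened"), nrow(deltas))
  if (!is.null(out)) {
    write_edge_deltas(deltas, out)
    return(invisible(deltas))
  }
  deltas
}

#' Simulate replicates to disk (pipeline stage)
#'
#' Writes one MRF per replicate seed plus the reference FASTA, the
#' ground-truth pair table, a scenario echo and a manifest.
#'
#' @param scenario a `sim_scenario` or one of `"default"`, `"ligand"`,
#'   `"null"`.
#' @param out_dir output directory (created if needed).
#' @param seeds one RNG seed per replicate.
#' @return character vector of MRF paths, invisibly.
#' @export
run_simulate <- function(scenario = "default", out_dir, seeds = c(1L, 2L)) {
  s <- if (inherits(scenario, "sim_scenario")) scenario
  else switch(scenario,
              default = default_domain_scenario(),
              ligand = ligand_scenario(),
              null = null_calibration_scenario(),
              stop("unknown scenario '", scenario, "'", call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(seeds)) {
    reads <- simulate_reads(s, seed = seeds[k],
                            prefix = sprintf("%s_r%d_", s$label, k))
    p <- file.path(out_dir, sprintf("%s_rep%d.mrf", s$label, k))
    write_mrf(reads, p)
    log_msg("simulate: wrote %d reads to %s", length(reads), p)
    paths <- c(paths, p)
  }
  write_reference(s$label, s$sequence,
                  file.path(out_dir, paste0(s$label, ".fa")))
  write_ground_truth(ground_truth(s),
                     file.path(out_dir, paste0(s$label, ".truth.tsv")))
  write_scenario(s, file.path(out_dir, paste0(s$label, ".scenario.txt")))
  write_manifest(file.path(out_dir, paste0(s$label, ".manifest.json")),
                 "simulate", list(scenario = s$label),
                 list(seeds = seeds, n_fragments = s$n_fragments))
  invisible(paths)
}

#' Full two-condition pipeline
#'
#' For each condition (two replicate MRF inputs): detect -> merge ->
#' network; then differential footprints and differential edges between
#' the two conditions. All stages use the thresholds in `cfg`.
#'
#' @param reads_a,reads_b character(2): replicate MRF paths per condition
#'   (a = baseline, b = comparison).
#' @param out_dir output directory.
#' @param mask optional mask path or `position_mask`.
#' @param cfg configuration list ([default_config()] keys).
#' @return list with per-condition rings/network results, `footprint` and
#'   `diffnet`, invisibly.
#' @export
run_all <- function(reads_a, reads_b, out_dir, mask = NULL,
                    cfg = default_config()) {
  stopifnot(length(reads_a) == 2L, length(reads_b) == 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  do_cond <- function(paths, tag) {
    reps <- lapply(seq_along(paths), function(k)
      run_detect(paths[k], mask,
                 out = file.path(out_dir,
                                 sprintf("%s_rep%d.rings.tsv", tag, k)),
                 chi2_min = cfg$chi2_min, depth_min = cfg$depth_min,
                 min_separation = cfg$min_separation,
                 sample = sprintf("%s_rep%d", tag, k)))
    merged <- run_merge(reps[[1]], reps[[2]],
                        out = file.path(out_dir,
                                        sprintf("%s.merged.tsv", tag)))
    net <- run_network(merged,
                       out_prefix = file.path(out_dir, tag),
                       weight_min = cfg$weight_min, kcore_k = cfg$kcore_k,
                       resolution = cfg$resolution,
                       seed = as.integer(cfg$seed))
    prof <- lapply(paths, function(p)
      compute_profile(as_read_set(p), as_mask(mask), sample = tag))
    list(merged = merged, net = net, profiles = prof)
  }
  a <- do_cond(reads_a, "cond_a")
  b <- do_cond(reads_b, "cond_b")
  # pool replicate profiles per condition by summing depth and counts
  pool <- function(ps, tag) {
    df <- ps[[1]]
    df$depth <- ps[[1]]$depth + ps[[2]]$depth
    df$mut_count <- ps[[1]]$mut_count + ps[[2]]$mut_count
    df$rate <- ifelse(df$depth > 0, df$mut_count / df$depth, NA_real_)
    df$rate[df$masked] <- NA_real_
    attr(df, "sample") <- tag
    df
  }
  fp <- run_footprint(pool(b$profiles, "cond_b"), pool(a$profiles, "cond_a"),
                      z_min = cfg$z_min, delta_min = cfg$delta_min,
                      out = file.path(out_dir, "footprint.tsv"))
  dn <- run_diffnet(a$merged, b$merged, weight_min = cfg$weight_min,
                    kcore_k = cfg$kcore_k,
                    edge_delta_min = cfg$edge_delta_min,
                    out = file.path(out_dir, "diffnet.tsv"))
  invisible(list(cond_a = a, cond_b = b, footprint = fp, diffnet = dn))
}
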