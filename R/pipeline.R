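#' Run manifest: full configuration of a pipeline run
#'
#' Names the per-round FASTQ files and fixes every analysis parameter, so
#' the whole pipeline is a pure function of (manifest, input bytes).
#' Labels follow the `R<k><+|->` convention, with `R0` the unselected
#' library; round 0 must be present. Enrichment runs over `R0` and the
#' bound (+) pools.
#'
#' @param fastq Named character vector/list: pool label -> FASTQ path
#'   (must include `"R0"` and at least one `"R<k>+"`).
#' @param spec A [library_spec].
#' @param max_mismatches Per-flank mismatch tolerance for trimming.
#' @param length_center,length_tol Length-filter window.
#' @param pseudocount A [pseudocount_policy()].
#' @param cluster_threshold Identity threshold for clustering.
#' @param cluster_k Number of most-enriched sequences fed to clustering.
#' @param report_k Number of candidates in the report.
#' @param prefix Candidate name prefix.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the run summary.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(fastq, spec = default_library_spec(),
                         max_mismatches = 2,
                         length_center = 25, length_tol = 2,
                         pseudocount = pseudocount_policy(),
                         cluster_threshold = 0.8, cluster_k = 1000,
                         report_k = 10, prefix = "APT",
                         out_dir = "aptenrich_out", seed = 1) {
  fastq <- unlist(fastq)
  if (is.null(names(fastq)) || any(names(fastq) == "")) {
    stop("fastq must be a named vector of pool label -> path", call. = FALSE)
  }
  structure(
    list(fastq = fastq, spec = spec, max_mismatches = max_mismatches,
         length_center = length_center, length_tol = length_tol,
         pseudocount = pseudocount, cluster_threshold = cluster_threshold,
         cluster_k = cluster_k, report_k = report_k, prefix = prefix,
         out_dir = out_dir, seed = seed),
    class = "run_manifest")
}

#' Validate a run manifest
#'
#' Checks, before any compute, that round 0 and at least one bound pool are
#' declared and that every referenced FASTQ file exists.
#'
#' @param manifest A [run_manifest].
#' @return The manifest, invisibly; otherwise an error.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  labels <- names(manifest$fastq)
  if (!"R0" %in% labels) {
    stop("manifest validation: round 0 ('R0') is required — enrichment is ",
         "undefined without the unselected library", call. = FALSE)
  }
  if (!any(grepl("^R[0-9]+\\+$", labels))) {
    stop("manifest validation: at least one bound pool ('R<k>+') is required",
         call. = FALSE)
  }
  missing <- manifest$fastq[!file.exists(manifest$fastq)]
  if (length(missing) > 0) {
    stop("manifest validation: missing FASTQ file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Write / read a run manifest as YAML
#'
#' A flat, human-readable provenance record; a copy is written into every
#' output directory.
#'
#' @param manifest A [run_manifest].
#' @param path YAML file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns a [run_manifest].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  y <- list(
    fastq = as.list(manifest$fastq),
    forward_primer = manifest$spec$forward_primer,
    reverse_tail = manifest$spec$reverse_tail,
    random_len = manifest$spec$random_len,
    base_weights = as.numeric(manifest$spec$base_weights),
    max_mismatches = manifest$max_mismatches,
    length_center = manifest$length_center,
    length_tol = manifest$length_tol,
    pseudocount_mode = manifest$pseudocount$mode,
    pseudocount_constant = manifest$pseudocount$constant,
    cluster_threshold = manifest$cluster_threshold,
    cluster_k = manifest$cluster_k,
    report_k = manifest$report_k,
    prefix = manifest$prefix,
    out_dir = manifest$out_dir,
    seed = manifest$seed)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  run_manifest(
    fastq = unlist(y$fastq),
    spec = library_spec(y$forward_primer, y$reverse_tail, y$random_len,
                        y$base_weights),
    max_mismatches = y$max_mismatches,
    length_center = y$length_center, length_tol = y$length_tol,
    pseudocount = pseudocount_policy(y$pseudocount_mode,
                                     y$pseudocount_constant),
    cluster_threshold = y$cluster_threshold, cluster_k = y$cluster_k,
    report_k = y$report_k, prefix = y$prefix,
    out_dir = y$out_dir, seed = y$seed)
}

#' Run the full enrichment pipeline
#'
#' Orchestrates preprocess -> enrich -> cluster -> report over the pools
#' named in the manifest, writing per-round count tables
#' (`counts_<label>.tsv`), the enrichment table (`enrichment.tsv`), the
#' cluster table (`clusters.tsv` + `cluster_representatives.fasta`), the
#' candidate report (`candidates.tsv`), a copy of the manifest
#' (`manifest.yaml`), and a machine-readable `run_summary.json` with
#' per-stage tallies (reads in = accepted + primer-rejected +
#' length-rejected is asserted per round). Identical manifests over
#' identical inputs produce identical outputs. On stage failure a `FAILED`
#' marker naming the stage is left in the output directory and the error is
#' re-thrown.
#'
#' @param manifest A [run_manifest].
#' @return Invisibly, a list with the output directory, pools, enrichment
#'   table, clusters, report, and the summary list.
#' @export
run_pipeline <- function(manifest) {
  validate_manifest(manifest)
  out <- manifest$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(out, "FAILED")
  if (file.exists(failed)) file.remove(failed)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               failed)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    write_manifest(manifest, file.path(out, "manifest.yaml"))
    policy <- trim_policy_from_spec(manifest$spec,
                                    max_mismatches = manifest$max_mismatches)

    stage <- "prep"
    labels <- names(manifest$fastq)
    raw_reads <- integer(length(labels))
    pools <- vector("list", length(labels))
    names(pools) <- labels
    for (i in seq_along(labels)) {
      recs <- read_fastq(manifest$fastq[[i]])
      raw_reads[i] <- nrow(recs)
      pools[[i]] <- prep_round(recs$bases, policy, labels[i],
                               center = manifest$length_center,
                               tol = manifest$length_tol)
      write_pool_tsv(pools[[i]],
                     file.path(out, sprintf("counts_%s.tsv",
                                            gsub("[+]", "plus",
                                                 gsub("[-]", "minus", labels[i])))))
    }
    tallies <- lapply(seq_along(labels), function(i) {
      p <- pools[[i]]
      stopifnot(p$total_reads + p$n_rejected_primer + p$n_rejected_length ==
                  raw_reads[i])  # conservation ledger
      list(label = labels[i], reads_in = raw_reads[i],
           accepted = p$total_reads,
           rejected_primer = p$n_rejected_primer,
           rejected_length = p$n_rejected_length,
           distinct = length(p$counts),
           duplication_pct = if (p$total_reads > 0)
             duplication_percent(p) else NA)
    })

    stage <- "enrich"
    bound_labels <- c("R0", sort(grep("^R[0-9]+\\+$", labels, value = TRUE)))
    profiles <- enrichment_table(pools[bound_labels], manifest$pseudocount)
    write_enrichment_tsv(rank_by(profiles, "comp_score"),
                         file.path(out, "enrichment.tsv"))

    stage <- "cluster"
    top <- top_k(profiles, k = manifest$cluster_k)
    clusters <- greedy_cluster(attach_primers(top, manifest$spec),
                               threshold = manifest$cluster_threshold)
    write_cluster_tsv(clusters, file.path(out, "clusters.tsv"),
                      file.path(out, "cluster_representatives.fasta"))

    stage <- "report"
    report <- build_report(profiles, clusters, k = manifest$report_k,
                           prefix = manifest$prefix, spec = manifest$spec)
    write_report_tsv(report, file.path(out, "candidates.tsv"))

    stage <- "summary"
    summary <- list(
      package = "aptenrich",
      version = as.character(utils::packageVersion("aptenrich")),
      seed = manifest$seed,
      parameters = list(
        max_mismatches = manifest$max_mismatches,
        length_center = manifest$length_center,
        length_tol = manifest$length_tol,
        pseudocount = manifest$pseudocount$mode,
        pseudocount_constant = manifest$pseudocount$constant,
        cluster_threshold = manifest$cluster_threshold,
        cluster_k = manifest$cluster_k,
        report_k = manifest$report_k),
      pools = tallies,
      n_profiles = nrow(profiles),
      n_clusters = length(attr(clusters, "representatives")))
    jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(out_dir = out, pools = pools, profiles = profiles,
                   clusters = clusters, report = report, summary = summary))
  }, error = on_fail)
}

#' Build a self-contained simulated fixture on disk
#'
#' Simulates a full SELEX experiment with planted winners and writes the
#' per-round FASTQ files (`R0.fastq`, `R1+.fastq`, `R1-.fastq`, ...), the
#' ground-truth table (`truth.tsv`), and a ready-to-run `manifest.yaml`
#' into `dir`. `"tiny"` is a seconds-scale test fixture (300 background
#' sequences, 5000 reads/pool); `"paper_scale"` runs the full 4-round
#' schedule with 6/9/12/15 washes, 1e4 background sequences and 1e5
#' reads/pool.
#'
#' @param size `"tiny"` or `"paper_scale"`.
#' @param seed RNG seed.
#' @param dir Output directory.
#' @return The [run_manifest], invisibly.
#' @export
make_fixture <- function(size = c("tiny", "paper_scale"), seed = 1,
                         dir = tempfile("aptenrich_fixture_")) {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- default_library_spec()
  n_background <- switch(size, tiny = 300, paper_scale = 1e4)
  reads <- switch(size, tiny = 5000, paper_scale = 1e5)

  exp0 <- plant_selex_experiment(spec, n_background = n_background,
                                 n_winners = 3, depth = reads, seed = seed)
  schedule <- round_schedule(n_rounds = 4, washes_per_round = c(6, 9, 12, 15),
                             reads_per_round = reads, seed = seed)
  sim <- simulate_selex(exp0$pool0, exp0$truth, schedule)

  paths <- c(R0 = file.path(dir, "R0.fastq"))
  write_round_fastq(sim$library, paths[["R0"]], seed = seed)
  for (k in seq_len(schedule$n_rounds)) {
    for (side in c("bound", "unbound")) {
      sgn <- if (side == "bound") "+" else "-"
      lab <- sprintf("R%d%s", k, sgn)
      p <- file.path(dir, sprintf("R%d%s.fastq", k, sgn))
      pool <- sim$rounds[[k]][[side]]
      if (pool$total_reads > 0) {
        write_round_fastq(pool, p, seed = seed + 100 * k +
                            (side == "unbound"))
        paths[lab] <- p
      }
    }
  }
  write_truth_tsv(exp0$truth, file.path(dir, "truth.tsv"))

  manifest <- run_manifest(
    fastq = paths, spec = spec,
    cluster_k = switch(size, tiny = 100, paper_scale = 1000),
    out_dir = file.path(dir, "out"), seed = seed)
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
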