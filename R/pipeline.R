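#' Configure an end-to-end pipeline run
#'
#' One structured configuration drives every stage (scan, align, project,
#' aggregate, clusters, enrich, and optionally a parsimony tree), with every
#' default surfaced so results echo the exact parameters used. Inputs come
#' either from files or from a bundled simulation ([simulation_config()]),
#' in which case the generated family is written alongside the results.
#'
#' @param outdir output directory for all stage artifacts.
#' @param loci_fasta,consensus_fasta,domain_table,matrix_file input paths
#'   (loci FASTA; consensus FASTA; tab-separated `label start end` domain
#'   table; TRANSFAC-format matrix file). Not needed when `simulate` is
#'   given, except `matrix_file` which is always required for scanning.
#' @param simulate optional [simulation_config()]: generate the locus set
#'   instead of reading it.
#' @param pseudocount,background,threshold_fraction PWM construction
#'   parameters ([build_pwm()]).
#' @param align_params [alignment_params()].
#' @param min_aligned_frac projection filter ([project_hits()]).
#' @param cluster_tolerance single-linkage tolerance `w` in nt
#'   ([cluster_shared_sites()]).
#' @param n_permutations domain-enrichment permutations
#'   ([domain_enrichment()]).
#' @param seed integer seed covering every stochastic stage.
#' @param ortholog_fasta optional aligned FASTA of an orthologous locus set;
#'   when given, an exact maximum-parsimony tree is built.
#' @param outgroup optional outgroup label for tree rooting.
#' @param stages character vector of stage toggles (default: every
#'   applicable stage).
#' @return a validated `pipeline_config` object.
#' @export
pipeline_config <- function(outdir,
                            matrix_file,
                            loci_fasta = NULL, consensus_fasta = NULL,
                            domain_table = NULL, simulate = NULL,
                            pseudocount = 0.25,
                            background = c(0.25, 0.25, 0.25, 0.25),
                            threshold_fraction = 0.8,
                            align_params = alignment_params(),
                            min_aligned_frac = 0.8,
                            cluster_tolerance = 5,
                            n_permutations = 1000L,
                            seed = 1L,
                            ortholog_fasta = NULL, outgroup = NULL,
                            stages = c(
                              "scan", "align", "project",
                              "aggregate", "clusters", "enrich", "mptree"
                            )) {
  if (missing(outdir) || is.null(outdir)) stop_input("configuration error: 'outdir' is required")
  if (missing(matrix_file) || is.null(matrix_file)) {
    stop_input("configuration error: 'matrix_file' is required")
  }
  if (is.null(simulate)) {
    for (f in c("loci_fasta", "consensus_fasta")) {
      v <- get(f)
      if (is.null(v)) stop_input("configuration error: '", f, "' is required unless simulating")
    }
  } else if (!inherits(simulate, "sim_config")) {
    stop_input("configuration error: 'simulate' must be a simulation_config()")
  }
  for (f in c(
    "loci_fasta", "consensus_fasta", "domain_table", "matrix_file",
    "ortholog_fasta"
  )) {
    v <- get(f)
    if (!is.null(v) && !file.exists(v)) {
      stop_input("configuration error: '", f, "' does not exist: ", v)
    }
  }
  structure(
    list(
      outdir = outdir, matrix_file = matrix_file,
      loci_fasta = loci_fasta, consensus_fasta = consensus_fasta,
      domain_table = domain_table, simulate = simulate,
      pseudocount = pseudocount, background = background,
      threshold_fraction = threshold_fraction, align_params = align_params,
      min_aligned_frac = min_aligned_frac,
      cluster_tolerance = cluster_tolerance,
      n_permutations = as.integer(n_permutations), seed = as.integer(seed),
      ortholog_fasta = ortholog_fasta, outgroup = outgroup, stages = stages
    ),
    class = "pipeline_config"
  )
}

pipeline_log <- function(con, quiet, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  if (!quiet) message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full shared-binding-site pipeline
#'
#' Orchestrates simulate/load -> PWM scan -> consensus alignment ->
#' projection -> position histogram -> shared-site clusters -> domain
#' enrichment (-> parsimony tree) under one seed, writing every stage
#' artifact into `config$outdir`. Identical configuration and seed give
#' byte-identical artifacts, and the run is exactly the composition of the
#' per-stage functions.
#'
#' Artifacts: `config.yaml` (parameter echo), `loci.fasta` /
#' `consensus.fasta` / `domains.tsv` / `truth.tsv` (simulated runs),
#' `hits.tsv`, `alignments.tsv`, `projected.bed`, `rejected.tsv`,
#' `histogram.tsv`, `clusters.tsv`, `enrichment.tsv`, `tree.nwk`,
#' `report.yaml`, `run.log`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress console logging (default `FALSE`).
#' @return a `sine_run_report`: per-stage record counts (`hits` always
#'   equals `projected + rejected`), rejected-hit tally by reason, top
#'   shared-site clusters, the enrichment table, package version and config
#'   hash.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logcon))
  say <- function(stage, fmt, ...) {
    pipeline_log(logcon, quiet, stage, sprintf(fmt, ...))
  }
  stage_guard <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    if (!quiet) {
      message(sprintf(
        "[%s] done in %.2f s", stage, proc.time()[["elapsed"]] - t0
      ))
    }
    r
  }
  counts <- list()

  # ---- inputs --------------------------------------------------------------
  family <- NULL
  if (!is.null(config$simulate)) {
    motifs0 <- read_transfac(config$matrix_file)
    family <- stage_guard("simulate", simulate_family(config$simulate, motifs0))
    write_family(family, config$outdir)
    loci <- family$loci
    consensus <- family$consensus
    say("simulate", "%d loci, consensus %d nt", length(loci), consensus$length)
  } else {
    loci <- stage_guard("load", read_fasta(config$loci_fasta))
    names(loci) <- sub("\\|.*$", "", names(loci))
    cf <- read_fasta(config$consensus_fasta)
    dom <- if (!is.null(config$domain_table)) read_domain_table(config$domain_table)
    consensus <- sine_consensus(cf[[1]], domains = dom, name = names(cf)[1])
    say("load", "%d loci, consensus %d nt", length(loci), consensus$length)
  }
  counts$loci <- length(loci)

  cfg_echo <- config
  cfg_echo$align_params <- unclass(cfg_echo$align_params)
  cfg_echo$simulate <- if (!is.null(config$simulate)) {
    s <- unclass(config$simulate)
    s$domain_layout <- NULL
    s$embeddings <- lapply(s$embeddings, unclass)
    s
  }
  yaml::write_yaml(unclass(cfg_echo), file.path(config$outdir, "config.yaml"))
  config_hash <- unname(tools::md5sum(file.path(config$outdir, "config.yaml")))

  pwms <- lapply(
    read_transfac(config$matrix_file), build_pwm,
    pseudocount = config$pseudocount, background = config$background,
    threshold_fraction = config$threshold_fraction
  )
  counts$motifs <- length(pwms)

  on_stage <- function(s) s %in% config$stages
  hits <- projected <- rejected <- clusters <- enrichment <- histogram <- NULL

  if (on_stage("scan")) {
    hits <- stage_guard("scan", scan_loci(pwms, loci))
    write_tsv_report(hits, file.path(config$outdir, "hits.tsv"))
    counts$hits <- nrow(hits)
    say("scan", "%d hits from %d motifs", nrow(hits), length(pwms))
  }

  maps <- NULL
  if (on_stage("align")) {
    maps <- stage_guard("align", align_family(loci, consensus, config$align_params))
    write_alignment_maps(maps, file.path(config$outdir, "alignments.tsv"))
    counts$aligned <- length(maps)
    say(
      "align", "median aligned fraction %.3f",
      median(vapply(maps, `[[`, 0, "aligned_fraction"))
    )
  }

  if (on_stage("project") && !is.null(hits) && !is.null(maps)) {
    pr <- stage_guard(
      "project", project_hits(hits, maps, config$min_aligned_frac)
    )
    projected <- pr$projected
    rejected <- pr$rejected
    write_projected_bed(
      projected, file.path(config$outdir, "projected.bed"),
      consensus_name = consensus$name
    )
    write_tsv_report(rejected, file.path(config$outdir, "rejected.tsv"))
    counts$projected <- nrow(projected)
    counts$rejected <- nrow(rejected)
    say("project", "%d projected, %d rejected", nrow(projected), nrow(rejected))
  }

  if (on_stage("aggregate") && !is.null(projected)) {
    histogram <- stage_guard(
      "aggregate", aggregate_histogram(projected, consensus$length)
    )
    write_histogram(histogram, file.path(config$outdir, "histogram.tsv"))
    say("aggregate", "histogram mass %d", histogram$mass)
  }

  if (on_stage("clusters") && !is.null(projected)) {
    clusters <- stage_guard(
      "clusters", cluster_shared_sites(projected, config$cluster_tolerance)
    )
    write_clusters(clusters, file.path(config$outdir, "clusters.tsv"))
    counts$clusters <- nrow(clusters)
    say("clusters", "%d clusters (top n_loci = %s)", nrow(clusters), if (nrow(clusters)) clusters$n_loci[1] else "0")
  }

  if (on_stage("enrich") && !is.null(projected) && !is.null(consensus$domains)) {
    enrichment <- stage_guard("enrich", domain_enrichment(
      projected, consensus,
      n_permutations = config$n_permutations, seed = config$seed
    ))
    write_enrichment(enrichment, file.path(config$outdir, "enrichment.tsv"))
    say("enrich", "%d motif x domain tests", nrow(enrichment))
  }

  tree_newick <- NULL
  if (on_stage("mptree") && !is.null(config$ortholog_fasta)) {
    aln <- character_alignment(read_fasta(config$ortholog_fasta))
    sr <- stage_guard("mptree", search_mp(aln))
    tree_newick <- to_newick(
      sr$trees[[1]],
      outgroup = config$outgroup, alignment = aln
    )
    writeLines(tree_newick, file.path(config$outdir, "tree.nwk"))
    say("mptree", "length %d, %d optimal topologies", sr$length, sr$n_trees)
  }

  report <- structure(
    list(
      counts = counts,
      rejected_by_reason = if (!is.null(rejected) && nrow(rejected)) {
        as.list(table(rejected$reason))
      } else {
        list()
      },
      top_clusters = if (!is.null(clusters)) head(clusters, 10),
      enrichment = enrichment,
      tree = tree_newick,
      version = as.character(packageVersion("sinexapt")),
      config_hash = config_hash,
      outdir = config$outdir
    ),
    class = "sine_run_report"
  )
  rep_out <- list(
    version = report$version, config_hash = report$config_hash,
    counts = counts, rejected_by_reason = report$rejected_by_reason
  )
  yaml::write_yaml(rep_out, file.path(config$outdir, "report.yaml"))
  report
}

#' @export
print.sine_run_report <- function(x, ...) {
  cat("Pipeline run (sinexapt ", x$version, ", config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  for (nm in names(x$counts)) cat(sprintf("  %-10s %d\n", nm, x$counts[[nm]]))
  if (length(x$rejected_by_reason)) {
    cat("  rejected hits by reason:\n")
    for (nm in names(x$rejected_by_reason)) {
      cat(sprintf("    %-24s %d\n", nm, x$rejected_by_reason[[nm]]))
    }
  }
  if (!is.null(x$top_clusters) && nrow(x$top_clusters)) {
    cat("  top shared-site clusters:\n")
    tc <- head(x$top_clusters, 5)
    for (i in seq_len(nrow(tc))) {
      cat(sprintf(
        "    %-10s %s [%d,%d) n_loci=%d\n", tc$motif_id[i],
        tc$consensus_strand[i], tc$rep_start[i], tc$rep_end[i], tc$n_loci[i]
      ))
    }
  }
  if (!is.null(x$tree)) cat("  MP tree:", x$tree, "\n")
  invisible(x)
}
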