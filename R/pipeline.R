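#' End-to-end cohort analysis
#'
#' Runs the full workflow on a cohort: frequency summary, branching and/or
#' distance tree fits, bootstrap, and consensus report, writing a versioned
#' bundle of machine-readable outputs plus a markdown summary to `out_dir`.
#'
#' Files written (method-dependent): `frequencies.json`, `branching.json`,
#' `branching.dot`, `distance.json`, `distance.nwk`,
#' `bootstrap_<method>.json`, `consensus_<method>.tsv`,
#' `frequent_trees_<method>.txt`, `report.md`, and `run.log` (seed, clamp
#' floor, package version; the only file carrying a timestamp).
#'
#' @param input path to the cohort table, or an [alteration_matrix()].
#' @param out_dir output directory (created if missing).
#' @param dialect input dialect, see [read_matrix()].
#' @param call_threshold GISTIC binarization threshold, see [read_matrix()].
#' @param genes optional character vector restricting the event panel.
#' @param method `"branching"`, `"distance"`, or `"both"`.
#' @param B bootstrap replicate count (0 disables the bootstrap).
#' @param seed master seed.
#' @param consensus_threshold split-support display threshold in `[0, 1)`.
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_analysis <- function(input, out_dir, dialect = "binary_tsv",
                         call_threshold = 2L, genes = NULL,
                         method = c("both", "branching", "distance"),
                         B = 1000L, seed = 1L, consensus_threshold = 0.10) {
  method <- match.arg(method)
  if (consensus_threshold < 0 || consensus_threshold >= 1)
    stop("consensus threshold must lie in [0, 1)")
  mat <- if (inherits(input, "alteration_matrix")) input
         else read_matrix(input, dialect, call_threshold)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, colnames(mat))
    if (length(missing_genes))
      stop("panel gene(s) not in input header: ",
           paste(missing_genes, collapse = ", "))
    mat <- alteration_matrix(unclass(mat)[, genes, drop = FALSE])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  methods <- if (method == "both") c("branching", "distance") else method

  freq_sum <- frequency_summary(mat)
  freq_summary_json(freq_sum, path("frequencies.json"))
  out <- list(matrix = mat, frequencies = freq_sum, files = "frequencies.json")

  md <- c("# Oncogenetic tree analysis", "",
          sprintf("Cohort: %d samples, %d events (%s)", nrow(mat), ncol(mat),
                  paste(colnames(mat), collapse = ", ")), "",
          "## Alteration frequencies", "",
          "| event | count | percent |", "|---|---|---|",
          sprintf("| %s | %d | %d%% |", freq_sum$events$event,
                  freq_sum$events$count, freq_sum$events$percent),
          sprintf("| any event | %d | %d%% |", freq_sum$any$count,
                  freq_sum$any$percent), "")

  if ("branching" %in% methods) {
    btree <- fit_branching(mat)
    onco_tree_json(btree, path("branching.json"))
    onco_tree_dot(btree, path("branching.dot"))
    out$branching <- btree
    md <- c(md, "## Branching tree", "", "```",
            utils::capture.output(print(btree)), "```", "")
  }
  if ("distance" %in% methods) {
    dtree <- fit_distance(mat)
    wrt_json(dtree, path("distance.json"))
    write_newick(dtree, path("distance.nwk"))
    out$distance <- dtree
    md <- c(md, "## Distance-based tree", "", "```",
            write_newick(dtree), "```", "")
  }
  if (B > 0L) for (mth in methods) {
    bs <- bootstrap(mat, mth, B = B, seed = seed)
    bootstrap_json(bs, path(sprintf("bootstrap_%s.json", mth)))
    cons <- consensus_report(bs, consensus_threshold)
    utils::write.table(cons$consensus,
                       path(sprintf("consensus_%s.tsv", mth)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_frequent_trees(bs, path(sprintf("frequent_trees_%s.txt", mth)))
    out[[paste0("bootstrap_", mth)]] <- bs
    ft <- frequent_trees(bs, 5)
    md <- c(md,
            sprintf("## Bootstrap (%s, B = %d)", mth, B), "",
            sprintf("Original topology reconstructed %d/%d times.",
                    if (bs$original_topology %in% names(bs$topology_counts))
                      bs$topology_counts[[bs$original_topology]] else 0L,
                    bs$B), "",
            "| topology | count |", "|---|---|",
            sprintf("| `%s` | %d |", ft$topology, ft$count), "",
            sprintf("Splits with support > %.0f%%: %d (see consensus_%s.tsv).",
                    100 * consensus_threshold, nrow(cons$consensus), mth), "")
  }
  writeLines(md, path("report.md"))
  writeLines(c(sprintf("oncotreefit %s",
                       as.character(utils::packageVersion("oncotreefit"))),
               sprintf("timestamp: %s", format(Sys.time())),
               sprintf("seed: %d", as.integer(seed)),
               sprintf("clamp floor: %g", 1 / (2 * nrow(mat))),
               sprintf("R %s", as.character(getRversion()))),
             path("run.log"))
  invisible(out)
}

cli_spec <- function() {
  list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--dialect", type = "character",
                          default = "binary_tsv"),
    optparse::make_option("--call-threshold", type = "integer", default = 2L,
                          dest = "call_threshold"),
    optparse::make_option("--genes", type = "character", default = NULL,
                          help = "comma-separated event panel"),
    optparse::make_option("--method", type = "character", default = "both"),
    optparse::make_option("--bootstrap-B", type = "integer", default = 1000L,
                          dest = "B"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--consensus-threshold", type = "double",
                          default = 0.10, dest = "consensus_threshold"),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--n", type = "integer", default = 963L),
    optparse::make_option("--spec", type = "character", default = NULL,
                          help = "generative spec JSON (simulate)"),
    optparse::make_option("--variant", type = "character",
                          default = "sibling"))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (cohort from a generative spec JSON or the
#' built-in reference tree), `fixture` (deterministic count-matched cohort),
#' `freq`, `branching`, `disttree`, `bootstrap`, and `run` (the full
#' [run_analysis()] bundle).  User errors exit with status 2 and a message,
#' never a traceback.
#'
#' @param args character vector of command-line arguments (first element the
#'   subcommand); defaults to the process arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
onco_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: oncotreefit",
                 "{simulate|fixture|freq|branching|disttree|bootstrap|run}",
                 "[options]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  run <- function() {
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = cli_spec()), args[-1L])
    genes <- if (!is.null(opts$genes))
      strsplit(opts$genes, ",")[[1L]] else NULL
    need_input <- function() {
      if (is.null(opts$input)) stop("--input is required for '", cmd, "'")
      read_matrix(opts$input, opts$dialect, opts$call_threshold)
    }
    switch(cmd,
      simulate = {
        spec <- if (!is.null(opts$spec)) read_spec_json(opts$spec)
                else paper_tree_fixture(opts$variant, n = opts$n,
                                        seed = opts$seed)
        spec$seed <- opts$seed
        write_matrix(simulate_cohort(spec), opts$out)
      },
      fixture = {
        counts <- breast_cna_counts()
        write_matrix(fixture_from_counts(opts$n, counts,
                                         attr(counts, "any_altered")),
                     opts$out)
      },
      freq = cat(freq_summary_json(frequency_summary(need_input())), "\n"),
      branching = cat(onco_tree_json(fit_branching(need_input())), "\n"),
      disttree = cat(write_newick(fit_distance(need_input())), "\n"),
      bootstrap = cat(bootstrap_json(
        bootstrap(need_input(),
                  if (opts$method == "both") "branching" else opts$method,
                  B = opts$B, seed = opts$seed)), "\n"),
      run = run_analysis(opts$input, opts$out, opts$dialect,
                         opts$call_threshold, genes, opts$method, opts$B,
                         opts$seed, opts$consensus_threshold),
      stop("unknown subcommand '", cmd, "'\n", usage))
    invisible(0L)
  }
  tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(2L)
  })
}
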