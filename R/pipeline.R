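## Pipeline driver: simulate -> score -> tree -> hybridtest -> topotest,
## with manifests and a thin command-line front end.

#' Pipeline configuration
#'
#' @param stages character subset of
#'   `c("simulate", "score", "tree", "hybridtest", "topotest")`, run in that
#'   order
#' @param sim a [sim_config()] for the simulate stage
#' @param score list: `grid` (a [threshold_grid()]), `min_retained_frac`
#' @param tree list: `n_boot`, `transform`, `outgroup` (species label used
#'   to root the rendered tree, or NULL), `suppress_below`
#' @param hybridtest list: `n_boot`, `min_delta`, `fence`
#' @param topotest list: `n_rell`, `conditioning`, `mcmc_gens`,
#'   `burnin_frac`, `topologies` (paths to Newick files with extra
#'   candidate topologies, may be empty)
#' @param seed master seed; all stage seeds are derived from it
#' @param outdir output directory
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(stages = c("simulate", "score", "tree",
                                       "hybridtest", "topotest"),
                            sim = sim_config(),
                            score = list(),
                            tree = list(),
                            hybridtest = list(),
                            topotest = list(),
                            seed = 1L,
                            outdir = "aflphylo_out") {
  stages <- match.arg(stages, several.ok = TRUE)
  score <- modifyList(list(grid = threshold_grid(),
                           min_retained_frac = 0.1), score)
  tree <- modifyList(list(n_boot = 1000L, transform = "one-minus-f",
                          outgroup = NULL, suppress_below = 50), tree)
  hybridtest <- modifyList(list(n_boot = 100L, min_delta = 10,
                                fence = "tukey"), hybridtest)
  topotest <- modifyList(list(n_rell = 1000L, conditioning = "noabsencesites",
                              mcmc_gens = 5000L, burnin_frac = 0.5,
                              topologies = character()), topotest)
  structure(list(stages = stages, sim = sim, score = score, tree = tree,
                 hybridtest = hybridtest, topotest = topotest,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

manifest_entry <- function(files, stage, seed, params) {
  list(stage = stage, seed = seed, parameters = params,
       version = as.character(packageVersion("aflphylo")),
       files = lapply(files, function(f)
         list(path = f, md5 = unname(tools::md5sum(f)))))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order, writing every artifact plus a
#' `manifest.json` (per-stage parameters, derived seed, and an md5 for each
#' output file). Later stages read the artifacts of earlier ones from
#' `outdir`, so a partial pipeline can be resumed against existing files.
#'
#' @param config a [pipeline_config()]
#' @param matrix optional [aflp_binary] to use instead of the scored matrix
#'   when the simulate/score stages are disabled
#' @return list of stage results, invisibly; artifacts land in
#'   `config$outdir`
#' @export
run_pipeline <- function(config, matrix = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$outdir, ...)
  manifest <- list()
  results <- list()
  truth <- NULL

  if ("simulate" %in% config$stages) {
    message("[simulate] ", config$sim$n_species, " species, ",
            config$sim$n_loci, " loci, seed ", config$sim$seed)
    truth <- simulate_aflp_dataset(config$sim)
    write_binary_matrix(truth$matrix, p("true_matrix.tsv"))
    write_peak_table(truth$peaks, p("peaks.tsv"))
    write_tree(truth$species_tree, p("species_tree.nwk"),
               with_support = FALSE)
    jsonlite::write_json(
      truth$hybrid_assignments, p("ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$simulate <- manifest_entry(
      list(p("true_matrix.tsv"), p("peaks.tsv"), p("species_tree.nwk"),
           p("ground_truth.json")),
      "simulate", config$sim$seed,
      config$sim[setdiff(names(config$sim), "hybrid_specs")])
    results$simulate <- truth
  }

  if ("score" %in% config$stages) {
    peaks <- if (!is.null(truth)) truth$peaks else
      read_peak_table(p("peaks.tsv"))
    message("[score] optimizing thresholds over ",
            length(config$score$grid$retention), " retention levels")
    opt <- optimize_thresholds(peaks, config$score$grid,
                               config$score$min_retained_frac)
    calls <- call_phenotypes(peaks, opt$thresholds)
    scored <- filter_unique_loci(
      aflp_binary(calls$calls[setdiff(rownames(calls$calls),
                                      calls$replicates), , drop = FALSE],
                  calls$species))
    write_binary_matrix(scored, p("scored_matrix.tsv"))
    write_binary_matrix(scored, p("scored_matrix.nex"), dialect = "nexus")
    jsonlite::write_json(
      list(thresholds = unclass(opt$thresholds),
           overall_error = opt$report$overall_error,
           pair_mean_error = opt$report$pair_mean_error,
           n_retained_loci = opt$report$n_retained_loci),
      p("scoring_report.json"), auto_unbox = TRUE, digits = NA)
    manifest$score <- manifest_entry(
      list(p("scored_matrix.tsv"), p("scored_matrix.nex"),
           p("scoring_report.json")),
      "score", config$seed,
      list(min_retained_frac = config$score$min_retained_frac))
    results$score <- list(thresholds = opt$thresholds, report = opt$report,
                          matrix = scored)
    matrix <- scored
  }

  if (is.null(matrix) &&
      any(c("tree", "hybridtest", "topotest") %in% config$stages))
    matrix <- read_binary_matrix(p("scored_matrix.tsv"))

  bs <- NULL
  if ("tree" %in% config$stages) {
    message("[tree] NJ + ", config$tree$n_boot, " bootstrap pseudoreplicates")
    bs <- bootstrap_support(matrix, config$tree$n_boot,
                            seed = derive_seed(config$seed, "tree"),
                            transform = config$tree$transform)
    display <- bs$tree
    if (!is.null(config$tree$outgroup)) {
      og <- names(matrix$species)[matrix$species == config$tree$outgroup]
      og <- intersect(og, display$tip.label)
      if (length(og) > 0)
        display <- tryCatch(ape::root(display, og, resolve.root = TRUE),
                            error = function(e) display)
    }
    write_tree(bs$tree, p("nj_tree.nwk"))
    write_tree(display, p("nj_tree_display.nwk"),
               suppress_below = config$tree$suppress_below)
    write_support_table(bs$support, p("support.tsv"))
    manifest$tree <- manifest_entry(
      list(p("nj_tree.nwk"), p("nj_tree_display.nwk"), p("support.tsv")),
      "tree", derive_seed(config$seed, "tree"),
      config$tree[c("n_boot", "transform")])
    results$tree <- bs
  }

  if ("hybridtest" %in% config$stages) {
    message("[hybridtest] leave-one-species-out, ",
            config$hybridtest$n_boot, " bootstraps per removal")
    hx <- homoplasy_excess_test(matrix, config$hybridtest$n_boot,
                                seed = config$seed,
                                min_delta = config$hybridtest$min_delta,
                                fence = config$hybridtest$fence,
                                transform = config$tree$transform)
    jsonlite::write_json(
      list(flagged = as.list(hx$flagged),
           verdict = as.list(hx$verdict),
           outliers = hx$outliers,
           parameters = hx$parameters),
      p("homoplasy_result.json"), auto_unbox = TRUE, digits = NA)
    dt <- data.frame(removed_species = rownames(hx$deltas), hx$deltas,
                     check.names = FALSE)
    write.table(dt, p("homoplasy_deltas.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$hybridtest <- manifest_entry(
      list(p("homoplasy_result.json"), p("homoplasy_deltas.tsv")),
      "hybridtest", config$seed, config$hybridtest)
    results$hybridtest <- hx
  }

  if ("topotest" %in% config$stages) {
    model <- estimate_state_frequencies(matrix,
                                        config$topotest$conditioning)
    nj_tree <- if (!is.null(bs)) bs$tree else
      neighbor_joining(nei_li_matrix(matrix))
    cands <- list(nj = strip_support(nj_tree))
    for (f in config$topotest$topologies)
      cands[[tools::file_path_sans_ext(basename(f))]] <- ape::read.tree(f)
    if (length(cands) < 2) {
      ## no user topology: compare the NJ tree against a species-consensus
      ## NJ alternative so the machinery is still exercised end to end
      cands$sample_upgma <- strip_support(
        ape::as.phylo(stats::hclust(stats::as.dist(nei_li_matrix(matrix)),
                                    method = "average")))
    }
    message("[topotest] SH over ", length(cands), " topologies, ",
            config$topotest$n_rell, " RELL replicates")
    sh <- sh_test(matrix, cands, model, config$topotest$n_rell,
                  seed = derive_seed(config$seed, "sh"))
    ml <- lapply(names(cands), function(nm)
      marginal_likelihood_harmonic(sh$trees[[nm]], model, matrix,
                                   n_gens = config$topotest$mcmc_gens,
                                   burnin_frac = config$topotest$burnin_frac,
                                   seed = derive_seed(config$seed, nm)))
    names(ml) <- names(cands)
    bf <- list()
    nms <- names(cands)
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i >= j) next
      key <- paste(nms[i], "vs", nms[j])
      bf[[key]] <- bayes_factor(ml[[i]]$ln_marginal, ml[[j]]$ln_marginal)
    }
    jsonlite::write_json(
      list(sh_pvalues = as.list(sh$sh_pvalues),
           logliks = as.list(sh$logliks),
           deltas = as.list(sh$deltas),
           marginal = lapply(ml, function(m) m$ln_marginal),
           bayes_factors = bf),
      p("topotest_result.json"), auto_unbox = TRUE, digits = NA)
    manifest$topotest <- manifest_entry(
      list(p("topotest_result.json")), "topotest",
      derive_seed(config$seed, "sh"),
      config$topotest[c("n_rell", "conditioning", "mcmc_gens")])
    results$topotest <- list(sh = sh, marginal = ml, bayes_factors = bf)
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(results)
}

strip_support <- function(phy) {
  phy$node.label <- NULL
  phy
}

#' Command-line entry point
#'
#' `aflphylo_cli(c("run", "--seed", "7", "--outdir", "out"))` runs the full
#' pipeline; subcommands `simulate`, `score`, `tree`, `hybridtest`,
#' `topotest` run a single stage. A JSON config file (`--config`) may
#' override any [pipeline_config()] field; flags override the file.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`)
#' @return exit status, invisibly (0 on success)
#' @export
aflphylo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !(args[1] %in% c("run", "simulate", "score", "tree", "hybridtest",
                       "topotest"))) {
    cat("usage: aflphylo <run|simulate|score|tree|hybridtest|topotest>",
        "[--config FILE] [--seed S] [--outdir DIR] [--boot N]",
        "[--min-delta D] [--rell N]\n")
    return(invisible(1L))
  }
  stage <- args[1]
  opt <- list(seed = 1L, outdir = "aflphylo_out", config = NULL,
              boot = NULL, min_delta = NULL, rell = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!(key %in% names(opt))) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg_args <- list(seed = as.integer(opt$seed), outdir = opt$outdir)
  if (!is.null(opt$config))
    cfg_args <- modifyList(jsonlite::read_json(opt$config,
                                               simplifyVector = TRUE),
                           cfg_args)
  if (!is.null(cfg_args$sim) && !inherits(cfg_args$sim, "sim_config"))
    cfg_args$sim <- do.call(sim_config, as.list(cfg_args$sim))
  cfg <- do.call(pipeline_config, cfg_args)
  cfg$sim$seed <- cfg$seed
  if (stage != "run") cfg$stages <- stage
  if (!is.null(opt$boot)) {
    cfg$tree$n_boot <- as.integer(opt$boot)
    cfg$hybridtest$n_boot <- as.integer(opt$boot)
  }
  if (!is.null(opt$min_delta))
    cfg$hybridtest$min_delta <- as.numeric(opt$min_delta)
  if (!is.null(opt$rell)) cfg$topotest$n_rell <- as.integer(opt$rell)
  run_pipeline(cfg)
  invisible(0L)
}
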