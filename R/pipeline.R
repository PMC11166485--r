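# End-to-end analysis pipeline ---------------------------------------------

PIPELINE_RESPONSES <- c("diversity", "total_tgcn", "median_eps",
                        "gc_ending_diversity", "at_ending_diversity")

#' Build or validate a pipeline configuration
#'
#' Exactly one of `inputs` (paths to real data) and `synthetic` (a
#' [simulation_config()] or a list of its arguments) must be supplied.
#'
#' @param inputs list with elements `tgcn`, `metadata`, `tree` (file
#'   paths).
#' @param synthetic a `sim_config` or argument list for
#'   [simulation_config()].
#' @param responses responses to regress (subset of diversity, total_tgcn,
#'   median_eps, gc_ending_diversity, at_ending_diversity).
#' @param params a [model_params()] object.
#' @param rules a [wobble_rules()] object.
#' @param out_dir output directory, or NULL to skip writing files.
#' @param seed integer seed recorded in the report (and used for the
#'   synthetic block when it carries no seed of its own).
#' @param figures write histogram figures (PDF) alongside the tables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            responses = PIPELINE_RESPONSES,
                            params = model_params(),
                            rules = wobble_rules(),
                            out_dir = NULL, seed = 1L, figures = FALSE) {
  if (is.null(inputs) == is.null(synthetic)) {
    stop("provide exactly one of 'inputs' and 'synthetic'", call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("tgcn", "metadata", "tree")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name tgcn, metadata and tree paths", call. = FALSE)
    }
    missing <- !vapply(inputs[need], file.exists, logical(1))
    if (any(missing)) {
      stop("input file(s) not found: ",
           paste(unlist(inputs[need][missing]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(synthetic) && !inherits(synthetic, "sim_config")) {
    if (is.null(synthetic$seed)) synthetic$seed <- seed
    synthetic <- do.call(simulation_config, synthetic)
  }
  responses <- match.arg(responses, PIPELINE_RESPONSES, several.ok = TRUE)
  structure(list(inputs = inputs, synthetic = synthetic,
                 responses = responses, params = params,
                 rules = rules, out_dir = out_dir, seed = as.integer(seed),
                 figures = isTRUE(figures)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]: an `inputs` or
#' `synthetic` block, plus optional `responses`, `model_params` (argument
#' list for [model_params()]), `wobble_rules` (argument list or `pairs`
#' records for [wobble_rules()]), `out_dir`, `seed`, `figures`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$inputs)) args$inputs <- cfg$inputs
  if (!is.null(cfg$synthetic)) args$synthetic <- cfg$synthetic
  if (!is.null(cfg$responses)) args$responses <- unlist(cfg$responses)
  if (!is.null(cfg$model_params)) {
    args$params <- do.call(model_params, cfg$model_params)
  }
  if (!is.null(cfg$wobble_rules)) {
    args$rules <- do.call(wobble_rules, cfg$wobble_rules)
  }
  for (k in c("out_dir", "seed", "figures")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(pipeline_config, args)
}

.pipeline_load <- function(config) {
  if (!is.null(config$synthetic)) {
    ds <- simulate_dataset(config$synthetic)
    list(tgcn = ds$tgcn, metadata = ds$metadata, tree = ds$tree,
         truth = ds$truth)
  } else {
    list(tgcn = load_tgcn_table(config$inputs$tgcn),
         metadata = load_species_metadata(config$inputs$metadata),
         tree = ape::read.tree(config$inputs$tree),
         truth = NULL)
  }
}

#' Run the full comparative analysis
#'
#' Stages, in order: load or generate inputs; compute pool summaries
#' (total tGCN, anticodon diversity and its GC-/AT-ending split); compute
#' per-species missense-error profiles from the elongation model; join
#' summaries with metadata and prune the tree to the shared species; fit
#' the temperature-class + GC regression for each configured response
#' under both BM and OU covariance and select by AIC; compute phylogenetic
#' independent contrasts and their Spearman correlations for the headline
#' trait pairs; assemble (and optionally write) the report. Each stage
#' logs row counts via `message()`.
#'
#' @param config a `pipeline_config`, or a YAML path.
#' @return list of class `analysis_report`: `pool_summary`,
#'   `error_profiles`, `regressions` (per response: `bm`, `ou`, `chosen`),
#'   `regression_table` (flat per-term table), `pic_spearman`, `histograms`,
#'   `dropped_species`, `seed`, `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dat <- .pipeline_load(config)
  message("loaded ", nrow(dat$tgcn), " species x ", ncol(dat$tgcn),
          " anticodons; tree with ", length(dat$tree$tip.label), " tips")

  pool <- pool_summary(dat$tgcn)
  nbhd <- build_codon_neighborhoods(rules = config$rules)
  errs <- error_profiles(dat$tgcn, nbhd, config$params)
  traits <- merge(merge(pool, errs[, c("species", "median_eps")],
                        by = "species"),
                  dat$metadata, by = "species")

  shared <- intersect(traits$species, dat$tree$tip.label)
  if (length(shared) < 3) {
    stop("fewer than 3 species shared between tree and tables; aborting",
         call. = FALSE)
  }
  dropped <- setdiff(union(traits$species, dat$tree$tip.label), shared)
  if (length(dropped)) {
    message("dropped ", length(dropped),
            " species absent from tree or tables")
  }
  tree <- ape::keep.tip(dat$tree, shared)
  traits <- traits[match(tree$tip.label, traits$species), ]
  message("analyzing ", nrow(traits), " species")

  regressions <- lapply(config$responses, function(resp) {
    bm <- fit_phylo_lm(resp, traits, tree, model = "BM")
    ou <- fit_phylo_lm(resp, traits, tree, model = "OU")
    chosen <- select_model(list(BM = bm, OU = ou))
    message("regression ", resp, ": chose ", chosen$model,
            " (delta AIC = ", signif(chosen$delta_AIC, 4), ")")
    list(bm = bm, ou = ou, chosen = chosen)
  })
  names(regressions) <- config$responses

  reg_table <- do.call(rbind, lapply(config$responses, function(resp) {
    ch <- regressions[[resp]]$chosen
    data.frame(response = resp, model = ch$model, ch$coefficients,
               sigma2 = unname(ch$sigma2), alpha = unname(ch$alpha),
               AIC = ch$AIC, delta_AIC = ch$delta_AIC, adj_r2 = ch$adj_r2,
               n = ch$n, row.names = NULL, check.names = FALSE)
  }))

  pic_pairs <- list(c("diversity", "gc"),
                    c("diversity", "median_eps"),
                    c("median_eps", "gc"),
                    c("gc_ending_diversity", "gc"),
                    c("at_ending_diversity", "gc"))
  pics <- lapply(names(traits)[-1], function(v) {
    x <- traits[[v]]
    if (!is.numeric(x)) return(NULL)
    names(x) <- traits$species
    pic_contrasts(tree, x)
  })
  names(pics) <- names(traits)[-1]
  pic_spearman <- do.call(rbind, lapply(pic_pairs, function(pr) {
    s <- spearman_pic(pics[[pr[1]]], pics[[pr[2]]])
    data.frame(trait1 = pr[1], trait2 = pr[2], rho = s$rho,
               p_value = s$p_value)
  }))

  histograms <- list(
    total_tgcn = .hist_table(pool$total_tgcn, width = 5),
    diversity = .hist_table(pool$diversity, width = 1)
  )

  report <- structure(list(pool_summary = pool, error_profiles = errs,
                           traits = traits, regressions = regressions,
                           regression_table = reg_table,
                           pic_spearman = pic_spearman,
                           histograms = histograms,
                           dropped_species = dropped,
                           seed = config$seed, truth = dat$truth),
                      class = "analysis_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir, figures = config$figures)
  }
  report
}

.hist_table <- function(x, width) {
  breaks <- seq(floor(min(x) / width) * width,
                ceiling(max(x) / width) * width + width, by = width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_start = h$breaks[-length(h$breaks)],
             bin_end = h$breaks[-1], count = h$counts)
}

#' Write an analysis report to disk
#'
#' Writes `pool_summary.tsv`, `error_profiles.tsv`, `regressions.tsv`,
#' `regressions.json` (per-response model choice, AIC, alpha, sigma2,
#' adjusted R2 and coefficients), `pic_spearman.tsv` and histogram tables;
#' with `figures = TRUE`, also PDF histograms of total pool size and
#' diversity.
#'
#' @param report an `analysis_report`.
#' @param dir output directory.
#' @param figures also draw PDF histograms.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, figures = FALSE) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$pool_summary, "pool_summary.tsv")
  wt(report$error_profiles, "error_profiles.tsv")
  wt(report$regression_table, "regressions.tsv")
  wt(report$pic_spearman, "pic_spearman.tsv")
  wt(report$histograms$total_tgcn, "hist_total_tgcn.tsv")
  wt(report$histograms$diversity, "hist_diversity.tsv")
  js <- lapply(report$regressions, function(r) {
    ch <- r$chosen
    list(model = ch$model, AIC = ch$AIC, delta_AIC = ch$delta_AIC,
         alpha = ch$alpha, sigma2 = ch$sigma2, adj_r2 = ch$adj_r2,
         n = ch$n,
         coefficients = ch$coefficients)
  })
  jsonlite::write_json(list(seed = report$seed, regressions = js),
                       file.path(dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (isTRUE(figures)) {
    grDevices::pdf(file.path(dir, "histograms.pdf"), width = 8, height = 4)
    graphics::par(mfrow = c(1, 2))
    graphics::hist(report$pool_summary$total_tgcn, breaks = 20,
                   main = "Total tRNA genes", xlab = "total tGCN")
    graphics::hist(report$pool_summary$diversity, breaks = 20,
                   main = "Anticodon diversity", xlab = "diversity")
    grDevices::dev.off()
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report:", nrow(x$traits), "species,",
      length(x$regressions), "regressions\n")
  cat("\nChosen models:\n")
  tab <- unique(x$regression_table[, c("response", "model", "AIC",
                                       "delta_AIC", "adj_r2")])
  print(tab, row.names = FALSE, digits = 4)
  cat("\nPIC Spearman correlations:\n")
  print(x$pic_spearman, row.names = FALSE, digits = 4)
  invisible(x)
}
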