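#' Pipeline configuration
#'
#' Bundles the inputs and stage parameters for [run_pipeline()]. Exactly one
#' of `sim_config` (a [bn_config()]/[cline_config()]) or `ped`/`map` paths
#' must be supplied.
#'
#' @param sim_config simulation configuration, or `NULL` to read files.
#' @param ped,map,metadata input file paths (metadata optional with a
#'   simulation, mandatory for the geographic stage on file input).
#' @param qc a [qc_params()].
#' @param pca_k number of principal components.
#' @param admixture_K vector of component counts to fit.
#' @param fst_grouping metadata column defining the F_ST groups.
#' @param n_boot bootstrap replicates for pairwise F_ST.
#' @param geo_axis coordinate axis for the PC correlation.
#' @param seed global seed fanned out to every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim_config = NULL, ped = NULL, map = NULL,
                            metadata = NULL, qc = qc_params(), pca_k = 10,
                            admixture_K = 2, fst_grouping = "region",
                            n_boot = 200, geo_axis = "latitude", seed = 1,
                            out_dir = tempfile("finestruct_")) {
  problems <- character(0)
  if (is.null(sim_config)) {
    if (is.null(ped) || is.null(map)) {
      problems <- c(problems, "either sim_config or both ped and map are required")
    }
    for (p in c(ped = ped, map = map, metadata = metadata)) {
      if (!is.null(p) && !file.exists(p)) {
        problems <- c(problems, paste0("file not found: ", p))
      }
    }
  } else if (!inherits(sim_config, "bn_config")) {
    problems <- c(problems, "sim_config must be a bn_config/cline_config")
  }
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(list(sim_config = sim_config, ped = ped, map = map,
                 metadata = metadata, qc = qc, pca_k = pca_k,
                 admixture_K = admixture_K, fst_grouping = fst_grouping,
                 n_boot = n_boot, geo_axis = geo_axis, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages in order: data (simulate or ingest), QC, PCA, admixture, F_ST,
#' geographic correlation. Each stage writes plain-text outputs under
#' `out_dir` and appends to a manifest recording inputs, parameters, seeds
#' and resulting dimensions; a stage failure halts with the partial manifest
#' written.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, started = format(Sys.time()), stages = list())
  results <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(...), list(stage = stage))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- data ------------------------------------------------------------------
  if (!is.null(cfg$sim_config)) {
    sim_cfg <- cfg$sim_config
    sim_cfg$seed <- derive_seed(cfg$seed, 1L)
    sim <- if (inherits(sim_cfg, "cline_config")) simulate_cline(sim_cfg)
      else simulate_balding_nichols(sim_cfg)
    ds <- sim$dataset
    md <- sim$metadata
    if (is.null(md)) {
      md <- data.frame(sample_id = ds$samples, state = sim$pop_labels,
                       region = sim$pop_labels,
                       latitude = NA_real_, stringsAsFactors = FALSE)
    }
    note("data", source = "simulation", samples = n_samples(ds),
         snps = n_variants(ds))
  } else {
    ds <- read_ped_map(cfg$ped, cfg$map)
    md <- if (!is.null(cfg$metadata)) read_metadata(cfg$metadata) else NULL
    note("data", source = cfg$ped, samples = n_samples(ds),
         snps = n_variants(ds))
  }
  results$dataset <- ds
  results$metadata <- md

  # -- qc --------------------------------------------------------------------
  qc_res <- run_qc(ds, cfg$qc)
  ds <- qc_res$dataset
  utils::write.table(qc_res$report, file.path(cfg$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ped_map(ds, file.path(cfg$out_dir, "post_qc.ped"),
                file.path(cfg$out_dir, "post_qc.map"))
  note("qc", retained_samples = n_samples(ds), retained_snps = n_variants(ds))
  results$qc <- qc_res
  if (!is.null(md)) md <- md[md$sample_id %in% ds$samples, , drop = FALSE]

  # -- pca -------------------------------------------------------------------
  k <- min(cfg$pca_k, n_samples(ds) - 1, n_variants(ds))
  pca <- compute_pca(ds, k)
  ev_tab <- data.frame(sample_id = rownames(pca$scores), pca$scores)
  utils::write.table(ev_tab, file.path(cfg$out_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format(pca$eigenvalues, digits = 10),
             file.path(cfg$out_dir, "pca_eigenvalues.txt"))
  note("pca", k = k)
  results$pca <- pca

  # -- admixture -------------------------------------------------------------
  results$admixture <- list()
  for (K in cfg$admixture_K) {
    fit <- fit_admixture(ds, K, seed = derive_seed(cfg$seed, 100L + K))
    q_tab <- data.frame(sample_id = rownames(fit$Q), fit$Q)
    utils::write.table(q_tab,
                       file.path(cfg$out_dir, sprintf("admixture_Q_K%d.tsv", K)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$admixture[[as.character(K)]] <- fit
  }
  note("admixture", K = cfg$admixture_K)

  # -- fst -------------------------------------------------------------------
  fst_res <- NULL
  if (!is.null(md) && cfg$fst_grouping %in% names(md)) {
    grouping <- stats::setNames(md[[cfg$fst_grouping]], md$sample_id)
    if (length(unique(grouping)) >= 2) {
      fst_res <- pairwise_fst_matrix(ds, grouping, n_boot = cfg$n_boot,
                                     seed = derive_seed(cfg$seed, 200L))
      utils::write.table(fst_res$point,
                         file.path(cfg$out_dir, "fst_pairwise.tsv"),
                         sep = "\t", quote = FALSE)
      groups <- unique(unname(grouping))
      tab <- snp_fst_table(ds, names(grouping)[grouping == groups[1]],
                           names(grouping)[grouping == groups[2]])
      utils::write.table(tab, file.path(cfg$out_dir, "fst_per_snp.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$fst_per_snp <- tab
    }
  }
  results$fst <- fst_res
  note("fst", computed = !is.null(fst_res))

  # -- geo -------------------------------------------------------------------
  geo_res <- NULL
  if (!is.null(md) && cfg$geo_axis %in% names(md) &&
      !anyNA(md[[cfg$geo_axis]]) &&
      length(unique(md$state)) >= 3) {
    geo_res <- pc_vs_latitude(pca, md, axis = cfg$geo_axis)
    pts <- attr(geo_res, "points")
    utils::write.table(pts, file.path(cfg$out_dir, "pc1_vs_coordinate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results$geo <- geo_res
  note("geo", computed = !is.null(geo_res))

  results$manifest <- manifest
  invisible(results)
}

#' Summarize pipeline outputs as a text report
#'
#' Tabulates QC accounting, the pairwise F_ST matrix, the most differentiated
#' SNPs, the PC-geography correlation and per-region admixture means;
#' stages that did not run are marked absent.
#'
#' @param results the list returned by [run_pipeline()].
#' @param top_fraction fraction for the differentiated-SNP table.
#' @return character vector of report lines (also usable with `writeLines`).
#' @export
make_report <- function(results, top_fraction = 0.01) {
  out <- c("== finestruct pipeline report ==", "")
  out <- c(out, "-- QC --",
           utils::capture.output(print(results$qc$report, row.names = FALSE)), "")
  out <- c(out, "-- pairwise F_ST --")
  if (is.null(results$fst)) {
    out <- c(out, "(absent: no grouping available)", "")
  } else {
    out <- c(out, utils::capture.output(print(signif(results$fst$point, 4))), "")
  }
  out <- c(out, "-- top differentiated SNPs --")
  if (is.null(results$fst_per_snp)) {
    out <- c(out, "(absent)", "")
  } else {
    top <- top_differentiated(results$fst_per_snp, top_fraction = top_fraction)
    cols <- c("snp_id", "chrom", "pos", "theta", "p1", "p2")
    out <- c(out, utils::capture.output(
      print(utils::head(top[, cols], 10), row.names = FALSE)), "")
  }
  out <- c(out, "-- PC1 vs geography --")
  if (is.null(results$geo)) {
    out <- c(out, "(absent: no coordinates available)", "")
  } else {
    out <- c(out, utils::capture.output(print(results$geo)), "")
  }
  out <- c(out, "-- admixture --")
  if (length(results$admixture) == 0) {
    out <- c(out, "(absent)")
  } else {
    for (K in names(results$admixture)) {
      fit <- results$admixture[[K]]
      md <- results$metadata
      if (!is.null(md) && "region" %in% names(md)) {
        idx <- match(rownames(fit$Q), md$sample_id)
        reg <- md$region[idx]
        means <- stats::aggregate(fit$Q, by = list(region = reg), FUN = mean)
        out <- c(out, paste0("K = ", K, " mean ancestry by region:"),
                 utils::capture.output(print(means, row.names = FALSE)))
      } else {
        out <- c(out, paste0("K = ", K, ": fitted (no region metadata)"))
      }
    }
  }
  out
}
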