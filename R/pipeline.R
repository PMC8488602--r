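#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. With `model_dir = NULL` the
#' bundled toy model and synthetic transcriptome stand in for external inputs
#' (the self-contained fixture mode).
#'
#' @param outdir output directory for stage artifacts.
#' @param model_dir toy-table model directory, or NULL for the bundled model.
#' @param rpkm_paths optional character vector of 2 RPKM table paths
#'   (CSV/XLSX); NULL generates the synthetic transcriptome.
#' @param bounds_path optional condition-bounds CSV; NULL uses the packaged
#'   table.
#' @param objective_pair `"atpm"`, `"psi"` or `"psii"` -- the secondary
#'   objective paired with biomass.
#' @param gamma expression mapping strength (> 0).
#' @param flux_threshold zeroing cutoff for fluxes and flux fold changes.
#' @param lasso_cutoff MPC retention threshold.
#' @param k_range silhouette-scan cluster counts.
#' @param seed RNG seed governing every stochastic step.
#' @param include_control_transcripts include the all-ones control row in the
#'   transcript-only PCA matrix (default FALSE, matching the 23-row reference
#'   layout; flux matrices always carry the control as row 24).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, model_dir = NULL, rpkm_paths = NULL,
                            bounds_path = NULL,
                            objective_pair = c("atpm", "psi", "psii"),
                            gamma = 1, flux_threshold = 1e-4,
                            lasso_cutoff = 0.01, k_range = 2:8, seed = 1,
                            include_control_transcripts = FALSE) {
  objective_pair <- match.arg(objective_pair)
  stopifnot(gamma > 0, flux_threshold >= 0, lasso_cutoff >= 0)
  structure(list(outdir = outdir, model_dir = model_dir,
                 rpkm_paths = rpkm_paths, bounds_path = bounds_path,
                 objective_pair = objective_pair, gamma = gamma,
                 flux_threshold = flux_threshold, lasso_cutoff = lasso_cutoff,
                 k_range = k_range, seed = seed,
                 include_control_transcripts = include_control_transcripts),
            class = "pipeline_config")
}

objective_pair_names <- function(which) {
  switch(which,
         atpm = c("Biomass", "ATP maintenance requirment"),
         psi  = c("Biomass", "Photosystem I Reaction (cytochrome c6)"),
         psii = c("Biomass", "photosystem II reaction"))
}

pipeline_stage_order <- c("prepare", "fba", "multiomic", "pca", "pathway-pca",
                          "cluster", "lasso", "corr", "pathway-corr")

#' Run the analysis pipeline
#'
#' Orchestrates the stages of the protocol: model/transcriptome preparation,
#' condition-specific regularized bi-level FBA, multi-omic fusion, PCA and
#' pathway-level PCA, silhouette-guided k-means with nonmetric MDS, LASSO
#' with MPC filtering, and Pearson correlation with pathway binning. Each
#' stage writes CSV artifacts named after the reference protocol's inventory
#' (e.g. `all_atp_flux.csv`, `all_ATPTF.csv`, `contrib_all_atp_flux.csv`) and
#' a `manifest.json` records parameters, seed and content hashes so a rerun
#' with the same configuration reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of
#'   `c("prepare","fba","multiomic","pca","pathway-pca","cluster","lasso",`
#'   `"corr","pathway-corr")`; stages run in canonical order and later stages
#'   require their prerequisites within the same call.
#' @param verbose print per-condition objective values during FBA.
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, stages = pipeline_stage_order, verbose = FALSE) {
  stages <- match.arg(stages, pipeline_stage_order, several.ok = TRUE)
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  need <- function(what, from) {
    if (!exists(what, st))
      stop("stage dependency missing: run stage '", from, "' first")
    get(what, st)
  }
  out_files <- character()
  emit <- function(obj, file, row_names = TRUE) {
    path <- file.path(config$outdir, file)
    utils::write.csv(obj, path, row.names = row_names)
    out_files <<- c(out_files, path)
  }
  tag <- switch(config$objective_pair, atpm = "atp", psi = "p1", psii = "p2")

  for (stage in stages) {
    if (stage == "prepare") {
      model <- if (is.null(config$model_dir)) make_toy_model()
      else {
        m <- read_model(config$model_dir, "toy-table")
        split_multi_subsystems(normalize_subsystem_names(m))
      }
      pair <- objective_pair_names(config$objective_pair)
      model <- set_objective_pair(model, pair[1], pair[2])
      assign("model", model, st)
      if (is.null(config$rpkm_paths)) {
        tx <- make_synthetic_transcriptome(model, seed = config$seed)
        d1 <- tx$dataset1; d2 <- tx$dataset2
      } else {
        d1 <- read_rpkm_table(config$rpkm_paths[1])
        d2 <- read_rpkm_table(config$rpkm_paths[2])
      }
      to_fc <- function(df) {
        num <- df[vapply(df, is.numeric, TRUE)]
        m <- as.matrix(num)
        rownames(m) <- df$gene_id
        ctrl <- grep("^control", colnames(m))
        rpkm_to_foldchange(m, ctrl, setdiff(seq_len(ncol(m)), ctrl))
      }
      transcripts <- t(cbind(to_fc(d1), to_fc(d2)))  # conditions x genes
      assign("transcripts", transcripts, st)
      emit(transcripts, "transcriptsnew.csv")
      specs <- builtin_condition_bounds(config$bounds_path)
      assign("specs", specs, st)
    } else if (stage == "fba") {
      model <- need("model", "prepare")
      transcripts <- need("transcripts", "prepare")
      specs <- need("specs", "prepare")
      profiles <- lapply(rownames(transcripts),
                         function(cn) transcripts[cn, ])
      names(profiles) <- rownames(transcripts)
      flux <- run_all_conditions(model, profiles, specs,
                                 gamma = config$gamma,
                                 flux_threshold = config$flux_threshold,
                                 verbose = verbose)
      assign("flux", flux, st)
      emit(flux, sprintf("all_%s_flux.csv", tag))
      emit(attr(flux, "objectives"), sprintf("objectives_%s.csv", tag))
    } else if (stage == "multiomic") {
      flux <- need("flux", "fba")
      transcripts <- need("transcripts", "prepare")
      flux_fc <- flux_foldchange(flux, control_row = nrow(flux),
                                 threshold = config$flux_threshold)
      fused <- build_multiomic(transcripts, flux_fc)
      assign("fused", fused, st)
      emit(fused, sprintf("all_%sTF.csv", toupper(tag)))
    } else if (stage == "pca") {
      transcripts <- need("transcripts", "prepare")
      flux <- need("flux", "fba")
      fused <- need("fused", "multiomic")
      tx_pca_input <- if (config$include_control_transcripts)
        rbind(transcripts, `Standard control` = rep(1, ncol(transcripts)))
      else transcripts
      fits <- list(transcripts = pca_fit(tx_pca_input),
                   flux = suppressWarnings(pca_fit(flux)),
                   fused = suppressWarnings(pca_fit(fused)))
      assign("pca", fits, st)
      emit(fits$transcripts$var_contrib, "contrib_transcripts.csv")
      emit(fits$flux$var_contrib, sprintf("contrib_all_%s_flux.csv", tag))
      emit(fits$fused$var_contrib, sprintf("contrib_all_%sTF.csv", toupper(tag)))
      emit(fits$flux$ind_coord, sprintf("ind_coord_all_%s_flux.csv", tag))
    } else if (stage == "pathway-pca") {
      model <- need("model", "prepare")
      fits <- need("pca", "pca")
      index <- build_subsystem_index(model)
      agg <- pathway_pca_aggregate(fits$flux$var_contrib, index,
                                   rxns = model$rxns)
      assign("pathway_pca", agg, st)
      emit(agg, sprintf("pathway_contrib_%s.csv", toupper(tag)), row_names = FALSE)
    } else if (stage == "cluster") {
      transcripts <- need("transcripts", "prepare")
      genes_vs_profiles <- t(transcripts)  # features x conditions
      k_max <- min(max(config$k_range), nrow(genes_vs_profiles) - 1)
      scan <- silhouette_scan(genes_vs_profiles,
                              k_range = config$k_range[config$k_range <= k_max],
                              seed = config$seed)
      km <- kmeans_cluster(genes_vs_profiles, scan$best_k,
                           method = "cityblock", seed = config$seed)
      d <- correlation_distance(genes_vs_profiles)
      emb <- nonmetric_mds(d, dims = 2, seed = config$seed)
      assign("cluster", list(scan = scan, km = km, mds = emb), st)
      emit(data.frame(k = scan$k, mean_silhouette = scan$mean_silhouette),
           "silh_transcripts.csv", row_names = FALSE)
      emit(data.frame(feature = rownames(genes_vs_profiles),
                      cluster = km$labels,
                      mds1 = emb$points[, 1], mds2 = emb$points[, 2]),
           "kmeans_transcripts.csv", row_names = FALSE)
    } else if (stage == "lasso" || stage == "corr") {
      transcripts <- need("transcripts", "prepare")
      flux <- need("flux", "fba")
      fused <- need("fused", "multiomic")
      gr <- builtin_growth_rates()
      y <- stats::setNames(gr$growth_rate, gr$condition)
      avail <- gr$condition[gr$condition != "Standard control"]
      subsets <- list(
        transcripts = subset_growth_conditions(transcripts, avail, y),
        flux = subset_growth_conditions(flux, avail, y),
        fused = subset_growth_conditions(fused, avail, y))
      assign("subsets", subsets, st)
      if (stage == "lasso") {
        las <- lapply(subsets, function(s)
          lasso_mpc(s$x, s$y, cutoff = config$lasso_cutoff))
        assign("lasso", las, st)
        emit(las$transcripts$retained, "B_transcripts_nonzero.csv", row_names = FALSE)
        emit(las$flux$retained, sprintf("B_%s_nonzero.csv", toupper(tag)),
             row_names = FALSE)
        emit(las$fused$retained, sprintf("B_%sTF_nonzero.csv", toupper(tag)),
             row_names = FALSE)
      } else {
        cors <- lapply(subsets, function(s) pearson_with_ci(s$x, s$y))
        assign("corr", cors, st)
        emit(cors$transcripts, "corr_transcript_table.csv", row_names = FALSE)
        emit(cors$flux, sprintf("corr_%s_table.csv", toupper(tag)), row_names = FALSE)
      }
    } else if (stage == "pathway-corr") {
      model <- need("model", "prepare")
      cors <- need("corr", "corr")
      index <- build_subsystem_index(model)
      r <- cors$flux$r[match(model$rxns, cors$flux$feature)]
      pc <- pathway_correlation(r, index)
      assign("pathway_corr", pc, st)
      emit(pc, sprintf("all_corr_%s.csv", toupper(tag)), row_names = FALSE)
      emit(pc[c("subsystem", "mean_abs_r")],
           sprintf("%s_PCC_mean.csv", toupper(tag)), row_names = FALSE)
    }
  }

  manifest <- list(
    parameters = config[setdiff(names(config), "outdir")],
    stages = stages,
    files = as.list(tools::md5sum(sort(unique(out_files)))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results <- as.list(st)
  results$manifest <- manifest
  invisible(results)
}
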