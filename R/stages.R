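# Stage-wise entry points: each stage is runnable standalone from cached
# artifacts under a working directory, so clustering can be re-run without
# retraining. Artifact names are fixed: views.tsv, features.rds,
# checkpoint.rds, embeddings.tsv, bins/.

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "'; run the `", produced_by,
         "` stage first", call. = FALSE)
  }
  path
}

#' Build a synthetic fixture community on disk
#'
#' @param dir Output directory.
#' @param preset Preset name for [community_preset()].
#' @param seed Integer seed.
#' @return Paths of the written files.
#' @export
stage_fixture <- function(dir, preset = "easy", seed = 1L) {
  comm <- simulate_community(community_preset(preset, seed = seed))
  write_community(comm, dir)
}

#' Compute and cache features
#'
#' @param cfg A [run_config()]; artifacts go to `cfg$outdir`.
#' @return Path of the cached feature block.
#' @export
stage_features <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  contigs <- read_fasta(cfg$contigs, cfg$min_contig_len)
  tracks <- lapply(cfg$depth_paths, read_depth, contigs = contigs)
  views <- augment_contigs(contigs, n_aug = cfg$n_aug,
                           min_frag_len = cfg$min_contig_len,
                           seed = derive_seed(cfg$seed, "augment"))
  write_view_table(views, file.path(cfg$outdir, "views.tsv"))
  feats <- build_features(views, tracks)
  saveRDS(list(features = feats, n50 = contigs$n50,
               lengths = contigs$lengths),
          file.path(cfg$outdir, "features.rds"))
  file.path(cfg$outdir, "features.rds")
}

#' Train from cached features
#'
#' @param cfg A [run_config()].
#' @return Path of the checkpoint.
#' @export
stage_train <- function(cfg) {
  fr <- readRDS(require_artifact(file.path(cfg$outdir, "features.rds"),
                                 "features"))
  tcfg <- cfg$train_cfg
  tcfg$seed <- derive_seed(cfg$seed, "train")
  model <- train_encoder(fr$features, cfg$encoder_cfg, tcfg,
                         assembly_n50 = fr$n50)
  utils::write.table(
    data.frame(epoch = seq_along(model$loss_history),
               loss = model$loss_history),
    file.path(cfg$outdir, "loss_history.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  save_checkpoint(model, file.path(cfg$outdir, "checkpoint.rds"))
}

#' Embed original contigs from a checkpoint
#'
#' @param cfg A [run_config()].
#' @return Path of the embeddings table.
#' @export
stage_embed <- function(cfg) {
  model <- load_checkpoint(require_artifact(file.path(cfg$outdir, "checkpoint.rds"),
                                            "train"))
  fr <- readRDS(require_artifact(file.path(cfg$outdir, "features.rds"),
                                 "features"))
  Z <- embed_contigs(model, fr$features)
  out <- file.path(cfg$outdir, "embeddings.tsv")
  utils::write.table(data.frame(contig_id = rownames(Z), Z),
                     out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Cluster cached embeddings, select and write final bins
#'
#' @param cfg A [run_config()].
#' @return The final `bin_assignment`.
#' @export
stage_cluster <- function(cfg) {
  fr <- readRDS(require_artifact(file.path(cfg$outdir, "features.rds"),
                                 "features"))
  ztab <- utils::read.table(require_artifact(file.path(cfg$outdir, "embeddings.tsv"),
                                             "embed"),
                            header = TRUE, sep = "\t")
  Z <- as.matrix(ztab[, -1, drop = FALSE])
  rownames(Z) <- ztab$contig_id
  contigs <- read_fasta(cfg$contigs, cfg$min_contig_len)
  scg <- if (is.null(cfg$scg)) {
    scg_table(data.frame(contig_id = character(0), marker_id = character(0)),
              marker_universe = character(0))
  } else read_scg_table(cfg$scg, contigs)
  sweep <- run_sweep_and_select(Z, scg, fr$lengths, grid = cfg$grid,
                                knn_k = cfg$knn_k,
                                seed = derive_seed(cfg$seed, "leiden"))
  utils::write.table(sweep$diagnostics,
                     file.path(cfg$outdir, "sweep_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  final <- filter_small_bins(sweep$assignment, fr$lengths, cfg$min_bin_bp)
  write_bins(final, contigs, file.path(cfg$outdir, "bins"))
}
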